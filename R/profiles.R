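#' Construct an antero-posterior expression profile
#'
#' @param x Positions in %EL, strictly increasing.
#' @param intensity Intensities in arbitrary units (same length as `x`).
#' @param embryo_id,gene,time_class,genotype Metadata labels.
#' @return An object of class `ap_profile`.
#' @export
ap_profile <- function(x, intensity, embryo_id = NA_character_,
                       gene = NA_character_, time_class = NA_character_,
                       genotype = NA_character_) {
  if (length(x) != length(intensity))
    stop("'x' and 'intensity' must have the same length")
  if (is.unsorted(x, strictly = TRUE))
    stop("'x' must be strictly increasing")
  structure(list(embryo_id = embryo_id, gene = gene,
                 time_class = time_class, genotype = genotype,
                 x = as.numeric(x), intensity = as.numeric(intensity)),
            class = "ap_profile")
}

#' @export
print.ap_profile <- function(x, ...) {
  cat("ap_profile ", x$embryo_id, " / ", x$gene, " (", x$time_class, "): ",
      length(x$x), " samples on [", round(min(x$x), 2), ", ",
      round(max(x$x), 2), "] %EL\n", sep = "")
  invisible(x)
}

#' Extract the lateral strip of an embryo record
#'
#' Keeps the nuclei within a band around the lateral midline (dorso-
#' ventral height 50%) covering `height_fraction` of the embryo's
#' height, and returns their positions and intensities as a 1-D profile
#' sorted by A--P position. Ties in `x` are broken by a stable
#' infinitesimal jitter so the profile's positions stay strictly
#' increasing.
#'
#' @param record An `embryo_record`.
#' @param gene Gene channel to extract.
#' @param height_fraction Fraction of embryo height retained (default
#'   0.10, i.e. nuclei with |y - 50| <= 5).
#' @return An [ap_profile()].
#' @export
extract_strip <- function(record, gene, height_fraction = 0.10) {
  stopifnot(inherits(record, "embryo_record"))
  if (height_fraction <= 0 || height_fraction > 1)
    stop("'height_fraction' must be in (0, 1]")
  nuc <- record$nuclei
  if (!gene %in% names(nuc))
    stop("gene '", gene, "' not present in embryo ", record$embryo_id)
  keep <- abs(nuc$y - 50) <= 100 * height_fraction / 2
  if (!any(keep))
    stop("empty strip: no nuclei within ", height_fraction * 100,
         "% of embryo height for embryo ", record$embryo_id)
  ord <- order(nuc$x[keep])
  x <- nuc$x[keep][ord]
  dup <- duplicated(x)
  if (any(dup)) x <- x + cumsum(dup) * 1e-9
  ap_profile(x, nuc[[gene]][keep][ord], embryo_id = record$embryo_id,
             gene = gene, time_class = record$time_class,
             genotype = record$genotype)
}

#' Remove non-specific background staining from a profile
#'
#' Estimates a smooth baseline from the low-intensity envelope of the
#' profile: within windows of 10 %EL the samples at or below the given
#' intensity quantile are taken as baseline points, a polynomial of the
#' given degree is least-squares fitted through them, subtracted, and
#' the result clamped at zero. Adding a constant to all intensities
#' leaves the output unchanged, and re-running on an already corrected
#' profile is a no-op to within one intensity unit.
#'
#' @param profile An [ap_profile()].
#' @param quantile Per-window quantile defining baseline points
#'   (0 < quantile < 0.5, default 0.1).
#' @param poly_degree Baseline polynomial degree, 0, 1 or 2 (default 2).
#' @return The corrected [ap_profile()].
#' @export
remove_background <- function(profile, quantile = 0.1, poly_degree = 2) {
  stopifnot(inherits(profile, "ap_profile"))
  if (quantile <= 0 || quantile >= 0.5)
    stop("'quantile' must be in (0, 0.5)")
  if (!poly_degree %in% 0:2) stop("'poly_degree' must be 0, 1 or 2")
  x <- profile$x; y <- profile$intensity
  win <- pmin(9, floor(x / 10))
  # rank-based selection (lowest ceiling(q*n) samples per window) rather
  # than a value threshold: exactly invariant under constant offsets
  base_idx <- unlist(lapply(split(seq_along(x), win), function(ii) {
    k <- max(1L, ceiling(quantile * length(ii)))
    ii[order(y[ii])[seq_len(k)]]
  }), use.names = FALSE)
  # robust drop of candidates sitting on domain flanks rather than true
  # baseline (e.g. a window fully covered by signal): keeps the fit a
  # no-op on already-corrected profiles
  vals <- y[base_idx]
  keep <- vals <= stats::median(vals) + 4 * stats::mad(vals) + 0.5
  if (sum(keep) >= poly_degree + 1) base_idx <- base_idx[keep]
  if (length(base_idx) < poly_degree + 1)
    stop("degenerate baseline fit: only ", length(base_idx),
         " baseline points for degree ", poly_degree)
  X <- outer(x / 50 - 1, 0:poly_degree, `^`)  # scaled for conditioning
  fit <- stats::lm.fit(X[base_idx, , drop = FALSE], y[base_idx])
  baseline <- as.numeric(X %*% fit$coefficients)
  out <- profile
  out$intensity <- pmax(0, y - baseline)
  out
}

#' Integrate profiles into a 100-bin averaged profile
#'
#' Pools the samples of all profiles, assigns each to the half-open
#' 1-%EL bin `[b, b+1)` containing it, and averages within bins. Bins
#' that receive no sample are filled by linear interpolation from their
#' neighbours (constant extrapolation at the ends).
#'
#' @param profiles List of [ap_profile()] objects with the same gene,
#'   time class and genotype.
#' @return An object of class `integrated_profile` with fields
#'   `genotype`, `gene`, `time_class`, `bins` (100 mean intensities) and
#'   `n_embryos`.
#' @export
integrate_profiles <- function(profiles) {
  if (!length(profiles)) stop("empty input: no profiles to integrate")
  stopifnot(all(vapply(profiles, inherits, logical(1), "ap_profile")))
  meta <- unique(t(vapply(profiles, function(p)
    c(p$gene, p$time_class, p$genotype), character(3))))
  if (nrow(meta) > 1)
    stop("profiles must share one gene, time class and genotype")
  x <- unlist(lapply(profiles, `[[`, "x"))
  y <- unlist(lapply(profiles, `[[`, "intensity"))
  bin <- pmin(99, floor(x))
  sums <- tapply(y, factor(bin, levels = 0:99), mean)
  bins <- as.numeric(sums)
  if (all(is.na(bins))) stop("empty input: no samples in any bin")
  if (anyNA(bins)) {
    filled <- which(!is.na(bins))
    bins <- stats::approx(filled, bins[filled], xout = 1:100, rule = 2)$y
  }
  structure(list(genotype = meta[1, 3], gene = meta[1, 1],
                 time_class = meta[1, 2], bins = bins,
                 n_embryos = length(unique(vapply(profiles, `[[`,
                                                  character(1),
                                                  "embryo_id")))),
            class = "integrated_profile")
}

#' @export
print.integrated_profile <- function(x, ...) {
  cat("integrated_profile ", x$genotype, " / ", x$gene, " (", x$time_class,
      "): 100 bins from ", x$n_embryos, " embryos, max ",
      round(max(x$bins), 1), "\n", sep = "")
  invisible(x)
}

#' Gaussian-filter an integrated profile
#'
#' Discrete Gaussian convolution with reflective boundary handling;
#' `sigma_bins = 0` is the identity.
#'
#' @param profile An `integrated_profile`.
#' @param sigma_bins Kernel standard deviation in bins (default 1).
#' @return The smoothed `integrated_profile`.
#' @export
smooth_gaussian <- function(profile, sigma_bins = 1) {
  stopifnot(inherits(profile, "integrated_profile"))
  if (sigma_bins < 0) stop("'sigma_bins' must be >= 0")
  if (sigma_bins == 0) return(profile)
  r <- max(1L, ceiling(4 * sigma_bins))
  kern <- stats::dnorm(-r:r, sd = sigma_bins)
  kern <- kern / sum(kern)
  v <- profile$bins
  n <- length(v)
  padded <- c(v[r:1], v, v[n:(n - r + 1)])
  sm <- stats::convolve(padded, rev(kern), type = "filter")
  profile$bins <- sm
  profile
}

#' Scale one integrated profile onto another's intensity range
#'
#' Computes the multiplicative factor equating the 95th-percentile bin
#' values of target and reference (reference / target), and applies it
#' to the target. Used to put mutant expression levels on the wild-type
#' intensity scale (or vice versa for genes where the mutant channel is
#' the brighter, more reliable one, such as Hkb).
#'
#' @param target,reference `integrated_profile`s with the same gene and
#'   time class.
#' @param percentile Percentile used for matching (default 0.95).
#' @return List with the scaled `profile` and the `factor` applied.
#' @export
scale_to_reference <- function(target, reference, percentile = 0.95) {
  stopifnot(inherits(target, "integrated_profile"),
            inherits(reference, "integrated_profile"))
  if (!identical(target$gene, reference$gene) ||
      !identical(target$time_class, reference$time_class))
    stop("target and reference must share gene and time class")
  qt <- stats::quantile(target$bins, percentile, names = FALSE)
  if (qt <= 0) stop("degenerate scaling: target ",
                    round(percentile * 100), "th percentile is 0")
  factor <- stats::quantile(reference$bins, percentile, names = FALSE) / qt
  target$bins <- target$bins * factor
  list(profile = target, factor = factor)
}

#' Register a cohort of profiles onto a common frame
#'
#' Estimates, per profile, a bounded affine map of the A--P coordinate
#' `x' = a*x + b` that minimises the mean squared difference between
#' the profile's smoothing-spline evaluation and a reference trace on a
#' common grid. With `reference = "self-mean"` the reference is the
#' binwise mean of the (unregistered) cohort and the fit is iterated
#' twice, re-deriving the reference from the registered profiles after
#' the first pass. Fitted offsets are re-centred so their cohort mean is
#' zero: registration corrects egg-length and mounting differences
#' without moving the cohort as a whole.
#'
#' @param profiles List of [ap_profile()]s (same gene and time class).
#' @param reference An `integrated_profile` to align to, or
#'   `"self-mean"` (default).
#' @param a_bounds Length-2 bounds on the scale `a` (default 0.9--1.1).
#' @param b_bound Bound on |offset| in %EL (default 5).
#' @param smoothing Spline smoothing used for profile evaluation.
#' @return List with `profiles` (registered) and `maps`, a data frame
#'   (embryo_id, a, b, residual, registered); profiles whose fit fails
#'   pass through unregistered with `registered = FALSE`.
#' @export
register_profiles <- function(profiles, reference = "self-mean",
                              a_bounds = c(0.9, 1.1), b_bound = 5,
                              smoothing = 0.5) {
  if (length(profiles) < 2) stop("need at least 2 profiles to register")
  grid <- seq(1, 99, by = 0.5)
  splines_ <- lapply(profiles, fit_quadratic_spline, smoothing = smoothing)
  ranges <- lapply(profiles, function(p) range(p$x))
  iterations <- if (identical(reference, "self-mean")) 2L else 1L
  ref_vals <- if (identical(reference, "self-mean"))
    stats::approx(seq(0.5, 99.5, 1), integrate_profiles(profiles)$bins,
                  xout = grid, rule = 2)$y
  else predict(fit_quadratic_spline(reference, smoothing = 0), grid)

  # Deterministic two-stage grid search: coarse sweep over the bounded
  # (a, b) box, then local refinement around the coarse optimum. The
  # profile is pre-evaluated once on a fine grid so each candidate map
  # costs one linear interpolation.
  fit_one <- function(spl, rng) {
    xs <- seq(rng[1], rng[2], by = 0.25)
    vals <- predict(spl, xs)
    obj <- function(a, b) {
      src <- (grid - b) / a
      v <- stats::approx(xs, vals, xout = src, rule = 1)$y
      ok <- !is.na(v)
      if (sum(ok) < 20) return(Inf)
      mean((v[ok] - ref_vals[ok])^2)
    }
    best <- list(a = 1, b = 0, value = obj(1, 0))
    sweep <- function(avals, bvals) {
      for (a in avals) for (b in bvals) {
        v <- obj(a, b)
        if (is.finite(v) && v < best$value) best <<- list(a = a, b = b,
                                                          value = v)
      }
    }
    sweep(seq(a_bounds[1], a_bounds[2], length.out = 9),
          seq(-b_bound, b_bound, by = 0.2))
    sweep(pmin(a_bounds[2], pmax(a_bounds[1],
                                 best$a + seq(-0.03, 0.03, by = 0.005))),
          pmin(b_bound, pmax(-b_bound,
                             best$b + seq(-0.25, 0.25, by = 0.02))))
    if (!is.finite(best$value))
      return(list(a = 1, b = 0, residual = NA_real_, registered = FALSE))
    list(a = best$a, b = best$b, residual = best$value, registered = TRUE)
  }

  n <- length(profiles)
  # accumulated map per profile: x_registered = a_tot * x_raw + b_tot
  a_tot <- rep(1, n); b_tot <- rep(0, n)
  registered_flag <- rep(TRUE, n)
  residual <- rep(NA_real_, n)
  current <- profiles
  for (it in seq_len(iterations)) {
    if (it > 1) {
      splines_ <- lapply(current, fit_quadratic_spline, smoothing = smoothing)
      ranges <- lapply(current, function(p) range(p$x))
      ref_vals <- stats::approx(seq(0.5, 99.5, 1),
                                integrate_profiles(current)$bins,
                                xout = grid, rule = 2)$y
    }
    maps <- lapply(seq_len(n), function(i) fit_one(splines_[[i]], ranges[[i]]))
    ok <- vapply(maps, `[[`, logical(1), "registered")
    a <- vapply(maps, `[[`, numeric(1), "a")
    b <- vapply(maps, `[[`, numeric(1), "b")
    b <- b - if (any(ok)) mean(b[ok]) else 0
    registered_flag <- registered_flag & ok
    residual <- vapply(maps, `[[`, numeric(1), "residual")
    current <- lapply(seq_len(n), function(i) {
      p <- current[[i]]
      if (ok[i]) p$x <- a[i] * p$x + b[i]
      p
    })
    a_tot <- ifelse(ok, a * a_tot, a_tot)
    b_tot <- ifelse(ok, a * b_tot + b, b_tot)
  }
  map_df <- data.frame(
    embryo_id = vapply(profiles, `[[`, character(1), "embryo_id"),
    a = a_tot, b = b_tot, residual = residual,
    registered = registered_flag, stringsAsFactors = FALSE)
  list(profiles = current, maps = map_df)
}
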