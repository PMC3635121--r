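#' Default domain search windows derived from a genotype preset
#'
#' Assigning a peak to a named domain ("which stripe is this?") needs
#' prior knowledge of where each domain is expected. These windows are
#' built from a preset's expected class-shifted centres: interior limits
#' sit midway between adjacent expected centres of the same gene, outer
#' limits at four Gaussian scales beyond the outermost centres (clipped
#' to [0, 100]). Fully user-overridable: any data frame with columns
#' `gene`, `domain`, `lo`, `hi` works wherever windows are accepted.
#'
#' @param preset A [genotype_preset()].
#' @param time_class Time-class label.
#' @param genes Optional subset of genes.
#' @return Data frame with columns `gene`, `domain`, `lo`, `hi`, ordered
#'   anterior to posterior within gene.
#' @export
search_windows <- function(preset, time_class, genes = NULL) {
  stopifnot(inherits(preset, "genotype_preset"))
  doms <- preset$domains
  if (!is.null(genes))
    doms <- Filter(function(d) d$gene %in% genes, doms)
  if (!length(doms)) stop("no domains for requested genes")
  rows <- lapply(split(doms, vapply(doms, `[[`, character(1), "gene")),
                 function(dg) {
    centers <- vapply(dg, expected_center, numeric(1), time_class)
    ord <- order(centers)
    dg <- dg[ord]; centers <- centers[ord]
    sig <- vapply(dg, `[[`, numeric(1), "sigma")
    mid <- if (length(centers) > 1)
      (centers[-1] + centers[-length(centers)]) / 2 else numeric(0)
    lo <- c(max(0, centers[1] - 4 * sig[1]), mid)
    hi <- c(mid, min(100, centers[length(centers)] +
                       4 * sig[length(sig)]))
    data.frame(gene = vapply(dg, `[[`, character(1), "gene"),
               domain = vapply(dg, `[[`, character(1), "domain"),
               lo = lo, hi = hi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$hi <= out$lo)) stop("degenerate search window")
  out
}

#' Locate domain peaks on a fitted spline
#'
#' Within each search window the spline is evaluated on a 0.01 %EL grid;
#' the grid argmax is refined by local quadratic interpolation through
#' its two neighbours. Peaks whose refined intensity falls below
#' `min_rel_amplitude` times the spline's global maximum over [0, 100]
#' are reported absent (absence is a value, not an error). Ties go to
#' the most anterior position.
#'
#' @param spline A `quad_spline`.
#' @param windows Data frame with columns `domain`, `lo`, `hi`.
#' @param min_rel_amplitude Relative-amplitude threshold in [0, 1).
#' @return Data frame (domain, peak, peak_intensity, present); `peak`
#'   is `NA` for absent domains.
#' @export
find_domain_peaks <- function(spline, windows, min_rel_amplitude = 0.1) {
  stopifnot(inherits(spline, "quad_spline"))
  if (min_rel_amplitude < 0 || min_rel_amplitude >= 1)
    stop("'min_rel_amplitude' must be in [0, 1)")
  global_grid <- seq(0, 100, by = 0.05)
  global_max <- max(predict(spline, global_grid))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    pk <- spline_window_max(spline, windows$lo[i], windows$hi[i])
    # an argmax sitting on a window edge is the flank of a neighbouring
    # domain, not a peak of this one
    interior <- pk$x > windows$lo[i] + 0.03 && pk$x < windows$hi[i] - 0.03
    present <- interior && global_max > 0 &&
      pk$value >= min_rel_amplitude * global_max
    data.frame(domain = windows$domain[i],
               peak = if (present) pk$x else NA_real_,
               peak_intensity = if (present) pk$value else NA_real_,
               present = present, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Grid argmax over [lo, hi] at 0.01 %EL, refined by a local parabola.
spline_window_max <- function(spline, lo, hi) {
  grid <- seq(lo, hi, by = 0.01)
  v <- predict(spline, grid)
  i <- which.max(v)  # ties resolve to the most anterior grid point
  if (i > 1 && i < length(v)) {
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (denom < 0) {
      delta <- 0.5 * (v[i - 1] - v[i + 1]) / denom
      xr <- grid[i] + delta * 0.01
      return(list(x = xr, value = predict(spline, xr)))
    }
  }
  list(x = grid[i], value = v[i])
}

#' Half-maximum boundaries of an expression domain
#'
#' Walks from the peak towards each window edge looking for the closest
#' crossing of half the peak intensity, then refines it by bisection to
#' better than 1e-4 %EL. If a flank never drops below half maximum
#' before the window edge (fused neighbouring domains), that side is
#' censored with reason `"no-half-max-crossing"`.
#'
#' @param spline A `quad_spline`.
#' @param peak Peak position (%EL), inside the window.
#' @param peak_intensity Spline intensity at the peak (> 0).
#' @param lo,hi Window limits in %EL.
#' @return List with `anterior`, `posterior` (position or `NA`),
#'   and `censored` (character vector naming censored sides).
#' @export
half_max_boundaries <- function(spline, peak, peak_intensity, lo, hi) {
  if (peak_intensity <= 0) stop("invalid domain: peak intensity must be > 0")
  if (peak < lo || peak > hi) stop("peak must lie inside the window")
  half <- peak_intensity / 2
  f <- function(x) predict(spline, x) - half
  cross <- function(from, to) {
    grid <- seq(from, to, by = if (to > from) 0.01 else -0.01)
    if (length(grid) < 2) return(NA_real_)
    v <- f(grid)
    below <- which(v <= 0)
    if (!length(below)) return(NA_real_)
    j <- below[1]
    if (j == 1) return(grid[1])
    stats::uniroot(f, sort(c(grid[j - 1], grid[j])), tol = 1e-6)$root
  }
  anterior <- cross(peak, lo)
  posterior <- cross(peak, hi)
  censored <- c(if (is.na(anterior)) "anterior" else NULL,
                if (is.na(posterior)) "posterior" else NULL)
  if (length(censored))
    attr(censored, "reason") <- "no-half-max-crossing"
  list(anterior = anterior, posterior = posterior, censored = censored)
}

#' Width of a domain from its features
#'
#' @param features A list or one-row data frame with `anterior` and
#'   `posterior` entries (either may be `NA` when censored).
#' @return Posterior minus anterior boundary in %EL, or `NA` if either
#'   side is censored.
#' @export
domain_width <- function(features) {
  a <- features$anterior; p <- features$posterior
  if (is.null(a) || is.null(p) || is.na(a) || is.na(p)) return(NA_real_)
  p - a
}

#' Extent of the expressed region from first to last stripe peak
#'
#' @param stripe_peaks Numeric vector of uncensored peak positions, %EL.
#' @return Last peak minus first peak, %EL.
#' @export
total_expression_extent <- function(stripe_peaks) {
  pk <- stripe_peaks[!is.na(stripe_peaks)]
  if (length(pk) < 2)
    stop("insufficient peaks: need at least 2 uncensored stripe peaks")
  max(pk) - min(pk)
}

#' Temporal shift of a domain peak between two time classes
#'
#' @param features_a,features_b Lists or one-row data frames with
#'   `domain` and `peak` entries, `features_a` at the earlier class.
#' @return `peak_a - peak_b` in %EL; positive values are anterior
#'   movement over time.
#' @export
compute_shift <- function(features_a, features_b) {
  if (!identical(features_a$domain, features_b$domain))
    stop("invalid pair: shifts compare the same domain across classes")
  features_a$peak - features_b$peak
}

#' Classify the Eve stripe-7 pattern of one profile
#'
#' Implements the three late-blastoderm pattern classes: six stripes
#' only, six plus a partial seventh, or seven fully formed stripes.
#' With `A7` the stripe-7 window peak relative to the stripe-6 peak and
#' `V` the 6/7 inter-stripe valley minimum relative to the smaller of
#' the two peaks, the rule is: `six` if `A7 < rel_amp_partial`;
#' `full_seven` if `A7 >= rel_amp_full` and `V <= valley_frac`;
#' otherwise `partial_seven`. The dorso-ventral completeness criterion
#' used on embryo images is not available in 1-D profiles; reduced
#' relative amplitude stands in for it.
#'
#' @param spline A `quad_spline` of an Eve profile.
#' @param windows Window data frame containing rows for `eve_stripe_6`
#'   and `eve_stripe_7`.
#' @param rel_amp_partial,rel_amp_full Relative-amplitude thresholds
#'   (defaults 0.15 and 0.50, `0 < partial <= full < 1`).
#' @param valley_frac Maximum relative valley for a fully separated
#'   stripe (default 0.50).
#' @return List of class `stripe_pattern` with `class` (one of `"six"`,
#'   `"partial_seven"`, `"full_seven"`), `a7` and `valley`.
#' @export
classify_stripe7 <- function(spline, windows, rel_amp_partial = 0.15,
                             rel_amp_full = 0.50, valley_frac = 0.50) {
  if (!(rel_amp_partial > 0 && rel_amp_partial <= rel_amp_full &&
        rel_amp_full < 1))
    stop("need 0 < rel_amp_partial <= rel_amp_full < 1")
  if (valley_frac <= 0 || valley_frac >= 1)
    stop("'valley_frac' must be in (0, 1)")
  w6 <- windows[windows$domain == "eve_stripe_6", ]
  w7 <- windows[windows$domain == "eve_stripe_7", ]
  if (nrow(w6) != 1 || nrow(w7) != 1)
    stop("windows must contain eve_stripe_6 and eve_stripe_7")
  p6 <- spline_window_max(spline, w6$lo, w6$hi)
  p7 <- spline_window_max(spline, w7$lo, w7$hi)
  global_max <- max(predict(spline, seq(0, 100, by = 0.05)))
  if (p6$value < 0.1 * global_max)
    stop("unclassifiable: Eve stripe 6 absent from profile")
  # an argmax on the stripe-7 window edge is the stripe-6 flank, not a
  # seventh stripe
  a7 <- if (p7$x > w7$lo + 0.03 && p7$x < w7$hi - 0.03)
    max(0, p7$value) / p6$value else 0
  vx <- seq(p6$x, p7$x, by = 0.01)
  valley <- if (length(vx) > 1) {
    min(predict(spline, vx)) / min(p6$value, p7$value)
  } else 1
  valley <- max(0, min(1, valley))
  cls <- if (a7 < rel_amp_partial) "six"
  else if (a7 >= rel_amp_full && valley <= valley_frac) "full_seven"
  else "partial_seven"
  structure(list(class = cls, a7 = a7, valley = valley),
            class = "stripe_pattern")
}

#' Extract domain features for every embryo of a cohort
#'
#' Runs the per-embryo chain strip extraction, background removal,
#' quadratic-spline fit, peak location and half-maximum boundary
#' extraction, optionally after cohort-wise registration (per gene and
#' time class), and returns one tidy row per embryo x domain.
#'
#' @param embryos List of `embryo_record`s (or a `bv_cohort`).
#' @param preset The [genotype_preset()] whose expected domain layout
#'   defines the search windows; defaults to the built-in preset named
#'   by the embryos' genotype.
#' @param genes Genes to process (default: all channels present).
#' @param height_fraction,bg_quantile,bg_degree,smoothing,min_rel_amplitude
#'   Processing parameters, see [extract_strip()], [remove_background()],
#'   [fit_quadratic_spline()] and [find_domain_peaks()].
#' @param register Logical: register each gene x time-class cohort to
#'   its own mean before feature extraction (default `FALSE`; the
#'   synthetic generator produces already-oriented embryos, whereas
#'   scanned embryos normally need this step).
#' @return Data frame with columns `embryo_id`, `genotype`,
#'   `time_class`, `gene`, `domain`, `peak`, `peak_intensity`,
#'   `anterior`, `posterior`, `width`, `present`,
#'   `censored` (`""`, `"anterior"`, `"posterior"` or `"both"`).
#' @export
extract_features <- function(embryos, preset = NULL, genes = NULL,
                             height_fraction = 0.10, bg_quantile = 0.1,
                             bg_degree = 2, smoothing = 0.5,
                             min_rel_amplitude = 0.1, register = FALSE) {
  if (inherits(embryos, "bv_cohort")) embryos <- embryos$embryos
  if (!length(embryos)) stop("no embryos to process")
  if (is.null(preset))
    preset <- get_preset(embryos[[1]]$genotype)
  if (is.null(genes))
    genes <- intersect(
      unique(vapply(preset$domains, `[[`, character(1), "gene")),
      setdiff(names(embryos[[1]]$nuclei), c("nucleus_id", "x", "y")))
  tcs <- vapply(embryos, `[[`, character(1), "time_class")
  out <- list()
  for (g in genes) {
    for (tc in unique(tcs)) {
      idx <- which(tcs == tc)
      profs <- lapply(embryos[idx], function(e)
        remove_background(extract_strip(e, g, height_fraction),
                          quantile = bg_quantile, poly_degree = bg_degree))
      if (register && length(profs) >= 2)
        profs <- register_profiles(profs, smoothing = smoothing)$profiles
      win <- search_windows(preset, tc, genes = g)
      for (p in profs) {
        if (length(p$x) < 6) next
        spl <- fit_quadratic_spline(p, smoothing = smoothing)
        pk <- find_domain_peaks(spl, win, min_rel_amplitude)
        for (j in seq_len(nrow(pk))) {
          if (pk$present[j]) {
            bnd <- half_max_boundaries(spl, pk$peak[j], pk$peak_intensity[j],
                                       win$lo[j], win$hi[j])
            cens <- paste(bnd$censored, collapse = "+")
            if (identical(cens, "anterior+posterior")) cens <- "both"
          } else {
            bnd <- list(anterior = NA_real_, posterior = NA_real_)
            cens <- ""
          }
          out[[length(out) + 1L]] <- data.frame(
            embryo_id = p$embryo_id, genotype = p$genotype, time_class = tc,
            gene = g, domain = pk$domain[j], peak = pk$peak[j],
            peak_intensity = pk$peak_intensity[j],
            anterior = bnd$anterior, posterior = bnd$posterior,
            width = domain_width(bnd), present = pk$present[j],
            censored = cens, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the stripe-7 pattern of every Eve-stained embryo
#'
#' @inheritParams extract_features
#' @param rel_amp_partial,rel_amp_full,valley_frac See
#'   [classify_stripe7()].
#' @return Data frame (embryo_id, genotype, time_class, class, a7,
#'   valley).
#' @export
classify_cohort_stripe7 <- function(embryos, preset = NULL,
                                    height_fraction = 0.10,
                                    bg_quantile = 0.1, bg_degree = 2,
                                    smoothing = 0.5, rel_amp_partial = 0.15,
                                    rel_amp_full = 0.50,
                                    valley_frac = 0.50) {
  if (inherits(embryos, "bv_cohort")) embryos <- embryos$embryos
  if (!length(embryos)) stop("no embryos to classify")
  if (is.null(preset))
    preset <- get_preset(embryos[[1]]$genotype)
  rows <- lapply(embryos, function(e) {
    p <- remove_background(extract_strip(e, "eve", height_fraction),
                           quantile = bg_quantile, poly_degree = bg_degree)
    spl <- fit_quadratic_spline(p, smoothing = smoothing)
    win <- search_windows(preset, e$time_class, genes = "eve")
    cl <- classify_stripe7(spl, win, rel_amp_partial, rel_amp_full,
                           valley_frac)
    data.frame(embryo_id = e$embryo_id, genotype = e$genotype,
               time_class = e$time_class, class = cl$class, a7 = cl$a7,
               valley = cl$valley, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
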