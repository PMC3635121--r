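#' Generate one synthetic embryo
#'
#' Simulates per-nucleus expression measurements for one blastoderm
#' embryo. Nuclei are placed at quasi-regular antero-posterior positions
#' spanning 0--100 %EL with small positional scatter and uniformly
#' random dorso-ventral heights. The intensity of each gene channel at
#' position `x` is the sum over that gene's present domains of
#' `amplitude * exp(-(x - center')^2 / (2 sigma^2))` plus the
#' background and additive noise, clipped to the 8-bit range 0--255.
#' The realised centre `center'` is the class-shifted centre plus one
#' per-embryo jitter draw per domain.
#'
#' @param preset A [genotype_preset()].
#' @param time_class Time-class label (`c13`, `t1`..`t8`).
#' @param n_nuclei Number of nuclei to simulate (>= 20). The default of
#'   1000 yields roughly 100 nuclei inside the standard 10% lateral
#'   strip, matching the roughly one-nucleus-per-%EL resolution of
#'   quantified blastoderm data.
#' @param seed Integer seed; identical arguments give identical output.
#' @param embryo_id Identifier stored in the record.
#' @param genes Optional character vector restricting which gene
#'   channels are simulated (default: all genes in the preset).
#' @param position_scatter Positional scatter of nuclei as a fraction of
#'   the inter-nucleus spacing (0 gives exactly regular positions).
#' @return A list with components `record` (class `embryo_record`: the
#'   metadata plus a per-nucleus `data.frame`) and `ground_truth` (one
#'   row per simulated domain: realised centre, analytic half-maximum
#'   boundaries, presence and partial flags).
#' @export
generate_embryo <- function(preset, time_class, n_nuclei = 1000, seed = 1,
                            embryo_id = "embryo_1", genes = NULL,
                            position_scatter = 0.3) {
  stopifnot(inherits(preset, "genotype_preset"))
  idx <- time_class_index(time_class)
  if (n_nuclei < 20) stop("'n_nuclei' must be >= 20")
  domains <- preset$domains
  if (!is.null(genes)) {
    keep <- vapply(domains, function(d) d$gene %in% genes, logical(1))
    if (!any(keep)) stop("no preset domain matches genes: ",
                         paste(genes, collapse = ", "))
    domains <- domains[keep]
  }
  gene_names <- unique(vapply(domains, `[[`, character(1), "gene"))
  bg <- preset$background

  with_seed(seed, {
    spacing <- 100 / n_nuclei
    x <- (seq_len(n_nuclei) - 0.5) * spacing +
      stats::runif(n_nuclei, -position_scatter, position_scatter) * spacing
    x <- pmin(100, pmax(0, x))
    # dorso-ventral heights are stratified (golden-ratio sequence plus
    # jitter) rather than i.i.d. uniform: nuclei tile the blastoderm
    # surface, so any lateral strip samples the A-P axis without gaps
    phi <- (sqrt(5) - 1) / 2
    y <- 100 * ((seq_len(n_nuclei) * phi) %% 1) +
      stats::runif(n_nuclei, -2, 2)
    y <- pmin(100, pmax(0, y))

    # shared jitter draws: one standard normal per jitter group per embryo
    groups <- unique(stats::na.omit(
      vapply(domains, `[[`, character(1), "jitter_group")))
    group_z <- stats::setNames(stats::rnorm(length(groups)), sort(groups))

    gt <- vector("list", length(domains))
    intens <- matrix(0, n_nuclei, length(gene_names),
                     dimnames = list(NULL, gene_names))
    hw <- sqrt(2 * log(2))  # half-width at half maximum, in units of sigma
    for (i in seq_along(domains)) {
      d <- domains[[i]]
      z <- if (!is.na(d$jitter_group)) group_z[[d$jitter_group]]
           else stats::rnorm(1)
      center <- d$center - d$shift_per_class * idx + d$jitter_sd * z
      present <- stats::runif(1) < d$presence_prob[[time_class]]
      partial <- present && stats::runif(1) < d$partial_prob[[time_class]]
      amp <- d$amplitude * max(0, 1 + d$amplitude_cv * stats::rnorm(1))
      if (partial) amp <- amp * d$partial_frac
      if (present && amp > 0)
        intens[, d$gene] <- intens[, d$gene] +
          amp * exp(-(x - center)^2 / (2 * d$sigma^2))
      gt[[i]] <- data.frame(
        embryo_id = embryo_id, gene = d$gene, domain = d$domain,
        center = center, anterior = center - hw * d$sigma,
        posterior = center + hw * d$sigma,
        present = present, partial = partial,
        stringsAsFactors = FALSE)
    }
    baseline <- bg$constant + bg$quadratic_coeff * (x - 50)^2
    for (g in gene_names) {
      noisy <- intens[, g] + baseline + stats::rnorm(n_nuclei, 0, bg$noise_sd)
      intens[, g] <- pmin(255, pmax(0, noisy))
    }

    nuclei <- data.frame(nucleus_id = seq_len(n_nuclei), x = x, y = y,
                         stringsAsFactors = FALSE)
    nuclei <- cbind(nuclei, as.data.frame(intens))
    record <- structure(
      list(embryo_id = embryo_id, genotype = preset$name,
           time_class = time_class, nuclei = nuclei),
      class = "embryo_record")
    list(record = record, ground_truth = do.call(rbind, gt))
  })
}

#' @export
print.embryo_record <- function(x, ...) {
  cat("embryo_record ", x$embryo_id, " (", x$genotype, ", ", x$time_class,
      "): ", nrow(x$nuclei), " nuclei, channels ",
      paste(setdiff(names(x$nuclei), c("nucleus_id", "x", "y")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate a seeded synthetic cohort
#'
#' Concatenates [generate_embryo()] draws across time classes, with
#' per-embryo seeds derived deterministically from the master seed
#' (`seed + running embryo index`), so the same `(preset, n_per_class,
#' seed)` always yields byte-identical cohorts.
#'
#' @inheritParams generate_embryo
#' @param n_per_class Named integer vector of embryos per time class,
#'   e.g. `c(t7 = 50, t8 = 50)`; counts must be >= 0.
#' @return A list of class `bv_cohort` with components `embryos` (list
#'   of `embryo_record`) and `ground_truth` (row-bound ground truth with
#'   genotype and time-class columns added).
#' @export
generate_cohort <- function(preset, n_per_class, seed = 1, n_nuclei = 1000,
                            genes = NULL, position_scatter = 0.3) {
  stopifnot(inherits(preset, "genotype_preset"))
  if (is.null(names(n_per_class)) || any(is.na(match(names(n_per_class),
                                                     time_classes()))))
    stop("'n_per_class' must be named by valid time classes")
  if (any(n_per_class < 0)) stop("counts in 'n_per_class' must be >= 0")
  embryos <- list()
  gts <- list()
  k <- 0L
  for (tc in names(n_per_class)) {
    for (j in seq_len(n_per_class[[tc]])) {
      k <- k + 1L
      id <- sprintf("%s_%s_%03d", preset$name, tc, j)
      out <- generate_embryo(preset, tc, n_nuclei = n_nuclei,
                             seed = seed + k, embryo_id = id, genes = genes,
                             position_scatter = position_scatter)
      embryos[[k]] <- out$record
      gt <- out$ground_truth
      gt$genotype <- preset$name
      gt$time_class <- tc
      gts[[k]] <- gt
    }
  }
  gt_all <- if (k > 0) do.call(rbind, gts) else
    data.frame(embryo_id = character(), gene = character(),
               domain = character(), center = numeric(),
               anterior = numeric(), posterior = numeric(),
               present = logical(), partial = logical(),
               genotype = character(), time_class = character(),
               stringsAsFactors = FALSE)
  structure(list(embryos = embryos, ground_truth = gt_all),
            class = "bv_cohort")
}

#' @export
print.bv_cohort <- function(x, ...) {
  tcs <- vapply(x$embryos, `[[`, character(1), "time_class")
  cat("bv_cohort: ", length(x$embryos), " embryos",
      if (length(tcs)) paste0(" (",
        paste(sprintf("%s:%d", names(table(tcs)), table(tcs)),
              collapse = ", "), ")"), "\n", sep = "")
  invisible(x)
}
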