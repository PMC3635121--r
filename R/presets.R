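#' Specify one expression domain for the synthetic generator
#'
#' A domain is a Gaussian bump on the antero-posterior (A--P) axis whose
#' centre drifts anteriorly over developmental time and jitters from
#' embryo to embryo. Gaussians are used because they are smooth and
#' analytically invertible: the half-maximum boundaries of a Gaussian of
#' scale `sigma` on a zero baseline sit at `center +/- sigma*sqrt(2*log(2))`,
#' which gives exact ground truth for parameter-recovery tests.
#'
#' @param gene Gene name (e.g. `"eve"`).
#' @param domain Domain label (e.g. `"eve_stripe_6"`, `"gt_posterior"`).
#' @param center Domain centre in %EL at the reference time class `c13`
#'   (class index 0). The realised centre at class index `k` is
#'   `center - shift_per_class * k` plus the per-embryo jitter.
#' @param amplitude Peak intensity in arbitrary units on the 0--255 scale.
#' @param sigma Gaussian scale in %EL (`sigma > 0`).
#' @param shift_per_class Anterior shift in %EL per time-class step;
#'   positive values move the domain towards the anterior over time.
#' @param jitter_sd Embryo-to-embryo standard deviation of the centre, in
#'   %EL. Drawn once per embryo per domain: this models embryo-to-embryo
#'   positional variability, not nuclear noise.
#' @param amplitude_cv Coefficient of variation of the per-embryo
#'   amplitude (Gaussian, truncated at 0).
#' @param presence_prob Probability that the domain is expressed at all,
#'   either a single number or a named vector over time classes
#'   (missing classes default to the scalar default 1). Models
#'   stochastic domains such as the delayed Eve stripe 7 in *tll*
#'   mutants.
#' @param partial_prob Probability, given presence, that the domain is
#'   only partially formed (rendered at `partial_frac` of its full
#'   amplitude); scalar or named vector over time classes.
#' @param partial_frac Amplitude fraction used for partial domains.
#' @param jitter_group Optional label; domains sharing a label within
#'   one embryo share a single standard-normal jitter draw (scaled by
#'   their own `jitter_sd`), producing correlated positions such as the
#'   abdominal Kni posterior border and the Eve stripe 6 anterior border.
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(gene, domain, center, amplitude, sigma,
                        shift_per_class = 0, jitter_sd = 0,
                        amplitude_cv = 0, presence_prob = 1,
                        partial_prob = 0, partial_frac = 0.3,
                        jitter_group = NA_character_) {
  stopifnot_scalar_number(center, "center")
  stopifnot_scalar_number(amplitude, "amplitude")
  stopifnot_scalar_number(sigma, "sigma")
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (center < 0 || center > 100) stop("'center' must lie in [0, 100] %EL")
  presence <- expand_by_class(presence_prob, "presence_prob")
  partial <- expand_by_class(partial_prob, "partial_prob")
  if (any(presence < 0 | presence > 1)) stop("'presence_prob' must lie in [0, 1]")
  if (any(partial < 0 | partial > 1)) stop("'partial_prob' must lie in [0, 1]")
  structure(
    list(gene = gene, domain = domain, center = center,
         amplitude = amplitude, sigma = sigma,
         shift_per_class = shift_per_class, jitter_sd = jitter_sd,
         amplitude_cv = amplitude_cv, presence_prob = presence,
         partial_prob = partial, partial_frac = partial_frac,
         jitter_group = jitter_group),
    class = "domain_spec")
}

# Recycle a scalar, or complete a named vector, over the nine time classes.
expand_by_class <- function(x, name) {
  tc <- time_classes()
  if (length(x) == 1L && is.null(names(x))) {
    out <- rep(as.numeric(x), length(tc))
    names(out) <- tc
    return(out)
  }
  if (is.null(names(x)) || !all(names(x) %in% tc))
    stop("'", name, "' must be a scalar or a vector named by time classes")
  out <- rep(NA_real_, length(tc))
  names(out) <- tc
  out[names(x)] <- as.numeric(x)
  # unnamed classes inherit the last class given earlier in time, else 0
  filled <- out
  last <- 0
  for (i in seq_along(filled)) {
    if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
  }
  filled
}

#' Specify the non-specific staining background
#'
#' Additive baseline `constant + quadratic_coeff * (x - 50)^2` plus
#' i.i.d. Gaussian measurement noise, standing in for the non-specific
#' background that real antibody stainings carry.
#'
#' @param constant Baseline intensity (units).
#' @param quadratic_coeff Curvature in units per (%EL)^2; positive values
#'   give a shallow bowl rising towards the poles.
#' @param noise_sd Standard deviation of additive per-nucleus noise.
#' @return An object of class `background_spec`.
#' @export
background_spec <- function(constant = 8, quadratic_coeff = 0.001,
                            noise_sd = 3) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  bg <- function(x) constant + quadratic_coeff * (x - 50)^2
  if (min(bg(c(0, 50, 100))) < 0)
    stop("background must be non-negative over [0, 100] %EL")
  structure(list(constant = constant, quadratic_coeff = quadratic_coeff,
                 noise_sd = noise_sd),
            class = "background_spec")
}

#' Assemble a genotype preset
#'
#' @param name Genotype label, e.g. `"wildtype"` or `"tll"`.
#' @param domains List of [domain_spec()] objects; domain labels must be
#'   unique within the preset and every gene must appear at least once.
#' @param background A [background_spec()].
#' @return An object of class `genotype_preset`.
#' @export
genotype_preset <- function(name, domains, background = background_spec()) {
  if (!length(domains)) stop("a preset needs at least one domain")
  if (!all(vapply(domains, inherits, logical(1), "domain_spec")))
    stop("'domains' must be a list of domain_spec objects")
  labels <- vapply(domains, `[[`, character(1), "domain")
  if (anyDuplicated(labels))
    stop("duplicate domain labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  structure(list(name = name, domains = domains, background = background),
            class = "genotype_preset")
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat("genotype_preset '", x$name, "': ", length(x$domains),
      " domains over genes ",
      paste(unique(vapply(x$domains, `[[`, character(1), "gene")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Built-in wild-type-like genotype preset
#'
#' Seven Eve stripes plus the principal gap domains (anterior/posterior
#' Hb, anterior/posterior Gt, abdominal Kni, central Kr). Late (t8)
#' stripe positions span 47 %EL from stripe 1 to stripe 7, and the
#' per-class anterior shift rates are set so that the t3 to t8 shifts of
#' the posterior Gt domain, Eve stripe 6 and Eve stripe 7 are 4.34, 2.62
#' and 4.36 %EL respectively. Embryo-to-embryo positional jitter is a
#' uniform 0.75 %EL across Eve stripes.
#'
#' @param jitter_sd Positional jitter applied to every Eve stripe, %EL.
#' @return A [genotype_preset()].
#' @export
preset_wildtype <- function(jitter_sd = 0.75) {
  # Eve stripe positions at t8 (%EL) and shift rates (%EL per class step);
  # centres are back-projected to the c13 reference (index 0).
  p8 <- c(33.5, 41.0, 48.0, 55.5, 63.0, 71.0, 80.5)
  rate <- c(0.30, 0.33, 0.36, 0.40, 0.45, 2.62 / 5, 4.36 / 5)
  eve <- lapply(1:7, function(k) {
    domain_spec(
      gene = "eve", domain = paste0("eve_stripe_", k),
      center = p8[k] + 8 * rate[k], amplitude = if (k == 7) 160 else 180,
      sigma = 1.8, shift_per_class = rate[k], jitter_sd = jitter_sd,
      amplitude_cv = 0.08,
      presence_prob = if (k == 7) c(c13 = 0, t1 = 0, t2 = 1) else 1,
      jitter_group = if (k == 6) "posterior_gap" else NA_character_)
  })
  gap <- list(
    domain_spec("hb", "hb_anterior", center = 24, amplitude = 200, sigma = 8,
                shift_per_class = 0.2, jitter_sd = 0.75, amplitude_cv = 0.08),
    domain_spec("hb", "hb_posterior", center = 92, amplitude = 150, sigma = 4,
                shift_per_class = 0.5, jitter_sd = 1.0, amplitude_cv = 0.10),
    domain_spec("gt", "gt_anterior", center = 32, amplitude = 150, sigma = 5,
                shift_per_class = 0.3, jitter_sd = 0.75, amplitude_cv = 0.10),
    domain_spec("gt", "gt_posterior", center = 82 + 8 * (4.34 / 5),
                amplitude = 180, sigma = 3.5, shift_per_class = 4.34 / 5,
                jitter_sd = 1.0, amplitude_cv = 0.10),
    domain_spec("kni", "kni_abdominal", center = 64 + 8 * 0.6, amplitude = 180,
                sigma = 4.5, shift_per_class = 0.6, jitter_sd = 0.9,
                amplitude_cv = 0.10, jitter_group = "posterior_gap"),
    domain_spec("kr", "kr_central", center = 52 + 8 * 0.3, amplitude = 200,
                sigma = 6, shift_per_class = 0.3, jitter_sd = 0.8,
                amplitude_cv = 0.08))
  genotype_preset("wildtype", c(eve, gap))
}

#' Built-in tailless-like genotype preset
#'
#' Emulates the posterior patterning defects of *tll* loss-of-function
#' embryos: no posterior Hb domain; a posteriorly expanded Gt domain
#' with a larger t3 to t8 shift (5.92 %EL); a slightly posteriorly
#' dislocated abdominal Kni domain; Eve stripes 4--6 displaced
#' posteriorly, stripe 6 shifting 4.16 %EL between t3 and t8; and a
#' stochastic, delayed stripe 7 that is absent through t6, present
#' (partially or fully formed) in 45% of embryos at t7 and 92% at t8.
#' Positional jitter is inflated for the posterior stripes
#' (1.6--2.0 %EL versus 0.75 %EL anteriorly), the synthetic counterpart
#' of the mutant's loss of canalisation.
#'
#' @param posterior_jitter_sd Jitter for Eve stripe 6 (stripe 5 and 7 use
#'   `0.8 *` this value), %EL.
#' @return A [genotype_preset()].
#' @export
preset_tll <- function(posterior_jitter_sd = 2.0) {
  p8 <- c(33.5, 41.0, 48.0, 56.5, 65.5, 74.8, 90.5)
  rate <- c(0.30, 0.33, 0.36, 0.40, 0.70, 4.16 / 5, 4.36 / 5)
  jit <- c(0.75, 0.75, 0.75, 0.75, 0.8 * posterior_jitter_sd,
           posterior_jitter_sd, 0.8 * posterior_jitter_sd)
  # stripe-7 presence: absent through t6, then 45% at t7 and 92% at t8;
  # given presence, the partial:full split is 33:12 at t7 and 47:45 at t8.
  pres7 <- c(c13 = 0, t1 = 0, t2 = 0, t3 = 0, t4 = 0, t5 = 0, t6 = 0,
             t7 = 0.45, t8 = 0.92)
  part7 <- c(c13 = 0, t7 = 0.33 / 0.45, t8 = 0.47 / 0.92)
  eve <- lapply(1:7, function(k) {
    domain_spec(
      gene = "eve", domain = paste0("eve_stripe_", k),
      center = p8[k] + 8 * rate[k], amplitude = if (k == 7) 160 else 180,
      sigma = 1.8, shift_per_class = rate[k], jitter_sd = jit[k],
      amplitude_cv = 0.08,
      presence_prob = if (k == 7) pres7 else 1,
      partial_prob = if (k == 7) part7 else 0,
      jitter_group = if (k == 6) "posterior_gap" else NA_character_)
  })
  gap <- list(
    domain_spec("hb", "hb_anterior", center = 24, amplitude = 200, sigma = 8,
                shift_per_class = 0.2, jitter_sd = 0.75, amplitude_cv = 0.08),
    domain_spec("gt", "gt_anterior", center = 32, amplitude = 150, sigma = 5,
                shift_per_class = 0.3, jitter_sd = 0.75, amplitude_cv = 0.10),
    domain_spec("gt", "gt_posterior", center = 85.5 + 8 * (5.92 / 5),
                amplitude = 180, sigma = 5, shift_per_class = 5.92 / 5,
                jitter_sd = 2.0, amplitude_cv = 0.12),
    domain_spec("kni", "kni_abdominal", center = 65.5 + 8 * 0.75,
                amplitude = 180, sigma = 4.5, shift_per_class = 0.75,
                jitter_sd = 1.2, amplitude_cv = 0.10,
                jitter_group = "posterior_gap"),
    domain_spec("kr", "kr_central", center = 52 + 8 * 0.3, amplitude = 200,
                sigma = 6, shift_per_class = 0.3, jitter_sd = 0.8,
                amplitude_cv = 0.08))
  genotype_preset("tll", c(eve, gap))
}

#' Fetch a built-in preset by name
#' @param name `"wildtype"` or `"tll"`.
#' @return A [genotype_preset()].
#' @export
get_preset <- function(name) {
  switch(name,
         wildtype = preset_wildtype(),
         tll = preset_tll(),
         stop("unknown preset '", name, "' (built-ins: wildtype, tll)"))
}

#' Expected (noise-free) domain centre at a time class
#'
#' @param spec A [domain_spec()].
#' @param time_class Time-class label.
#' @return Centre position in %EL.
#' @export
expected_center <- function(spec, time_class) {
  spec$center - spec$shift_per_class * time_class_index(time_class)
}

#' Read / write a genotype preset as YAML
#'
#' @param path File path.
#' @rdname preset_yaml
#' @return `read_preset` returns a [genotype_preset()]; `write_preset`
#'   returns `path` invisibly.
#' @export
read_preset <- function(path) {
  raw <- yaml::read_yaml(path)
  domains <- lapply(raw$domains, function(d) {
    d$presence_prob <- unlist(d$presence_prob)
    d$partial_prob <- if (is.null(d$partial_prob)) 0 else unlist(d$partial_prob)
    do.call(domain_spec, d)
  })
  bg <- if (is.null(raw$background)) background_spec()
        else do.call(background_spec, raw$background)
  genotype_preset(raw$name, domains, bg)
}

#' @param preset A [genotype_preset()].
#' @rdname preset_yaml
#' @export
write_preset <- function(preset, path) {
  domains <- lapply(preset$domains, function(d) {
    d <- unclass(d)
    d$presence_prob <- as.list(d$presence_prob)
    d$partial_prob <- as.list(d$partial_prob)
    if (is.na(d$jitter_group)) d$jitter_group <- NULL
    d
  })
  yaml::write_yaml(list(name = preset$name, domains = domains,
                        background = unclass(preset$background)), path)
  invisible(path)
}
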