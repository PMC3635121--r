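# Small fixtures built in code, shared across test files.

# A minimal one-gene preset: a single Gaussian domain, optionally noise-free.
single_domain_preset <- function(center = 50, amplitude = 150, sigma = 4,
                                 jitter_sd = 0, shift_per_class = 0,
                                 amplitude_cv = 0, noise_sd = 0,
                                 constant = 0, quadratic_coeff = 0,
                                 name = "wildtype") {
  genotype_preset(
    name,
    list(domain_spec("eve", "eve_stripe_1", center = center,
                     amplitude = amplitude, sigma = sigma,
                     shift_per_class = shift_per_class,
                     jitter_sd = jitter_sd, amplitude_cv = amplitude_cv)),
    background_spec(constant = constant, quadratic_coeff = quadratic_coeff,
                    noise_sd = noise_sd))
}

# Evaluate a profile of arbitrary shape on a regular grid.
profile_from_function <- function(f, by = 0.5, ...) {
  x <- seq(0, 100, by = by)
  ap_profile(x, f(x), embryo_id = "fx", gene = "eve", time_class = "t8",
             genotype = "wildtype", ...)
}

gaussian_fun <- function(center, amplitude = 100, sigma = 4) {
  function(x) amplitude * exp(-(x - center)^2 / (2 * sigma^2))
}

# One embryo record placed entirely on the lateral midline.
flat_record <- function(x, intensity, gene = "eve", y = 50,
                        id = "e1", genotype = "wildtype",
                        time_class = "t8") {
  nuc <- data.frame(nucleus_id = seq_along(x), x = x,
                    y = rep_len(y, length(x)))
  nuc[[gene]] <- intensity
  structure(list(embryo_id = id, genotype = genotype,
                 time_class = time_class, nuclei = nuc),
            class = "embryo_record")
}
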