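test_that("quadratic polynomials and constants are reproduced by the spline", {
  x <- seq(0, 100, by = 1)
  quad <- fit_quadratic_spline(list(x = x, y = (x - 50)^2), smoothing = 0)
  mids <- seq(0.5, 99.5, by = 1)
  expect_equal(predict(quad, mids), (mids - 50)^2, tolerance = 1e-4)

  const <- fit_quadratic_spline(list(x = x, y = rep(7, length(x))),
                                smoothing = 0)
  expect_equal(predict(const, seq(0, 100, 0.25)),
               rep(7, 401), tolerance = 1e-6)
})

test_that("the spline tracks a noisy broad Gaussian within 2 units", {
  set.seed(14)
  g <- gaussian_fun(50, 100, 4)
  x <- seq(0, 100, by = 0.25)
  rms <- replicate(5, {
    spl <- fit_quadratic_spline(list(x = x, y = g(x) + rnorm(length(x), 0, 5)))
    grid <- seq(0, 100, 0.2)
    sqrt(mean((predict(spl, grid) - g(grid))^2))
  })
  expect_lt(mean(rms), 2)
})

test_that("peaks of separated Gaussians are found at their centres", {
  f <- function(x) gaussian_fun(40, 100, 3)(x) + gaussian_fun(60, 80, 3)(x)
  spl <- fit_quadratic_spline(profile_from_function(f), smoothing = 0)
  win <- data.frame(gene = "eve", domain = c("d1", "d2"),
                    lo = c(30, 50), hi = c(50, 70))
  pk <- find_domain_peaks(spl, win)
  expect_equal(pk$peak, c(40, 60), tolerance = 0.01)
  expect_true(all(pk$present))

  flat <- fit_quadratic_spline(
    profile_from_function(function(x) rep(0, length(x))), smoothing = 0)
  expect_true(all(!find_domain_peaks(flat, win)$present))
})

test_that("low-amplitude domains are reported absent, not errored", {
  f <- function(x) gaussian_fun(40, 100, 3)(x) + gaussian_fun(70, 4, 3)(x)
  spl <- fit_quadratic_spline(profile_from_function(f), smoothing = 0)
  win <- data.frame(gene = "eve", domain = c("big", "small"),
                    lo = c(30, 60), hi = c(50, 80))
  pk <- find_domain_peaks(spl, win, min_rel_amplitude = 0.1)
  expect_identical(pk$present, c(TRUE, FALSE))
  expect_true(is.na(pk$peak[2]))
})

test_that("half-max boundaries match the Gaussian closed form and linear flanks", {
  sg <- 4; hw <- sg * sqrt(2 * log(2))
  spl <- fit_quadratic_spline(
    profile_from_function(gaussian_fun(50, 100, sg), by = 0.25),
    smoothing = 0)
  pk <- spline_window_max(spl, 35, 65)
  b <- half_max_boundaries(spl, pk$x, pk$value, 35, 65)
  expect_equal(b$anterior, 50 - hw, tolerance = 0.02)
  expect_equal(b$posterior, 50 + hw, tolerance = 0.02)
  expect_equal(domain_width(b), 2 * hw, tolerance = 0.03)

  tri <- function(x) pmax(0, 100 * (1 - abs(x - 50) / 10))
  spl2 <- fit_quadratic_spline(profile_from_function(tri, by = 0.25),
                               smoothing = 0)
  pk2 <- spline_window_max(spl2, 38, 62)
  b2 <- half_max_boundaries(spl2, pk2$x, pk2$value, 38, 62)
  expect_equal(b2$anterior, 45, tolerance = 0.05)
  expect_equal(b2$posterior, 55, tolerance = 0.05)
  expect_equal(domain_width(b2), 10, tolerance = 0.1)
})

test_that("fused domains censor the unreachable flank", {
  # two Gaussians whose valley stays above half maximum
  f <- function(x) gaussian_fun(47, 100, 5)(x) + gaussian_fun(57, 100, 5)(x)
  spl <- fit_quadratic_spline(profile_from_function(f, by = 0.25),
                              smoothing = 0)
  pk <- spline_window_max(spl, 40, 52)
  b <- half_max_boundaries(spl, pk$x, pk$value, 40, 52)
  expect_false(is.na(b$anterior))
  expect_true(is.na(b$posterior))
  expect_true("posterior" %in% b$censored)
  expect_identical(attr(b$censored, "reason"), "no-half-max-crossing")
  expect_true(is.na(domain_width(b)))
})

test_that("widths, extents and shifts are simple position arithmetic", {
  expect_equal(domain_width(list(anterior = 45, posterior = 60)), 15)
  expect_true(is.na(domain_width(list(anterior = 45, posterior = NA))))
  expect_equal(total_expression_extent(c(30, 40, 77)), 47)
  expect_error(total_expression_extent(c(30)), "insufficient")
  expect_equal(compute_shift(list(domain = "gt_posterior", peak = 88.0),
                             list(domain = "gt_posterior", peak = 83.66)),
               4.34)
  expect_equal(compute_shift(list(domain = "d", peak = 50),
                             list(domain = "d", peak = 50)), 0)
  expect_error(compute_shift(list(domain = "a", peak = 1),
                             list(domain = "b", peak = 2)), "invalid pair")
})

test_that("positional features are invariant under intensity scaling", {
  f <- function(x) gaussian_fun(62, 120, 3)(x)
  win <- data.frame(gene = "eve", domain = "d", lo = 50, hi = 74)
  feats <- function(scale) {
    spl <- fit_quadratic_spline(
      profile_from_function(function(x) scale * f(x), by = 0.25),
      smoothing = 0)
    pk <- spline_window_max(spl, 50, 74)
    b <- half_max_boundaries(spl, pk$x, pk$value, 50, 74)
    c(pk$x, b$anterior, b$posterior)
  }
  expect_equal(feats(1), feats(3.7), tolerance = 1e-6)
})

test_that("stripe-7 classification follows the amplitude/valley rule", {
  win <- data.frame(gene = "eve", domain = c("eve_stripe_6", "eve_stripe_7"),
                    lo = c(65, 82), hi = c(82, 98))
  mk <- function(a7_amp) {
    f <- function(x) gaussian_fun(75, 150, 2)(x) +
      gaussian_fun(90, a7_amp, 2)(x)
    fit_quadratic_spline(profile_from_function(f, by = 0.25), smoothing = 0)
  }
  expect_identical(classify_stripe7(mk(0), win)$class, "six")
  expect_identical(classify_stripe7(mk(150 * 0.8), win)$class, "full_seven")
  expect_identical(classify_stripe7(mk(150 * 0.3), win)$class,
                   "partial_seven")
  # a tall stripe 7 not fully separated from stripe 6 (distinct local
  # maximum but valley above half) is partial, not full
  win_f <- data.frame(gene = "eve",
                      domain = c("eve_stripe_6", "eve_stripe_7"),
                      lo = c(65, 83), hi = c(83, 98))
  fused <- function(x) gaussian_fun(78, 150, 3.2)(x) +
    gaussian_fun(88, 140, 3.2)(x)
  spl <- fit_quadratic_spline(profile_from_function(fused, by = 0.25),
                              smoothing = 0)
  cl <- classify_stripe7(spl, win_f)
  expect_identical(cl$class, "partial_seven")
  expect_gt(cl$valley, 0.5)
  # absent stripe 6 is an error, not a class
  none <- fit_quadratic_spline(
    profile_from_function(gaussian_fun(30, 100, 3)), smoothing = 0)
  expect_error(classify_stripe7(none, win), "unclassifiable")
})

test_that("cohort feature extraction recovers ground truth on clean data", {
  pre <- single_domain_preset(center = 60, sigma = 3, noise_sd = 0,
                              constant = 0)
  cohort <- generate_cohort(pre, c(t4 = 3), seed = 41, n_nuclei = 1000)
  feats <- extract_features(cohort, preset = pre, smoothing = 0.1)
  gt <- cohort$ground_truth
  m <- merge(feats, gt, by = c("embryo_id", "domain"))
  expect_lt(max(abs(m$peak - m$center)), 0.05)
  true_width <- 2 * 3 * sqrt(2 * log(2))
  expect_lt(max(abs(m$width - true_width)), 0.02 * true_width)
  expect_true(all(m$anterior.x < m$peak & m$peak < m$posterior.x))
})

test_that("higher injected jitter raises every measured positional SD", {
  measure <- function(jit) {
    pre <- single_domain_preset(center = 55, sigma = 3, jitter_sd = jit,
                                noise_sd = 3, constant = 8)
    cohort <- generate_cohort(pre, c(t4 = 60), seed = 51, n_nuclei = 500)
    f <- extract_features(cohort, preset = pre)
    c(sd(f$peak, na.rm = TRUE), sd(f$anterior, na.rm = TRUE),
      sd(f$posterior, na.rm = TRUE))
  }
  lo <- measure(0.5); hi <- measure(2.0)
  expect_true(all(hi > lo))
})
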