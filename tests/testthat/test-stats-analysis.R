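test_that("directional t-test behaves at its symmetry and separation limits", {
  a <- c(10.2, 11.1, 9.8, 10.5)
  r <- t_test_directional(a, a, "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 0.5)
  expect_equal(r$df, 6)

  # a = {1,2,3} vs b = a + 10: pooled t = -12.25 on 4 df, p = 1.276e-4
  b <- c(1, 2, 3); b10 <- b + 10
  expect_equal(t_test_directional(b, b10, "less")$p_raw,
               pt(-10 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_lt(t_test_directional(b, b10, "less")$p_raw, 2e-4)
  expect_gt(t_test_directional(b, b10, "greater")$p_raw, 1 - 2e-4)

  # the two directions partition the probability
  set.seed(1)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(t_test_directional(x, y, "less")$p_raw +
                 t_test_directional(x, y, "greater")$p_raw, 1,
               tolerance = 1e-12)
})

test_that("degenerate zero-variance t inputs use the documented conventions", {
  expect_equal(t_test_directional(c(5, 5), c(5, 5), "less")$p_raw, 0.5)
  expect_equal(t_test_directional(c(4, 4), c(5, 5), "less")$p_raw, 0)
  expect_equal(t_test_directional(c(4, 4), c(5, 5), "greater")$p_raw, 1)
})

test_that("brown_forsythe reproduces the hand-evaluated W on a fixed example", {
  # a = {-10,0,10}, b = {-1,0,1}: numerator 54, denominator 606/9, factor 4
  r <- brown_forsythe(c(-10, 0, 10), c(-1, 0, 1), "greater")
  expect_equal(r$statistic, 4 * 54 / (606 / 9), tolerance = 1e-12)
  expect_equal(r$statistic, 3.2079, tolerance = 1e-4)
  expect_equal(r$df2, 4)
})

test_that("identical groups give W = 0 and directional p-values that partition", {
  r <- brown_forsythe(1:5, 1:5, "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_twosided, 1)

  set.seed(2)
  x <- rnorm(15, sd = 2); y <- rnorm(12)
  rl <- brown_forsythe(x, y, "less")
  rg <- brown_forsythe(x, y, "greater")
  expect_equal(rl$p_twosided, rg$p_twosided)
  expect_equal(min(rl$p_raw, rg$p_raw), rl$p_twosided / 2, tolerance = 1e-12)
  expect_equal(rl$p_raw + rg$p_raw, 1, tolerance = 1e-12)
})

test_that("brown_forsythe matches the reference implementation on random samples", {
  skip_if_not_installed("car")
  set.seed(3)
  for (i in 1:200) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- rnorm(n1, sd = runif(1, 0.5, 3))
    b <- rnorm(n2, sd = runif(1, 0.5, 3))
    mine <- brown_forsythe(a, b, "greater")
    ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(n1, n2))),
                           center = stats::median)
    expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(mine$p_twosided, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("degenerate all-constant groups return p = 1 with a flag", {
  r <- brown_forsythe(c(2, 2, 2), c(7, 7, 7), "greater")
  expect_true(r$degenerate)
  expect_equal(r$p_raw, 1)
})

test_that("bonferroni caps, preserves order and rejects bad input", {
  expect_equal(bonferroni(0.001, 168), 0.168)
  expect_equal(bonferroni(0.5, 3), 1.0)
  set.seed(4)
  p <- runif(20)
  expect_true(all(diff(bonferroni(sort(p), 50)) >= 0))
  expect_error(bonferroni(c(0.1, 1.2), 10), "\\[0, 1\\]")
  # corrected significance is non-increasing in the family size
  for (n in c(10, 50, 168, 500))
    expect_true(sum(bonferroni(p, n) < 0.05) <=
                  sum(bonferroni(p, 10) < 0.05))
})

test_that("the default Eve grid enumerates 7 stripes x 3 features x 8 classes", {
  g <- default_eve_grid()
  expect_equal(nrow(g$cells), 168)
  expect_equal(g$n_tests, 168)
  expect_setequal(unique(g$cells$domain), paste0("eve_stripe_", 1:7))
  expect_setequal(unique(g$cells$feature),
                  c("peak", "anterior", "posterior"))
  expect_setequal(unique(g$cells$time_class), paste0("t", 1:8))
  expect_error(test_grid(data.frame(domain = character(),
                                    feature = character(),
                                    time_class = character())), "empty")
})

test_that("run_test_grid detects an injected variance increase and skips sparse cells", {
  set.seed(5)
  mk_features <- function(sds) {
    do.call(rbind, lapply(paste0("t", 1:2), function(tc)
      do.call(rbind, lapply(names(sds), function(dm)
        data.frame(embryo_id = paste0(dm, tc, 1:30), domain = dm,
                   time_class = tc, peak = rnorm(30, 50, sds[[dm]]),
                   anterior = rnorm(30, 46, sds[[dm]]),
                   posterior = rnorm(30, 54, sds[[dm]]))))))
  }
  a <- mk_features(list(eve_stripe_1 = 1, eve_stripe_6 = 1))
  b <- mk_features(list(eve_stripe_1 = 1, eve_stripe_6 = 4))
  grid <- test_grid(expand.grid(domain = c("eve_stripe_1", "eve_stripe_6",
                                           "eve_stripe_7"),
                                feature = c("peak", "anterior", "posterior"),
                                time_class = paste0("t", 1:2),
                                stringsAsFactors = FALSE))
  res <- run_test_grid(a, b, grid, alpha = 0.005)
  hits <- res[!res$skipped & res$test == "brown_forsythe_var" &
                res$direction == "less" & res$significant, ]
  expect_true(all(hits$domain == "eve_stripe_6"))
  expect_gt(nrow(hits), 0)
  s1 <- res[!res$skipped & res$domain == "eve_stripe_1", ]
  expect_true(all(!s1$significant))
  expect_true(all(res$skipped[res$domain == "eve_stripe_7"]))
})

test_that("a null grid rarely flags anything after Bonferroni", {
  set.seed(6)
  grid <- default_eve_grid(time_classes_ = paste0("t", 1:2))
  n_sig <- replicate(50, {
    mk_feats <- function() {
      cells <- unique(grid$cells[c("domain", "time_class")])
      do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
        data.frame(embryo_id = paste0("e", 1:15), domain = cells$domain[i],
                   time_class = cells$time_class[i],
                   peak = rnorm(15, 50, 1), anterior = rnorm(15, 46, 1),
                   posterior = rnorm(15, 54, 1))))
    }
    res <- run_test_grid(mk_feats(), mk_feats(),
                         test_grid(grid$cells, n_tests = 168),
                         alpha = 0.005)
    sum(res$significant, na.rm = TRUE)
  })
  expect_gte(mean(n_sig == 0), 0.9)
})

test_that("sd_summary uses the sample SD and excludes censored values", {
  f <- data.frame(embryo_id = paste0("e", 1:3), domain = "d",
                  time_class = "t1", peak = c(10, 10, 10),
                  anterior = c(1, 3, NA), posterior = c(NA, NA, NA),
                  width = c(2, NA, NA))
  s <- sd_summary(f)
  expect_equal(s$sd[s$feature == "peak"], 0)
  expect_equal(s$sd[s$feature == "anterior"], sqrt(2))
  expect_equal(s$n[s$feature == "anterior"], 2)
  expect_true(is.na(s$sd[s$feature == "width"]))
  expect_equal(s$n[s$feature == "posterior"], 0)
})

test_that("pattern class frequencies count and normalise per time class", {
  cl <- data.frame(embryo_id = paste0("e", 1:10), genotype = "tll",
                   time_class = "t7", class = rep("six", 10))
  f <- pattern_class_frequencies(cl)
  expect_equal(f$fraction[f$class == "six"], 1)
  expect_equal(f$count[f$class == "six"], 10)

  cl2 <- data.frame(embryo_id = paste0("e", 1:20), genotype = "tll",
                    time_class = "t8",
                    class = rep(c("six", "partial_seven", "full_seven"),
                                c(11, 6, 3)))
  f2 <- pattern_class_frequencies(cl2)
  expect_equal(f2$fraction, c(0.55, 0.30, 0.15))
  expect_equal(sum(f2$fraction), 1)
})

test_that("boundary correlation is exact on affine pairs and near zero under independence", {
  mk <- function(dm, v) data.frame(embryo_id = paste0("e", seq_along(v)),
                                   domain = dm, time_class = "t5",
                                   posterior = v, anterior = v)
  set.seed(7)
  x <- rnorm(50, 68, 1.5)
  f <- rbind(mk("kni_abdominal", x), mk("eve_stripe_6", x + 5))
  r <- boundary_correlation(f, "kni_abdominal", "posterior",
                            "eve_stripe_6", "anterior")
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$n, 50)

  f2 <- rbind(mk("kni_abdominal", rnorm(1000)), mk("eve_stripe_6",
                                                   rnorm(1000)))
  expect_lt(abs(boundary_correlation(f2, "kni_abdominal", "posterior",
                                     "eve_stripe_6", "anterior")$r), 0.1)

  f3 <- rbind(mk("kni_abdominal", rep(1, 5)), mk("eve_stripe_6", rnorm(5)))
  expect_true(boundary_correlation(f3, "kni_abdominal", "posterior",
                                   "eve_stripe_6", "anterior")$undefined)
})

test_that("domains sharing a jitter group produce strongly correlated boundaries", {
  # isolated Kni / Eve-6 pair driven by one shared jitter draw
  pre <- genotype_preset("wildtype", list(
    domain_spec("kni", "kni_abdominal", center = 68, amplitude = 180,
                sigma = 4.5, jitter_sd = 1.2, jitter_group = "pg"),
    domain_spec("eve", "eve_stripe_6", center = 77, amplitude = 180,
                sigma = 1.8, jitter_sd = 2.0, jitter_group = "pg")))
  cohort <- generate_cohort(pre, c(t5 = 50), seed = 61, n_nuclei = 1000)
  feats <- extract_features(cohort, preset = pre)
  r <- boundary_correlation(feats, "kni_abdominal", "posterior",
                            "eve_stripe_6", "anterior")
  expect_gt(r$r, 0.9)
  expect_gte(r$n, 45)
})
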