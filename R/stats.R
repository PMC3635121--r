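#' Directional two-sample Student t-test on mean position
#'
#' Pooled-variance (Student, not Welch) two-sample t-test with a
#' one-sided alternative. `direction = "less"` tests whether the mean
#' of `a` is smaller than that of `b`; `"greater"` the reverse. When the
#' pooled variance is zero the test degenerates: equal means give
#' `p = 0.5` by convention, unequal means give `p` of 0 or 1 by the
#' sign of the difference.
#'
#' @param a,b Numeric vectors of per-embryo feature values (n >= 2).
#' @param direction `"less"` or `"greater"`.
#' @return One-row data frame: `test`, `direction`, `statistic`, `df`,
#'   `p_raw`.
#' @export
t_test_directional <- function(a, b, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need at least 2 values")
  df <- length(a) + length(b) - 2
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    d <- mean(a) - mean(b)
    p <- if (d == 0) 0.5 else {
      match_dir <- (d < 0) == (direction == "less")
      if (match_dir) 0 else 1
    }
    return(data.frame(test = "t_mean", direction = direction,
                      statistic = if (d == 0) 0 else sign(d) * Inf,
                      df = df, p_raw = p, stringsAsFactors = FALSE))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE, alternative = direction)
  data.frame(test = "t_mean", direction = direction,
             statistic = unname(ht$statistic), df = unname(ht$parameter),
             p_raw = ht$p.value, stringsAsFactors = FALSE)
}

#' Directional Brown-Forsythe test on positional variance
#'
#' Levene's variance-equality test computed on absolute deviations from
#' the group *median* (the Brown-Forsythe variant, robust to small
#' samples and mild non-normality). With `Z_ij = |x_ij - median_i|` the
#' statistic is
#' `W = (N - 2) * sum_i n_i (Zbar_i - Zbar)^2 / sum_ij (Z_ij - Zbar_i)^2`
#' for two groups, compared against F(1, N - 2). The F test is
#' inherently one-tailed in W, so the directional p-value is obtained by
#' halving the two-sided p when the observed ordering of the group
#' Z-means matches the requested direction, and `1 - p/2` otherwise
#' (`direction = "greater"` asks whether `a` is more variable than `b`).
#'
#' @param a,b Numeric vectors of per-embryo feature values (n >= 3).
#' @param direction `"less"` or `"greater"`.
#' @return One-row data frame: `test`, `direction`, `statistic`,
#'   `df1`, `df2`, `p_raw`, `p_twosided`, `degenerate`.
#' @export
brown_forsythe <- function(a, b, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("both samples need at least 3 values")
  za <- abs(a - stats::median(a))
  zb <- abs(b - stats::median(b))
  n1 <- length(za); n2 <- length(zb); N <- n1 + n2
  m1 <- mean(za); m2 <- mean(zb)
  grand <- (n1 * m1 + n2 * m2) / N
  num <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  den <- sum((za - m1)^2) + sum((zb - m2)^2)
  if (den == 0) {
    return(data.frame(test = "brown_forsythe_var", direction = direction,
                      statistic = 0, df1 = 1, df2 = N - 2, p_raw = 1,
                      p_twosided = 1, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  W <- (N - 2) * num / den
  p2 <- stats::pf(W, 1, N - 2, lower.tail = FALSE)
  match_dir <- (m1 > m2) == (direction == "greater")
  p_dir <- if (m1 == m2) 0.5 else if (match_dir) p2 / 2 else 1 - p2 / 2
  data.frame(test = "brown_forsythe_var", direction = direction,
             statistic = W, df1 = 1, df2 = N - 2, p_raw = p_dir,
             p_twosided = p2, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Bonferroni correction with an explicit family size
#'
#' @param p_raw Numeric vector of raw p-values in [0, 1].
#' @param n_tests Family size (>= `length(p_raw)` is allowed and typical
#'   when a grid's cells are corrected jointly).
#' @return `pmin(1, p_raw * n_tests)`, order-preserving.
#' @export
bonferroni <- function(p_raw, n_tests) {
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1))
    stop("p-values must lie in [0, 1]")
  if (n_tests < 1) stop("'n_tests' must be >= 1")
  pmin(1, p_raw * n_tests)
}

#' The default Eve comparison grid
#'
#' Seven Eve stripes crossed with three positional features (peak,
#' anterior boundary, posterior boundary) and the eight time classes of
#' cleavage cycle 14A: 168 cells, each Bonferroni-corrected as one
#' family member (the two directions of one test share a cell).
#'
#' @param features Feature kinds per stripe (default peak, anterior,
#'   posterior).
#' @param time_classes_ Time classes included (default `t1`..`t8`).
#' @return Object of class `test_grid`: list with `cells` (data frame
#'   domain/feature/time_class) and `n_tests`.
#' @export
default_eve_grid <- function(features = c("peak", "anterior", "posterior"),
                             time_classes_ = paste0("t", 1:8)) {
  cells <- expand.grid(domain = paste0("eve_stripe_", 1:7),
                       feature = features, time_class = time_classes_,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(list(cells = cells, n_tests = nrow(cells)), class = "test_grid")
}

#' Build a test grid from explicit cells
#'
#' @param cells Data frame with columns `domain`, `feature`,
#'   `time_class`.
#' @param n_tests Family size for Bonferroni correction (default: the
#'   number of cells).
#' @return A `test_grid`.
#' @export
test_grid <- function(cells, n_tests = nrow(cells)) {
  stopifnot(all(c("domain", "feature", "time_class") %in% names(cells)))
  if (!nrow(cells)) stop("invalid argument: empty test grid")
  structure(list(cells = cells, n_tests = n_tests), class = "test_grid")
}

#' @export
print.test_grid <- function(x, ...) {
  cat("test_grid: ", nrow(x$cells), " cells (",
      length(unique(x$cells$domain)), " domains x ",
      length(unique(x$cells$feature)), " features x ",
      length(unique(x$cells$time_class)), " time classes), n_tests = ",
      x$n_tests, "\n", sep = "")
  invisible(x)
}

#' Run the directional test grid comparing two cohorts
#'
#' For every cell (domain x feature x time class) runs both directional
#' Student t-tests on the mean and both directional Brown-Forsythe
#' tests on the variance of the per-embryo feature values of cohort `a`
#' versus cohort `b`, applies the Bonferroni correction with the grid's
#' family size, and flags significance at `alpha` on the corrected
#' p-value. Censored values (NA) are dropped per cell; cells with fewer
#' than 3 values on either side are skipped with a recorded reason.
#'
#' @param features_a,features_b Feature tables from
#'   [extract_features()] (cohorts a and b).
#' @param grid A `test_grid` (default [default_eve_grid()]).
#' @param alpha Significance level on corrected p-values (default
#'   0.005).
#' @return Data frame with one row per cell x test x direction:
#'   `domain`, `feature`, `time_class`, `test`, `direction`, `n_a`,
#'   `n_b`, `statistic`, `p_raw`, `p_corrected`, `significant`,
#'   `skipped`, `skip_reason`.
#' @export
run_test_grid <- function(features_a, features_b, grid = default_eve_grid(),
                          alpha = 0.005) {
  stopifnot(inherits(grid, "test_grid"))
  cells <- grid$cells
  pull <- function(df, domain, tc, feature) {
    v <- df[df$domain == domain & df$time_class == tc, feature]
    v[!is.na(v)]
  }
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    dm <- cells$domain[i]; ft <- cells$feature[i]; tc <- cells$time_class[i]
    va <- pull(features_a, dm, tc, ft)
    vb <- pull(features_b, dm, tc, ft)
    if (length(va) < 3 || length(vb) < 3) {
      rows[[length(rows) + 1L]] <- data.frame(
        domain = dm, feature = ft, time_class = tc, test = NA_character_,
        direction = NA_character_, n_a = length(va), n_b = length(vb),
        statistic = NA_real_, p_raw = NA_real_, p_corrected = NA_real_,
        significant = FALSE, skipped = TRUE,
        skip_reason = "fewer than 3 uncensored values",
        stringsAsFactors = FALSE)
      next
    }
    for (dir in c("less", "greater")) {
      for (res in list(t_test_directional(va, vb, dir),
                       brown_forsythe(va, vb, dir))) {
        rows[[length(rows) + 1L]] <- data.frame(
          domain = dm, feature = ft, time_class = tc, test = res$test,
          direction = dir, n_a = length(va), n_b = length(vb),
          statistic = res$statistic, p_raw = res$p_raw,
          p_corrected = NA_real_, significant = FALSE, skipped = FALSE,
          skip_reason = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  run <- !out$skipped
  out$p_corrected[run] <- bonferroni(out$p_raw[run], grid$n_tests)
  out$significant[run] <- out$p_corrected[run] < alpha
  out
}

#' Per-cell mean/SD summary of positional features
#'
#' @param features Feature table from [extract_features()].
#' @param feature_kinds Which feature columns to summarise.
#' @return Data frame (domain, feature, time_class, mean, sd, n);
#'   sample SD with the n-1 denominator, `NA` when n < 2; censored
#'   values excluded.
#' @export
sd_summary <- function(features,
                       feature_kinds = c("peak", "anterior", "posterior",
                                         "width")) {
  rows <- list()
  for (ft in feature_kinds) {
    agg <- split(features[[ft]],
                 list(features$domain, features$time_class), drop = TRUE)
    for (key in names(agg)) {
      v <- agg[[key]]; v <- v[!is.na(v)]
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        domain = parts[1], feature = ft, time_class = parts[2],
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$domain, out$feature, out$time_class), ]
}

#' Stripe-pattern class frequencies per time class
#'
#' @param classes Data frame from [classify_cohort_stripe7()].
#' @return Data frame (time_class, class, count, fraction); fractions
#'   sum to 1 within each time class.
#' @export
pattern_class_frequencies <- function(classes) {
  lv <- c("six", "partial_seven", "full_seven")
  rows <- list()
  for (tc in unique(classes$time_class)) {
    sub <- classes[classes$time_class == tc, ]
    counts <- table(factor(sub$class, levels = lv))
    rows[[length(rows) + 1L]] <- data.frame(
      time_class = tc, class = lv, count = as.integer(counts),
      fraction = as.numeric(counts) / nrow(sub), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pearson correlation of two boundary features paired by embryo
#'
#' @param features Feature table containing both domains.
#' @param domain_x,feature_x First variable (e.g. the abdominal Kni
#'   posterior boundary).
#' @param domain_y,feature_y Second variable (e.g. the Eve stripe 6
#'   anterior boundary).
#' @param time_class Optional time-class restriction.
#' @return List with `r`, `n` (complete pairs) and `undefined` (TRUE
#'   when either variable has zero variance).
#' @export
boundary_correlation <- function(features, domain_x, feature_x,
                                 domain_y, feature_y, time_class = NULL) {
  sub <- if (is.null(time_class)) features
         else features[features$time_class %in% time_class, ]
  fx <- sub[sub$domain == domain_x, c("embryo_id", feature_x)]
  fy <- sub[sub$domain == domain_y, c("embryo_id", feature_y)]
  names(fx)[2] <- "vx"; names(fy)[2] <- "vy"
  m <- merge(fx, fy, by = "embryo_id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3)
    stop("need at least 3 embryos with both features uncensored")
  if (stats::var(m$vx) == 0 || stats::var(m$vy) == 0)
    return(list(r = NA_real_, n = nrow(m), undefined = TRUE))
  list(r = stats::cor(m$vx, m$vy), n = nrow(m), undefined = FALSE)
}
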