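#' blastovar: positional variability analysis of blastoderm expression
#'
#' Processing of per-nucleus blastoderm expression records into
#' integrated antero-posterior profiles, quadratic-spline extraction of
#' expression-domain features, and embryo-to-embryo variability
#' statistics for comparing canalisation between genotypes, with a
#' seeded synthetic-cohort generator.
#'
#' @keywords internal
"_PACKAGE"

#' Time classes of the late blastoderm
#'
#' Cleavage cycle 13 (`c13`) followed by the eight time classes
#' `t1`--`t8` of cleavage cycle 14A, each a little over 6 minutes long.
#' Domain shifts are modelled as linear in the class index
#' (`c13` = 0, `t1`..`t8` = 1..8).
#'
#' @return Character vector of the nine valid time-class labels, in
#'   temporal order.
#' @export
time_classes <- function() c("c13", paste0("t", 1:8))

#' Numeric index of a time class
#'
#' @param time_class One or more time-class labels.
#' @return Integer index (c13 = 0, t1..t8 = 1..8).
#' @export
time_class_index <- function(time_class) {
  idx <- match(time_class, time_classes())
  if (anyNA(idx)) {
    stop("unknown time class: ", paste(time_class[is.na(idx)], collapse = ", "),
         " (valid: ", paste(time_classes(), collapse = ", "), ")")
  }
  idx - 1L
}

# Run `code` with a private RNG stream seeded at `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, code) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
}

# Deterministic text rendering for tab-delimited outputs: 6 significant
# digits, no scientific notation surprises across platforms.
render_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(signif(v, 6), format = "g", digits = 6)
  }, character(1))
  out
}
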