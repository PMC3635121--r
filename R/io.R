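# Tab-delimited cohort tables: one row per nucleus with columns
# embryo_id, genotype, time_class, nucleus_id, x (%EL), y (%height),
# then one intensity column per gene channel. Numbers are rendered at 6
# significant digits so repeated writes are byte-identical.

#' Write a cohort to a tab-delimited per-nucleus table
#'
#' @param embryos List of `embryo_record`s or a `bv_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(embryos, path) {
  if (inherits(embryos, "bv_cohort")) embryos <- embryos$embryos
  genes <- if (length(embryos))
    setdiff(names(embryos[[1]]$nuclei), c("nucleus_id", "x", "y"))
  else character(0)
  header <- c("embryo_id", "genotype", "time_class", "nucleus_id", "x", "y",
              genes)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  ord <- order(vapply(embryos, `[[`, character(1), "embryo_id"))
  for (e in embryos[ord]) {
    nuc <- e$nuclei[order(e$nuclei$nucleus_id), ]
    cols <- c(list(rep(e$embryo_id, nrow(nuc)), rep(e$genotype, nrow(nuc)),
                   rep(e$time_class, nrow(nuc)),
                   as.character(nuc$nucleus_id),
                   render_num(nuc$x), render_num(nuc$y)),
              lapply(genes, function(g) render_num(nuc[[g]])))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a tab-delimited per-nucleus cohort table
#'
#' Validates the dialect strictly: constant column count, finite
#' coordinates within range, known time classes and one genotype/time
#' class per embryo; violations raise errors naming the offending line.
#'
#' @param path File path.
#' @return List of `embryo_record`s.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1)
    stop("ragged rows: line ",
         which(nf != nf[1])[1], " has ", nf[nf != nf[1]][1],
         " fields, expected ", nf[1])
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  required <- c("embryo_id", "genotype", "time_class", "nucleus_id", "x", "y")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  genes <- setdiff(names(tab), required)
  if (!length(genes)) stop("cohort table has no gene channel columns")
  line <- seq_len(nrow(tab)) + 1L  # header is line 1
  check_range <- function(v, name, lo, hi) {
    bad <- !is.finite(v) | v < lo | v > hi
    if (any(bad))
      stop("parse error at line ", line[bad][1], ": ", name, " = ",
           v[bad][1], " outside [", lo, ", ", hi, "]")
  }
  check_range(tab$x, "x", 0, 100)
  check_range(tab$y, "y", 0, 100)
  for (g in genes) check_range(tab[[g]], g, 0, 255)
  bad_tc <- !(tab$time_class %in% time_classes())
  if (any(bad_tc))
    stop("parse error at line ", line[bad_tc][1],
         ": unknown time class '", tab$time_class[bad_tc][1], "'")
  lapply(split(tab, tab$embryo_id), function(sub) {
    if (length(unique(sub$genotype)) > 1 ||
        length(unique(sub$time_class)) > 1)
      stop("inconsistent metadata for embryo ", sub$embryo_id[1],
           " near line ", line[match(sub$embryo_id[1], tab$embryo_id)])
    structure(list(embryo_id = sub$embryo_id[1],
                   genotype = sub$genotype[1],
                   time_class = sub$time_class[1],
                   nuclei = data.frame(
                     nucleus_id = sub$nucleus_id, x = sub$x, y = sub$y,
                     sub[, genes, drop = FALSE], row.names = NULL)),
              class = "embryo_record")
  })
}

#' Write a ground-truth table
#' @param ground_truth Ground-truth data frame from [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  write_tsv(ground_truth, path)
}

# Generic deterministic TSV writer with optional provenance header.
write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), ": ",
                      unlist(provenance)), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(v) {
      if (is.numeric(v)) render_num(v) else as.character(v)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    quote = "")
}

#' Default run configuration
#'
#' Every pipeline parameter with its default. Presets name the two
#' genotypes compared (`genotype_a` is the reference cohort, typically
#' wild-type-like). `scaling$flip_genes` lists genes whose scaling
#' direction is reversed (reference scaled to target), mirroring the
#' treatment of channels where the mutant staining is the more reliable
#' intensity reference.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    genotype_a = "wildtype",
    genotype_b = "tll",
    generate = list(enabled = TRUE, n_per_class = list(t3 = 40, t8 = 40),
                    n_nuclei = 1000, genes = "eve"),
    cohorts = list(a = NULL, b = NULL),
    strip = list(height_fraction = 0.10),
    background = list(quantile = 0.1, degree = 2),
    registration = list(enabled = TRUE, a_min = 0.9, a_max = 1.1,
                        b_bound = 5),
    smoothing = list(sigma_bins = 1),
    spline = list(smoothing = 0.5, knot_spacing = 1),
    scaling = list(percentile = 0.95, flip_genes = "hkb"),
    features = list(min_rel_amplitude = 0.1, register = FALSE),
    classify = list(rel_amp_partial = 0.15, rel_amp_full = 0.50,
                    valley_frac = 0.50),
    grid = list(name = "default-eve", alpha = 0.005)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Starts from [default_run_config()] and overlays the keys present in
#' the file; unknown keys are rejected with an error naming the key.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, new, prefix = "") {
    for (key in names(new)) {
      full <- paste0(prefix, key)
      if (!key %in% names(base))
        stop("unknown configuration key: '", full, "'")
      if (is.list(base[[key]]) && is.list(new[[key]]) &&
          !key %in% c("n_per_class", "cohorts"))
        base[[key]] <- merge_cfg(base[[key]], new[[key]],
                                 paste0(full, "."))
      else base[[key]] <- new[[key]]
    }
    base
  }
  structure(merge_cfg(unclass(cfg), user), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Drives the whole chain on two genotype cohorts: generation (or
#' loading), lateral-strip extraction, background removal, optional
#' registration, integration into 100-bin profiles, Gaussian smoothing,
#' cross-genotype intensity scaling, per-embryo feature extraction,
#' stripe-7 classification, the directional t / Brown-Forsythe
#' Bonferroni test grid, SD summaries, pattern-class frequency tables
#' and the Kni/Eve boundary correlation where both domains are present.
#' All outputs are tab-delimited tables carrying a provenance header
#' (package version, configuration hash, master seed); re-running with
#' identical inputs reproduces them byte-identically.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`features_a`,
#'   `features_b`, `tests`, `sd_a`, `sd_b`, `classes_b`,
#'   `class_frequencies`, `integrated`, `log`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  prov <- list(package = "blastovar",
               version = as.character(utils::packageVersion("blastovar")),
               config_hash = rlang::hash(unclass(config)),
               seed = config$seed)

  # --- stage: obtain cohorts -------------------------------------------
  cohorts <- list()
  if (isTRUE(config$generate$enabled)) {
    npc <- unlist(config$generate$n_per_class)
    for (side in c("a", "b")) {
      gname <- config[[paste0("genotype_", side)]]
      cohorts[[side]] <- generate_cohort(
        get_preset(gname), npc,
        seed = config$seed + if (side == "a") 0L else 500000L,
        n_nuclei = config$generate$n_nuclei,
        genes = config$generate$genes)
      note("generated ", length(cohorts[[side]]$embryos), " ", gname,
           " embryos")
    }
  } else {
    for (side in c("a", "b")) {
      p <- config$cohorts[[side]]
      if (is.null(p)) stop("config$cohorts$", side,
                           " must be set when generation is disabled")
      recs <- read_cohort(p)
      gt_found <- unique(vapply(recs, `[[`, character(1), "genotype"))
      want <- config[[paste0("genotype_", side)]]
      if (!want %in% gt_found)
        stop("missing genotype: cohort ", side, " (", p,
             ") contains no '", want, "' embryos")
      recs <- Filter(function(r) r$genotype == want, recs)
      cohorts[[side]] <- list(embryos = recs)
      note("loaded ", length(recs), " ", want, " embryos from ", p)
    }
  }

  genes <- config$generate$genes
  if (is.null(genes))
    genes <- setdiff(names(cohorts$a$embryos[[1]]$nuclei),
                     c("nucleus_id", "x", "y"))

  # --- stage: integrated profiles --------------------------------------
  integrated <- list()
  for (side in c("a", "b")) {
    embryos <- cohorts[[side]]$embryos
    tcs <- vapply(embryos, `[[`, character(1), "time_class")
    for (g in genes) for (tc in unique(tcs)) {
      profs <- lapply(embryos[tcs == tc], function(e)
        remove_background(extract_strip(e, g, config$strip$height_fraction),
                          quantile = config$background$quantile,
                          poly_degree = config$background$degree))
      if (isTRUE(config$registration$enabled) && length(profs) >= 2) {
        reg <- register_profiles(
          profs, a_bounds = c(config$registration$a_min,
                              config$registration$a_max),
          b_bound = config$registration$b_bound,
          smoothing = config$spline$smoothing)
        nfail <- sum(!reg$maps$registered)
        if (nfail) note("registration failed for ", nfail, " profiles (",
                        g, ", ", tc, ", cohort ", side, ")")
        profs <- reg$profiles
      }
      ip <- smooth_gaussian(integrate_profiles(profs),
                            config$smoothing$sigma_bins)
      integrated[[paste(side, g, tc, sep = ".")]] <- ip
    }
  }
  # cross-genotype intensity scaling: target (cohort b) onto reference
  # (cohort a), direction flipped for genes listed in scaling$flip_genes
  for (g in genes) {
    flip <- g %in% config$scaling$flip_genes
    for (tc in unique(vapply(cohorts$b$embryos, `[[`, character(1),
                             "time_class"))) {
      ka <- paste("a", g, tc, sep = "."); kb <- paste("b", g, tc, sep = ".")
      if (is.null(integrated[[ka]]) || is.null(integrated[[kb]])) next
      if (flip) {
        sc <- scale_to_reference(integrated[[ka]], integrated[[kb]],
                                 config$scaling$percentile)
        integrated[[ka]] <- sc$profile
      } else {
        sc <- scale_to_reference(integrated[[kb]], integrated[[ka]],
                                 config$scaling$percentile)
        integrated[[kb]] <- sc$profile
      }
      note("scaled ", g, " ", tc, " by factor ",
           signif(sc$factor, 4), if (flip) " (flipped direction)" else "")
    }
  }
  ip_rows <- lapply(names(integrated), function(k) {
    ip <- integrated[[k]]
    data.frame(genotype = ip$genotype, gene = ip$gene,
               time_class = ip$time_class, bin = 0:99, value = ip$bins,
               n_embryos = ip$n_embryos, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, ip_rows),
            file.path(out_dir, "integrated_profiles.tsv"), prov)

  # --- stage: per-embryo features --------------------------------------
  features <- list()
  for (side in c("a", "b")) {
    gname <- config[[paste0("genotype_", side)]]
    features[[side]] <- extract_features(
      cohorts[[side]]$embryos, preset = get_preset(gname), genes = genes,
      height_fraction = config$strip$height_fraction,
      bg_quantile = config$background$quantile,
      bg_degree = config$background$degree,
      smoothing = config$spline$smoothing,
      min_rel_amplitude = config$features$min_rel_amplitude,
      register = isTRUE(config$features$register))
    cens <- sum(features[[side]]$censored != "")
    note("cohort ", side, ": ", nrow(features[[side]]),
         " feature rows, ", cens, " with censored boundaries")
    write_tsv(features[[side]],
              file.path(out_dir, paste0("features_", side, ".tsv")), prov)
  }

  # --- stage: statistics ------------------------------------------------
  grid <- default_eve_grid()
  tests <- run_test_grid(features$a, features$b, grid,
                         alpha = config$grid$alpha)
  write_tsv(tests, file.path(out_dir, "test_grid.tsv"), prov)
  note(sum(tests$significant), " of ", sum(!tests$skipped),
       " test rows significant at corrected alpha ", config$grid$alpha)

  sd_a <- sd_summary(features$a); sd_b <- sd_summary(features$b)
  write_tsv(sd_a, file.path(out_dir, "sd_summary_a.tsv"), prov)
  write_tsv(sd_b, file.path(out_dir, "sd_summary_b.tsv"), prov)

  classes_b <- NULL; freq <- NULL
  if ("eve" %in% genes) {
    classes_b <- classify_cohort_stripe7(
      cohorts$b$embryos, preset = get_preset(config$genotype_b),
      height_fraction = config$strip$height_fraction,
      bg_quantile = config$background$quantile,
      bg_degree = config$background$degree,
      smoothing = config$spline$smoothing,
      rel_amp_partial = config$classify$rel_amp_partial,
      rel_amp_full = config$classify$rel_amp_full,
      valley_frac = config$classify$valley_frac)
    freq <- pattern_class_frequencies(classes_b)
    write_tsv(classes_b, file.path(out_dir, "stripe7_classes_b.tsv"), prov)
    write_tsv(freq, file.path(out_dir, "stripe7_frequencies_b.tsv"), prov)
  }

  correlations <- NULL
  if (all(c("eve", "kni") %in% genes)) {
    rows <- lapply(c("a", "b"), function(side) {
      r <- tryCatch(
        boundary_correlation(features[[side]], "kni_abdominal", "posterior",
                             "eve_stripe_6", "anterior"),
        error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(cohort = side, x = "kni_abdominal.posterior",
                 y = "eve_stripe_6.anterior", r = r$r, n = r$n,
                 stringsAsFactors = FALSE)
    })
    correlations <- do.call(rbind, rows)
    if (!is.null(correlations) && nrow(correlations))
      write_tsv(correlations, file.path(out_dir, "boundary_correlations.tsv"),
                prov)
  }

  writeLines(c(paste0("# ", names(prov), ": ", unlist(prov)), log_lines),
             file.path(out_dir, "run_log.txt"))
  invisible(list(features_a = features$a, features_b = features$b,
                 tests = tests, sd_a = sd_a, sd_b = sd_b,
                 classes_b = classes_b, class_frequencies = freq,
                 correlations = correlations,
                 integrated = integrated, log = log_lines))
}
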