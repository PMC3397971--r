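#' Build a run configuration for the full pipeline
#'
#' Collects everything a reproducible end-to-end run needs: the task variant,
#' cohort size, trial counts, coherence source, generative observer, staircase
#' constants, bootstrap size for the model comparisons, the minimum-trial filter
#' and one master seed from which all stage seeds are derived. The configuration
#' round-trips losslessly through YAML/JSON via [write_config()]/[read_config()].
#'
#' @param variant Task variant, one of `"SN"`, `"SW"`, `"FN"`, `"FW"`.
#' @param n_subjects,n_trials Cohort size and per-subject trial count (single
#'   number or `c(min, max)` range); `NULL` uses [variant_defaults()].
#' @param coherence_mode `"fixed"` or `"staircase"`.
#' @param levels Fixed coherence levels (%).
#' @param levels_invalid Optional separate invalid-cue levels
#'   (matched-performance control design).
#' @param observer An [observer_params()] object.
#' @param subject_sd Between-subject relative SD of thresholds.
#' @param staircase A [staircase_options()] list.
#' @param n_sims Bootstrap simulations per model comparison. Default 1000 — a
#'   desk-scale reduction of the emulated analysis' 10000, overridable here.
#' @param min_trials Minimum-trial filter for cell inclusion, default 90.
#' @param filter_scope `"level"` or `"cell"` (see [cell_means()]).
#' @param pairing Pairing unit for the certainty-vs-accuracy Δz test:
#'   `"subject"` (default; one averaged pair per subject, pairs independent) or
#'   `"cell"` (one pair per subject and coherence level).
#' @param lambda Lapse policy for the psychometric fits (`NULL` = free).
#' @param seed Master integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(variant = "SN", n_subjects = NULL, n_trials = NULL,
                       coherence_mode = "fixed", levels = c(5, 20, 50, 100),
                       levels_invalid = NULL, observer = observer_params(),
                       subject_sd = 0.12, staircase = staircase_options(),
                       n_sims = 1000, min_trials = 90,
                       filter_scope = "level", pairing = "subject",
                       lambda = NULL, seed = 1) {
  cfg <- list(
    variant = match.arg(variant, .variants),
    n_subjects = n_subjects, n_trials = n_trials,
    coherence_mode = coherence_mode, levels = levels,
    levels_invalid = levels_invalid, observer = observer,
    subject_sd = subject_sd, staircase = staircase, n_sims = n_sims,
    min_trials = min_trials, filter_scope = filter_scope,
    pairing = match.arg(pairing, c("subject", "cell")), lambda = lambda,
    seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()] object.
#' @param path File path; `.yaml`/`.yml` uses YAML (requires the yaml package),
#'   anything else JSON.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   restored `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- unclass(config)
  plain$observer <- unclass(config$observer)
  plain$staircase <- unclass(config$staircase)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(plain, path)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  plain <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  obs <- do.call(observer_params, plain$observer)
  stair <- do.call(staircase_options, plain$staircase)
  args <- plain[setdiff(names(plain), c("observer", "staircase"))]
  args <- lapply(args, function(x) if (length(x) == 0) NULL else x)
  do.call(run_config, c(args, list(observer = obs, staircase = stair)))
}

# Derived per-stage seeds, kept below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 977L + stage * 9973L) %% 2147483629L
}

#' Run the full simulate → fit → compare → group-statistics pipeline
#'
#' Executes every analysis stage for one task variant: simulates the cohort,
#' fits the four psychometric functions (accuracy/certainty × valid/invalid),
#' runs the six Monte-Carlo model comparisons (accuracy valid-vs-invalid,
#' certainty valid-vs-invalid, accuracy-vs-certainty within each cue condition,
#' and certainty valid-vs-invalid restricted to correct and to incorrect choices),
#' computes cell means, z-standardized values and attention deltas, runs the
#' paired tests (accuracy Δz, certainty Δz, and certainty-vs-accuracy Δz), and
#' repeats the Δz statistics for the control subsets (non-congruent trials only;
#' coherences below 50%; modified-z outlier screen; overlapping coherences when
#' the design uses distinct invalid-cue levels). Every stochastic stage receives
#' a seed derived from the master seed.
#'
#' @param config A [run_config()] object.
#' @param out_dir Optional directory: when given, trial tables and result tables
#'   are written as provenance-stamped CSV plus a JSON report.
#' @return A list of class `attencert_run` with elements `config`, `trials`,
#'   `fits` (named list of `pf_fit`), `comparisons` (named list of
#'   `pf_comparison`), `cells`, `deltas`, `tests` (tibble), and `controls`
#'   (named list of rerun Δz test tibbles with exclusion manifests).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  trials <- simulate_experiment(
    variant = config$variant, n_subjects = config$n_subjects,
    n_trials = config$n_trials, params = config$observer,
    coherence_mode = config$coherence_mode, levels = config$levels,
    levels_invalid = config$levels_invalid, subject_sd = config$subject_sd,
    staircase = config$staircase, seed = stage_seed(config$seed, 1L)
  )

  fits <- list(
    accuracy_valid = fit_pf(pf_data(trials, "accuracy", "valid"), lambda = config$lambda),
    accuracy_invalid = fit_pf(pf_data(trials, "accuracy", "invalid"), lambda = config$lambda),
    certainty_valid = fit_pf(pf_data(trials, "certainty", "valid"), lambda = config$lambda),
    certainty_invalid = fit_pf(pf_data(trials, "certainty", "invalid"), lambda = config$lambda)
  )

  correct_tr <- control_subsets(trials, "correct_only")
  incorrect_tr <- control_subsets(trials, "incorrect_only")
  comparison_specs <- list(
    accuracy_valid_vs_invalid = list(
      pf_data(trials, "accuracy", "valid"), pf_data(trials, "accuracy", "invalid")
    ),
    certainty_valid_vs_invalid = list(
      pf_data(trials, "certainty", "valid"), pf_data(trials, "certainty", "invalid")
    ),
    accuracy_vs_certainty_valid = list(
      pf_data(trials, "accuracy", "valid"), pf_data(trials, "certainty", "valid")
    ),
    accuracy_vs_certainty_invalid = list(
      pf_data(trials, "accuracy", "invalid"), pf_data(trials, "certainty", "invalid")
    ),
    certainty_valid_vs_invalid_correct = list(
      pf_data(correct_tr, "certainty", "valid"), pf_data(correct_tr, "certainty", "invalid")
    ),
    certainty_valid_vs_invalid_incorrect = list(
      pf_data(incorrect_tr, "certainty", "valid"), pf_data(incorrect_tr, "certainty", "invalid")
    )
  )
  comparisons <- purrr::imap(comparison_specs, function(dd, nm) {
    mc_model_comparison(
      dd[[1]], dd[[2]],
      n_sims = config$n_sims, lambda = config$lambda,
      seed = stage_seed(config$seed, 2L + match(nm, names(comparison_specs)))
    )
  })

  group <- delta_z_report(trials,
    min_trials = config$min_trials,
    filter_scope = config$filter_scope,
    pairing = config$pairing
  )
  controls <- run_controls(trials, config)

  run <- structure(
    list(
      config = config, trials = trials, fits = fits, comparisons = comparisons,
      cells = group$cells, deltas = group$deltas, tests = group$tests,
      controls = controls
    ),
    class = "attencert_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Cells -> z -> deltas -> paired tests for one trial table. Pairing unit for
# the certainty-vs-accuracy test: "subject" (default) averages each subject's
# deltas per measure so pairs are independent across subjects; "cell" pairs
# subject x coherence cells directly (cells within a subject share a z-pool,
# which makes this variant anticonservative — kept for sensitivity analyses).
delta_z_report <- function(trials, min_trials = 90, filter_scope = "level",
                           pairing = c("subject", "cell")) {
  pairing <- match.arg(pairing)
  cells <- zstandardize(cell_means(trials, min_trials, filter_scope))
  deltas <- delta_z(cells)
  tests <- NULL
  paired_units <- if (pairing == "subject") {
    deltas |>
      dplyr::group_by(.data$subject_id, .data$measure) |>
      dplyr::summarise(delta = mean(.data$delta), .groups = "drop")
  } else {
    deltas
  }
  wide <- paired_units |>
    tidyr::pivot_wider(names_from = "measure", values_from = "delta") |>
    dplyr::filter(!is.na(.data$accuracy), !is.na(.data$certainty))
  if (nrow(wide) >= 2) {
    zero <- function(x) rep(0, length(x))
    tests <- dplyr::bind_rows(
      dplyr::mutate(paired_t(wide$accuracy, zero(wide$accuracy)),
        comparison = "accuracy delta vs 0"
      ),
      dplyr::mutate(paired_t(wide$certainty, zero(wide$certainty)),
        comparison = "certainty delta vs 0"
      ),
      dplyr::mutate(paired_t(wide$certainty, wide$accuracy),
        comparison = "certainty vs accuracy delta"
      )
    )
  }
  list(cells = cells, deltas = deltas, tests = tests)
}

run_controls <- function(trials, config) {
  rerun <- function(tr) {
    delta_z_report(tr, config$min_trials, config$filter_scope, config$pairing)$tests
  }
  controls <- list()
  nc <- control_subsets(trials, "noncongruent_only")
  controls$noncongruent_only <- list(
    tests = rerun(nc), manifest = attr(nc, "manifest")
  )
  lo <- control_subsets(trials, "coherence_below_50")
  controls$coherence_below_50 <- list(
    tests = rerun(lo), manifest = attr(lo, "manifest")
  )
  # outlier screen: drop subject x coherence cells whose accuracy or certainty
  # mean is a gross outlier by the modified z-score, then rerun
  cells <- cell_means(trials, config$min_trials, config$filter_scope)
  wide <- tidyr::pivot_wider(cells,
    names_from = "measure", values_from = "mean_value",
    id_cols = c("subject_id", "condition", "coherence")
  )
  keep <- rep(TRUE, nrow(wide))
  if (nrow(wide) >= 3) {
    suppressWarnings({
      keep <- modified_z_outliers(wide$accuracy) & modified_z_outliers(wide$certainty)
    })
  }
  bad <- wide[!keep, c("subject_id", "coherence", "condition")]
  screened <- dplyr::anti_join(trials,
    dplyr::mutate(bad, cue_valid = bad$condition == "valid"),
    by = c("subject_id", "coherence", "cue_valid")
  )
  controls$outlier_screened <- list(
    tests = rerun(screened),
    manifest = list(
      mode = "modified_z_outliers", n_cells_excluded = sum(!keep),
      fraction_cells_excluded = if (nrow(wide)) sum(!keep) / nrow(wide) else 0
    )
  )
  if (!is.null(config$levels_invalid)) {
    ov <- control_subsets(trials, "overlapping_coherences")
    controls$overlapping_coherences <- list(
      tests = rerun(ov), manifest = attr(ov, "manifest")
    )
  }
  controls
}

#' @export
print.attencert_run <- function(x, ...) {
  cat(sprintf(
    "<attencert_run: %s>  %d subjects, %d trials, seed %d\n",
    x$config$variant, dplyr::n_distinct(x$trials$subject_id),
    nrow(x$trials), x$config$seed
  ))
  cat("comparisons:\n")
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf(
      "  %-38s TLR = %8.2f  MC p = %.4f%s\n", nm, cmp$tlr_observed, cmp$p_mc,
      if (cmp$significant) " *" else ""
    ))
  }
  if (!is.null(x$tests)) {
    cat("delta-z paired tests:\n")
    for (i in seq_len(nrow(x$tests))) {
      cat(sprintf(
        "  %-38s t = %6.2f  p = %.2g  (n = %d)\n",
        x$tests$comparison[i], x$tests$t[i], x$tests$p_value[i], x$tests$n[i]
      ))
    }
  }
  invisible(x)
}

# Write a run bundle: provenance-stamped CSVs + JSON report.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  stamp <- sprintf(
    "attencert run: variant=%s seed=%d config_hash=%s",
    cfg$variant, cfg$seed, config_hash(cfg)
  )
  write_trials(run$trials, file.path(out_dir, "trials.csv"), comment = stamp)
  write_stamped_csv(run$cells, file.path(out_dir, "cells.csv"), stamp)
  write_stamped_csv(run$deltas, file.path(out_dir, "deltas.csv"), stamp)
  report <- list(
    stamp = stamp,
    config = config_plain(cfg),
    fits = purrr::map(run$fits, function(f) {
      list(
        alpha = f$alpha, beta = f$beta, gamma = f$gamma, lambda = f$lambda,
        loglik = f$loglik, n_trials = f$n_trials
      )
    }),
    comparisons = purrr::map(run$comparisons, function(cmp) {
      list(
        tlr = cmp$tlr_observed, p_mc = cmp$p_mc, n_sims = cmp$n_sims,
        significant = cmp$significant
      )
    }),
    tests = run$tests,
    controls = purrr::map(run$controls, function(ct) {
      list(tests = ct$tests, manifest = ct$manifest)
    })
  )
  jsonlite::write_json(
    report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(out_dir)
}

write_stamped_csv <- function(df, path, stamp) {
  writeLines(paste0("# ", stamp), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

config_plain <- function(config) {
  p <- unclass(config)
  p$observer <- unclass(p$observer)
  p$staircase <- unclass(p$staircase)
  p
}

# Small content hash of the serialized config (FNV-1a over the JSON bytes;
# provenance stamp only, not cryptographic).
config_hash <- function(config) {
  txt <- jsonlite::toJSON(
    config_plain(config),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  bytes <- as.integer(charToRaw(as.character(txt)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write deterministic fixture trial tables
#'
#' Produces small trial CSVs for tests and examples: `tiny` writes 2 subjects
#' with 200 trials each; `standard` emulates the spatial-attention/ratings
#' cohort (13 subjects, 1000–1100 trials each).
#'
#' @param size `"tiny"` or `"standard"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(size = c("tiny", "standard"), seed = 7, dir = ".") {
  size <- match.arg(size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- switch(size,
    tiny = list(n_subjects = 2, n_trials = 200),
    standard = list(n_subjects = 13, n_trials = c(1000, 1100))
  )
  trials <- simulate_experiment(
    "SN",
    n_subjects = spec$n_subjects, n_trials = spec$n_trials, seed = seed
  )
  path <- file.path(dir, sprintf("fixture_%s.csv", size))
  write_trials(trials, path, comment = sprintf("attencert fixture size=%s seed=%d", size, seed))
  invisible(path)
}
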