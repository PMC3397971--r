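#' Map raw confidence reports to the certainty index
#'
#' Recodes confidence onto the `[0.25, 1]` certainty-index scale shared with
#' accuracy: numerical ratings 0/1/2/3 become 0.25/0.50/0.75/1.0 and wagers
#' low/high become 0.25/1.0, so the index floor matches 4AFC chance and its
#' ceiling matches perfect discrimination.
#'
#' @param raw Vector of raw reports: ratings in 0–3 (numeric or character) for
#'   the rating variants, `"low"`/`"high"` for the wagering variants.
#' @param variant One of `"SN"`, `"FN"` (ratings) or `"SW"`, `"FW"` (wagers);
#'   scalar or vector recycled against `raw`.
#' @return Numeric vector with values in {0.25, 0.5, 0.75, 1}.
#' @examples
#' map_confidence(c(0, 1, 2, 3), "SN")
#' map_confidence(c("low", "high"), "SW")
#' @export
map_confidence <- function(raw, variant) {
  if (length(variant) == 1) variant <- rep(variant, length(raw))
  stopifnot(length(variant) == length(raw), all(variant %in% .variants))
  is_rating <- variant %in% .rating_variants
  out <- rep(NA_real_, length(raw))
  if (any(is_rating)) {
    r <- suppressWarnings(as.numeric(raw[is_rating]))
    if (any(is.na(r)) || any(!r %in% 0:3)) {
      stop("rating confidence must be in 0..3", call. = FALSE)
    }
    out[is_rating] <- 0.25 + 0.25 * r
  }
  if (any(!is_rating)) {
    w <- as.character(raw[!is_rating])
    if (any(!w %in% c("low", "high"))) {
      stop("wager confidence must be 'low' or 'high'", call. = FALSE)
    }
    out[!is_rating] <- ifelse(w == "high", 1, 0.25)
  }
  out
}

#' Per-cell means of accuracy and certainty with the minimum-trial filter
#'
#' Summarizes trials into cells — one per subject, measure (accuracy/certainty),
#' cue condition (valid/invalid) and coherence level — carrying the cell mean
#' (`mean_value`: proportion correct, or mean certainty index) and an inclusion
#' flag for the downstream z-pools. By default a subject's coherence level is
#' included when it carries at least `min_trials` trials counted across both cue
#' conditions (`filter_scope = "level"`); `filter_scope = "cell"` applies the
#' count to each condition cell separately.
#'
#' @param trials Trial tibble.
#' @param min_trials Minimum trial count for inclusion, default 90.
#' @param filter_scope `"level"` (default) or `"cell"`; see Details above.
#' @return A tibble of cells: `subject_id`, `measure`, `condition`, `coherence`,
#'   `n_trials`, `mean_value`, `included`. Empty input yields an empty tibble.
#' @export
cell_means <- function(trials, min_trials = 90, filter_scope = c("level", "cell")) {
  filter_scope <- match.arg(filter_scope)
  if (nrow(trials) == 0) {
    return(tibble::tibble(
      subject_id = character(0), measure = character(0), condition = character(0),
      coherence = numeric(0), n_trials = integer(0), mean_value = numeric(0),
      included = logical(0)
    ))
  }
  cells <- trials |>
    dplyr::mutate(condition = ifelse(.data$cue_valid, "valid", "invalid")) |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$coherence) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy = mean(.data$correct),
      certainty = mean(.data$certainty_index),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(
      c("accuracy", "certainty"),
      names_to = "measure", values_to = "mean_value"
    )
  cells <- if (filter_scope == "cell") {
    dplyr::mutate(cells, included = .data$n_trials >= min_trials)
  } else {
    cells |>
      dplyr::group_by(.data$subject_id, .data$coherence) |>
      dplyr::mutate(included = sum(.data$n_trials) / 2 >= min_trials) |>
      dplyr::ungroup()
  }
  dplyr::select(
    cells, "subject_id", "measure", "condition", "coherence",
    "n_trials", "mean_value", "included"
  ) |>
    dplyr::arrange(.data$subject_id, .data$measure, .data$condition, .data$coherence)
}

#' Z-standardize cell means within subject and measure
#'
#' Standardizes each subject's included cell means of one measure — valid and
#' invalid conditions pooled — to mean 0 and SD 1, the common scale on which
#' accuracy and certainty changes can be compared without committing to the
#' numerical coding of the certainty categories (the transform is invariant to
#' any affine recoding of equidistant categories). Excluded cells receive
#' `z_value = NA` and never enter the pools.
#'
#' @param cells Output of [cell_means()].
#' @return `cells` with a `z_value` column. Subject-measure pools with fewer than
#'   2 included cells or zero spread are flagged: their `z_value` is `NA` and
#'   they are listed in the `"standardization_failures"` attribute.
#' @export
zstandardize <- function(cells) {
  failures <- cells |>
    dplyr::filter(.data$included) |>
    dplyr::group_by(.data$subject_id, .data$measure) |>
    dplyr::summarise(
      n_cells = dplyr::n(), spread = sd(.data$mean_value), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_cells < 2 | .data$spread == 0 | is.na(.data$spread))
  out <- cells |>
    dplyr::group_by(.data$subject_id, .data$measure) |>
    dplyr::mutate(
      z_value = {
        pool <- .data$mean_value[.data$included]
        m <- mean(pool)
        s <- sd(pool)
        ifelse(.data$included & length(pool) >= 2 & !is.na(s) & s > 0,
          (.data$mean_value - m) / s, NA_real_
        )
      }
    ) |>
    dplyr::ungroup()
  if (nrow(failures) > 0) {
    attr(out, "standardization_failures") <- failures
  }
  out
}

#' Attention-related differences of standardized cell means
#'
#' Pairs each subject's valid and invalid z-values at matched measure and
#' coherence and returns `delta = z(valid) - z(invalid)`; positive values mean
#' the measure increased with attention. Cells without a matched partner (or
#' without a z-value) are skipped and counted in the `"n_unmatched"` attribute.
#'
#' @param cells Output of [zstandardize()].
#' @return A tibble `subject_id`, `measure`, `coherence`, `delta`.
#' @export
delta_z <- function(cells) {
  wide <- cells |>
    dplyr::filter(!is.na(.data$z_value)) |>
    dplyr::select("subject_id", "measure", "condition", "coherence", "z_value") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "z_value")
  if (!"valid" %in% names(wide)) wide$valid <- NA_real_
  if (!"invalid" %in% names(wide)) wide$invalid <- NA_real_
  unmatched <- sum(is.na(wide$valid) | is.na(wide$invalid))
  out <- wide |>
    dplyr::filter(!is.na(.data$valid), !is.na(.data$invalid)) |>
    dplyr::mutate(delta = .data$valid - .data$invalid) |>
    dplyr::select("subject_id", "measure", "coherence", "delta")
  attr(out, "n_unmatched") <- unmatched
  out
}

#' Classical paired t-test
#'
#' Textbook paired t: `t = mean(d) / (sd(d) / sqrt(n))` on differences
#' `d = x - y`, with a two-sided p from the t distribution on `n - 1` degrees of
#' freedom. When all differences are exactly zero the statistic is reported as 0
#' with an undefined (`NA`) p-value; a nonzero constant difference (zero variance
#' around a nonzero mean) is an error.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2).
#' @return A one-row tibble: `t`, `df`, `p_value`, `n`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2) stop("paired_t needs >= 2 complete pairs", call. = FALSE)
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) {
      return(tibble::tibble(t = 0, df = n - 1, p_value = NA_real_, n = n, mean_diff = 0))
    }
    stop("paired_t: zero variance of nonzero differences", call. = FALSE)
  }
  t_stat <- m / (s / sqrt(n))
  tibble::tibble(
    t = t_stat, df = n - 1,
    p_value = 2 * pt(-abs(t_stat), n - 1),
    n = n, mean_diff = m
  )
}

#' Robust outlier screen via modified z-scores
#'
#' Flags gross outliers with the modified z-score
#' `M_i = 0.6745 (x_i - median) / MAD`, where MAD is the median absolute
#' deviation about the median; values with `|M| > criterion` (default 3.5, the
#' standard cut) are excluded. Used as a numerical guide for sensitivity reruns,
#' not as a significance test. A zero MAD (e.g. all values equal) yields a
#' warning and no exclusions.
#'
#' @param values Numeric vector (>= 3 values).
#' @param criterion Exclusion bound on `|M|`, default 3.5.
#' @return Logical inclusion mask (TRUE = keep), with the scores in the
#'   `"modified_z"` attribute.
#' @examples
#' modified_z_outliers(c(1, 1.2, 0.9, 1.1, 100))
#' @export
modified_z_outliers <- function(values, criterion = 3.5) {
  stopifnot(length(values) >= 3)
  med <- median(values)
  mad_raw <- median(abs(values - med))
  if (mad_raw == 0) {
    warning("MAD is zero; no values excluded", call. = FALSE)
    mask <- rep(TRUE, length(values))
    attr(mask, "modified_z") <- rep(0, length(values))
    return(mask)
  }
  m <- 0.6745 * (values - med) / mad_raw
  mask <- abs(m) <= criterion
  attr(mask, "modified_z") <- m
  mask
}

#' Rating frequencies around each observer's certainty threshold
#'
#' For each subject, fits the certainty psychometric function to the supplied
#' trials, locates the coherence at which the certainty index reaches 0.625 (the
#' inflection point for a zero-lapse fit), and tabulates how often each rating
#' 0–3 was used within `threshold +/- window` % coherence. If observers use the
#' equidistant categories uniformly, the lowest and highest ratings (and the two
#' middle ones) should be equally frequent in this band; the group-level paired
#' t-tests 0 vs 3, 1 vs 2 and (0+1) vs (2+3) check exactly that. Subjects whose
#' certainty threshold is undefined (e.g. certainty never reaches 0.625 within
#' the coherence range) are skipped and counted.
#'
#' @param trials Trial tibble from a rating variant (`SN`/`FN`), typically
#'   already restricted to one cue condition.
#' @param window Half-width of the coherence band in percentage points,
#'   default 10.
#' @param lambda Lapse policy for the per-subject certainty fits (default fixed
#'   at 0, making the 0.625 criterion the inflection point).
#' @param thresholds Optional externally supplied certainty thresholds: a data
#'   frame with columns `subject_id` and `threshold` (e.g. thresholds from a
#'   separate fit, or known generative thresholds in simulation studies). When
#'   `NULL` (default) each subject's threshold is estimated by fitting the
#'   certainty psychometric function to the supplied trials.
#' @return A list with `frequencies` (tibble: `subject_id`, `threshold`,
#'   `n_trials_window`, `f0`–`f3` relative frequencies), `tests` (tibble of the
#'   three paired comparisons) and `n_skipped`.
#' @export
rating_frequencies <- function(trials, window = 10, lambda = 0, thresholds = NULL) {
  stopifnot(all(trials$variant %in% .rating_variants))
  per_subject <- trials |>
    dplyr::group_split(.data$subject_id) |>
    purrr::map(function(tr) {
      if (!is.null(thresholds)) {
        hit <- match(tr$subject_id[1], thresholds$subject_id)
        thr <- if (is.na(hit)) NA_real_ else thresholds$threshold[hit]
      } else {
        fit <- tryCatch(
          fit_pf(pf_data(tr, "certainty", "pooled"), lambda = lambda),
          error = function(e) NULL
        )
        thr <- if (is.null(fit)) NA_real_ else threshold_at(fit, 0.625)
      }
      if (is.na(thr)) {
        return(tibble::tibble(subject_id = tr$subject_id[1], threshold = NA_real_))
      }
      win <- dplyr::filter(
        tr, .data$coherence >= thr - window, .data$coherence <= thr + window
      )
      if (nrow(win) == 0) {
        return(tibble::tibble(subject_id = tr$subject_id[1], threshold = thr))
      }
      counts <- table(factor(win$confidence_raw, levels = as.character(0:3)))
      freq <- as.numeric(counts) / nrow(win)
      tibble::tibble(
        subject_id = tr$subject_id[1], threshold = thr,
        n_trials_window = nrow(win),
        f0 = freq[1], f1 = freq[2], f2 = freq[3], f3 = freq[4]
      )
    }) |>
    dplyr::bind_rows()
  ok <- if ("f0" %in% names(per_subject)) {
    dplyr::filter(per_subject, !is.na(.data$threshold), !is.na(.data$f0))
  } else {
    per_subject[0, ]
  }
  n_skipped <- nrow(per_subject) - nrow(ok)
  tests <- NULL
  if (nrow(ok) >= 2) {
    tests <- dplyr::bind_rows(
      dplyr::mutate(paired_t(ok$f0, ok$f3), comparison = "0 vs 3"),
      dplyr::mutate(paired_t(ok$f1, ok$f2), comparison = "1 vs 2"),
      dplyr::mutate(paired_t(ok$f0 + ok$f1, ok$f2 + ok$f3), comparison = "low vs high")
    )
  }
  list(frequencies = ok, tests = tests, n_skipped = n_skipped)
}

#' Control-analysis trial subsets
#'
#' Pure filters implementing the sensitivity reruns: `noncongruent_only` drops
#' the ~25% of trials where both stimuli carried the same direction (which make
#' some invalid cues effectively valid); `coherence_below_50` keeps the rising
#' part of the psychometric function (strictly < 50% coherence) to rule out
#' ceiling effects; `correct_only` / `incorrect_only` split by choice outcome;
#' `overlapping_coherences` keeps, per subject, only coherence levels presented
#' under both cue conditions (matched-performance design).
#'
#' @param trials Trial tibble.
#' @param mode One of `"noncongruent_only"`, `"coherence_below_50"`,
#'   `"correct_only"`, `"incorrect_only"`, `"overlapping_coherences"`.
#' @return The filtered tibble with a `"manifest"` attribute recording mode and
#'   exclusion counts.
#' @export
control_subsets <- function(trials,
                            mode = c(
                              "noncongruent_only", "coherence_below_50",
                              "correct_only", "incorrect_only",
                              "overlapping_coherences"
                            )) {
  mode <- match.arg(mode)
  out <- switch(mode,
    noncongruent_only = dplyr::filter(trials, !.data$congruent),
    coherence_below_50 = dplyr::filter(trials, .data$coherence < 50),
    correct_only = dplyr::filter(trials, .data$correct),
    incorrect_only = dplyr::filter(trials, !.data$correct),
    overlapping_coherences = trials |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::filter({
        lv <- unique(.data$coherence[.data$cue_valid])
        li <- unique(.data$coherence[!.data$cue_valid])
        .data$coherence %in% intersect(lv, li)
      }) |>
      dplyr::ungroup()
  )
  attr(out, "manifest") <- list(
    mode = mode, n_before = nrow(trials), n_after = nrow(out),
    n_excluded = nrow(trials) - nrow(out)
  )
  out
}
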