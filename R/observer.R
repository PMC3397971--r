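#' Parametric synthetic observer for 4AFC motion-coherence discrimination
#'
#' Defines the generative model used to simulate choices and confidence reports.
#' The observer is purely a modeling construct of this package: accuracy follows a
#' logistic psychometric function of motion coherence between the 4AFC chance floor
#' (0.25) and an upper asymptote `1 - lapse`, with a lower (better) threshold when
#' the attention cue is valid. Internal confidence follows its own logistic of
#' coherence — on the certainty-index scale `[0.25, 1]` — with trial-to-trial
#' Gaussian jitter, and is discretized into 4-level numerical ratings or binary
#' wagers. Attention may shift the confidence threshold more than the accuracy
#' threshold, which is the dissociation the downstream statistics are designed to
#' detect.
#'
#' @param acc_threshold_valid,acc_threshold_invalid Coherence (%) at which
#'   P(correct) crosses the 62.5% midpoint for valid / invalid cues. Valid must
#'   not exceed invalid (attention helps).
#' @param acc_slope Logistic slope of the accuracy function, per % coherence.
#' @param lapse Lapse probability in `[0, 0.06]`; caps the accuracy asymptote at
#'   `1 - lapse`.
#' @param cert_threshold_valid,cert_threshold_invalid Coherence (%) at which the
#'   expected certainty index crosses 0.625 for valid / invalid cues.
#' @param cert_slope Logistic slope of the confidence function, per % coherence.
#' @param cert_noise_sd Trial-to-trial SD of internal confidence, in certainty-index
#'   units.
#' @param cert_correct_boost Optional additive shift (index units) of internal
#'   confidence on correct trials, coupling confidence to the choice outcome.
#'   Default 0: confidence depends on coherence and cue only, not on whether the
#'   particular choice succeeded.
#' @param rating_cuts Three strictly increasing cut points in (0, 1) discretizing
#'   rescaled internal confidence into ratings 0–3.
#' @param wager_cut Single cut point in (0, 1) for the low/high wager.
#'
#' @return An object of class `observer_params` (a validated named list).
#' @examples
#' obs <- observer_params()
#' p_correct(c(5, 20, 50, 100), cue_valid = TRUE, params = obs)
#' @export
observer_params <- function(acc_threshold_valid = 20,
                            acc_threshold_invalid = 30,
                            acc_slope = 0.12,
                            lapse = 0.02,
                            cert_threshold_valid = 25,
                            cert_threshold_invalid = 45,
                            cert_slope = 0.08,
                            cert_noise_sd = 0.15,
                            cert_correct_boost = 0,
                            rating_cuts = c(0.25, 0.5, 0.75),
                            wager_cut = 0.5) {
  p <- list(
    acc_threshold_valid = acc_threshold_valid,
    acc_threshold_invalid = acc_threshold_invalid,
    acc_slope = acc_slope,
    lapse = lapse,
    cert_threshold_valid = cert_threshold_valid,
    cert_threshold_invalid = cert_threshold_invalid,
    cert_slope = cert_slope,
    cert_noise_sd = cert_noise_sd,
    cert_correct_boost = cert_correct_boost,
    rating_cuts = rating_cuts,
    wager_cut = wager_cut
  )
  validate_observer_params(p)
  structure(p, class = "observer_params")
}

validate_observer_params <- function(p) {
  stopifnot(
    "thresholds must be positive" = all(c(
      p$acc_threshold_valid, p$acc_threshold_invalid,
      p$cert_threshold_valid, p$cert_threshold_invalid
    ) > 0),
    "valid thresholds must not exceed invalid thresholds" =
      p$acc_threshold_valid <= p$acc_threshold_invalid &&
        p$cert_threshold_valid <= p$cert_threshold_invalid,
    "slopes must be positive" = p$acc_slope > 0 && p$cert_slope > 0,
    "lapse must lie in [0, 0.06]" = p$lapse >= 0 && p$lapse <= 0.06,
    "cert_noise_sd must be non-negative" = p$cert_noise_sd >= 0,
    "rating_cuts must be 3 strictly increasing values in (0,1)" =
      length(p$rating_cuts) == 3 && all(diff(p$rating_cuts) > 0) &&
        all(p$rating_cuts > 0) && all(p$rating_cuts < 1),
    "wager_cut must lie in (0,1)" = p$wager_cut > 0 && p$wager_cut < 1
  )
  invisible(p)
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf(
    "  accuracy : threshold %g%% (valid) / %g%% (invalid), slope %g, lapse %g\n",
    x$acc_threshold_valid, x$acc_threshold_invalid, x$acc_slope, x$lapse
  ))
  cat(sprintf(
    "  certainty: threshold %g%% (valid) / %g%% (invalid), slope %g, noise SD %g\n",
    x$cert_threshold_valid, x$cert_threshold_invalid, x$cert_slope, x$cert_noise_sd
  ))
  invisible(x)
}

#' Probability of a correct 4AFC choice under the generative observer
#'
#' Evaluates `0.25 + (1 - 0.25 - lapse) * L(x; threshold, slope)` where `L` is the
#' standard logistic and the threshold is the valid- or invalid-cue accuracy
#' threshold. At `x = threshold` (and zero lapse) the value is 0.625, the midpoint
#' between 4AFC chance and perfect performance.
#'
#' @param coherence Motion coherence in % (vectorized), each in `[0, 100]`.
#' @param cue_valid Logical (scalar or vector recycled against `coherence`).
#' @param params An [observer_params()] object.
#' @return Numeric vector of probabilities.
#' @export
p_correct <- function(coherence, cue_valid, params) {
  stopifnot(inherits(params, "observer_params"))
  if (any(coherence < 0 | coherence > 100)) {
    stop("coherence must lie in [0, 100]", call. = FALSE)
  }
  thr <- ifelse(cue_valid, params$acc_threshold_valid, params$acc_threshold_invalid)
  0.25 + (1 - 0.25 - params$lapse) * plogis(params$acc_slope * (coherence - thr))
}

# Expected internal confidence (certainty-index units, before noise).
expected_confidence <- function(coherence, cue_valid, params) {
  thr <- ifelse(cue_valid, params$cert_threshold_valid, params$cert_threshold_invalid)
  0.25 + 0.75 * plogis(params$cert_slope * (coherence - thr))
}

# Draw choices and confidence for vectors of trial specs. Internal engine shared
# by simulate_trial() and simulate_experiment(); relies on the current RNG state.
# Discretization order is fixed: index-scale confidence -> rescale to [0,1] via
# (c - 0.25)/0.75 -> clip to [0,1] -> cut.
draw_responses <- function(coherence, cue_valid, true_direction, variant, params) {
  n <- length(coherence)
  pc <- p_correct(coherence, cue_valid, params)
  correct <- runif(n) < pc
  choice <- true_direction
  wrong <- !correct
  if (any(wrong)) {
    # errors uniform over the 3 wrong directions
    choice[wrong] <- vapply(true_direction[wrong], function(d) {
      sample(setdiff(.directions, d), 1L)
    }, character(1))
  }
  conf <- expected_confidence(coherence, cue_valid, params) +
    params$cert_correct_boost * as.numeric(correct) +
    rnorm(n, 0, params$cert_noise_sd)
  u <- pmin(pmax((conf - 0.25) / 0.75, 0), 1)
  if (variant %in% .rating_variants) {
    raw <- findInterval(u, params$rating_cuts, left.open = TRUE)  # 0..3
  } else {
    raw <- ifelse(u > params$wager_cut, "high", "low")
  }
  list(choice = choice, correct = correct, confidence_raw = raw)
}

#' Simulate a single trial
#'
#' Draws one choice (correct with probability [p_correct()]; errors uniform over
#' the three wrong directions) and one confidence report from the generative
#' observer, returning a one-row trial tibble.
#'
#' @param spec A list or one-row data frame with elements `coherence`,
#'   `cue_valid`, `variant`, and optionally `true_direction`, `other_direction`,
#'   `subject_id`, `trial_index` (defaults: random directions, subject `"s1"`,
#'   index 1).
#' @param params An [observer_params()] object.
#' @param seed Optional integer seed; if supplied the trial is reproducible.
#' @return A one-row tibble with the standard trial-record columns (see
#'   [simulate_experiment()]).
#' @export
simulate_trial <- function(spec, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(params, "observer_params"))
  if (!spec$variant %in% .variants) {
    stop("unknown variant: ", spec$variant, call. = FALSE)
  }
  td <- spec$true_direction %||% sample(.directions, 1L)
  od <- spec$other_direction %||% sample(.directions, 1L)
  resp <- draw_responses(spec$coherence, spec$cue_valid, td, spec$variant, params)
  tibble::tibble(
    subject_id = spec$subject_id %||% "s1",
    variant = spec$variant,
    trial_index = spec$trial_index %||% 1L,
    cue_valid = spec$cue_valid,
    coherence = spec$coherence,
    true_direction = td,
    other_direction = od,
    congruent = td == od,
    choice = resp$choice,
    correct = resp$correct,
    confidence_raw = as.character(resp$confidence_raw),
    certainty_index = map_confidence(resp$confidence_raw, spec$variant)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full experiment for one of the four task variants
#'
#' Generates per-subject trial tables with the structure of the four precue/postcue
#' experiments: 80% valid cueing (exact allocation), two independently and
#' uniformly drawn motion directions per trial, coherence drawn equally from fixed
#' levels or controlled by the adaptive staircase, and choices/confidence drawn
#' from a per-subject generative observer. Per-subject observer parameters are
#' jittered around `params` so the cohort is heterogeneous; the true parameters
#' are recorded in the `"subject_params"` attribute for parameter-recovery checks.
#'
#' @param variant One of `"SN"`, `"SW"`, `"FN"`, `"FW"` (spatial/feature attention
#'   crossed with numerical ratings / post-decision wagering).
#' @param n_subjects Number of simulated subjects.
#' @param n_trials Trials per subject: a single number or a `c(min, max)` range
#'   from which each subject's count is drawn uniformly. Defaults to the cohort
#'   sizes of the emulated study (see [variant_defaults()]).
#' @param params An [observer_params()] object giving cohort-mean parameters.
#' @param coherence_mode `"fixed"` (levels sampled equally) or `"staircase"`.
#' @param levels Fixed coherence levels in %, default `c(5, 20, 50, 100)`.
#' @param levels_invalid Optional distinct fixed levels for invalid-cue trials
#'   (matched-performance control design, where the unattended condition receives
#'   on average higher coherences). Default `NULL`: same levels for both cues.
#' @param p_valid Probability of a valid cue, default 0.8.
#' @param exact_valid Use exact allocation of valid cues (default) or Bernoulli.
#' @param subject_sd Relative between-subject SD applied to the four thresholds
#'   (truncated at 40% below the mean). Default 0.12.
#' @param staircase A [staircase_options()] list (used when
#'   `coherence_mode = "staircase"`).
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial and columns `subject_id`, `variant`,
#'   `trial_index`, `cue_valid`, `coherence`, `true_direction`, `other_direction`,
#'   `congruent`, `choice`, `correct`, `confidence_raw`, `certainty_index`.
#' @examples
#' trials <- simulate_experiment("SN", n_subjects = 2, n_trials = 100, seed = 1)
#' dplyr::count(trials, cue_valid)
#' @export
simulate_experiment <- function(variant,
                                n_subjects = NULL,
                                n_trials = NULL,
                                params = observer_params(),
                                coherence_mode = c("fixed", "staircase"),
                                levels = c(5, 20, 50, 100),
                                levels_invalid = NULL,
                                p_valid = 0.8,
                                exact_valid = TRUE,
                                subject_sd = 0.12,
                                staircase = staircase_options(),
                                seed = NULL) {
  coherence_mode <- match.arg(coherence_mode)
  variant <- match.arg(variant, .variants)
  if (!is.null(seed)) set.seed(seed)
  defaults <- variant_defaults(variant)
  n_subjects <- n_subjects %||% defaults$n_subjects
  n_trials <- n_trials %||% defaults$n_trials
  if (any(n_trials <= 0)) stop("n_trials must be positive", call. = FALSE)

  subj_params <- purrr::map(seq_len(n_subjects), function(i) {
    jitter_observer(params, subject_sd)
  })
  names(subj_params) <- sprintf("s%02d", seq_len(n_subjects))

  trials <- purrr::imap(subj_params, function(sp, sid) {
    nt <- if (length(n_trials) == 2) {
      sample(seq(n_trials[1], n_trials[2]), 1L)
    } else {
      as.integer(n_trials)
    }
    sched <- generate_schedule(nt, p_valid = p_valid, exact = exact_valid)
    if (coherence_mode == "fixed") {
      coh <- sample(levels, nt, replace = TRUE)
      if (!is.null(levels_invalid)) {
        n_inv <- sum(!sched$cue_valid)
        coh[!sched$cue_valid] <- sample(levels_invalid, n_inv, replace = TRUE)
      }
      resp <- draw_responses(coh, sched$cue_valid, sched$true_direction, variant, sp)
    } else {
      coh <- numeric(nt)
      correct <- logical(nt)
      choice <- character(nt)
      raw <- if (variant %in% .rating_variants) integer(nt) else character(nt)
      st <- staircase_init(staircase)
      for (i in seq_len(nt)) {
        coh[i] <- st$coherence
        r <- draw_responses(
          coh[i], sched$cue_valid[i], sched$true_direction[i], variant, sp
        )
        choice[i] <- r$choice
        correct[i] <- r$correct
        raw[i] <- r$confidence_raw
        st <- staircase_update(st, correct[i])
        if (st$terminated) st <- staircase_init(staircase)
      }
      resp <- list(choice = choice, correct = correct, confidence_raw = raw)
    }
    tibble::tibble(
      subject_id = sid,
      variant = variant,
      trial_index = seq_len(nt),
      cue_valid = sched$cue_valid,
      coherence = coh,
      true_direction = sched$true_direction,
      other_direction = sched$other_direction,
      congruent = sched$true_direction == sched$other_direction,
      choice = resp$choice,
      correct = resp$correct,
      confidence_raw = as.character(resp$confidence_raw),
      certainty_index = map_confidence(resp$confidence_raw, variant)
    )
  })
  out <- dplyr::bind_rows(trials)
  attr(out, "subject_params") <- subj_params
  out
}

# Per-subject parameter jitter: thresholds get multiplicative Gaussian noise
# (truncated to keep them positive and ordered), other parameters are shared.
jitter_observer <- function(params, rel_sd) {
  if (rel_sd == 0) return(params)
  jit <- function(x) x * max(0.6, 1 + rnorm(1, 0, rel_sd))
  p <- unclass(params)
  p$acc_threshold_valid <- jit(p$acc_threshold_valid)
  p$acc_threshold_invalid <- max(jit(p$acc_threshold_invalid), p$acc_threshold_valid)
  p$cert_threshold_valid <- jit(p$cert_threshold_valid)
  p$cert_threshold_invalid <- max(jit(p$cert_threshold_invalid), p$cert_threshold_valid)
  structure(p, class = "observer_params")
}

#' Study-cohort defaults per task variant
#'
#' Subject counts and per-subject trial ranges emulating the four task cohorts:
#' spatial attention with numerical ratings (13 subjects, 1000–1100 trials),
#' spatial/wagering (11, 1000–1100), feature/numerical (11, 1100–1200) and
#' feature/wagering (11, 900–1000).
#'
#' @param variant One of `"SN"`, `"SW"`, `"FN"`, `"FW"`.
#' @return A list with `n_subjects` and `n_trials` (a `c(min, max)` range).
#' @export
variant_defaults <- function(variant) {
  switch(match.arg(variant, .variants),
    SN = list(n_subjects = 13, n_trials = c(1000, 1100)),
    SW = list(n_subjects = 11, n_trials = c(1000, 1100)),
    FN = list(n_subjects = 11, n_trials = c(1100, 1200)),
    FW = list(n_subjects = 11, n_trials = c(900, 1000))
  )
}

#' Write / read a trial table as CSV
#'
#' Fixed-header CSV interchange for trial tables: logical columns are written as
#' 0/1, directions and wagers as lowercase strings. A comment line carrying
#' provenance (written by [run_experiment()]) is tolerated on read.
#'
#' @param trials A trial tibble (see [simulate_experiment()]).
#' @param path File path.
#' @param comment Optional provenance string written as a `#` comment header.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns the
#'   trial tibble with types restored.
#' @export
write_trials <- function(trials, path, comment = NULL) {
  out <- dplyr::mutate(
    trials,
    dplyr::across(dplyr::where(is.logical), as.integer)
  )
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- readr::read_csv(
    path,
    comment = "#",
    col_types = readr::cols(
      subject_id = "c", variant = "c", trial_index = "i", cue_valid = "i",
      coherence = "d", true_direction = "c", other_direction = "c",
      congruent = "i", choice = "c", correct = "i", confidence_raw = "c",
      certainty_index = "d"
    )
  )
  dplyr::mutate(
    tr,
    cue_valid = as.logical(.data$cue_valid),
    congruent = as.logical(.data$congruent),
    correct = as.logical(.data$correct)
  )
}
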