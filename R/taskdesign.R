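#' Generate a cue-validity trial schedule
#'
#' Builds the per-trial design: a valid/invalid attention cue (80% valid by
#' default) and two motion directions — the instructed stimulus' true direction
#' and the other stimulus' direction — drawn independently and uniformly from
#' up/right/down/left, so about a quarter of trials are congruent (both stimuli
#' carry the same direction).
#'
#' @param n_trials Number of trials (> 0).
#' @param p_valid Probability of a valid cue, in (0, 1). Default 0.8.
#' @param exact With exact allocation (default) exactly `floor(p_valid * n)`
#'   trials are valid, in shuffled order; otherwise validity is Bernoulli.
#' @return A tibble with columns `cue_valid` (logical), `true_direction`,
#'   `other_direction` (character) and `congruent` (logical).
#' @examples
#' sched <- generate_schedule(1000)
#' sum(sched$cue_valid)  # exactly 800
#' @export
generate_schedule <- function(n_trials, p_valid = 0.8, exact = TRUE) {
  if (n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  if (p_valid <= 0 || p_valid >= 1) stop("p_valid must lie in (0, 1)", call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (exact) {
    n_valid <- floor(p_valid * n_trials)
    cue_valid <- sample(rep(c(TRUE, FALSE), c(n_valid, n_trials - n_valid)))
  } else {
    cue_valid <- runif(n_trials) < p_valid
  }
  true_direction <- sample(.directions, n_trials, replace = TRUE)
  other_direction <- sample(.directions, n_trials, replace = TRUE)
  tibble::tibble(
    cue_valid = cue_valid,
    true_direction = true_direction,
    other_direction = other_direction,
    congruent = true_direction == other_direction
  )
}

#' Staircase controller constants
#'
#' Tunables of the PEST-style adaptive staircase tracking the 62.5%-correct
#' threshold: start at 80% coherence with a 20% step; a sequential count at the
#' current level decides whether performance is above or below target; step size
#' halves on a direction reversal and doubles (capped at `step_max`) after
#' `double_after` consecutive same-direction steps; the run terminates when the
#' step falls below 0.02%.
#'
#' @param start Starting coherence (%), default 80.
#' @param step_start Initial step size (%), default 20.
#' @param step_max Cap applied when doubling (%), default 20 (the starting step).
#' @param step_min Termination bound (%): the staircase terminates when the step
#'   size falls below this value. Default 0.02.
#' @param target Tracked proportion correct, default 0.625 (midpoint of a 4AFC
#'   psychometric function).
#' @param deviation_bound Sequential-count decision bound `W`: a step is taken
#'   once `|k - target * n|` at the current level exceeds `W`. Default 1.
#' @param double_after Number of consecutive same-direction steps after which the
#'   step size doubles. Default 3.
#' @param coherence_min,coherence_max Clamp bounds for the coherence level (%).
#' @return A named list of class `staircase_options`.
#' @export
staircase_options <- function(start = 80, step_start = 20, step_max = 20,
                              step_min = 0.02, target = 0.625,
                              deviation_bound = 1, double_after = 3,
                              coherence_min = 0.02, coherence_max = 100) {
  stopifnot(
    start > 0, step_start > 0, step_min > 0, step_min < step_start,
    target > 0, target < 1, deviation_bound >= 0, double_after >= 2,
    coherence_min > 0, coherence_max <= 100, coherence_min < coherence_max
  )
  structure(
    list(
      start = start, step_start = step_start, step_max = step_max,
      step_min = step_min, target = target, deviation_bound = deviation_bound,
      double_after = double_after, coherence_min = coherence_min,
      coherence_max = coherence_max
    ),
    class = "staircase_options"
  )
}

#' Initialize the adaptive staircase
#'
#' Returns a fresh staircase state at 80% coherence with a 20% step, no trial
#' history and no movement direction yet. A terminated staircase restarts by
#' calling this again.
#'
#' @param options A [staircase_options()] list.
#' @return A `staircase_state` list with fields `coherence`, `step`, `direction`
#'   (`NA`, `"down"` or `"up"`), `n_level`/`k_level` (trials and successes at the
#'   current level), `run_counter` (consecutive same-direction steps),
#'   `terminated`, and a `history` data frame of `(coherence, correct)` pairs
#'   since the last restart.
#' @export
staircase_init <- function(options = staircase_options()) {
  stopifnot(inherits(options, "staircase_options"))
  structure(
    list(
      coherence = options$start,
      step = options$step_start,
      direction = NA_character_,
      n_level = 0L,
      k_level = 0L,
      run_counter = 0L,
      terminated = FALSE,
      history = data.frame(coherence = numeric(0), correct = logical(0)),
      options = options
    ),
    class = "staircase_state"
  )
}

#' Advance the staircase by one trial outcome
#'
#' Records one correct/incorrect outcome at the current coherence level and
#' applies the PEST decision rule: once the accumulated successes at this level
#' deviate from the 62.5% expectation by more than the deviation bound, coherence
#' steps down (performance above target) or up (below target). A reversal halves
#' the step size; continued movement in the same direction doubles it after
#' `double_after` consecutive steps, capped at `step_max`. When a halving drives
#' the step below `step_min` (0.02% by default) the state is marked terminated;
#' updating a terminated state is an error.
#'
#' @param state A `staircase_state` from [staircase_init()] or a previous update.
#' @param correct Logical: was the response on this trial correct?
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct), length(correct) == 1)
  if (state$terminated) {
    stop("cannot update a terminated staircase; restart with staircase_init()",
      call. = FALSE
    )
  }
  opt <- state$options
  state$n_level <- state$n_level + 1L
  state$k_level <- state$k_level + as.integer(correct)
  state$history <- rbind(
    state$history,
    data.frame(coherence = state$coherence, correct = correct)
  )
  dev <- state$k_level - opt$target * state$n_level
  if (abs(dev) <= opt$deviation_bound) {
    return(state) # keep testing at this level
  }
  new_dir <- if (dev > 0) "down" else "up"
  if (is.na(state$direction)) {
    # first decision: no reversal bookkeeping yet
    state$run_counter <- 1L
  } else if (new_dir != state$direction) {
    state$step <- state$step / 2
    state$run_counter <- 1L
  } else {
    state$run_counter <- state$run_counter + 1L
    if (state$run_counter >= opt$double_after) {
      state$step <- min(state$step * 2, opt$step_max)
    }
  }
  state$direction <- new_dir
  if (state$step < opt$step_min) {
    state$terminated <- TRUE
    return(state)
  }
  delta <- if (new_dir == "down") -state$step else state$step
  state$coherence <- min(max(state$coherence + delta, opt$coherence_min), opt$coherence_max)
  state$n_level <- 0L
  state$k_level <- 0L
  state
}

#' Run staircases against a simulated observer
#'
#' Drives the staircase with Bernoulli responses from a known accuracy function
#' until termination (or a trial cap), over several independent restarts. Used to
#' check that terminal coherence levels track the 62.5%-correct target.
#'
#' @param p_fun Function `(coherence) -> P(correct)`, the simulated observer.
#' @param n_restarts Number of independent staircase runs. Default 10.
#' @param max_trials Per-run trial cap (safety against non-termination). Default 400.
#' @param options A [staircase_options()] list.
#' @param seed Optional integer seed.
#' @return A tibble with one row per restart: `restart`, `n_trials`, `terminated`,
#'   `terminal_coherence`, and `true_p` (`p_fun` evaluated at the terminal level).
#'   The full per-trial trace is in the `"trace"` attribute (a tibble with
#'   `restart`, `trial`, `coherence`, `step`, `direction`, `correct`).
#' @examples
#' obs <- observer_params(lapse = 0)
#' runs <- run_staircase(function(x) p_correct(x, TRUE, obs), seed = 1)
#' mean(runs$true_p)  # close to 0.625
#' @export
run_staircase <- function(p_fun, n_restarts = 10, max_trials = 400,
                          options = staircase_options(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traces <- vector("list", n_restarts)
  summaries <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    st <- staircase_init(options)
    coh <- step <- numeric(max_trials)
    dir <- character(max_trials)
    corr <- logical(max_trials)
    i <- 0L
    while (!st$terminated && i < max_trials) {
      i <- i + 1L
      coh[i] <- st$coherence
      step[i] <- st$step
      dir[i] <- if (is.na(st$direction)) "none" else st$direction
      corr[i] <- runif(1) < p_fun(st$coherence)
      st <- staircase_update(st, corr[i])
    }
    terminal <- if (st$terminated) st$coherence else coh[i]
    traces[[r]] <- tibble::tibble(
      restart = r, trial = seq_len(i), coherence = coh[seq_len(i)],
      step = step[seq_len(i)], direction = dir[seq_len(i)], correct = corr[seq_len(i)]
    )
    summaries[[r]] <- tibble::tibble(
      restart = r, n_trials = i, terminated = st$terminated,
      terminal_coherence = terminal, true_p = p_fun(terminal)
    )
  }
  out <- dplyr::bind_rows(summaries)
  attr(out, "trace") <- dplyr::bind_rows(traces)
  out
}
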