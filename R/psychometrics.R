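#' Per-level psychometric summary of a trial table
#'
#' Collapses trials to per-coherence binomial summaries suitable for
#' [fit_pf()]. Accuracy uses one Bernoulli success per trial (the correct flag).
#' Certainty-index data are converted to pseudo-binomial counts so a single ML
#' machinery serves both measures: a trial's index `v` in {0.25, 0.5, 0.75, 1}
#' contributes `k = 3 (v - 0.25) / 0.75` successes out of 3 (numerical ratings),
#' or `k` in {0, 1} out of 1 (wagers) — the index levels are equidistant by task
#' instruction, so this is an order-preserving recoding.
#'
#' @param trials Trial tibble (see [simulate_experiment()]).
#' @param measure `"accuracy"` or `"certainty"`.
#' @param condition `"valid"`, `"invalid"` or `"pooled"`: which cue condition to
#'   keep before summarizing.
#' @return A tibble with columns `coherence`, `n` (binomial denominators) and
#'   `k` (successes), plus `measure` and `condition`.
#' @export
pf_data <- function(trials, measure = c("accuracy", "certainty"),
                    condition = c("pooled", "valid", "invalid")) {
  measure <- match.arg(measure)
  condition <- match.arg(condition)
  tr <- switch(condition,
    pooled = trials,
    valid = dplyr::filter(trials, .data$cue_valid),
    invalid = dplyr::filter(trials, !.data$cue_valid)
  )
  if (measure == "accuracy") {
    out <- tr |>
      dplyr::group_by(coherence = .data$coherence) |>
      dplyr::summarise(
        n = dplyr::n(), k = sum(.data$correct), .groups = "drop"
      )
  } else {
    is_wager <- all(tr$variant %in% .wager_variants)
    m <- if (is_wager) 1L else 3L
    out <- tr |>
      dplyr::group_by(coherence = .data$coherence) |>
      dplyr::summarise(
        n = m * dplyr::n(),
        k = sum(round(m * (.data$certainty_index - 0.25) / 0.75)),
        .groups = "drop"
      )
  }
  dplyr::mutate(out, measure = measure, condition = condition)
}

# psi(x) = gamma + (1 - gamma - lambda) * L(x; alpha, beta)
psi_logistic <- function(x, alpha, beta, gamma = 0.25, lambda = 0) {
  gamma + (1 - gamma - lambda) * plogis(beta * (x - alpha))
}

# Binomial log-likelihood of per-level (n, k) counts under psi.
pf_loglik <- function(par, data, gamma, lambda_fixed) {
  alpha <- par[1]
  beta <- par[2]
  lambda <- if (is.null(lambda_fixed)) par[3] else lambda_fixed
  p <- psi_logistic(data$coherence, alpha, beta, gamma, lambda)
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  sum(data$k * log(p) + (data$n - data$k) * log(1 - p))
}

# Analytic gradient of pf_loglik (same parameterization).
pf_loglik_grad <- function(par, data, gamma, lambda_fixed) {
  alpha <- par[1]
  beta <- par[2]
  lambda <- if (is.null(lambda_fixed)) par[3] else lambda_fixed
  span <- 1 - gamma - lambda
  f <- plogis(beta * (data$coherence - alpha))
  p <- pmin(pmax(gamma + span * f, 1e-10), 1 - 1e-10)
  w <- data$k / p - (data$n - data$k) / (1 - p)
  ff <- f * (1 - f)
  g <- c(
    sum(w * (-span * beta * ff)),
    sum(w * (span * (data$coherence - alpha) * ff))
  )
  if (is.null(lambda_fixed)) g <- c(g, sum(w * (-f)))
  g
}

# Lean single-start ML fit on bare vectors; returns list(par, loglik). Used in
# the parametric-bootstrap inner loop where tibble/multi-start overhead matters.
fit_quick <- function(x, n, k, gamma, lambda_fixed, start) {
  data <- list(coherence = x, n = n, k = k)
  free_lambda <- is.null(lambda_fixed)
  lower <- c(0.1, 1e-3, if (free_lambda) 0)
  upper <- c(200, 10, if (free_lambda) 0.1)
  res <- optim(pmin(pmax(start, lower), upper), pf_loglik, gr = pf_loglik_grad,
    data = data, gamma = gamma, lambda_fixed = lambda_fixed,
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(fnscale = -1, maxit = 200)
  )
  list(par = res$par, loglik = res$value)
}

#' Maximum-likelihood logistic psychometric fit
#'
#' Fits `psi(x) = gamma + (1 - gamma - lambda) * L(x; alpha, beta)` to per-level
#' binomial counts by maximizing the binomial log-likelihood with bounded
#' multi-start numerical optimization (`optim`, L-BFGS-B). `gamma` is fixed
#' (default 0.25, 4AFC chance — also the floor of the certainty index); `lambda`
#' is free in `[0, 0.1]` unless fixed. Bounds: `alpha` in `[0.1, 200]`, `beta` in
#' `[1e-3, 10]`; ties between starts are broken by best log-likelihood, then
#' smallest slope.
#'
#' @param data Per-level summary tibble with columns `coherence`, `n`, `k`
#'   (from [pf_data()] or built directly).
#' @param measure Label stored on the fit: `"accuracy"` or `"certainty"`.
#' @param condition Label stored on the fit: `"valid"`, `"invalid"` or `"pooled"`.
#' @param gamma Fixed lower asymptote. Default 0.25.
#' @param lambda Either `NULL` (free lapse in `[0, 0.1]`, the default) or a fixed
#'   value.
#' @param n_starts Number of optimizer starts spread over a threshold grid.
#'   Default 5.
#' @param start Optional explicit `c(alpha, beta[, lambda])` start appended to
#'   the grid starts (used by the parametric bootstrap with `n_starts = 1`).
#' @return An object of class `pf_fit` with elements `alpha`, `beta`, `gamma`,
#'   `lambda`, `loglik`, `n_trials`, `measure`, `condition`, `data`,
#'   `degenerate` (all responses identical across levels) and `flat` (slope at
#'   its lower bound, threshold effectively undefined).
#' @examples
#' obs <- observer_params(lapse = 0)
#' d <- tibble::tibble(
#'   coherence = c(5, 10, 20, 40, 80),
#'   n = 200,
#'   k = rbinom(5, 200, p_correct(c(5, 10, 20, 40, 80), TRUE, obs))
#' )
#' fit <- fit_pf(d)
#' coef(fit)
#' @export
fit_pf <- function(data, measure = c("accuracy", "certainty"),
                   condition = c("pooled", "valid", "invalid"),
                   gamma = 0.25, lambda = NULL, n_starts = 5, start = NULL) {
  measure <- if ("measure" %in% names(data)) data$measure[1] else match.arg(measure)
  condition <- if ("condition" %in% names(data)) data$condition[1] else match.arg(condition)
  stopifnot(all(c("coherence", "n", "k") %in% names(data)))
  data <- dplyr::arrange(dplyr::as_tibble(data)[c("coherence", "n", "k")], .data$coherence)
  if (nrow(data) < 2) stop("need >= 2 distinct coherence levels", call. = FALSE)
  if (any(data$k < 0 | data$k > data$n)) stop("inconsistent counts", call. = FALSE)

  degenerate <- all(data$k == data$n) || all(data$k == 0) ||
    length(unique(data$k / data$n)) == 1
  free_lambda <- is.null(lambda)
  lower <- c(0.1, 1e-3, if (free_lambda) 0)
  upper <- c(200, 10, if (free_lambda) 0.1)

  rng <- range(data$coherence)
  alpha_grid <- seq(rng[1], rng[2], length.out = max(n_starts, 1))
  starts <- lapply(alpha_grid, function(a) c(a, 0.1, if (free_lambda) 0.02))
  if (!is.null(start)) {
    starts <- c(list(pmin(pmax(start, lower), upper)), starts[seq_len(max(n_starts - 1, 0))])
  }

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, pf_loglik,
        gr = pf_loglik_grad,
        data = data, gamma = gamma, lambda_fixed = lambda,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(fnscale = -1, maxit = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value > best$value + 1e-9 ||
      (abs(res$value - best$value) <= 1e-9 && res$par[2] < best$par[2])) {
      best <- res
    }
  }
  if (is.null(best)) stop("psychometric fit failed to converge from all starts", call. = FALSE)

  structure(
    list(
      alpha = unname(best$par[1]),
      beta = unname(best$par[2]),
      gamma = gamma,
      lambda = if (free_lambda) unname(best$par[3]) else lambda,
      lambda_free = free_lambda,
      loglik = best$value,
      n_trials = sum(data$n),
      measure = measure,
      condition = condition,
      data = data,
      degenerate = degenerate,
      flat = unname(best$par[2]) <= lower[2] * (1 + 1e-6)
    ),
    class = "pf_fit"
  )
}

#' @export
print.pf_fit <- function(x, ...) {
  cat(sprintf(
    "<pf_fit: %s, %s>  alpha = %.3f, beta = %.4f, gamma = %.2f, lambda = %.4f\n",
    x$measure, x$condition, x$alpha, x$beta, x$gamma, x$lambda
  ))
  cat(sprintf(
    "  logLik = %.3f on %d trials at %d levels%s%s\n",
    x$loglik, x$n_trials, nrow(x$data),
    if (x$degenerate) " [degenerate]" else "",
    if (x$flat) " [flat: threshold undefined]" else ""
  ))
  invisible(x)
}

#' @export
coef.pf_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, gamma = object$gamma, lambda = object$lambda)
}

#' @export
logLik.pf_fit <- function(object, ...) {
  structure(object$loglik, df = if (is.null(object$lambda)) 3 else 2, class = "logLik")
}

#' Predicted response probability from a fitted psychometric function
#' @param object A `pf_fit`.
#' @param newdata Optional tibble with a `coherence` column (default: the fitted
#'   levels).
#' @param ... Unused.
#' @return Numeric vector of psi values.
#' @export
predict.pf_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$coherence else newdata$coherence
  psi_logistic(x, object$alpha, object$beta, object$gamma, object$lambda)
}

#' Invert a fitted psychometric function at a criterion level
#'
#' Analytic inversion of `psi` at a response criterion — e.g. the coherence at
#' which the certainty index reaches 0.625, the inflection point when the lapse
#' is zero (then `threshold_at(fit, 0.625)` returns `alpha` exactly). Returns
#' `NA` (an "undefined" marker, not an error) when the criterion is unreachable:
#' outside the open asymptote interval `(gamma, 1 - lambda)`, on a degenerate or
#' flat fit, or requiring coherence above 100% — the latter occurs in hard
#' unattended conditions where even full coherence does not reach the criterion.
#'
#' @param fit A `pf_fit`.
#' @param criterion Target response level, e.g. 0.625.
#' @return Coherence in % or `NA_real_`.
#' @export
threshold_at <- function(fit, criterion = 0.625) {
  stopifnot(inherits(fit, "pf_fit"))
  if (fit$flat || fit$degenerate) return(NA_real_)
  span <- 1 - fit$gamma - fit$lambda
  p <- (criterion - fit$gamma) / span
  if (!is.finite(p) || p <= 0 || p >= 1) return(NA_real_)
  x <- fit$alpha + qlogis(p) / fit$beta
  if (x > 100) return(NA_real_)
  x
}

#' Transformed likelihood ratio between pooled and condition-wise fits
#'
#' Deviance statistic comparing a single psychometric function fit to the
#' concatenated data of two conditions against separate fits per condition:
#' `TLR = 2 (logLik_A + logLik_B - logLik_pooled)`, non-negative up to optimizer
#' tolerance because the pooled model is nested in the separate one.
#'
#' @param data_A,data_B Per-level summary tibbles (`coherence`, `n`, `k`).
#' @param gamma,lambda,n_starts,start Passed to [fit_pf()] (one shared `lambda`
#'   policy for all three fits; `start` seeds the pooled fit, condition fits are
#'   seeded from the pooled estimate).
#' @return The TLR (numeric scalar) with the three fits attached as attributes
#'   `fit_pooled`, `fit_A`, `fit_B`.
#' @export
tlr <- function(data_A, data_B, gamma = 0.25, lambda = NULL, n_starts = 5,
                start = NULL) {
  stopifnot(nrow(data_A) > 0, nrow(data_B) > 0)
  pooled_data <- dplyr::bind_rows(
    data_A[c("coherence", "n", "k")],
    data_B[c("coherence", "n", "k")]
  ) |>
    dplyr::group_by(.data$coherence) |>
    dplyr::summarise(n = sum(.data$n), k = sum(.data$k), .groups = "drop")
  fit_pooled <- fit_pf(pooled_data, gamma = gamma, lambda = lambda,
                       n_starts = n_starts, start = start)
  seed_par <- c(fit_pooled$alpha, fit_pooled$beta,
                if (is.null(lambda)) fit_pooled$lambda)
  fit_A <- fit_pf(data_A, gamma = gamma, lambda = lambda, n_starts = n_starts,
                  start = seed_par)
  fit_B <- fit_pf(data_B, gamma = gamma, lambda = lambda, n_starts = n_starts,
                  start = seed_par)
  out <- 2 * (fit_A$loglik + fit_B$loglik - fit_pooled$loglik)
  attr(out, "fit_pooled") <- fit_pooled
  attr(out, "fit_A") <- fit_A
  attr(out, "fit_B") <- fit_B
  out
}

#' Monte-Carlo (parametric bootstrap) model comparison of two conditions
#'
#' Tests whether two conditions share one psychometric function. The observed
#' transformed likelihood ratio is referred to a parametric-bootstrap null:
#' `n_sims` dataset pairs are simulated from the pooled single-function fit with
#' the observed per-level trial counts, both models are refit to each pair, and
#' the two conditions are declared significantly different when the observed TLR
#' exceeds 95% of the null TLRs. The Monte-Carlo p-value uses the add-one
#' estimator `p = (1 + #{null >= observed}) / (n_sims + 1)`.
#'
#' Bootstrap refits start from the generating (pooled-fit) parameters with
#' `n_starts = 1`; the observed-data fits use the full multi-start procedure.
#'
#' @inheritParams tlr
#' @param n_sims Number of bootstrap simulations (>= 100 for inferential use;
#'   must be positive). The emulated analysis used 10000; desk-scale runs use
#'   500–1000.
#' @param alpha_level Exceedance criterion, default 0.05 (the 95% rule).
#' @param seed Optional integer seed.
#' @return An object of class `pf_comparison`: `tlr_observed`, `null_tlrs`,
#'   `n_sims`, `p_mc`, `significant`, `critical` (the exceeded null quantile)
#'   and the three observed fits.
#' @examples
#' obs <- observer_params(lapse = 0)
#' tr <- simulate_experiment("SN", n_subjects = 1, n_trials = 400,
#'                           params = obs, seed = 2)
#' cmp <- mc_model_comparison(
#'   pf_data(tr, "accuracy", "valid"), pf_data(tr, "accuracy", "invalid"),
#'   n_sims = 200, lambda = 0, seed = 3
#' )
#' cmp$p_mc
#' @export
mc_model_comparison <- function(data_A, data_B, n_sims = 1000, gamma = 0.25,
                                lambda = NULL, alpha_level = 0.05,
                                n_starts = 5, seed = NULL) {
  if (n_sims < 1) stop("n_sims must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  observed <- tlr(data_A, data_B, gamma = gamma, lambda = lambda, n_starts = n_starts)
  fit_pooled <- attr(observed, "fit_pooled")
  gen_par <- c(fit_pooled$alpha, fit_pooled$beta,
               if (is.null(lambda)) fit_pooled$lambda)
  p_A <- predict(fit_pooled, data_A)
  p_B <- predict(fit_pooled, data_B)

  # precomputed structures for the lean bootstrap loop
  x_A <- data_A$coherence
  n_A <- data_A$n
  x_B <- data_B$coherence
  n_B <- data_B$n
  x_all <- c(x_A, x_B)
  x_pool <- sort(unique(x_all))
  idx_pool <- match(x_all, x_pool)
  n_pool <- as.numeric(rowsum(c(n_A, n_B), idx_pool))

  null_tlrs <- numeric(n_sims)
  failures <- 0L
  for (s in seq_len(n_sims)) {
    k_A <- rbinom(length(x_A), n_A, p_A)
    k_B <- rbinom(length(x_B), n_B, p_B)
    k_pool <- as.numeric(rowsum(c(k_A, k_B), idx_pool))
    val <- tryCatch({
      fp <- fit_quick(x_pool, n_pool, k_pool, gamma, lambda, gen_par)
      fa <- fit_quick(x_A, n_A, k_A, gamma, lambda, fp$par)
      fb <- fit_quick(x_B, n_B, k_B, gamma, lambda, fp$par)
      2 * (fa$loglik + fb$loglik - fp$loglik)
    }, error = function(e) NA_real_)
    if (is.na(val)) failures <- failures + 1L
    null_tlrs[s] <- val
  }
  if (failures > 0.05 * n_sims) {
    stop(sprintf(
      "Monte-Carlo comparison failed: %d of %d bootstrap refits did not converge",
      failures, n_sims
    ), call. = FALSE)
  }
  null_tlrs <- null_tlrs[!is.na(null_tlrs)]
  obs_val <- as.numeric(observed)
  # "exceeds 95% of null TLRs": strictly above the ceiling(0.95 n)-th order statistic
  crit <- sort(null_tlrs)[ceiling((1 - alpha_level) * length(null_tlrs))]
  structure(
    list(
      tlr_observed = obs_val,
      null_tlrs = null_tlrs,
      n_sims = length(null_tlrs),
      p_mc = (1 + sum(null_tlrs >= obs_val)) / (length(null_tlrs) + 1),
      significant = obs_val > crit,
      critical = crit,
      alpha_level = alpha_level,
      fit_pooled = fit_pooled,
      fit_A = attr(observed, "fit_A"),
      fit_B = attr(observed, "fit_B")
    ),
    class = "pf_comparison"
  )
}

#' @export
print.pf_comparison <- function(x, ...) {
  cat(sprintf(
    "<pf_comparison>  TLR = %.3f, MC p = %.4f (%d sims), %ssignificant at the %d%% criterion\n",
    x$tlr_observed, x$p_mc, x$n_sims, if (x$significant) "" else "not ",
    round(100 * (1 - x$alpha_level))
  ))
  invisible(x)
}
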