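#' Tidy a psychometric fit
#'
#' @param x A `pf_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `fixed`.
#' @method tidy pf_fit
#' @export
tidy.pf_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "gamma", "lambda"),
    estimate = c(x$alpha, x$beta, x$gamma, x$lambda),
    fixed = c(FALSE, FALSE, TRUE, !isTRUE(x$lambda_free))
  )
}

#' @rdname tidy.pf_fit
#' @return `glance()`: a one-row tibble with `alpha`, `beta`, `gamma`, `lambda`,
#'   `logLik`, `n_trials`, `n_levels`, `measure`, `condition`, `threshold_625`
#'   (coherence at the 0.625 criterion, `NA` when undefined), `degenerate`,
#'   `flat`.
#' @method glance pf_fit
#' @export
glance.pf_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, beta = x$beta, gamma = x$gamma, lambda = x$lambda,
    logLik = x$loglik, n_trials = x$n_trials, n_levels = nrow(x$data),
    measure = x$measure, condition = x$condition,
    threshold_625 = threshold_at(x, 0.625),
    degenerate = x$degenerate, flat = x$flat
  )
}

#' Tidy a Monte-Carlo model comparison
#'
#' @param x A `pf_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the null TLR sample, one row per simulation; `glance()`:
#'   a one-row summary (`tlr_observed`, `critical`, `p_mc`, `n_sims`,
#'   `significant`).
#' @method tidy pf_comparison
#' @export
tidy.pf_comparison <- function(x, ...) {
  tibble::tibble(sim = seq_along(x$null_tlrs), null_tlr = x$null_tlrs)
}

#' @rdname tidy.pf_comparison
#' @method glance pf_comparison
#' @export
glance.pf_comparison <- function(x, ...) {
  tibble::tibble(
    tlr_observed = x$tlr_observed, critical = x$critical, p_mc = x$p_mc,
    n_sims = x$n_sims, significant = x$significant
  )
}

#' Tidy a pipeline run
#'
#' @param x An `attencert_run`.
#' @param ... Unused.
#' @return `tidy()`: the Δz paired-test table with the control reruns appended
#'   (`analysis` column distinguishes them); `glance()`: one row per model
#'   comparison.
#' @method tidy attencert_run
#' @export
tidy.attencert_run <- function(x, ...) {
  main <- dplyr::mutate(x$tests, analysis = "main")
  ctrl <- purrr::imap(x$controls, function(ct, nm) {
    if (is.null(ct$tests)) return(NULL)
    dplyr::mutate(ct$tests, analysis = nm)
  })
  dplyr::bind_rows(c(list(main), ctrl))
}

#' @rdname tidy.attencert_run
#' @method glance attencert_run
#' @export
glance.attencert_run <- function(x, ...) {
  purrr::imap(x$comparisons, function(cmp, nm) {
    dplyr::mutate(glance(cmp), comparison = nm)
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("comparison")
}
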