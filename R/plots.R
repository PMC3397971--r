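#' Plot a fitted psychometric function over its data
#'
#' Observed per-level proportions (point size scaled by trial count) with the
#' fitted logistic curve, in the style of the standard
#' performance-vs-coherence panel.
#'
#' @param object A `pf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_fit
#' @export
autoplot.pf_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$data, prop = .data$k / .data$n)
  grid <- tibble::tibble(
    coherence = seq(min(obs$coherence), max(obs$coherence), length.out = 200)
  )
  grid$prop <- predict(object, grid)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$coherence, y = .data$prop)) +
    ggplot2::geom_line(data = grid, linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "motion coherence (%)",
      y = if (object$measure == "accuracy") "proportion correct" else "certainty index",
      title = sprintf("%s (%s cues)", object$measure, object$condition)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the Monte-Carlo null distribution of a model comparison
#'
#' Histogram of the bootstrap null TLR sample with the observed TLR and the
#' 95% exceedance criterion marked.
#'
#' @param object A `pf_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_comparison
#' @export
autoplot.pf_comparison <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_tlr)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$critical, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$tlr_observed, colour = "#b2182b") +
    ggplot2::labs(
      x = "transformed likelihood ratio (null simulations)", y = "count",
      title = sprintf(
        "observed TLR = %.2f, MC p = %.4f", object$tlr_observed, object$p_mc
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of attention-related delta z-values
#'
#' Group means with standard errors of the z-standardized valid-minus-invalid
#' differences, accuracy next to certainty; positive bars mean the measure
#' increased with attention.
#'
#' @param deltas Output of [delta_z()] (or the `deltas` element of a run).
#' @return A ggplot object.
#' @export
plot_delta_z <- function(deltas) {
  summ <- deltas |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      mean = mean(.data$delta),
      se = sd(.data$delta) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$measure, y = .data$mean, fill = .data$measure)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.15
    ) +
    ggplot2::scale_fill_manual(values = c(accuracy = "grey25", certainty = "#762a83")) +
    ggplot2::labs(x = NULL, y = expression(Delta * " z-value (valid - invalid)")) +
    ggplot2::theme_minimal()
}

#' @method autoplot attencert_run
#' @export
autoplot.attencert_run <- function(object, ...) {
  plot_delta_z(object$deltas)
}

#' Plot a staircase trace
#'
#' Coherence level against trial number for each staircase restart.
#'
#' @param runs Output of [run_staircase()] (with its `"trace"` attribute).
#' @return A ggplot object.
#' @export
plot_staircase <- function(runs) {
  trace <- attr(runs, "trace")
  stopifnot(!is.null(trace))
  ggplot2::ggplot(
    trace,
    ggplot2::aes(x = .data$trial, y = .data$coherence, group = .data$restart)
  ) +
    ggplot2::geom_step(alpha = 0.6, colour = "#2166ac") +
    ggplot2::labs(x = "trial", y = "motion coherence (%)") +
    ggplot2::theme_minimal()
}
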