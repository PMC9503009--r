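# ggplot2 visualisations for the fitted objects.

#' Plot a Michaelis-Menten fit
#'
#' Specific uptake versus substrate concentration with the fitted saturation
#' curve per experiment.
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  d <- object$data
  d$conc <- d[[object$conc]]
  d$v <- d[[object$value]]
  d$experiment <- factor(d$experiment_id)
  grid <- tidyr::expand_grid(
    conc = seq(0, max(d$conc), length.out = 120),
    object$by_experiment[c("experiment_id", "Km", "Vmax")]
  ) |>
    dplyr::mutate(
      v = .data$Vmax * .data$conc / (.data$Km + .data$conc),
      experiment = factor(.data$experiment_id)
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$conc, .data$v, colour = .data$experiment)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(
      x = "substrate (uM)", y = "specific uptake (AFU)",
      colour = "experiment"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an inhibition fit
#'
#' Remaining activity versus MTS reagent concentration (log scale; the
#' zero-concentration anchor is drawn at the left edge) with the fitted
#' curve per experiment.
#'
#' @param object An `inhibition_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot inhibition_fit
#' @export
autoplot.inhibition_fit <- function(object, ...) {
  d <- object$data
  d$conc <- d[[object$conc]]
  d$activity <- d[[object$value]]
  cmin <- min(d$conc[d$conc > 0])
  d$conc_plot <- ifelse(d$conc == 0, cmin / 10, d$conc)
  d$experiment <- factor(d$experiment_id)
  b <- dplyr::filter(object$by_experiment, !.data$below_detection, .data$converged)
  t_exp <- object$t_exposure
  grid <- NULL
  if (nrow(b)) {
    grid <- tidyr::expand_grid(
      conc = 10^seq(log10(cmin / 10), log10(max(d$conc)), length.out = 150),
      b[c("experiment_id", "A0", "floor", "k")]
    ) |>
      dplyr::mutate(
        activity = .data$floor +
          (.data$A0 - .data$floor) * exp(-.data$k * .data$conc * t_exp),
        conc_plot = .data$conc,
        experiment = factor(.data$experiment_id)
      )
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$conc_plot, .data$activity,
    colour = .data$experiment
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "MTS reagent (M)", y = "remaining activity (AFU)",
      colour = "experiment"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(grid)) p <- p + ggplot2::geom_line(data = grid)
  p
}

#' Bar plot of rate-constant fold-changes
#'
#' @param comparisons A tibble of [compare_conditions()] rows.
#' @param ... Unused.
#' @return A ggplot with significance marks (`*` for p below 0.05).
#' @export
plot_comparisons <- function(comparisons, ...) {
  d <- dplyr::mutate(
    tibble::as_tibble(comparisons),
    sig = ifelse(.data$p_value < 0.05, "*", "")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$fold_change)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig),
      vjust = -0.3, size = 6
    ) +
    ggplot2::labs(x = NULL, y = "rate-constant fold vs control") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
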