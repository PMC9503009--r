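# broom-style methods for fitted objects.

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return Long tibble: `experiment_id`, `term`, `estimate`, `std.error`.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  b <- x$by_experiment
  dplyr::bind_rows(
    tibble::tibble(
      experiment_id = b$experiment_id, term = "Km",
      estimate = b$Km, std.error = b$Km_se
    ),
    tibble::tibble(
      experiment_id = b$experiment_id, term = "Vmax",
      estimate = b$Vmax, std.error = b$Vmax_se
    )
  ) |> dplyr::arrange(.data$experiment_id, .data$term)
}

#' Glance at a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return One-row tibble with cross-experiment `Km`, `Km_sem`, `Vmax`,
#'   `Vmax_sem`, `n_experiments`, `unreliable`.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) x$summary

#' Tidy an inhibition fit
#'
#' @param x An `inhibition_fit`.
#' @param ... Unused.
#' @return Long tibble of per-experiment parameters (`A0`, `floor`, `c50`,
#'   `k`), with the standard error for `k`.
#' @method tidy inhibition_fit
#' @export
tidy.inhibition_fit <- function(x, ...) {
  b <- x$by_experiment
  purrr::map(c("A0", "floor", "c50", "k"), function(tm) {
    tibble::tibble(
      experiment_id = b$experiment_id, term = tm, estimate = b[[tm]],
      std.error = if (tm == "k") b$k_se else NA_real_,
      below_detection = b$below_detection
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$experiment_id)
}

#' Glance at an inhibition fit
#'
#' @param x An `inhibition_fit`.
#' @param ... Unused.
#' @return One-row tibble with the cross-experiment rate-constant summary.
#' @method glance inhibition_fit
#' @export
glance.inhibition_fit <- function(x, ...) {
  dplyr::mutate(x$summary, model = x$model, t_exposure = x$t_exposure)
}
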