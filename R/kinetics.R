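#' Subtract fluoxetine-defined nonspecific signal
#'
#' Specific accumulation is total minus the signal measured with 10 uM
#' fluoxetine present, matched concentration-wise (and per experiment when an
#' `experiment_id` column is present). No interpolation: both series must
#' cover the same concentration grid.
#'
#' @param total,blocked Tibbles with the concentration column, a value column,
#'   and optionally `experiment_id`. When `blocked` is `NULL`, `total` must
#'   contain a logical `fluoxetine_block` column and is split internally.
#' @param conc Name of the concentration column.
#' @param value Name of the value column.
#' @return A tibble like `total` with `value` replaced by the specific signal
#'   (negative differences floored at 0 with a warning) and a `blocked`
#'   column holding the subtracted component.
#' @export
subtract_nonspecific <- function(total, blocked = NULL,
                                 conc = "substrate_conc_uM", value = "mean") {
  total <- tibble::as_tibble(total)
  if (is.null(blocked)) {
    if (!"fluoxetine_block" %in% names(total)) {
      abort("supply `blocked` or a `fluoxetine_block` column")
    }
    blocked <- dplyr::filter(total, .data$fluoxetine_block)
    total <- dplyr::filter(total, !.data$fluoxetine_block)
  }
  blocked <- tibble::as_tibble(blocked)
  keys <- c(
    conc,
    intersect(
      c("experiment_id", "ion_medium", "digitonin_ug_ml", "mutant", "substrate"),
      intersect(names(total), names(blocked))
    )
  )
  tkey <- do.call(paste, total[keys])
  bkey <- do.call(paste, blocked[keys])
  if (anyDuplicated(tkey) || anyDuplicated(bkey)) {
    abort("duplicate concentration keys; aggregate per condition first")
  }
  if (length(tkey) != length(bkey) || !setequal(tkey, bkey)) {
    abort("total and blocked series are on different concentration grids")
  }
  blocked_vals <- blocked[[value]][match(tkey, bkey)]
  specific <- total[[value]] - blocked_vals
  if (any(specific < 0)) {
    warn(sprintf(
      "%d specific value(s) were negative and floored at 0",
      sum(specific < 0)
    ))
    specific <- pmax(specific, 0)
  }
  out <- total
  out[[value]] <- specific
  out$blocked <- blocked_vals
  out
}

mm_start <- function(s, v) {
  vmax0 <- max(v)
  half <- vmax0 / 2
  km0 <- s[which.min(abs(v - half))]
  list(Vmax = vmax0, Km = max(km0, min(s[s > 0]) / 2))
}

fit_mm_one <- function(s, v) {
  if (length(unique(s)) < 4L) abort("need >= 4 distinct concentrations")
  st <- mm_start(s, v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * s / (Km + s),
      start = st, lower = c(Vmax = 0, Km = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(
      Km = NA_real_, Vmax = NA_real_, Km_se = NA_real_, Vmax_se = NA_real_,
      n_points = length(s), rss = NA_real_, converged = FALSE,
      unreliable = TRUE
    ))
  }
  co <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  tibble::tibble(
    Km = co[["Km"]], Vmax = co[["Vmax"]],
    Km_se = se[["Km"]], Vmax_se = se[["Vmax"]],
    n_points = length(s), rss = sum(stats::resid(fit)^2),
    converged = TRUE, unreliable = co[["Km"]] > max(s)
  )
}

#' Fit Michaelis-Menten transport kinetics
#'
#' Unweighted least-squares fit of `v = Vmax * S / (Km + S)` to specific
#' (nonspecific-subtracted) uptake, per experiment, with parameter standard
#' errors from the fit curvature. Experiments are aggregated as the mean of
#' per-experiment estimates with its SEM (mean-of-fits, not a pooled fit).
#' A fit whose Km exceeds the highest tested concentration is flagged
#' unreliable.
#'
#' @param specific Tibble of specific uptake (e.g. from
#'   [subtract_nonspecific()]).
#' @param conc,value Column names for concentration (uM) and uptake (AFU).
#' @return An object of class `mm_fit`: list with `by_experiment` (tibble of
#'   per-experiment fits) and `summary` (cross-experiment mean +/- SEM).
#' @export
fit_mm <- function(specific, conc = "substrate_conc_uM", value = "mean") {
  specific <- tibble::as_tibble(specific)
  if (!"experiment_id" %in% names(specific)) specific$experiment_id <- 1L
  by_exp <- specific |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::group_modify(~ fit_mm_one(.x[[conc]], .x[[value]])) |>
    dplyr::ungroup()
  ok <- dplyr::filter(by_exp, .data$converged)
  n <- nrow(ok)
  summary <- tibble::tibble(
    n_experiments = n,
    Km = mean(ok$Km), Km_sem = if (n > 1) sd(ok$Km) / sqrt(n) else NA_real_,
    Vmax = mean(ok$Vmax),
    Vmax_sem = if (n > 1) sd(ok$Vmax) / sqrt(n) else NA_real_,
    unreliable = any(ok$unreliable)
  )
  structure(
    list(by_experiment = by_exp, summary = summary, data = specific,
         conc = conc, value = value),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mm_fit> Km = %.3g +/- %.2g uM, Vmax = %.3g +/- %.2g AFU (%d experiment%s)%s\n",
    s$Km, s$Km_sem, s$Vmax, s$Vmax_sem, s$n_experiments,
    if (s$n_experiments == 1) "" else "s",
    if (isTRUE(s$unreliable)) " [unreliable]" else ""
  ))
  invisible(x)
}

#' Ion dependence of specific uptake
#'
#' Normalizes specific uptake per ion medium to the NaCl reference
#' (NaCl = 1). Media are averaged over experiments first when several are
#' present.
#'
#' @param condition_means Tibble with `ion_medium` and a value column of
#'   specific uptake.
#' @param value Value column name.
#' @return Tibble with `ion_medium`, `uptake`, `relative_uptake`.
#' @export
ion_uptake_panel <- function(condition_means, value = "mean") {
  df <- tibble::as_tibble(condition_means)
  if (!"ion_medium" %in% names(df)) abort("no `ion_medium` column")
  df <- df |>
    dplyr::group_by(.data$ion_medium) |>
    dplyr::summarise(uptake = mean(.data[[value]]), .groups = "drop")
  ref <- df$uptake[df$ion_medium == "NaCl"]
  if (length(ref) != 1L) abort("NaCl reference medium is missing")
  if (!is.finite(ref) || ref <= 0) abort("NaCl reference uptake is zero; cannot normalize")
  dplyr::mutate(df, relative_uptake = .data$uptake / ref)
}
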