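# Concentration-inhibition fitting and conversion to pseudo-first-order
# modification rate constants -- the core statistic of the assay.

#' First-order rate at half-maximal modification
#'
#' When a fixed exposure of duration `t_exposure` produces half-maximal
#' modification, the modification half-time equals the exposure time, so the
#' first-order rate constant is `ln(2) / t_exposure` (7.7e-4 s^-1 for a
#' 15-min exposure).
#'
#' @param t_exposure Exposure time in seconds.
#' @return Rate constant in s^-1.
#' @export
first_order_rate <- function(t_exposure) {
  if (any(!is.finite(t_exposure) | t_exposure <= 0)) {
    abort("`t_exposure` must be > 0")
  }
  log(2) / t_exposure
}

#' Convert a half-maximal reagent concentration into a rate constant
#'
#' The pseudo-first-order modification rate constant is the first-order rate
#' constant at half-maximal modification, `ln(2)/t_exposure`, divided by the
#' half-maximal reagent concentration:
#' `k = ln(2) / (t_exposure * c50)`, in M^-1 s^-1.
#'
#' @param c50 Half-maximal reagent concentration, molar.
#' @param t_exposure Exposure time, seconds.
#' @return k in M^-1 s^-1 (vectorized).
#' @export
rate_constant_from_c50 <- function(c50, t_exposure) {
  if (any(!is.finite(t_exposure) | t_exposure <= 0)) abort("`t_exposure` must be > 0")
  if (any(is.na(c50)) || any(c50 <= 0)) abort("`c50` must be > 0")
  first_order_rate(t_exposure) / c50
}

# Fit one activity-vs-concentration series. Returns a one-row tibble.
fit_inhibition_one <- function(conc, activity, t_exposure,
                               model = c("exponential", "logistic"),
                               floor_threshold = 0.05,
                               detection_threshold = 0.2) {
  model <- match.arg(model)
  if (length(unique(conc)) < 4L || !any(conc == 0)) {
    abort("need >= 4 reagent concentrations including 0")
  }
  check_number(t_exposure, "t_exposure", positive = TRUE)
  a0_start <- mean(activity[conc == 0])
  c_max <- max(conc)
  detection_bound <- first_order_rate(t_exposure) / c_max
  row0 <- tibble::tibble(
    A0 = a0_start, floor = 0, c50 = NA_real_, k = NA_real_, k_se = NA_real_,
    below_detection = FALSE, detection_bound = detection_bound,
    t_exposure = t_exposure, model = model, converged = TRUE
  )

  top <- conc == c_max
  max_inhib <- 1 - min(mean(activity[top]), min(activity)) / a0_start
  if (!is.finite(max_inhib) || max_inhib < detection_threshold) {
    row0$below_detection <- TRUE
    return(row0)
  }
  plateau_frac <- mean(activity[top]) / a0_start
  fit_floor <- plateau_frac > floor_threshold

  if (model == "exponential") {
    mid <- conc > 0 & activity > 0 & activity < 0.9 * a0_start
    k0 <- if (any(mid)) {
      median(-log(pmax(activity[mid] / a0_start, 1e-6)) / (conc[mid] * t_exposure))
    } else {
      first_order_rate(t_exposure) / median(conc[conc > 0])
    }
    fit <- NULL
    if (fit_floor) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          activity ~ fl + (A0 - fl) * exp(-k * conc * t_exposure),
          start = list(A0 = a0_start, fl = plateau_frac * a0_start, k = k0),
          lower = c(A0 = 0, fl = 0, k = 0),
          control = minpack.lm::nls.lm.control(maxiter = 500)
        ),
        error = function(e) NULL
      )
    }
    if (is.null(fit)) {
      fit_floor <- FALSE
      fit <- tryCatch(
        minpack.lm::nlsLM(
          activity ~ A0 * exp(-k * conc * t_exposure),
          start = list(A0 = a0_start, k = k0), lower = c(A0 = 0, k = 0),
          control = minpack.lm::nls.lm.control(maxiter = 500)
        ),
        error = function(e) NULL
      )
    }
    if (is.null(fit)) {
      row0$converged <- FALSE
      return(row0)
    }
    co <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(co)))
    row0$A0 <- co[["A0"]]
    row0$floor <- if (fit_floor) co[["fl"]] else 0
    row0$k <- co[["k"]]
    row0$k_se <- unname(se[which(names(co) == "k")])
    # for first-order modification the half-point between A0 and the floor
    # always sits at exp(-k c t) = 1/2
    row0$c50 <- log(2) / (co[["k"]] * t_exposure)
  } else {
    c50_0 <- conc[which.min(abs(activity - (a0_start + plateau_frac * a0_start) / 2))]
    if (c50_0 <= 0) c50_0 <- median(conc[conc > 0])
    fit <- NULL
    if (fit_floor) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          activity ~ fl + (A0 - fl) / (1 + (conc / c50)^h),
          start = list(A0 = a0_start, fl = plateau_frac * a0_start, c50 = c50_0, h = 1),
          lower = c(A0 = 0, fl = 0, c50 = 1e-12, h = 0.2),
          control = minpack.lm::nls.lm.control(maxiter = 500)
        ),
        error = function(e) NULL
      )
    }
    if (is.null(fit)) {
      fit_floor <- FALSE
      fit <- tryCatch(
        minpack.lm::nlsLM(
          activity ~ A0 / (1 + (conc / c50)^h),
          start = list(A0 = a0_start, c50 = c50_0, h = 1),
          lower = c(A0 = 0, c50 = 1e-12, h = 0.2),
          control = minpack.lm::nls.lm.control(maxiter = 500)
        ),
        error = function(e) NULL
      )
    }
    if (is.null(fit)) {
      row0$converged <- FALSE
      return(row0)
    }
    co <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(co)))
    c50 <- co[["c50"]]
    c50_se <- unname(se[which(names(co) == "c50")])
    row0$A0 <- co[["A0"]]
    row0$floor <- if (fit_floor) co[["fl"]] else 0
    row0$c50 <- c50
    row0$k <- rate_constant_from_c50(c50, t_exposure)
    row0$k_se <- if (is.finite(c50_se)) row0$k * c50_se / c50 else NA_real_
  }
  row0
}

#' Fit MTS concentration-inhibition curves
#'
#' Fits remaining activity versus reagent concentration after a fixed
#' exposure, per experiment, and converts the half-maximal concentration into
#' the pseudo-first-order modification rate constant
#' `k = ln(2)/(t_exposure * c50)`.
#'
#' Two curve models are available. The `exponential` model (default) fits the
#' first-order kinetic scheme `A(c) = floor + (A0 - floor) exp(-k c t)`
#' directly for `k`; its half-maximal concentration is `ln(2)/(k t)` exactly.
#' The `logistic` model fits an empirical sigmoid
#' `A(c) = floor + (A0 - floor)/(1 + (c/c50)^h)` and converts the fitted
#' midpoint. The floor (residual-activity plateau) is fixed at 0 unless the
#' high-concentration plateau exceeds `floor_threshold` of A0 (default 5%,
#' which captures the nonspecific-signal plateau of uncorrected
#' accumulation readouts). When maximal observed
#' inhibition is below 20%, no rate is fitted and `k` is reported only as
#' below the detection bound `ln(2)/(t_exposure * c_max)`.
#'
#' @param data Tibble with reagent concentration and activity columns,
#'   optionally `experiment_id`.
#' @param conc,value Column names (concentration in molar; activity in AFU).
#' @param t_exposure Exposure time in seconds; defaults to the table's
#'   `mts_time_s`.
#' @param model `"exponential"` or `"logistic"`.
#' @param floor_threshold Plateau fraction of A0 above which a floor is
#'   fitted.
#' @param detection_threshold Minimal observed inhibition fraction for a fit.
#' @return Object of class `inhibition_fit`: `by_experiment` tibble and a
#'   cross-experiment `summary` (mean k +/- SEM over experiments).
#' @export
fit_inhibition <- function(data, conc = "mts_conc_M", value = "mean",
                           t_exposure = NULL,
                           model = c("exponential", "logistic"),
                           floor_threshold = 0.05, detection_threshold = 0.2) {
  model <- match.arg(model)
  data <- tibble::as_tibble(data)
  if (is.null(t_exposure)) {
    if (!"mts_time_s" %in% names(data)) {
      abort("supply `t_exposure` or an `mts_time_s` column")
    }
    tt <- unique(data$mts_time_s[data[[conc]] > 0])
    if (length(tt) != 1L) abort("exposure time is not unique in the data")
    t_exposure <- tt
  }
  if (!"experiment_id" %in% names(data)) data$experiment_id <- 1L
  by_exp <- data |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::group_modify(~ fit_inhibition_one(
      .x[[conc]], .x[[value]], t_exposure,
      model = model,
      floor_threshold = floor_threshold,
      detection_threshold = detection_threshold
    )) |>
    dplyr::ungroup()
  ok <- dplyr::filter(by_exp, .data$converged & !.data$below_detection)
  n <- nrow(ok)
  summary <- tibble::tibble(
    n_experiments = nrow(by_exp),
    n_fitted = n,
    k = if (n) mean(ok$k) else NA_real_,
    k_sem = if (n > 1) sd(ok$k) / sqrt(n) else NA_real_,
    c50 = if (n) mean(ok$c50) else NA_real_,
    below_detection = all(by_exp$below_detection),
    detection_bound = first_order_rate(t_exposure) / max(data[[conc]])
  )
  structure(
    list(
      by_experiment = by_exp, summary = summary, data = data,
      conc = conc, value = value, t_exposure = t_exposure, model = model
    ),
    class = "inhibition_fit"
  )
}

#' @export
print.inhibition_fit <- function(x, ...) {
  s <- x$summary
  if (isTRUE(s$below_detection)) {
    cat(sprintf(
      "<inhibition_fit> below detection: k < %.3g M^-1 s^-1 (%s model, t = %g s)\n",
      s$detection_bound, x$model, x$t_exposure
    ))
  } else {
    cat(sprintf(
      "<inhibition_fit> k = %.4g +/- %.2g M^-1 s^-1, c50 = %.3g M (%s model, t = %g s, %d experiment%s)\n",
      s$k, s$k_sem, s$c50, x$model, x$t_exposure, s$n_experiments,
      if (s$n_experiments == 1) "" else "s"
    ))
  }
  invisible(x)
}

#' Fit inhibition curves for every condition in a table
#'
#' Groups a condition-level table by the non-concentration condition columns
#' and fits each group with [fit_inhibition()], returning tidy
#' per-(condition, experiment) rows. The zero-concentration (reagent "none")
#' rows within each (mutant, ligand, medium, digitonin) stratum anchor A0.
#'
#' @param data Condition-level tibble (e.g. [aggregate_cells()] output).
#' @param value Activity column.
#' @param ... Passed to [fit_inhibition()].
#' @return Tibble of per-experiment fits with grouping columns.
#' @export
fit_inhibition_panel <- function(data, value = "mean", ...) {
  data <- tibble::as_tibble(data)
  groups <- intersect(
    c("mutant", "ligand", "ion_medium", "digitonin_ug_ml", "substrate"),
    names(data)
  )
  # ligand/reagent of the zero-concentration anchor rows is "none"; regroup
  # them with each treated stratum
  strata <- dplyr::distinct(
    dplyr::filter(data, .data$mts_conc_M > 0),
    dplyr::across(dplyr::all_of(groups))
  )
  purrr::map(seq_len(nrow(strata)), function(i) {
    st <- strata[i, ]
    match_cols <- setdiff(groups, "ligand")
    sel <- rep(TRUE, nrow(data))
    for (cl in match_cols) sel <- sel & data[[cl]] == st[[cl]]
    if ("ligand" %in% groups) {
      sel <- sel & (data$ligand == st$ligand |
        (data$mts_conc_M == 0 & data$ligand == "none"))
    }
    sub <- data[sel, ]
    fit <- fit_inhibition(sub, value = value, ...)
    dplyr::bind_cols(st[rep(1L, nrow(fit$by_experiment)), ], fit$by_experiment)
  }) |>
    dplyr::bind_rows()
}

#' Ligand protection at a fixed, half-inhibiting reagent concentration
#'
#' The simplified protocol: the MTS reagent is applied once at (about) its
#' half-inhibiting concentration with and without a ligand, and the implied
#' fold-change of the modification rate constant is back-calculated under the
#' first-order model:
#' `k_ligand / k_ctrl = log(A_ligand/A0) / log(A_ctrl/A0)`.
#'
#' @param activity_mts Remaining activity with reagent alone (per experiment).
#' @param activity_mts_ligand Remaining activity with reagent + ligand.
#' @param activity_untreated Activity without reagent (A0).
#' @return Tibble per experiment: remaining-activity fractions `f_ctrl`,
#'   `f_ligand`, the rate fold-change `k_fold`, and a `flag`
#'   (`"full_protection"` when the ligand abolishes modification,
#'   `"capped"` when activity hit 0, otherwise `NA`). Warns when the
#'   reagent-alone condition is far from half-inhibition (outside 0.3-0.7 of
#'   untreated).
#' @export
fixed_concentration_protection <- function(activity_mts, activity_mts_ligand,
                                           activity_untreated) {
  n <- length(activity_mts)
  if (length(activity_mts_ligand) != n || length(activity_untreated) != n) {
    abort("per-experiment activity vectors must have equal length")
  }
  f_ctrl <- activity_mts / activity_untreated
  f_lig <- activity_mts_ligand / activity_untreated
  if (any(f_ctrl < 0.3 | f_ctrl > 0.7)) {
    warn("reagent-alone activity is outside 0.3-0.7 of untreated; the back-calculated fold is less reliable")
  }
  flag <- rep(NA_character_, n)
  k_fold <- numeric(n)
  for (i in seq_len(n)) {
    if (f_lig[i] >= 1) {
      k_fold[i] <- 0
      flag[i] <- "full_protection"
    } else if (f_lig[i] <= 0) {
      k_fold[i] <- log(1e-6) / log(f_ctrl[i])
      flag[i] <- "capped"
    } else {
      k_fold[i] <- log(f_lig[i]) / log(f_ctrl[i])
    }
  }
  tibble::tibble(
    experiment = seq_len(n), f_ctrl = f_ctrl, f_ligand = f_lig,
    k_fold = k_fold, flag = flag
  )
}
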