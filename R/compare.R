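# Rate-constant comparison across conditions and the conformational call.

#' Compare rate constants between a condition and its control
#'
#' Pairs per-experiment rate constants (or single-concentration remaining
#' activities back-calculated to rate folds) by experiment, tests the paired
#' difference with Student's paired t-test, and summarizes the effect as the
#' geometric mean of per-experiment ratios (so swapping condition and control
#' inverts the fold exactly and leaves the p-value unchanged).
#'
#' @param fits_cond,fits_ctrl Tibbles with `experiment_id` and a value column
#'   (default `k`), one row per experiment.
#' @param value Value column name.
#' @param alpha Significance level.
#' @param min_fold Minimal fold (on either side of 1) for calling a
#'   direction; effects with `|log(fold)| < log(min_fold)` are "unchanged"
#'   regardless of p.
#' @param condition,control Labels carried into the result.
#' @param pathway Optional pathway label ("extracellular"/"cytoplasmic").
#' @return One-row tibble of class `scam_comparison`: `condition`, `control`,
#'   `pathway`, `n_pairs`, `fold_change`, `folds` (list column of
#'   per-experiment ratios), `p_value`, `direction`.
#' @export
compare_conditions <- function(fits_cond, fits_ctrl, value = "k",
                               alpha = 0.05, min_fold = 1.2,
                               condition = "condition", control = "control",
                               pathway = NA_character_) {
  fits_cond <- tibble::as_tibble(fits_cond)
  fits_ctrl <- tibble::as_tibble(fits_ctrl)
  for (df in list(fits_cond, fits_ctrl)) {
    if (!all(c("experiment_id", value) %in% names(df))) {
      abort(sprintf("fit tables need columns `experiment_id` and `%s`", value))
    }
  }
  if (!setequal(fits_cond$experiment_id, fits_ctrl$experiment_id) ||
    anyDuplicated(fits_cond$experiment_id) ||
    anyDuplicated(fits_ctrl$experiment_id)) {
    abort("experiments are not paired one-to-one between condition and control")
  }
  if (nrow(fits_cond) < 2L) abort("need >= 2 paired experiments")
  ord <- match(fits_ctrl$experiment_id, fits_cond$experiment_id)
  x <- fits_cond[[value]][ord]
  y <- fits_ctrl[[value]]
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(y <= 0) || any(x <= 0)) {
    abort("rate constants must be finite and > 0 in both groups (below-detection fits cannot be compared)")
  }
  folds <- x / y
  fold <- geometric_mean(folds)
  d <- x - y
  p <- if (all(d == 0)) {
    1
  } else if (sd(d) == 0) {
    # perfectly consistent nonzero paired difference
    0
  } else {
    t.test(x, y, paired = TRUE)$p.value
  }
  direction <- if (p >= alpha || abs(log(fold)) < log(min_fold)) {
    "unchanged"
  } else if (fold > 1) {
    "increased"
  } else {
    "decreased"
  }
  out <- tibble::tibble(
    condition = condition, control = control, pathway = pathway,
    n_pairs = length(folds), fold_change = fold, folds = list(folds),
    p_value = p, direction = direction
  )
  class(out) <- c("scam_comparison", class(out))
  out
}

#' Classify the conformational effect from both pathways
#'
#' Maps the accessibility directions of the extracellular and cytoplasmic
#' reporter cysteines onto a conformational call:
#'
#' * extracellular increased, cytoplasmic decreased -> "outward-open
#'   stabilized" (the antidepressant / vilazodone pattern);
#' * extracellular decreased, cytoplasmic increased -> "inward-open shifted"
#'   when both folds pass the full-shift thresholds, otherwise
#'   "partial/intermediate" (the Cl- pattern);
#' * both unchanged -> "no change";
#' * anything else -> "discordant".
#'
#' @param extracellular,cytoplasmic `scam_comparison` rows for the two
#'   pathways (same control condition).
#' @param full_shift_ext Extracellular fold at or below which an inward shift
#'   counts as full.
#' @param full_shift_cyto Cytoplasmic fold at or above which an inward shift
#'   counts as full.
#' @return One-row tibble: directions, folds and `call`.
#' @export
call_conformation <- function(extracellular, cytoplasmic,
                              full_shift_ext = 0.6, full_shift_cyto = 1.67) {
  if (!identical(extracellular$control, cytoplasmic$control)) {
    abort("extracellular and cytoplasmic comparisons use different controls")
  }
  de <- extracellular$direction
  dc <- cytoplasmic$direction
  call <- if (de == "increased" && dc == "decreased") {
    "outward-open stabilized"
  } else if (de == "decreased" && dc == "increased") {
    if (extracellular$fold_change <= full_shift_ext &&
      cytoplasmic$fold_change >= full_shift_cyto) {
      "inward-open shifted"
    } else {
      "partial/intermediate"
    }
  } else if (de == "unchanged" && dc == "unchanged") {
    "no change"
  } else {
    "discordant"
  }
  tibble::tibble(
    condition = extracellular$condition,
    control = extracellular$control,
    extracellular_direction = de, cytoplasmic_direction = dc,
    extracellular_fold = extracellular$fold_change,
    cytoplasmic_fold = cytoplasmic$fold_change,
    call = call
  )
}

#' Ordered ion-panel contrasts for one pathway
#'
#' Reproduces the standard ion-panel analysis: every medium against the
#' NMDG-gluconate reference, plus NaCl vs Na-isethionate (the Cl- effect in
#' the presence of Na+) and NaCl+5-HT vs NaCl (the substrate effect). Flags
#' the chloride signature: NaCl shifted from Na-isethionate toward the
#' 5-HT direction but not beyond it.
#'
#' @param fits Tibble of per-experiment rate constants with columns
#'   `ion_medium`, `experiment_id`, and the value column.
#' @param value Value column (default `k`).
#' @param alpha,min_fold Passed to [compare_conditions()].
#' @return List with `comparisons` (tibble of contrasts) and
#'   `chloride_signature` (logical).
#' @export
ion_panel_analysis <- function(fits, value = "k", alpha = 0.05,
                               min_fold = 1.2) {
  fits <- tibble::as_tibble(fits)
  media <- ion_medium_levels()
  missing <- setdiff(media, unique(fits$ion_medium))
  if (length(missing)) {
    abort(paste0("ion media missing from fits: ", paste(missing, collapse = ", ")))
  }
  get_m <- function(m) dplyr::filter(fits, .data$ion_medium == m)
  contrasts <- list(
    c("NMDG-Cl", "NMDG-gluconate"),
    c("Na-isethionate", "NMDG-gluconate"),
    c("NaCl", "NMDG-gluconate"),
    c("NaCl+5-HT", "NMDG-gluconate"),
    c("NaCl", "Na-isethionate"),
    c("NaCl+5-HT", "NaCl")
  )
  comparisons <- purrr::map(contrasts, function(ct) {
    compare_conditions(get_m(ct[1]), get_m(ct[2]),
      value = value,
      alpha = alpha, min_fold = min_fold,
      condition = ct[1], control = ct[2]
    )
  }) |> dplyr::bind_rows()

  cl_effect <- comparisons[comparisons$condition == "NaCl" &
    comparisons$control == "Na-isethionate", ]
  ht_vs_iseth <- geometric_mean(
    get_m("NaCl+5-HT")[[value]] / get_m("Na-isethionate")[[value]][
      match(
        get_m("NaCl+5-HT")$experiment_id,
        get_m("Na-isethionate")$experiment_id
      )
    ]
  )
  # qualitative signature: adding Cl- moves the rate in the direction the
  # substrate moves it, but only part of the way
  same_direction <- sign(log(cl_effect$fold_change)) == sign(log(ht_vs_iseth))
  not_beyond <- abs(log(cl_effect$fold_change)) < abs(log(ht_vs_iseth))
  chloride_signature <- isTRUE(same_direction && not_beyond &&
    abs(log(cl_effect$fold_change)) > 0)
  list(comparisons = comparisons, chloride_signature = chloride_signature)
}
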