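#' Mechanistic parameters of the simulated assay
#'
#' Collects every constant of the generative model: Michaelis-Menten transport
#' of the fluorescent substrates APP+ and ASP+, saturable ASP+ membrane
#' binding, fluoxetine-insensitive (nonspecific) signal, pseudo-first-order
#' MTS modification rate constants per reporter cysteine, multiplicative
#' ligand/ion accessibility factors, digitonin permeabilization behaviour and
#' biological cell-to-cell variability.
#'
#' Transport defaults are the wild-type constants measured for the serotonin
#' transporter with these substrates: Km 2.63 uM (APP+) and 8.52 uM (ASP+),
#' Vmax 30.5 and 75.8 AFU. Nonspecific fractions are parameterized so that 95%
#' of APP+ and 84% of ASP+ accumulation at the top of the default
#' concentration ladder is blockable by 10 uM fluoxetine. Baseline
#' modification rate constants are 70 M^-1 s^-1 (Y107C/C109A, MTSET),
#' 308 M^-1 s^-1 (S404C/C109A, MTSET), 11.97 M^-1 s^-1 (S277C/X5C, MTSEA) and
#' 0.05 M^-1 s^-1 (X5C background, MTSEA); C109A carries no MTSET-reactive
#' cysteine and the cytoplasmic Cys277 is inaccessible to the bulkier MTSET
#' even after permeabilization.
#'
#' @param km_app,km_asp Michaelis constants, micromolar.
#' @param vmax_app,vmax_asp Maximal specific uptake, AFU.
#' @param kd_bind_asp,bmax_asp ASP+ surface-binding affinity (uM) and
#'   capacity (AFU).
#' @param ns_uptake_frac_app,ns_uptake_frac_asp Fraction of *total*
#'   accumulation that is nonspecific at the reference (near-saturating)
#'   concentration.
#' @param ref_conc_app,ref_conc_asp Reference concentrations (uM) at which the
#'   nonspecific fractions are defined; defaults are the top of the standard
#'   kinetics ladders.
#' @param ns_bind_frac Nonspecific fraction of ASP+ membrane binding at
#'   `ref_conc_bind`.
#' @param ref_conc_bind Reference concentration for `ns_bind_frac` (uM); the
#'   standard binding-assay concentration.
#' @param k_base Tibble (`mutant`, `reagent`, `k`) of baseline modification
#'   rate constants, per molar per second.
#' @param ligand_fold Tibble (`ligand`, `pathway`, `fold`) of multiplicative
#'   ligand effects on the rate constant.
#' @param ion_fold Tibble (`medium`, `pathway`, `fold`) of multiplicative ion
#'   effects on the rate constant (modification-phase medium).
#' @param residual_modifiable_floor Fraction of activity that can never be
#'   inhibited even at complete modification.
#' @param digitonin_uptake_ic50,digitonin_uptake_hill Digitonin concentration
#'   (ug/mL) halving specific uptake, and the Hill slope of the loss.
#' @param digitonin_bind_retention_25 Fraction of specific ASP+ membrane
#'   binding retained at 25 ug/mL digitonin (retention decays geometrically
#'   with concentration).
#' @param digitonin_access Two-column matrix-like (`conc`, `completeness`)
#'   giving the modifiable fraction of cytoplasmic-pathway cysteines versus
#'   digitonin concentration; linearly interpolated, clamped to [0, 1].
#' @param exposure_time_mtset,exposure_time_mtsea Default MTS exposure times,
#'   seconds (15 min for MTSET on intact cells, 5 min for MTSEA on
#'   permeabilized cells).
#' @param uptake_time Substrate accumulation time, seconds.
#' @param cell_autofluor Substrate-independent cellular autofluorescence,
#'   AFU. Part of the fluoxetine-insensitive signal (it is present in blocked
#'   conditions and removed by nonspecific subtraction); it keeps cells
#'   detectable in conditions with little specific signal.
#' @param cell_cv Lognormal coefficient of variation of per-cell expression
#'   applied to specific signal components.
#' @return An object of class `mechanism_params`.
#' @export
mechanism_params <- function(
    km_app = 2.63, vmax_app = 30.5,
    km_asp = 8.52, vmax_asp = 75.8,
    kd_bind_asp = 5, bmax_asp = 40,
    ns_uptake_frac_app = 0.05, ns_uptake_frac_asp = 0.16,
    ref_conc_app = 15, ref_conc_asp = 40,
    ns_bind_frac = 0.10, ref_conc_bind = 10,
    k_base = default_k_base(),
    ligand_fold = default_ligand_fold(),
    ion_fold = default_ion_fold(),
    residual_modifiable_floor = 0,
    digitonin_uptake_ic50 = 5, digitonin_uptake_hill = 2,
    digitonin_bind_retention_25 = 0.65,
    digitonin_access = default_digitonin_access(),
    exposure_time_mtset = 900, exposure_time_mtsea = 300,
    uptake_time = 300, cell_autofluor = 1, cell_cv = 0.2) {
  for (nm in c(
    "km_app", "vmax_app", "km_asp", "vmax_asp", "kd_bind_asp", "bmax_asp",
    "ref_conc_app", "ref_conc_asp", "ref_conc_bind",
    "digitonin_uptake_ic50", "digitonin_uptake_hill",
    "exposure_time_mtset", "exposure_time_mtsea", "uptake_time"
  )) {
    check_number(get(nm), nm, positive = TRUE)
  }
  for (nm in c(
    "ns_uptake_frac_app", "ns_uptake_frac_asp", "ns_bind_frac",
    "residual_modifiable_floor", "digitonin_bind_retention_25"
  )) {
    check_fraction(get(nm), nm)
  }
  check_number(cell_cv, "cell_cv", nonneg = TRUE)
  check_number(cell_autofluor, "cell_autofluor", nonneg = TRUE)
  k_base <- tibble::as_tibble(k_base)
  stopifnot(all(c("mutant", "reagent", "k") %in% names(k_base)))
  if (any(k_base$k < 0)) abort("rate constants must be >= 0")
  structure(
    list(
      km_app = km_app, vmax_app = vmax_app, km_asp = km_asp,
      vmax_asp = vmax_asp, kd_bind_asp = kd_bind_asp, bmax_asp = bmax_asp,
      ns_uptake_frac_app = ns_uptake_frac_app,
      ns_uptake_frac_asp = ns_uptake_frac_asp,
      ref_conc_app = ref_conc_app, ref_conc_asp = ref_conc_asp,
      ns_bind_frac = ns_bind_frac, ref_conc_bind = ref_conc_bind,
      k_base = k_base,
      ligand_fold = tibble::as_tibble(ligand_fold),
      ion_fold = tibble::as_tibble(ion_fold),
      residual_modifiable_floor = residual_modifiable_floor,
      digitonin_uptake_ic50 = digitonin_uptake_ic50,
      digitonin_uptake_hill = digitonin_uptake_hill,
      digitonin_bind_retention_25 = digitonin_bind_retention_25,
      digitonin_access = as.data.frame(digitonin_access),
      exposure_time_mtset = exposure_time_mtset,
      exposure_time_mtsea = exposure_time_mtsea,
      uptake_time = uptake_time, cell_autofluor = cell_autofluor,
      cell_cv = cell_cv
    ),
    class = "mechanism_params"
  )
}

#' @export
print.mechanism_params <- function(x, ...) {
  cat(sprintf(
    "<mechanism_params> Km(APP+)=%.3g uM Vmax=%.3g AFU; Km(ASP+)=%.3g uM Vmax=%.3g AFU; %d rate constants\n",
    x$km_app, x$vmax_app, x$km_asp, x$vmax_asp, nrow(x$k_base)
  ))
  invisible(x)
}

#' @rdname mechanism_params
#' @export
default_k_base <- function() {
  tibble::tribble(
    ~mutant, ~reagent, ~k,
    "WT", "MTSET", 0,
    "C109A", "MTSET", 0,
    "Y107C/C109A", "MTSET", 70,
    "S404C/C109A", "MTSET", 308,
    "S277C/X5C", "MTSEA", 11.97,
    "X5C", "MTSEA", 0.05,
    "S277C/X5C", "MTSET", 0,
    "X5C", "MTSET", 0
  )
}

#' @rdname mechanism_params
#' @export
default_ligand_fold <- function() {
  tibble::tribble(
    ~ligand, ~pathway, ~fold,
    "fluoxetine", "extracellular", 2.0,
    "paroxetine", "extracellular", 2.2,
    "citalopram", "extracellular", 1.7,
    "imipramine", "extracellular", 1.9,
    "5-HT", "extracellular", 0.5,
    "5-HTP", "extracellular", 1.0,
    "Trp", "extracellular", 1.0,
    "vilazodone", "extracellular", 1.8,
    "fluoxetine", "cytoplasmic", 0.5,
    "paroxetine", "cytoplasmic", 0.5,
    "citalopram", "cytoplasmic", 0.33,
    "imipramine", "cytoplasmic", 0.5,
    "5-HT", "cytoplasmic", 2.0,
    "5-HTP", "cytoplasmic", 1.0,
    "Trp", "cytoplasmic", 1.0,
    "vilazodone", "cytoplasmic", 0.5
  )
}

#' @rdname mechanism_params
#' @export
default_ion_fold <- function() {
  # NaCl is the reference (fold 1): baseline rate constants are defined in
  # the standard NaCl-containing buffer. Relative to Na-free NMDG media,
  # Na+ opens the extracellular pathway and closes the cytoplasmic one;
  # adding Cl- (NaCl vs Na-isethionate) partially reverses both.
  tibble::tribble(
    ~medium, ~pathway, ~fold,
    "NMDG-gluconate", "extracellular", 0.8,
    "NMDG-Cl", "extracellular", 0.8,
    "Na-isethionate", "extracellular", 1.28,
    "NaCl", "extracellular", 1.0,
    "NMDG-gluconate", "cytoplasmic", 1.25,
    "NMDG-Cl", "cytoplasmic", 1.25,
    "Na-isethionate", "cytoplasmic", 0.75,
    "NaCl", "cytoplasmic", 1.0
  )
}

#' @rdname mechanism_params
#' @export
default_digitonin_access <- function() {
  data.frame(
    conc = c(0, 10, 15, 25),
    completeness = c(0, 0.40, 0.50, 1.0)
  )
}

# ---- lookups -------------------------------------------------------------

mutant_pathway <- function(mutant) {
  ifelse(mutant %in% c("S277C/X5C", "X5C"), "cytoplasmic", "extracellular")
}

lookup_k_base <- function(mech, mutant, reagent) {
  hit <- mech$k_base$k[mech$k_base$mutant == mutant &
    mech$k_base$reagent == reagent]
  if (length(hit) != 1L) {
    abort(sprintf("no baseline rate constant for %s with %s", mutant, reagent))
  }
  hit
}

lookup_ligand_fold <- function(mech, ligand, pathway) {
  if (ligand == "none") {
    return(1)
  }
  hit <- mech$ligand_fold$fold[mech$ligand_fold$ligand == ligand &
    mech$ligand_fold$pathway == pathway]
  if (length(hit) != 1L) abort(sprintf("unknown ligand '%s'", ligand))
  hit
}

lookup_ion_fold <- function(mech, medium, pathway) {
  base <- sub("\\+5-HT$", "", medium)
  hit <- mech$ion_fold$fold[mech$ion_fold$medium == base &
    mech$ion_fold$pathway == pathway]
  if (length(hit) != 1L) abort(sprintf("unknown ion medium '%s'", medium))
  if (grepl("\\+5-HT$", medium)) {
    hit <- hit * lookup_ligand_fold(mech, "5-HT", pathway)
  }
  hit
}

# Combined condition -> multiplier on k_base.
accessibility_fold <- function(mech, medium, ligand, pathway) {
  lookup_ion_fold(mech, medium, pathway) *
    lookup_ligand_fold(mech, ligand, pathway)
}

digitonin_uptake_factor <- function(mech, d) {
  1 / (1 + (d / mech$digitonin_uptake_ic50)^mech$digitonin_uptake_hill)
}

digitonin_bind_retention <- function(mech, d) {
  mech$digitonin_bind_retention_25^(d / 25)
}

digitonin_access_completeness <- function(mech, d) {
  pts <- mech$digitonin_access
  out <- approx(pts$conc, pts$completeness,
    xout = pmin(d, max(pts$conc)),
    rule = 2
  )$y
  pmin(pmax(out, 0), 1)
}
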