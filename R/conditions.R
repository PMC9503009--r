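# Assay-condition tables. Every simulator and fitting function speaks this
# schema; one row fully describes one imaged condition in one experiment.

#' Controlled vocabularies for assay conditions
#'
#' @name condition_vocab
#' @keywords internal
NULL

substrate_levels <- function() c("APP+", "ASP+")
mts_reagent_levels <- function() c("none", "MTSET", "MTSEA")
ligand_levels <- function() {
  c(
    "none", "fluoxetine", "paroxetine", "citalopram", "imipramine",
    "5-HT", "5-HTP", "Trp", "vilazodone"
  )
}
ion_medium_levels <- function() {
  c("NMDG-gluconate", "NMDG-Cl", "Na-isethionate", "NaCl", "NaCl+5-HT")
}
mutant_levels <- function() {
  c("WT", "C109A", "Y107C/C109A", "S404C/C109A", "S277C/X5C", "X5C")
}

#' Build a table of assay conditions
#'
#' Constructs the tidy condition table used throughout the pipeline. All
#' arguments are recycled to a common length (use [tidyr::expand_grid()] or
#' the preset constructors for factorial designs). Concentrations follow the
#' assay conventions: substrate in micromolar, MTS reagent in molar, ligand in
#' micromolar, digitonin in micrograms per mL.
#'
#' `ion_medium` is the medium of the stage it applies to: the uptake medium
#' when no MTS reagent is present (where specific transport requires both Na+
#' and Cl-), and the modification-phase medium when an MTS reagent is present
#' (substrate readout then always happens after washing into NaCl buffer).
#' `fluoxetine_block` marks the parallel condition with 10 uM fluoxetine
#' present during the substrate readout, which defines the nonspecific signal.
#'
#' @param substrate,substrate_conc_uM Fluorescent substrate and concentration.
#' @param mts_reagent,mts_conc_M,mts_time_s MTS reagent, molar concentration
#'   and exposure time (seconds). `mts_time_s = NA` picks the protocol default
#'   for the reagent (900 s MTSET, 300 s MTSEA).
#' @param ligand,ligand_conc_uM Modification-phase ligand and concentration.
#' @param ion_medium One of the 150 mM ion-substitution media.
#' @param digitonin_ug_ml Digitonin concentration during the modification
#'   phase.
#' @param mutant Transporter construct.
#' @param fluoxetine_block Logical; fluoxetine present during readout.
#' @param experiment_id,replicate_id Experiment and replicate indices.
#' @return A tibble with one row per condition, validated.
#' @export
conditions <- function(substrate = "APP+", substrate_conc_uM = 2,
                       mts_reagent = "none", mts_conc_M = 0, mts_time_s = NA,
                       ligand = "none", ligand_conc_uM = 0,
                       ion_medium = "NaCl", digitonin_ug_ml = 0,
                       mutant = "WT", fluoxetine_block = FALSE,
                       experiment_id = 1L, replicate_id = 1L) {
  df <- tibble::tibble(
    substrate = substrate, substrate_conc_uM = substrate_conc_uM,
    mts_reagent = mts_reagent, mts_conc_M = mts_conc_M,
    mts_time_s = as.numeric(mts_time_s),
    ligand = ligand, ligand_conc_uM = ligand_conc_uM,
    ion_medium = ion_medium, digitonin_ug_ml = digitonin_ug_ml,
    mutant = mutant, fluoxetine_block = fluoxetine_block,
    experiment_id = as.integer(experiment_id),
    replicate_id = as.integer(replicate_id)
  )
  validate_conditions(df)
}

#' Validate a condition table
#'
#' Checks vocabulary membership, the mutual exclusivity of ion media, and the
#' rule that an MTS concentration of zero is equivalent to no reagent.
#'
#' @param df A condition tibble as produced by [conditions()].
#' @return The validated tibble (with default exposure times filled in),
#'   invisibly usable in pipes.
#' @export
validate_conditions <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c(
    "substrate", "substrate_conc_uM", "mts_reagent", "mts_conc_M",
    "ligand", "ion_medium", "digitonin_ug_ml", "mutant", "experiment_id"
  )
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("condition table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (!"mts_time_s" %in% names(df)) df$mts_time_s <- NA_real_
  if (!"fluoxetine_block" %in% names(df)) df$fluoxetine_block <- FALSE
  if (!"ligand_conc_uM" %in% names(df)) {
    df$ligand_conc_uM <- ifelse(df$ligand == "none", 0, 10)
  }
  if (!"replicate_id" %in% names(df)) df$replicate_id <- 1L
  bad <- function(col, levels) {
    v <- unique(df[[col]])
    v[!v %in% levels]
  }
  for (chk in list(
    list("substrate", substrate_levels()),
    list("mts_reagent", mts_reagent_levels()),
    list("ligand", ligand_levels()),
    list("ion_medium", ion_medium_levels()),
    list("mutant", mutant_levels())
  )) {
    b <- bad(chk[[1]], chk[[2]])
    if (length(b)) {
      abort(sprintf("unknown %s: %s", chk[[1]], paste(b, collapse = ", ")))
    }
  }
  if (any(df$substrate_conc_uM <= 0)) abort("substrate_conc_uM must be > 0")
  if (any(df$mts_conc_M < 0) || any(df$digitonin_ug_ml < 0)) {
    abort("concentrations must be >= 0")
  }
  none <- df$mts_reagent == "none"
  if (any(none & df$mts_conc_M > 0)) {
    abort("mts_conc_M > 0 requires a named MTS reagent")
  }
  if (any(!none & is.na(df$mts_conc_M))) abort("mts_conc_M missing")
  df$mts_time_s <- ifelse(
    !is.na(df$mts_time_s), df$mts_time_s,
    dplyr::case_when(
      df$mts_reagent == "MTSET" ~ 900,
      df$mts_reagent == "MTSEA" ~ 300,
      TRUE ~ 0
    )
  )
  if (any(!none & df$mts_time_s <= 0)) abort("mts_time_s must be > 0 when a reagent is applied")
  df
}

# A stable identifier for a condition (everything except experiment and
# replicate), used as grouping key and in file names.
condition_id <- function(df) {
  paste(
    df$mutant, df$substrate, df$substrate_conc_uM, df$mts_reagent,
    signif(df$mts_conc_M, 6), df$ligand, df$ion_medium, df$digitonin_ug_ml,
    ifelse(df$fluoxetine_block, "block", "total"),
    sep = "|"
  )
}
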