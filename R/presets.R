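# Bundled experimental designs. Each returns a condition tibble replicating
# one of the standard assay layouts; the generator's mechanism defaults are
# the ground truth they are simulated under.

mtset_ladder <- function() c(0, 1e-7, 3e-7, 1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 1e-3)
mtsea_ladder <- function() c(0, 1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 5e-3)

#' Bundled assay designs
#'
#' Factory functions producing the condition tables of the standard assay
#' layouts, each over `n_experiments` independent experiments:
#'
#' * `design_substrate_kinetics()`: substrate concentration ladder with and
#'   without the 10 uM fluoxetine block, for Michaelis-Menten fitting with
#'   nonspecific subtraction.
#' * `design_ion_uptake()`: uptake in the four 150 mM ion-substitution media
#'   (specific transport requires Na+ and Cl- together).
#' * `design_mts_ladder()`: MTS reagent concentration ladder (default the
#'   MTSET ladder, 0.1 uM - 1 mM plus 0, on the extracellular reporter
#'   mutants) for concentration-inhibition fitting.
#' * `design_ligand_ladder()`: MTS ladder under modification-phase ligands.
#' * `design_fixed_conc_protection()`: the simplified single-concentration
#'   protocol, MTS at the half-inhibiting concentration under a ligand panel,
#'   plus the untreated reference.
#' * `design_digitonin()`: digitonin titration of APP+ uptake and ASP+
#'   membrane binding (no MTS).
#' * `design_digitonin_access()`: MTSEA ladders on the cytoplasmic reporter
#'   at sub-permeabilizing and permeabilizing digitonin doses, plus the
#'   background construct.
#' * `design_cytoplasmic_ladder()`: MTSEA ladder on the permeabilized
#'   cytoplasmic reporter under a ligand panel (ASP+ membrane binding
#'   readout).
#' * `design_ion_panel()`: fixed-concentration MTS exposure in the five ion
#'   media for one pathway, plus untreated references.
#' * `design_vilazodone()`: MTS ladders with and without 10 uM vilazodone on
#'   both pathways.
#'
#' @param substrate,concentrations,mutants,mutant,reagent,ligands,pathway,
#'   digitonin Design knobs; defaults reproduce the standard layouts.
#' @param n_experiments Number of independent experiments.
#' @return A validated condition tibble.
#' @name designs
NULL

#' @rdname designs
#' @export
design_substrate_kinetics <- function(substrate = "APP+",
                                      concentrations = NULL,
                                      n_experiments = 3) {
  if (is.null(concentrations)) {
    concentrations <- if (substrate == "APP+") {
      c(0.5, 1, 2, 4, 6, 8, 10, 15)
    } else {
      c(1, 2, 4, 8, 12, 20, 30, 40)
    }
  }
  g <- tidyr::expand_grid(
    substrate_conc_uM = concentrations,
    fluoxetine_block = c(FALSE, TRUE),
    experiment_id = seq_len(n_experiments)
  )
  conditions(
    substrate = substrate, substrate_conc_uM = g$substrate_conc_uM,
    fluoxetine_block = g$fluoxetine_block, experiment_id = g$experiment_id
  )
}

#' @rdname designs
#' @export
design_ion_uptake <- function(substrate = "APP+", n_experiments = 3) {
  g <- tidyr::expand_grid(
    ion_medium = c("NMDG-gluconate", "NMDG-Cl", "Na-isethionate", "NaCl"),
    fluoxetine_block = c(FALSE, TRUE),
    experiment_id = seq_len(n_experiments)
  )
  conditions(
    substrate = substrate,
    substrate_conc_uM = if (substrate == "APP+") 2 else 10,
    ion_medium = g$ion_medium, fluoxetine_block = g$fluoxetine_block,
    experiment_id = g$experiment_id
  )
}

#' @rdname designs
#' @export
design_mts_ladder <- function(mutants = c("C109A", "Y107C/C109A", "S404C/C109A"),
                              reagent = "MTSET",
                              concentrations = mtset_ladder(),
                              digitonin = 0,
                              n_experiments = 3) {
  g <- tidyr::expand_grid(
    mutant = mutants, mts_conc_M = concentrations,
    experiment_id = seq_len(n_experiments)
  )
  conditions(
    substrate = if (reagent == "MTSEA") "ASP+" else "APP+",
    substrate_conc_uM = if (reagent == "MTSEA") 10 else 2,
    mutant = g$mutant,
    mts_reagent = ifelse(g$mts_conc_M > 0, reagent, "none"),
    mts_conc_M = g$mts_conc_M,
    digitonin_ug_ml = digitonin,
    experiment_id = g$experiment_id
  )
}

#' @rdname designs
#' @export
design_ligand_ladder <- function(mutant = "Y107C/C109A",
                                 ligands = c("none", "fluoxetine", "citalopram", "5-HT"),
                                 n_experiments = 3) {
  g <- tidyr::expand_grid(
    ligand = ligands, mts_conc_M = mtset_ladder(),
    experiment_id = seq_len(n_experiments)
  )
  conditions(
    substrate = "APP+", substrate_conc_uM = 2, mutant = mutant,
    mts_reagent = ifelse(g$mts_conc_M > 0, "MTSET", "none"),
    mts_conc_M = g$mts_conc_M, ligand = g$ligand,
    ligand_conc_uM = ifelse(g$ligand == "none", 0, 10),
    experiment_id = g$experiment_id
  )
}

# Half-inhibiting MTSET concentration per extracellular mutant (molar).
protection_mts_conc <- function(mutant) {
  switch(mutant,
    "Y107C/C109A" = 1e-5,
    "S404C/C109A" = 2e-6,
    abort(sprintf("no standard half-inhibiting concentration for %s", mutant))
  )
}

#' @rdname designs
#' @export
design_fixed_conc_protection <- function(mutant = "Y107C/C109A",
                                         ligands = c(
                                           "none", "fluoxetine", "paroxetine",
                                           "citalopram", "imipramine", "5-HT",
                                           "5-HTP", "Trp"
                                         ),
                                         n_experiments = 3) {
  conc <- protection_mts_conc(mutant)
  g <- tidyr::expand_grid(
    ligand = c("untreated", ligands),
    experiment_id = seq_len(n_experiments)
  )
  untreated <- g$ligand == "untreated"
  conditions(
    substrate = "APP+", substrate_conc_uM = 2, mutant = mutant,
    mts_reagent = ifelse(untreated, "none", "MTSET"),
    mts_conc_M = ifelse(untreated, 0, conc),
    ligand = ifelse(untreated, "none", g$ligand),
    ligand_conc_uM = ifelse(untreated | g$ligand == "none", 0, 10),
    experiment_id = g$experiment_id
  )
}

#' @rdname designs
#' @export
design_digitonin <- function(digitonin = c(0, 5, 10, 15, 25, 50, 100),
                             n_experiments = 3) {
  g <- tidyr::expand_grid(
    substrate = c("APP+", "ASP+"), digitonin_ug_ml = digitonin,
    experiment_id = seq_len(n_experiments)
  )
  conditions(
    substrate = g$substrate,
    substrate_conc_uM = ifelse(g$substrate == "APP+", 2, 10),
    digitonin_ug_ml = g$digitonin_ug_ml, experiment_id = g$experiment_id
  )
}

#' @rdname designs
#' @export
design_digitonin_access <- function(n_experiments = 3) {
  g <- dplyr::bind_rows(
    tidyr::expand_grid(
      mutant = "S277C/X5C", digitonin_ug_ml = c(10, 15, 25),
      mts_conc_M = mtsea_ladder()
    ),
    tidyr::expand_grid(
      mutant = "X5C", digitonin_ug_ml = 25, mts_conc_M = mtsea_ladder()
    )
  )
  g <- tidyr::expand_grid(g, experiment_id = seq_len(n_experiments))
  conditions(
    substrate = "ASP+", substrate_conc_uM = 10, mutant = g$mutant,
    mts_reagent = ifelse(g$mts_conc_M > 0, "MTSEA", "none"),
    mts_conc_M = g$mts_conc_M, digitonin_ug_ml = g$digitonin_ug_ml,
    experiment_id = g$experiment_id
  )
}

#' @rdname designs
#' @export
design_cytoplasmic_ladder <- function(ligands = c("none", "fluoxetine", "citalopram", "5-HT"),
                                      n_experiments = 3) {
  g <- tidyr::expand_grid(
    ligand = ligands, mts_conc_M = mtsea_ladder(),
    experiment_id = seq_len(n_experiments)
  )
  conditions(
    substrate = "ASP+", substrate_conc_uM = 10, mutant = "S277C/X5C",
    mts_reagent = ifelse(g$mts_conc_M > 0, "MTSEA", "none"),
    mts_conc_M = g$mts_conc_M, ligand = g$ligand,
    ligand_conc_uM = ifelse(g$ligand == "none", 0, 10),
    digitonin_ug_ml = 25, experiment_id = g$experiment_id
  )
}

#' @rdname designs
#' @export
design_ion_panel <- function(pathway = c("extracellular", "cytoplasmic"),
                             mutant = NULL, n_experiments = 3) {
  pathway <- match.arg(pathway)
  if (is.null(mutant)) {
    mutant <- if (pathway == "extracellular") "Y107C/C109A" else "S277C/X5C"
  }
  media <- ion_medium_levels()
  reagent <- if (pathway == "extracellular") "MTSET" else "MTSEA"
  conc <- if (pathway == "extracellular") protection_mts_conc(mutant) else 1.2e-4
  dig <- if (pathway == "extracellular") 0 else 25
  g <- tidyr::expand_grid(
    ion_medium = media, treated = TRUE,
    experiment_id = seq_len(n_experiments)
  )
  # one untreated reference per experiment; substrate readout is always in
  # NaCl buffer after the modification-phase medium is washed out
  g <- dplyr::bind_rows(
    g,
    tibble::tibble(
      ion_medium = "NaCl", treated = FALSE,
      experiment_id = seq_len(n_experiments)
    )
  )
  conditions(
    substrate = if (pathway == "extracellular") "APP+" else "ASP+",
    substrate_conc_uM = if (pathway == "extracellular") 2 else 10,
    mutant = mutant,
    mts_reagent = ifelse(g$treated, reagent, "none"),
    mts_conc_M = ifelse(g$treated, conc, 0),
    ion_medium = g$ion_medium, digitonin_ug_ml = dig,
    experiment_id = g$experiment_id
  )
}

#' @rdname designs
#' @export
design_vilazodone <- function(n_experiments = 3) {
  ext <- tidyr::expand_grid(
    mutant = "Y107C/C109A", mts_conc_M = mtset_ladder(),
    ligand = c("none", "vilazodone"), experiment_id = seq_len(n_experiments)
  )
  cyt <- tidyr::expand_grid(
    mutant = "S277C/X5C", mts_conc_M = mtsea_ladder(),
    ligand = c("none", "vilazodone"), experiment_id = seq_len(n_experiments)
  )
  dplyr::bind_rows(
    conditions(
      substrate = "APP+", substrate_conc_uM = 2, mutant = ext$mutant,
      mts_reagent = ifelse(ext$mts_conc_M > 0, "MTSET", "none"),
      mts_conc_M = ext$mts_conc_M, ligand = ext$ligand,
      ligand_conc_uM = ifelse(ext$ligand == "none", 0, 10),
      experiment_id = ext$experiment_id
    ),
    conditions(
      substrate = "ASP+", substrate_conc_uM = 10, mutant = cyt$mutant,
      mts_reagent = ifelse(cyt$mts_conc_M > 0, "MTSEA", "none"),
      mts_conc_M = cyt$mts_conc_M, ligand = cyt$ligand,
      ligand_conc_uM = ifelse(cyt$ligand == "none", 0, 10),
      digitonin_ug_ml = 25, experiment_id = cyt$experiment_id
    )
  )
}

#' Look up a bundled design by name
#'
#' @param name One of `"substrate_kinetics"`, `"ion_uptake"`, `"mts_ladder"`,
#'   `"ligand_ladder"`, `"fixed_conc_protection"`, `"digitonin"`,
#'   `"digitonin_access"`, `"cytoplasmic_ladder"`, `"ion_panel_extracellular"`,
#'   `"ion_panel_cytoplasmic"`, `"vilazodone"`.
#' @param ... Passed to the design constructor.
#' @return A condition tibble.
#' @export
preset_design <- function(name, ...) {
  switch(name,
    substrate_kinetics = design_substrate_kinetics(...),
    ion_uptake = design_ion_uptake(...),
    mts_ladder = design_mts_ladder(...),
    ligand_ladder = design_ligand_ladder(...),
    fixed_conc_protection = design_fixed_conc_protection(...),
    digitonin = design_digitonin(...),
    digitonin_access = design_digitonin_access(...),
    cytoplasmic_ladder = design_cytoplasmic_ladder(...),
    ion_panel_extracellular = design_ion_panel("extracellular", ...),
    ion_panel_cytoplasmic = design_ion_panel("cytoplasmic", ...),
    vilazodone = design_vilazodone(...),
    abort(sprintf("unknown preset '%s'", name))
  )
}
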