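mech <- mechanism_params()

test_that("no reagent means no modification", {
  s <- signal_model(conditions(mutant = "Y107C/C109A"), mech)
  expect_identical(s$unmodified_fraction, 1)
})

test_that("the half-life dose leaves exactly half the transporters unmodified", {
  k <- 70 # Y107C/C109A with MTSET in NaCl (fold 1)
  cond <- conditions(
    mutant = "Y107C/C109A", mts_reagent = "MTSET",
    mts_conc_M = log(2) / (k * 900)
  )
  s <- signal_model(cond, mech)
  expect_equal(s$unmodified_fraction, 0.5, tolerance = 1e-12)
})

test_that("specific uptake requires Na+ and Cl- together", {
  cond <- conditions(ion_medium = c(
    "NMDG-gluconate", "NMDG-Cl",
    "Na-isethionate", "NaCl"
  ))
  s <- signal_model(cond, mech)
  expect_equal(s$specific_interior[1:3], rep(0, 3))
  expect_gt(s$specific_interior[4], 0)
})

test_that("fluoxetine blocks 95% of APP+ and 84% of ASP+ at the reference dose", {
  for (case in list(
    list(sub = "APP+", conc = 15, frac = 0.95),
    list(sub = "ASP+", conc = 40, frac = 0.84)
  )) {
    tot <- signal_model(
      conditions(substrate = case$sub, substrate_conc_uM = case$conc), mech
    )
    blk <- signal_model(
      conditions(
        substrate = case$sub, substrate_conc_uM = case$conc,
        fluoxetine_block = TRUE
      ), mech
    )
    expect_equal(1 - blk$interior_mean / tot$interior_mean, case$frac,
      tolerance = 1e-10
    )
  }
})

test_that("interior signal decreases strictly with MTS dose iff the cysteine reacts", {
  ladder <- c(1e-7, 1e-6, 1e-5, 1e-4, 1e-3)
  reactive <- signal_model(
    conditions(
      mutant = "Y107C/C109A", mts_reagent = "MTSET",
      mts_conc_M = ladder
    ), mech
  )
  expect_true(all(diff(reactive$specific_interior) < 0))
  inert <- signal_model(
    conditions(mutant = "C109A", mts_reagent = "MTSET", mts_conc_M = ladder),
    mech
  )
  expect_true(all(diff(inert$specific_interior) == 0))
})

test_that("digitonin abolishes uptake but spares most membrane binding at 25 ug/mL", {
  app <- signal_model(
    conditions(substrate = "APP+", digitonin_ug_ml = c(0, 25)), mech
  )
  expect_lt(app$specific_interior[2] / app$specific_interior[1], 0.05)
  asp <- signal_model(
    conditions(
      substrate = "ASP+", substrate_conc_uM = 10,
      digitonin_ug_ml = c(0, 25)
    ), mech
  )
  expect_gt(asp$membrane_mean[2] / asp$membrane_mean[1], 0.6)
})

test_that("cytoplasmic cysteine access follows digitonin dose for MTSEA but stays shut for MTSET", {
  saturating <- conditions(
    substrate = "ASP+", substrate_conc_uM = 10, mutant = "S277C/X5C",
    mts_reagent = "MTSEA", mts_conc_M = 5e-3,
    digitonin_ug_ml = c(10, 15, 25)
  )
  s <- signal_model(saturating, mech)
  # maximal achievable inhibition is capped by permeabilization completeness
  expect_equal(1 - s$unmodified_fraction, c(0.40, 0.50, 1.00), tolerance = 0.02)
  mtset <- signal_model(
    conditions(
      substrate = "ASP+", substrate_conc_uM = 10, mutant = "S277C/X5C",
      mts_reagent = "MTSET", mts_conc_M = 5e-3, digitonin_ug_ml = 25
    ), mech
  )
  expect_equal(mtset$unmodified_fraction, 1)
})

test_that("unknown ligands and media are configuration errors", {
  expect_error(conditions(ligand = "caffeine"), "ligand")
  expect_error(conditions(ion_medium = "KCl"), "ion_medium")
  expect_error(conditions(mts_reagent = "none", mts_conc_M = 1e-5), "reagent")
})
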