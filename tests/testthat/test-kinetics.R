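test_that("nonspecific subtraction handles the degenerate cases", {
  total <- tibble::tibble(substrate_conc_uM = c(1, 2, 4), mean = c(5, 8, 12))
  zero <- tibble::tibble(substrate_conc_uM = c(1, 2, 4), mean = c(0, 0, 0))
  expect_equal(subtract_nonspecific(total, zero)$mean, total$mean)
  expect_equal(subtract_nonspecific(total, total)$mean, rep(0, 3))
  expect_warning(
    out <- subtract_nonspecific(zero, total),
    "floored"
  )
  expect_equal(out$mean, rep(0, 3))
})

test_that("mismatched concentration grids are an error, not interpolated", {
  total <- tibble::tibble(substrate_conc_uM = c(1, 2, 4), mean = c(5, 8, 12))
  blocked <- tibble::tibble(substrate_conc_uM = c(1, 2, 8), mean = c(1, 1, 1))
  expect_error(subtract_nonspecific(total, blocked), "grids")
})

test_that("generator defaults leave 95% of saturating APP+ signal as specific", {
  mech <- mechanism_params()
  des <- design_substrate_kinetics("APP+", concentrations = 15, n_experiments = 1)
  sig <- signal_model(des, mech)
  agg <- tibble::as_tibble(sig)[, c(names(des), "interior_mean")]
  names(agg)[names(agg) == "interior_mean"] <- "mean"
  out <- subtract_nonspecific(agg)
  expect_equal(out$mean / (out$mean + out$blocked), 0.95, tolerance = 1e-10)
})

test_that("noise-free Michaelis-Menten data are recovered exactly", {
  km <- 2.63
  vmax <- 30.5
  s <- c(0.5, 1, 2, 4, 6, 8, 10, 15)
  v <- vmax * s / (km + s)
  fit <- fit_mm(tibble::tibble(substrate_conc_uM = s, mean = v))
  expect_lt(abs(fit$summary$Km - km) / km, 1e-6)
  expect_lt(abs(fit$summary$Vmax - vmax) / vmax, 1e-6)
  # on the fitted curve, v at S = Km is Vmax/2
  b <- fit$by_experiment
  expect_equal(b$Vmax * b$Km / (b$Km + b$Km), b$Vmax / 2)
})

test_that("fit_mm is scale-equivariant in the fluorescence axis", {
  set.seed(33)
  s <- c(0.5, 1, 2, 4, 6, 8, 10, 15)
  v <- 30.5 * s / (2.63 + s) * exp(rnorm(8, 0, 0.03))
  f1 <- fit_mm(tibble::tibble(substrate_conc_uM = s, mean = v))
  f2 <- fit_mm(tibble::tibble(substrate_conc_uM = s, mean = 7 * v))
  expect_equal(f2$summary$Km, f1$summary$Km, tolerance = 1e-8)
  expect_equal(f2$summary$Vmax, 7 * f1$summary$Vmax, tolerance = 1e-8)
})

test_that("a Km beyond the tested range is flagged unreliable", {
  s <- c(1, 2, 4, 8)
  v <- 100 * s / (50 + s)
  fit <- fit_mm(tibble::tibble(substrate_conc_uM = s, mean = v))
  expect_true(fit$summary$unreliable)
})

test_that("simulated kinetics recover Km within 10% under default noise", {
  mech <- mechanism_params()
  errs <- vapply(1:5, function(i) {
    agg <- sim_agg(design_substrate_kinetics("APP+"), mech, seed = 100 + i)
    fit <- fit_mm(subtract_nonspecific(agg))
    c(
      abs(fit$summary$Km - mech$km_app) / mech$km_app,
      abs(fit$summary$Vmax - mech$vmax_app) / mech$vmax_app
    )
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("median Km over many simulated experiments is within 5% of truth", {
  mech <- mechanism_params()
  kms <- vapply(1:60, function(i) {
    agg <- sim_agg(design_substrate_kinetics("APP+", n_experiments = 1),
      mech,
      seed = 4000 + i
    )
    fit_mm(subtract_nonspecific(agg))$summary$Km
  }, numeric(1))
  expect_lt(abs(median(kms) - mech$km_app) / mech$km_app, 0.05)
})

test_that("the ion panel normalizes to NaCl and rejects a degenerate reference", {
  tab <- tibble::tibble(
    ion_medium = c("NMDG-gluconate", "NMDG-Cl", "Na-isethionate", "NaCl"),
    mean = c(0.1, 0.2, 0.1, 12)
  )
  pan <- ion_uptake_panel(tab)
  expect_equal(pan$relative_uptake[pan$ion_medium == "NaCl"], 1)
  expect_true(all(pan$relative_uptake[pan$ion_medium != "NaCl"] < 0.02))
  same <- tibble::tibble(ion_medium = c("NaCl", "NMDG-Cl"), mean = c(3, 3))
  expect_equal(ion_uptake_panel(same)$relative_uptake, c(1, 1))
  expect_error(
    ion_uptake_panel(tibble::tibble(ion_medium = "NMDG-Cl", mean = 1)),
    "NaCl"
  )
  expect_error(
    ion_uptake_panel(tibble::tibble(ion_medium = "NaCl", mean = 0)),
    "zero"
  )
})

test_that("simulated ion dependence shows transport only in NaCl", {
  mech <- mechanism_params()
  agg <- sim_agg(design_ion_uptake("APP+"), mech, seed = 55)
  # Na-free media have no specific uptake, so subtraction noise gets floored
  spec <- suppressWarnings(subtract_nonspecific(agg))
  pan <- ion_uptake_panel(spec)
  expect_equal(pan$relative_uptake[pan$ion_medium == "NaCl"], 1)
  expect_true(all(abs(pan$relative_uptake[pan$ion_medium != "NaCl"]) < 0.1))
})
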