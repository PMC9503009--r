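test_that("the half-maximal first-order rate and c50 conversion match the printed arithmetic", {
  # 15-min exposure: first-order rate constant at the half-maximal dose
  expect_equal(first_order_rate(900), log(2) / 900)
  expect_equal(first_order_rate(900), 7.7e-4, tolerance = 1e-2)
  # printed half-maximal concentrations of the two extracellular reporters
  expect_equal(rate_constant_from_c50(1.1e-5, 900), 70.0, tolerance = 1e-2)
  expect_equal(rate_constant_from_c50(2.5e-6, 900), 308, tolerance = 1e-2)
  # their ratio reproduces the reported 4-5-fold difference
  expect_equal(
    rate_constant_from_c50(2.5e-6, 900) / rate_constant_from_c50(1.1e-5, 900),
    4.4,
    tolerance = 1e-10
  )
  # k vanishes as c50 grows without bound
  expect_lt(rate_constant_from_c50(1e12, 900), 1e-15)
  expect_error(rate_constant_from_c50(-1, 900), "c50")
  expect_error(rate_constant_from_c50(1e-5, 0), "t_exposure")
})

test_that("shrinking c50 strictly increases k at fixed exposure", {
  c50s <- 10^seq(-7, -2, length.out = 30)
  ks <- rate_constant_from_c50(c50s, 900)
  expect_true(all(diff(ks) < 0))
})

test_that("exponential fit and the c50 conversion are the same number on clean data", {
  k <- 70
  t <- 900
  conc <- c(0, 1e-7, 1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 1e-3)
  a <- 14 * exp(-k * conc * t)
  fit <- fit_inhibition(tibble::tibble(mts_conc_M = conc, mean = a),
    t_exposure = t
  )
  b <- fit$by_experiment
  expect_equal(b$k, k, tolerance = 1e-8)
  expect_equal(b$k, rate_constant_from_c50(b$c50, t), tolerance = 1e-12)
  expect_equal(b$floor, 0)
})

test_that("flat concentration dependence is reported as below detection, not a failure", {
  conc <- c(0, 1e-6, 1e-5, 1e-4, 1e-3)
  a <- rep(14, 5)
  fit <- fit_inhibition(tibble::tibble(mts_conc_M = conc, mean = a),
    t_exposure = 900
  )
  expect_true(fit$summary$below_detection)
  expect_true(is.na(fit$summary$k))
  expect_equal(fit$summary$detection_bound, log(2) / (900 * 1e-3))
})

test_that("a genuine residual plateau is picked up as a nonzero floor", {
  k <- 50
  t <- 900
  conc <- c(0, 1e-7, 1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 1e-3)
  a <- 3 + 11 * exp(-k * conc * t)
  fit <- fit_inhibition(tibble::tibble(mts_conc_M = conc, mean = a),
    t_exposure = t
  )
  b <- fit$by_experiment
  expect_equal(b$floor, 3, tolerance = 1e-6)
  expect_equal(b$k, k, tolerance = 1e-6)
})

test_that("logistic midpoints agree with the exponential half-life on clean exponential data", {
  set.seed(77)
  t_grid <- c(300, 900)
  for (i in 1:25) {
    k <- 10^runif(1, 0.5, 2.5)
    t <- sample(t_grid, 1)
    c50_true <- log(2) / (k * t)
    conc <- c(0, c50_true * 10^seq(-2, 2, length.out = 7))
    a <- 12 * exp(-k * conc * t)
    fit <- fit_inhibition(tibble::tibble(mts_conc_M = conc, mean = a),
      t_exposure = t, model = "logistic"
    )
    expect_lt(abs(fit$by_experiment$c50 - c50_true) / c50_true, 0.05)
  }
})

test_that("simulated MTSET ladders recover the generator rate constant", {
  mech <- mechanism_params()
  agg <- sim_agg(design_mts_ladder(mutants = "Y107C/C109A"), mech, seed = 300)
  fit <- fit_inhibition(agg, t_exposure = 900)
  expect_lt(abs(fit$summary$k - 70) / 70, 0.15)
  aggc <- sim_agg(design_mts_ladder(mutants = "C109A", n_experiments = 1),
    mech,
    seed = 301
  )
  fitc <- fit_inhibition(aggc, t_exposure = 900)
  expect_true(fitc$summary$below_detection)
})

test_that("protection back-calculation reproduces the textbook ratios", {
  out1 <- fixed_concentration_protection(0.5, 0.5, 1)
  expect_equal(out1$k_fold, 1)
  out2 <- fixed_concentration_protection(0.5, 0.25, 1)
  expect_equal(out2$k_fold, 2)
  out3 <- fixed_concentration_protection(0.5, 1.05, 1)
  expect_equal(out3$k_fold, 0)
  expect_equal(out3$flag, "full_protection")
  expect_warning(fixed_concentration_protection(0.9, 0.5, 1), "0.3-0.7")
})

test_that("half-dose protection by the substrate recovers a 0.5 rate fold under noise", {
  mech <- mechanism_params()
  agg <- sim_agg(
    design_fixed_conc_protection("Y107C/C109A", ligands = c("none", "5-HT")),
    mech,
    seed = 310
  )
  a0 <- agg[agg$mts_conc_M == 0, ]
  ctl <- agg[agg$mts_conc_M > 0 & agg$ligand == "none", ]
  ht <- agg[agg$ligand == "5-HT", ]
  pro <- fixed_concentration_protection(ctl$mean, ht$mean, a0$mean)
  # the remaining activity should sit near sqrt(1/2) of untreated
  expect_equal(mean(pro$f_ligand), 2^-0.5, tolerance = 0.1)
  expect_equal(mean(pro$k_fold), 0.5, tolerance = 0.1)
})
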