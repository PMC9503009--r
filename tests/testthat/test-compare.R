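fits_tbl <- function(k, ids = seq_along(k)) {
  tibble::tibble(experiment_id = ids, k = k)
}

test_that("identical rate constants compare as unchanged with fold 1", {
  cmp <- compare_conditions(fits_tbl(c(2, 2.2, 1.9)), fits_tbl(c(2, 2.2, 1.9)))
  expect_equal(cmp$fold_change, 1)
  expect_equal(cmp$direction, "unchanged")
})

test_that("the paired t statistic matches the closed-form hand calculation", {
  x <- c(2.0, 2.1, 1.9)
  y <- c(1.0, 1.05, 0.95)
  cmp <- compare_conditions(fits_tbl(x), fits_tbl(y))
  d <- x - y
  t_stat <- mean(d) / (sd(d) / sqrt(3))
  p_hand <- 2 * stats::pt(-abs(t_stat), df = 2)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-12)
  expect_equal(cmp$fold_change, exp(mean(log(x / y))), tolerance = 1e-12)
  expect_equal(cmp$fold_change, 2, tolerance = 0.01)
  expect_equal(cmp$direction, "increased")
})

test_that("swapping condition and control inverts the fold and keeps p", {
  set.seed(90)
  for (i in 1:20) {
    x <- exp(rnorm(3, 1, 0.3))
    y <- exp(rnorm(3, 0.5, 0.3))
    ab <- compare_conditions(fits_tbl(x), fits_tbl(y))
    ba <- compare_conditions(fits_tbl(y), fits_tbl(x))
    expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
})

test_that("unpaired or insufficient experiments are an error", {
  expect_error(
    compare_conditions(fits_tbl(c(1, 2), 1:2), fits_tbl(c(1, 2), 2:3)),
    "paired"
  )
  expect_error(
    compare_conditions(fits_tbl(1), fits_tbl(2)),
    ">= 2"
  )
})

test_that("the false-positive rate at a true fold of 1 stays near alpha", {
  # 5-HTP carries a generator fold of exactly 1, so comparing it against the
  # reagent-alone control over simulated triplicates probes the null
  mech <- mechanism_params()
  des <- design_fixed_conc_protection("Y107C/C109A", ligands = c("none", "5-HTP"))
  hits <- vapply(1:200, function(i) {
    cells <- simulate_cells(des, mech, n_cells = 30, seed = 20000 + i)
    agg <- suppressWarnings(aggregate_cells(cells, value = "mean_fluor"))
    a0 <- agg[agg$mts_conc_M == 0, ]
    ctl <- agg[agg$mts_conc_M > 0 & agg$ligand == "none", ]
    trt <- agg[agg$ligand == "5-HTP", ]
    kf <- function(a) {
      -log(pmin(a$mean / a0$mean, 0.999)) / (a$mts_conc_M * a$mts_time_s)
    }
    cmp <- compare_conditions(
      fits_tbl(kf(trt), trt$experiment_id),
      fits_tbl(kf(ctl), ctl$experiment_id),
      min_fold = 1
    )
    cmp$direction != "unchanged"
  }, logical(1))
  expect_lte(mean(hits), 0.07)
})

test_that("conformational calls follow the two-pathway direction logic", {
  mk <- function(dir, fold, pathway) {
    tibble::tibble(
      condition = "drug", control = "none", pathway = pathway,
      n_pairs = 3, fold_change = fold, folds = list(rep(fold, 3)),
      p_value = ifelse(dir == "unchanged", 0.6, 0.01), direction = dir
    )
  }
  expect_equal(
    call_conformation(
      mk("increased", 2, "extracellular"),
      mk("decreased", 0.5, "cytoplasmic")
    )$call,
    "outward-open stabilized"
  )
  expect_equal(
    call_conformation(
      mk("decreased", 0.4, "extracellular"),
      mk("increased", 2.2, "cytoplasmic")
    )$call,
    "inward-open shifted"
  )
  expect_equal(
    call_conformation(
      mk("decreased", 0.78, "extracellular"),
      mk("increased", 1.33, "cytoplasmic")
    )$call,
    "partial/intermediate"
  )
  expect_equal(
    call_conformation(
      mk("unchanged", 1.02, "extracellular"),
      mk("unchanged", 0.97, "cytoplasmic")
    )$call,
    "no change"
  )
  expect_equal(
    call_conformation(
      mk("increased", 2, "extracellular"),
      mk("increased", 2, "cytoplasmic")
    )$call,
    "discordant"
  )
  bad <- mk("increased", 2, "cytoplasmic")
  bad$control <- "other"
  expect_error(
    call_conformation(mk("increased", 2, "extracellular"), bad),
    "different controls"
  )
})

test_that("ion panel analysis needs all five media and sees no effect in flat data", {
  flat <- tidyr::expand_grid(
    ion_medium = c(
      "NMDG-gluconate", "NMDG-Cl", "Na-isethionate", "NaCl",
      "NaCl+5-HT"
    ),
    experiment_id = 1:3
  )
  flat$k <- 70 * rep(c(1, 1.001, 0.999), 5)
  pan <- ion_panel_analysis(flat)
  expect_true(all(pan$comparisons$direction == "unchanged"))
  expect_false(pan$chloride_signature)
  expect_error(
    ion_panel_analysis(flat[flat$ion_medium != "NaCl", ]),
    "NaCl"
  )
})

test_that("simulated ion panels mirror between the two pathways", {
  mech <- mechanism_params()
  run_panel <- function(preset, seed) {
    agg <- sim_agg(design_ion_panel(preset), mech,
      seed = seed,
      value = if (preset == "cytoplasmic") "surface_mean" else "mean_fluor"
    )
    a0 <- agg[agg$mts_conc_M == 0, c("experiment_id", "mean")]
    names(a0)[2] <- "A0"
    k_tbl <- dplyr::inner_join(
      agg[agg$mts_conc_M > 0, ], a0,
      by = "experiment_id"
    )
    k_tbl$k <- -log(pmin(k_tbl$mean / k_tbl$A0, 0.999)) /
      (k_tbl$mts_conc_M * k_tbl$mts_time_s)
    ion_panel_analysis(k_tbl)
  }
  ext <- run_panel("extracellular", 410)
  cyt <- run_panel("cytoplasmic", 411)
  dir_of <- function(pan, cond, ctrl) {
    pan$comparisons$direction[pan$comparisons$condition == cond &
      pan$comparisons$control == ctrl]
  }
  # Na+ opens the extracellular pathway and closes the cytoplasmic one;
  # Cl- plus substrate reverses both
  expect_equal(dir_of(ext, "Na-isethionate", "NMDG-gluconate"), "increased")
  expect_equal(dir_of(cyt, "Na-isethionate", "NMDG-gluconate"), "decreased")
  expect_equal(dir_of(ext, "NaCl+5-HT", "NaCl"), "decreased")
  expect_equal(dir_of(cyt, "NaCl+5-HT", "NaCl"), "increased")
  expect_true(ext$chloride_signature)
  expect_true(cyt$chloride_signature)
})
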