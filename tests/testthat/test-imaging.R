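test_that("read_stack rejects missing and malformed files", {
  expect_error(read_stack(tempfile()), "no such file")
  bad <- tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(read_stack(bad), "TIFF")
})

test_that("noise-free synthetic frame segments into exactly its true cells", {
  sc <- build_scene(small_plan(n_cells = 5), seed = 10)
  cond <- conditions(substrate = "APP+", substrate_conc_uM = 2)
  r <- render_stack(sc, cond, mech_clean(), noise_free(), seed = 1)
  # a noise-free frame needs no pre-smoothing; the masks come back exact
  labs <- segment_cells(r$pages[[1]], smooth_sigma = 0)
  expect_equal(max(labs), 5)
  iou <- iou_per_cell(sc$labels, labs)
  expect_equal(iou, rep(1, 5))
})

test_that("a uniform frame yields zero labels", {
  labs <- segment_cells(matrix(5, 128, 128))
  expect_true(all(labs == 0L))
})

test_that("default-noise segmentation recovers all cells with IoU >= 0.8", {
  sc <- build_scene(scene_plan(n_cells = 30), seed = 21)
  cond <- conditions(substrate = "APP+", substrate_conc_uM = 2)
  r <- render_stack(sc, cond, mechanism_params(), noise_params(), seed = 22)
  labs <- segment_cells(r$pages[[1]])
  expect_equal(max(labs), 30)
  expect_true(all(iou_per_cell(sc$labels, labs) >= 0.8))
})

test_that("a uniform cell over background quantifies to intensity minus background", {
  labels <- matrix(0L, 64, 64)
  labels[20:40, 20:40] <- 1L
  frame <- matrix(3, 64, 64)
  frame[labels == 1L] <- 10
  q <- quantify_cells(frame, labels, ring_width = 2, background = 3)
  expect_equal(q$mean_fluor, 7)
  expect_equal(q$interior_mean, 7)
  expect_equal(q$surface_mean, 0)
})

test_that("decomposition conserves the total signal exactly", {
  sc <- build_scene(small_plan(n_cells = 6), seed = 12)
  cond <- conditions(substrate = "ASP+", substrate_conc_uM = 10)
  r <- render_stack(sc, cond, mechanism_params(), noise_params(), seed = 13)
  q <- quantify_cells(r$pages[[1]], sc$labels, ring_width = sc$ring_px)
  expect_equal(
    q$total_fluor,
    q$interior_fluor + q$surface_mean * q$membrane_area,
    tolerance = 1e-9
  )
  expect_true(all(q$cell_area > q$membrane_area))
  expect_true(all(q$membrane_area > 0))
})

test_that("membrane-only cells recover the generator's surface signal", {
  # permeabilized ASP+ condition: binding retained, uptake abolished
  sc <- build_scene(small_plan(n_cells = 8), seed = 14)
  cond <- conditions(
    substrate = "ASP+", substrate_conc_uM = 10,
    digitonin_ug_ml = 25
  )
  mech <- mech_clean()
  sig <- signal_model(cond, mech)
  r <- render_stack(sc, cond, mech, noise_free(), seed = 15)
  q <- quantify_cells(r$pages[[1]], sc$labels, ring_width = sc$ring_px)
  expect_equal(mean(q$surface_mean), sig$membrane_mean, tolerance = 0.02)
  expect_equal(mean(q$interior_mean), sig$interior_mean, tolerance = 0.02)
})

test_that("quantification matches the model prediction under default noise", {
  sc <- build_scene(scene_plan(n_cells = 30), seed = 16)
  cond <- conditions(substrate = "APP+", substrate_conc_uM = 2)
  mech <- mechanism_params()
  sig <- signal_model(cond, mech)
  r <- render_stack(sc, cond, mech, noise_params(), seed = 17)
  labs <- segment_cells(r$pages[[1]])
  q <- quantify_cells(r$pages[[1]], labs)
  expect_equal(mean(q$mean_fluor), sig$interior_mean, tolerance = 0.05 * sig$interior_mean)
})

test_that("too-small cells are flagged and excluded from the decomposition", {
  labels <- matrix(0L, 32, 32)
  labels[10:12, 10:12] <- 1L # 3x3 cell, erosion by 3 px empties it
  frame <- matrix(0, 32, 32)
  frame[labels == 1L] <- 5
  q <- quantify_cells(frame, labels, ring_width = 3, background = 0)
  expect_true(q$too_small)
  expect_equal(q$mean_fluor, 5)
  expect_true(is.na(q$surface_mean))
})

test_that("edge-touching cells are excluded by default but kept on request", {
  labels <- matrix(0L, 32, 32)
  labels[1:6, 10:15] <- 1L
  labels[15:22, 15:22] <- 2L
  frame <- matrix(1, 32, 32)
  q1 <- quantify_cells(frame, labels, ring_width = 1, background = 0)
  expect_equal(q1$cell_label, 2L)
  q2 <- quantify_cells(frame, labels,
    ring_width = 1, background = 0,
    exclude_edge = FALSE
  )
  expect_equal(q2$cell_label, c(1L, 2L))
  expect_true(q2$edge[1])
})

test_that("aggregation computes n, mean, SD and the cross-experiment SEM", {
  cells <- conditions(experiment_id = rep(1:3, each = 12))[rep(1:36, 1), ]
  cells <- tibble::as_tibble(cells)
  cells$mean_fluor <- rep(c(4, 5, 6), each = 12)
  agg <- aggregate_cells(cells, value = "mean_fluor")
  expect_equal(agg$n_cells, rep(12L, 3))
  expect_equal(agg$mean, c(4, 5, 6))
  expect_equal(agg$sd, rep(0, 3))
  summ <- summarize_conditions(agg)
  expect_equal(summ$mean, 5)
  expect_equal(summ$sem, sd(c(4, 5, 6)) / sqrt(3))
})

test_that("fewer than 10 cells per condition triggers a warning", {
  cells <- tibble::as_tibble(conditions(experiment_id = rep(1L, 9)))
  cells$mean_fluor <- rnorm(9, 10)
  expect_warning(aggregate_cells(cells, value = "mean_fluor"), "fewer than 10")
})

test_that("measurements referencing unknown stacks are an error", {
  cells <- tibble::tibble(stack_path = "ghost.tif", mean_fluor = 1)
  manifest <- tibble::tibble(stack_path = "real.tif", experiment_id = 1L)
  expect_error(aggregate_cells(cells, manifest), "absent from manifest")
})
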