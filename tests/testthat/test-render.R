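test_that("noise-free render reproduces model means on the masks exactly", {
  sc <- build_scene(small_plan(n_cells = 6), seed = 2)
  cond <- conditions(substrate = "ASP+", substrate_conc_uM = 10)
  mech <- mech_clean()
  sig <- signal_model(cond, mech)
  r <- render_stack(sc, cond, mech, noise_free(), seed = 1)
  px <- r$pages[[1]]
  bg <- sc$plan$background_level
  # 16-bit quantization at 100 counts/AFU bounds the error at half a count
  tol <- 0.005
  expect_lt(max(abs(px[sc$labels == 0] - bg)), tol)
  expect_lt(max(abs(px[sc$interior > 0] - (bg + sig$interior_mean))), tol)
  expect_lt(
    max(abs(px[sc$ring > 0] - (bg + sig$interior_mean + sig$membrane_mean))),
    tol
  )
  expect_equal(r$clip_fraction, 0)
})

test_that("rendering is deterministic down to the file bytes", {
  sc <- build_scene(small_plan(n_cells = 5), seed = 4)
  cond <- conditions()
  f1 <- tempfile(fileext = ".tif")
  f2 <- tempfile(fileext = ".tif")
  render_stack(sc, cond, mechanism_params(), noise_params(),
    seed = 9, path = f1
  )
  render_stack(sc, cond, mechanism_params(), noise_params(),
    seed = 9, path = f2
  )
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("per-cell empirical means converge to the model mean as shot noise vanishes", {
  sc <- build_scene(small_plan(n_cells = 4), seed = 6)
  cond <- conditions(substrate = "APP+", substrate_conc_uM = 2)
  mech <- mech_clean()
  sig <- signal_model(cond, mech)
  # Monte-Carlo over 100 independent renders at a high photon scale
  noise <- noise_params(psf_sigma = 0, read_sigma = 0, poisson_scale = 200)
  r <- render_stack(sc, cond, mech, noise, seed = 20, n_pages = 100)
  bg <- sc$plan$background_level
  cellmeans <- vapply(r$pages, function(p) mean(p[sc$labels > 0]) - bg, numeric(1))
  expect_lt(abs(mean(cellmeans) - sig$interior_mean) / sig$interior_mean, 0.01)
})

test_that("intensity overflow raises instead of clipping silently", {
  sc <- build_scene(small_plan(n_cells = 3), seed = 5)
  cond <- conditions(substrate = "ASP+", substrate_conc_uM = 10)
  expect_error(
    render_stack(sc, cond, mechanism_params(), noise_free(),
      seed = 1, intensity_scale = 5000
    ),
    "16-bit"
  )
})

test_that("generator output round-trips through read_stack bit-exactly", {
  sc <- build_scene(small_plan(n_cells = 4), seed = 8)
  cond <- conditions()
  f <- tempfile(fileext = ".tif")
  r <- render_stack(sc, cond, mechanism_params(), noise_params(),
    seed = 3, path = f, n_pages = 3
  )
  st <- read_stack(f)
  expect_equal(st$n_pages, 3)
  for (p in 1:3) expect_equal(st$pages[[p]], r$pages[[p]], tolerance = 1e-12)
})
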