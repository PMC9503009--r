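#' Noise model for rendered images
#'
#' Standard confocal approximation: Poisson shot noise on photon-scaled
#' intensities, additive Gaussian read noise, then Gaussian blur standing in
#' for the point-spread function.
#'
#' @param psf_sigma PSF blur sigma in pixels (0 disables blur).
#' @param read_sigma Read-noise standard deviation in AFU (0 disables).
#' @param poisson_scale Photon counts per AFU; `Inf` disables shot noise.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(psf_sigma = 1, read_sigma = 1.5, poisson_scale = 4) {
  check_number(psf_sigma, "psf_sigma", nonneg = TRUE)
  check_number(read_sigma, "read_sigma", nonneg = TRUE)
  if (!(is.numeric(poisson_scale) && length(poisson_scale) == 1L &&
    (is.infinite(poisson_scale) || poisson_scale > 0))) {
    abort("`poisson_scale` must be > 0 (Inf disables shot noise).")
  }
  structure(
    list(
      psf_sigma = psf_sigma, read_sigma = read_sigma,
      poisson_scale = poisson_scale
    ),
    class = "noise_params"
  )
}

# Lognormal per-cell expression factors with mean 1 and CV `cv`.
expression_factors <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate per-cell measurements directly (no image rendering)
#'
#' The fast path of the generator: draws per-cell measurements from the same
#' mechanism and cell-variability model the image renderer uses, skipping
#' rasterization. Per-cell specific components are scaled by a lognormal
#' expression factor (CV `mech$cell_cv`) and a Gaussian measurement error of
#' `sd_measure` AFU emulates the residual pixel-noise of an area-averaged
#' cell after quantification.
#'
#' @param design Condition tibble ([conditions()]).
#' @param mech [mechanism_params()].
#' @param n_cells Cells measured per condition row.
#' @param seed Integer seed (reproducible).
#' @param sd_measure Per-cell measurement noise, AFU.
#' @return Tibble: the condition columns plus `cell`, `mean_fluor` (interior
#'   accumulation per area) and `surface_mean` (membrane-surface signal per
#'   ring area; zero for APP+).
#' @export
simulate_cells <- function(design, mech = mechanism_params(), n_cells = 30,
                           seed = NULL, sd_measure = 1) {
  sig <- signal_model(design, mech)
  with_seed(seed, {
    out <- purrr::map(seq_len(nrow(sig)), function(i) {
      r <- sig[i, ]
      e <- expression_factors(n_cells, mech$cell_cv)
      interior <- r$specific_interior * e + r$nonspecific_interior +
        rnorm(n_cells, 0, sd_measure)
      membrane <- if (r$substrate == "ASP+") {
        r$specific_membrane * e + r$nonspecific_membrane +
          rnorm(n_cells, 0, sd_measure)
      } else {
        rep(0, n_cells)
      }
      tibble::tibble(
        r[rep(1L, n_cells), names(design)],
        cell = seq_len(n_cells),
        mean_fluor = pmax(interior, 0),
        surface_mean = pmax(membrane, 0)
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Render a multi-page image stack for one condition
#'
#' Rasterizes a scene under the mechanistic signal model. Interior pixels
#' carry the cytosolic accumulation signal; membrane-ring pixels carry the
#' cytosolic signal plus the surface-binding signal (2-D projection of a
#' labelled ring over cytosol). Per-cell specific components are scaled by
#' lognormal expression factors. Pages are independent noise realizations of
#' the same field. Intensities are stored as 16-bit grayscale TIFF with
#' `intensity_scale` counts per AFU.
#'
#' @param scene A [build_scene()] result.
#' @param cond One-row condition tibble.
#' @param mech [mechanism_params()].
#' @param noise [noise_params()].
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @param path Optional output TIFF path; when `NULL` nothing is written.
#' @param n_pages Number of pages.
#' @param intensity_scale Counts per AFU (dtype headroom check uses it).
#' @return List with `pages` (matrices, AFU), `truth` (per-cell tibble of
#'   true interior/membrane means), `clip_fraction` per page, and `path`.
#' @export
render_stack <- function(scene, cond, mech = mechanism_params(),
                         noise = noise_params(), seed = NULL, path = NULL,
                         n_pages = 1L, intensity_scale = 100) {
  if (!inherits(scene, "scene_truth")) abort("`scene` must be a scene_truth")
  cond <- validate_conditions(cond)
  if (nrow(cond) != 1L) abort("`cond` must be a single condition row")
  sig <- signal_model(cond, mech)
  max_afu <- 65535 / intensity_scale

  n_cells <- nrow(scene$cells)
  bg <- scene$plan$background_level
  with_seed(seed, {
    e <- expression_factors(n_cells, mech$cell_cv)
    interior_true <- sig$specific_interior * e + sig$nonspecific_interior
    membrane_true <- if (sig$substrate == "ASP+") {
      sig$specific_membrane * e + sig$nonspecific_membrane
    } else {
      rep(0, n_cells)
    }
    clean <- matrix(bg, nrow(scene$labels), ncol(scene$labels))
    for (i in seq_len(n_cells)) {
      clean[scene$interior == i] <- bg + interior_true[i]
      clean[scene$ring == i] <- bg + interior_true[i] + membrane_true[i]
    }
    if (max(clean) > max_afu) {
      abort(sprintf(
        "expected intensity %.1f AFU exceeds the 16-bit range at intensity_scale = %g",
        max(clean), intensity_scale
      ))
    }
    pages <- vector("list", n_pages)
    clip_fraction <- numeric(n_pages)
    for (p in seq_len(n_pages)) {
      img <- clean
      if (is.finite(noise$poisson_scale)) {
        img <- matrix(
          rpois(length(img), as.vector(img) * noise$poisson_scale),
          nrow(img)
        ) / noise$poisson_scale
      }
      if (noise$read_sigma > 0) {
        img <- img + matrix(rnorm(length(img), 0, noise$read_sigma), nrow(img))
      }
      if (noise$psf_sigma > 0) {
        img <- as.matrix(EBImage::gblur(img, sigma = noise$psf_sigma))
      }
      clip_fraction[p] <- mean(img < 0 | img > max_afu)
      img <- pmin(pmax(img, 0), max_afu)
      # quantize to the 16-bit grid so a written file round-trips exactly
      pages[[p]] <- round(img * intensity_scale) / intensity_scale
    }
    truth <- tibble::tibble(
      cell = scene$cells$cell,
      true_interior_mean = interior_true,
      true_membrane_mean = membrane_true,
      cell_area = scene$cells$cell_area,
      interior_area = scene$cells$interior_area,
      ring_area = scene$cells$ring_area
    )
    if (!is.null(path)) {
      # writeTIFF truncates when scaling to the 16-bit grid; offsetting the
      # integer counts by half a count makes the truncation exact
      tiff::writeTIFF(
        lapply(pages, function(m) (round(m * intensity_scale) + 0.5) / 65535),
        path,
        bits.per.sample = 16L, compression = "none"
      )
    }
    list(
      pages = pages, truth = truth, clip_fraction = clip_fraction,
      path = path, intensity_scale = intensity_scale
    )
  })
}

#' Generate a full synthetic experiment on disk
#'
#' Renders one TIFF stack per condition row, writes a manifest CSV (one row
#' per stack) and a ground-truth CSV keyed by (stack, cell). Default designs
#' image at least 30 cells per condition.
#'
#' @param design Condition tibble; duplicate
#'   (condition, experiment, replicate) keys are an error.
#' @param mech,plan,noise Model, scene and noise parameters.
#' @param out_dir Output directory (created).
#' @param seed Master seed; all per-stack seeds derive from it.
#' @param intensity_scale Counts per AFU in the written TIFFs.
#' @return Invisibly, a list with the `manifest` and `truth` tibbles and
#'   their file paths.
#' @export
generate_experiment <- function(design, mech = mechanism_params(),
                                plan = scene_plan(), noise = noise_params(),
                                out_dir, seed = 1L, intensity_scale = 100) {
  design <- validate_conditions(design)
  if (nrow(design) == 0L) abort("`design` is empty")
  key <- paste(condition_id(design), design$experiment_id, design$replicate_id)
  if (anyDuplicated(key)) {
    abort("duplicate (condition, experiment, replicate) keys in design")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", nrow(design))
  truths <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    r <- design[i, ]
    stack_seed <- derive_seed(seed, i)
    scene <- build_scene(plan, seed = derive_seed(stack_seed, 1L))
    fname <- sprintf("stack_%03d.tif", i)
    res <- render_stack(scene, r, mech, noise,
      seed = derive_seed(stack_seed, 2L),
      path = file.path(out_dir, fname),
      intensity_scale = intensity_scale
    )
    manifest[[i]] <- tibble::tibble(
      stack_path = fname,
      condition_id = condition_id(r),
      mutant = r$mutant, substrate = r$substrate,
      substrate_conc_uM = r$substrate_conc_uM,
      mts_reagent = r$mts_reagent, mts_conc_M = r$mts_conc_M,
      mts_time_s = r$mts_time_s, ligand = r$ligand,
      ligand_conc_uM = r$ligand_conc_uM, ion_medium = r$ion_medium,
      digitonin_ug_ml = r$digitonin_ug_ml,
      fluoxetine_block = r$fluoxetine_block,
      experiment_id = r$experiment_id, replicate_id = r$replicate_id,
      intensity_scale = intensity_scale
    )
    truths[[i]] <- dplyr::mutate(res$truth, stack_path = fname, .before = 1)
  }
  manifest <- dplyr::bind_rows(manifest)
  truth <- dplyr::bind_rows(truths)
  mpath <- file.path(out_dir, "manifest.csv")
  tpath <- file.path(out_dir, "truth.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  utils::write.csv(truth, tpath, row.names = FALSE)
  invisible(list(
    manifest = manifest, truth = truth,
    manifest_path = mpath, truth_path = tpath, out_dir = out_dir
  ))
}
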