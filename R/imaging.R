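#' Read a grayscale image stack
#'
#' Reads a multi-page 16-bit grayscale TIFF and converts pixel counts back to
#' arbitrary fluorescence units.
#'
#' @param path TIFF file path.
#' @param intensity_scale Counts per AFU used when the stack was written.
#' @return A list of class `image_stack`: `pages` (list of AFU matrices),
#'   `n_pages`, `path`, `intensity_scale`.
#' @export
read_stack <- function(path, intensity_scale = 100) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) abort(sprintf("cannot read '%s' as TIFF: %s", path, conditionMessage(e)))
  )
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2L) {
      abort(sprintf("'%s' is not single-channel grayscale", path))
    }
  }
  structure(
    list(
      pages = lapply(pages, function(p) p / intensity_scale),
      n_pages = length(pages), path = path,
      intensity_scale = intensity_scale
    ),
    class = "image_stack"
  )
}

#' Segment cells in a fluorescence frame
#'
#' Detection: Gaussian smoothing, global Otsu threshold, morphological
#' opening (removes noise speckle), hole filling, connected-component
#' labelling (optionally a watershed split of touching cells) and an area
#' filter. Each detected cell whose level stands well above the background
#' noise is then refined to its half-maximum boundary: a step edge blurred by
#' a symmetric PSF crosses half its height at the true edge, so thresholding
#' the cell's neighbourhood at `background + (level - background)/2` undoes
#' the blur-induced halo that a single global threshold leaves around bright
#' cells. Low-contrast cells keep their Otsu boundary.
#'
#' @param frame 2-D intensity matrix (AFU).
#' @param min_area,max_area Area filter in pixels.
#' @param smooth_sigma Smoothing sigma in pixels before thresholding.
#' @param split_touching Split touching cells by watershed on the distance
#'   map.
#' @return Integer label matrix (background 0); an all-background frame
#'   yields zero labels.
#' @export
segment_cells <- function(frame, min_area = 150, max_area = 20000,
                          smooth_sigma = 1, split_touching = FALSE) {
  if (length(dim(frame)) != 2L) abort("`frame` must be a 2-D matrix")
  rng <- range(frame)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) {
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  sm <- if (smooth_sigma > 0) {
    as.matrix(EBImage::gblur(frame, sigma = smooth_sigma))
  } else {
    frame
  }
  norm <- (sm - min(sm)) / (max(sm) - min(sm))
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  # morphological opening removes noise speckle that survives thresholding
  # in low-contrast frames
  mask <- EBImage::opening(mask * 1, EBImage::makeBrush(3, "disc")) > 0.5
  mask <- EBImage::fillHull(mask * 1) > 0.5
  labels <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(mask * 1))
  } else {
    EBImage::bwlabel(mask * 1)
  }
  labels <- matrix(as.integer(labels), nrow(frame))
  areas <- tabulate(labels[labels > 0L])
  bg <- median(sm[labels == 0L])
  noise_sd <- stats::mad(sm[labels == 0L])
  out <- matrix(0L, nrow(frame), ncol(frame))
  nl <- 0L
  # detect permissively so refinement can rescue weakly expressing cells,
  # then apply the full area filter to the final mask
  for (id in which(areas >= min_area / 2 & areas <= max_area)) {
    m <- labels == id
    vin <- median(sm[m])
    keep <- m
    if (smooth_sigma > 0 && (vin - bg) > 4 * noise_sd) {
      # half-maximum refinement for confidently detected cells
      region <- EBImage::dilate(m * 1, EBImage::makeBrush(7, "disc")) > 0.5
      refined <- region & (sm > bg + 0.5 * (vin - bg))
      refined <- EBImage::fillHull(refined * 1) > 0.5
      comp <- matrix(as.integer(EBImage::bwlabel(refined * 1)), nrow(frame))
      hits <- table(comp[m])
      hits <- hits[names(hits) != "0"]
      if (length(hits)) {
        cand <- comp == as.integer(names(which.max(hits)))
        if (sum(cand) <= max_area) keep <- cand
      }
    }
    if (sum(keep) < min_area || sum(keep) > max_area) next
    nl <- nl + 1L
    out[keep] <- nl
  }
  out
}

#' Per-cell fluorescence quantification with membrane/interior decomposition
#'
#' For every labelled cell, fluorescence is counted and normalized to the
#' cell area (mean fluorescence) after per-pixel background subtraction. The
#' interior compartment is the erosion of the cell mask by `ring_width`; the
#' membrane ring is the remainder. The intracellular component is assumed
#' uniform across the cell, so the intracellular contribution under the ring
#' is extrapolated from the interior mean and subtracted from the total; the
#' remainder, normalized to the ring area, is the membrane-surface signal.
#'
#' @param frame 2-D intensity matrix (AFU).
#' @param labels Integer label matrix from [segment_cells()] (or truth masks).
#' @param ring_width Membrane ring width in pixels (>= 1).
#' @param background Background level (AFU); default the median of non-cell
#'   pixels.
#' @param exclude_edge Drop cells touching the frame edge (their area is
#'   truncated).
#' @return A tibble with one row per cell: `cell_label`, `cell_area`,
#'   `interior_area`, `membrane_area`, `total_fluor`, `interior_fluor`
#'   (intracellular component over the whole cell), `mean_fluor`
#'   (total/area, floored at 0), `interior_mean`, `surface_mean`
#'   ((total - interior)/membrane area), and flags `edge`, `too_small`.
#'   Cells with an empty eroded interior keep `mean_fluor` but have `NA`
#'   decomposition.
#' @export
quantify_cells <- function(frame, labels, ring_width = 3, background = NULL,
                           exclude_edge = TRUE) {
  if (!all(dim(frame) == dim(labels))) abort("frame/labels dimension mismatch")
  if (ring_width < 1) abort("`ring_width` must be >= 1 pixel")
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(background)) {
    background <- if (any(labels == 0L)) median(frame[labels == 0L]) else 0
  }
  vals <- frame - background
  nr <- nrow(frame)
  nc <- ncol(frame)
  rows <- purrr::map(ids, function(id) {
    mask <- labels == id
    idx <- which(mask, arr.ind = TRUE)
    edge <- any(idx[, 1] %in% c(1L, nr)) || any(idx[, 2] %in% c(1L, nc))
    cell_area <- nrow(idx)
    # erode within a padded bounding box for speed
    r0 <- max(1L, min(idx[, 1]) - 1L)
    r1 <- min(nr, max(idx[, 1]) + 1L)
    c0 <- max(1L, min(idx[, 2]) - 1L)
    c1 <- min(nc, max(idx[, 2]) + 1L)
    sub <- mask[r0:r1, c0:c1, drop = FALSE]
    inner_sub <- erode_mask(sub, ring_width)
    inner <- matrix(FALSE, nr, nc)
    inner[r0:r1, c0:c1] <- inner_sub
    ring <- mask & !inner
    total <- sum(vals[mask])
    mean_fluor <- max(total / cell_area, 0)
    if (!any(inner)) {
      return(tibble::tibble(
        cell_label = id, cell_area = cell_area, interior_area = 0L,
        membrane_area = cell_area, total_fluor = total,
        interior_fluor = NA_real_, mean_fluor = mean_fluor,
        interior_mean = NA_real_, surface_mean = NA_real_,
        edge = edge, too_small = TRUE
      ))
    }
    interior_mean <- mean(vals[inner])
    interior_fluor <- interior_mean * cell_area
    membrane_area <- sum(ring)
    surface_mean <- (total - interior_fluor) / membrane_area
    tibble::tibble(
      cell_label = id, cell_area = cell_area, interior_area = sum(inner),
      membrane_area = membrane_area, total_fluor = total,
      interior_fluor = interior_fluor, mean_fluor = mean_fluor,
      interior_mean = interior_mean, surface_mean = surface_mean,
      edge = edge, too_small = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) && exclude_edge) out <- dplyr::filter(out, !.data$edge)
  out
}

#' Quantify every stack listed in a manifest
#'
#' Convenience wrapper: reads each stack, segments every page, quantifies
#' cells and binds the results with the stack identity.
#'
#' @param manifest Manifest tibble (as written by [generate_experiment()]).
#' @param dir Directory containing the stacks.
#' @param ring_width Ring width in pixels.
#' @param ... Passed to [segment_cells()].
#' @return Per-cell tibble with `stack_path` and `page` columns.
#' @export
quantify_stacks <- function(manifest, dir, ring_width = 3, ...) {
  manifest <- tibble::as_tibble(manifest)
  res <- purrr::map(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    st <- read_stack(file.path(dir, m$stack_path),
      intensity_scale = if ("intensity_scale" %in% names(m)) m$intensity_scale else 100
    )
    pages <- purrr::map(seq_along(st$pages), function(p) {
      fr <- st$pages[[p]]
      labs <- segment_cells(fr, ...)
      q <- quantify_cells(fr, labs, ring_width = ring_width)
      if (nrow(q)) dplyr::mutate(q, page = p) else q
    })
    out <- dplyr::bind_rows(pages)
    if (nrow(out)) dplyr::mutate(out, stack_path = m$stack_path, .before = 1) else out
  })
  dplyr::bind_rows(res)
}

#' Aggregate per-cell measurements to condition level
#'
#' Summarizes per-cell values per (condition, experiment): cell count, mean
#' and SD. When a manifest is supplied, measurements are joined to it by
#' `stack_path`; otherwise the measurement table must already carry the
#' condition columns (as [simulate_cells()] output does). Warns when a
#' condition has fewer than 10 cells.
#'
#' @param cells Per-cell tibble.
#' @param manifest Optional manifest tibble keyed by `stack_path`.
#' @param value Column to aggregate (`"mean_fluor"` or `"surface_mean"`).
#' @return Tibble per (condition, experiment) with `n_cells`, `mean`, `sd`
#'   and the condition columns.
#' @export
aggregate_cells <- function(cells, manifest = NULL, value = "mean_fluor") {
  cells <- tibble::as_tibble(cells)
  if (!value %in% names(cells)) abort(sprintf("no column '%s' in `cells`", value))
  if (!is.null(manifest)) {
    manifest <- tibble::as_tibble(manifest)
    missing <- setdiff(unique(cells$stack_path), manifest$stack_path)
    if (length(missing)) {
      abort(paste0("stacks absent from manifest: ", paste(missing, collapse = ", ")))
    }
    cells <- dplyr::inner_join(cells, manifest, by = "stack_path")
  }
  keys <- intersect(
    c(
      "condition_id", "mutant", "substrate", "substrate_conc_uM",
      "mts_reagent", "mts_conc_M", "mts_time_s", "ligand", "ligand_conc_uM",
      "ion_medium", "digitonin_ug_ml", "fluoxetine_block", "experiment_id"
    ),
    names(cells)
  )
  if (!"experiment_id" %in% keys) abort("no experiment_id column to aggregate by")
  out <- cells |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean = mean(.data[[value]]),
      sd = sd(.data[[value]]),
      .groups = "drop"
    )
  if (any(out$n_cells < 10)) {
    warn(sprintf(
      "%d condition(s) have fewer than 10 cells",
      sum(out$n_cells < 10)
    ))
  }
  out
}

#' Summarize experiment means across experiments
#'
#' Collapses a per-(condition, experiment) table to condition level: the mean
#' of experiment means and its standard error over experiments.
#'
#' @param per_experiment Output of [aggregate_cells()].
#' @param value Column holding the per-experiment mean.
#' @return Tibble per condition with `n_experiments`, `mean`, `sem`.
#' @export
summarize_conditions <- function(per_experiment, value = "mean") {
  keys <- setdiff(
    intersect(
      c(
        "condition_id", "mutant", "substrate", "substrate_conc_uM",
        "mts_reagent", "mts_conc_M", "mts_time_s", "ligand", "ligand_conc_uM",
        "ion_medium", "digitonin_ug_ml", "fluoxetine_block"
      ),
      names(per_experiment)
    ),
    "experiment_id"
  )
  per_experiment |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_experiments = dplyr::n(),
      sem = sd(.data[[value]]) / sqrt(dplyr::n()),
      mean = mean(.data[[value]]),
      .groups = "drop"
    )
}
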