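#' Plan a synthetic imaging field
#'
#' Describes the geometry of one simulated confocal field: frame size, pixel
#' calibration, number of cells, the range of cell semi-axes, and the width of
#' the membrane ring used to split each cell into a surface and an interior
#' compartment. The plan carries no fluorescence information; intensities come
#' from [signal_model()] at render time.
#'
#' @param image_width,image_height Frame size in pixels.
#' @param pixel_size Physical pixel size in micrometers per pixel.
#' @param n_cells Number of cells to place (may be 0).
#' @param cell_axes Length-2 numeric, minimum and maximum ellipse semi-axis in
#'   micrometers.
#' @param membrane_ring_width Width of the membrane ring in micrometers. The
#'   default (1.5 um, i.e. 3 px at 0.5 um/px) matches the ring used by the
#'   quantification stage.
#' @param background_level Background fluorescence in arbitrary fluorescence
#'   units (AFU) added outside and inside cells.
#' @param rng_seed Optional integer seed stored with the plan; [build_scene()]
#'   uses it when no explicit seed is given.
#' @return An object of class `scene_plan`.
#' @seealso [build_scene()], [render_stack()]
#' @export
scene_plan <- function(image_width = 320, image_height = 320,
                       pixel_size = 0.5, n_cells = 30,
                       cell_axes = c(4, 8), membrane_ring_width = 1.5,
                       background_level = 5, rng_seed = NULL) {
  check_number(image_width, "image_width", positive = TRUE)
  check_number(image_height, "image_height", positive = TRUE)
  check_number(pixel_size, "pixel_size", positive = TRUE)
  check_number(n_cells, "n_cells", nonneg = TRUE)
  if (length(cell_axes) != 2L || any(!is.finite(cell_axes)) ||
    any(cell_axes <= 0) || cell_axes[1] > cell_axes[2]) {
    abort("`cell_axes` must be c(min, max) semi-axes in micrometers, min <= max.")
  }
  check_number(membrane_ring_width, "membrane_ring_width", positive = TRUE)
  check_number(background_level, "background_level", nonneg = TRUE)
  structure(
    list(
      image_width = as.integer(image_width),
      image_height = as.integer(image_height),
      pixel_size = pixel_size, n_cells = as.integer(n_cells),
      cell_axes = as.numeric(cell_axes),
      membrane_ring_width = membrane_ring_width,
      background_level = background_level,
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
    ),
    class = "scene_plan"
  )
}

#' @export
print.scene_plan <- function(x, ...) {
  cat(sprintf(
    "<scene_plan> %d x %d px (%.2f um/px), %d cells, ring %.2f um\n",
    x$image_width, x$image_height, x$pixel_size, x$n_cells,
    x$membrane_ring_width
  ))
  invisible(x)
}

# Shared erosion used both for ground-truth ring/interior partition and for
# quantification, so the two agree exactly on noise-free data.
erode_mask <- function(mask, ring_px) {
  if (ring_px < 1) abort("ring width must be at least 1 pixel")
  brush <- EBImage::makeBrush(2L * as.integer(ring_px) + 1L, shape = "disc")
  out <- EBImage::erode(mask * 1, brush)
  matrix(as.numeric(out) > 0.5, nrow = nrow(mask))
}

rasterize_ellipse <- function(nr, nc, cx, cy, a, b, theta) {
  row <- matrix(seq_len(nr), nr, nc) - cx
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cy
  u <- row * cos(theta) + col * sin(theta)
  v <- -row * sin(theta) + col * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Build the ground-truth geometry of a synthetic field
#'
#' Places non-overlapping elliptical cells fully inside the frame by rejection
#' sampling and partitions each cell into an interior and a membrane ring by
#' disc erosion. The same erosion is used by [quantify_cells()], so on
#' noise-free images quantification reproduces the truth exactly.
#'
#' @param plan A [scene_plan()].
#' @param seed Integer seed; defaults to the plan's `rng_seed`. The same plan
#'   and seed always yield bit-identical masks.
#' @param max_tries Placement attempts per cell before giving up.
#' @return An object of class `scene_truth`: a list with integer label
#'   matrices `labels`, `interior`, `ring` (0 = background) and a tibble
#'   `cells` of per-cell geometry (centre, semi-axes in px, orientation,
#'   pixel counts).
#' @export
build_scene <- function(plan, seed = plan$rng_seed, max_tries = 200L) {
  if (!inherits(plan, "scene_plan")) abort("`plan` must be a scene_plan")
  nr <- plan$image_height
  nc <- plan$image_width
  ring_px <- max(1L, as.integer(round(plan$membrane_ring_width / plan$pixel_size)))
  ax_px <- plan$cell_axes / plan$pixel_size
  if (2 * max(ax_px) + 2 > min(nr, nc) && plan$n_cells > 0) {
    abort("frame too small for the requested cell size")
  }
  cells <- with_seed(seed, {
    placed <- list()
    for (i in seq_len(plan$n_cells)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        a <- runif(1, ax_px[1], ax_px[2])
        b <- runif(1, ax_px[1], ax_px[2])
        r <- max(a, b)
        cx <- runif(1, r + 1.5, nr - r - 0.5)
        cy <- runif(1, r + 1.5, nc - r - 0.5)
        theta <- runif(1, 0, pi)
        clear <- TRUE
        for (p in placed) {
          if (sqrt((cx - p$cx)^2 + (cy - p$cy)^2) < r + p$r + 2) {
            clear <- FALSE
            break
          }
        }
        if (clear) {
          placed[[i]] <- list(cx = cx, cy = cy, a = a, b = b, r = r, theta = theta)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "could not place cell %d of %d without overlap; enlarge the frame or reduce n_cells",
          i, plan$n_cells
        ))
      }
    }
    placed
  })

  labels <- matrix(0L, nr, nc)
  interior <- matrix(0L, nr, nc)
  geom <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    p <- cells[[i]]
    mask <- rasterize_ellipse(nr, nc, p$cx, p$cy, p$a, p$b, p$theta)
    inner <- erode_mask(mask, ring_px)
    labels[mask] <- i
    interior[inner] <- i
    geom[[i]] <- tibble::tibble(
      cell = i, cx = p$cx, cy = p$cy, a_px = p$a, b_px = p$b,
      theta = p$theta, cell_area = sum(mask), interior_area = sum(inner),
      ring_area = sum(mask) - sum(inner)
    )
  }
  ring <- labels
  ring[interior > 0L] <- 0L
  structure(
    list(
      labels = labels, interior = interior, ring = ring,
      cells = if (length(geom)) dplyr::bind_rows(geom) else tibble::tibble(
        cell = integer(), cx = numeric(), cy = numeric(), a_px = numeric(),
        b_px = numeric(), theta = numeric(), cell_area = integer(),
        interior_area = integer(), ring_area = integer()
      ),
      plan = plan, ring_px = ring_px
    ),
    class = "scene_truth"
  )
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %d cells in %d x %d px, ring %d px\n",
    nrow(x$cells), nrow(x$labels), ncol(x$labels), x$ring_px
  ))
  invisible(x)
}
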