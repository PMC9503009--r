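# Shared fixtures: everything is generated in code at test time.

small_plan <- function(n_cells = 10, ...) {
  scene_plan(image_width = 256, image_height = 256, n_cells = n_cells, ...)
}

noise_free <- function() noise_params(psf_sigma = 0, read_sigma = 0, poisson_scale = Inf)

# mechanism with deterministic cells (no expression spread, no autofluor)
mech_clean <- function(...) mechanism_params(cell_cv = 0, cell_autofluor = 0, ...)

# per-truth-cell intersection-over-union against a segmentation
iou_per_cell <- function(truth_labels, seg_labels) {
  n <- max(truth_labels)
  vapply(seq_len(n), function(i) {
    tm <- truth_labels == i
    hits <- table(seg_labels[tm])
    hits <- hits[names(hits) != "0"]
    if (!length(hits)) {
      return(0)
    }
    j <- as.integer(names(which.max(hits)))
    sm <- seg_labels == j
    sum(tm & sm) / sum(tm | sm)
  }, numeric(1))
}

# simulate one condition table and aggregate the named readout
sim_agg <- function(design, mech, seed, value = "mean_fluor", n_cells = 30) {
  cells <- simulate_cells(design, mech, n_cells = n_cells, seed = seed)
  suppressWarnings(aggregate_cells(cells, value = value))
}
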