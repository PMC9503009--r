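# End-to-end orchestration: simulate -> quantify -> fit -> compare, driven by
# one structured config and one master seed.

pipeline_defaults <- function() {
  list(
    preset = "mts_ladder",
    preset_args = list(),
    level = "images", # "images" renders TIFF stacks; "cells" skips rendering
    scene = list(),
    mechanism = list(),
    noise = list(),
    imaging = list(ring_width = 3, min_area = 150, max_area = 20000),
    fitting = list(model = "exponential"),
    compare = list(alpha = 0.05, min_fold = 1.2)
  )
}

#' Assemble a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and merges it over the defaults. The
#' config plus the master seed fully determine every output.
#'
#' @param x Path to a YAML file, or a named list, or `NULL` for defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL) {
  cfg <- pipeline_defaults()
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.null(x)) {
    if (!is.list(x)) abort("config must be a list or a YAML file path")
    for (nm in names(x)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(x[[nm]])) {
        modifyList(cfg[[nm]], x[[nm]])
      } else {
        x[[nm]]
      }
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

# Which per-cell column is the activity readout for a condition: ASP+ on
# permeabilized cells reports membrane binding, everything else reports
# area-normalized accumulation.
readout_column <- function(substrate, digitonin) {
  ifelse(substrate == "ASP+" & digitonin > 0, "surface_mean", "mean_fluor")
}

# Back-calculate a per-experiment pseudo-first-order rate constant from a
# single fixed-concentration exposure: k = -log(A/A0) / (c * t).
back_calculate_k <- function(agg) {
  treated <- dplyr::filter(agg, .data$mts_conc_M > 0)
  untreated <- dplyr::filter(agg, .data$mts_conc_M == 0)
  # the untreated activity A0 does not depend on the modification-phase
  # ligand or medium (both are washed out before the readout)
  join_cols <- c(
    intersect(c("mutant", "substrate", "digitonin_ug_ml"), names(agg)),
    "experiment_id"
  )
  ref <- untreated |>
    dplyr::group_by(dplyr::across(dplyr::all_of(join_cols))) |>
    dplyr::summarise(A0 = mean(.data$mean), .groups = "drop")
  out <- dplyr::inner_join(treated, ref, by = join_cols)
  if (nrow(out) < nrow(treated)) {
    abort("missing untreated reference rows for fixed-concentration back-calculation")
  }
  dplyr::mutate(out,
    remaining_fraction = pmin(.data$mean / .data$A0, 0.999),
    k = pmax(
      -log(.data$remaining_fraction) / (.data$mts_conc_M * .data$mts_time_s),
      1e-12
    )
  )
}

write_pipeline_csv <- function(df, path) {
  df <- dplyr::select(df, -dplyr::where(is.list))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates a bundled design (at image or per-cell level), quantifies cells,
#' aggregates to condition level, fits the appropriate model (Michaelis-Menten
#' uptake kinetics for MTS-free designs with a fluoxetine-block arm;
#' concentration-inhibition rate constants for MTS ladders; back-calculated
#' rate constants for fixed-concentration protocols), compares conditions
#' against their controls, and classifies conformational effects when both
#' pathways are present. All randomness derives from `seed`; a rerun with the
#' same config and seed writes byte-identical CSVs.
#'
#' @param config A [pipeline_config()] (or list/YAML path coerced to one).
#' @param out_dir Output directory; stage CSVs, a config echo and a plain log
#'   are written there.
#' @param seed Master seed.
#' @return Invisibly, a list with `cells`, `conditions`, `fits`,
#'   `comparisons`, `calls`, `ion_panels` (as applicable).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  fail_stage <- function(stage, e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  design <- tryCatch(
    do.call(preset_design, c(list(name = config$preset), config$preset_args)),
    error = function(e) fail_stage("design", e)
  )
  mech <- do.call(mechanism_params, config$mechanism)
  say("design '%s': %d condition rows", config$preset, nrow(design))

  # ---- simulate + quantify -------------------------------------------------
  cells <- tryCatch(
    {
      if (identical(config$level, "images")) {
        plan <- do.call(scene_plan, config$scene)
        noise <- do.call(noise_params, config$noise)
        sim_dir <- file.path(out_dir, "stacks")
        gen <- generate_experiment(design, mech, plan, noise,
          out_dir = sim_dir, seed = derive_seed(seed, 1L)
        )
        q <- quantify_stacks(gen$manifest, sim_dir,
          ring_width = config$imaging$ring_width,
          min_area = config$imaging$min_area,
          max_area = config$imaging$max_area
        )
        dplyr::inner_join(q, gen$manifest, by = "stack_path")
      } else {
        simulate_cells(design, mech, seed = derive_seed(seed, 1L)) |>
          dplyr::mutate(condition_id = condition_id(dplyr::pick(dplyr::everything())))
      }
    },
    error = function(e) fail_stage("simulate/quantify", e)
  )
  say("quantified %d cells", nrow(cells))

  # ---- aggregate (readout depends on the condition) ------------------------
  agg <- tryCatch(
    {
      cells$readout <- readout_column(cells$substrate, cells$digitonin_ug_ml)
      dplyr::bind_rows(
        if (any(cells$readout == "mean_fluor")) {
          aggregate_cells(dplyr::filter(cells, .data$readout == "mean_fluor"),
            value = "mean_fluor"
          )
        },
        if (any(cells$readout == "surface_mean")) {
          aggregate_cells(dplyr::filter(cells, .data$readout == "surface_mean"),
            value = "surface_mean"
          )
        }
      )
    },
    error = function(e) fail_stage("aggregate", e)
  )
  say("aggregated to %d condition x experiment rows", nrow(agg))

  fits <- comparisons <- calls <- NULL
  ion_panels <- list()
  alpha <- config$compare$alpha
  min_fold <- config$compare$min_fold

  if (any(design$mts_conc_M > 0)) {
    # ---- accessibility analysis -------------------------------------------
    n_pos_conc <- agg |>
      dplyr::filter(.data$mts_conc_M > 0) |>
      dplyr::group_by(.data$mutant, .data$ligand, .data$ion_medium) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$mts_conc_M), .groups = "drop")
    ladder <- max(n_pos_conc$n) >= 3
    fits <- tryCatch(
      {
        if (ladder) {
          fit_inhibition_panel(agg, value = "mean", model = config$fitting$model)
        } else {
          back_calculate_k(agg)
        }
      },
      error = function(e) fail_stage("fit-accessibility", e)
    )
    say("fitted %d rate-constant rows (%s)", nrow(fits),
      if (ladder) "concentration ladders" else "fixed-concentration back-calculation")

    usable <- fits
    if ("below_detection" %in% names(usable)) {
      usable <- dplyr::filter(usable, !.data$below_detection, .data$converged)
    }
    comparisons <- tryCatch(
      {
        out <- list()
        media <- unique(design$ion_medium)
        if (length(media) >= 5) {
          for (mut in unique(usable$mutant)) {
            sub <- dplyr::filter(usable, .data$mutant == mut)
            pan <- ion_panel_analysis(sub, alpha = alpha, min_fold = min_fold)
            ion_panels[[mut]] <- pan
            out[[length(out) + 1L]] <- dplyr::mutate(
              pan$comparisons,
              mutant = mut, pathway = mutant_pathway(mut)
            )
          }
        } else {
          for (mut in unique(usable$mutant)) {
            sub <- dplyr::filter(usable, .data$mutant == mut)
            ctrl <- dplyr::filter(sub, .data$ligand == "none")
            if (!nrow(ctrl)) next
            for (lig in setdiff(unique(sub$ligand), "none")) {
              cond <- dplyr::filter(sub, .data$ligand == lig)
              out[[length(out) + 1L]] <- dplyr::mutate(
                compare_conditions(cond, ctrl,
                  alpha = alpha, min_fold = min_fold,
                  condition = lig, control = "none",
                  pathway = mutant_pathway(mut)
                ),
                mutant = mut
              )
            }
          }
        }
        if (length(out)) dplyr::bind_rows(out) else NULL
      },
      error = function(e) fail_stage("compare", e)
    )
    if (!is.null(comparisons)) say("%d comparisons", nrow(comparisons))

    # conformational calls need the same contrast on both pathways
    if (!is.null(comparisons) && "pathway" %in% names(comparisons)) {
      both <- intersect(
        comparisons$condition[comparisons$pathway == "extracellular"],
        comparisons$condition[comparisons$pathway == "cytoplasmic"]
      )
      if (length(both)) {
        calls <- purrr::map(both, function(cc) {
          ext <- comparisons[comparisons$condition == cc &
            comparisons$pathway == "extracellular", ][1, ]
          cyt <- comparisons[comparisons$condition == cc &
            comparisons$pathway == "cytoplasmic", ][1, ]
          call_conformation(ext, cyt)
        }) |> dplyr::bind_rows()
        say("%d conformational call(s)", nrow(calls))
      }
    }
  } else if (any(design$fluoxetine_block)) {
    # ---- transport kinetics -----------------------------------------------
    fits <- tryCatch(
      {
        specific <- subtract_nonspecific(agg)
        out <- list()
        for (sub in unique(specific$substrate)) {
          ss <- dplyr::filter(specific, .data$substrate == sub)
          if (dplyr::n_distinct(ss$substrate_conc_uM) >= 4) {
            f <- fit_mm(ss)
            out[[length(out) + 1L]] <- dplyr::mutate(
              glance(f),
              substrate = sub
            )
          }
          if (dplyr::n_distinct(ss$ion_medium) > 1) {
            ion_panels[[sub]] <- ion_uptake_panel(ss)
          }
        }
        if (length(out)) dplyr::bind_rows(out) else specific
      },
      error = function(e) fail_stage("fit-kinetics", e)
    )
    say("kinetics fitted")
  } else {
    say("no MTS arm and no block arm: reporting aggregated conditions only")
  }

  # ---- outputs -------------------------------------------------------------
  write_pipeline_csv(cells, file.path(out_dir, "cells.csv"))
  write_pipeline_csv(agg, file.path(out_dir, "conditions.csv"))
  if (!is.null(fits)) write_pipeline_csv(fits, file.path(out_dir, "fits.csv"))
  if (!is.null(comparisons)) {
    write_pipeline_csv(comparisons, file.path(out_dir, "comparisons.csv"))
  }
  if (!is.null(calls)) write_pipeline_csv(calls, file.path(out_dir, "calls.csv"))
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  invisible(list(
    cells = cells, conditions = agg, fits = fits,
    comparisons = comparisons, calls = calls, ion_panels = ion_panels
  ))
}
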