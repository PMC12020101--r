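# End-to-end orchestration: simulate -> (segment -> features) -> score ->
# call hits -> report, from a single validated configuration.

# An effect entry in a config is either multiplier-type
# (ld_count_multiplier / ld_radius_multiplier) or a planted shift_sd vector.
parse_effect <- function(x, name) {
  if (inherits(x, "phenotype_profile")) return(x)
  check_known_keys(x, c("name", "ld_count_multiplier", "ld_radius_multiplier",
                        "shift_sd"), paste0("effects$", name))
  shift <- x$shift_sd
  if (!is.null(shift)) {
    shift <- unlist(shift)
    if (is.null(names(shift))) {
      if (length(shift) != 4) {
        abort("unnamed shift_sd must have four values (ld_params order).",
              class = "ldscreen_bad_config")
      }
      names(shift) <- LD_PARAMS
    }
  }
  phenotype_profile(x$name %||% name,
                    x$ld_count_multiplier %||% 1,
                    x$ld_radius_multiplier %||% 1,
                    shift_sd = shift)
}

#' Run the full screening pipeline
#'
#' Builds the synthetic plate described by the configuration (feature mode,
#' or image mode with segmentation + morphometry per field), computes plate
#' QC, scores every compound against the sample median, calls four-parameter
#' hits, and (when `out_dir` is set) writes the artifact chain: plate map,
#' per-well features, scores, hits, QC report JSON and a run manifest.
#' Re-running an identical configuration reproduces identical artifacts.
#'
#' @param config A [run_config()] (or a list coercible to one, or a YAML
#'   path).
#' @param out_dir Optional output directory (overrides the config).
#' @return List (invisible when writing): `wells`, `qc`, `scores`, `hits`,
#'   `manifest`, and `paths` when artifacts were written.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- run_config(config)
  out_dir <- out_dir %||% config$out_dir

  scene <- do.call(scene_spec, config$scene)
  layout <- plate_layout(n_rows = config$plate$n_rows,
                         n_cols = config$plate$n_cols,
                         n_compounds = config$plate$n_compounds,
                         n_negative = config$plate$n_negative,
                         n_positive_per_line = config$plate$n_positive_per_line,
                         positive_lines = unlist(config$plate$positive_lines))
  plate <- plate_spec(layout, base_scene = scene,
                      fields_per_well = config$plate$fields_per_well,
                      noise_sd = unlist(config$plate$noise_sd),
                      baseline_compactness = config$plate$baseline_compactness,
                      seed = config$seed)
  effects <- purrr::imap(config$effects, parse_effect)

  built <- build_plate(plate, planted_effects = effects, mode = config$mode)

  if (config$mode == "features") {
    wells <- built$wells
  } else {
    rows <- purrr::map(seq_len(nrow(built$wells)), function(i) {
      fields <- built$wells$fields[[i]]
      measured <- purrr::map(fields, function(f) measure_field(f$image))
      aggregate_well(purrr::map(measured, "features"),
                     n_cells = purrr::map_int(measured, "n_cells"),
                     well = built$wells$well[i],
                     orphan_puncta = sum(purrr::map_int(measured, "orphan_puncta")))
    })
    wells <- dplyr::bind_cols(
      built$wells[, c("well", "row", "col", "role", "compound_id",
                      "concentration_uM", "cell_line")],
      bind_rows(rows)[, c("n_cells", "n_puncta", LD_PARAMS, "orphan_puncta",
                          "qc_flag")]
    )
  }

  qc <- plate_qc(wells, parameter = config$qc_parameter)
  scores <- score_plate(wells,
                        reference_source = config$scoring$reference_source,
                        robust_sd = isTRUE(config$scoring$robust_sd))
  hits <- call_hits(scores,
                    thresholds = unlist(config$thresholds)[LD_PARAMS],
                    directions = unlist(config$directions)[LD_PARAMS])

  manifest <- c(built$manifest, list(
    package_version = as.character(utils::packageVersion("ldscreen")),
    config = unclass(config),
    records = list(wells = nrow(wells), scores = nrow(scores),
                   compounds = nrow(hits), hits = sum(hits$hit))
  ))

  result <- list(wells = wells, qc = qc, scores = scores, hits = hits,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      plate_map = file.path(out_dir, "plate_map.csv"),
      features = file.path(out_dir, "well_features.csv"),
      scores = file.path(out_dir, "scores.csv"),
      hits = file.path(out_dir, "hits.csv"),
      qc = file.path(out_dir, "qc_report.json"),
      manifest = file.path(out_dir, "manifest.json")
    )
    write_plate_map(layout, paths$plate_map)
    write_well_features(dplyr::select(wells, -dplyr::any_of("fields")),
                        paths$features)
    write_scores(scores, paths$scores)
    write_hits(hits, paths$hits)
    jsonlite::write_json(list(zprime = qc), paths$qc, auto_unbox = TRUE,
                         digits = NA, na = "null")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, na = "null")
    result$paths <- paths
    return(invisible(result))
  }
  result
}
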