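# File I/O: plate maps, feature/score/hit CSVs, multi-channel TIFF fields
# with sidecar channel maps, 16-bit label-map TIFFs, YAML run configs and
# JSON manifests. CSV dialect: comma-separated, UTF-8, mandatory header,
# "." decimal separator; undefined statistics serialise as empty fields.

#' Read and validate a plate-map CSV
#'
#' Required columns: `well,row,col,role,compound_id,concentration_uM,
#' cell_line`. Roles must be `negative_control`, `positive_control`,
#' `compound` or `empty`; well addresses must be unique; concentrations
#' numeric.
#'
#' @param path CSV path.
#' @return Validated layout tibble (see [plate_layout()]).
#' @export
read_plate_map <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(), row = readr::col_integer(),
    col = readr::col_integer(), role = readr::col_character(),
    compound_id = readr::col_character(),
    concentration_uM = readr::col_character(),
    cell_line = readr::col_character()), na = c("", "NA"))
  conc <- suppressWarnings(as.numeric(df$concentration_uM))
  bad <- !is.na(df$concentration_uM) & is.na(conc)
  if (any(bad)) {
    abort(paste0("non-numeric concentration in well(s): ",
                 paste(df$well[bad], collapse = ", ")),
          class = "ldscreen_bad_plate_map")
  }
  df$concentration_uM <- conc
  validate_layout(df)
  df
}

#' Write tabular screen artifacts
#'
#' `write_plate_map()`, `write_well_features()`, `write_scores()` and
#' `write_hits()` serialise the corresponding tibbles as UTF-8 CSV with a
#' header row; undefined values become empty fields (never 0).
#'
#' @param x The tibble to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(x, path) {
  validate_layout(x)
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname write_plate_map
#' @export
write_well_features <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname write_plate_map
#' @export
write_scores <- function(x, path) {
  readr::write_csv(as_tibble(x), path, na = "")
  invisible(path)
}

#' @rdname write_plate_map
#' @export
write_hits <- function(x, path) {
  readr::write_csv(as_tibble(x), path, na = "")
  invisible(path)
}

#' Read a per-well feature CSV
#' @param path CSV path written by [write_well_features()].
#' @return Tibble.
#' @export
read_well_features <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(), role = readr::col_character(),
    compound_id = readr::col_character(),
    cell_line = readr::col_character(),
    qc_flag = readr::col_character(),
    .default = readr::col_double()), na = "")
}

#' Write / read a multi-channel field as TIFF + sidecar channel map
#'
#' Channels are stored as pages of one TIFF (16-bit, intensities clamped to
#' `[0, 1]`); the channel order, pixel size and identifiers go to a sidecar
#' JSON named `<path>.json`.
#'
#' @param img An `image_set`.
#' @param path Output `.tif` path.
#' @return `path` (write) or an `image_set` (read).
#' @export
write_image_set <- function(img, path) {
  stopifnot(inherits(img, "image_set"))
  pages <- lapply(img$channels, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(channels = names(img$channels), pixel_size = img$pixel_size,
                  well = img$well, field = img$field)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  channels <- setNames(pages, sidecar$channels)
  new_image_set(channels, sidecar$pixel_size,
                well = sidecar$well %||% NA_character_,
                field = sidecar$field %||% NA_integer_)
}

#' Write / read a label map as 16-bit single-channel TIFF
#'
#' Labels are scaled by 1/65535 on disk (the TIFF convention for 16-bit
#' greyscale); at most 65535 objects per field.
#'
#' @param lm A `label_map`.
#' @param path Output `.tif` path.
#' @param kind Object kind when reading (`"nuclei"`, `"cells"`, `"puncta"`).
#' @return `path` (write) or a `label_map` (read; parent mapping not stored).
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"), max(lm$labels) <= 65535L)
  tiff::writeTIFF(lm$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path, kind = "puncta") {
  m <- tiff::readTIFF(path)
  new_label_map(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)), kind)
}

# ---- run configuration -----------------------------------------------------

default_run_config <- function() {
  list(
    seed = 1L,
    mode = "features",
    out_dir = NULL,
    plate = list(n_rows = 16L, n_cols = 24L, n_compounds = 348L,
                 n_negative = 12L, n_positive_per_line = 12L,
                 positive_lines = c("GM05400", "GM05381"),
                 fields_per_well = 12L, noise_sd = 1,
                 baseline_compactness = 1.15),
    scene = list(),
    effects = list(),
    scoring = list(reference_source = "all_samples", robust_sd = FALSE),
    thresholds = as.list(default_thresholds()),
    directions = as.list(default_directions()),
    qc_parameter = "ld_total_area"
  )
}

check_known_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s) in ", where, ": ",
                 paste(unknown, collapse = ", ")),
          class = "ldscreen_bad_config")
  }
}

#' Build, read and write pipeline run configurations
#'
#' `run_config()` merges user settings into the defaults and validates them
#' (unknown keys are rejected); `read_run_config()`/`write_run_config()`
#' round-trip the configuration through YAML losslessly.
#'
#' @param ... Named top-level settings (`seed`, `mode`, `out_dir`, `plate`,
#'   `scene`, `effects`, `scoring`, `thresholds`, `directions`,
#'   `qc_parameter`). Sub-lists are merged key-wise into the defaults.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  def <- default_run_config()
  check_known_keys(user, names(def), "config")
  cfg <- def
  for (k in names(user)) {
    cfg[k] <- list(if (is.list(def[[k]]) && !is.null(names(def[[k]])) &&
                       k != "effects") {
      check_known_keys(user[[k]], names(def[[k]]), k)
      modifyList(def[[k]], user[[k]])
    } else user[[k]])
  }
  scene_known <- names(formals(scene_spec))
  check_known_keys(cfg$scene, scene_known, "scene")
  if (!cfg$mode %in% c("features", "images")) {
    abort("mode must be 'features' or 'images'.", class = "ldscreen_bad_config")
  }
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
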