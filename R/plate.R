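# Plate-level synthetic data: layout construction and whole-plate generation
# in feature mode (per-well parameter tables) or image mode (rendered fields).

#' Build a 384-well screen layout
#'
#' Mirrors the screen's plate design: patient cells + DMSO as negative
#' controls (12 wells/plate), two healthy control lines + DMSO as positive
#' controls (12 wells per line), and one compound per remaining well. Wells
#' are addressed `A01`..`P24` (letter row, zero-padded column).
#'
#' @param n_rows,n_cols Plate geometry (default 16 x 24 = 384).
#' @param n_compounds Number of compound wells.
#' @param n_negative Negative-control wells (patient + DMSO).
#' @param n_positive_per_line Positive-control wells per control cell line.
#' @param positive_lines Names of the healthy control lines.
#' @param concentration_uM Screening concentration recorded for compound wells.
#' @return Tibble: `well`, `row`, `col`, `role`, `compound_id`,
#'   `concentration_uM`, `cell_line`. Roles are `negative_control`,
#'   `positive_control`, `compound` or `empty`.
#' @export
plate_layout <- function(n_rows = 16L, n_cols = 24L, n_compounds = 348L,
                         n_negative = 12L, n_positive_per_line = 12L,
                         positive_lines = c("GM05400", "GM05381"),
                         concentration_uM = 10) {
  n_wells <- n_rows * n_cols
  n_controls <- n_negative + n_positive_per_line * length(positive_lines)
  if (n_controls + n_compounds > n_wells) {
    abort("layout does not fit the plate geometry.", class = "ldscreen_bad_spec")
  }
  if (n_negative < 2 || n_positive_per_line < 2) {
    abort("need >= 2 wells per control role so SDs are estimable.",
          class = "ldscreen_bad_spec")
  }
  grid <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  grid$well <- well_address(grid$row, grid$col)
  roles <- c(rep("negative_control", n_negative),
             rep("positive_control", n_positive_per_line * length(positive_lines)),
             rep("compound", n_compounds))
  roles <- c(roles, rep("empty", n_wells - length(roles)))
  lines <- c(rep("patient", n_negative),
             rep(positive_lines, each = n_positive_per_line),
             rep("patient", n_compounds),
             rep(NA_character_, n_wells - n_controls - n_compounds))
  ids <- c(rep(NA_character_, n_controls),
           sprintf("CMP-%04d", seq_len(n_compounds)),
           rep(NA_character_, n_wells - n_controls - n_compounds))
  conc <- ifelse(roles == "compound", concentration_uM,
                 ifelse(roles == "empty", NA_real_, 0))
  tibble(well = grid$well, row = grid$row, col = grid$col, role = roles,
         compound_id = ids, concentration_uM = conc, cell_line = lines)
}

#' Well address helpers
#'
#' `well_address()` converts numeric row/column to zero-padded letter-number
#' addresses (`A01` ... `P24`); rows beyond 26 use doubled letters.
#'
#' @param row,col Integer vectors.
#' @return Character vector of addresses.
#' @export
well_address <- function(row, col) {
  letters_ext <- c(LETTERS, paste0("A", LETTERS))
  paste0(letters_ext[row], sprintf("%02d", col))
}

#' Describe a synthetic screening plate
#'
#' Bundles a layout, the baseline scene, the control phenotypes and the noise
#' model into a plate specification consumed by [build_plate()].
#'
#' @param layout A layout tibble from [plate_layout()] (or read via
#'   [read_plate_map()]).
#' @param base_scene A [scene_spec()]; the patient baseline.
#' @param fields_per_well Fields imaged per well.
#' @param noise_sd Per-parameter well noise SD (see
#'   [simulate_well_features()]).
#' @param negative_profile,positive_profile Phenotypes of the control roles.
#' @param baseline_compactness Feature-mode compactness baseline.
#' @param seed Integer master seed for the plate.
#' @return Object of class `plate_spec`.
#' @export
plate_spec <- function(layout = plate_layout(), base_scene = scene_spec(),
                       fields_per_well = 12L, noise_sd = 1,
                       negative_profile = profile_patient(),
                       positive_profile = profile_healthy(),
                       baseline_compactness = 1.15, seed = 1L) {
  validate_layout(layout)
  structure(
    list(layout = layout, base_scene = base_scene,
         fields_per_well = as.integer(fields_per_well),
         noise_sd = expand_noise_sd(noise_sd),
         negative_profile = negative_profile,
         positive_profile = positive_profile,
         baseline_compactness = baseline_compactness,
         seed = as.integer(seed)),
    class = "plate_spec"
  )
}

validate_layout <- function(layout) {
  req <- c("well", "row", "col", "role", "compound_id", "concentration_uM",
           "cell_line")
  missing_cols <- setdiff(req, names(layout))
  if (length(missing_cols)) {
    abort(paste0("plate map is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ldscreen_bad_plate_map")
  }
  dup <- layout$well[duplicated(layout$well)]
  if (length(dup)) {
    abort(paste0("duplicated well address(es): ",
                 paste(unique(dup), collapse = ", ")),
          class = "ldscreen_bad_plate_map")
  }
  bad_role <- setdiff(unique(layout$role),
                      c("negative_control", "positive_control", "compound", "empty"))
  if (length(bad_role)) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")),
          class = "ldscreen_bad_plate_map")
  }
  if (!is.numeric(layout$concentration_uM)) {
    abort("`concentration_uM` must be numeric.", class = "ldscreen_bad_plate_map")
  }
  cmp <- layout$compound_id[layout$role == "compound"]
  dup_cmp <- unique(cmp[duplicated(cmp)])
  dup_cmp <- dup_cmp[!is.na(dup_cmp)]
  if (length(dup_cmp)) {
    abort(paste0("duplicate compound_id in multiple wells (mark replicates explicitly): ",
                 paste(dup_cmp, collapse = ", ")),
          class = "ldscreen_bad_plate_map")
  }
  invisible(layout)
}

profile_for_well <- function(plate, role, compound_id, planted_effects) {
  if (role == "negative_control") return(plate$negative_profile)
  if (role == "positive_control") return(plate$positive_profile)
  if (role == "compound") {
    if (!is.na(compound_id) && compound_id %in% names(planted_effects)) {
      return(planted_effects[[compound_id]])
    }
    return(plate$negative_profile) # untreated phenotype = patient baseline
  }
  NULL
}

#' Generate a whole synthetic plate with known ground truth
#'
#' In `"features"` mode each non-empty well gets the four LD parameters from
#' [simulate_well_features()] under its role's phenotype; compound wells
#' without a planted effect are statistically exchangeable with negative
#' controls. In `"images"` mode each well's fields are rendered with
#' [render_field()] (planted effects must then be multiplier-type profiles).
#' Every well/field draws under a sub-seed derived from the plate seed, so a
#' plate regenerates byte-identically.
#'
#' @param plate A [plate_spec()].
#' @param planted_effects Named list `compound_id -> phenotype_profile` of
#'   planted perturbations; compounds absent from the list are null.
#' @param mode `"features"` or `"images"`.
#' @return List with `wells` (feature mode: layout + parameter columns;
#'   image mode: layout tibble with a list-column `fields` of rendered
#'   field/truth pairs) and `manifest` (seed, mode, planted effect summary,
#'   `planted_hits` = compound ids carrying a planted effect, expectations).
#' @export
build_plate <- function(plate, planted_effects = list(),
                        mode = c("features", "images")) {
  mode <- match.arg(mode)
  stopifnot(inherits(plate, "plate_spec"))
  unknown <- setdiff(names(planted_effects),
                     plate$layout$compound_id[plate$layout$role == "compound"])
  if (length(unknown)) {
    abort(paste0("planted effect(s) for unknown compound_id: ",
                 paste(unknown, collapse = ", ")),
          class = "ldscreen_bad_spec")
  }
  layout <- plate$layout
  active <- layout$role != "empty"

  if (mode == "features") {
    rows <- purrr::map(which(active), function(i) {
      prof <- profile_for_well(plate, layout$role[i], layout$compound_id[i],
                               planted_effects)
      simulate_well_features(prof, plate$base_scene, plate$fields_per_well,
                             plate$noise_sd,
                             seed = derive_seed(plate$seed, 100L + i),
                             baseline_compactness = plate$baseline_compactness)
    })
    feats <- bind_rows(rows)
    wells <- dplyr::bind_cols(layout[active, ], feats)
  } else {
    shifted <- purrr::map_lgl(planted_effects,
                              function(p) !is.null(p$shift_sd))
    if (any(shifted)) {
      abort("image mode requires multiplier-type planted effects (no shift_sd).",
            class = "ldscreen_bad_spec")
    }
    wells <- layout[active, ]
    wells$fields <- purrr::map(seq_len(nrow(wells)), function(i) {
      prof <- profile_for_well(plate, wells$role[i], wells$compound_id[i],
                               planted_effects)
      purrr::map(seq_len(plate$fields_per_well), function(f) {
        out <- render_field(plate$base_scene, prof,
                            seed = derive_seed(plate$seed,
                                               1000L + 64L * which(layout$well == wells$well[i]) + f))
        out$image$well <- wells$well[i]
        out$image$field <- f
        out
      })
    })
  }

  manifest <- list(
    mode = mode,
    seed = plate$seed,
    n_wells = sum(active),
    fields_per_well = plate$fields_per_well,
    noise_sd = as.list(plate$noise_sd),
    planted_hits = names(planted_effects),
    planted_effects = purrr::map(planted_effects, function(p) {
      list(name = p$name, ld_count_multiplier = p$ld_count_multiplier,
           ld_radius_multiplier = p$ld_radius_multiplier,
           shift_sd = if (is.null(p$shift_sd)) NULL else as.list(p$shift_sd))
    }),
    expected_negative = as.list(expected_ld_params(plate$base_scene,
                                                   plate$negative_profile,
                                                   plate$baseline_compactness)),
    expected_positive = as.list(expected_ld_params(plate$base_scene,
                                                   plate$positive_profile,
                                                   plate$baseline_compactness))
  )
  list(wells = wells, manifest = manifest)
}
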