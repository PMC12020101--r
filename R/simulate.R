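#' Simulate one well's screen parameters without rendering images
#'
#' Fast feature-level path: the four LD parameters for a well are drawn around
#' their closed-form expectations under the phenotype profile (see
#' [expected_ld_params()]), with Gaussian well-to-well noise of the stated
#' per-parameter SDs. If the profile carries planted `shift_sd` displacements,
#' the well's parameters are set to expectation + shift x noise SD exactly
#' (deterministic ground truth for recovery tests); with `noise_sd = 0` the
#' shifts are read as absolute parameter units.
#'
#' @param profile A [phenotype_profile()].
#' @param base A [scene_spec()] giving the baseline scene.
#' @param n_fields Number of imaged fields pooled into the well (>= 1);
#'   contributes `n_fields * base$n_cells` cells to the well record.
#' @param noise_sd Per-parameter Gaussian well-to-well noise SDs: a single
#'   number or a named vector over [ld_params()].
#' @param seed Integer seed; identical arguments + seed reproduce the well.
#' @param baseline_compactness Baseline LD compactness (see
#'   [expected_ld_params()]).
#' @return One-row tibble: `n_cells`, the four parameters, `qc_flag`.
#' @export
simulate_well_features <- function(profile, base = scene_spec(), n_fields = 12L,
                                   noise_sd = 1, seed = 1L,
                                   baseline_compactness = 1.15) {
  stopifnot(n_fields >= 1)
  noise_sd <- expand_noise_sd(noise_sd)
  expectation <- expected_ld_params(base, profile, baseline_compactness)
  values <- draw_well_values(expectation, profile, noise_sd, seed)
  tibble(
    n_cells = as.integer(n_fields * base$n_cells),
    ld_area = values[["ld_area"]],
    ld_total_area = values[["ld_total_area"]],
    ld_compactness = values[["ld_compactness"]],
    ld_form_factor = values[["ld_form_factor"]],
    qc_flag = NA_character_
  )
}

expand_noise_sd <- function(noise_sd) {
  if (length(noise_sd) == 1 && is.null(names(noise_sd))) {
    noise_sd <- setNames(rep(noise_sd, 4), LD_PARAMS)
  }
  if (!all(LD_PARAMS %in% names(noise_sd))) {
    abort("`noise_sd` must be a single number or named over ld_params().",
          class = "ldscreen_bad_spec")
  }
  noise_sd <- noise_sd[LD_PARAMS]
  if (any(noise_sd < 0)) abort("noise SDs must be >= 0.", class = "ldscreen_bad_spec")
  noise_sd
}

# One well's four parameter values. Planted shift_sd displacements are exact;
# all other wells get independent Gaussian noise per parameter.
draw_well_values <- function(expectation, profile, noise_sd, seed) {
  if (!is.null(profile$shift_sd)) {
    unit <- ifelse(noise_sd > 0, noise_sd, 1)
    return(expectation + profile$shift_sd * unit)
  }
  eps <- with_seed(seed, rnorm(4))
  expectation + eps * noise_sd
}

#' Simulate per-cell organelle counts and sizes for two groups
#'
#' Generates the kind of data produced by per-cell organelle quantification
#' (e.g. peroxisome counting after particle segmentation): per-cell counts are
#' Poisson, per-cell mean sizes are log-normal. Used to study the behaviour of
#' [compare_groups()] under planted contrasts such as "more but smaller
#' peroxisomes in patient cells".
#'
#' @param n_cells Cells per group.
#' @param count_rate Baseline Poisson rate (organelles per cell).
#' @param count_ratio Group-2 rate multiplier.
#' @param size_meanlog,size_sdlog Log-normal parameters of per-cell mean
#'   organelle area (um^2).
#' @param size_ratio Group-2 median-size multiplier.
#' @param seed Integer seed.
#' @return List of two tibbles (`group1`, `group2`) with columns `cell`,
#'   `count`, `mean_size`.
#' @export
simulate_organelle_groups <- function(n_cells = 150L, count_rate = 200,
                                      count_ratio = 1.3,
                                      size_meanlog = log(0.25), size_sdlog = 0.3,
                                      size_ratio = 0.8, seed = 1L) {
  with_seed(seed, {
    g1 <- tibble(cell = seq_len(n_cells),
                 count = rpois(n_cells, count_rate),
                 mean_size = rlnorm(n_cells, size_meanlog, size_sdlog))
    g2 <- tibble(cell = seq_len(n_cells),
                 count = rpois(n_cells, count_rate * count_ratio),
                 mean_size = rlnorm(n_cells, size_meanlog + log(size_ratio),
                                    size_sdlog))
    list(group1 = g1, group2 = g2)
  })
}
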