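#' Describe one synthetic microscopy field
#'
#' A scene specification parameterises the synthetic field generator: how many
#' fibroblast-like cells to place, their size, the per-cell lipid droplet (LD)
#' load, and the optics/noise model. LD count per cell is Poisson with rate
#' `ld_count_mean`; LD radius is log-normal with median `ld_radius_median`
#' (pixels) and log-space SD `ld_radius_sigma`. These forms reproduce the
#' "many small droplets" disease phenotype while keeping all per-well
#' expectations available in closed form (see [expected_ld_params()]).
#'
#' @param image_shape Integer vector `c(height, width)` in pixels.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param n_cells Number of cells to place in the field.
#' @param cell_radius_range Range (pixels) for the cell semi-major axis.
#' @param nucleus_radius_fraction Nucleus size as a fraction of the cell axes.
#' @param ld_count_mean Poisson rate: expected LDs per cell (patient baseline).
#' @param ld_radius_median Median LD radius in pixels.
#' @param ld_radius_sigma Log-space SD of the LD radius.
#' @param channel_intensities Named list of `c(fg, bg)` intensity levels
#'   (arbitrary units in `[0, 1]`) for the `nucleus`, `cell` and `puncta`
#'   channels.
#' @param noise_sd Additive Gaussian pixel noise SD.
#' @param psf_sigma Gaussian point-spread-function sigma in pixels.
#' @param seed Integer seed; identical spec + seed reproduces a scene exactly.
#'
#' @return An object of class `scene_spec` (a validated list).
#' @seealso [render_field()], [phenotype_profile()]
#' @export
scene_spec <- function(image_shape = c(256L, 256L),
                       pixel_size = 0.65,
                       n_cells = 20L,
                       cell_radius_range = c(16, 24),
                       nucleus_radius_fraction = 0.35,
                       ld_count_mean = 8,
                       ld_radius_median = 2,
                       ld_radius_sigma = 0.25,
                       channel_intensities = list(
                         nucleus = c(fg = 0.80, bg = 0.04),
                         cell    = c(fg = 0.45, bg = 0.04),
                         puncta  = c(fg = 0.90, bg = 0.04)
                       ),
                       noise_sd = 0.02,
                       psf_sigma = 1,
                       seed = 1L) {
  spec <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_cells = as.integer(n_cells), cell_radius_range = cell_radius_range,
    nucleus_radius_fraction = nucleus_radius_fraction,
    ld_count_mean = ld_count_mean, ld_radius_median = ld_radius_median,
    ld_radius_sigma = ld_radius_sigma,
    channel_intensities = channel_intensities,
    noise_sd = noise_sd, psf_sigma = psf_sigma, seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  if (length(spec$image_shape) != 2 || any(spec$image_shape <= 0)) {
    abort("`image_shape` must be two positive integers (H, W).",
          class = "ldscreen_bad_spec")
  }
  if (spec$n_cells < 0) abort("`n_cells` must be >= 0.", class = "ldscreen_bad_spec")
  if (spec$ld_count_mean < 0) abort("`ld_count_mean` (Poisson rate) must be >= 0.",
                                    class = "ldscreen_bad_spec")
  if (spec$ld_radius_median <= 0) abort("`ld_radius_median` must be > 0.",
                                        class = "ldscreen_bad_spec")
  if (spec$ld_radius_sigma < 0) abort("`ld_radius_sigma` must be >= 0.",
                                      class = "ldscreen_bad_spec")
  ints <- unlist(spec$channel_intensities)
  if (any(ints < 0)) abort("channel intensities must be >= 0.",
                           class = "ldscreen_bad_spec")
  if (spec$noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "ldscreen_bad_spec")
  if (diff(range(spec$cell_radius_range)) < 0 || min(spec$cell_radius_range) <= 0) {
    abort("`cell_radius_range` must be positive and ordered.",
          class = "ldscreen_bad_spec")
  }
  spec
}

#' Phenotype profiles: how a condition or compound perturbs lipid droplets
#'
#' A profile acts multiplicatively on the scene's Poisson LD rate
#' (`ld_count_multiplier`) and on the median LD radius
#' (`ld_radius_multiplier`). In feature mode a profile may additionally carry
#' `shift_sd`: exact per-parameter displacements, in units of the well-to-well
#' noise SD, imposed on the well's four parameters. Planting a k-SD shift
#' means the well's value *is* expectation + k x noise SD — the displacement
#' is the ground truth a recovery test compares against, so shifted wells do
#' not receive additional random noise.
#'
#' @param name Label for the profile.
#' @param ld_count_multiplier Factor (> 0) on the Poisson LD rate.
#' @param ld_radius_multiplier Factor (> 0) on the median LD radius.
#' @param shift_sd Optional named numeric (names among [ld_params()]):
#'   exact additive displacements in noise-SD units (feature mode only).
#' @return An object of class `phenotype_profile`.
#' @export
phenotype_profile <- function(name,
                              ld_count_multiplier = 1,
                              ld_radius_multiplier = 1,
                              shift_sd = NULL) {
  if (ld_count_multiplier < 0 || ld_radius_multiplier <= 0) {
    abort("profile multipliers must be positive (count multiplier may be 0).",
          class = "ldscreen_bad_spec")
  }
  if (!is.null(shift_sd)) {
    if (is.null(names(shift_sd)) || !all(names(shift_sd) %in% LD_PARAMS)) {
      abort("`shift_sd` must be named with parameters among ld_params().",
            class = "ldscreen_bad_spec")
    }
    full <- setNames(numeric(4), LD_PARAMS)
    full[names(shift_sd)] <- shift_sd
    shift_sd <- full
  }
  structure(
    list(name = name, ld_count_multiplier = ld_count_multiplier,
         ld_radius_multiplier = ld_radius_multiplier, shift_sd = shift_sd),
    class = "phenotype_profile"
  )
}

#' @rdname phenotype_profile
#' @details `profile_patient()` is the disease baseline (LD-laden patient
#'   fibroblasts); `profile_healthy()` emulates control fibroblasts with few,
#'   slightly smaller LDs. The compound archetypes mirror the effect classes
#'   observed among screen hits: `profile_clearance()` (fewer and smaller
#'   LDs), `profile_fusion()` (fewer droplets but the remaining ones
#'   enlarged), `profile_null()` (no effect) and `profile_accumulation()`
#'   (increased LD burden).
#' @export
profile_patient <- function() phenotype_profile("patient", 1, 1)

#' @rdname phenotype_profile
#' @export
profile_healthy <- function() phenotype_profile("healthy", 0.25, 0.9)

#' @rdname phenotype_profile
#' @export
profile_clearance <- function() phenotype_profile("clearance", 0.35, 0.7)

#' @rdname phenotype_profile
#' @export
profile_fusion <- function() phenotype_profile("fusion", 0.3, 1.5)

#' @rdname phenotype_profile
#' @export
profile_null <- function() phenotype_profile("null", 1, 1)

#' @rdname phenotype_profile
#' @export
profile_accumulation <- function() phenotype_profile("accumulation", 1.6, 1.15)

#' Closed-form expectations of the four well parameters
#'
#' Under the generator's model (LD count per cell ~ Poisson(lambda x cm),
#' radius ~ log-normal with median m x rm and log-SD sigma), the expected
#' per-object LD area is `pi * (m * rm * pixel_size)^2 * exp(2 sigma^2)` um^2
#' and the expected total LD area per cell is lambda x cm times that. Hence
#' expected total area is linear in the count multiplier and quadratic in the
#' radius multiplier. Compactness has no closed form under rendering; feature
#' mode uses the stated baseline (and form factor its exact reciprocal).
#'
#' @param spec A [scene_spec()].
#' @param profile A [phenotype_profile()].
#' @param baseline_compactness Feature-mode baseline LD compactness (>= 1).
#' @return Named numeric vector over [ld_params()]; areas in um^2.
#' @export
expected_ld_params <- function(spec, profile = profile_patient(),
                               baseline_compactness = 1.15) {
  stopifnot(inherits(spec, "scene_spec"), inherits(profile, "phenotype_profile"))
  m_um <- spec$ld_radius_median * profile$ld_radius_multiplier * spec$pixel_size
  mean_area <- pi * m_um^2 * exp(2 * spec$ld_radius_sigma^2)
  lambda <- spec$ld_count_mean * profile$ld_count_multiplier
  c(ld_area = mean_area,
    ld_total_area = lambda * mean_area,
    ld_compactness = baseline_compactness,
    ld_form_factor = 1 / baseline_compactness)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %dx%d px (%.2f um/px), %d cells, LD ~ Pois(%.2f), r ~ LN(median %.2f px, sigma %.2f), seed %d\n",
    x$image_shape[1], x$image_shape[2], x$pixel_size, x$n_cells,
    x$ld_count_mean, x$ld_radius_median, x$ld_radius_sigma, x$seed))
  invisible(x)
}

#' @export
print.phenotype_profile <- function(x, ...) {
  cat(sprintf("<phenotype_profile> %s: count x%.2f, radius x%.2f%s\n",
              x$name, x$ld_count_multiplier, x$ld_radius_multiplier,
              if (!is.null(x$shift_sd)) {
                paste0(", planted shifts [",
                       paste(sprintf("%g", x$shift_sd), collapse = ", "), "]")
              } else ""))
  invisible(x)
}
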