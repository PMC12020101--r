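# Per-object morphometry and per-well aggregation of the four screen
# parameters, plus the active/total mitochondrial intensity ratio.

shift_mask <- function(M, dr, dc) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(FALSE, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  rok <- rs >= 1 & rs <= H; cok <- cs >= 1 & cs <= W
  out[rok, cok] <- M[rs[rok], cs[cok]]
  out
}

#' Crofton perimeter of a binary object
#'
#' Four-direction Crofton estimator: chords of the object are counted along
#' the horizontal, vertical and both diagonal scan directions and combined as
#' `P = pi/4 * (c0 + c90 + (c45 + c135)/sqrt(2))`. This is the least-biased
#' standard perimeter estimator for small digitised objects (a digitised disk
#' of radius r gives ~2*pi*r within ~1%).
#'
#' @param mask Logical matrix (TRUE = object).
#' @return Perimeter estimate in pixel units.
#' @export
crofton_perimeter <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) return(0)
  starts <- function(dr, dc) sum(mask & !shift_mask(mask, dr, dc))
  c0 <- starts(0, 1)    # horizontal chords
  c90 <- starts(1, 0)   # vertical chords
  c45 <- starts(1, 1)   # down-right diagonal
  c135 <- starts(1, -1) # down-left diagonal
  (pi / 4) * (c0 + c90 + (c45 + c135) / sqrt(2))
}

#' Per-object shape features of labelled puncta
#'
#' Computes for every labelled punctum: area (pixel count, and um^2 via the
#' pixel size), Crofton perimeter, centroid, compactness `P^2/(4*pi*A)` and
#' form factor `4*pi*A/P^2`. The definitional identity
#' `compactness * form_factor = 1` holds exactly: the form factor is stored
#' as the reciprocal of the computed compactness.
#'
#' @param labels A `label_map` of kind `"puncta"`.
#' @param pixel_size Pixel size in um/px.
#' @return Tibble with one row per object: `object_id`, `parent_cell`,
#'   `area_px2`, `area_um2`, `perimeter_px`, `perimeter_um`, `compactness`,
#'   `form_factor`, `centroid_y`, `centroid_x`. Empty map gives an empty
#'   tibble.
#' @export
object_features <- function(labels, pixel_size = 1) {
  stopifnot(inherits(labels, "label_map"))
  if (labels$kind != "puncta") {
    abort("object_features expects a puncta label map.", class = "ldscreen_bad_labels")
  }
  k <- max(labels$labels)
  empty <- tibble(object_id = integer(), parent_cell = integer(),
                  area_px2 = numeric(), area_um2 = numeric(),
                  perimeter_px = numeric(), perimeter_um = numeric(),
                  compactness = numeric(), form_factor = numeric(),
                  centroid_y = numeric(), centroid_x = numeric())
  if (k == 0) return(empty)
  labs <- labels$labels
  H <- nrow(labs)
  idx <- which(labs > 0)
  lab_v <- labs[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(lab_v, nbins = k)
  cy <- tapply(rows, lab_v, mean)
  cx <- tapply(cols, lab_v, mean)
  perim <- vapply(seq_len(k), function(l) {
    sel <- lab_v == l
    r0 <- range(rows[sel]); c0 <- range(cols[sel])
    sub <- matrix(FALSE, r0[2] - r0[1] + 1L, c0[2] - c0[1] + 1L)
    sub[cbind(rows[sel] - r0[1] + 1L, cols[sel] - c0[1] + 1L)] <- TRUE
    crofton_perimeter(sub)
  }, numeric(1))
  compact <- perim^2 / (4 * pi * area)
  parent <- if (!is.null(labels$parent_of)) {
    as.integer(labels$parent_of[as.character(seq_len(k))])
  } else rep(NA_integer_, k)
  tibble(
    object_id = seq_len(k), parent_cell = parent,
    area_px2 = as.numeric(area), area_um2 = area * pixel_size^2,
    perimeter_px = perim, perimeter_um = perim * pixel_size,
    compactness = compact, form_factor = 1 / compact,
    centroid_y = as.numeric(cy), centroid_x = as.numeric(cx)
  )
}

#' Aggregate per-field puncta features into one well summary
#'
#' Pools all puncta across the well's fields. `ld_area`, `ld_compactness`
#' and `ld_form_factor` are unweighted per-object means (robust to cells with
#' zero LDs); `ld_total_area` is the summed LD area divided by the total cell
#' count (um^2/cell), so wells with different cell numbers are comparable.
#'
#' @param puncta_features A tibble from [object_features()] (fields may be
#'   row-bound), or a list of such tibbles.
#' @param n_cells Integer vector of per-field cell counts (or total).
#' @param well Optional well address.
#' @param orphan_puncta QC tally of dropped orphan puncta.
#' @param per_cell Normalise total area per cell (default); `FALSE` restores
#'   the raw per-well sum.
#' @return One-row tibble: `well`, `n_cells`, `n_puncta`, the four
#'   parameters, `orphan_puncta`, `qc_flag`. With zero cells the four
#'   parameters are `NA` (never zeros) and `qc_flag = "no_cells"`.
#' @export
aggregate_well <- function(puncta_features, n_cells, well = NA_character_,
                           orphan_puncta = 0L, per_cell = TRUE) {
  if (is.list(puncta_features) && !is.data.frame(puncta_features)) {
    puncta_features <- bind_rows(puncta_features)
  }
  total_cells <- sum(n_cells)
  if (total_cells == 0) {
    return(tibble(well = well, n_cells = 0L, n_puncta = 0L,
                  ld_area = NA_real_, ld_total_area = NA_real_,
                  ld_compactness = NA_real_, ld_form_factor = NA_real_,
                  orphan_puncta = as.integer(orphan_puncta),
                  qc_flag = "no_cells"))
  }
  n_p <- nrow(puncta_features)
  if (n_p == 0) {
    return(tibble(well = well, n_cells = as.integer(total_cells), n_puncta = 0L,
                  ld_area = NA_real_, ld_total_area = 0,
                  ld_compactness = NA_real_, ld_form_factor = NA_real_,
                  orphan_puncta = as.integer(orphan_puncta),
                  qc_flag = "no_puncta"))
  }
  total_area <- sum(puncta_features$area_um2)
  tibble(
    well = well, n_cells = as.integer(total_cells), n_puncta = n_p,
    ld_area = mean(puncta_features$area_um2),
    ld_total_area = if (per_cell) total_area / total_cells else total_area,
    ld_compactness = mean(puncta_features$compactness),
    ld_form_factor = mean(puncta_features$form_factor),
    orphan_puncta = as.integer(orphan_puncta),
    qc_flag = NA_character_
  )
}

# Histogram mode of an intensity vector (most populated of 256 bins).
intensity_mode <- function(v, n_breaks = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_breaks + 1)
  h <- tabulate(pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L),
                     n_breaks), nbins = n_breaks)
  (br[which.max(h)] + br[which.max(h) + 1L]) / 2
}

#' Per-cell active/total mitochondrial intensity ratio
#'
#' For each segmented cell, the mean background-subtracted intensity of the
#' potential-dependent (`active_mito`, TMRE-like) and potential-independent
#' (`total_mito`, MitoTracker-like) channels over the cell mask; the ratio
#' active/total indexes the active fraction of the mitochondrial pool.
#' Background per channel is estimated from non-cell pixels (histogram mode
#' by default).
#'
#' @param img An `image_set` with `active_mito` and `total_mito` channels.
#' @param cells `label_map` of kind `"cells"`.
#' @param background `"mode"` (default) or `"median"` of non-cell pixels.
#' @return Tibble: `cell`, `active_mean`, `total_mean`, `ratio` (`NA` when
#'   the total-channel mean is not positive).
#' @export
mito_ratio <- function(img, cells, background = c("mode", "median")) {
  background <- match.arg(background)
  stopifnot(inherits(img, "image_set"), inherits(cells, "label_map"))
  act <- img$channels$active_mito
  tot <- img$channels$total_mito
  if (is.null(act) || is.null(tot)) {
    abort("active_mito and total_mito channels are required.",
          class = "ldscreen_missing_channel")
  }
  k <- max(cells$labels)
  if (k == 0) {
    abort("all-background field: no segmented cells.", class = "ldscreen_no_cells")
  }
  outside <- cells$labels == 0
  bg_fun <- if (background == "mode") intensity_mode else median
  bg_act <- if (any(outside)) bg_fun(act[outside]) else 0
  bg_tot <- if (any(outside)) bg_fun(tot[outside]) else 0
  lab_v <- cells$labels[cells$labels > 0]
  act_mean <- as.numeric(tapply(act[cells$labels > 0], lab_v, mean)) - bg_act
  tot_mean <- as.numeric(tapply(tot[cells$labels > 0], lab_v, mean)) - bg_tot
  tibble(
    cell = sort(unique(lab_v)),
    active_mean = act_mean,
    total_mean = tot_mean,
    ratio = ifelse(tot_mean > 0, act_mean / tot_mean, NA_real_)
  )
}

#' Measure a whole field: segment and summarise in one call
#'
#' Convenience wrapper running [segment_nuclei()], [segment_cells()] and
#' [segment_puncta()] with the given parameter lists and returning the
#' per-object feature table plus counts, ready for [aggregate_well()].
#'
#' @param img An `image_set`.
#' @param nuclei_params,cell_params,puncta_params Parameter lists passed to
#'   the respective segmenters.
#' @return List: `features` (per-object tibble), `n_cells`, `n_nuclei`,
#'   `orphan_puncta`, and the three label maps.
#' @export
measure_field <- function(img, nuclei_params = list(), cell_params = list(),
                          puncta_params = list()) {
  nuc <- do.call(segment_nuclei, c(list(img), nuclei_params))
  cells <- do.call(segment_cells, c(list(img, nuc), cell_params))
  puncta <- do.call(segment_puncta, c(list(img, cells), puncta_params))
  feats <- object_features(puncta, pixel_size = img$pixel_size)
  list(features = feats, n_cells = n_objects(cells), n_nuclei = n_objects(nuc),
       orphan_puncta = puncta$orphan_count,
       nuclei = nuc, cells = cells, puncta = puncta)
}
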