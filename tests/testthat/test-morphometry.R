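# Morphometry: per-object shape features, well aggregation, intensity ratios.

test_that("a digitised disk is circular within discretisation tolerance", {
  mask <- oracle_disk(80, 80, 40, 40, 30)
  f <- object_features(mask_as_puncta(mask), pixel_size = 0.5)
  expect_gt(f$form_factor, 0.95)
  expect_lt(f$form_factor, 1.05)
  expect_gt(f$compactness, 0.95)
  expect_lt(f$compactness, 1.05)
  expect_equal(f$compactness * f$form_factor, 1, tolerance = 1e-15)
  # area within 2% of the analytic disk
  expect_lt(abs(f$area_px2 / (pi * 30^2) - 1), 0.02)
  expect_equal(f$area_um2, f$area_px2 * 0.25, tolerance = 1e-12)
  # perimeter near 2*pi*r
  expect_lt(abs(f$perimeter_px / (2 * pi * 30) - 1), 0.03)
})

test_that("rectangle features match the independent boundary-walk oracle", {
  mask <- matrix(FALSE, 30, 60)
  mask[11:20, 11:50] <- TRUE # 10 x 40 rectangle
  f <- object_features(mask_as_puncta(mask))
  expect_equal(f$area_px2, 400)
  walk <- oracle_perimeter_convex(mask)
  expect_equal(walk, 2 * (10 - 1) + 2 * (40 - 1)) # sanity of the oracle itself
  expect_lt(abs(f$perimeter_px - walk) / walk, 0.05)
  expect_equal(f$form_factor, 4 * pi * 400 / f$perimeter_px^2, tolerance = 1e-12)
})

test_that("features are invariant to translation, 90-degree rotation and label renumbering", {
  set.seed(8)
  H <- 90
  labs <- matrix(0L, H, H)
  labs[oracle_disk(H, H, 25, 30, 6)] <- 1L
  blob <- oracle_disk(H, H, 60, 55, 9) | oracle_disk(H, H, 60, 62, 7)
  labs[blob] <- 2L
  lm <- ldscreen:::new_label_map(labs, "puncta")
  f0 <- object_features(lm)

  shifted <- matrix(0L, H, H)
  shifted[11:H, 6:H] <- labs[1:(H - 10), 1:(H - 5)]
  f_shift <- object_features(ldscreen:::new_label_map(shifted, "puncta"))
  rotated <- t(labs[H:1, ])
  f_rot <- object_features(ldscreen:::new_label_map(rotated, "puncta"))
  renum <- labs
  renum[labs == 1L] <- 2L; renum[labs == 2L] <- 1L
  f_renum <- object_features(ldscreen:::new_label_map(renum, "puncta"))

  cols <- c("area_px2", "perimeter_px", "compactness", "form_factor")
  for (col in cols) {
    expect_equal(f_shift[[col]], f0[[col]], tolerance = 1e-12)
    expect_equal(f_rot[[col]], f0[[col]], tolerance = 1e-12)
    expect_equal(sort(f_renum[[col]]), sort(f0[[col]]), tolerance = 1e-12)
  }
  # empty map -> empty feature table
  empty <- ldscreen:::new_label_map(matrix(0L, 4, 4), "puncta")
  expect_equal(nrow(object_features(empty)), 0)
})

test_that("well aggregation: arithmetic, pooling invariance, conservation, degenerate wells", {
  feats <- tibble::tibble(area_um2 = c(2, 4), compactness = c(1.2, 1.4),
                          form_factor = 1 / c(1.2, 1.4))
  w <- aggregate_well(feats, n_cells = 1, well = "A01")
  expect_equal(w$ld_area, 3)
  expect_equal(w$ld_total_area, 6)

  # duplicating a field leaves means and total-per-cell unchanged
  w2 <- aggregate_well(list(feats, feats), n_cells = c(1, 1))
  expect_equal(w2$ld_area, w$ld_area)
  expect_equal(w2$ld_form_factor, w$ld_form_factor)
  expect_equal(w2$ld_total_area, w$ld_total_area)
  expect_equal(w2$n_cells, 2L)

  # conservation to machine precision on a rendered field
  out <- render_field(scene_spec(seed = 13))
  m <- measure_field(out$image)
  agg <- aggregate_well(m$features, n_cells = m$n_cells)
  expect_equal(agg$ld_total_area * agg$n_cells, sum(m$features$area_um2),
               tolerance = 1e-12)
  # raw per-well sums restorable
  raw <- aggregate_well(m$features, n_cells = m$n_cells, per_cell = FALSE)
  expect_equal(raw$ld_total_area, sum(m$features$area_um2), tolerance = 1e-12)

  # zero cells: undefined markers, never zeros
  w0 <- aggregate_well(feats[0, ], n_cells = 0)
  expect_true(is.na(w0$ld_area) && is.na(w0$ld_total_area))
  expect_equal(w0$qc_flag, "no_cells")
  # cells but no puncta: total area genuinely 0, means undefined
  wnp <- aggregate_well(feats[0, ], n_cells = 5)
  expect_equal(wnp$ld_total_area, 0)
  expect_true(is.na(wnp$ld_area))
  expect_equal(wnp$qc_flag, "no_puncta")
})

test_that("noiseless rendered wells recover the closed-form total LD area", {
  sp <- scene_spec(ld_count_mean = 10, noise_sd = 0, seed = 2)
  ms <- lapply(seq_len(12), function(f) {
    measure_field(render_field(sp, seed = ldscreen:::derive_seed(2, 500L + f))$image)
  })
  w <- aggregate_well(lapply(ms, `[[`, "features"),
                      n_cells = vapply(ms, `[[`, integer(1), "n_cells"))
  expectation <- expected_ld_params(sp)
  expect_lt(abs(w$ld_total_area / expectation[["ld_total_area"]] - 1), 0.05)
})

test_that("mitochondrial intensity ratios behave at the identities and under noise", {
  H <- 120
  cells_lab <- matrix(0L, H, H)
  cells_lab[oracle_disk(H, H, 30, 30, 18)] <- 1L
  cells_lab[oracle_disk(H, H, 80, 70, 20)] <- 2L
  cells <- ldscreen:::new_label_map(cells_lab, "cells")
  base <- matrix(0.05, H, H)
  base[cells_lab > 0] <- 0.6

  # active == total -> every ratio 1
  img_eq <- image_set(list(active_mito = base, total_mito = base), 1)
  r <- mito_ratio(img_eq, cells)
  expect_equal(r$ratio, c(1, 1), tolerance = 1e-12)

  # active flat at background -> ratios 0
  img0 <- image_set(list(active_mito = matrix(0.05, H, H), total_mito = base), 1)
  expect_equal(mito_ratio(img0, cells)$ratio, c(0, 0), tolerance = 1e-6)

  # missing channel and empty field errors
  expect_error(mito_ratio(image_set(list(total_mito = base), 1), cells),
               class = "ldscreen_missing_channel")
  empty_cells <- ldscreen:::new_label_map(matrix(0L, H, H), "cells")
  expect_error(mito_ratio(img_eq, empty_cells), class = "ldscreen_no_cells")

  # Monte-Carlo: active = 0.5 * (total - bg) + bg + noise
  set.seed(31)
  n_rep <- 60
  ratios <- replicate(n_rep, {
    act <- 0.05 + 0.5 * (base - 0.05) + matrix(rnorm(H * H, 0, 0.01), H, H)
    img <- image_set(list(active_mito = pmax(act, 0), total_mito = base), 1)
    mean(mito_ratio(img, cells)$ratio)
  })
  se <- sd(ratios) / sqrt(n_rep)
  expect_lt(abs(mean(ratios) - 0.5), 3 * se + 1e-3)
})
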