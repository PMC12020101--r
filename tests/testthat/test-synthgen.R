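# Synthetic generator: spec validation, seeded determinism, closed-form
# expectations, plate bookkeeping.

test_that("scene and profile specifications reject invalid parameters", {
  expect_error(scene_spec(n_cells = -1), class = "ldscreen_bad_spec")
  expect_error(scene_spec(ld_count_mean = -2), class = "ldscreen_bad_spec")
  expect_error(scene_spec(ld_radius_median = 0), class = "ldscreen_bad_spec")
  expect_error(scene_spec(noise_sd = -0.1), class = "ldscreen_bad_spec")
  expect_error(scene_spec(image_shape = c(0, 64)), class = "ldscreen_bad_spec")
  expect_error(phenotype_profile("x", ld_radius_multiplier = 0),
               class = "ldscreen_bad_spec")
  expect_error(phenotype_profile("x", shift_sd = c(bogus = 1)),
               class = "ldscreen_bad_spec")
  expect_error(simulate_well_features(profile_null(), noise_sd = -1),
               class = "ldscreen_bad_spec")
  # default presets satisfy the control-vs-patient ordering
  expect_lt(profile_healthy()$ld_count_multiplier,
            profile_patient()$ld_count_multiplier)
})

test_that("empty fields and zero LD rates give empty ground truth", {
  out <- render_field(scene_spec(n_cells = 0, image_shape = c(64, 64), seed = 2))
  expect_equal(nrow(out$truth$cells), 0)
  expect_equal(nrow(out$truth$lds), 0)
  expect_equal(dim(out$image$channels$puncta), c(64, 64))
  # pure background: nothing near the foreground level anywhere
  expect_lt(max(out$image$channels$puncta), 0.5)

  out0 <- render_field(scene_spec(n_cells = 10, image_shape = c(200, 200),
                                  seed = 3),
                       profile = phenotype_profile("off", ld_count_multiplier = 0))
  expect_equal(nrow(out0$truth$lds), 0)
  expect_equal(nrow(out0$truth$cells), 10)
})

test_that("rendered LD counts replay the seeded Poisson draws", {
  sp <- scene_spec(n_cells = 20, ld_count_mean = 8, image_shape = c(320, 320),
                   seed = 7)
  out <- render_field(sp)
  replayed <- ldscreen:::with_seed(ldscreen:::derive_seed(7, 2L), rpois(20, 8))
  expect_identical(out$truth$ld_counts, replayed)
  expect_equal(nrow(out$truth$lds), sum(replayed))
  # every LD's parent cell exists
  expect_true(all(out$truth$lds$cell %in% out$truth$cells$cell))
})

test_that("field rendering is deterministic and conserves LD area", {
  sp <- scene_spec(seed = 11)
  a <- render_field(sp)
  b <- render_field(sp)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$lds, b$truth$lds)
  # conservation: per-LD areas sum to the field total by construction
  expect_equal(sum(a$truth$lds$area_um2),
               sum(pi * a$truth$lds$r_px^2) * sp$pixel_size^2,
               tolerance = 1e-12)
  # a different seed moves the scene
  expect_false(identical(a$truth$lds,
                         render_field(sp, seed = 12)$truth$lds))
})

test_that("cell placement fails loudly when the field is too crowded", {
  expect_error(render_field(scene_spec(n_cells = 60, image_shape = c(128, 128),
                                       seed = 1)),
               class = "ldscreen_placement")
})

test_that("zero-noise well features equal closed-form expectations and scale laws hold", {
  base <- scene_spec()
  w <- simulate_well_features(profile_patient(), base, noise_sd = 0, seed = 5)
  expectation <- expected_ld_params(base, profile_patient())
  expect_equal(w$ld_area, expectation[["ld_area"]])
  expect_equal(w$ld_total_area, expectation[["ld_total_area"]])
  expect_equal(w$ld_compactness * w$ld_form_factor, 1, tolerance = 1e-12)

  # total area linear in the count multiplier ...
  half <- simulate_well_features(phenotype_profile("h", 0.5, 1), base,
                                 noise_sd = 0, seed = 5)
  expect_equal(half$ld_total_area / w$ld_total_area, 0.5, tolerance = 1e-12)
  # ... and quadratic in the radius multiplier
  dbl <- simulate_well_features(phenotype_profile("d", 1, 2), base,
                                noise_sd = 0, seed = 5)
  expect_equal(dbl$ld_total_area / w$ld_total_area, 4, tolerance = 1e-12)
  expect_equal(dbl$ld_area / w$ld_area, 4, tolerance = 1e-12)
})

test_that("replicate well means match closed-form expectations (Monte Carlo)", {
  base <- scene_spec()
  expectation <- expected_ld_params(base, profile_patient())
  n <- 10000
  sds <- c(ld_area = 0.5, ld_total_area = 2, ld_compactness = 0.1,
           ld_form_factor = 0.1)
  draws <- purrr::map_dfr(seq_len(n), function(i) {
    simulate_well_features(profile_patient(), base, noise_sd = sds, seed = i)
  })
  for (p in ld_params()) {
    se <- sds[[p]] / sqrt(n)
    expect_lt(abs(mean(draws[[p]]) - expectation[[p]]), 3 * se)
  }
})

test_that("plate building: null wells match negative controls, manifests list planted hits, rebuilds are byte-identical", {
  layout <- plate_layout(n_compounds = 30, n_negative = 4,
                         n_positive_per_line = 2)
  # zero noise: every null compound well is identical to the negative controls
  pl0 <- plate_spec(layout, noise_sd = 0, seed = 3)
  b0 <- build_plate(pl0)
  neg <- b0$wells[b0$wells$role == "negative_control", ld_params()]
  cmp <- b0$wells[b0$wells$role == "compound", ld_params()]
  for (p in ld_params()) expect_true(all(cmp[[p]] == neg[[p]][1]))

  # manifest bookkeeping: exactly the planted compound ids
  eff <- list(
    `CMP-0003` = profile_clearance(),
    `CMP-0010` = phenotype_profile("s", shift_sd = c(ld_total_area = -5)),
    `CMP-0019` = profile_fusion(),
    `CMP-0025` = profile_accumulation()
  )
  pl <- plate_spec(layout, seed = 9)
  b <- build_plate(pl, eff)
  expect_setequal(b$manifest$planted_hits, names(eff))
  expect_error(build_plate(pl, list(`CMP-9999` = profile_null())),
               class = "ldscreen_bad_spec")

  # byte-identical regeneration through CSV serialisation
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_well_features(build_plate(pl, eff)$wells, f1)
  write_well_features(build_plate(pl, eff)$wells, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("an all-null plate yields standard-normal-like scores", {
  pl <- plate_spec(acceptance_layout(), seed = 17)
  b <- build_plate(pl)
  sc <- score_plate(b$wells)
  for (p in ld_params()) {
    z <- sc$z[sc$parameter == p]
    expect_lt(abs(mean(z)), 0.1)
    expect_gt(sd(z), 0.8)
    expect_lt(sd(z), 1.2)
  }
})
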