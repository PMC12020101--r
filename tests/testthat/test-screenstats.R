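# Plate statistics: Z-prime, SD-distance scoring, hit calling, gated
# two-group comparison.

test_that("zprime reproduces the closed form, its limits and its symmetry", {
  # zero-variance limit
  expect_equal(zprime(c(10, 10), c(0, 0))$value, 1)
  # hand-evaluated 4-vs-4 example: 1 - 3*(0 + 1)/9.5
  zp <- zprime(c(10, 10, 10, 10), c(0, 0, 0, 2))
  expect_equal(zp$value, 1 - 3 * (0 + 1) / 9.5, tolerance = 1e-12)
  expect_equal(zp$sd_neg, 1)
  expect_equal(zp$mean_neg, 0.5)
  # symmetry under swapping groups
  set.seed(2)
  a <- rnorm(8, 10); b <- rnorm(8, 2)
  expect_equal(zprime(a, b)$value, zprime(b, a)$value, tolerance = 1e-14)
  # value <= 1 on random inputs
  for (i in 1:20) {
    x <- rnorm(5, runif(1, -5, 5)); y <- rnorm(5, runif(1, -5, 5))
    expect_lte(zprime(x, y)$value, 1)
  }
  # equal means: undefined and flagged
  zeq <- zprime(c(1, 2, 3), c(3, 2, 1))
  expect_true(is.na(zeq$value))
  expect_equal(zeq$flag, "equal_means")
  expect_error(zprime(1, c(1, 2)), class = "ldscreen_bad_spec")
  # tidy/glance expose the same numbers
  expect_equal(glance(zp)$zprime, zp$value)
})

test_that("scores match direct arithmetic and are location invariant", {
  # reference {1..9}: median 5, sample SD sqrt(60/8); compound at 10.4776
  wells <- tibble::tibble(
    well = sprintf("W%02d", 1:10),
    role = c(rep("negative_control", 9), "compound"),
    compound_id = c(rep(NA, 9), "CMP-0001"))
  for (p in ld_params()) wells[[p]] <- c(1:9, 10.4776)
  sc <- score_plate(wells, reference_source = "negative_controls")
  expected_z <- (10.4776 - 5) / sqrt(sum((1:9 - 5)^2) / 8)
  expect_equal(unique(sc$z), expected_z, tolerance = 1e-12)
  expect_equal(round(expected_z, 3), 2.000) # the arithmetic oracle itself

  # compound at the reference median scores zero everywhere
  wells0 <- wells
  for (p in ld_params()) wells0[[p]][10] <- 5
  expect_true(all(score_plate(wells0, "negative_controls")$z == 0))

  # adding a constant to every well leaves scores unchanged
  shifted <- wells
  for (p in ld_params()) shifted[[p]] <- shifted[[p]] + 123.4
  expect_equal(score_plate(shifted, "negative_controls")$z, sc$z,
               tolerance = 1e-10)

  # degenerate reference SD: undefined scores with a warning
  const <- wells
  for (p in ld_params()) const[[p]] <- c(rep(2, 9), 7)
  expect_warning(scc <- score_plate(const, "negative_controls"), "zero reference")
  expect_true(all(is.na(scc$z)))
})

test_that("score_plate equals a brute-force median/SD recomputation", {
  for (seed in 1:20) {
    wells <- random_wells(n_compounds = 30 + seed, seed = seed)
    for (src in c("all_samples", "negative_controls")) {
      sc <- score_plate(wells, reference_source = src)
      br <- oracle_scores(wells, reference_source = src)
      merged <- merge(as.data.frame(sc), br,
                      by = c("compound_id", "parameter"))
      expect_gt(nrow(merged), 0)
      expect_lt(max(abs(merged$z.x - merged$z.y) /
                      pmax(abs(merged$z.y), 1e-12)), 1e-10)
    }
  }
  # robust SD variant equals the direct MAD formula
  wells <- random_wells(seed = 99)
  scr <- score_plate(wells, robust_sd = TRUE)
  v <- wells$ld_area[wells$role == "compound"]
  expect_equal(scr$z[scr$parameter == "ld_area"][1],
               (v[1] - median(v)) / mad(v), tolerance = 1e-12)
})

test_that("hit calling enforces per-parameter thresholds, directions and the four-way intersection", {
  z_hit <- c(ld_area = -2.5, ld_total_area = -2.5, ld_compactness = -2.5,
             ld_form_factor = -4.5)
  z_ff_short <- c(ld_area = -2.5, ld_total_area = -2.5, ld_compactness = -2.5,
                  ld_form_factor = -3.9)
  z_incr_total <- c(ld_area = 2.5, ld_total_area = 2.5, ld_compactness = 2.5,
                    ld_form_factor = 4.5)
  sc <- score_plate(wells_with_z(list(A = z_hit, B = z_ff_short,
                                      C = z_incr_total)),
                    reference_source = "negative_controls")
  h <- call_hits(sc)
  expect_true(h$hit[h$compound_id == "A"])
  expect_false(h$hit[h$compound_id == "B"])  # form factor misses the 4 SD bar
  expect_false(h$hit[h$compound_id == "C"])  # total area must decrease
  expect_equal(h$direction_total_area[h$compound_id == "C"], "increase")

  # with a two-sided total-area policy, C becomes a hit
  dirs <- default_directions(); dirs["ld_total_area"] <- "two_sided"
  h2 <- call_hits(sc, directions = dirs)
  expect_true(h2$hit[h2$compound_id == "C"])

  # raising any threshold never converts a non-hit into a hit
  set.seed(6)
  zs <- purrr::map(1:25, function(i) {
    stats::setNames(rnorm(4, 0, 3), ld_params())
  })
  names(zs) <- sprintf("R%02d", 1:25)
  scr <- score_plate(wells_with_z(zs), reference_source = "negative_controls")
  base_hits <- call_hits(scr)$hit
  for (p in ld_params()) {
    thr <- default_thresholds(); thr[p] <- thr[p] + 1.5
    expect_true(all(call_hits(scr, thresholds = thr)$hit <= base_hits))
  }

  # an undefined score excludes the compound with a flag, never a silent pass
  sc_na <- sc
  sc_na$z[sc_na$compound_id == "A" & sc_na$parameter == "ld_area"] <- NA
  h_na <- call_hits(sc_na)
  expect_false(h_na$hit[h_na$compound_id == "A"])
  expect_equal(h_na$flag[h_na$compound_id == "A"], "undefined_score")
})

test_that("planted 5-SD four-parameter shifts are always called; three-parameter shifts never", {
  layout <- acceptance_layout()
  ids4 <- c("CMP-0010", "CMP-0100", "CMP-0200")
  id3 <- "CMP-0300"
  eff <- c(
    stats::setNames(lapply(ids4, function(id) {
      phenotype_profile("hit4", shift_sd = stats::setNames(
        c(-5, -5, -5, -5), ld_params()))
    }), ids4),
    stats::setNames(list(phenotype_profile("hit3", shift_sd = stats::setNames(
      c(-5, -5, -5, 0), ld_params()))), id3)
  )
  for (seed in 1:5) {
    b <- build_plate(plate_spec(layout, seed = seed), eff)
    h <- call_hits(score_plate(b$wells))
    called <- h$compound_id[h$hit]
    expect_true(all(ids4 %in% called))
    expect_false(id3 %in% called)
  }
})

test_that("the normality gate selects the right test and handles degenerate data", {
  set.seed(12)
  g_norm <- compare_groups(rnorm(40, 5), rnorm(40, 5.2))
  expect_equal(g_norm$test_used, "t")
  g_ln <- compare_groups(rlnorm(60, 0, 1), rlnorm(60, 0.5, 1))
  expect_equal(g_ln$test_used, "mann-whitney")

  # identical non-normal samples: Mann-Whitney path, p exactly 1
  x <- rlnorm(50, 0, 1.5)
  g_id <- compare_groups(x, x)
  expect_equal(g_id$test_used, "mann-whitney")
  expect_equal(g_id$p_value, 1, tolerance = 1e-12)

  # all-tied data: normality undefined -> Mann-Whitney fallback, flagged
  g_tied <- compare_groups(rep(2, 10), rep(2, 12))
  expect_equal(g_tied$test_used, "mann-whitney")
  expect_equal(g_tied$flag, "normality_undefined")

  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), class = "ldscreen_bad_spec")
  expect_equal(glance(g_ln)$test_used, "mann-whitney")
  expect_equal(nrow(tidy(g_ln)), 2)
})

test_that("canonical SSMD matches its definition on replicate data", {
  x <- c(4, 5, 6); ref <- c(1, 2, 3, 2)
  expect_equal(ssmd_canonical(x, ref),
               (mean(x) - mean(ref)) / sqrt(var(x) + var(ref)),
               tolerance = 1e-14)
  expect_error(ssmd_canonical(1, ref), class = "ldscreen_bad_spec")
})

test_that("plate_qc reports one Z-prime per positive-control line", {
  b <- build_plate(plate_spec(plate_layout(n_compounds = 40, n_negative = 6,
                                           n_positive_per_line = 6), seed = 4))
  qc <- plate_qc(b$wells)
  expect_equal(sort(qc$cell_line), c("GM05381", "GM05400"))
  expect_true(all(qc$zprime > 0.5)) # the planted disease/control window is wide
})
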