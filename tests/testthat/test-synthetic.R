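test_that("generators are deterministic under a fixed seed", {
  cfg <- cell_field_config(n_cells = 30L, seed = 9L)
  a <- make_bacteria_field(cfg); b <- make_bacteria_field(cfg)
  expect_identical(a$pi$data, b$pi$data)
  expect_identical(a$phase$data, b$phase$data)
  expect_identical(a$truth$cells, b$truth$cells)

  scfg <- contact_scene_config(seed = 4L, volume_shape = c(8L, 64L, 64L),
                               n_droplets = 6L, n_mito_tubes = 2L,
                               tube_length_um = 1.5)
  s1 <- make_contact_volume(scfg); s2 <- make_contact_volume(scfg)
  expect_identical(s1$ld$data, s2$ld$data)
  expect_identical(s1$truth$contact, s2$truth$contact)

  c1 <- make_cfu_counts(0.3, 1e8, seed = 2L)
  c2 <- make_cfu_counts(0.3, 1e8, seed = 2L)
  expect_identical(c1, c2)
})

test_that("planted positive count is exactly round(n_cells x fraction)", {
  for (f in c(0, 0.06, 0.34, 0.5, 0.66, 1)) {
    fld <- make_bacteria_field(cell_field_config(
      n_cells = 50L, positive_fraction = f, seed = 3L))
    expect_equal(sum(fld$truth$cells$positive), round(50 * f))
    expect_equal(fld$truth$true_positive_fraction, round(50 * f) / 50)
  }
  expect_error(cell_field_config(positive_fraction = 1.2), "\\[0, 1\\]")
})

test_that("noiseless bacterial fields are recovered with zero errors", {
  fld <- make_bacteria_field(cell_field_config(
    n_cells = 60L, positive_fraction = 0.5, noise_sigma = 0,
    intensity_positive = 600, intensity_negative = 60, seed = 8L))
  cells <- segment_cells(fld$phase, "rod")
  expect_equal(nrow(cells), 60L)
  cells <- per_cell_intensity(cells, fld$pi)
  cells <- classify_positive(cells)
  m <- match_truth(cells, fld$truth)
  expect_equal(sum(m$positive != m$true_positive), 0L)
  expect_equal(mean(cells$positive), 0.5)
})

test_that("contact-scene ground truth equals the brute-force face oracle", {
  for (seed in c(1L, 6L, 14L)) {
    scn <- make_contact_volume(contact_scene_config(
      seed = seed, volume_shape = c(10L, 72L, 72L), n_droplets = 8L,
      n_mito_tubes = 3L, tube_length_um = 2))
    orc <- oracle_contact(scn$truth$ld_mask$data, scn$truth$mito_mask$data,
                          scn$config$voxel_size)
    expect_identical(scn$truth$contact$n_contact_faces, orc$n_faces)
    expect_equal(scn$truth$contact$contact_area_um2, orc$area_um2)
  }
})

test_that("fully separated scenes have exactly zero contact", {
  scn <- make_contact_volume(contact_scene_config(
    seed = 2L, target_contact_fraction = 0, gap_um = 2,
    psf_sigma_um = 0, poisson_noise = FALSE))
  expect_equal(scn$truth$contact$contact_area_um2, 0)
  expect_equal(scn$truth$contact$contact_ratio, 0)
})

test_that("an empty droplet scene is flagged, not an error", {
  scn <- make_contact_volume(contact_scene_config(
    seed = 2L, n_droplets = 0L, psf_sigma_um = 0, poisson_noise = FALSE))
  expect_true(scn$truth$contact$ld_empty)
  expect_equal(scn$truth$contact$contact_ratio, 0)
  expect_equal(scn$truth$contact$ld_volume_um3, 0)
  # droplet channel is pure background
  expect_true(all(scn$ld$data == scn$config$background))
})

test_that("widening the planted gap never increases the contact ratio", {
  ratios_true <- c(); ratios_est <- c()
  for (gap in c(0.3, 0.6, 1.2)) {
    scn <- make_contact_volume(contact_scene_config(
      seed = 31L, target_contact_fraction = 0.25, gap_um = gap,
      psf_sigma_um = 0, poisson_noise = FALSE))
    ratios_true <- c(ratios_true, scn$truth$contact$contact_ratio)
    est <- contact_area(segment(preprocess(scn$ld, 0, 0)),
                        segment(preprocess(scn$mito, 0, 0)))
    ratios_est <- c(ratios_est, est$contact_ratio)
  }
  expect_true(all(diff(ratios_true) <= 0))
  expect_true(all(diff(ratios_est) <= 0))
})

test_that("impossible placements raise a placement error", {
  expect_error(make_bacteria_field(cell_field_config(
    field_shape = c(40L, 40L), n_cells = 200L, seed = 1L)),
    "could not place")
  expect_error(make_contact_volume(contact_scene_config(
    volume_shape = c(4L, 24L, 24L), n_droplets = 60L, seed = 1L)),
    "placement failed")
})

test_that("JC-1 fields plant exact and scattered ratios", {
  base <- cell_field_config(cell_geometry = "round", n_cells = 40L,
                            field_shape = c(320L, 320L), seed = 12L)
  # no scatter, no noise, zero background: every measured ratio exact
  cfg <- utils::modifyList(base, list(ratio_scatter_sd = 0,
                                      green_scatter_sd = 0,
                                      noise_sigma = 0, background = 0,
                                      red_green_ratio = 2))
  fld <- make_jc1_field(cfg)
  cells <- segment_cells(fld$green, "round")
  cells <- jc1_ratio(cells, fld$red, fld$green)
  expect_equal(cells$ratio, rep(2, nrow(cells)), tolerance = 1e-10)

  cfg1 <- utils::modifyList(cfg, list(red_green_ratio = 1))
  fld1 <- make_jc1_field(cfg1)
  cells1 <- segment_cells(fld1$green, "round")
  cells1 <- jc1_ratio(cells1, fld1$red, fld1$green)
  expect_equal(cells1$ratio, rep(1, nrow(cells1)), tolerance = 1e-10)

  # 10% per-cell scatter, n = 100: mean ratio within 3 SEM of planted 1.5
  cfg2 <- cell_field_config(cell_geometry = "round", n_cells = 100L,
                            field_shape = c(512L, 512L), seed = 13L,
                            red_green_ratio = 1.5, ratio_scatter_sd = 0.1)
  fld2 <- make_jc1_field(cfg2)
  cells2 <- segment_cells(fld2$green, "round")
  cells2 <- jc1_ratio(cells2, fld2$red, fld2$green)
  sem <- stats::sd(cells2$ratio) / sqrt(sum(!is.na(cells2$ratio)))
  expect_lt(abs(mean(cells2$ratio, na.rm = TRUE) - 1.5), 3 * sem)
})

test_that("CFU simulation honours the survival model", {
  # sterilized culture: all counts zero
  tbl0 <- make_cfu_counts(0, 1e8, seed = 1L)
  expect_true(all(tbl0$count == 0L))
  expect_error(make_cfu_counts(-0.1, 1e8), "non-negative")
  expect_error(make_cfu_counts(0.5, 1e8, dilutions = c(10, 25)),
               "powers of ten")
  # arithmetic identity: 1e8 CFU/ml x 0.01 ml / 1e6 = 1 expected colony
  set.seed(99)
  counts <- replicate(2000, make_cfu_counts(1, 1e8,
                                            dilutions = 1e6)$count)
  expect_lt(abs(mean(counts) - 1), 3 * sd(counts) / sqrt(2000))
})

test_that("presets encode the planted study conditions", {
  expect_error(preset("nope"), "unknown preset")
  p <- preset("dual_fever_40", seed = 5L)
  expect_equal(nrow(p$pi), 6L)          # 2 conditions x 3 replicates
  fr <- vapply(p$pi$cfg, function(cfg) cfg$positive_fraction, numeric(1))
  expect_equal(unique(fr[p$pi$condition == "40C"]) /
                 unique(fr[p$pi$condition == "37C"]), 11)
  expect_equal(p$pi$seed[p$pi$condition == "37C"], c(5L, 6L, 7L))

  p385 <- preset("dual_fever_385", seed = 1L)
  fr385 <- vapply(p385$pi$cfg, function(cfg) cfg$positive_fraction,
                  numeric(1))
  expect_equal(max(fr385) / min(fr385), 7)

  pact <- preset("ll37_activity_37")
  ratios <- vapply(pact$jc1$cfg, function(cfg) cfg$red_green_ratio,
                   numeric(1))
  expect_equal(sort(unique(ratios)), c(1.2, 2.0))

  pc <- preset("contact_glucose_temp")
  cf <- vapply(pc$contact$cfg, function(cfg) cfg$target_contact_fraction,
               numeric(1))
  expect_equal(sort(unique(cf)), c(0.15, 0.6))
  expect_equal(nrow(pc$contact), 27L)   # 3 conditions x 3 reps x 3 fields
})
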