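test_that("segmentation handles blank fields and area filters", {
  expect_warning(cells <- segment_cells(matrix(7, 50, 50), "rod"), "flat")
  expect_equal(nrow(cells), 0L)

  # one in-range disk, one giant blob above max_area, one speck below min
  img <- matrix(0, 80, 80)
  img[30:70, 5:75] <- 0          # big blob region below
  mk_disk <- function(img, cy, cx, r, val) {
    for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img))) {
      if ((y - cy)^2 + (x - cx)^2 <= r^2) img[y, x] <- val
    }
    img
  }
  img <- mk_disk(img, 15, 15, 5, 100)     # ~78 px, kept
  img[40:75, 10:70] <- 100                # 2196 px, above max_area
  img[5, 60] <- 100                       # 1 px, below min_area
  cells <- segment_cells(volume_image(img), "round",
                         min_area = 20, max_area = 2000)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$centroid_y, 15, tolerance = 0.1)
  expect_equal(cells$centroid_x, 15, tolerance = 0.1)
})

test_that("noiseless rod fields segment to planted centroids", {
  fld <- make_bacteria_field(cell_field_config(
    n_cells = 40L, noise_sigma = 0, seed = 4L))
  cells <- segment_cells(fld$phase, "rod")
  expect_equal(nrow(cells), 40L)
  m <- match_truth(cells, fld$truth)
  expect_true(all(abs(m$centroid_y -
                        fld$truth$cells$center_y[m$true_label]) <= 1))
  expect_true(all(abs(m$centroid_x -
                        fld$truth$cells$center_x[m$true_label]) <= 1))
  # labels are raster-ordered by centroid
  expect_equal(cells$label, order(order(round(cells$centroid_y),
                                        cells$centroid_x)))
})

test_that("per-cell intensity is background-subtracted exactly", {
  img <- matrix(0, 40, 40)
  img[10:14, 10:14] <- 1         # 25-px square cell
  cells <- segment_cells(volume_image(img), "round", min_area = 5,
                         max_area = 100)
  # uniform fluorescence equal to background -> all zeros
  flat <- matrix(37, 40, 40)
  c0 <- per_cell_intensity(cells, volume_image(flat))
  expect_equal(c0$mean_intensity, 0)
  # cell at background + 50 -> exactly 50
  fl <- matrix(100, 40, 40)
  fl[10:14, 10:14] <- 150
  c1 <- per_cell_intensity(cells, volume_image(fl))
  expect_equal(c1$mean_intensity, 50)
  expect_equal(attr(c1, "background"), 100)
  expect_error(per_cell_intensity(cells, volume_image(matrix(0, 10, 10))),
               "shapes differ")
  # noiseless planted field: values equal planted intensity exactly
  fld <- make_bacteria_field(cell_field_config(
    n_cells = 30L, noise_sigma = 0, positive_fraction = 0.5,
    intensity_positive = 500, intensity_negative = 50, seed = 6L))
  cc <- per_cell_intensity(segment_cells(fld$phase, "rod"), fld$pi)
  m <- match_truth(cc, fld$truth)
  expect_equal(sort(unique(m$mean_intensity)), c(50, 500))
  expect_true(all(m$mean_intensity[m$true_positive] == 500))
})

test_that("positivity rules classify exactly at their boundaries", {
  # planted bimodal 50/100: otsu on cells gives exactly half positive
  fld <- make_bacteria_field(cell_field_config(
    n_cells = 100L, noise_sigma = 0, positive_fraction = 0.5, seed = 2L))
  cc <- per_cell_intensity(segment_cells(fld$phase, "rod"), fld$pi)
  cc <- classify_positive(cc)
  expect_equal(mean(cc$positive), 0.5)
  m <- match_truth(cc, fld$truth)
  expect_equal(sum(m$positive != m$true_positive), 0L)

  # all cells at the same level: nothing is positive under otsu
  same <- cc
  same$mean_intensity <- rep(5, nrow(same))
  expect_equal(mean(classify_positive(same)$positive), 0)

  # k-sigma rule is strict: 31 > 30 is positive, 29 is not
  two <- cc[1:2, ]
  two$mean_intensity <- c(31, 29)
  two <- classify_positive(two, "background_k_sigma", k_sigma = 3,
                           background_sd = 10)
  expect_identical(two$positive, c(TRUE, FALSE))

  one <- cc[1, ]
  expect_error(classify_positive(one), "k_sigma|k-sigma")

  # fraction is invariant under relabeling
  shuf <- cc[sample(nrow(cc)), ]
  expect_equal(fraction_positive(shuf)$fraction_positive,
               fraction_positive(cc)$fraction_positive)
})

test_that("JC-1 ratios divide background-subtracted channels", {
  img <- matrix(0, 60, 60)
  img[10:20, 10:20] <- 1
  img[35:45, 35:45] <- 1
  seg_src <- volume_image(img * 400)
  cells <- segment_cells(seg_src, "round", min_area = 50, max_area = 500)
  expect_equal(nrow(cells), 2L)
  red <- volume_image(img * 300 + 10)
  green <- volume_image(img * 300 + 10)
  cc <- jc1_ratio(cells, red, green)
  expect_equal(cc$ratio, c(1, 1))
  red2 <- volume_image(img * 600 + 10)
  cc2 <- jc1_ratio(cells, red2, green)
  expect_equal(cc2$ratio, c(2, 2))
  # invariant to common positive rescaling of both channels
  s <- 3.7
  cc3 <- jc1_ratio(cells, volume_image(red2$data * s),
                   volume_image(green$data * s))
  expect_equal(cc3$ratio, cc2$ratio)
  # green floor excludes dim cells and warns when none remain
  dim_green <- volume_image(img * 0 + 10)
  expect_warning(cc4 <- jc1_ratio(cells, red2, dim_green), "excluded")
  expect_true(all(is.na(cc4$ratio)))
  expect_equal(attr(cc4, "n_excluded"), 2L)
})

test_that("replicate summaries and fold changes propagate error", {
  df <- tibble::tibble(
    condition = rep(c("A", "B"), each = 6),
    replicate = rep(rep(1:3, each = 2), 2),
    value = c(1, 3, 2, 4, 3, 5,   10, 12, 11, 13, 12, 14))
  s <- summarize_replicates(df, value, condition, replicate)
  expect_equal(s$grand_mean, c(3, 12))
  expect_equal(s$sem, c(sd(c(2, 3, 4)) / sqrt(3), sd(c(11, 12, 13)) / sqrt(3)))
  expect_equal(s$n_replicates, c(3L, 3L))
  expect_equal(s$n_cells_total, c(6L, 6L))

  fc <- fold_change(s, condition_a = "B", condition_b = "A")
  expect_equal(fc$fold, 4)
  expect_equal(fc$rel_error,
               sqrt((s$sem[2] / 12)^2 + (s$sem[1] / 3)^2))
  # reciprocal folds multiply to one
  fc_rev <- fold_change(s, condition_a = "A", condition_b = "B")
  expect_equal(fc$fold * fc_rev$fold, 1)
  # equal summaries give fold 1 with sqrt(2) x relative sem
  fc_same <- fold_change(s[1, ], s[1, ])
  expect_equal(fc_same$fold, 1)
  expect_equal(fc_same$rel_error, sqrt(2) * s$sem[1] / s$grand_mean[1])
  # the printed example: 0.66 over 0.06 is an 11-fold increase
  a <- tibble::tibble(grand_mean = 0.66, sem = 0)
  b <- tibble::tibble(grand_mean = 0.06, sem = 0)
  expect_equal(fold_change(a, b)$fold, 11)
  expect_error(fold_change(b, tibble::tibble(grand_mean = 0, sem = 0)),
               "not positive")
})
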