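make_vol <- function(arr, vs = 2.75) grayscale_volume(arr, voxel_size = vs)

test_that("histogram counts are exact and mask-restricted", {
  arr <- array(7L, dim = c(8, 8, 8))
  h <- compute_histogram(make_vol(arr))
  expect_identical(h$counts[8L], 512L)       # bin 8 holds intensity 7
  expect_identical(sum(h$counts), 512L)

  arr[1, , ] <- 200L
  v <- make_vol(arr)
  m <- binary_mask(array(rep(c(TRUE, FALSE), c(64, 448)), dim = c(8, 8, 8)),
                   "leaf")
  hr <- compute_histogram(v, m)
  expect_identical(sum(hr$counts), 64L)
  empty <- binary_mask(array(FALSE, dim = c(8, 8, 8)), "leaf")
  expect_error(compute_histogram(v, empty), "empty")
  small <- binary_mask(array(TRUE, dim = c(8, 8, 9)), "leaf")
  expect_error(compute_histogram(v, small), "shape")
})

test_that("IsoData threshold solves the symmetric two-delta case and is a fixed point", {
  h <- rep(0, 256); h[10 + 1] <- 100; h[200 + 1] <- 100
  expect_identical(isodata_threshold(h), 105L)

  set.seed(42)
  for (rep in 1:20) {
    counts <- random_bimodal_hist()
    t <- isodata_threshold(counts)
    v <- 0:255
    lo <- counts[1:(t + 1)]; hi <- counts[(t + 2):256]
    mu_lo <- sum(lo * v[1:(t + 1)]) / sum(lo)
    mu_hi <- sum(hi * v[(t + 2):256]) / sum(hi)
    expect_identical(t, as.integer(floor((mu_lo + mu_hi) / 2 + 0.5)))
  }
  expect_error(isodata_threshold(c(rep(0, 100), 5, rep(0, 155))), "degenerate")
})

test_that("both thresholds match independent oracles on 100+ random histograms", {
  set.seed(101)
  n_iso <- 0L; n_min <- 0L
  for (rep in 1:110) {
    counts <- random_bimodal_hist()
    expect_identical(isodata_threshold(counts), isodata_oracle(counts))
    n_iso <- n_iso + 1L
    t_min <- tryCatch(minimum_threshold(counts), error = function(e) NA_integer_)
    expect_identical(t_min, minimum_oracle(counts))
    if (!is.na(t_min)) n_min <- n_min + 1L
  }
  expect_gte(n_iso, 100L)
  expect_gte(n_min, 100L)
})

test_that("minimum threshold finds a constructed valley and sits between modes", {
  # V-shaped valley with unique minimum at bin 120, peaks at 50 and 200
  b <- 0:255
  h <- rep(0, 256)
  h[b >= 30 & b <= 50] <- 10 + (b[b >= 30 & b <= 50] - 30) * 4
  h[b > 50 & b <= 120] <- 90 - (b[b > 50 & b <= 120] - 50)
  h[b > 120 & b <= 200] <- 20 + (b[b > 120 & b <= 200] - 120)
  h[b > 200 & b <= 220] <- 100 - (b[b > 200 & b <= 220] - 200) * 5
  expect_identical(minimum_threshold(h), 120L)

  # two-intensity image: valley strictly between the two values
  arr <- array(40L, dim = c(10, 10, 10)); arr[, , 6:10] <- 190L
  t <- minimum_threshold(compute_histogram(make_vol(arr)))
  expect_gt(t, 40); expect_lt(t, 190)

  # translation equivariance: shifting all bin indices by +10 shifts t by 10
  h2 <- rep(0, 256)
  h2[41:231] <- h[31:221]
  expect_identical(minimum_threshold(h2), minimum_threshold(h) + 10L)

  expect_error(minimum_threshold(dnorm(0:255, 128, 30)), "not bimodal")
})

test_that("leaf mask recovers a disc phantom against the truth labels", {
  cfg <- quick_config(shape = c(50L, 90L, 90L), disc = TRUE)
  tr <- build_label_volume(cfg, seed = 3)
  img <- render_grayscale(tr, cfg, seed = 4)
  leaf <- make_leaf_mask(img)
  truth_leaf <- tr$labels != 0L
  mismatch <- xor(leaf$data, truth_leaf)
  # mismatches confined to the disc boundary shell (±1 voxel)
  expect_lt(sum(mismatch) / sum(truth_leaf), 0.05)
  inner <- array(leafspace:::.bin_erode_cpp(truth_leaf, dim(truth_leaf), 2),
                 dim(truth_leaf))
  expect_true(all(leaf$data[inner]))
})

test_that("leaf mask trivial and degenerate cases behave", {
  arr <- array(200L, dim = c(10, 12, 12)); arr[1:2, , ] <- 10L
  leaf <- make_leaf_mask(make_vol(arr), method = "fixed", fixed_t = 100)
  expect_true(all(leaf$data[3:10, , ]))
  dark <- array(5L, dim = c(8, 8, 8))
  expect_error(make_leaf_mask(make_vol(dark), method = "fixed", fixed_t = 100),
               "empty foreground")
})

test_that("noiseless phantom segments to the truth masks exactly", {
  cfg <- quick_config(shape = c(50L, 70L, 70L), noise_sd = 0)
  tr <- build_label_volume(cfg, seed = 8)
  img <- render_grayscale(tr, cfg, seed = 9)
  leaf <- make_leaf_mask(img)
  tissue <- segment_tissue(img, leaf)
  airspace <- extract_airspace(leaf, tissue)
  tm <- truth_masks(tr)
  expect_identical(leaf$data, tm$leaf$data)
  expect_identical(tissue$data, tm$tissue$data)
  expect_identical(airspace$data, tm$airspace$data)
})

test_that("fixed-threshold extremes give empty tissue or tissue == leaf", {
  cfg <- quick_config(shape = c(40L, 50L, 50L))
  tr <- build_label_volume(cfg, seed = 2)
  img <- render_grayscale(tr, cfg, seed = 3)
  leaf <- make_leaf_mask(img)
  t_hi <- segment_tissue(img, leaf, method = "fixed", fixed_t = 255)
  expect_identical(sum(t_hi$data), 0L)
  t_lo <- segment_tissue(img, leaf, method = "fixed", fixed_t = -1)
  expect_identical(t_lo$data, leaf$data)
})

test_that("airspace extraction is exact XOR and enforces subset preconditions", {
  d <- c(10, 10, 10)
  leaf <- binary_mask(array(TRUE, d), "leaf")
  tis_all <- binary_mask(array(TRUE, d), "tissue")
  expect_identical(sum(extract_airspace(leaf, tis_all)$data), 0L)
  tis_none <- binary_mask(array(FALSE, d), "tissue")
  expect_identical(extract_airspace(leaf, tis_none)$data, leaf$data)

  small_leaf <- binary_mask(array(c(FALSE, rep(TRUE, 999)), d), "leaf")
  expect_error(extract_airspace(small_leaf, tis_all), "subset")
})

test_that("mask algebra holds exactly on segmented volumes", {
  for (seed in 1:3) {
    cfg <- quick_config(shape = c(40L, 60L, 60L))
    tr <- build_label_volume(cfg, seed = seed)
    img <- render_grayscale(tr, cfg, seed = seed + 10)
    leaf <- make_leaf_mask(img)
    tissue <- segment_tissue(img, leaf)
    airspace <- extract_airspace(leaf, tissue)
    expect_false(any(tissue$data & airspace$data))
    expect_identical(tissue$data | airspace$data, leaf$data)
    expect_false(any(airspace$data & !leaf$data))
  }
})

test_that("voxel misclassification stays below 1% at noise_sd 15", {
  cfg <- quick_config(shape = c(50L, 80L, 80L), noise_sd = 15)
  tr <- build_label_volume(cfg, seed = 12)
  img <- render_grayscale(tr, cfg, seed = 13)
  leaf <- make_leaf_mask(img)
  tissue <- segment_tissue(img, leaf)
  truth_tissue <- tr$labels %in% c(1L, 2L, 3L)
  err <- mean(tissue$data != truth_tissue)
  expect_lt(err, 0.01)
})

test_that("IsoData and minimum porosities differ by under 2 pp on clean phantoms", {
  cfg <- quick_config(shape = c(50L, 80L, 80L), noise_sd = 10)
  tr <- build_label_volume(cfg, seed = 21)
  img <- render_grayscale(tr, cfg, seed = 22)
  leaf <- make_leaf_mask(img)
  p <- vapply(c("isodata", "minimum"), function(m) {
    tis <- segment_tissue(img, leaf, method = m)
    total_porosity(extract_airspace(leaf, tis), leaf)
  }, numeric(1))
  expect_lt(abs(p[1] - p[2]), 2)
})

test_that("crop_roi preserves content, composes, and keeps porosity stable", {
  cfg <- phantom_config(shape = c(60L, 80L, 80L),
                        target_profile = list(edge = 25, plateau = 25,
                                              rise_length_um = 1e-6),
                        stoma_sites = list(), noise_sd = 0)
  tr <- build_label_volume(cfg, seed = 2)
  tm <- truth_masks(tr)
  full <- list(z = c(1, 60), y = c(1, 80), x = c(1, 80))
  expect_identical(crop_roi(tm$leaf, full)$data, tm$leaf$data)

  b1 <- list(z = c(5, 50), y = c(10, 70), x = c(10, 70))
  b2 <- list(z = c(3, 40), y = c(1, 50), x = c(5, 60))
  once <- crop_roi(crop_roi(tm$leaf, b1), b2)
  inter <- list(z = c(b1$z[1] + b2$z[1] - 1, min(b1$z[2], b1$z[1] + b2$z[2] - 1)),
                y = c(b1$y[1] + b2$y[1] - 1, min(b1$y[2], b1$y[1] + b2$y[2] - 1)),
                x = c(b1$x[1] + b2$x[1] - 1, min(b1$x[2], b1$x[1] + b2$x[2] - 1)))
  expect_identical(once$data, crop_roi(tm$leaf, inter)$data)

  box <- list(z = c(1, 60), y = c(15, 66), x = c(15, 66))
  p_full <- total_porosity(tm$airspace, tm$leaf)
  p_crop <- total_porosity(crop_roi(tm$airspace, box), crop_roi(tm$leaf, box))
  expect_lt(abs(p_full - p_crop), 2)

  expect_error(crop_roi(tm$leaf, list(z = c(0, 60), y = c(1, 80), x = c(1, 80))),
               "out of range")
})
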