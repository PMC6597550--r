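test_that("slice porosity follows its definition and flags absent slices", {
  d <- c(4, 10, 25)                       # 250 voxels per slice
  leaf <- array(TRUE, d); leaf[4, , ] <- FALSE
  air <- array(FALSE, d)
  air[2, 1:10, 1:10] <- TRUE              # 100 of 250 -> 40%
  air[3, 1, 1:5] <- TRUE                  # 5 of 250 -> 2%
  p <- porosity_profile(binary_mask(air, "airspace"), binary_mask(leaf, "leaf"))
  expect_equal(p$porosity_pct, c(0, 40, 2, NA))
  expect_equal(p$leaf_voxels, c(250, 250, 250, 0))
  expect_true(all(diff(p$fractional_depth) > 0))
})

test_that("total porosity equals the leaf-weighted profile mean and the roi rules hold", {
  tr <- build_label_volume(quick_config(shape = c(50L, 60L, 60L)), seed = 4)
  tm <- truth_masks(tr)
  p <- porosity_profile(tm$airspace, tm$leaf)
  tot <- total_porosity(tm$airspace, tm$leaf)
  w <- sum(p$porosity_pct * p$leaf_voxels, na.rm = TRUE) /
       sum(p$leaf_voxels[!is.na(p$porosity_pct)])
  expect_equal(tot, w, tolerance = 1e-9)
  expect_equal(tot, tr$total_porosity, tolerance = 1e-12)

  expect_equal(total_porosity(tm$airspace, tm$leaf, slices = 25),
               p$porosity_pct[25])
  expect_equal(total_porosity(tm$leaf, tm$leaf), 100)
  expect_error(total_porosity(tm$airspace, tm$leaf, slices = integer(0)),
               "empty")
})

test_that("digital air sphere in tissue has surface area within 5% of 4 pi r^2", {
  m <- ball_masks(20)
  sa <- surface_area(m$tissue, m$air)
  expect_lt(abs(sa$total_um2 - 4 * pi * 20^2) / (4 * pi * 20^2), 0.05)
  # raw face counting overestimates a smooth sphere badly (~1.5x)
  expect_gt(sa$voxel_faces_um2 / (4 * pi * 20^2), 1.3)
})

test_that("surface area is additive over disjoint components and zero without airspace", {
  one <- ball_masks(8, n = 60, centre = c(15, 30, 30))
  two_air <- one$air$data
  ax <- seq_len(60)
  d2 <- outer(outer((ax - 45)^2, (ax - 30)^2, `+`), (ax - 30)^2, `+`)
  two_air <- two_air | (d2 <= 8^2)
  a1 <- surface_area(one$tissue, one$air)$total_um2
  a2 <- surface_area(binary_mask(!two_air, "tissue", voxel_size = 1),
                     binary_mask(two_air, "airspace", voxel_size = 1))$total_um2
  expect_equal(a2, 2 * a1, tolerance = 1e-6)

  none <- binary_mask(array(FALSE, c(10, 10, 10)), "airspace")
  all_t <- binary_mask(array(TRUE, c(10, 10, 10)), "tissue")
  expect_warning(sa0 <- surface_area(all_t, none), "empty")
  expect_equal(sa0$total_um2, 0)
})

test_that("per-volume and per-area normalisations are consistent", {
  m <- ball_masks(10, voxel_size = 2)
  sa <- surface_area(m$tissue, m$air)
  n <- dim(m$air$data)[1]
  expect_equal(sa$per_tissue_volume, sa$total_um2 / (sum(m$tissue$data) * 8),
               tolerance = 1e-12)
  expect_equal(sa$per_leaf_area, sa$total_um2 / (n * n * 4), tolerance = 1e-12)
})

test_that("connectivity 26 joins diagonal voxels that 6 separates", {
  arr <- array(FALSE, c(8, 8, 8))
  arr[3, 3, 3] <- TRUE; arr[4, 4, 4] <- TRUE
  m <- binary_mask(arr, "airspace", voxel_size = 1)
  expect_identical(nrow(label_components(m, connectivity = 26)), 1L)
  expect_identical(nrow(label_components(m, connectivity = 6)), 2L)
  cc <- label_components(m, connectivity = 6)
  expect_identical(sum(cc$voxels), 2L)
})

test_that("component table accounts for every foreground voxel", {
  tr <- build_label_volume(sparse_config(), seed = 6)
  tm <- truth_masks(tr)
  cc <- label_components(tm$airspace)
  expect_identical(sum(cc$voxels), sum(tm$airspace$data))
  expect_true(all(cc$volume_um3 > 0))
})

test_that("cavity detection recovers the phantom cavities exactly", {
  cfg <- sparse_config(n_stomata = 5L)
  tr <- build_label_volume(cfg, seed = 3)
  tm <- truth_masks(tr)
  cav <- detect_cavities(tm$airspace, tm$leaf, cfg$epidermis_thickness,
                         min_volume_um3 = 9000, surface = "abaxial")
  expect_identical(nrow(cav), 5L)
  # filter monotonicity and the degenerate infinite threshold
  n_by_thresh <- vapply(c(0, 5000, 9000, 2e4, Inf), function(v) {
    nrow(detect_cavities(tm$airspace, tm$leaf, cfg$epidermis_thickness,
                         min_volume_um3 = v, surface = "abaxial"))
  }, integer(1))
  expect_true(all(diff(n_by_thresh) <= 0))
  expect_identical(n_by_thresh[length(n_by_thresh)], 0L)
  expect_error(detect_cavities(tm$airspace, tm$leaf, 1e5, surface = "abaxial"),
               "outside")
})

test_that("stoma matching recovers presence/absence fractions exactly", {
  cfg <- sparse_config(n_stomata = 5L)
  tr <- build_label_volume(cfg, seed = 3)
  tm <- truth_masks(tr)
  cav <- detect_cavities(tm$airspace, tm$leaf, cfg$epidermis_thickness,
                         min_volume_um3 = 9000, surface = "abaxial")
  sites <- tr$stoma_sites[tr$stoma_sites$surface == "abaxial", ]
  m_all <- match_cavities_to_stomata(cav, sites)
  expect_equal(attr(m_all, "fraction_subtended"), 1.0)

  cfg2 <- sparse_config(n_stomata = 5L, cavity_fraction = 0.6)
  tr2 <- build_label_volume(cfg2, seed = 3)
  tm2 <- truth_masks(tr2)
  cav2 <- detect_cavities(tm2$airspace, tm2$leaf, cfg2$epidermis_thickness,
                          min_volume_um3 = 9000, surface = "abaxial")
  sites2 <- tr2$stoma_sites[tr2$stoma_sites$surface == "abaxial", ]
  m2 <- match_cavities_to_stomata(cav2, sites2)
  expect_equal(attr(m2, "fraction_subtended"), 0.6)
  expect_identical(sum(m2$has_cavity),
                   sum(tr2$stoma_sites$has_cavity))

  # zero radius matches only on exact centroid coincidence; laterally
  # offset sites therefore match nothing
  sites_off <- sites
  sites_off$y_um <- sites_off$y_um + 1.3
  m0 <- match_cavities_to_stomata(cav, sites_off, radius_um = 0)
  expect_equal(attr(m0, "fraction_subtended"), 0)
  expect_error(match_cavities_to_stomata(cav, sites, radius_um = -1),
               "non-negative")
})

test_that("spongy slice selection takes the band argmax with the low-index tie rule", {
  p <- data.frame(slice_index = 1:4,
                  depth_um = (1:4 - 0.5) * 2.75,
                  fractional_depth = ((1:4) - 0.5) / 4,
                  porosity_pct = c(5, 10, 30, 20),
                  leaf_voxels = rep(100L, 4))
  class(p) <- c("porosity_profile", "data.frame")
  expect_identical(select_spongy_slice(p), 3L)
  p$porosity_pct <- c(10, 30, 30, 5)
  expect_identical(select_spongy_slice(p), 2L)
  expect_error(select_spongy_slice(p, band = c(2, 3)), "no slices")
})

test_that("layer-slice selection lands in the correct truth band of a eudicot phantom", {
  cfg <- phantom_config(shape = c(80L, 90L, 90L), mode = "eudicot",
                        target_profile = list(edge = 4, rise_length_um = 30),
                        palisade_plateau = 12, spongy_plateau = 32,
                        band_boundary_frac = 0.45,
                        stoma_sites = list(), noise_sd = 0)
  tr <- build_label_volume(cfg, seed = 7)
  tm <- truth_masks(tr)
  p <- porosity_profile(tm$airspace, tm$leaf)
  nm <- tr$meso_z[2] - tr$meso_z[1] + 1
  boundary_slice <- tr$meso_z[1] + 0.45 * nm
  spongy <- select_spongy_slice(p, band = c(0.4, 1))
  expect_gt(spongy, boundary_slice)
  pal_band <- c((tr$meso_z[1] - 0.5) / 80, (boundary_slice - 0.5) / 80)
  pal <- select_palisade_slice(p, pal_band)
  expect_gte(pal, tr$meso_z[1]); expect_lte(pal, ceiling(boundary_slice))
  expect_lt(p$porosity_pct[pal], p$porosity_pct[spongy])
})

test_that("palisade slice honours the fractional position rule", {
  p <- data.frame(slice_index = 1:10,
                  depth_um = (1:10 - 0.5) * 2.75,
                  fractional_depth = ((1:10) - 0.5) / 10,
                  porosity_pct = rep(10, 10),
                  leaf_voxels = rep(500L, 10))
  class(p) <- c("porosity_profile", "data.frame")
  expect_identical(select_palisade_slice(p, band = c(0, 1), fraction = 0.5), 5L)
  expect_identical(select_palisade_slice(p, band = c(0, 1), fraction = 0), 1L)
  expect_identical(select_palisade_slice(p, band = c(0, 1), fraction = 1), 10L)
})

test_that("flipping the depth axis reverses the profile, preserving totals and area", {
  tr <- build_label_volume(quick_config(shape = c(40L, 60L, 60L)), seed = 5)
  tm <- truth_masks(tr)
  flip <- function(m) binary_mask(m$data[rev(seq_len(dim(m$data)[1])), , ],
                                  m$role, m$voxel_size)
  fl <- lapply(tm, flip)
  p1 <- porosity_profile(tm$airspace, tm$leaf)
  p2 <- porosity_profile(fl$airspace, fl$leaf)
  expect_equal(p2$porosity_pct, rev(p1$porosity_pct))
  expect_equal(total_porosity(fl$airspace, fl$leaf),
               total_porosity(tm$airspace, tm$leaf))
  # the tetrahedral decomposition has a slight orientational anisotropy,
  # so mesh area is reflection-invariant only to ~0.1%
  expect_equal(surface_area(fl$tissue, fl$airspace)$total_um2,
               surface_area(tm$tissue, tm$airspace)$total_um2,
               tolerance = 1e-3)
})

test_that("voxel size scales areas as k^2 and volumes as k^3, porosity unchanged", {
  m1 <- ball_masks(9, voxel_size = 1)
  m2 <- ball_masks(9, voxel_size = 3)
  sa1 <- surface_area(m1$tissue, m1$air)
  sa2 <- surface_area(m2$tissue, m2$air)
  expect_equal(sa2$total_um2, 9 * sa1$total_um2, tolerance = 1e-12)
  cc1 <- label_components(m1$air)
  cc2 <- label_components(m2$air)
  expect_equal(cc2$volume_um3, 27 * cc1$volume_um3, tolerance = 1e-12)
  expect_equal(total_porosity(m2$air, binary_mask(array(TRUE, dim(m2$air$data)),
                                                  "leaf", 3)),
               total_porosity(m1$air, binary_mask(array(TRUE, dim(m1$air$data)),
                                                  "leaf", 1)))
})

test_that("surface-area error shrinks as resolution doubles", {
  rel_err <- vapply(c(8, 16, 10, 20), function(r) {
    m <- ball_masks(r)
    abs(surface_area(m$tissue, m$air)$total_um2 - 4 * pi * r^2) / (4 * pi * r^2)
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1])   # halving voxel size, r 8 -> 16
  expect_lt(rel_err[4], rel_err[3])   # halving voxel size, r 10 -> 20
})
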