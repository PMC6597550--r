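#' Porosity depth profile
#'
#' Per-slice mesophyll porosity along leaf depth, from the adaxial (slice 1)
#' to the abaxial surface. Porosity of a slice is
#' `100 * airspace voxels / leaf voxels`; slices without leaf voxels are
#' reported as `NA` (absent), not zero.
#'
#' @param airspace `"airspace"` [binary_mask()].
#' @param leaf `"leaf"` [binary_mask()].
#' @return Data frame of class `porosity_profile`: `slice_index`,
#'   `depth_um` (slice centre from the adaxial surface), `fractional_depth`
#'   in `[0, 1]`, `porosity_pct`, `leaf_voxels`.
#' @export
porosity_profile <- function(airspace, leaf) {
  stopifnot(inherits(airspace, "binary_mask"), inherits(leaf, "binary_mask"))
  .check_same_shape(airspace, leaf)
  if (!any(leaf$data)) stop("leaf mask is empty")
  if (any(airspace$data & !leaf$data))
    stop("airspace mask is not a subset of the leaf mask")
  nz <- dim(leaf$data)[1]
  lv <- .slice_counts(leaf$data)
  av <- .slice_counts(airspace$data)
  out <- data.frame(slice_index = seq_len(nz),
                    depth_um = (seq_len(nz) - 0.5) * leaf$voxel_size,
                    fractional_depth = (seq_len(nz) - 0.5) / nz,
                    porosity_pct = ifelse(lv > 0, 100 * av / lv, NA_real_),
                    leaf_voxels = lv)
  class(out) <- c("porosity_profile", "data.frame")
  out
}

#' Total mesophyll porosity
#'
#' `100 * airspace voxels / leaf voxels` over an optional band of slices.
#' Equal by identity to the leaf-voxel-weighted mean of the slice profile.
#'
#' @inheritParams porosity_profile
#' @param slices optional integer vector of slice indices to restrict to.
#' @return Porosity in percent.
#' @export
total_porosity <- function(airspace, leaf, slices = NULL) {
  stopifnot(inherits(airspace, "binary_mask"), inherits(leaf, "binary_mask"))
  .check_same_shape(airspace, leaf)
  nz <- dim(leaf$data)[1]
  if (is.null(slices)) slices <- seq_len(nz)
  slices <- as.integer(slices)
  if (length(slices) == 0L || any(slices < 1L) || any(slices > nz))
    stop("empty or out-of-range slice band")
  lv <- sum(.slice_counts(leaf$data)[slices])
  av <- sum(.slice_counts(airspace$data)[slices])
  if (lv == 0) stop("no leaf voxels in the requested band")
  100 * av / lv
}

#' Exposed mesophyll surface area
#'
#' Area of the tissue-airspace interface, estimated from a triangulated
#' iso-surface: the binary airspace mask is smoothed with a 3x3x3 box mean
#' and the 0.5 iso-surface is triangulated by marching tetrahedra with
#' linear edge interpolation (a marching-cubes-style mesh estimator; raw
#' voxel-face counting overestimates smooth interfaces by up to ~50% and is
#' reported only as a diagnostic). Mesh cells containing no tissue voxel
#' are excluded, so airspace interfaces with the background do not count.
#'
#' @param tissue `"tissue"` [binary_mask()].
#' @param airspace `"airspace"` [binary_mask()].
#' @param voxel_size voxel edge in micrometres; defaults to the mask's.
#' @return List of class `surface_area_result`: `total_um2`,
#'   `per_tissue_volume` (um^2 per um^3 of tissue), `per_leaf_area`
#'   (um^2 per um^2 of projected leaf area, dimensionless),
#'   `voxel_faces_um2` (raw face-count diagnostic), `n_triangles`,
#'   `estimator`.
#' @export
surface_area <- function(tissue, airspace, voxel_size = tissue$voxel_size) {
  stopifnot(inherits(tissue, "binary_mask"), inherits(airspace, "binary_mask"))
  .check_same_shape(tissue, airspace)
  if (any(tissue$data & airspace$data))
    stop("tissue and airspace masks overlap")
  d <- dim(tissue$data)
  res <- .surface_area_mt_cpp(as.logical(airspace$data), as.logical(tissue$data),
                              d, TRUE)
  if (res$area_voxel_units == 0)
    warning("empty tissue-airspace interface; surface area is zero")
  total <- res$area_voxel_units * voxel_size^2
  tis_vol <- sum(tissue$data) * voxel_size^3
  leaf_proj <- sum(apply(tissue$data | airspace$data, c(2, 3), any)) * voxel_size^2
  structure(list(total_um2 = total,
                 per_tissue_volume = if (tis_vol > 0) total / tis_vol else 0,
                 per_leaf_area = if (leaf_proj > 0) total / leaf_proj else 0,
                 voxel_faces_um2 = res$voxel_faces * voxel_size^2,
                 n_triangles = res$n_triangles,
                 estimator = "box3-smoothed marching tetrahedra"),
            class = "surface_area_result")
}

#' Label connected components of a mask
#'
#' Maximal connected components under 6- or 26-connectivity with exact
#' voxel counts and centroids; the particle-analysis substrate for cavity
#' detection.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6 or 26 (default 26: airspace is a thin connected
#'   network and diagonal contacts matter).
#' @param voxel_size voxel edge in micrometres.
#' @return Data frame of class `cavity_set`: `id`, `voxels`, `volume_um3`,
#'   centroid coordinates in micrometres, and depth extrema per component.
#' @export
label_components <- function(mask, connectivity = 26L,
                             voxel_size = mask$voxel_size) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  lab <- .cc_label_cpp(as.logical(mask$data), d, as.integer(connectivity))
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    out <- data.frame(id = integer(), voxels = integer(), volume_um3 = numeric(),
                      centroid_depth_um = numeric(), centroid_y_um = numeric(),
                      centroid_x_um = numeric(), min_slice = integer(),
                      max_slice = integer())
    class(out) <- c("cavity_set", "data.frame")
    return(out)
  }
  nz <- d[1]; ny <- d[2]
  z <- ((idx - 1L) %% nz) + 1L
  y <- (((idx - 1L) %/% nz) %% ny) + 1L
  x <- ((idx - 1L) %/% (nz * ny)) + 1L
  g <- lab[idx]
  agg <- rowsum(cbind(n = 1, z = z, y = y, x = x), g)
  ids <- as.integer(rownames(agg))
  n <- agg[, "n"]
  out <- data.frame(id = ids,
                    voxels = as.integer(n),
                    volume_um3 = n * voxel_size^3,
                    centroid_depth_um = (agg[, "z"] / n - 0.5) * voxel_size,
                    centroid_y_um = (agg[, "y"] / n - 0.5) * voxel_size,
                    centroid_x_um = (agg[, "x"] / n - 0.5) * voxel_size,
                    min_slice = as.integer(tapply(z, g, min)),
                    max_slice = as.integer(tapply(z, g, max)))
  rownames(out) <- NULL
  out <- out[order(out$id), , drop = FALSE]
  class(out) <- c("cavity_set", "data.frame")
  attr(out, "connectivity") <- as.integer(connectivity)
  out
}

#' Detect sub-stomatal cavities
#'
#' Sub-stomatal cavities are large airspace components that reach the
#' sub-epidermal band of the chosen leaf surface. A component counts as a
#' cavity when (i) at least one of its voxels lies within
#' `[epidermis_depth_um, epidermis_depth_um + band_width_um]` of that
#' surface and (ii) its volume is at least `min_volume_um3`. The default
#' minimum volume (8000 um^3, a sphere of radius ~12.4 um) separates
#' cavities from interstitial channels at 2.75 um voxels.
#'
#' @param airspace `"airspace"` [binary_mask()].
#' @param leaf `"leaf"` [binary_mask()].
#' @param epidermis_depth_um epidermis thickness of the chosen surface.
#' @param min_volume_um3 minimum cavity volume.
#' @param surface `"adaxial"` or `"abaxial"`.
#' @param band_width_um width of the sub-epidermal search band.
#' @param connectivity component connectivity (default 26).
#' @return A `cavity_set` data frame (see [label_components()]) restricted
#'   to cavities, with a `touches_subepidermal` column.
#' @export
detect_cavities <- function(airspace, leaf, epidermis_depth_um,
                            min_volume_um3 = 8000, surface = c("abaxial", "adaxial"),
                            band_width_um = 15, connectivity = 26L) {
  surface <- match.arg(surface)
  stopifnot(inherits(airspace, "binary_mask"), inherits(leaf, "binary_mask"))
  .check_same_shape(airspace, leaf)
  vs <- airspace$voxel_size
  nz <- dim(leaf$data)[1]
  lv <- .slice_counts(leaf$data)
  present <- which(lv > 0)
  if (length(present) == 0L) stop("leaf mask is empty")
  z_top <- min(present); z_bot <- max(present)
  # slice band measured from the relevant leaf surface
  if (surface == "adaxial") {
    zlo <- z_top + epidermis_depth_um / vs
    zhi <- z_top + (epidermis_depth_um + band_width_um) / vs
  } else {
    zhi <- z_bot - epidermis_depth_um / vs
    zlo <- z_bot - (epidermis_depth_um + band_width_um) / vs
  }
  if (zhi < 1 || zlo > nz) stop("sub-epidermal band lies outside the volume")
  comps <- label_components(airspace, connectivity = connectivity, voxel_size = vs)
  if (nrow(comps) == 0L) return(comps)
  touches <- comps$max_slice >= zlo & comps$min_slice <= zhi
  comps$touches_subepidermal <- touches
  out <- comps[touches & comps$volume_um3 >= min_volume_um3, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cavity_set", "data.frame")
  out
}

#' Match cavities to stomatal sites
#'
#' A stoma is subtended by a cavity when some cavity centroid lies within
#' `radius_um` of it laterally (in the leaf plane); each cavity is consumed
#' by its nearest stoma only. The default radius (30 um) is on the order of
#' one stomatal complex length.
#'
#' @param cavities a `cavity_set` (from [detect_cavities()]).
#' @param stoma_sites data frame with columns `stoma_id`, `y_um`, `x_um`
#'   (e.g. the `stoma_sites` table of a phantom truth).
#' @param radius_um lateral matching radius in micrometres.
#' @return Data frame with one row per stoma (`stoma_id`, `has_cavity`,
#'   `cavity_id`, `distance_um`) and attribute `fraction_subtended`.
#' @export
match_cavities_to_stomata <- function(cavities, stoma_sites, radius_um = 30) {
  if (radius_um < 0) stop("radius_um must be non-negative")
  stopifnot(is.data.frame(stoma_sites), all(c("stoma_id", "y_um", "x_um") %in%
                                            names(stoma_sites)))
  n_st <- nrow(stoma_sites)
  res <- data.frame(stoma_id = stoma_sites$stoma_id,
                    has_cavity = logical(n_st),
                    cavity_id = NA_integer_,
                    distance_um = NA_real_)
  if (nrow(cavities) > 0L && n_st > 0L) {
    for (i in seq_len(nrow(cavities))) {
      dy <- stoma_sites$y_um - cavities$centroid_y_um[i]
      dx <- stoma_sites$x_um - cavities$centroid_x_um[i]
      dist <- sqrt(dy^2 + dx^2)
      j <- which.min(dist)
      if (dist[j] <= radius_um) {
        if (!res$has_cavity[j] || dist[j] < res$distance_um[j]) {
          res$has_cavity[j] <- TRUE
          res$cavity_id[j] <- cavities$id[i]
          res$distance_um[j] <- dist[j]
        }
      }
    }
  }
  attr(res, "fraction_subtended") <- if (n_st > 0) mean(res$has_cavity) else NA_real_
  res
}

#' Select the representative spongy mesophyll slice
#'
#' The slice with the maximum porosity within a fractional-depth band
#' (lowest index on ties); depth profiles consistently show a pronounced
#' porosity peak in the spongy mesophyll, which this selects.
#'
#' @param profile a [porosity_profile()].
#' @param band length-2 fractional-depth interval searched (default the
#'   abaxial half of the leaf).
#' @return Slice index.
#' @export
select_spongy_slice <- function(profile, band = c(0, 1)) {
  stopifnot(inherits(profile, "porosity_profile"))
  in_band <- profile$fractional_depth >= band[1] &
             profile$fractional_depth <= band[2] &
             profile$leaf_voxels > 0 & !is.na(profile$porosity_pct)
  if (!any(in_band)) stop("no slices in the requested band")
  cand <- profile[in_band, ]
  cand$slice_index[which.max(cand$porosity_pct)]
}

#' Select a representative palisade slice
#'
#' Automated surrogate for visual selection: the slice at a configured
#' fractional position within the palisade band, restricted to slices that
#' are entirely within the masked leaf (leaf voxel count closest to the
#' band median).
#'
#' @param profile a [porosity_profile()].
#' @param band length-2 fractional-depth interval of the palisade band.
#' @param fraction fractional position within the band (default 0.5).
#' @return Slice index.
#' @export
select_palisade_slice <- function(profile, band, fraction = 0.5) {
  stopifnot(inherits(profile, "porosity_profile"))
  in_band <- profile$fractional_depth >= band[1] &
             profile$fractional_depth <= band[2] & profile$leaf_voxels > 0
  if (!any(in_band)) stop("no slices in the requested band")
  cand <- profile[in_band, ]
  n <- nrow(cand)
  pos <- max(1L, ceiling(fraction * n))
  med <- median(cand$leaf_voxels)
  full <- which(abs(cand$leaf_voxels - med) == min(abs(cand$leaf_voxels - med)))
  pick <- full[which.min(abs(full - pos))]
  cand$slice_index[pick]
}
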