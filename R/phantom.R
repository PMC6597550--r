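#' Configuration for a synthetic leaf phantom
#'
#' Defines a seeded synthetic leaf volume with known airspace structure.
#' The phantom is a full-width tissue slab (optionally masked to a
#' cylindrical leaf disc) bounded by an airspace-free epidermis on each
#' surface. Intercellular airspace is carved as spherical pockets whose
#' per-slice amount follows a parametric porosity-versus-depth curve:
#' porosity rises from `edge_porosity` at each epidermis to a mid-leaf
#' plateau over `rise_length_um`, matching the depth profiles seen in real
#' leaves. In `eudicot` mode the mesophyll is split into an adaxial
#' palisade band and an abaxial spongy band with separate plateau
#' porosities. A roughly hemispherical sub-stomatal cavity is carved
#' beneath each stomatal site unless suppressed.
#'
#' @param shape integer vector `(depth, y, x)` in voxels.
#' @param voxel_size isotropic voxel edge, micrometres (default 2.75).
#' @param epidermis_thickness epidermis thickness per surface, micrometres.
#' @param target_profile list with `edge` and `plateau` porosities (%) and
#'   `rise_length_um`; in eudicot mode `plateau` is ignored in favour of
#'   `palisade_plateau` / `spongy_plateau`.
#' @param mode `"monocot"` (single mesophyll plateau) or `"eudicot"`
#'   (palisade/spongy bands).
#' @param palisade_plateau,spongy_plateau plateau porosities (%) for the two
#'   eudicot bands.
#' @param band_boundary_frac fractional mesophyll depth of the
#'   palisade/spongy boundary (eudicot mode).
#' @param stoma_sites per-surface stomatal sites: a list with elements
#'   `adaxial` and/or `abaxial`, each either a count (sites laid out on a
#'   regular grid) or a 2-column matrix of `(y, x)` voxel coordinates.
#' @param cavity_radius sub-stomatal cavity radius, micrometres.
#' @param cavity_fraction fraction of stomatal sites that receive a cavity
#'   (the first `round(fraction * n)` sites in order); emulates arrested
#'   stomatal precursors that lack a cavity.
#' @param pocket_radius_um length-2 `(min, max)` air-pocket radius range,
#'   micrometres.
#' @param tissue_mean,air_mean rendered class mean intensities in `[0, 255]`
#'   (air and background dark, tissue bright).
#' @param noise_sd Gaussian intensity noise standard deviation (default 10
#'   on the 8-bit range: classes stay separable while thresholding is
#'   genuinely exercised).
#' @param disc if `TRUE`, restrict the slab to a cylindrical leaf disc so
#'   that leaf-mask creation against a background is exercised.
#' @param disc_radius_frac disc radius as a fraction of the smaller lateral
#'   half-extent.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(120L, 200L, 200L),
                           voxel_size = 2.75,
                           epidermis_thickness = 22,
                           target_profile = list(edge = 5, plateau = 25,
                                                 rise_length_um = 55),
                           mode = c("monocot", "eudicot"),
                           palisade_plateau = 15,
                           spongy_plateau = 35,
                           band_boundary_frac = 0.45,
                           stoma_sites = list(abaxial = 4L),
                           cavity_radius = 16.5,
                           cavity_fraction = 1,
                           pocket_radius_um = c(5.5, 16.5),
                           tissue_mean = 180,
                           air_mean = 30,
                           noise_sd = 10,
                           disc = FALSE,
                           disc_radius_frac = 0.46) {
  mode <- match.arg(mode)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) stop("shape must be 3 extents >= 8")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  tp <- target_profile
  if (is.null(tp$edge) || is.null(tp$rise_length_um))
    stop("target_profile needs edge and rise_length_um")
  if (mode == "monocot" && is.null(tp$plateau))
    stop("target_profile needs plateau in monocot mode")
  plateaus <- if (mode == "monocot") tp$plateau else c(palisade_plateau, spongy_plateau)
  if (any(c(tp$edge, plateaus) < 0) || any(c(tp$edge, plateaus) > 100))
    stop("porosities must lie in [0, 100]")
  if (any(plateaus < tp$edge)) stop("plateau porosity must be >= edge porosity")
  if (2 * epidermis_thickness >= shape[1] * voxel_size)
    stop("epidermis layers thicker than the leaf")
  if (any(c(tissue_mean, air_mean) < 0) || any(c(tissue_mean, air_mean) > 255))
    stop("intensities must lie in [0, 255]")
  if (cavity_radius <= 0) stop("cavity_radius must be positive")
  if (length(pocket_radius_um) != 2L || any(pocket_radius_um <= 0) ||
      pocket_radius_um[1] > pocket_radius_um[2])
    stop("pocket_radius_um must be an increasing positive (min, max) pair")
  if (cavity_fraction < 0 || cavity_fraction > 1)
    stop("cavity_fraction must lie in [0, 1]")
  max_achievable <- 90
  if (max(plateaus) > max_achievable)
    stop(sprintf(
      "requested plateau porosity %.1f%% unreachable with spherical pockets; achievable maximum ~%.0f%%",
      max(plateaus), max_achievable))
  structure(list(shape = shape, voxel_size = voxel_size,
                 epidermis_thickness = epidermis_thickness,
                 target_profile = tp, mode = mode,
                 palisade_plateau = palisade_plateau,
                 spongy_plateau = spongy_plateau,
                 band_boundary_frac = band_boundary_frac,
                 stoma_sites = stoma_sites,
                 cavity_radius = cavity_radius,
                 cavity_fraction = cavity_fraction,
                 pocket_radius_um = pocket_radius_um,
                 tissue_mean = tissue_mean, air_mean = air_mean,
                 noise_sd = noise_sd, disc = disc,
                 disc_radius_frac = disc_radius_frac),
            class = "phantom_config")
}

# Label codes used throughout the phantom module.
PHANTOM_LABELS <- c(background = 0L, adaxial_epidermis = 1L,
                    abaxial_epidermis = 2L, tissue = 3L, airspace = 4L)

# Target porosity (%) for every slice; 0 in the epidermis bands.
.phantom_target_profile <- function(config) {
  nz <- config$shape[1]
  vs <- config$voxel_size
  e <- max(1L, round(config$epidermis_thickness / vs))
  z0 <- e + 1L                # first mesophyll slice
  z1 <- nz - e                # last mesophyll slice
  tp <- config$target_profile
  target <- numeric(nz)
  nmeso <- z1 - z0 + 1L
  for (z in z0:z1) {
    d_ad <- (z - z0 + 0.5) * vs
    d_ab <- (z1 - z + 0.5) * vs
    frac <- (z - z0 + 0.5) / nmeso
    plateau <- if (config$mode == "monocot") tp$plateau
               else if (frac < config$band_boundary_frac) config$palisade_plateau
               else config$spongy_plateau
    ramp <- min(1, min(d_ad, d_ab) / tp$rise_length_um)
    target[z] <- tp$edge + (plateau - tp$edge) * ramp
  }
  list(target_pct = target, meso_z = c(z0, z1), epidermis_slices = e)
}

# Deterministic stomatal site layout: a regular grid inside the lateral
# margins, spacing validated against the 2 x cavity-radius exclusion rule.
.phantom_sites <- function(config) {
  vs <- config$voxel_size
  rc_vox <- config$cavity_radius / vs
  min_sep <- 2 * rc_vox
  out <- list()
  for (surf in c("adaxial", "abaxial")) {
    spec <- config$stoma_sites[[surf]]
    if (is.null(spec)) next
    if (is.matrix(spec)) {
      sites <- spec
      if (nrow(sites) > 1L) {
        dd <- as.matrix(stats::dist(sites))
        diag(dd) <- Inf
        if (min(dd) < min_sep)
          stop("stoma sites closer than 2 x cavity_radius on the ", surf, " surface")
      }
    } else {
      n <- as.integer(spec)
      if (n == 0L) next
      ny <- config$shape[2]; nx <- config$shape[3]
      m <- ceiling(sqrt(n))
      margin <- ceiling(rc_vox) + 2
      ys <- round(seq(margin, ny - margin, length.out = m))
      xs <- round(seq(margin, nx - margin, length.out = m))
      grid <- as.matrix(expand.grid(y = ys, x = xs))
      if (m > 1L && min(diff(ys)) < min_sep)
        stop("too many stoma sites for the lateral extent at this cavity_radius")
      sites <- grid[seq_len(n), , drop = FALSE]
    }
    out[[surf]] <- sites
  }
  out
}

#' Build a phantom label volume with exact ground truth
#'
#' Carves sub-stomatal cavities and then stamps spherical air pockets into
#' the mesophyll until the realized airspace fraction of every slice is
#' within 0.2 percentage points of the configured depth profile (or the
#' slice is saturated). Pocket centres are drawn at the slice with the
#' largest remaining porosity deficit, so the realized profile tracks the
#' target closely by construction. All ground-truth fields are obtained by
#' exhaustive voxel counting over the generated labels.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; identical `(config, seed)` pairs give
#'   bit-identical volumes.
#' @return An object of class `phantom_truth`: `labels` (integer array,
#'   codes 0 background / 1 adaxial epidermis / 2 abaxial epidermis /
#'   3 tissue / 4 airspace), `slice_porosity` (% per slice, `NA` where a
#'   slice holds no leaf voxels), `total_porosity` (%), `surface_area`
#'   (tissue-airspace interface, um^2, computed with the same estimator as
#'   [surface_area()] and therefore estimator-dependent), `cavities`
#'   (data frame: id, stoma id, centroid um, volume um^3), `stoma_sites`
#'   (data frame per surface), `meso_z` (first/last mesophyll slice), and
#'   the generating `config` and `seed`.
#' @export
build_label_volume <- function(config, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  nz <- config$shape[1]; ny <- config$shape[2]; nx <- config$shape[3]
  vs <- config$voxel_size
  prof <- .phantom_target_profile(config)
  z0 <- prof$meso_z[1]; z1 <- prof$meso_z[2]

  labels <- array(PHANTOM_LABELS[["tissue"]], dim = c(nz, ny, nx))
  labels[seq_len(z0 - 1L), , ] <- PHANTOM_LABELS[["adaxial_epidermis"]]
  labels[(z1 + 1L):nz, , ] <- PHANTOM_LABELS[["abaxial_epidermis"]]

  rim_shell <- NULL
  if (isTRUE(config$disc)) {
    cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
    r <- config$disc_radius_frac * min(ny, nx)
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    d2 <- (yy - cy)^2 + (xx - cx)^2
    in_disc <- d2 <= r^2
    # keep a 2-voxel tissue shell at the rim airspace-free so the leaf
    # boundary stays watertight
    rim_shell <- in_disc & d2 > (r - 2)^2
    for (z in seq_len(nz)) {
      sl <- labels[z, , ]
      sl[!in_disc] <- PHANTOM_LABELS[["background"]]
      labels[z, , ] <- sl
    }
  }
  .protect <- function(labels) {
    if (is.null(rim_shell)) return(labels)
    for (z in seq_len(nz)) {
      sl <- labels[z, , ]
      sl[rim_shell & sl == PHANTOM_LABELS[["tissue"]]] <- 5L
      labels[z, , ] <- sl
    }
    labels
  }
  .unprotect <- function(labels) {
    labels[labels == 5L] <- PHANTOM_LABELS[["tissue"]]
    labels
  }
  labels <- .protect(labels)

  set.seed(as.integer(seed))

  # --- sub-stomatal cavities -------------------------------------------------
  sites <- .phantom_sites(config)
  rc <- config$cavity_radius / vs
  cavities <- list()
  site_rows <- list()
  cav_id <- 0L
  stoma_id <- 0L
  for (surf in names(sites)) {
    sm <- sites[[surf]]
    n <- nrow(sm)
    n_cav <- round(config$cavity_fraction * n)
    for (k in seq_len(n)) {
      stoma_id <- stoma_id + 1L
      has_cav <- k <= n_cav
      cy <- sm[k, 1]; cx <- sm[k, 2]
      vol_vox <- 0L
      ctr <- c(NA_real_, NA_real_, NA_real_)
      if (has_cav) {
        cav_id <- cav_id + 1L
        czc <- if (surf == "adaxial") z0 else z1   # cavity apex at the epidermis
        ri <- floor(rc)
        zs <- max(z0, czc - ri):min(z1, czc + ri)
        acc <- c(0, 0, 0)
        for (z in zs) {
          dz <- z - czc
          rr <- rc^2 - dz^2
          if (rr <= 0) next
          ys <- max(1L, floor(cy - sqrt(rr))):min(ny, ceiling(cy + sqrt(rr)))
          xs <- max(1L, floor(cx - sqrt(rr))):min(nx, ceiling(cx + sqrt(rr)))
          for (y in ys) for (x in xs) {
            if ((y - cy)^2 + (x - cx)^2 <= rr &&
                labels[z, y, x] == PHANTOM_LABELS[["tissue"]]) {
              labels[z, y, x] <- PHANTOM_LABELS[["airspace"]]
              vol_vox <- vol_vox + 1L
              acc <- acc + c(z, y, x)
            }
          }
        }
        if (vol_vox > 0L) ctr <- acc / vol_vox
        cavities[[cav_id]] <- data.frame(
          cavity_id = cav_id, stoma_id = stoma_id, surface = surf,
          centroid_depth_um = (ctr[1] - 0.5) * vs,
          centroid_y_um = (ctr[2] - 0.5) * vs,
          centroid_x_um = (ctr[3] - 0.5) * vs,
          volume_um3 = vol_vox * vs^3)
      }
      site_rows[[stoma_id]] <- data.frame(
        stoma_id = stoma_id, surface = surf,
        y_vox = cy, x_vox = cx,
        y_um = (cy - 0.5) * vs, x_um = (cx - 0.5) * vs,
        has_cavity = has_cav && vol_vox > 0L)
    }
  }
  stoma_df <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(stoma_id = integer(), surface = character(), y_vox = numeric(),
               x_vox = numeric(), y_um = numeric(), x_um = numeric(),
               has_cavity = logical())
  cav_df <- if (length(cavities)) do.call(rbind, cavities) else
    data.frame(cavity_id = integer(), stoma_id = integer(), surface = character(),
               centroid_depth_um = numeric(), centroid_y_um = numeric(),
               centroid_x_um = numeric(), volume_um3 = numeric())

  # --- air pockets shaped by the target profile ------------------------------
  leaf_per_slice <- .slice_counts(labels != PHANTOM_LABELS[["background"]])
  target_air <- prof$target_pct / 100 * leaf_per_slice
  tol <- pmax(1, 0.002 * leaf_per_slice)
  rmin <- max(1.5, config$pocket_radius_um[1] / vs)
  rmax <- max(rmin, config$pocket_radius_um[2] / vs)
  res <- .stamp_pockets_cpp(as.integer(labels), dim(labels), target_air,
                            z0 - 1L, z1 - 1L, rmin, rmax, 1L, max(tol),
                            500000L)
  labels <- .unprotect(array(res$labels, dim = c(nz, ny, nx)))

  # --- exhaustive ground truth -----------------------------------------------
  leaf_per_slice <- .slice_counts(labels != PHANTOM_LABELS[["background"]])
  air_per_slice <- .slice_counts(labels == PHANTOM_LABELS[["airspace"]])
  slice_por <- ifelse(leaf_per_slice > 0, 100 * air_per_slice / leaf_per_slice, NA)
  total_por <- 100 * sum(air_per_slice) / sum(leaf_per_slice)

  tissue_mask <- binary_mask(labels == PHANTOM_LABELS[["tissue"]] |
                             labels == PHANTOM_LABELS[["adaxial_epidermis"]] |
                             labels == PHANTOM_LABELS[["abaxial_epidermis"]],
                             role = "tissue", voxel_size = vs)
  air_mask <- binary_mask(labels == PHANTOM_LABELS[["airspace"]],
                          role = "airspace", voxel_size = vs)
  sa <- if (any(air_mask$data)) surface_area(tissue_mask, air_mask)$total_um2 else 0

  structure(list(labels = labels, voxel_size = vs,
                 slice_porosity = slice_por,
                 total_porosity = total_por,
                 surface_area_um2 = sa,
                 cavities = cav_df, stoma_sites = stoma_df,
                 meso_z = c(z0, z1),
                 target_pct = prof$target_pct,
                 config = config, seed = as.integer(seed)),
            class = "phantom_truth")
}

# Foreground voxel count per depth slice (fast: slice axis is fastest).
.slice_counts <- function(mask3d) {
  nz <- dim(mask3d)[1]
  rowSums(matrix(mask3d, nrow = nz))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s, total porosity %.2f%%, %d cavities, %d stoma sites\n",
              paste(dim(x$labels), collapse = " x "), x$total_porosity,
              nrow(x$cavities), nrow(x$stoma_sites)))
  invisible(x)
}

#' Render a phantom as a noisy grayscale scan
#'
#' Each voxel takes its class mean intensity (tissue bright, airspace and
#' background dark) plus zero-mean Gaussian noise, clipped to `[0, 255]`
#' and quantized to integers.
#'
#' @param truth a [build_label_volume()] result.
#' @param config the generating [phantom_config()]; defaults to the one
#'   stored in `truth`.
#' @param seed integer seed for the noise field.
#' @return A [grayscale_volume()].
#' @export
render_grayscale <- function(truth, config = truth$config, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (config$tissue_mean <= config$air_mean)
    stop("tissue must be brighter than air (tissue_mean > air_mean)")
  if (abs(config$tissue_mean - config$air_mean) <= 4 * config$noise_sd)
    stop("tissue and air intensity classes are unseparable at this noise level")
  lab <- truth$labels
  img <- array(config$air_mean, dim = dim(lab))
  img[lab == PHANTOM_LABELS[["tissue"]] |
      lab == PHANTOM_LABELS[["adaxial_epidermis"]] |
      lab == PHANTOM_LABELS[["abaxial_epidermis"]]] <- config$tissue_mean
  if (config$noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + rnorm(length(img), 0, config$noise_sd)
  }
  img <- round(pmin(255, pmax(0, img)))
  grayscale_volume(array(as.integer(img), dim = dim(lab)),
                   voxel_size = truth$voxel_size)
}

#' Write phantom truth and rendering to disk
#'
#' Writes the grayscale volume and the label volume as multi-page 8-bit
#' TIFF stacks, the truth tables as CSV, and the configuration as a plain
#' `key = value` text file.
#'
#' @param truth [build_label_volume()] result.
#' @param volume [render_grayscale()] result.
#' @param directory output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_phantom <- function(truth, volume, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- c(volume = file.path(directory, "volume.tif"),
             labels = file.path(directory, "labels.tif"),
             profile = file.path(directory, "truth_slice_porosity.csv"),
             cavities = file.path(directory, "truth_cavities.csv"),
             stomata = file.path(directory, "truth_stoma_sites.csv"),
             summary = file.path(directory, "truth_summary.csv"),
             config = file.path(directory, "phantom_config.txt"))
  write_volume_tiff(volume, paths[["volume"]])
  write_volume_tiff(truth$labels, paths[["labels"]])
  nz <- dim(truth$labels)[1]
  write.csv(data.frame(slice = seq_len(nz),
                       depth_um = (seq_len(nz) - 0.5) * truth$voxel_size,
                       porosity_pct = truth$slice_porosity),
            paths[["profile"]], row.names = FALSE)
  write.csv(truth$cavities, paths[["cavities"]], row.names = FALSE)
  write.csv(truth$stoma_sites, paths[["stomata"]], row.names = FALSE)
  write.csv(data.frame(total_porosity_pct = truth$total_porosity,
                       surface_area_um2 = truth$surface_area_um2,
                       n_cavities = nrow(truth$cavities),
                       n_stoma_sites = nrow(truth$stoma_sites),
                       seed = truth$seed),
            paths[["summary"]], row.names = FALSE)
  write_config_file(.phantom_config_kv(truth$config), paths[["config"]])
  invisible(paths)
}

.phantom_config_kv <- function(config) {
  tp <- config$target_profile
  list(shape = paste(config$shape, collapse = ","),
       voxel_size = config$voxel_size,
       epidermis_thickness = config$epidermis_thickness,
       edge_porosity = tp$edge,
       plateau_porosity = if (is.null(tp$plateau)) NA else tp$plateau,
       rise_length_um = tp$rise_length_um,
       mode = config$mode,
       cavity_radius = config$cavity_radius,
       cavity_fraction = config$cavity_fraction,
       pocket_radius_min_um = config$pocket_radius_um[1],
       pocket_radius_max_um = config$pocket_radius_um[2],
       tissue_mean = config$tissue_mean,
       air_mean = config$air_mean,
       noise_sd = config$noise_sd,
       disc = config$disc)
}
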