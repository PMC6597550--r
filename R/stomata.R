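#' Physical constants for the anatomical conductance model
#'
#' Diffusivity of water vapour in air and molar volume of air, both at
#' 22 degrees C (and 101.325 kPa for the molar volume). `pi_value` defaults
#' to machine precision pi; set it to 3.142 to replicate arithmetic done
#' with the rounded constant.
#'
#' @param d diffusivity of water vapour in air, m^2 s^-1.
#' @param v molar volume of air, m^3 mol^-1.
#' @param pi_value value used for pi in the pore-geometry term.
#' @return List of class `physical_constants`.
#' @export
physical_constants <- function(d = 2.49e-5, v = 2.424e-2, pi_value = pi) {
  if (d <= 0 || v <= 0 || pi_value <= 0) stop("constants must be positive")
  structure(list(d = d, v = v, pi_value = pi_value),
            class = "physical_constants")
}

#' Stomatal traits for one leaf surface
#'
#' @param surface `"adaxial"` or `"abaxial"`.
#' @param D stomatal density, mm^-2.
#' @param a_max mean maximum stomatal pore area, um^2.
#' @param l stomatal pore depth, um (taken equal to guard cell width at the
#'   middle of the stoma).
#' @return List of class `stomatal_traits`.
#' @export
stomatal_traits <- function(surface = c("abaxial", "adaxial"), D, a_max, l) {
  surface <- match.arg(surface)
  if (any(c(D, a_max, l) < 0)) stop("traits must be non-negative")
  if (D > 0 && l <= 0) stop("pore depth must be positive when stomata are present")
  structure(list(surface = surface, D = D, a_max = a_max, l = l),
            class = "stomatal_traits")
}

#' Anatomical maximum stomatal conductance for one surface
#'
#' Computes `g_smax = d * D * a_max / (v * (l + (pi/2) * sqrt(a_max / pi)))`
#' with all quantities first converted to SI units (D from mm^-2 to m^-2,
#' a_max from um^2 to m^2, l from um to m). The result is linear in density,
#' increasing in pore area and decreasing in pore depth.
#'
#' @param traits a [stomatal_traits()] object, or a density in mm^-2 when
#'   `a_max` and `l` are given directly.
#' @param constants a [physical_constants()] object.
#' @param a_max,l traits given directly (um^2, um) when `traits` is numeric.
#' @return Conductance in mol m^-2 s^-1.
#' @export
anatomical_gsmax <- function(traits, constants = physical_constants(),
                             a_max = NULL, l = NULL) {
  if (inherits(traits, "stomatal_traits")) {
    D <- traits$D; a_max <- traits$a_max; l <- traits$l
  } else {
    D <- traits
    if (is.null(a_max) || is.null(l)) stop("a_max and l required")
  }
  if (D < 0 || a_max < 0 || l < 0) stop("traits must be non-negative")
  if (D == 0) return(0)
  if (a_max == 0) stop("undefined pore geometry: positive density with zero pore area")
  p <- constants$pi_value
  D_m <- D * 1e6          # mm^-2 -> m^-2
  a_m <- a_max * 1e-12    # um^2  -> m^2
  l_m <- l * 1e-6         # um    -> m
  constants$d * D_m * a_m / (constants$v * (l_m + (p / 2) * sqrt(a_m / p)))
}

#' Total anatomical g_smax over both leaf surfaces
#'
#' Per-surface values are computed independently and summed.
#'
#' @param adaxial,abaxial [stomatal_traits()] for the two surfaces.
#' @param constants a [physical_constants()] object.
#' @return Conductance in mol m^-2 s^-1.
#' @export
total_gsmax <- function(adaxial, abaxial, constants = physical_constants()) {
  anatomical_gsmax(adaxial, constants) + anatomical_gsmax(abaxial, constants)
}

#' Stomatal density from field counts
#'
#' Per-surface density is the mean over counting fields of count / field
#' area (the counting protocol uses several fields on either side of a
#' major vein, repeated on both surfaces); total density is the sum of the
#' two per-surface densities.
#'
#' @param fields data frame with columns `surface`, `count`,
#'   `field_area_mm2`.
#' @return List with per-surface densities (mm^-2) and `total`.
#' @export
stomatal_density <- function(fields) {
  stopifnot(is.data.frame(fields),
            all(c("surface", "count", "field_area_mm2") %in% names(fields)))
  if (nrow(fields) == 0L) stop("empty field list")
  if (any(fields$field_area_mm2 <= 0)) stop("field areas must be positive")
  per <- tapply(fields$count / fields$field_area_mm2, fields$surface, mean)
  out <- as.list(per)
  out$total <- sum(per)
  out
}

#' Instantaneous water-use efficiency
#'
#' `iWUE = A400 / gs`: net CO2 assimilation at 400 ppm reference CO2
#' divided by stomatal conductance to water vapour.
#'
#' @param A400 net assimilation rate, umol m^-2 s^-1.
#' @param gs stomatal conductance, mol m^-2 s^-1; must be positive.
#' @return iWUE in umol CO2 per mol H2O. Vectorized.
#' @export
iwue <- function(A400, gs) {
  if (any(gs <= 0)) stop("gs must be positive to compute iWUE")
  A400 / gs
}

#' Aggregate leaf-level trait tables to line-level g_smax
#'
#' Follows the convention that stomatal density is taken per individual
#' leaf while pore area and pore depth enter as line means: for every leaf,
#' per-surface g_smax is computed from that leaf's `D` and the line-mean
#' `a_max` and `l` of the matching surface, surfaces are summed, and line
#' values are the means over leaves.
#'
#' @param traits data frame with columns `line`, `leaf`, `surface`, `D`,
#'   `a_max`, `l` (units as in [stomatal_traits()]).
#' @param constants a [physical_constants()] object.
#' @return List with `per_leaf` (line, leaf, gsmax_total) and `per_line`
#'   (line, gsmax_mean, n_leaves) data frames.
#' @export
aggregate_line_gsmax <- function(traits, constants = physical_constants()) {
  stopifnot(is.data.frame(traits),
            all(c("line", "leaf", "surface", "D", "a_max", "l") %in% names(traits)))
  key <- interaction(traits$line, traits$surface, drop = TRUE)
  a_bar <- tapply(traits$a_max, key, mean)
  l_bar <- tapply(traits$l, key, mean)
  g_surf <- mapply(function(D, k) {
    anatomical_gsmax(D, constants, a_max = a_bar[[k]], l = l_bar[[k]])
  }, traits$D, as.character(key))
  leaf_key <- interaction(traits$line, traits$leaf, drop = TRUE)
  g_leaf <- tapply(g_surf, leaf_key, sum)
  line_of <- tapply(as.character(traits$line), leaf_key, `[`, 1L)
  per_leaf <- data.frame(line = unname(line_of),
                         leaf = sub("^.*\\.", "", names(g_leaf)),
                         gsmax_total = unname(g_leaf))
  g_line <- tapply(per_leaf$gsmax_total, per_leaf$line, mean)
  per_line <- data.frame(line = names(g_line),
                         gsmax_mean = unname(g_line),
                         n_leaves = as.integer(table(per_leaf$line)[names(g_line)]))
  list(per_leaf = per_leaf, per_line = per_line)
}
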