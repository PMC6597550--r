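#' Intensity histogram of a volume
#'
#' Exact voxel counts in 256 bins over the 8-bit range, optionally
#' restricted to a mask. Both automatic threshold algorithms operate on
#' this histogram.
#'
#' @param volume a [grayscale_volume()].
#' @param restrict optional [binary_mask()] of the same shape; only voxels
#'   inside the mask are counted.
#' @return Object of class `intensity_histogram` with `counts` (integer,
#'   length 256; element `i` counts intensity `i - 1`).
#' @export
compute_histogram <- function(volume, restrict = NULL) {
  stopifnot(inherits(volume, "grayscale_volume"))
  vals <- volume$data
  if (!is.null(restrict)) {
    stopifnot(inherits(restrict, "binary_mask"))
    .check_same_shape(volume, restrict)
    vals <- vals[restrict$data]
    if (length(vals) == 0L) stop("restriction mask is empty")
  }
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  structure(list(counts = counts), class = "intensity_histogram")
}

.as_histogram <- function(h) {
  if (inherits(h, "intensity_histogram")) return(h)
  if (is.numeric(h) && length(h) == 256L)
    return(structure(list(counts = h), class = "intensity_histogram"))
  stop("need an intensity_histogram or a length-256 count vector")
}

# round-half-up (R's round() is round-half-even)
.round_half_up <- function(x) floor(x + 0.5)

#' IsoData (Ridler-Calvard) automatic threshold
#'
#' Returns the smallest intensity `t` that is a fixed point of the
#' Ridler-Calvard map `t <- round((mean below t + mean above t) / 2)`,
#' where the mean below averages bins `<= t` and the mean above averages
#' bins `> t` (round half up). Voxels with intensity strictly above the
#' threshold are foreground (tissue). A fixed point is located by an
#' exhaustive scan over the 255 candidate thresholds, which makes the
#' smallest-fixed-point tie rule exact by construction; the classical
#' iteration from the histogram-mass midpoint converges to the same value
#' on bimodal histograms.
#'
#' @param h an `intensity_histogram` (or length-256 count vector).
#' @return Integer threshold in `[0, 254]`.
#' @export
isodata_threshold <- function(h) {
  h <- .as_histogram(h)
  counts <- as.numeric(h$counts)
  if (sum(counts > 0) < 2L) stop("degenerate histogram: fewer than two occupied bins")
  v <- 0:255
  csum <- cumsum(counts)
  cwsum <- cumsum(counts * v)
  total <- csum[256]; wtotal <- cwsum[256]
  for (t in 0:254) {
    n_lo <- csum[t + 1L]
    n_hi <- total - n_lo
    if (n_lo == 0 || n_hi == 0) next
    mu_lo <- cwsum[t + 1L] / n_lo
    mu_hi <- (wtotal - cwsum[t + 1L]) / n_hi
    if (t == .round_half_up((mu_lo + mu_hi) / 2)) return(as.integer(t))
  }
  stop("IsoData iteration failed to reach a fixed point")  # unreachable guard
}

# one pass of 3-point moving-average smoothing with mirrored ends
.smooth3 <- function(x) {
  n <- length(x)
  left <- c(x[2], x[seq_len(n - 1)])
  right <- c(x[2:n], x[n - 1])
  (left + x + right) / 3
}

# indices (first bin of each plateau) of local maxima, plateaus counted once
.local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in seq_len(k)) {
    lower_left <- i == 1L || r$values[i - 1] < r$values[i]
    lower_right <- i == k || r$values[i + 1] < r$values[i]
    if (lower_left && lower_right && r$values[i] > 0) out <- c(out, starts[i])
  }
  out
}

#' Minimum-algorithm automatic threshold
#'
#' Repeatedly smooths the histogram with an unweighted 3-point moving
#' average (mirrored ends) until exactly two local maxima survive, then
#' returns the bin of minimum smoothed count strictly between them (lowest
#' index on ties). Voxels strictly above the threshold are foreground.
#'
#' @param h an `intensity_histogram` (or length-256 count vector).
#' @param max_iter smoothing iteration cap (default 10000).
#' @return Integer threshold.
#' @export
minimum_threshold <- function(h, max_iter = 10000L) {
  h <- .as_histogram(h)
  s <- as.numeric(h$counts)
  if (sum(s > 0) < 2L) stop("degenerate histogram: fewer than two occupied bins")
  for (it in seq_len(max_iter)) {
    mx <- .local_maxima(s)
    if (length(mx) == 2L) {
      lo <- mx[1]; hi <- mx[2]
      if (hi - lo < 2L) stop("histogram not bimodal")
      between <- (lo + 1L):(hi - 1L)
      t_bin <- between[which.min(s[between])]
      return(as.integer(t_bin - 1L))
    }
    if (length(mx) < 2L) stop("histogram not bimodal")
    s <- .smooth3(s)
  }
  stop("histogram not bimodal")
}

.threshold_for <- function(h, method, fixed_t = NULL) {
  method <- match.arg(method, c("isodata", "minimum", "fixed"))
  if (method == "fixed") {
    if (is.null(fixed_t)) stop("fixed threshold requested but fixed_t missing")
    return(as.integer(fixed_t))
  }
  if (method == "isodata") isodata_threshold(h) else minimum_threshold(h)
}

#' Create a leaf mask separating the leaf from the background
#'
#' Thresholds the whole volume, then closes the foreground morphologically
#' (ball radius 2 voxels by default), fills internal holes slice by slice,
#' and keeps the largest 26-connected component. The result contains both
#' tissue and enclosed airspace, i.e. the whole leaf.
#'
#' @param volume a [grayscale_volume()].
#' @param method `"isodata"`, `"minimum"` or `"fixed"`.
#' @param fixed_t fixed threshold when `method = "fixed"`.
#' @param close_radius closing ball radius in voxels.
#' @param invert set `TRUE` for data with opposite contrast (tissue dark).
#' @return A [binary_mask()] with role `"leaf"`.
#' @export
make_leaf_mask <- function(volume, method = "isodata", fixed_t = NULL,
                           close_radius = 2, invert = FALSE) {
  stopifnot(inherits(volume, "grayscale_volume"))
  h <- compute_histogram(volume)
  t <- .threshold_for(h, method, fixed_t)
  fg <- if (invert) volume$data < t else volume$data > t
  if (!any(fg)) stop("empty foreground: no voxels above threshold")
  d <- dim(volume$data)
  fg <- as.logical(fg)
  if (close_radius > 0) {
    fg <- .bin_dilate_cpp(fg, d, close_radius)
    fg <- .bin_erode_cpp(fg, d, close_radius)
  }
  fg <- .fill_holes_slices_cpp(fg, d)
  lab <- .cc_label_cpp(fg, d, 26L)
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  binary_mask(array(lab == keep, dim = d), role = "leaf",
              voxel_size = volume$voxel_size)
}

#' Segment plant tissue inside the leaf mask
#'
#' Computes the threshold on the histogram restricted to the leaf mask and
#' returns the leaf voxels above it.
#'
#' @inheritParams make_leaf_mask
#' @param leaf_mask a `"leaf"` [binary_mask()].
#' @return A [binary_mask()] with role `"tissue"`, a subset of the leaf.
#' @export
segment_tissue <- function(volume, leaf_mask, method = "isodata",
                           fixed_t = NULL, invert = FALSE) {
  stopifnot(inherits(volume, "grayscale_volume"),
            inherits(leaf_mask, "binary_mask"))
  .check_same_shape(volume, leaf_mask)
  t <- if (identical(method, "fixed") && !is.null(fixed_t)) as.integer(fixed_t)
       else .threshold_for(compute_histogram(volume, leaf_mask), method, fixed_t)
  tis <- if (invert) volume$data < t else volume$data > t
  binary_mask(leaf_mask$data & tis, role = "tissue",
              voxel_size = volume$voxel_size)
}

#' Extract the airspace mask as leaf XOR tissue
#'
#' The pore space is everything inside the leaf that is not plant
#' material. The three-mask algebra holds exactly afterwards:
#' `tissue & airspace` is empty and `tissue | airspace` equals the leaf.
#'
#' @param leaf `"leaf"` [binary_mask()].
#' @param tissue `"tissue"` [binary_mask()]; must be a subset of the leaf.
#' @return A [binary_mask()] with role `"airspace"`.
#' @export
extract_airspace <- function(leaf, tissue) {
  stopifnot(inherits(leaf, "binary_mask"), inherits(tissue, "binary_mask"))
  .check_same_shape(leaf, tissue)
  if (any(tissue$data & !leaf$data))
    stop("tissue mask is not a subset of the leaf mask")
  binary_mask(xor(leaf$data, tissue$data), role = "airspace",
              voxel_size = leaf$voxel_size)
}
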