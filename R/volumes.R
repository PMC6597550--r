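#' Grayscale microCT volume
#'
#' Wraps a 3D integer array of 8-bit intensities together with its physical
#' voxel size. The array layout is `dim = c(depth, y, x)` with slice 1 at
#' the adaxial leaf surface.
#'
#' @param data 3D numeric array with values in `[0, 255]`.
#' @param voxel_size isotropic voxel edge length in micrometres
#'   (default 2.75, the scan resolution the pipeline is designed around).
#' @return An object of class `grayscale_volume` with elements `data`
#'   (integer array) and `voxel_size`.
#' @export
grayscale_volume <- function(data, voxel_size = 2.75) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) < 8L)) stop("all three extents must be at least 8 voxels")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number")
  rng <- range(data)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]")
  storage.mode(data) <- "integer"
  structure(list(data = data, voxel_size = voxel_size),
            class = "grayscale_volume")
}

#' Binary voxel mask with a role tag
#'
#' @param data 3D logical array, same layout as [grayscale_volume()].
#' @param role one of `"leaf"`, `"tissue"`, `"airspace"`.
#' @param voxel_size voxel edge length in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, role = c("leaf", "tissue", "airspace"),
                        voxel_size = 2.75) {
  role <- match.arg(role)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (!is.logical(data)) {
    data <- array(as.logical(data), dim = dim(data))
  }
  if (anyNA(data)) stop("mask must not contain NA")
  structure(list(data = data, role = role, voxel_size = voxel_size),
            class = "binary_mask")
}

#' @export
print.grayscale_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("grayscale_volume: %d x %d x %d voxels (depth x y x x), %.3g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("binary_mask [%s]: %d x %d x %d voxels, %d foreground\n",
              x$role, d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volume/mask shapes do not match")
  invisible(TRUE)
}

#' Crop a volume or mask to a box
#'
#' Mirrors the manual cropping step used to remove damaged leaf-disc edges
#' before thresholding. The box is given in 1-based inclusive voxel
#' coordinates; contents inside the box are preserved bit-exactly.
#'
#' @param x a `grayscale_volume` or `binary_mask`.
#' @param box list with elements `z`, `y`, `x`, each a length-2 inclusive
#'   range; ranges must lie within the extents of `x`.
#' @return Object of the same class as `x`, cropped.
#' @export
crop_roi <- function(x, box) {
  if (!inherits(x, c("grayscale_volume", "binary_mask")))
    stop("x must be a grayscale_volume or binary_mask")
  d <- dim(x$data)
  for (ax in c("z", "y", "x")) {
    r <- box[[ax]]
    if (is.null(r) || length(r) != 2L) stop("box must have z, y, x ranges")
  }
  rz <- as.integer(box$z); ry <- as.integer(box$y); rx <- as.integer(box$x)
  if (rz[1] < 1L || rz[2] > d[1] || ry[1] < 1L || ry[2] > d[2] ||
      rx[1] < 1L || rx[2] > d[3] || rz[1] > rz[2] || ry[1] > ry[2] ||
      rx[1] > rx[2])
    stop("crop box out of range")
  x$data <- x$data[rz[1]:rz[2], ry[1]:ry[2], rx[1]:rx[2], drop = FALSE]
  x
}

#' Read a multi-page TIFF stack as a grayscale volume
#'
#' Pages are depth slices (page 1 = adaxial surface); each page is a
#' `y` by `x` 8-bit image.
#'
#' @param path TIFF file path.
#' @param voxel_size voxel edge length in micrometres.
#' @return A [grayscale_volume()].
#' @export
read_volume_tiff <- function(path, voxel_size = 2.75) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0L, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- as.integer(pages[[i]])
  grayscale_volume(arr, voxel_size = voxel_size)
}

#' Write a volume or mask as a multi-page 8-bit TIFF stack
#'
#' Masks are written with foreground = 255, background = 0. Re-reading with
#' [read_volume_tiff()] reproduces the voxel data bit-exactly.
#'
#' @param x `grayscale_volume`, `binary_mask`, or a 3D integer array in
#'   `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(x, path) {
  arr <- if (inherits(x, "grayscale_volume")) x$data
         else if (inherits(x, "binary_mask")) array(ifelse(x$data, 255L, 0L), dim(x$data))
         else x
  if (length(dim(arr)) != 3L) stop("need a 3D array")
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 255)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8L), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF at ", path, ": ", attr(ok, "condition")$message)
  invisible(path)
}
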