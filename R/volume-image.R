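#' Default voxel dimensions
#'
#' Voxel size used throughout the package when none is supplied:
#' 0.329 um z-spacing (the lattice-SIM z-stack interval) and a 0.063 um
#' lateral pixel pitch typical of a reconstructed SIM image. All three are
#' overridable everywhere a voxel size is accepted.
#'
#' @return Numeric vector `c(z, y, x)` in micrometres.
#' @export
default_voxel_size <- function() {
  c(z = 0.329, y = 0.063, x = 0.063)
}

#' Construct a VolumeImage
#'
#' A `volume_image` is one channel of a 3D (or 2D, promoted to z-extent 1)
#' intensity grid together with its physical voxel dimensions. The axis
#' convention is ZYX with 1-based R indexing; channels are always separate
#' `volume_image` objects, never interleaved.
#'
#' @param data Numeric matrix (y, x) or 3D array (z, y, x) of intensities.
#' @param voxel_size Numeric `(z, y, x)` voxel edge lengths in um, all > 0.
#' @return An object of class `volume_image` with fields `data` and
#'   `voxel_size`.
#' @export
volume_image <- function(data, voxel_size = default_voxel_size()) {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1L, dim(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 2D matrix or 3D array (z, y, x)", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be three strictly positive lengths (z, y, x)",
         call. = FALSE)
  }
  names(voxel_size) <- c("z", "y", "x")
  structure(list(data = data, voxel_size = voxel_size),
            class = "volume_image")
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels (z,y,x), voxel %.3f x %.3f x %.3f um\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
as.array.volume_image <- function(x, ...) x$data

#' Physical volume of one voxel
#' @param x A `volume_image` or `binary_mask3d`.
#' @return Voxel volume in um^3.
#' @export
voxel_volume <- function(x) prod(x$voxel_size)

#' Construct a BinaryMask3D
#'
#' Segmentation mask sharing the geometry of its source [volume_image()].
#'
#' @param data Logical 3D array (z, y, x); a matrix is promoted to z = 1.
#' @param voxel_size Voxel `(z, y, x)` edge lengths in um.
#' @return An object of class `binary_mask3d`.
#' @export
binary_mask3d <- function(data, voxel_size = default_voxel_size()) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("mask `data` must be a 2D matrix or 3D array", call. = FALSE)
  }
  storage.mode(data) <- "logical"
  vi <- volume_image(array(0, dim(data)), voxel_size)
  structure(list(data = data, voxel_size = vi$voxel_size),
            class = "binary_mask3d")
}

#' @export
dim.binary_mask3d <- function(x) dim(x$data)

#' @export
print.binary_mask3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask3d> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(unname(a$voxel_size), unname(b$voxel_size)))
}
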