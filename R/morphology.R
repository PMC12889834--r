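# Low-level 3D image numerics: separable Gaussian filtering, grayscale
# morphology with an anisotropy-aware ball element, Otsu thresholding on the
# full 3D histogram, and connected-component labeling on the voxel grid.
# These operate on plain arrays; the user-facing wrappers live in contact3d.R.

# Convolution matrix for one axis with replicate (clamp-to-edge) boundary.
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (k in -r:r) {
    j <- pmin(pmax(seq_len(n) + k, 1L), n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + kernel[k + r + 1L]
  }
  K
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  w / sum(w)
}

# Apply a 1D convolution along one axis of a 3D array via a band-matrix
# product (arrays here are small enough that the dense product is fastest).
filter_axis <- function(arr, axis, kernel) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  K <- conv_band_matrix(d[axis], kernel)
  out <- K %*% m
  a <- array(out, dim = d[perm])
  aperm(a, order(perm))
}

#' Separable anisotropic Gaussian blur of a 3D array
#'
#' @param arr 3D numeric array (z, y, x).
#' @param sigma_vox Per-axis standard deviations in voxels `(z, y, x)`;
#'   an axis with sigma 0 is left untouched.
#' @return Blurred array, same shape.
#' @keywords internal
gaussian_blur3d <- function(arr, sigma_vox) {
  stopifnot(length(sigma_vox) == 3L, all(sigma_vox >= 0))
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0 && dim(arr)[axis] > 1L) {
      arr <- filter_axis(arr, axis, gaussian_kernel(sigma_vox[axis]))
    }
  }
  arr
}

# Integer voxel offsets inside an ellipsoid of physical radius `radius_um`.
ball_offsets <- function(radius_um, voxel_size) {
  rmax <- pmax(0L, as.integer(floor(radius_um / voxel_size)))
  g <- expand.grid(dz = -rmax[1]:rmax[1], dy = -rmax[2]:rmax[2],
                   dx = -rmax[3]:rmax[3])
  keep <- (g$dz * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 +
    (g$dx * voxel_size[3])^2 <= radius_um^2 + 1e-12
  as.matrix(g[keep, , drop = FALSE])
}

# Grayscale erosion/dilation over an explicit offset set (compiled kernel;
# out-of-volume neighbours act as +Inf when eroding, -Inf when dilating).
morph_gray <- function(arr, offsets, erode) {
  out <- morph_gray_cpp(as.numeric(arr), dim(arr),
                        matrix(as.integer(offsets), ncol = 3), erode)
  array(out, dim(arr))
}

#' White top-hat background subtraction with a ball structuring element
#'
#' Subtracts the grayscale opening (erosion then dilation) computed with an
#' ellipsoidal element whose physical radius is `radius_um` on every axis,
#' converted to voxel offsets per axis so anisotropic stacks are handled
#' correctly. Removes any background structure wider than the element while
#' preserving objects smaller than it.
#'
#' @param arr 3D numeric array.
#' @param radius_um Element radius in um; 0 skips the operation.
#' @param voxel_size Voxel `(z, y, x)` sizes in um.
#' @return Non-negative array of the same shape.
#' @keywords internal
white_tophat3d <- function(arr, radius_um, voxel_size) {
  if (radius_um <= 0) return(arr)
  off <- ball_offsets(radius_um, voxel_size)
  eroded <- morph_gray(arr, off, erode = TRUE)
  opened <- morph_gray(eroded, off, erode = FALSE)
  pmax(arr - opened, 0)
}

# Binary dilation with an arbitrary offset set (used by tests/properties).
dilate_mask <- function(mask, offsets) {
  out <- morph_gray(mask * 1, offsets, erode = FALSE)
  array(is.finite(out) & out > 0, dim(mask))
}

#' Otsu threshold on a full intensity histogram
#'
#' Classic between-class variance maximization on `nbins` equal-width bins
#' spanning the observed intensity range. Works on arrays of any rank (the
#' histogram is over all voxels).
#'
#' @param x Numeric vector or array of intensities.
#' @param nbins Number of histogram bins (default 256).
#' @return The threshold intensity (upper edge of the optimal bin), or `NA`
#'   when the histogram is degenerate (all values equal).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b[-nbins])
  edges[k + 1L]
}

#' Label 6-connected components of a 3D mask
#'
#' Builds the voxel-adjacency graph of foreground voxels and labels its
#' connected components (6-connectivity). Labels are 1..n in order of each
#' component's smallest linear index.
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components3d <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  vox_id <- integer(prod(d))
  vox_id[idx] <- seq_along(idx)
  edges <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  coords <- arrayInd(idx, d)
  for (axis in 1:3) {
    ok <- coords[, axis] < d[axis]
    nb <- idx[ok] + strides[axis]
    both <- mask[nb]
    if (any(both)) {
      edges[[axis]] <- cbind(vox_id[idx[ok][both]], vox_id[nb[both]])
    }
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(rbind(edges,
                                         cbind(seq_along(idx), seq_along(idx))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by first-seen voxel order
  first <- !duplicated(comp)
  remap <- integer(max(comp))
  remap[comp[first]] <- seq_len(sum(first))
  lab[idx] <- remap[comp]
  lab
}

# Remove connected components smaller than min_voxels from a logical mask.
filter_small_components <- function(mask, min_voxels) {
  if (min_voxels <= 1L || !any(mask)) return(mask)
  lab <- label_components3d(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}
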