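# Lipid-droplet / mitochondria contact quantification on two-channel 3D
# stacks: blur -> top-hat background subtraction -> threshold -> voxel-face
# contact area normalized by total droplet volume ("contact ratio", um^-1).

#' Preprocess a 3D channel for segmentation
#'
#' Gaussian blur (per-axis sigma derived from the physical sigma and the
#' voxel size) followed by white top-hat background subtraction with a
#' ball structuring element. Either step can be disabled by passing 0.
#'
#' @param vol A [volume_image()].
#' @param blur_sigma_um Gaussian sigma in um (0 = skip).
#' @param tophat_radius_um Ball element radius in um (0 = skip). Must exceed
#'   the scale of objects meant to survive; smaller structures are kept,
#'   larger background is removed.
#' @return A [volume_image()] of non-negative intensities, same shape.
#' @export
preprocess <- function(vol, blur_sigma_um = 0.04, tophat_radius_um = 0.5) {
  stopifnot(inherits(vol, "volume_image"))
  if (blur_sigma_um < 0 || tophat_radius_um < 0) {
    stop("blur sigma and top-hat radius must be non-negative", call. = FALSE)
  }
  x <- vol$data
  if (blur_sigma_um > 0) {
    x <- gaussian_blur3d(x, blur_sigma_um / vol$voxel_size)
  }
  x <- white_tophat3d(x, tophat_radius_um, vol$voxel_size)
  volume_image(pmax(x, 0), vol$voxel_size)
}

#' Segment a 3D channel by thresholding
#'
#' Thresholds the volume (`otsu`: 256-bin Otsu on the full 3D histogram;
#' `fixed`: a supplied intensity) keeping voxels strictly above the
#' threshold, then removes connected components below a minimum voxel count.
#'
#' @param vol A [volume_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity cutoff, required for `method = "fixed"`.
#' @param min_component_voxels Minimum 6-connected component size kept
#'   (0 or 1 disables the filter).
#' @return A [binary_mask3d()] with attribute `"threshold"`. A degenerate
#'   histogram (all voxels equal) under Otsu yields an empty mask with a
#'   warning rather than an error.
#' @export
segment <- function(vol, method = c("otsu", "fixed"), fixed_threshold = NULL,
                    min_component_voxels = 0L) {
  stopifnot(inherits(vol, "volume_image"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_threshold)) {
      stop("`fixed_threshold` is required when method = \"fixed\"",
           call. = FALSE)
    }
    thr <- fixed_threshold
  } else {
    thr <- otsu_threshold(vol$data)
    if (is.na(thr)) {
      warning("degenerate intensity histogram (all voxels equal); ",
              "returning an empty mask", call. = FALSE)
      m <- binary_mask3d(array(FALSE, dim(vol$data)), vol$voxel_size)
      attr(m, "threshold") <- NA_real_
      return(m)
    }
  }
  mask <- vol$data > thr
  if (min_component_voxels > 1L) {
    mask <- filter_small_components(mask, min_component_voxels)
  }
  m <- binary_mask3d(mask, vol$voxel_size)
  attr(m, "threshold") <- thr
  m
}

# Shift a logical 3D array by k voxels along `axis` in direction `dir`
# (out-of-range voxels become FALSE).
shift_mask <- function(mask, axis, dir, k = 1L) {
  d <- dim(mask)
  out <- array(FALSE, d)
  n <- d[axis]
  if (k >= n) return(out)
  src <- vector("list", 3); dst <- vector("list", 3)
  for (a in 1:3) src[[a]] <- dst[[a]] <- seq_len(d[a])
  if (dir > 0) {          # out[i] <- mask[i + k]
    dst[[axis]] <- seq_len(n - k); src[[axis]] <- (k + 1L):n
  } else {                # out[i] <- mask[i - k]
    dst[[axis]] <- (k + 1L):n; src[[axis]] <- seq_len(n - k)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Lipid-droplet / mitochondria contact area and contact ratio
#'
#' A contact face is an exposed droplet-surface face — the face between a
#' droplet voxel `a` and a 6-neighbor `b` outside the droplet mask — such
#' that a mitochondria voxel lies within `contact_distance_voxels` steps
#' beyond `a` along that axis (distance 1: `b` itself is mitochondrial).
#' Faces are weighted by their physical area per axis (z-neighbor faces have
#' area dy*dx, y-neighbor faces dz*dx, x-neighbor faces dz*dy), so
#' anisotropic stacks are handled without resampling. The contact ratio is
#' the summed face area divided by the total droplet volume (um^-1).
#'
#' @param ld,mito [binary_mask3d()] masks sharing shape and voxel size.
#' @param contact_distance_voxels Maximum voxel distance (>= 1) at which a
#'   mitochondrial voxel counts as touching an exposed droplet face.
#' @param source Optional identifier copied into the result row.
#' @return One-row tibble: `source`, `n_ld_voxels`, `n_mito_voxels`,
#'   `n_contact_faces`, `contact_area_um2`, `ld_volume_um3`,
#'   `contact_ratio`, `ld_empty`. The ratio is 0 (with `ld_empty = TRUE`)
#'   when the droplet mask is empty.
#' @export
contact_area <- function(ld, mito, contact_distance_voxels = 1L,
                         source = NA_character_) {
  stopifnot(inherits(ld, "binary_mask3d"), inherits(mito, "binary_mask3d"))
  if (!same_geometry(ld, mito)) {
    stop("ld and mito masks must share shape and voxel_size", call. = FALSE)
  }
  d <- as.integer(contact_distance_voxels)
  if (d < 1L) stop("contact_distance_voxels must be >= 1", call. = FALSE)
  vs <- ld$voxel_size
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  n_faces_axis <- integer(3)
  L <- ld$data; M <- mito$data
  for (axis in 1:3) {
    for (dir in c(1L, -1L)) {
      nb_ld <- shift_mask(L, axis, dir, 1L)
      mito_near <- array(FALSE, dim(L))
      for (k in seq_len(d)) {
        mito_near <- mito_near | shift_mask(M, axis, dir, k)
      }
      n_faces_axis[axis] <- n_faces_axis[axis] +
        sum(L & !nb_ld & mito_near)
    }
  }
  n_ld <- sum(L)
  area <- sum(n_faces_axis * face_area)
  ld_vol <- n_ld * prod(vs)
  empty <- n_ld == 0L || sum(M) == 0L
  if (empty) {
    area <- 0
    n_faces_axis <- integer(3)
  }
  tibble::tibble(
    source = source,
    n_ld_voxels = n_ld,
    n_mito_voxels = sum(M),
    n_contact_faces = sum(n_faces_axis),
    contact_area_um2 = area,
    ld_volume_um3 = ld_vol,
    contact_ratio = if (ld_vol > 0) area / ld_vol else 0,
    ld_empty = n_ld == 0L
  )
}

#' Batch contact quantification over two-channel image files
#'
#' Streams the files one at a time (a single volume pair plus a constant
#' number of same-shape temporaries is resident at any moment): for each
#' file, read, [preprocess()] both channels, [segment()], and
#' [contact_area()]. Per-file failures are caught, logged, and reported in
#' an `error` column; the batch continues.
#'
#' @param paths Character vector of two-channel TIFF paths (channels
#'   `mito`, `ld` in that order).
#' @param config Pipeline parameter list, see [default_config()].
#' @return Tibble of contact results in input order, with an `error` column
#'   (`NA` on success).
#' @export
batch_contact <- function(paths, config = default_config()) {
  config <- validate_config(config)
  res <- purrr::map(paths, function(p) {
    tryCatch({
      img <- read_image(p, channel_names = c("mito", "ld"),
                        voxel_size = config$voxel_size)
      row <- contact_channels(img$channels$mito, img$channels$ld, config,
                              source = p)
      row$error <- NA_character_
      row
    }, error = function(e) {
      message("batch_contact: ", p, " failed: ", conditionMessage(e))
      tibble::tibble(source = p, n_ld_voxels = NA_integer_,
                     n_mito_voxels = NA_integer_, n_contact_faces = NA_integer_,
                     contact_area_um2 = NA_real_, ld_volume_um3 = NA_real_,
                     contact_ratio = NA_real_, ld_empty = NA,
                     error = conditionMessage(e))
    })
  })
  dplyr::bind_rows(res)
}

# Full single-scene pipeline on in-memory channels (shared by batch_contact
# and the preset reproduction code).
contact_channels <- function(mito, ld, config = default_config(),
                             source = NA_character_) {
  config <- validate_config(config)
  pp <- function(v) preprocess(v, config$blur_sigma_um, config$tophat_radius_um)
  sg <- function(v) segment(v, config$threshold_method,
                            config$fixed_threshold,
                            config$min_component_voxels)
  contact_area(sg(pp(ld)), sg(pp(mito)),
               contact_distance_voxels = config$contact_distance_voxels,
               source = source)
}
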