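# TIFF image + CSV table I/O. Images are stored as 16-bit multi-page TIFFs
# (pages ordered channel-major: all z planes of channel 1, then channel 2,
# ...), with a JSON sidecar `<path>.json` carrying channel names, axes tag,
# voxel size, and bit depth. Integer intensities in [0, 65535] round-trip
# bit-for-bit.

TIFF_MAX <- 65535

#' Write a multi-channel image stack
#'
#' @param channels Named list of [volume_image()] objects (or arrays) that
#'   share one shape; names are the channel names.
#' @param path Destination `.tif` path; a `<path>.json` metadata sidecar is
#'   written alongside.
#' @param voxel_size Voxel `(z, y, x)` sizes in um (taken from the first
#'   `volume_image` if not given).
#' @return `path`, invisibly.
#' @export
write_image <- function(channels, path, voxel_size = NULL) {
  if (inherits(channels, "volume_image")) channels <- list(channel = channels)
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  arrs <- lapply(channels, function(ch) {
    if (inherits(ch, "volume_image")) {
      if (is.null(voxel_size)) voxel_size <<- unname(ch$voxel_size)
      ch$data
    } else if (is.matrix(ch)) array(ch, c(1L, dim(ch))) else ch
  })
  if (is.null(voxel_size)) voxel_size <- unname(default_voxel_size())
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1)))) {
    stop("all channels must share one shape", call. = FALSE)
  }
  if (any(vapply(arrs, function(a) any(a < 0 | a > TIFF_MAX), logical(1)))) {
    stop("intensities must lie in [0, ", TIFF_MAX, "] for 16-bit storage",
         call. = FALSE)
  }
  pages <- unlist(lapply(arrs, function(a) {
    lapply(seq_len(d[1]), function(z) round(a[z, , ]) / TIFF_MAX)
  }), recursive = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(channels = names(channels), axes = "ZYX",
               shape = d, voxel_size_um = voxel_size, bit_depth = 16L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-channel image stack
#'
#' Reads a multi-page TIFF written by [write_image()] (or any plain TIFF
#' stack, in which case channel structure comes from `channel_names` and
#' geometry from `voxel_size`). Metadata from the JSON sidecar wins when
#' present; a requested channel count that does not match the file is a
#' format error.
#'
#' @param path TIFF file.
#' @param channel_names Expected channel names; `NULL` accepts whatever the
#'   sidecar declares (single channel `"channel"` if no sidecar).
#' @param voxel_size Fallback voxel size when the sidecar is absent.
#' @return List with `record` (one-row tibble: path, channels, axes,
#'   voxel size, bit depth) and `channels` (named list of [volume_image()]).
#' @export
read_image <- function(path, channel_names = NULL, voxel_size = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  file_channels <- if (!is.null(meta)) as.character(meta$channels)
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(file_channels)) file_channels else "channel"
  }
  nc <- length(channel_names)
  if (!is.null(file_channels) && length(file_channels) != nc) {
    stop(sprintf("channel count mismatch for %s: expected %d (%s), found %d (%s)",
                 path, nc, paste(channel_names, collapse = ","),
                 length(file_channels),
                 paste(file_channels, collapse = ",")), call. = FALSE)
  }
  if (n_pages %% nc != 0L) {
    stop(sprintf("channel count mismatch for %s: %d pages not divisible by %d requested channels",
                 path, n_pages, nc), call. = FALSE)
  }
  if (is.null(voxel_size)) {
    voxel_size <- if (!is.null(meta)) as.numeric(meta$voxel_size_um)
    else unname(default_voxel_size())
  }
  nz <- n_pages %/% nc
  py <- nrow(pages[[1]]); px <- ncol(pages[[1]])
  channels <- stats::setNames(vector("list", nc), channel_names)
  for (c_i in seq_len(nc)) {
    a <- array(0, c(nz, py, px))
    for (z in seq_len(nz)) {
      a[z, , ] <- round(pages[[(c_i - 1L) * nz + z]] * TIFF_MAX)
    }
    channels[[c_i]] <- volume_image(a, voxel_size)
  }
  record <- tibble::tibble(
    path = path,
    channels = paste(channel_names, collapse = ","),
    axes = "ZYX",
    voxel_z_um = voxel_size[1], voxel_y_um = voxel_size[2],
    voxel_x_um = voxel_size[3],
    bit_depth = if (!is.null(meta)) as.integer(meta$bit_depth) else 16L,
    n_z = nz, n_y = py, n_x = px
  )
  list(record = record, channels = channels)
}

#' Write a results table as CSV
#'
#' Header row always present (an empty record set yields a header-only
#' file); floating-point values are written at full (shortest round-trip)
#' precision; rows keep their input order.
#'
#' @param records Data frame / tibble of result rows.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path CSV file.
#' @return Tibble.
#' @export
read_results_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
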