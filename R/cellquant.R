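# Per-cell fluorescence quantification: 2D segmentation of rod-shaped
# bacteria (phase contrast) or round macrophages, background-subtracted
# per-cell intensities, positivity calling (PI / Annexin V), JC-1 red/green
# ratios, and replicate-level condition summaries.

as_matrix2d <- function(image) {
  if (inherits(image, "volume_image")) {
    d <- dim(image$data)
    if (d[1] != 1L) stop("a 2D (single-plane) image is required", call. = FALSE)
    image$data[1, , ]
  } else if (is.matrix(image)) {
    image
  } else {
    stop("`image` must be a matrix or single-plane volume_image",
         call. = FALSE)
  }
}

#' Segment cells in a 2D field
#'
#' Rod geometry assumes cells darker than background (phase contrast): the
#' image is inverted before a 256-bin Otsu threshold. Round geometry assumes
#' cells brighter than background. Connected components are filtered by area
#' and components touching the field border are dropped. Surviving cells are
#' relabeled 1..n in raster order of their centroids.
#'
#' @param image 2D matrix or single-plane [volume_image()] (the
#'   segmentation channel: phase contrast for bacteria, a cytoplasmic or
#'   dye channel for round cells).
#' @param geometry `"rod"` or `"round"`.
#' @param min_area,max_area Pixel-area bounds for kept components.
#' @return A `cell_records` tibble (`label`, `centroid_y`, `centroid_x`,
#'   `area_px`) carrying the relabeled label image as attribute
#'   `"label_image"`. Zero surviving cells yields an empty tibble with a
#'   warning.
#' @export
segment_cells <- function(image, geometry = c("rod", "round"),
                          min_area = 20L, max_area = 2000L) {
  geometry <- match.arg(geometry)
  img <- as_matrix2d(image)
  work <- if (geometry == "rod") max(img) - img else img
  thr <- otsu_threshold(work)
  if (is.na(thr)) {
    warning("flat image: no cells found", call. = FALSE)
    return(empty_cell_records(array(0L, dim(img))))
  }
  binary <- work > thr
  lab <- EBImage::bwlabel(binary)
  lab <- as.matrix(lab)
  n <- max(lab)
  if (n == 0L) {
    warning("no cells found after thresholding", call. = FALSE)
    return(empty_cell_records(lab))
  }
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  areas <- tabulate(lab[lab > 0L], n)
  keep <- setdiff(which(areas >= min_area & areas <= max_area),
                  border_labels)
  if (length(keep) == 0L) {
    warning("no cells survive the area/border filters", call. = FALSE)
    return(empty_cell_records(array(0L, dim(lab))))
  }
  idx <- which(lab > 0L & array(lab %in% keep, dim(lab)))
  coords <- arrayInd(idx, dim(lab))
  old <- lab[idx]
  cy <- tapply(coords[, 1], old, mean)
  cx <- tapply(coords[, 2], old, mean)
  ord <- order(round(cy), cx)       # raster order of centroids
  old_sorted <- as.integer(names(cy))[ord]
  remap <- integer(n)
  remap[old_sorted] <- seq_along(old_sorted)
  new_lab <- array(0L, dim(lab))
  new_lab[idx] <- remap[old]
  records <- tibble::tibble(
    label = seq_along(old_sorted),
    centroid_y = as.numeric(cy[ord]),
    centroid_x = as.numeric(cx[ord]),
    area_px = as.integer(areas[old_sorted])
  )
  new_cell_records(records, new_lab)
}

new_cell_records <- function(df, label_image) {
  structure(tibble::as_tibble(df), label_image = label_image,
            class = c("cell_records", class(tibble::tibble())))
}

empty_cell_records <- function(label_image) {
  new_cell_records(
    tibble::tibble(label = integer(), centroid_y = numeric(),
                   centroid_x = numeric(), area_px = integer()),
    label_image)
}

#' @export
print.cell_records <- function(x, ...) {
  cat(sprintf("<cell_records> %d cells\n", nrow(x)))
  NextMethod()
}

#' Background-subtracted per-cell mean intensity
#'
#' The field background is the median of all non-cell pixels of the
#' fluorescence channel (robust to bright cells); each cell's mean intensity
#' over its own pixels is background-subtracted and floored at zero. The
#' background level and its robust noise sd (MAD) are stored as attributes
#' `"background"` / `"background_sd"` for the k-sigma positivity rule.
#'
#' @param cells A `cell_records` tibble from [segment_cells()].
#' @param fluor Fluorescence channel, same shape as the segmented image.
#' @param col Name of the intensity column to add.
#' @return `cells` with the new intensity column.
#' @export
per_cell_intensity <- function(cells, fluor, col = "mean_intensity") {
  lab <- attr(cells, "label_image")
  img <- as_matrix2d(fluor)
  if (!identical(dim(lab), dim(img))) {
    stop("label image and fluorescence channel shapes differ", call. = FALSE)
  }
  bg_pixels <- img[lab == 0L]
  bg <- stats::median(bg_pixels)
  bg_sd <- stats::mad(bg_pixels)
  vals <- rep(NA_real_, nrow(cells))
  if (nrow(cells) > 0L) {
    means <- tapply(img[lab > 0L], lab[lab > 0L], mean)
    vals <- pmax(as.numeric(means[as.character(cells$label)]) - bg, 0)
  }
  cells[[col]] <- vals
  attr(cells, "background") <- bg
  attr(cells, "background_sd") <- bg_sd
  cells
}

#' Call cells positive for a stain
#'
#' `otsu_on_cells` thresholds the per-cell mean-intensity distribution
#' itself (pool cells across all conditions of one experiment before
#' calling, so a single cutoff applies everywhere). `background_k_sigma`
#' calls a cell positive when its background-subtracted mean intensity
#' strictly exceeds `k_sigma` times the background noise sd — the fallback
#' for unimodal intensity distributions.
#'
#' @param cells `cell_records` with an intensity column.
#' @param rule `"otsu_on_cells"` or `"background_k_sigma"`.
#' @param k_sigma Multiplier for the k-sigma rule.
#' @param background_sd Noise sd for the k-sigma rule; defaults to the
#'   `"background_sd"` attribute set by [per_cell_intensity()].
#' @param col Intensity column to classify.
#' @return `cells` with a logical `positive` column; the cutoff used is
#'   attribute `"positive_threshold"`.
#' @export
classify_positive <- function(cells, rule = c("otsu_on_cells",
                                              "background_k_sigma"),
                              k_sigma = 3, background_sd = NULL,
                              col = "mean_intensity") {
  rule <- match.arg(rule)
  v <- cells[[col]]
  if (rule == "otsu_on_cells") {
    if (length(v) < 2L) {
      stop("otsu_on_cells needs at least 2 cells; ",
           "use rule = \"background_k_sigma\"", call. = FALSE)
    }
    thr <- otsu_threshold(v)
    if (is.na(thr)) thr <- Inf   # all equal: nothing is positive
  } else {
    if (is.null(background_sd)) background_sd <- attr(cells, "background_sd")
    if (is.null(background_sd)) {
      stop("background_k_sigma needs `background_sd` ",
           "(run per_cell_intensity first or pass it)", call. = FALSE)
    }
    thr <- k_sigma * background_sd
  }
  cells$positive <- v > thr
  attr(cells, "positive_threshold") <- thr
  cells
}

#' Fraction of positive cells
#'
#' @param cells Tibble with a logical `positive` column.
#' @param ... Grouping columns (tidy-select), e.g. `condition, replicate`.
#' @return Tibble of `n_cells`, `n_positive`, `fraction_positive` per group
#'   (one row when ungrouped).
#' @export
fraction_positive <- function(cells, ...) {
  cells |>
    dplyr::group_by(...) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_positive = sum(.data$positive),
                     fraction_positive = mean(.data$positive),
                     .groups = "drop")
}

#' Per-cell JC-1 red/green ratio
#'
#' One segmentation is applied to both channels; each cell's ratio is its
#' background-subtracted red mean over its background-subtracted green mean.
#' Cells whose green mean does not exceed `green_floor` are excluded from
#' the ratio (flagged, ratio `NA`) and counted in attribute `"n_excluded"`.
#'
#' @param cells `cell_records` from [segment_cells()].
#' @param red,green The two JC-1 channels (same shape as the segmentation).
#' @param green_floor Minimum green mean for a usable ratio.
#' @return `cells` with `red_mean`, `green_mean`, `excluded`, `ratio`
#'   columns. All cells excluded yields a warning.
#' @export
jc1_ratio <- function(cells, red, green, green_floor = 1) {
  cells <- per_cell_intensity(cells, red, col = "red_mean")
  cells <- per_cell_intensity(cells, green, col = "green_mean")
  cells$excluded <- !(cells$green_mean > green_floor)
  cells$ratio <- ifelse(cells$excluded, NA_real_,
                        cells$red_mean / cells$green_mean)
  attr(cells, "n_excluded") <- sum(cells$excluded)
  if (nrow(cells) > 0L && all(cells$excluded)) {
    warning("all cells excluded by the green floor; empty JC-1 summary",
            call. = FALSE)
  }
  cells
}

#' Replicate-level condition summary
#'
#' Statistics are computed per biological replicate first (mean of the
#' per-cell values), then summarized across replicates: the grand mean is
#' the mean of replicate means and the SEM is their sd over sqrt(number of
#' replicates) — matching how imaging figures with three biological
#' replicates report error bars.
#'
#' @param df Per-cell tibble.
#' @param value Column of per-cell values (tidy-select).
#' @param condition,replicate Grouping columns (tidy-select).
#' @return A `condition_summary` tibble: `condition`, `grand_mean`, `sem`,
#'   `n_replicates`, `n_cells_total`, plus a `replicate_values` list-column
#'   of the per-replicate means.
#' @export
summarize_replicates <- function(df, value, condition, replicate) {
  per_rep <- df |>
    dplyr::group_by({{ condition }}, {{ replicate }}) |>
    dplyr::summarise(.value = mean({{ value }}, na.rm = TRUE),
                     .n = sum(!is.na({{ value }})), .groups = "drop")
  names(per_rep)[1:2] <- c("condition", "replicate")
  out <- per_rep |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      grand_mean = mean(.data$.value),
      sem = stats::sd(.data$.value) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      n_cells_total = sum(.data$.n),
      replicate_values = list(.data$.value),
      .groups = "drop")
  class(out) <- c("condition_summary", class(out))
  out
}

#' Fold change between two condition summaries
#'
#' `fold = grand_mean(a) / grand_mean(b)`, with first-order error
#' propagation: `rel_error = sqrt((sem_a/mean_a)^2 + (sem_b/mean_b)^2)` and
#' `se_fold = fold * rel_error`.
#'
#' @param a,b One-row `condition_summary` tibbles (numerator, denominator);
#'   with a multi-row summary, pass `condition_a` / `condition_b` to select
#'   rows by condition id.
#' @param condition_a,condition_b Optional condition ids used to pick rows
#'   when `a` (and possibly `b`) have several rows.
#' @return One-row tibble: `fold`, `rel_error`, `se_fold`,
#'   `condition_num`, `condition_den`.
#' @export
fold_change <- function(a, b = NULL, condition_a = NULL, condition_b = NULL) {
  if (!is.null(condition_a)) {
    stopifnot(!is.null(condition_b))
    b <- a[a$condition == condition_b, , drop = FALSE]
    a <- a[a$condition == condition_a, , drop = FALSE]
  }
  if (nrow(a) != 1L || nrow(b) != 1L) {
    stop("fold_change needs exactly one summary row on each side",
         call. = FALSE)
  }
  if (b$grand_mean <= 0) {
    stop("fold change undefined: denominator grand mean is not positive",
         call. = FALSE)
  }
  fold <- a$grand_mean / b$grand_mean
  rel_a <- if (a$grand_mean > 0) a$sem / a$grand_mean else 0
  rel <- sqrt(rel_a^2 + (b$sem / b$grand_mean)^2)
  cond_of <- function(df, default) {
    if ("condition" %in% names(df)) as.character(df$condition) else default
  }
  tibble::tibble(
    condition_num = cond_of(a, "a"),
    condition_den = cond_of(b, "b"),
    fold = fold,
    rel_error = rel,
    se_fold = fold * rel
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
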