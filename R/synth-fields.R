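# Synthetic 2D microscopy fields with planted ground truth: rod-shaped
# bacteria (phase contrast + PI channel) and round macrophages (JC-1
# red/green channels). Everything downstream of the pixel values is known
# exactly, so the quantification pipelines can be validated end to end.

# Evaluate `code` under `seed`, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic 2D cell field
#'
#' Defaults emulate the study's imaging conditions: 100 cells per field
#' (one field per biological replicate), rods of roughly E. coli size at a
#' ~0.063 um pixel pitch, and a clearly bimodal stain intensity
#' distribution. `positive_fraction` is planted exactly:
#' `round(n_cells * positive_fraction)` cells get `intensity_positive`.
#'
#' @param field_shape `(y, x)` field size in pixels.
#' @param n_cells Number of cells placed without overlap.
#' @param cell_geometry `"rod"` (bacteria) or `"round"` (macrophages).
#' @param rod_length_px,rod_width_px Rod capsule dimensions (rods).
#' @param cell_radius_px Disk radius (round cells).
#' @param positive_fraction Planted fraction of stain-positive cells.
#' @param intensity_positive,intensity_negative Mean stain intensity added
#'   above background for positive / negative cells.
#' @param noise_sigma Gaussian read-noise sd on every channel.
#' @param background Fluorescence background level.
#' @param phase_background,phase_cell Phase-contrast background and
#'   (darker) cell levels.
#' @param red_green_ratio Planted JC-1 red/green ratio (round cells).
#' @param ratio_scatter_sd Log-normal sdlog of per-cell ratio scatter.
#' @param green_mean,green_scatter_sd Base green intensity and its
#'   log-normal per-cell scatter (round cells).
#' @param seed RNG seed.
#' @return A validated `cell_field_config` list.
#' @export
cell_field_config <- function(field_shape = c(256L, 256L),
                              n_cells = 100L,
                              cell_geometry = c("rod", "round"),
                              rod_length_px = 12, rod_width_px = 4,
                              cell_radius_px = 8,
                              positive_fraction = 0.5,
                              intensity_positive = 600,
                              intensity_negative = 60,
                              noise_sigma = 10,
                              background = 100,
                              phase_background = 600,
                              phase_cell = 300,
                              red_green_ratio = 2,
                              ratio_scatter_sd = 0.1,
                              green_mean = 400,
                              green_scatter_sd = 0.1,
                              seed = 1L) {
  cfg <- list(field_shape = as.integer(field_shape), n_cells = as.integer(n_cells),
              cell_geometry = match.arg(cell_geometry),
              rod_length_px = rod_length_px, rod_width_px = rod_width_px,
              cell_radius_px = cell_radius_px,
              positive_fraction = positive_fraction,
              intensity_positive = intensity_positive,
              intensity_negative = intensity_negative,
              noise_sigma = noise_sigma, background = background,
              phase_background = phase_background, phase_cell = phase_cell,
              red_green_ratio = red_green_ratio,
              ratio_scatter_sd = ratio_scatter_sd,
              green_mean = green_mean, green_scatter_sd = green_scatter_sd,
              seed = as.integer(seed))
  if (cfg$positive_fraction < 0 || cfg$positive_fraction > 1) {
    stop("positive_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$intensity_positive <= 0 || cfg$intensity_negative <= 0 ||
      cfg$green_mean <= 0) {
    stop("stain intensities must be positive", call. = FALSE)
  }
  if (cfg$noise_sigma < 0 || cfg$background < 0) {
    stop("noise_sigma and background must be non-negative", call. = FALSE)
  }
  if (cfg$red_green_ratio <= 0) {
    stop("red_green_ratio must be positive", call. = FALSE)
  }
  cfg
}

# Pixel set of a capsule (rod) of total length L, width w, centered at
# (cy, cx) with orientation theta, inside a field of dims d. NULL when it
# leaves the allowed margin.
rod_pixels <- function(cy, cx, theta, length_px, width_px, d, margin = 2L,
                       extra_radius = 0) {
  r <- width_px / 2 + extra_radius
  h <- max((length_px - width_px) / 2, 0)
  dy <- sin(theta); dx <- cos(theta)
  half_y <- abs(h * dy) + r; half_x <- abs(h * dx) + r
  y0 <- floor(cy - half_y); y1 <- ceiling(cy + half_y)
  x0 <- floor(cx - half_x); x1 <- ceiling(cx + half_x)
  if (y0 < 1 + margin || x0 < 1 + margin ||
      y1 > d[1] - margin || x1 > d[2] - margin) return(NULL)
  g <- expand.grid(y = y0:y1, x = x0:x1)
  py <- g$y - cy; px <- g$x - cx
  t_proj <- pmin(pmax(py * dy + px * dx, -h), h)
  dist2 <- (py - t_proj * dy)^2 + (px - t_proj * dx)^2
  keep <- dist2 <= r^2
  cbind(g$y[keep], g$x[keep])
}

disk_pixels <- function(cy, cx, radius, d, margin = 2L, extra_radius = 0) {
  r <- radius + extra_radius
  y0 <- floor(cy - r); y1 <- ceiling(cy + r)
  x0 <- floor(cx - r); x1 <- ceiling(cx + r)
  if (y0 < 1 + margin || x0 < 1 + margin ||
      y1 > d[1] - margin || x1 > d[2] - margin) return(NULL)
  g <- expand.grid(y = y0:y1, x = x0:x1)
  keep <- (g$y - cy)^2 + (g$x - cx)^2 <= r^2
  cbind(g$y[keep], g$x[keep])
}

# Place n_cells non-overlapping cells (1-px clearance). Returns a label
# image and a per-cell geometry tibble; errors when the retry budget is
# exhausted, reporting the achieved count.
place_cells <- function(cfg) {
  d <- cfg$field_shape
  lab <- array(0L, d)
  rows <- vector("list", cfg$n_cells)
  budget <- 200L * max(cfg$n_cells, 1L)
  placed <- 0L
  while (placed < cfg$n_cells && budget > 0L) {
    budget <- budget - 1L
    cy <- stats::runif(1, 1, d[1]); cx <- stats::runif(1, 1, d[2])
    theta <- stats::runif(1, 0, pi)
    if (cfg$cell_geometry == "rod") {
      px_cell <- rod_pixels(cy, cx, theta, cfg$rod_length_px,
                            cfg$rod_width_px, d)
      px_clear <- rod_pixels(cy, cx, theta, cfg$rod_length_px,
                             cfg$rod_width_px, d, extra_radius = 1.5)
    } else {
      px_cell <- disk_pixels(cy, cx, cfg$cell_radius_px, d)
      px_clear <- disk_pixels(cy, cx, cfg$cell_radius_px, d,
                              extra_radius = 1.5)
    }
    if (is.null(px_cell) || is.null(px_clear) ||
        any(lab[px_clear] != 0L)) next
    placed <- placed + 1L
    lab[px_cell] <- placed
    rows[[placed]] <- tibble::tibble(label = placed, center_y = cy,
                                     center_x = cx, theta = theta,
                                     area_px = nrow(px_cell))
  }
  if (placed < cfg$n_cells) {
    stop(sprintf("could not place %d cells (placed %d); enlarge the field or reduce n_cells",
                 cfg$n_cells, placed), call. = FALSE)
  }
  list(label_image = lab, cells = dplyr::bind_rows(rows))
}

add_noise <- function(img, sigma) {
  if (sigma <= 0) return(img)
  pmax(img + stats::rnorm(length(img), 0, sigma), 0)
}

#' Synthesize a bacterial PI field
#'
#' Places non-overlapping rods, renders a phase-contrast channel (cells
#' darker than background) and a PI channel in which exactly
#' `round(n_cells * positive_fraction)` randomly chosen cells carry
#' `intensity_positive` above background and the rest
#' `intensity_negative`, then adds Gaussian noise. Identical config and
#' seed give identical arrays.
#'
#' @param cfg A [cell_field_config()] with `cell_geometry = "rod"`.
#' @return List of class `bacteria_field`: `phase` and `pi`
#'   ([volume_image()]s), `truth` (label image, per-cell tibble with
#'   planted `positive` flags, `true_positive_fraction`), and `config`.
#' @export
make_bacteria_field <- function(cfg = cell_field_config()) {
  stopifnot(cfg$cell_geometry == "rod")
  with_seed(cfg$seed, {
    pl <- place_cells(cfg)
    n_pos <- round(cfg$n_cells * cfg$positive_fraction)
    pos_labels <- sample(cfg$n_cells, n_pos)
    positive <- seq_len(cfg$n_cells) %in% pos_labels
    lab <- pl$label_image
    phase <- array(cfg$phase_background, dim(lab))
    phase[lab > 0L] <- cfg$phase_cell
    pi_img <- array(cfg$background, dim(lab))
    cell_px <- lab > 0L
    pi_img[cell_px] <- cfg$background +
      ifelse(positive[lab[cell_px]], cfg$intensity_positive,
             cfg$intensity_negative)
    phase <- add_noise(phase, cfg$noise_sigma)
    pi_img <- add_noise(pi_img, cfg$noise_sigma)
    truth <- list(label_image = lab,
                  cells = dplyr::mutate(pl$cells, positive = positive),
                  true_positive_fraction = n_pos / cfg$n_cells)
    structure(list(phase = volume_image(phase), pi = volume_image(pi_img),
                   truth = truth, config = cfg),
              class = "bacteria_field")
  })
}

#' Synthesize a JC-1 macrophage field
#'
#' Places round cells; each cell's green intensity is drawn log-normally
#' around `green_mean` and its red intensity is `green x red_green_ratio x
#' exp(N(0, ratio_scatter_sd))`, so the planted per-cell red/green ratio
#' has median `red_green_ratio`. Background and Gaussian noise as
#' configured.
#'
#' @param cfg A [cell_field_config()] with `cell_geometry = "round"`.
#' @return List of class `jc1_field`: `red` and `green`
#'   ([volume_image()]s), `truth` (label image, per-cell tibble with the
#'   planted green level and ratio, `true_red_green_ratio`), and `config`.
#' @export
make_jc1_field <- function(cfg = cell_field_config(cell_geometry = "round",
                                                   n_cells = 60L,
                                                   field_shape = c(384L, 384L))) {
  stopifnot(cfg$cell_geometry == "round")
  with_seed(cfg$seed, {
    pl <- place_cells(cfg)
    n <- cfg$n_cells
    green_i <- cfg$green_mean * exp(stats::rnorm(n, 0, cfg$green_scatter_sd))
    ratio_i <- cfg$red_green_ratio * exp(stats::rnorm(n, 0, cfg$ratio_scatter_sd))
    red_i <- green_i * ratio_i
    lab <- pl$label_image
    cell_px <- lab > 0L
    green <- array(cfg$background, dim(lab))
    red <- array(cfg$background, dim(lab))
    green[cell_px] <- cfg$background + green_i[lab[cell_px]]
    red[cell_px] <- cfg$background + red_i[lab[cell_px]]
    green <- add_noise(green, cfg$noise_sigma)
    red <- add_noise(red, cfg$noise_sigma)
    truth <- list(label_image = lab,
                  cells = dplyr::mutate(pl$cells, green = green_i,
                                        ratio = ratio_i),
                  true_red_green_ratio = cfg$red_green_ratio)
    structure(list(red = volume_image(red), green = volume_image(green),
                   truth = truth, config = cfg),
              class = "jc1_field")
  })
}

#' Match segmented cells to planted ground truth
#'
#' Looks up each segmented centroid in the ground-truth label image and
#' joins the planted per-cell columns.
#'
#' @param cells `cell_records` from [segment_cells()].
#' @param truth `truth` element of a synthetic field.
#' @return `cells` with `true_label` plus the truth tibble's per-cell
#'   columns (prefixed `true_` for `positive`/`ratio`/`green`).
#' @export
match_truth <- function(cells, truth) {
  lab <- truth$label_image
  idx <- cbind(pmin(pmax(round(cells$centroid_y), 1), nrow(lab)),
               pmin(pmax(round(cells$centroid_x), 1), ncol(lab)))
  cells$true_label <- lab[idx]
  tcols <- truth$cells[, intersect(c("label", "positive", "ratio", "green"),
                                   names(truth$cells))]
  names(tcols) <- c("true_label",
                    paste0("true_", names(tcols)[-1]))
  dplyr::left_join(cells, tcols, by = "true_label")
}
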