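#' Default pipeline configuration
#'
#' A single flat list of every tunable pipeline parameter. Values here are
#' documented estimates suitable for SIM-scale two-channel stacks and
#' epifluorescence cell fields; all are overridable from a YAML config file
#' ([read_config()]) or CLI flags (flags win over file values).
#'
#' @return Named list of parameters:
#' \describe{
#'   \item{blur_sigma_um}{Gaussian blur sigma (um), default 0.04.}
#'   \item{tophat_radius_um}{Top-hat ball radius (um), default 0.5.}
#'   \item{threshold_method}{`"otsu"` or `"fixed"`.}
#'   \item{fixed_threshold}{Intensity for `"fixed"`, else `NULL`.}
#'   \item{contact_distance_voxels}{Contact search distance, default 1.}
#'   \item{min_component_voxels}{3D min component size, default 5.}
#'   \item{pi_positive_rule}{`"otsu_on_cells"` or `"background_k_sigma"`.}
#'   \item{k_sigma}{Multiplier for the k-sigma positivity rule, default 3.}
#'   \item{min_cell_area_px, max_cell_area_px}{2D cell area filter.}
#'   \item{green_floor}{JC-1 green-channel exclusion floor, default 1.}
#'   \item{voxel_size}{`(z, y, x)` um, see [default_voxel_size()].}
#'   \item{seed}{Master RNG seed.}
#' }
#' @export
default_config <- function() {
  list(
    blur_sigma_um = 0.04,
    tophat_radius_um = 0.5,
    threshold_method = "otsu",
    fixed_threshold = NULL,
    contact_distance_voxels = 1L,
    min_component_voxels = 5L,
    pi_positive_rule = "otsu_on_cells",
    k_sigma = 3,
    min_cell_area_px = 20L,
    max_cell_area_px = 2000L,
    green_floor = 1,
    voxel_size = unname(default_voxel_size()),
    seed = 1L
  )
}

#' Validate (and complete) a pipeline configuration
#'
#' Missing entries are filled from [default_config()]; invariants are
#' checked (non-negative lengths, valid enums, min < max cell area).
#'
#' @param config Named list of parameter overrides.
#' @return The completed, validated config list.
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)
  if (cfg$blur_sigma_um < 0 || cfg$tophat_radius_um < 0) {
    stop("blur_sigma_um and tophat_radius_um must be non-negative",
         call. = FALSE)
  }
  if (!cfg$threshold_method %in% c("otsu", "fixed")) {
    stop("threshold_method must be \"otsu\" or \"fixed\"", call. = FALSE)
  }
  if (cfg$threshold_method == "fixed" && is.null(cfg$fixed_threshold)) {
    stop("fixed_threshold required when threshold_method = \"fixed\"",
         call. = FALSE)
  }
  if (!cfg$pi_positive_rule %in% c("otsu_on_cells", "background_k_sigma")) {
    stop("pi_positive_rule must be \"otsu_on_cells\" or ",
         "\"background_k_sigma\"", call. = FALSE)
  }
  if (cfg$min_cell_area_px >= cfg$max_cell_area_px) {
    stop("min_cell_area_px must be < max_cell_area_px", call. = FALSE)
  }
  if (cfg$contact_distance_voxels < 1) {
    stop("contact_distance_voxels must be >= 1", call. = FALSE)
  }
  if (length(cfg$voxel_size) != 3 || any(cfg$voxel_size <= 0)) {
    stop("voxel_size must be three positive lengths (z, y, x)", call. = FALSE)
  }
  cfg
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; entries override [default_config()].
#' @return Validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Write a resolved configuration as YAML
#'
#' Written next to pipeline outputs for provenance (every CLI run does this).
#'
#' @param config Config list.
#' @param path Destination file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
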