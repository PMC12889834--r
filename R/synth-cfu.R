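#' Simulate a CFU serial-dilution count table
#'
#' Expected colonies in the droplet plated at ten-fold dilution `d` are
#' `true_survival x control_cfu_per_ml x plated_ml / d`; observed counts
#' are Poisson.
#'
#' @param true_survival Surviving fraction of the treated culture in
#'   `[0, Inf)` (values above 1 mean net growth; 0 means sterilized).
#' @param control_cfu_per_ml Untreated-control titre (CFU/ml).
#' @param dilutions Ten-fold dilution factors plated (default `10^(0:6)`).
#' @param plated_ul Droplet volume in ul (default 10).
#' @param condition Condition id written into the table.
#' @param seed Optional RNG seed.
#' @return Tibble with columns `condition`, `dilution`, `count`,
#'   `plated_ul`.
#' @export
make_cfu_counts <- function(true_survival, control_cfu_per_ml,
                            dilutions = 10^(0:6), plated_ul = 10,
                            condition = "treated", seed = NULL) {
  if (true_survival < 0 || control_cfu_per_ml < 0 || plated_ul <= 0) {
    stop("survival, titre and plated volume must be non-negative ",
         "(plated volume positive)", call. = FALSE)
  }
  lp <- log10(dilutions)
  if (any(dilutions <= 0) || any(abs(lp - round(lp)) > 1e-9)) {
    stop("dilutions must be powers of ten", call. = FALSE)
  }
  sim <- function() {
    expected <- true_survival * control_cfu_per_ml * (plated_ul / 1000) /
      dilutions
    stats::rpois(length(dilutions), expected)
  }
  counts <- if (is.null(seed)) sim() else with_seed(seed, sim())
  tibble::tibble(condition = condition, dilution = dilutions,
                 count = counts, plated_ul = plated_ul)
}
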