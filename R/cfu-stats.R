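# CFU serial-dilution survival estimation and the statistical layer:
# unequal-variance (Welch) two-sample t-tests on replicate-level values,
# fold changes, and pairwise condition comparisons.

#' Estimate CFU/ml from a ten-fold serial dilution series
#'
#' Rows whose colony count falls inside the countable range contribute; the
#' pooled estimate is total colonies over total effective plated volume,
#' i.e. each countable row's `count x dilution / plated_ml` weighted by its
#' observed colonies (the Poisson-information weighting). Per-row estimates
#' disagreeing by more than 2x are flagged discordant. A series with zero
#' colonies everywhere (including the undiluted row) is reported as 0 with
#' a below-detection flag.
#'
#' @param series Data frame with columns `dilution` (the ten-fold dilution
#'   factor: 1, 10, ..., 1e6) and `count` (colonies in the plated droplet).
#' @param plated_ul Plated droplet volume in microlitres (default 10).
#' @param countable_range Colony-count window treated as reliable
#'   (default 3–30 for 10 ul droplets).
#' @return One-row tibble: `cfu_per_ml`, `n_countable_rows`,
#'   `discordant`, `below_detection`, `flag`.
#' @export
cfu_per_ml <- function(series, plated_ul = 10,
                       countable_range = c(3, 30)) {
  stopifnot(all(c("dilution", "count") %in% names(series)))
  if (plated_ul <= 0) stop("plated volume must be positive", call. = FALSE)
  if (any(series$count < 0) || any(series$count != round(series$count))) {
    stop("colony counts must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(series$dilution)) {
    stop("dilution factors must be unique within a series", call. = FALSE)
  }
  plated_ml <- plated_ul / 1000
  ok <- series$count >= countable_range[1] & series$count <= countable_range[2]
  if (!any(ok)) {
    if (all(series$count == 0)) {
      return(tibble::tibble(cfu_per_ml = 0, n_countable_rows = 0L,
                            discordant = FALSE, below_detection = TRUE,
                            flag = "below detection"))
    }
    side <- if (all(series$count < countable_range[1])) "below" else "above"
    stop("no dilution lands in the countable range (all countable rows ",
         side, " range [", countable_range[1], ", ", countable_range[2],
         "])", call. = FALSE)
  }
  rows <- series[ok, , drop = FALSE]
  est_rows <- rows$count * rows$dilution / plated_ml
  pooled <- sum(rows$count) / sum(plated_ml / rows$dilution)
  discordant <- length(est_rows) > 1L &&
    max(est_rows) / min(est_rows) > 2
  tibble::tibble(
    cfu_per_ml = pooled,
    n_countable_rows = sum(ok),
    discordant = discordant,
    below_detection = FALSE,
    flag = if (discordant) "countable rows discordant > 2x" else NA_character_
  )
}

#' Survival fraction relative to the untreated control
#'
#' `survival = treated / control`, always paired within the same
#' temperature; values above 1 (net growth) are allowed. A treated estimate
#' of 0 (below detection) gives survival 0 with a flag.
#'
#' @param treated,control CFU/ml estimates (control from the untreated
#'   culture at the same temperature).
#' @return One-row tibble: `survival`, `flag`.
#' @export
survival_fraction <- function(treated, control) {
  if (!is.finite(control) || control <= 0) {
    stop("cannot normalize: control CFU/ml is not positive", call. = FALSE)
  }
  tibble::tibble(
    survival = treated / control,
    flag = if (treated == 0) "treated below detection" else NA_character_
  )
}

#' Welch two-sample t-test (unequal variances)
#'
#' `t = (mean_x - mean_y) / sqrt(s2_x/n_x + s2_y/n_y)` with n-1 sample
#' variances, Welch–Satterthwaite degrees of freedom, and a two-sided p from
#' the t distribution. Degenerate inputs (both variances zero) give t = 0,
#' p = 1 for equal means and p = 0 with a flag for unequal means.
#'
#' @param x,y Numeric samples, each with at least two finite values.
#' @return Object of class `welch_ttest`: `t_statistic`, `df`,
#'   `p_two_sided`, `n_x`, `n_y`, `mean_x`, `mean_y`, `degenerate`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
welch_ttest <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_ttest needs at least 2 observations per sample",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("welch_ttest requires finite values", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  degenerate <- FALSE
  if (se2 == 0) {
    degenerate <- TRUE
    if (mx == my) {
      t_stat <- 0; p <- 1; df <- nx + ny - 2
    } else {
      t_stat <- sign(mx - my) * Inf; p <- 0; df <- nx + ny - 2
    }
  } else {
    t_stat <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  }
  structure(list(t_statistic = t_stat, df = df, p_two_sided = p,
                 n_x = nx, n_y = ny, mean_x = mx, mean_y = my,
                 degenerate = degenerate),
            class = "welch_ttest")
}

#' @export
print.welch_ttest <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.3f, p = %.4g\n",
              x$t_statistic, x$df, x$p_two_sided))
  cat(sprintf("  mean_x = %.4g (n = %d), mean_y = %.4g (n = %d)%s\n",
              x$mean_x, x$n_x, x$mean_y, x$n_y,
              if (x$degenerate) "  [degenerate: zero variance]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.welch_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_x - x$mean_y,
    estimate1 = x$mean_x,
    estimate2 = x$mean_y,
    statistic = x$t_statistic,
    p.value = x$p_two_sided,
    parameter = x$df,
    method = "Welch two-sample t-test",
    alternative = "two.sided"
  )
}

#' @export
glance.welch_ttest <- function(x, ...) tidy(x)

#' Pairwise Welch comparisons of replicate-level condition statistics
#'
#' For each requested pair, runs [welch_ttest()] on the replicate values of
#' the two conditions, computes the fold change of their means with
#' propagated error, and attaches the significance label used in the
#' figures: `"ns"` when p > 0.05, otherwise the p value. No
#' multiple-testing correction is applied by default (each test is reported
#' as-is); `holm = TRUE` adjusts the p values across the requested pairs.
#'
#' @param table Data frame with columns `condition`, `replicate`, `value`
#'   (one replicate-level statistic per row).
#' @param pairs List of length-2 character vectors `c(numerator,
#'   denominator)`.
#' @param alpha Significance level for the label (default 0.05).
#' @param holm Apply a Holm correction across the pairs (off by default).
#' @return Tibble with one row per pair: conditions, means, `fold`,
#'   `se_fold`, `t_statistic`, `df`, `p_value`, `label`.
#' @export
compare_conditions <- function(table, pairs, alpha = 0.05, holm = FALSE) {
  stopifnot(all(c("condition", "replicate", "value") %in% names(table)))
  if (length(pairs) == 0L) {
    return(tibble::tibble(condition_num = character(),
                          condition_den = character(),
                          mean_num = numeric(), mean_den = numeric(),
                          fold = numeric(), se_fold = numeric(),
                          t_statistic = numeric(), df = numeric(),
                          p_value = numeric(), label = character()))
  }
  rows <- purrr::map(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    xa <- table$value[table$condition == pr[1]]
    xb <- table$value[table$condition == pr[2]]
    if (length(xa) == 0L || length(xb) == 0L) {
      stop("condition not found in table: ",
           pr[if (length(xa) == 0L) 1 else 2], call. = FALSE)
    }
    if (length(xa) < 2L || length(xb) < 2L) {
      stop("need >= 2 replicates per condition for pair ",
           pr[1], " vs ", pr[2], call. = FALSE)
    }
    tt <- welch_ttest(xa, xb)
    sum_tbl <- tibble::tibble(
      condition = pr,
      grand_mean = c(mean(xa), mean(xb)),
      sem = c(stats::sd(xa) / sqrt(length(xa)),
              stats::sd(xb) / sqrt(length(xb))))
    fc <- fold_change(sum_tbl, condition_a = pr[1], condition_b = pr[2])
    tibble::tibble(
      condition_num = pr[1], condition_den = pr[2],
      mean_num = tt$mean_x, mean_den = tt$mean_y,
      fold = fc$fold, se_fold = fc$se_fold,
      t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_two_sided)
  })
  out <- dplyr::bind_rows(rows)
  if (holm) out$p_value <- stats::p.adjust(out$p_value, method = "holm")
  out$label <- ifelse(out$p_value > alpha, "ns",
                      formatC(out$p_value, format = "g", digits = 3))
  out
}
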