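# Synthetic experiment presets calibrated to the published fold effects,
# and the end-to-end pipelines that recover those effects from the
# generated images. Planted absolutes (the reports are folds; per-condition
# absolutes are not available): PI-positive baseline fraction 0.06 at the
# lower temperature, untreated JC-1 red/green ratio 2.0, mitochondrial
# damage 0.30 at 37C for the fold presets, contact fractions 0.6 vs 0.15
# for the glucose/temperature scene. See the methods vignette.

PRESET_NAMES <- c("dual_fever_40", "dual_fever_385", "ll37_mito_fold",
                  "ohcath_mito_fold", "ll37_activity_37",
                  "contact_glucose_temp")

PI_BASELINE_FRACTION <- 0.06
JC1_UNTREATED_RATIO <- 2.0
MITO_DAMAGE_37 <- 0.30

rep_seeds <- function(seed, condition_index) {
  # replicates use fixed offsets seed, seed+1, seed+2; conditions are
  # separated by blocks of 10
  seed + 10L * (condition_index - 1L) + 0:2
}

pi_conditions <- function(conditions, fractions, seed) {
  purrr::map2(conditions, seq_along(conditions), function(cond, j) {
    s <- rep_seeds(seed, j)
    tibble::tibble(
      condition = cond, replicate = 1:3, seed = s,
      cfg = purrr::map(s, ~ cell_field_config(positive_fraction = fractions[j],
                                              seed = .x)))
  }) |> dplyr::bind_rows()
}

jc1_conditions <- function(grid, seed) {
  # grid: tibble(condition, ratio); one block of replicate seeds per row
  purrr::map(seq_len(nrow(grid)), function(j) {
    s <- rep_seeds(seed, j)
    tibble::tibble(
      condition = grid$condition[j], replicate = 1:3, seed = s,
      cfg = purrr::map(s, ~ cell_field_config(
        cell_geometry = "round", n_cells = 60L,
        field_shape = c(384L, 384L),
        red_green_ratio = grid$ratio[j], seed = .x)))
  }) |> dplyr::bind_rows()
}

# A biological replicate of the contact experiment is the mean over
# `fields_per_replicate` imaged volumes (one field images a handful of
# droplets; replicate-level statistics in this assay always pool several
# fields per dish).
contact_conditions <- function(grid, seed, fields_per_replicate = 3L) {
  purrr::map(seq_len(nrow(grid)), function(j) {
    base <- rep_seeds(seed, j)
    tidyr::expand_grid(replicate = 1:3,
                       field = seq_len(fields_per_replicate)) |>
      dplyr::mutate(
        condition = grid$condition[j],
        seed = base[.data$replicate] + 100L * (.data$field - 1L),
        cfg = purrr::map(.data$seed, ~ contact_scene_config(
          target_contact_fraction = grid$contact_fraction[j], seed = .x))) |>
      dplyr::select("condition", "replicate", "field", "seed", "cfg")
  }) |> dplyr::bind_rows()
}

#' Synthetic experiment presets encoding the published fold effects
#'
#' Each preset bundles 3 replicate generator configs per condition
#' (replicate seeds `seed`, `seed+1`, `seed+2`; condition blocks offset by
#' 10) whose planted parameters encode the published effects:
#'
#' * `dual_fever_40` — PI-positive fractions 0.06 (37C) vs 0.66 (40C):
#'   planted 11-fold synergy increase of the dual histone + LL-37
#'   treatment at febrile temperature.
#' * `dual_fever_385` — fractions 0.06 vs 0.42: the 7-fold increase at the
#'   moderate febrile temperature.
#' * `ll37_mito_fold` — JC-1 damage 0.30 (37C) vs 0.51 (40C) and PI
#'   fractions 0.06 vs 0.102: the matched 1.7-fold increases in
#'   mitochondrial damage and PI uptake for LL-37.
#' * `ohcath_mito_fold` — JC-1 damage 0.30 vs 0.36: the 1.2-fold increase
#'   for the snake AMP OH-CATH.
#' * `ll37_activity_37` — treated/untreated JC-1 ratio 0.6 at 37C and 1.0
#'   at 35C.
#' * `contact_glucose_temp` — planted droplet contact fractions 0.6 at
#'   (low glucose, 37C) and 0.15 at (high glucose, 37C) and (low glucose,
#'   40C): contact drops at febrile temperature to the high-glucose level.
#'
#' @param name One of `dual_fever_40`, `dual_fever_385`, `ll37_mito_fold`,
#'   `ohcath_mito_fold`, `ll37_activity_37`, `contact_glucose_temp`.
#' @param seed Master seed from which replicate seeds are derived.
#' @return List of class `amp_preset`: `name`, `seed`, `kind`, `planted`
#'   (the planted effect value(s)), and one or more condition tibbles
#'   (`condition`, `replicate`, `seed`, `cfg`).
#' @export
preset <- function(name, seed = 1L) {
  if (!name %in% PRESET_NAMES) {
    stop("unknown preset \"", name, "\"; available: ",
         paste(PRESET_NAMES, collapse = ", "), call. = FALSE)
  }
  seed <- as.integer(seed)
  out <- switch(
    name,
    dual_fever_40 = list(
      kind = "pi",
      planted = list(pi_fold = 11),
      pi = pi_conditions(c("37C", "40C"),
                         PI_BASELINE_FRACTION * c(1, 11), seed)),
    dual_fever_385 = list(
      kind = "pi",
      planted = list(pi_fold = 7),
      pi = pi_conditions(c("37C", "38.5C"),
                         PI_BASELINE_FRACTION * c(1, 7), seed)),
    ll37_mito_fold = list(
      kind = "jc1+pi",
      planted = list(damage_fold = 1.7, pi_fold = 1.7,
                     damage_37 = MITO_DAMAGE_37),
      jc1 = jc1_conditions(tibble::tibble(
        condition = c("37C_untreated", "37C_treated",
                      "40C_untreated", "40C_treated"),
        ratio = JC1_UNTREATED_RATIO *
          c(1, 1 - MITO_DAMAGE_37, 1, 1 - 1.7 * MITO_DAMAGE_37)), seed),
      # baseline 0.20 so that both planted counts are integers out of 100
      # cells (0.20 -> 20, 0.34 -> 34: an exact 1.7-fold)
      pi = pi_conditions(c("37C", "40C"), 0.20 * c(1, 1.7), seed + 500L)),
    ohcath_mito_fold = list(
      kind = "jc1",
      planted = list(damage_fold = 1.2, damage_37 = MITO_DAMAGE_37),
      jc1 = jc1_conditions(tibble::tibble(
        condition = c("37C_untreated", "37C_treated",
                      "40C_untreated", "40C_treated"),
        ratio = JC1_UNTREATED_RATIO *
          c(1, 1 - MITO_DAMAGE_37, 1, 1 - 1.2 * MITO_DAMAGE_37)), seed)),
    ll37_activity_37 = list(
      kind = "jc1",
      planted = list(activity_quotient_37 = 0.6, activity_quotient_35 = 1.0),
      jc1 = jc1_conditions(tibble::tibble(
        condition = c("35C_untreated", "35C_treated",
                      "37C_untreated", "37C_treated"),
        ratio = JC1_UNTREATED_RATIO * c(1, 1, 1, 0.6)), seed)),
    contact_glucose_temp = list(
      kind = "contact",
      planted = list(contact_fraction_high = 0.6,
                     contact_fraction_low = 0.15),
      contact = contact_conditions(tibble::tibble(
        condition = c("lowglu_37C", "highglu_37C", "lowglu_40C"),
        contact_fraction = c(0.6, 0.15, 0.15)), seed))
  )
  structure(c(list(name = name, seed = seed), out), class = "amp_preset")
}

#' @export
print.amp_preset <- function(x, ...) {
  cat(sprintf("<amp_preset> %s (kind %s, seed %d)\n", x$name, x$kind, x$seed))
  cat("planted:", paste(names(x$planted), unlist(x$planted), sep = " = ",
                        collapse = ", "), "\n")
  invisible(x)
}

# ---- end-to-end pipelines on preset condition tables -------------------

#' Run the PI pipeline on a table of bacterial-field conditions
#'
#' For each replicate: generate the field, segment on phase contrast,
#' measure background-subtracted per-cell PI intensity; then classify
#' positives with a single Otsu cutoff pooled across *all* conditions of
#' the experiment.
#'
#' @param conds Tibble (`condition`, `replicate`, `cfg`) as produced by
#'   [preset()].
#' @param config Pipeline parameters ([default_config()]).
#' @return Per-cell tibble with `condition`, `replicate`, intensities and
#'   `positive` flags.
#' @export
run_pi_pipeline <- function(conds, config = default_config()) {
  config <- validate_config(config)
  cells <- purrr::pmap(conds, function(condition, replicate, cfg, ...) {
    fld <- make_bacteria_field(cfg)
    cc <- segment_cells(fld$phase, "rod",
                        min_area = config$min_cell_area_px,
                        max_area = config$max_cell_area_px)
    cc <- per_cell_intensity(cc, fld$pi)
    cc$condition <- condition
    cc$replicate <- replicate
    tibble::as_tibble(cc)
  }) |> dplyr::bind_rows()
  classify_positive(cells, rule = config$pi_positive_rule,
                    k_sigma = config$k_sigma)
}

#' Run the JC-1 pipeline on a table of macrophage-field conditions
#'
#' Generates each field, segments on the green channel (round geometry),
#' and measures per-cell background-subtracted red/green ratios.
#'
#' @inheritParams run_pi_pipeline
#' @return Per-cell tibble with `condition`, `replicate`, `ratio`.
#' @export
run_jc1_pipeline <- function(conds, config = default_config()) {
  config <- validate_config(config)
  purrr::pmap(conds, function(condition, replicate, cfg, ...) {
    fld <- make_jc1_field(cfg)
    cc <- segment_cells(fld$green, "round",
                        min_area = config$min_cell_area_px,
                        max_area = config$max_cell_area_px)
    cc <- jc1_ratio(cc, fld$red, fld$green, green_floor = config$green_floor)
    cc$condition <- condition
    cc$replicate <- replicate
    tibble::as_tibble(cc)
  }) |> dplyr::bind_rows()
}

#' Run the contact pipeline on a table of 3D scene conditions
#'
#' Generates each scene and runs the full contact quantification
#' (preprocess, segment, face-contact area) on the noisy channels.
#'
#' @inheritParams run_pi_pipeline
#' @return Tibble with one row per imaged field: `condition`, `replicate`,
#'   `field`, contact metrics, and the ground-truth `true_contact_ratio`.
#' @export
run_contact_pipeline <- function(conds, config = default_config()) {
  config <- validate_config(config)
  purrr::pmap(conds, function(condition, replicate, cfg, ...) {
    dots <- list(...)
    field <- dots$field %||% 1L
    scn <- make_contact_volume(cfg)
    res <- contact_channels(scn$mito, scn$ld, config,
                            source = sprintf("%s_rep%d_field%d", condition,
                                             replicate, field))
    res$condition <- condition
    res$replicate <- replicate
    res$field <- field
    res$true_contact_ratio <- scn$truth$contact$contact_ratio
    res
  }) |> dplyr::bind_rows()
}

# JC-1 mitochondrial damage per temperature with replicate pairing:
# damage_k = (untreated_k - treated_k) / untreated_k on replicate mean
# ratios. Returns a condition_summary over the per-replicate damages.
damage_summary <- function(jc1_cells, temps) {
  per_rep <- jc1_cells |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(ratio = mean(.data$ratio, na.rm = TRUE),
                     n = sum(!is.na(.data$ratio)), .groups = "drop") |>
    tidyr::separate("condition", into = c("temp", "treatment"), sep = "_")
  dmg <- per_rep |>
    tidyr::pivot_wider(names_from = "treatment", values_from = c("ratio", "n")) |>
    dplyr::mutate(value = (.data$ratio_untreated - .data$ratio_treated) /
                    .data$ratio_untreated) |>
    dplyr::filter(.data$temp %in% temps)
  out <- dmg |>
    dplyr::group_by(condition = .data$temp) |>
    dplyr::summarise(grand_mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     n_replicates = dplyr::n(),
                     n_cells_total = sum(.data$n_untreated + .data$n_treated),
                     replicate_values = list(.data$value),
                     .groups = "drop")
  class(out) <- c("condition_summary", class(out))
  out
}

#' Recover a preset's planted effect with the full pipelines
#'
#' Generates every replicate field of the preset, runs the corresponding
#' quantification pipeline end to end, and returns the estimated effect
#' size(s) with propagated standard errors next to the planted values.
#'
#' @param name Preset name (see [preset()]) or an `amp_preset`.
#' @param seed Master seed (ignored when an `amp_preset` is given).
#' @param config Pipeline parameters.
#' @return Tibble: `preset`, `statistic`, `estimate`, `se`, `planted`, `n`.
#' @export
recover_preset <- function(name, seed = 1L, config = default_config()) {
  p <- if (inherits(name, "amp_preset")) name else preset(name, seed)
  config <- validate_config(config)
  row <- function(statistic, estimate, se, planted, n) {
    tibble::tibble(preset = p$name, statistic = statistic,
                   estimate = estimate, se = se, planted = planted, n = n)
  }
  pi_fold <- function(cells, num, den) {
    summ <- summarize_replicates(cells, as.numeric(positive),
                                 condition, replicate)
    fc <- fold_change(summ, condition_a = num, condition_b = den)
    list(fold = fc, n = nrow(cells))
  }
  switch(
    p$kind,
    pi = {
      cells <- run_pi_pipeline(p$pi, config)
      hi <- setdiff(unique(p$pi$condition), "37C")
      pf <- pi_fold(cells, hi, "37C")
      row("pi_fold", pf$fold$fold, pf$fold$se_fold, p$planted$pi_fold, pf$n)
    },
    `jc1+pi` = {
      jc <- run_jc1_pipeline(p$jc1, config)
      ds <- damage_summary(jc, c("37C", "40C"))
      dfc <- fold_change(ds, condition_a = "40C", condition_b = "37C")
      cells <- run_pi_pipeline(p$pi, config)
      pf <- pi_fold(cells, "40C", "37C")
      dplyr::bind_rows(
        row("damage_fold", dfc$fold, dfc$se_fold, p$planted$damage_fold,
            sum(ds$n_cells_total)),
        row("pi_fold", pf$fold$fold, pf$fold$se_fold, p$planted$pi_fold,
            pf$n))
    },
    jc1 = {
      jc <- run_jc1_pipeline(p$jc1, config)
      if (p$name == "ohcath_mito_fold") {
        ds <- damage_summary(jc, c("37C", "40C"))
        dfc <- fold_change(ds, condition_a = "40C", condition_b = "37C")
        row("damage_fold", dfc$fold, dfc$se_fold, p$planted$damage_fold,
            sum(ds$n_cells_total))
      } else {
        summ <- summarize_replicates(jc, ratio, condition, replicate)
        q37 <- fold_change(summ, condition_a = "37C_treated",
                           condition_b = "37C_untreated")
        q35 <- fold_change(summ, condition_a = "35C_treated",
                           condition_b = "35C_untreated")
        tt35 <- welch_ttest(
          summ$replicate_values[[which(summ$condition == "35C_treated")]],
          summ$replicate_values[[which(summ$condition == "35C_untreated")]])
        dplyr::bind_rows(
          row("activity_quotient_37", q37$fold, q37$se_fold,
              p$planted$activity_quotient_37, sum(summ$n_cells_total)),
          row("activity_quotient_35", q35$fold, q35$se_fold,
              p$planted$activity_quotient_35, sum(summ$n_cells_total)),
          row("p_treated_vs_untreated_35", tt35$p_two_sided, NA_real_,
              NA_real_, tt35$n_x + tt35$n_y))
      }
    },
    contact = {
      res <- run_contact_pipeline(p$contact, config)
      # replicate statistic = mean contact ratio over the imaged fields
      tbl <- res |>
        dplyr::group_by(condition = .data$condition,
                        replicate = .data$replicate) |>
        dplyr::summarise(value = mean(.data$contact_ratio),
                         .groups = "drop")
      cmp <- compare_conditions(tbl, list(c("lowglu_37C", "highglu_37C"),
                                          c("lowglu_37C", "lowglu_40C")))
      means <- tbl |> dplyr::group_by(.data$condition) |>
        dplyr::summarise(m = mean(.data$value),
                         se = stats::sd(.data$value) / sqrt(dplyr::n()),
                         .groups = "drop")
      dplyr::bind_rows(
        purrr::map2(means$condition, seq_len(nrow(means)), function(cond, i) {
          row(paste0("contact_ratio_", cond), means$m[i], means$se[i],
              NA_real_, nrow(res))
        }) |> dplyr::bind_rows(),
        row("p_lowglu37_vs_highglu37", cmp$p_value[1], NA_real_, NA_real_,
            nrow(res)),
        row("p_lowglu37_vs_lowglu40", cmp$p_value[2], NA_real_, NA_real_,
            nrow(res)))
    })
}

#' Recover every preset's planted effects
#'
#' Runs [recover_preset()] for each preset: the one-call reproduction of
#' the package's planted-effect study. Deterministic for a fixed seed.
#'
#' @param seed Master seed.
#' @param presets Preset names (default: all).
#' @param config Pipeline parameters.
#' @return Combined tibble of recovered effect sizes.
#' @export
reproduce_effects <- function(seed = 1L, presets = PRESET_NAMES,
                              config = default_config()) {
  purrr::map(presets, recover_preset, seed = seed, config = config) |>
    dplyr::bind_rows()
}
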