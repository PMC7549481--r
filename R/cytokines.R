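# LLOQ-censored cytokine analysis: half-LLOQ imputation, baseline
# disease-vs-control comparison of log concentrations, and per-arm
# change-from-baseline tests against placebo.

#' Impute left-censored cytokine concentrations to half the LLOQ
#'
#' Measurements flagged `below_lloq` get concentration `0.5 * lloq`;
#' detectable measurements are untouched. Idempotent.
#'
#' @param measurements Cytokine tibble (analyte, patient_id, visit_week,
#'   concentration, lloq, below_lloq).
#' @return Same tibble with imputed concentrations.
#' @export
impute_lloq <- function(measurements) {
  check_columns(measurements,
                c("analyte", "patient_id", "visit_week", "concentration",
                  "lloq", "below_lloq"), "cytokine table")
  if (any(is.na(measurements$lloq)) || any(measurements$lloq <= 0)) {
    stop_jak("every measurement needs a positive, non-missing LLOQ")
  }
  dplyr::mutate(measurements, concentration = ifelse(
    .data$below_lloq, 0.5 * .data$lloq, .data$concentration
  ))
}

#' Baseline cytokine comparison: SLE versus healthy controls
#'
#' At week 0, reports the fraction of detectable (not below-LLOQ) samples
#' per group and a two-sided Mann-Whitney U test of log-transformed,
#' LLOQ-imputed concentrations in SLE (all arms pooled) versus healthy
#' controls. When every sample in both groups is censored the test is
#' degenerate and p is reported as 1 with a flag.
#'
#' @param measurements Cytokine tibble.
#' @param meta Sample metadata (patients to groups).
#' @param analyte Analyte name.
#' @return One-row tibble: analyte, n_sle, n_healthy,
#'   frac_detectable_sle, frac_detectable_healthy, p, degenerate.
#' @export
baseline_group_compare <- function(measurements, meta, analyte) {
  mm <- dplyr::filter(measurements, .data$analyte == !!analyte,
                      .data$visit_week == 0)
  if (nrow(mm) == 0) stop_jak("analyte not found at baseline: ", analyte)
  groups <- meta |> dplyr::distinct(.data$patient_id, .data$group)
  mm <- dplyr::inner_join(impute_lloq(mm), groups, by = "patient_id") |>
    dplyr::mutate(sle = .data$group != "healthy")
  if (!any(mm$sle) || !any(!mm$sle)) {
    stop_jak("both SLE and healthy baseline samples are required")
  }
  det <- mm |>
    dplyr::group_by(.data$sle) |>
    dplyr::summarise(n = dplyr::n(),
                     frac_detectable = mean(!.data$below_lloq),
                     .groups = "drop")
  degenerate <- all(mm$below_lloq)
  p <- if (degenerate) 1 else suppressWarnings(
    stats::wilcox.test(log(mm$concentration[mm$sle]),
                       log(mm$concentration[!mm$sle]))$p.value
  )
  tibble::tibble(
    analyte = analyte,
    n_sle = det$n[det$sle], n_healthy = det$n[!det$sle],
    frac_detectable_sle = det$frac_detectable[det$sle],
    frac_detectable_healthy = det$frac_detectable[!det$sle],
    p = p, degenerate = degenerate
  )
}

#' Change-from-baseline cytokine analysis versus placebo
#'
#' Per patient with both a baseline and a target-week measurement, the
#' delta is `log(conc_week) - log(conc_baseline)` after half-LLOQ
#' imputation (natural log). Patients censored at BOTH visits are excluded
#' and counted; patients censored at exactly one visit are retained with
#' the imputed value. Each active arm's deltas are compared with placebo
#' deltas by a two-sided Mann-Whitney U test (Welch's t available).
#'
#' @param measurements Cytokine tibble.
#' @param meta Sample metadata (patients to arms).
#' @param analyte Analyte name.
#' @param week Target post-baseline week (default 12).
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @return Tibble analyte, arm, week, n, n_excluded, median_delta, p
#'   (p is NA for the placebo reference row).
#' @export
delta_vs_placebo <- function(measurements, meta, analyte, week = 12,
                             test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  mm <- dplyr::filter(measurements, .data$analyte == !!analyte,
                      .data$visit_week %in% c(0, week))
  if (nrow(mm) == 0) stop_jak("analyte not found: ", analyte)
  arms <- meta |>
    dplyr::filter(.data$group != "healthy") |>
    dplyr::distinct(.data$patient_id, .data$group)
  wide <- impute_lloq(mm) |>
    dplyr::inner_join(arms, by = "patient_id") |>
    dplyr::select("patient_id", "group", "visit_week", "concentration",
                  "below_lloq") |>
    tidyr::pivot_wider(names_from = "visit_week",
                       values_from = c("concentration", "below_lloq")) |>
    dplyr::filter(!is.na(.data[[paste0("concentration_", 0)]]),
                  !is.na(.data[[paste0("concentration_", week)]]))
  wide$cens_both <- wide[[paste0("below_lloq_", 0)]] &
    wide[[paste0("below_lloq_", week)]]
  excl <- wide |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_excluded = sum(.data$cens_both), .groups = "drop")
  kept <- wide[!wide$cens_both, ]
  kept$delta <- log(kept[[paste0("concentration_", week)]]) -
    log(kept[[paste0("concentration_", 0)]])
  n_by_arm <- table(factor(kept$group, levels = trial_arms()))
  if (any(n_by_arm == 0)) {
    stop_jak("arm(s) with no eligible patients for ", analyte, ": ",
             paste(names(n_by_arm)[n_by_arm == 0], collapse = ", "))
  }
  placebo_delta <- kept$delta[kept$group == "placebo"]
  purrr::map(trial_arms(), function(arm) {
    d <- kept$delta[kept$group == arm]
    p <- if (arm == "placebo") NA_real_ else if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(d, placebo_delta)$p.value)
    } else {
      stats::t.test(d, placebo_delta)$p.value
    }
    tibble::tibble(analyte = analyte, arm = arm, week = week,
                   n = length(d),
                   n_excluded = excl$n_excluded[match(arm, excl$group)] %||% 0L,
                   median_delta = stats::median(d), p = p)
  }) |> dplyr::bind_rows()
}
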