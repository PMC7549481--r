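# Diagnostic figures. Thin ggplot2 wrappers over the result tibbles; all
# return ggplot objects so callers can restyle them.

#' Spaghetti plot of SLEDAI-2K changes by signature group
#'
#' Thin lines per patient, thick LOESS-smoothed group averages
#' (signature-high in red, signature-low in blue), the display used to
#' read the stratified treatment response.
#'
#' @param calls Signature calls.
#' @param trajectories Long SLEDAI-2K tibble.
#' @param meta Optional metadata; with `arm`, restricts to one arm.
#' @param arm Optional arm label.
#' @param span LOESS span.
#' @return A ggplot.
#' @export
plot_signature_trajectories <- function(calls, trajectories, meta = NULL,
                                        arm = NULL, span = 0.75) {
  if (!is.null(arm)) {
    if (is.null(meta)) stop_jak("meta is required to filter by arm")
    pats <- unique(meta$patient_id[meta$group == arm])
    calls <- dplyr::filter(calls, .data$patient_id %in% pats)
    trajectories <- dplyr::filter(trajectories, .data$patient_id %in% pats)
  }
  use <- dplyr::filter(calls, .data$status %in% c("high", "low"))
  tr <- trajectories |>
    dplyr::filter(.data$patient_id %in% use$patient_id) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(change = .data$sledai2k -
                    .data$sledai2k[.data$visit_week == 0]) |>
    dplyr::ungroup() |>
    dplyr::left_join(use[c("patient_id", "status")], by = "patient_id")
  smooth <- loess_group_trajectories(calls, trajectories, span = span)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$visit_week, y = .data$change,
                                   colour = .data$status)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       alpha = 0.3, linewidth = 0.3) +
    ggplot2::geom_line(data = smooth,
                       ggplot2::aes(y = .data$mean_change, group = .data$status),
                       linewidth = 1.4) +
    ggplot2::scale_colour_manual(values = c(high = "#c0392b", low = "#2e6da4")) +
    ggplot2::labs(x = "Week", y = "SLEDAI-2K change from baseline",
                  colour = "Signature", title = arm %||% NULL) +
    ggplot2::theme_minimal()
}

#' Null-distribution plot for a Monte Carlo trajectory test
#'
#' @param object A `nof1_perm` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nof1_perm
#' @export
autoplot.nof1_perm <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$null_stats),
                  ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "#c0392b", linewidth = 1) +
    ggplot2::labs(
      x = "null statistic (mean low - high SLEDAI-2K change)",
      y = "count",
      title = sprintf("%s: p = %.4g (B = %d)", object$arm, object$p_value,
                      object$B)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap-style summary of pharmacodynamic effects
#'
#' Genes by arm:week tiles filled with the estimated log2 PD effect; the
#' dose ordering (4 mg at least as strong as 2 mg) is visible at a glance.
#'
#' @param pd Output of [pd_effects()].
#' @param genes Optional gene ordering/subset.
#' @return A ggplot.
#' @export
plot_pd_heatmap <- function(pd, genes = NULL) {
  if (!is.null(genes)) {
    pd <- dplyr::filter(pd, .data$feature_id %in% genes)
    pd$feature_id <- factor(pd$feature_id, levels = rev(genes))
  }
  pd$cell <- paste0(pd$arm, " w", pd$week)
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$cell, y = .data$feature_id,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 PD effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Ranked baseline fold-difference plot
#'
#' @param de Output of [baseline_de()].
#' @param n Number of top elevated genes to show.
#' @return A ggplot.
#' @export
plot_baseline_ranking <- function(de, n = 50) {
  top <- top_genes(de, n = n, direction = "elevated")
  top$feature_id <- factor(top$feature_id, levels = rev(top$feature_id))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$log2_fold_difference,
                                    y = .data$feature_id)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::labs(x = "log2 fold difference (SLE - healthy)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Baseline cytokine boxplots with LLOQ lines
#'
#' Log-scale concentrations by group with the analyte LLOQ as a dashed
#' line; censored values appear at the imputed half-LLOQ.
#'
#' @param measurements Cytokine tibble.
#' @param meta Sample metadata.
#' @return A ggplot.
#' @export
plot_cytokine_baseline <- function(measurements, meta) {
  groups <- meta |> dplyr::distinct(.data$patient_id, .data$group)
  d <- impute_lloq(dplyr::filter(measurements, .data$visit_week == 0)) |>
    dplyr::inner_join(groups, by = "patient_id") |>
    dplyr::mutate(cohort = ifelse(.data$group == "healthy", "healthy", "SLE"))
  lloqs <- dplyr::distinct(d, .data$analyte, .data$lloq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cohort, y = .data$concentration)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(data = lloqs, ggplot2::aes(yintercept = .data$lloq),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "concentration (pg/mL)") +
    ggplot2::theme_minimal()
}
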