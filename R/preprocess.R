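# Probe-level preprocessing: background correction, quantile normalization
# and robust summarization of probes to transcript clusters (TCs) via a
# two-way sample + probe model fit by Huber IRLS (MASS::rlm). Probe tables
# share the wide layout of expression tables, with `probe_id` in place of
# `feature_id`; intensities are linear scale until log2 is taken just
# before summarization.

probe_values <- function(probes) {
  check_columns(probes, "probe_id", "probe table")
  m <- as.matrix(probes[setdiff(names(probes), "probe_id")])
  rownames(m) <- probes$probe_id
  if (!is.numeric(m)) stop_jak("probe intensities must be numeric")
  m
}

probe_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)), tibble::as_tibble(m))
}

#' Background-correct probe intensities
#'
#' The default `quantile_floor` method subtracts a per-sample lower-quantile
#' floor from every intensity and clamps the result to a small positive
#' epsilon so the subsequent log2 is defined. The `identity` method returns
#' the input unchanged (synthetic intensities carry no optical background).
#'
#' @param probes Wide probe tibble of positive linear-scale intensities.
#' @param method `"quantile_floor"` or `"identity"`.
#' @param floor_quantile Per-sample quantile used as the background floor.
#' @param eps Positive clamp applied after subtraction.
#' @return Background-corrected probe tibble.
#' @export
background_correct <- function(probes, method = c("quantile_floor", "identity"),
                               floor_quantile = 0.01, eps = 0.5) {
  method <- match.arg(method)
  if (method == "identity") return(probes)
  m <- probe_values(probes)
  if (any(m <= 0)) stop_jak("intensities must be strictly positive")
  floors <- apply(m, 2, stats::quantile, probs = floor_quantile, names = FALSE)
  m <- sweep(m, 2, floors, "-")
  m[m < eps] <- eps
  probe_tibble(m)
}

#' Quantile-normalize probe intensities across samples
#'
#' After normalization every sample's sorted value vector equals the
#' across-sample mean of sorted vectors; within-sample ranks are preserved
#' and ties receive the mean of their tied target quantiles.
#'
#' @param probes Wide probe tibble (>= 2 samples).
#' @return Quantile-normalized probe tibble.
#' @export
quantile_normalize <- function(probes) {
  m <- probe_values(probes)
  if (ncol(m) < 2) stop_jak("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  probe_tibble(out)
}

# Robust two-way fit for one TC: log2 y_ps = mu + probe_p + sample_s + eps,
# probe effects sum to zero, so the per-sample coefficient of the
# no-intercept sample design IS mu + sample effect — the TC summary.
fit_tc_rlm <- function(y, huber_k, max_iter, tol) {
  np <- nrow(y); ns <- ncol(y)
  sample_f <- factor(rep(colnames(y), each = np), levels = colnames(y))
  probe_f <- factor(rep(rownames(y), times = ns), levels = rownames(y))
  x_sample <- stats::model.matrix(~ 0 + sample_f)
  x_probe <- stats::model.matrix(~ probe_f,
                                 contrasts.arg = list(probe_f = "contr.sum"))[, -1, drop = FALSE]
  x <- cbind(x_sample, x_probe)
  fit <- suppressWarnings(MASS::rlm(
    x, as.vector(y), psi = MASS::psi.huber, k = huber_k,
    scale.est = "MAD", maxit = max_iter, acc = tol
  ))
  stats::coef(fit)[seq_len(ns)]
}

#' Summarize probe-level data to transcript clusters
#'
#' For each TC, fits `log2(y) = mu + probe + sample + noise` by iteratively
#' reweighted least squares with Huber weights (MAD scale, re-estimated each
#' iteration), probe effects constrained to sum to zero. The returned TC
#' value per sample is `mu + sample effect`. A TC with a single probe passes
#' that probe's values through (reported via a message).
#'
#' @param probes Wide probe tibble of log2-scale, normalized intensities.
#' @param probe_map Tibble `probe_id`, `tc_id` mapping every probe to
#'   exactly one transcript cluster.
#' @param huber_k Huber tuning constant on standardized residuals; the
#'   default 1.345 is the standard 95%-efficiency choice. Very large values
#'   recover the ordinary least-squares fit.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return Wide expression tibble at TC level (log2 scale).
#' @export
summarize_to_tc <- function(probes, probe_map, huber_k = 1.345,
                            max_iter = 50, tol = 1e-8) {
  check_columns(probe_map, c("probe_id", "tc_id"), "probe map")
  m <- probe_values(probes)
  if (ncol(m) < 2) stop_jak("summarization needs >= 2 samples")
  if (anyDuplicated(probe_map$probe_id)) {
    stop_jak("probe map assigns some probe to more than one TC")
  }
  missing <- setdiff(rownames(m), probe_map$probe_id)
  if (length(missing) > 0) {
    stop_jak("probes missing from map: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  tc_of <- stats::setNames(probe_map$tc_id, probe_map$probe_id)
  groups <- split(rownames(m), tc_of[rownames(m)])
  singletons <- names(groups)[lengths(groups) == 1]
  if (length(singletons) > 0) {
    rlang::inform(sprintf(
      "%d TC(s) with a single probe passed through unchanged", length(singletons)
    ))
  }
  summaries <- purrr::map(groups, function(pids) {
    y <- m[pids, , drop = FALSE]
    if (nrow(y) == 1) return(y[1, ])
    fit_tc_rlm(y, huber_k, max_iter, tol)
  })
  out <- do.call(rbind, summaries)
  colnames(out) <- colnames(m)
  expr_tibble(out[order(rownames(out)), , drop = FALSE])
}

#' Full probe-to-TC preprocessing pipeline
#'
#' Background correction, quantile normalization, log2 transform and robust
#' summarization, in that order — the standard robust multiarray-average
#' style chain with the summarization step done by robust regression.
#'
#' @param probes Wide probe tibble of linear-scale intensities.
#' @param probe_map Probe-to-TC map.
#' @param background Background method passed to [background_correct()].
#' @param ... Passed to [summarize_to_tc()].
#' @return Wide expression tibble at TC level (log2 scale).
#' @export
preprocess_probes <- function(probes, probe_map,
                              background = c("quantile_floor", "identity"), ...) {
  probes |>
    background_correct(method = match.arg(background)) |>
    quantile_normalize() |>
    (\(p) probe_tibble(log2(probe_values(p))))() |>
    summarize_to_tc(probe_map, ...)
}
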