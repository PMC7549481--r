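# N-of-1 single-subject signature stratification and the Monte Carlo
# trajectory test: each patient's baseline expression of a gene signature
# is compared with the cohort mean by a one-sample Wilcoxon signed-rank
# test over per-gene differences; signature-high and -low strata are then
# compared on their SLEDAI-2K change trajectories with a label-permutation
# Monte Carlo test. Also houses the percentile-based STAT1/STAT2
# co-elevation classification and a direct hypergeometric Fisher test.

#' Call per-patient signature status against the cohort mean
#'
#' For each patient, forms per-gene differences `d_g = x_{patient,g} -
#' mean_over_patients(x_{.,g})` over the signature genes and tests them
#' against zero with a two-sided Wilcoxon test. Patients with `p < alpha`
#' are called `high` (positive median difference) or `low` (negative);
#' everyone else is `neither`. Exact zero differences are dropped per the
#' signed-rank convention (reported via a message).
#'
#' @param expr_baseline Wide expression tibble of baseline samples, one
#'   column per patient (or per baseline sample; see `meta`).
#' @param signature Character vector of signature gene ids (>= 5 must
#'   resolve against the matrix; unresolved genes raise a warning naming
#'   them).
#' @param alpha Significance level for the call.
#' @param method `"signed_rank"` (one-sample test on paired differences,
#'   the default) or `"rank_sum"` (two-sample test of the patient's
#'   signature values against the per-gene cohort means).
#' @param leave_one_out If `TRUE`, the cohort mean for each patient
#'   excludes that patient.
#' @param meta Optional metadata used to map baseline sample columns to
#'   patient ids.
#' @return Tibble patient_id, signature_n_genes, median_delta, wilcoxon_p,
#'   status.
#' @export
call_signature_status <- function(expr_baseline, signature, alpha = 0.05,
                                  method = c("signed_rank", "rank_sum"),
                                  leave_one_out = FALSE, meta = NULL) {
  method <- match.arg(method)
  m <- expr_matrix(expr_baseline)
  if (!is.null(meta)) {
    map <- stats::setNames(meta$patient_id, meta$sample_id)
    keep <- colnames(m) %in% names(map)
    m <- m[, keep, drop = FALSE]
    colnames(m) <- map[colnames(m)]
  }
  unresolved <- setdiff(signature, rownames(m))
  if (length(unresolved) > 0) {
    rlang::warn(paste0("signature gene(s) not in expression matrix: ",
                       paste(unresolved, collapse = ", ")))
  }
  genes <- intersect(signature, rownames(m))
  if (length(genes) < 5) {
    stop_jak(sprintf("need >= 5 resolvable signature genes, have %d",
                     length(genes)))
  }
  sig <- m[genes, , drop = FALSE]
  pop_mean <- rowMeans(sig)
  n_pat <- ncol(sig)
  dropped_zeros <- 0L
  res <- purrr::map(seq_len(n_pat), function(j) {
    ref <- if (leave_one_out) rowMeans(sig[, -j, drop = FALSE]) else pop_mean
    d <- sig[, j] - ref
    med <- stats::median(d)
    p <- if (method == "signed_rank") {
      dnz <- d[d != 0]
      dropped_zeros <<- dropped_zeros + (length(d) - length(dnz))
      if (length(dnz) == 0) 1
      else suppressWarnings(stats::wilcox.test(dnz, mu = 0)$p.value)
    } else {
      suppressWarnings(stats::wilcox.test(sig[, j], ref)$p.value)
    }
    status <- if (p < alpha && med > 0) "high"
      else if (p < alpha && med < 0) "low"
      else "neither"
    tibble::tibble(patient_id = colnames(sig)[j],
                   signature_n_genes = length(genes),
                   median_delta = med, wilcoxon_p = p, status = status)
  }) |> dplyr::bind_rows()
  if (dropped_zeros > 0) {
    rlang::inform(sprintf("%d exact-zero difference(s) dropped across patients",
                          dropped_zeros))
  }
  res
}

# per-visit mean SLEDAI change for one label assignment; X is the
# patients x weeks change matrix, high a logical vector over rows
perm_stat <- function(X, high) {
  mh <- colMeans(X[high, , drop = FALSE], na.rm = TRUE)
  ml <- colMeans(X[!high, , drop = FALSE], na.rm = TRUE)
  mean(ml - mh)
}

#' Monte Carlo permutation test of trajectories by signature status
#'
#' Within one treatment arm, compares the average SLEDAI-2K change from
#' baseline between signature-high and signature-low patients. The observed
#' statistic is the mean over post-baseline visits of (low-group mean
#' change minus high-group mean change); each of B iterations shuffles the
#' high/low labels among the same patients (group sizes preserved) and
#' recomputes it. The one-sided p (does the high group improve more?) uses
#' the add-one convention `p = (1 + #(null >= observed)) / (B + 1)`, so
#' p is always in (0, 1].
#'
#' @param calls Signature calls as from [call_signature_status()];
#'   patients with status `neither` are excluded.
#' @param trajectories Long SLEDAI-2K tibble (patient_id, visit_week,
#'   sledai2k) including week 0.
#' @param meta Sample metadata mapping patients to arms.
#' @param arm Treatment arm to test.
#' @param B Number of Monte Carlo iterations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param direction `"high_improves"` (one-sided, default) or
#'   `"two_sided"`.
#' @return An object of class `nof1_perm` with the observed statistic, the
#'   null distribution, the p-value and per-visit group means.
#' @export
trajectory_permutation_test <- function(calls, trajectories, meta, arm,
                                        B = 10000, seed = NULL,
                                        direction = c("high_improves",
                                                      "two_sided")) {
  direction <- match.arg(direction)
  if (B < 1) stop_jak("B must be >= 1")
  check_columns(calls, c("patient_id", "status"), "signature calls")
  validate_trajectories(trajectories)
  arm_pat <- unique(meta$patient_id[meta$group == arm])
  use <- calls |>
    dplyr::filter(.data$status %in% c("high", "low"),
                  .data$patient_id %in% arm_pat)
  n_high <- sum(use$status == "high")
  n_low <- sum(use$status == "low")
  if (n_high < 2 || n_low < 2) {
    stop_jak(sprintf(
      "arm '%s' needs >= 2 patients per signature group (high = %d, low = %d)",
      arm, n_high, n_low))
  }
  tr <- trajectories |>
    dplyr::filter(.data$patient_id %in% use$patient_id) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(change = .data$sledai2k -
                    .data$sledai2k[.data$visit_week == 0]) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$visit_week > 0)
  wide <- tr |>
    dplyr::select("patient_id", "visit_week", "change") |>
    tidyr::pivot_wider(names_from = "visit_week", values_from = "change")
  # fix patient order to the (sorted) call order so results are invariant
  # to the row order of the inputs
  use <- dplyr::arrange(use, .data$patient_id)
  wide <- wide[match(use$patient_id, wide$patient_id), ]
  X <- as.matrix(wide[-1])
  high <- use$status == "high"
  observed <- perm_stat(X, high)
  n <- nrow(X)
  complete <- !anyNA(X)

  null_stats <- with_seed_if(seed, {
    if (complete) {
      # complete data: the statistic reduces to the difference of group
      # means of per-patient visit-averaged changes
      pm <- rowMeans(X)
      tot <- sum(pm)
      vapply(seq_len(B), function(b) {
        sh <- sum(pm[sample.int(n, n_high)])
        (tot - sh) / n_low - sh / n_high
      }, numeric(1))
    } else {
      vapply(seq_len(B), function(b) {
        perm_stat(X, seq_len(n) %in% sample.int(n, n_high))
      }, numeric(1))
    }
  })
  p <- if (direction == "high_improves") {
    (1 + sum(null_stats >= observed)) / (B + 1)
  } else {
    (1 + sum(abs(null_stats) >= abs(observed))) / (B + 1)
  }
  group_means <- tr |>
    dplyr::left_join(use[c("patient_id", "status")], by = "patient_id") |>
    dplyr::group_by(.data$visit_week, .data$status) |>
    dplyr::summarise(mean_change = mean(.data$change), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "status", values_from = "mean_change",
                       names_prefix = "mean_")
  structure(list(
    observed_stat = observed, null_stats = null_stats, p_value = p,
    B = B, seed = seed, direction = direction, arm = arm,
    n_high = n_high, n_low = n_low, group_means = group_means
  ), class = "nof1_perm")
}

#' @export
print.nof1_perm <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo trajectory test (arm %s): observed %.3f, p = %.4g (B = %d, %s)\n",
    x$arm, x$observed_stat, x$p_value, x$B, x$direction))
  cat(sprintf("signature-high n = %d, signature-low n = %d\n", x$n_high, x$n_low))
  invisible(x)
}

#' @method tidy nof1_perm
#' @export
tidy.nof1_perm <- function(x, ...) {
  dplyr::mutate(x$group_means, arm = x$arm, .before = 1)
}

#' @method glance nof1_perm
#' @export
glance.nof1_perm <- function(x, ...) {
  tibble::tibble(arm = x$arm, observed_stat = x$observed_stat,
                 p_value = x$p_value, B = x$B, n_high = x$n_high,
                 n_low = x$n_low, direction = x$direction)
}

#' LOESS-smoothed group trajectories
#'
#' Locally weighted linear regression (tricube weights, degree 1) of
#' per-patient SLEDAI-2K changes on week, per signature group, evaluated on
#' a week grid. Display only — the permutation statistic never uses the
#' smoothed curves.
#'
#' @param calls Signature calls; only high/low patients are plotted.
#' @param trajectories Long SLEDAI-2K tibble.
#' @param span LOESS span in (0, 1].
#' @param grid Weeks at which to evaluate (default: a fine grid over the
#'   observed range).
#' @return Tibble status, visit_week, mean_change.
#' @export
loess_group_trajectories <- function(calls, trajectories, span = 0.75,
                                     grid = NULL) {
  if (span <= 0 || span > 1) stop_jak("span must be in (0, 1]")
  validate_trajectories(trajectories)
  use <- dplyr::filter(calls, .data$status %in% c("high", "low"))
  tr <- trajectories |>
    dplyr::filter(.data$patient_id %in% use$patient_id) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(change = .data$sledai2k -
                    .data$sledai2k[.data$visit_week == 0]) |>
    dplyr::ungroup() |>
    dplyr::left_join(use[c("patient_id", "status")], by = "patient_id")
  if (dplyr::n_distinct(tr$visit_week) < 3) {
    stop_jak("need >= 3 distinct visit weeks to smooth")
  }
  if (is.null(grid)) {
    grid <- seq(min(tr$visit_week), max(tr$visit_week), length.out = 101)
  }
  tr |>
    dplyr::group_by(.data$status) |>
    dplyr::group_modify(function(d, key) {
      fit <- stats::loess(change ~ visit_week, data = d, span = span,
                          degree = 1, family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      tibble::tibble(visit_week = grid,
                     mean_change = unname(stats::predict(fit, newdata =
                       data.frame(visit_week = grid))))
    }) |>
    dplyr::ungroup()
}

#' Percentile-based co-elevation classification
#'
#' For each gene (typically STAT1 and STAT2), the threshold is the chosen
#' empirical percentile (linear-interpolation definition) of the healthy
#' controls; an SLE patient is flagged high iff strictly above it. Returns
#' per-patient flags and the 2x2 joint contingency table.
#'
#' @param expr_sle Wide expression tibble of SLE baseline samples (one per
#'   patient).
#' @param expr_healthy Wide expression tibble of healthy controls.
#' @param genes Two gene ids (default STAT1, STAT2).
#' @param percentile Percentile of the healthy distribution (default 95).
#' @return List with `calls` (tibble patient_id, <gene>_high flags) and
#'   `table` (class `contingency_2x2`: n_both_normal, n_a_only, n_b_only,
#'   n_both_high).
#' @export
percentile_classify <- function(expr_sle, expr_healthy,
                                genes = c("STAT1", "STAT2"),
                                percentile = 95) {
  if (length(genes) != 2) stop_jak("exactly two genes required")
  ms <- expr_matrix(expr_sle)
  mh <- expr_matrix(expr_healthy)
  for (g in genes) {
    if (!g %in% rownames(ms)) stop_jak("gene absent from SLE matrix: ", g)
    if (!g %in% rownames(mh)) stop_jak("gene absent from healthy matrix: ", g)
  }
  if (ncol(mh) < 20) {
    rlang::warn(sprintf(
      "only %d healthy controls; percentile threshold will be unstable",
      ncol(mh)))
  }
  thr <- vapply(genes, function(g) {
    stats::quantile(mh[g, ], probs = percentile / 100, names = FALSE, type = 7)
  }, numeric(1))
  a_high <- ms[genes[1], ] > thr[1]
  b_high <- ms[genes[2], ] > thr[2]
  calls <- tibble::tibble(patient_id = colnames(ms))
  calls[[paste0(genes[1], "_high")]] <- unname(a_high)
  calls[[paste0(genes[2], "_high")]] <- unname(b_high)
  tab <- contingency_2x2(
    n_both_normal = sum(!a_high & !b_high),
    n_a_only = sum(a_high & !b_high),
    n_b_only = sum(!a_high & b_high),
    n_both_high = sum(a_high & b_high),
    genes = genes
  )
  list(calls = calls, table = tab, thresholds = thr)
}

#' Construct a 2x2 joint-status contingency table
#'
#' @param n_both_normal,n_a_only,n_b_only,n_both_high Non-negative integer
#'   counts of the four joint categories.
#' @param genes Optional pair of gene labels.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(n_both_normal, n_a_only, n_b_only, n_both_high,
                            genes = c("A", "B")) {
  counts <- c(n_both_normal, n_a_only, n_b_only, n_both_high)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_jak("counts must be non-negative integers")
  }
  structure(list(n_both_normal = n_both_normal, n_a_only = n_a_only,
                 n_b_only = n_b_only, n_both_high = n_both_high,
                 genes = genes), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 joint status table (%s x %s)\n", x$genes[1], x$genes[2]))
  print(matrix(c(x$n_both_normal, x$n_a_only, x$n_b_only, x$n_both_high), 2, 2,
               dimnames = list(c("A normal", "A high"),
                               c("B normal", "B high"))))
  invisible(x)
}

#' Fisher's exact test for a 2x2 joint-status table
#'
#' The odds ratio is the sample odds ratio
#' `(n_both_normal * n_both_high) / (n_a_only * n_b_only)` (infinite when a
#' denominator count is zero). The two-sided p-value sums hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's.
#'
#' @param table A `contingency_2x2`, or a length-4 vector
#'   (both_normal, a_only, b_only, both_high).
#' @return Tibble odds_ratio, p_two_sided, n.
#' @export
fisher_exact_2x2 <- function(table) {
  if (inherits(table, "contingency_2x2")) {
    cnt <- c(table$n_both_normal, table$n_a_only, table$n_b_only,
             table$n_both_high)
  } else {
    cnt <- as.numeric(table)
    if (length(cnt) != 4) stop_jak("need 4 counts")
  }
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_jak("counts must be non-negative integers")
  }
  a <- cnt[1]; b <- cnt[2]; cc <- cnt[3]; d <- cnt[4]
  # margins: rows = gene A (normal/high), cols = gene B (normal/high)
  m <- a + cc      # B-normal column total
  nn <- b + d      # B-high column total
  k <- a + b       # A-normal row total
  if (any(c(k, cc + d, m, nn) == 0)) {
    stop_jak("table has an all-zero margin")
  }
  total <- a + b + cc + d
  or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  lo <- max(0, k - nn)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  tibble::tibble(odds_ratio = or, p_two_sided = p, n = total)
}
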