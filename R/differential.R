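# Baseline SLE-vs-healthy ranking and the per-gene mixed-model repeated
# measures (MMRM) treatment-vs-placebo contrast. The MMRM is a generalized
# least squares fit (nlme::gls) with treatment, discrete time and their
# interaction as fixed effects, control covariates, and a structured
# within-patient covariance: spatial power (rho^|week_i - week_j|),
# compound symmetry or independence.

#' Benjamini-Hochberg q-values
#'
#' Step-down FDR adjustment: `q_(i) = min_{j>=i} p_(j) * m / j`, clipped at
#' 1 and mapped back to input order.
#'
#' @param p Vector of p-values in \[0, 1\] (NA allowed, propagated).
#' @return Vector of q-values, same length and order.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_jak("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Baseline disease-vs-control differential expression
#'
#' Per gene: log2 fold difference of the SLE week-0 mean over the healthy
#' mean, Welch two-sample t-test p-value, BH q-value over all genes, and a
#' rank by descending fold difference (the ordering used for "top elevated"
#' lists; ascending gives the decreased list).
#'
#' @param expr Wide expression tibble (log2 scale).
#' @param meta Sample metadata; baseline = healthy samples plus SLE samples
#'   at week 0.
#' @return Tibble feature_id, log2_fold_difference, p, q, rank (descending
#'   fold difference), sorted by rank.
#' @export
baseline_de <- function(expr, meta) {
  validate_meta(meta)
  m <- expr_matrix(expr)
  sle_samp <- meta$sample_id[meta$group != "healthy" & meta$visit_week == 0]
  hc_samp <- meta$sample_id[meta$group == "healthy"]
  sle_samp <- intersect(sle_samp, colnames(m))
  hc_samp <- intersect(hc_samp, colnames(m))
  if (length(sle_samp) < 2 || length(hc_samp) < 2) {
    stop_jak("need >= 2 baseline SLE and >= 2 healthy samples")
  }
  x <- m[, sle_samp, drop = FALSE]
  y <- m[, hc_samp, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate zero-variance genes: identical means -> p = 1, else p = 0
  degen <- se2 == 0
  p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
  res <- tibble::tibble(
    feature_id = rownames(m),
    log2_fold_difference = unname(mx - my),
    p = unname(p),
    q = unname(bh_qvalues(p))
  ) |>
    dplyr::arrange(dplyr::desc(.data$log2_fold_difference)) |>
    dplyr::mutate(rank = dplyr::row_number())
  res
}

#' Extract a ranked top gene list from baseline results
#'
#' @param de Result of [baseline_de()].
#' @param n List length (the analyses use 50 elevated and 150 decreased).
#' @param direction `"elevated"` or `"decreased"`.
#' @param by Rank by `"fold"` difference (default) or `"significance"`.
#' @return Tibble of the top `n` rows in rank order.
#' @export
top_genes <- function(de, n = 50, direction = c("elevated", "decreased"),
                      by = c("fold", "significance")) {
  direction <- match.arg(direction)
  by <- match.arg(by)
  ord <- if (by == "fold") {
    if (direction == "elevated") order(-de$log2_fold_difference)
    else order(de$log2_fold_difference)
  } else {
    keep_sign <- if (direction == "elevated") de$log2_fold_difference > 0
                 else de$log2_fold_difference < 0
    order(!keep_sign, de$p)
  }
  utils::head(de[ord, ], n)
}

#' MMRM configuration
#'
#' @param covariance Within-patient covariance structure: `"spatial_power"`
#'   (correlation `rho^|week_i - week_j|`, the default for unequally spaced
#'   visits), `"compound_symmetry"` or `"independence"`.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param covariates Metadata columns entering as control covariates.
#' @param log_covariates Subset of `covariates` to log-transform (skewed
#'   cell counts).
#' @param max_iter,tol Optimizer settings.
#' @return A list of class `mmrm_config`.
#' @export
mmrm_config <- function(covariance = c("spatial_power", "compound_symmetry",
                                       "independence"),
                        estimation = c("REML", "ML"),
                        covariates = c("age", "sex", "leucocytes"),
                        log_covariates = "leucocytes",
                        max_iter = 100, tol = 1e-6) {
  structure(list(
    covariance = match.arg(covariance),
    estimation = match.arg(estimation),
    covariates = covariates,
    log_covariates = log_covariates,
    max_iter = max_iter,
    tol = tol
  ), class = "mmrm_config")
}

mmrm_correlation <- function(config) {
  switch(config$covariance,
    spatial_power = nlme::corCAR1(form = ~ visit_week | patient_id),
    compound_symmetry = nlme::corCompSymm(form = ~ 1 | patient_id),
    independence = NULL
  )
}

#' Fit per-gene MMRMs of log2 expression on treatment, time and covariates
#'
#' For each gene, fits `y ~ group * factor(week) + covariates` on the SLE
#' samples by generalized least squares maximizing the (RE)ML criterion,
#' with the configured within-patient covariance. Placebo and week 0 are
#' the reference levels, so each `group:week` interaction coefficient is
#' directly the treatment-vs-placebo difference in change from baseline at
#' that week — the pharmacodynamic (PD) effect. Patients missing the
#' baseline visit are excluded with a warning; genes whose fit fails to
#' converge are flagged, kept in the output and excluded from downstream
#' q-value computation.
#'
#' @param expr Wide expression tibble (log2 scale, SLE samples).
#' @param meta Sample metadata including the covariate columns.
#' @param config An [mmrm_config()].
#' @param genes Optional character vector restricting the fit to a gene
#'   subset (e.g. the top-50 baseline list).
#' @return An object of class `mmrm_fits`: per-gene coefficients,
#'   variance-covariance matrices and covariance-parameter summaries.
#' @export
fit_mmrm <- function(expr, meta, config = mmrm_config(), genes = NULL) {
  validate_meta(meta)
  m <- expr_matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) {
      stop_jak("genes absent from expression: ",
               paste(utils::head(missing, 5), collapse = ", "))
    }
    m <- m[genes, , drop = FALSE]
  }
  sle <- meta[meta$group != "healthy" & meta$sample_id %in% colnames(m), ]
  check_columns(sle, config$covariates, "sample metadata")
  with_base <- unique(sle$patient_id[sle$visit_week == 0])
  dropped <- setdiff(unique(sle$patient_id), with_base)
  if (length(dropped) > 0) {
    rlang::warn(sprintf("excluding %d patient(s) without a baseline visit: %s",
                        length(dropped),
                        paste(utils::head(dropped, 5), collapse = ", ")))
    sle <- sle[sle$patient_id %in% with_base, ]
  }
  if (nrow(sle) == 0) stop_jak("no SLE samples to fit")

  df <- tibble::as_tibble(sle)
  df$group <- factor(df$group, levels = trial_arms())
  df$week_f <- factor(df$visit_week, levels = sort(unique(df$visit_week)))
  for (cv in intersect(config$log_covariates, config$covariates)) {
    if (any(df[[cv]] <= 0)) stop_jak("covariate '", cv, "' must be positive to log")
    df[[cv]] <- log(df[[cv]])
  }
  if (any(vapply(df[config$covariates], function(x) any(is.na(x)), logical(1)))) {
    stop_jak("missing covariate values; covariates are required, not imputed")
  }
  rhs <- paste(c("group * week_f", config$covariates), collapse = " + ")
  corr <- mmrm_correlation(config)
  ctrl <- nlme::glsControl(maxIter = config$max_iter, msMaxIter = config$max_iter,
                           tolerance = config$tol, returnObject = FALSE)
  df <- df[order(df$patient_id, df$visit_week), ]

  fits <- purrr::map(rownames(m), function(g) {
    dat <- df
    dat$y <- as.numeric(m[g, dat$sample_id])
    fit <- tryCatch(
      nlme::gls(stats::as.formula(paste("y ~", rhs)), data = dat,
                correlation = corr, method = config$estimation, control = ctrl),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(list(converged = FALSE, message = conditionMessage(fit)))
    }
    cs <- if (!is.null(fit$modelStruct$corStruct)) {
      stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE)
    } else NULL
    list(
      converged = TRUE,
      coefficients = stats::coef(fit),
      vcov = stats::vcov(fit),
      sigma = fit$sigma,
      cor_param = if (is.null(cs)) NA_real_ else unname(cs[1]),
      logLik = as.numeric(stats::logLik(fit)),
      n = nrow(dat)
    )
  })
  names(fits) <- rownames(m)
  n_fail <- sum(!vapply(fits, `[[`, logical(1), "converged"))
  if (n_fail > 0) {
    rlang::warn(sprintf("%d gene(s) failed to converge; flagged and excluded from q-values",
                        n_fail))
  }
  structure(list(
    fits = fits,
    config = config,
    arms = setdiff(levels(df$group), "placebo"),
    weeks = as.numeric(setdiff(levels(df$week_f), "0"))
  ), class = "mmrm_fits")
}

#' @export
print.mmrm_fits <- function(x, ...) {
  cat(sprintf("MMRM fits for %d gene(s); covariance = %s, %s\n",
              length(x$fits), x$config$covariance, x$config$estimation))
  cat(sprintf("arms: %s; post-baseline weeks: %s\n",
              paste(x$arms, collapse = ", "), paste(x$weeks, collapse = ", ")))
  invisible(x)
}

#' Tidy per-gene MMRM coefficients
#'
#' @param x An `mmrm_fits` object.
#' @param ... Unused.
#' @return Tibble feature_id, term, estimate, std_error.
#' @method tidy mmrm_fits
#' @export
tidy.mmrm_fits <- function(x, ...) {
  purrr::imap(x$fits, function(f, g) {
    if (!isTRUE(f$converged)) return(NULL)
    tibble::tibble(feature_id = g, term = names(f$coefficients),
                   estimate = unname(f$coefficients),
                   std_error = sqrt(diag(f$vcov)))
  }) |> dplyr::bind_rows()
}

#' Per-gene MMRM fit summaries
#'
#' @param x An `mmrm_fits` object.
#' @param ... Unused.
#' @return Tibble feature_id, sigma, cor_param, logLik, n, converged.
#' @method glance mmrm_fits
#' @export
glance.mmrm_fits <- function(x, ...) {
  purrr::imap(x$fits, function(f, g) {
    if (!isTRUE(f$converged)) {
      return(tibble::tibble(feature_id = g, sigma = NA_real_,
                            cor_param = NA_real_, logLik = NA_real_,
                            n = NA_integer_, converged = FALSE))
    }
    tibble::tibble(feature_id = g, sigma = f$sigma, cor_param = f$cor_param,
                   logLik = f$logLik, n = f$n, converged = TRUE)
  }) |> dplyr::bind_rows()
}

#' Pharmacodynamic contrast for one arm and week
#'
#' The PD effect is the arm's change from baseline minus the placebo change
#' from baseline at the same week — exactly the `group:week` interaction
#' coefficient of the MMRM. Wald inference uses the normal reference
#' distribution. Contrasting placebo against itself returns an exact zero
#' with no uncertainty.
#'
#' @param fits An `mmrm_fits` object.
#' @param arm `"bari2mg"`, `"bari4mg"` (or `"placebo"` for the degenerate
#'   self-contrast).
#' @param week A post-baseline visit week present in the design.
#' @return Tibble feature_id, arm, week, estimate, se, p (one row per gene;
#'   non-converged genes carry NA).
#' @export
pd_contrast <- function(fits, arm, week) {
  if (!inherits(fits, "mmrm_fits")) stop_jak("fits must come from fit_mmrm()")
  if (!arm %in% c(fits$arms, "placebo")) {
    stop_jak("arm '", arm, "' absent from design")
  }
  if (!week %in% fits$weeks) stop_jak("week ", week, " absent from design")
  term <- sprintf("group%s:week_f%s", arm, format(week))
  rows <- purrr::imap(fits$fits, function(f, g) {
    if (arm == "placebo") {
      return(tibble::tibble(feature_id = g, arm = arm, week = week,
                            estimate = 0, se = 0, p = NA_real_))
    }
    if (!isTRUE(f$converged)) {
      return(tibble::tibble(feature_id = g, arm = arm, week = week,
                            estimate = NA_real_, se = NA_real_, p = NA_real_))
    }
    if (!term %in% names(f$coefficients)) {
      stop_jak("contrast term not found in fit: ", term)
    }
    est <- unname(f$coefficients[term])
    se <- sqrt(f$vcov[term, term])
    tibble::tibble(feature_id = g, arm = arm, week = week, estimate = est,
                   se = se, p = 2 * stats::pnorm(-abs(est / se)))
  })
  dplyr::bind_rows(rows)
}

#' All pharmacodynamic contrasts with BH q-values
#'
#' Evaluates every active arm at every post-baseline week and adjusts
#' p-values by Benjamini-Hochberg across genes within each (arm, week)
#' contrast. Non-converged genes keep NA q-values.
#'
#' @param fits An `mmrm_fits` object.
#' @param arms,weeks Subsets to evaluate (default: all in the design).
#' @return Tibble feature_id, arm, week, estimate, se, p, q.
#' @export
pd_effects <- function(fits, arms = fits$arms, weeks = fits$weeks) {
  tidyr::crossing(arm = arms, week = weeks) |>
    purrr::pmap(function(arm, week) pd_contrast(fits, arm, week)) |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$arm, .data$week) |>
    dplyr::mutate(q = bh_qvalues(.data$p)) |>
    dplyr::ungroup()
}
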