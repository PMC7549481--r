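# Synthetic trial generator. Emulates the statistical structure the
# downstream analyses assume: whole-blood log2 expression with an
# IFN-responsive gene block elevated in a subset of SLE patients, three
# arms (placebo, 2 mg, 4 mg) with dose- and time-dependent reduction of the
# elevated genes, SLEDAI-2K trajectories whose treatment response depends
# on baseline signature status, and log-normal cytokines left-censored at
# analyte-specific LLOQs. Every draw is recorded in a `truth` object so
# tests can score recovery against closed-form generative means.

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Simulate trial expression data with recorded ground truth
#'
#' The generative model for the log2 expression of gene g in patient i at
#' week w is
#' \deqn{y_{giw} = \mu_g + e_g 1[g \in IFN][i\ high] + \delta_g(arm_i, w)
#'   + b_{gi} + \epsilon_{giw}}
#' with gene baseline \eqn{\mu_g \sim N(7, 1)}, block elevation `e_g =
#' elevation_log2` carried only by IFN-high SLE patients, a pharmacodynamic
#' effect \eqn{\delta} equal to `pd_effect_log2` for IFN-block genes in the
#' 4 mg arm from `pd_onset_week` onwards (2 mg scaled by `dose_ratio`,
#' placebo and week 0 at zero), a per-(gene, patient) random intercept with
#' SD `intercept_sd` inducing within-patient correlation across visits, and
#' iid Gaussian noise. Healthy controls contribute one week-0 sample each.
#'
#' The first `n_signature_genes` features form the IFN-responsive block and
#' are named STAT1, STAT2, IFN003, ... so percentile-based co-elevation
#' analyses find the two STAT genes.
#'
#' @param n_per_arm SLE patients per treatment arm.
#' @param n_healthy Healthy controls (week 0 only).
#' @param n_genes Total number of genes/transcript clusters.
#' @param n_signature_genes Size of the IFN-responsive block.
#' @param frac_ifn_high Fraction of SLE patients carrying the elevated block.
#' @param elevation_log2 Baseline log2 elevation of block genes in IFN-high
#'   patients relative to healthy controls.
#' @param pd_effect_log2 Treatment effect (log2, usually negative) for block
#'   genes in the 4 mg arm at post-onset weeks.
#' @param dose_ratio 2 mg effect as a fraction of the 4 mg effect.
#' @param pd_onset_week First week at which the treatment effect is present.
#' @param noise_sd Residual SD (log2 units).
#' @param intercept_sd SD of the per-(gene, patient) random intercept;
#'   defaults to half the residual SD.
#' @param visit_weeks Visit schedule; must start at 0.
#' @param probe_level If `TRUE`, return a probe-level matrix (linear-scale
#'   intensities) with a probe-to-transcript-cluster map instead of a
#'   gene-level log2 matrix.
#' @param probes_per_tc Probes per transcript cluster when `probe_level`.
#' @param affinity_sd SD of per-probe affinity offsets (log2).
#' @param outlier_frac Fraction of probe cells shifted by `outlier_shift`.
#' @param outlier_shift Log2 shift applied to outlier probe cells.
#' @param seed Optional integer seed; same seed reproduces the output
#'   bit-identically.
#' @return A list with `expression` (wide tibble; probe-level runs also get
#'   `probes` and `probe_map`), `meta` and `truth`.
#' @export
simulate_expression <- function(n_per_arm = 90, n_healthy = 50,
                                n_genes = 200, n_signature_genes = 50,
                                frac_ifn_high = 0.625, elevation_log2 = 2,
                                pd_effect_log2 = -0.5, dose_ratio = 0.5,
                                pd_onset_week = 2, noise_sd = 0.5,
                                intercept_sd = noise_sd / 2,
                                visit_weeks = c(0, 2, 4, 12, 24),
                                probe_level = FALSE, probes_per_tc = 4,
                                affinity_sd = 1, outlier_frac = 0,
                                outlier_shift = 10, seed = NULL) {
  if (n_per_arm < 1 || n_healthy < 1 || n_genes < 1) {
    stop_jak("n_per_arm, n_healthy and n_genes must be positive")
  }
  if (frac_ifn_high < 0 || frac_ifn_high > 1) {
    stop_jak("frac_ifn_high must be in [0, 1]")
  }
  if (n_signature_genes > n_genes) {
    stop_jak("n_signature_genes cannot exceed n_genes")
  }
  if (visit_weeks[1] != 0) stop_jak("visit_weeks must start at week 0")

  with_seed_if(seed, {
    genes <- sprintf("TC%04d", seq_len(n_genes))
    if (n_signature_genes >= 2) {
      genes[1:2] <- c("STAT1", "STAT2")
      if (n_signature_genes > 2) {
        genes[3:n_signature_genes] <- sprintf("IFN%03d", 3:n_signature_genes)
      }
    } else if (n_signature_genes == 1) {
      genes[1] <- "STAT1"
    }
    ifn_block <- seq_len(n_signature_genes)

    n_sle <- 3 * n_per_arm
    sle_ids <- sprintf("P%03d", seq_len(n_sle))
    arms <- rep(trial_arms(), each = n_per_arm)
    n_high <- round(frac_ifn_high * n_sle)
    status <- rep("low", n_sle)
    status[sample.int(n_sle, n_high)] <- "high"
    hc_ids <- sprintf("H%03d", seq_len(n_healthy))

    patients <- tibble::tibble(
      patient_id = c(sle_ids, hc_ids),
      group = c(arms, rep("healthy", n_healthy)),
      status = c(status, rep(NA_character_, n_healthy)),
      age = pmin(pmax(round(stats::rnorm(n_sle + n_healthy, 45, 12)), 18), 80),
      sex = ifelse(stats::rbinom(n_sle + n_healthy, 1, 0.92) == 1, "F", "M"),
      leucocytes = round(stats::rlnorm(n_sle + n_healthy, log(5.5), 0.35), 2)
    )

    meta <- dplyr::bind_rows(
      tidyr::crossing(
        patients[patients$group != "healthy", ],
        visit_week = visit_weeks
      ),
      dplyr::mutate(patients[patients$group == "healthy", ], visit_week = 0)
    ) |>
      dplyr::mutate(sample_id = sprintf("%s_W%02d", .data$patient_id,
                                        .data$visit_week)) |>
      dplyr::select("sample_id", "patient_id", "group", "visit_week",
                    "age", "sex", "leucocytes")

    mu <- stats::rnorm(n_genes, 7, 1)
    # gene x sample mean surface
    n_samp <- nrow(meta)
    elev <- matrix(0, n_genes, n_samp)
    pd <- matrix(0, n_genes, n_samp)
    pat_status <- stats::setNames(patients$status, patients$patient_id)
    is_high <- !is.na(pat_status[meta$patient_id]) &
      pat_status[meta$patient_id] == "high"
    elev[ifn_block, is_high] <- elevation_log2
    scale_arm <- rep(0, n_samp)
    scale_arm[meta$group == "bari2mg"] <- dose_ratio
    scale_arm[meta$group == "bari4mg"] <- 1
    pd[ifn_block, ] <- rep(
      pd_effect_log2 * scale_arm * as.numeric(meta$visit_week >= pd_onset_week),
      each = length(ifn_block)
    )

    # per-(gene, patient) random intercept, shared across that patient's visits
    all_pat <- patients$patient_id
    b <- matrix(stats::rnorm(n_genes * length(all_pat), 0, intercept_sd),
                n_genes, length(all_pat), dimnames = list(genes, all_pat))
    y <- mu + elev + pd + b[, meta$patient_id, drop = FALSE] +
      matrix(stats::rnorm(n_genes * n_samp, 0, noise_sd), n_genes, n_samp)
    dimnames(y) <- list(genes, meta$sample_id)

    truth <- list(
      patients = patients,
      genes = tibble::tibble(
        feature_id = genes,
        ifn_block = seq_len(n_genes) %in% ifn_block,
        elevation_log2 = ifelse(seq_len(n_genes) %in% ifn_block,
                                elevation_log2, 0)
      ),
      pd_effects = tidyr::crossing(
        feature_id = genes[ifn_block],
        arm = c("bari2mg", "bari4mg"),
        week = setdiff(visit_weeks, 0)
      ) |>
        dplyr::mutate(effect_log2 = ifelse(
          .data$week >= pd_onset_week,
          pd_effect_log2 * dose_scale(.data$arm, dose_ratio), 0
        )),
      params = list(
        n_per_arm = n_per_arm, n_healthy = n_healthy, n_genes = n_genes,
        n_signature_genes = n_signature_genes, frac_ifn_high = frac_ifn_high,
        elevation_log2 = elevation_log2, pd_effect_log2 = pd_effect_log2,
        dose_ratio = dose_ratio, pd_onset_week = pd_onset_week,
        noise_sd = noise_sd, intercept_sd = intercept_sd,
        visit_weeks = visit_weeks, seed = seed
      )
    )

    out <- list(expression = expr_tibble(y), meta = meta, truth = truth)

    if (probe_level) {
      probe_ids <- as.vector(t(outer(genes, seq_len(probes_per_tc),
                                     function(g, k) sprintf("%s_p%02d", g, k))))
      probe_map <- tibble::tibble(
        probe_id = probe_ids,
        tc_id = rep(genes, each = probes_per_tc)
      )
      # probe intensities scatter around the per-sample TC signal surface
      # (mean structure + patient intercept, no residual), so summarizing
      # n probes recovers that surface with error ~ noise_sd / sqrt(n)
      signal <- mu + elev + pd + b[, meta$patient_id, drop = FALSE]
      dimnames(signal) <- list(genes, meta$sample_id)
      truth$tc_signal <- expr_tibble(signal)
      affinity <- stats::rnorm(length(probe_ids), 0, affinity_sd)
      ylog <- signal[probe_map$tc_id, , drop = FALSE] + affinity +
        matrix(stats::rnorm(length(probe_ids) * n_samp, 0, noise_sd),
               length(probe_ids), n_samp)
      if (outlier_frac > 0) {
        hit <- matrix(stats::rbinom(length(ylog), 1, outlier_frac) == 1,
                      nrow(ylog), ncol(ylog))
        ylog[hit] <- ylog[hit] + outlier_shift
        truth$outliers <- which(hit, arr.ind = TRUE)
      }
      intens <- 2^ylog
      dimnames(intens) <- list(probe_map$probe_id, meta$sample_id)
      out$probes <- dplyr::bind_cols(
        tibble::tibble(probe_id = probe_map$probe_id),
        tibble::as_tibble(intens)
      )
      out$probe_map <- probe_map
      out$truth <- truth
    }
    out
  })
}

#' Simulate SLEDAI-2K trajectories conditional on signature status
#'
#' Change from baseline at week w is
#' `placebo_drift[w] + dose_scale(arm) * 1[status == high] *
#' responder_benefit[w] + noise`, rounded to the nearest integer, with
#' scores floored at 0 and capped at 105. Week 0 change is identically 0.
#'
#' @param meta Sample metadata (SLE arms; healthy rows are ignored).
#' @param truth Truth object from [simulate_expression()] (supplies per-
#'   patient signature status), or a tibble with `patient_id` and `status`.
#' @param responder_benefit Named numeric: expected extra SLEDAI-2K change
#'   for signature-high patients in the 4 mg arm, by post-baseline week.
#' @param placebo_drift Named numeric: expected change for everyone, by
#'   post-baseline week.
#' @param noise_sd SD of the Gaussian noise before discretization.
#' @param dose_ratio 2 mg benefit as a fraction of the 4 mg benefit.
#' @param baseline_mean,baseline_sd Baseline score distribution (rounded,
#'   floored at 4 as the trial required active disease at entry).
#' @param seed Optional integer seed.
#' @return Long tibble `patient_id`, `visit_week`, `sledai2k`.
#' @export
simulate_trajectories <- function(meta, truth,
                                  responder_benefit = c(`2` = -1, `4` = -2,
                                                        `12` = -3, `24` = -4),
                                  placebo_drift = c(`2` = -0.5, `4` = -1,
                                                    `12` = -1, `24` = -1),
                                  noise_sd = 3, dose_ratio = 0.5,
                                  baseline_mean = 8.8, baseline_sd = 3,
                                  seed = NULL) {
  status_tbl <- if (is.list(truth) && !is.data.frame(truth)) truth$patients else truth
  check_columns(status_tbl, c("patient_id", "status"), "truth")
  sle <- meta |>
    dplyr::filter(.data$group != "healthy") |>
    dplyr::distinct(.data$patient_id, .data$group)
  unknown <- setdiff(sle$patient_id, status_tbl$patient_id)
  if (length(unknown) > 0) {
    stop_jak("patients missing from truth: ", paste(unknown, collapse = ", "))
  }
  sle <- dplyr::left_join(sle, status_tbl[c("patient_id", "status")],
                          by = "patient_id")
  weeks <- sort(unique(meta$visit_week[meta$group != "healthy"]))
  post <- setdiff(weeks, 0)
  miss <- setdiff(as.character(post), names(responder_benefit))
  if (length(miss) > 0) {
    stop_jak("responder_benefit missing week(s): ", paste(miss, collapse = ", "))
  }
  miss <- setdiff(as.character(post), names(placebo_drift))
  if (length(miss) > 0) {
    stop_jak("placebo_drift missing week(s): ", paste(miss, collapse = ", "))
  }

  with_seed_if(seed, {
    base <- pmax(4, round(stats::rnorm(nrow(sle), baseline_mean, baseline_sd)))
    base <- pmin(base, 105)
    purrr::pmap(list(sle$patient_id, sle$group, sle$status, base),
                function(pid, arm, st, b0) {
      cfb <- placebo_drift[as.character(post)] +
        dose_scale(arm, dose_ratio) * as.numeric(identical(st, "high")) *
          responder_benefit[as.character(post)] +
        stats::rnorm(length(post), 0, noise_sd)
      score <- pmin(pmax(round(b0 + cfb), 0), 105)
      tibble::tibble(patient_id = pid, visit_week = c(0, post),
                     sledai2k = c(b0, score))
    }) |>
      dplyr::bind_rows()
  })
}

#' Default cytokine panel with analyte-specific LLOQs
#'
#' Plausible pg/mL geometric means and lower limits of quantification for a
#' panel of SLE-relevant cytokines measured on ultrasensitive platforms.
#' `log_mean_*` columns are natural-log means of the log-normal
#' concentration model.
#'
#' @return Tibble with analyte, lloq, log_mean_healthy, log_mean_sle.
#' @export
default_cytokine_panel <- function() {
  tibble::tribble(
    ~analyte,    ~lloq, ~gm_healthy, ~gm_sle,
    "IFN-alpha",  0.02,       0.010,   0.080,
    "IFN-gamma",  0.20,       0.500,   1.500,
    "IL-6",       0.50,       0.300,   1.200,
    "IL-12p40",   5.00,      15.000,  45.000,
    "IL-10",      0.30,       0.200,   0.500,
    "IL-17A",     0.50,       1.000,   1.500
  ) |>
    dplyr::mutate(log_mean_healthy = log(.data$gm_healthy),
                  log_mean_sle = log(.data$gm_sle)) |>
    dplyr::select("analyte", "lloq", "log_mean_healthy", "log_mean_sle")
}

#' Default treatment effects on cytokine log-concentration
#'
#' Negative natural-log shifts for IL-6 and IL-12p40 in the active arms from
#' week 12 onwards; all other analyte/arm/week combinations are null.
#'
#' @param weeks Post-baseline visit weeks.
#' @return Tibble analyte, arm, week, effect_log.
#' @export
default_cytokine_effects <- function(weeks = c(2, 4, 12, 24)) {
  tidyr::crossing(analyte = c("IL-6", "IL-12p40"),
                  arm = c("bari2mg", "bari4mg"),
                  week = weeks) |>
    dplyr::mutate(effect_log = ifelse(
      .data$week >= 12,
      -0.4 * dose_scale(.data$arm, 0.5), 0
    ))
}

#' Simulate left-censored cytokine concentrations
#'
#' Per analyte, log concentration is Gaussian around the group mean
#' (`log_mean_healthy` / `log_mean_sle`) plus any arm/week treatment effect
#' and a per-(patient, analyte) random intercept; concentrations below the
#' analyte LLOQ are flagged `below_lloq` and exposed as missing, with the
#' latent value kept in the truth table.
#'
#' @param meta Sample metadata; healthy contribute week 0 only.
#' @param panel Analyte table as in [default_cytokine_panel()].
#' @param arm_effects Treatment-effect table as in
#'   [default_cytokine_effects()]; `NULL` for none.
#' @param sd_log Residual SD of log concentration.
#' @param patient_sd SD of the per-(patient, analyte) intercept.
#' @param seed Optional integer seed.
#' @return List with `measurements` (censored view) and `truth` (latent
#'   concentrations plus parameters).
#' @export
simulate_cytokines <- function(meta, panel = default_cytokine_panel(),
                               arm_effects = default_cytokine_effects(),
                               sd_log = 0.8, patient_sd = sd_log / 2,
                               seed = NULL) {
  check_columns(panel, c("analyte", "lloq", "log_mean_healthy", "log_mean_sle"),
                "cytokine panel")
  if (any(panel$lloq <= 0)) stop_jak("every analyte needs lloq > 0")
  visits <- meta |> dplyr::distinct(.data$patient_id, .data$group, .data$visit_week)
  with_seed_if(seed, {
    grid <- tidyr::crossing(visits, panel)
    pat_key <- paste(grid$patient_id, grid$analyte)
    u_all <- stats::rnorm(length(unique(pat_key)), 0, patient_sd)
    names(u_all) <- unique(pat_key)
    eff <- rep(0, nrow(grid))
    if (!is.null(arm_effects) && nrow(arm_effects) > 0) {
      m <- dplyr::left_join(
        grid[c("analyte", "group", "visit_week")],
        dplyr::rename(arm_effects, group = "arm", visit_week = "week"),
        by = c("analyte", "group", "visit_week")
      )
      eff <- ifelse(is.na(m$effect_log), 0, m$effect_log)
    }
    mu <- ifelse(grid$group == "healthy", grid$log_mean_healthy,
                 grid$log_mean_sle) + eff + u_all[pat_key]
    conc <- exp(mu + stats::rnorm(nrow(grid), 0, sd_log))
    below <- conc < grid$lloq
    truth <- tibble::tibble(
      analyte = grid$analyte, patient_id = grid$patient_id,
      visit_week = grid$visit_week, group = grid$group,
      latent_concentration = conc, lloq = grid$lloq, below_lloq = below
    )
    measurements <- tibble::tibble(
      analyte = grid$analyte, patient_id = grid$patient_id,
      visit_week = grid$visit_week,
      concentration = ifelse(below, NA_real_, conc),
      lloq = grid$lloq, below_lloq = below
    )
    list(measurements = measurements,
         truth = list(values = truth,
                      params = list(sd_log = sd_log, patient_sd = patient_sd,
                                    seed = seed)))
  })
}

#' Default gene signatures over the simulated IFN block
#'
#' Two nested signatures mirroring a JAK1-activated set (first 20 block
#' genes) and a broader JAK1/JAK2/TYK2-activated set (first 40).
#'
#' @param truth Truth object from [simulate_expression()].
#' @return Long signature tibble (GMT-shaped).
#' @export
default_signatures <- function(truth) {
  block <- truth$genes$feature_id[truth$genes$ifn_block]
  dplyr::bind_rows(
    tibble::tibble(signature = "JAK1_activated",
                   description = "synthetic JAK1-activated gene set",
                   gene = utils::head(block, 20)),
    tibble::tibble(signature = "JAK1_JAK2_TYK2_activated",
                   description = "synthetic JAK1/JAK2/TYK2-activated gene set",
                   gene = utils::head(block, 40))
  )
}

#' Simulate a full trial bundle
#'
#' Runs the expression, trajectory and cytokine generators with one seed and
#' returns everything downstream stages need, including signatures and the
#' serialized-ready truth.
#'
#' @param seed Integer seed.
#' @param ... Passed to [simulate_expression()].
#' @return List: expression, meta, trajectories, cytokines, signatures,
#'   truth (and probes/probe_map when probe-level).
#' @export
simulate_trial <- function(seed = 1L, ...) {
  sim <- simulate_expression(seed = seed, ...)
  traj <- simulate_trajectories(sim$meta, sim$truth, seed = seed + 1L)
  cyto <- simulate_cytokines(sim$meta, seed = seed + 2L)
  list(
    expression = sim$expression,
    probes = sim$probes,
    probe_map = sim$probe_map,
    meta = sim$meta,
    trajectories = traj,
    cytokines = cyto$measurements,
    cytokine_truth = cyto$truth,
    signatures = default_signatures(sim$truth),
    truth = sim$truth
  )
}

#' Serialize a truth object beside the data
#'
#' Writes the per-patient, per-gene and per-effect tables as TSV and the
#' scalar parameters as JSON, so recovery tests can reload the exact draws.
#'
#' @param truth Truth object from [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(truth$patients, file.path(dir, "truth_patients.tsv"),
                   progress = FALSE)
  readr::write_tsv(truth$genes, file.path(dir, "truth_genes.tsv"),
                   progress = FALSE)
  readr::write_tsv(truth$pd_effects, file.path(dir, "truth_pd_effects.tsv"),
                   progress = FALSE)
  jsonlite::write_json(truth$params, file.path(dir, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back a serialized truth object
#'
#' @param dir Directory written by [write_truth()].
#' @return Truth list (patients, genes, pd_effects, params).
#' @export
read_truth <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "truth_params.json"),
                                simplifyVector = TRUE)
  list(
    patients = readr::read_tsv(file.path(dir, "truth_patients.tsv"),
                               show_col_types = FALSE, progress = FALSE),
    genes = readr::read_tsv(file.path(dir, "truth_genes.tsv"),
                            show_col_types = FALSE, progress = FALSE),
    pd_effects = readr::read_tsv(file.path(dir, "truth_pd_effects.tsv"),
                                 show_col_types = FALSE, progress = FALSE),
    params = params
  )
}
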