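test_that("signature calls match the exact signed-rank enumeration oracle", {
  withr::with_seed(3, {
    coh <- make_signature_cohort(n_patients = 12, n_high = 3, n_low = 3,
                                 n_genes = 9, seed = 3)
  })
  calls <- call_signature_status(coh$expr, coh$genes)
  m <- expr_matrix(coh$expr)
  sig <- m[coh$genes, ]
  pop <- rowMeans(sig)
  for (j in c(1, 5, 12)) {
    d <- sig[, j] - pop
    expect_equal(calls$wilcoxon_p[j], exact_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("a patient equal to the population mean is called neither", {
  withr::with_seed(4, {
    base <- matrix(rnorm(60, 7, 1), 6, 10)
  })
  # make column 1 equal to the row means of the full matrix by construction:
  # set it to the mean of the others plus the solved offset
  base[, 1] <- rowMeans(base[, -1])  # then overall mean = col1 as well
  rownames(base) <- sprintf("SIG%03d", 1:6)
  colnames(base) <- sprintf("P%03d", 1:10)
  calls <- suppressMessages(
    call_signature_status(expr_tibble(base), rownames(base))
  )
  expect_equal(calls$status[1], "neither")
  expect_equal(calls$median_delta[1], 0)
})

test_that("planted high and low patients are recovered at high recall", {
  coh <- make_signature_cohort(n_patients = 200, n_high = 25, n_low = 25,
                               n_genes = 20, shift = 1, noise_sd = 0.5,
                               seed = 11)
  calls <- call_signature_status(coh$expr, coh$genes)
  recall_high <- mean(calls$status[coh$status == "high"] == "high")
  recall_low <- mean(calls$status[coh$status == "low"] == "low")
  expect_gte(recall_high, 0.95)
  expect_gte(recall_low, 0.95)
  # neither patients are rarely mis-called
  fp <- mean(calls$status[coh$status == "neither"] != "neither")
  expect_lt(fp, 0.2)
})

test_that("signature resolution is validated and reported", {
  coh <- make_signature_cohort(n_patients = 10, n_high = 2, n_low = 2,
                               n_genes = 6, seed = 2)
  expect_warning(
    calls <- call_signature_status(coh$expr, c(coh$genes, "NOT_A_GENE")),
    "NOT_A_GENE")
  expect_equal(unique(calls$signature_n_genes), 6)
  expect_error(
    suppressWarnings(call_signature_status(coh$expr, c("A", "B", "C", "D", "E"))),
    ">= 5")
})

test_that("permutation test p-values obey the add-one bound and determinism", {
  pats <- sprintf("P%02d", 1:12)
  calls <- tibble::tibble(patient_id = pats,
                          status = rep(c("high", "low"), each = 6))
  # high group improves dramatically: observed beats every permutation
  tr <- make_trajectories(pats, baseline = 20,
                          changes_by_week = list(`4` = rep(c(-10, 0), each = 6),
                                                 `12` = rep(c(-12, 0), each = 6)))
  meta <- make_baseline_meta(pats, rep("bari4mg", 12))
  res <- trajectory_permutation_test(calls, tr, meta, "bari4mg", B = 200,
                                     seed = 1)
  expect_equal(res$p_value, 1 / 201)
  expect_gt(res$observed_stat, 0)
  # determinism and patient-order invariance
  res2 <- trajectory_permutation_test(calls, tr, meta, "bari4mg", B = 200,
                                      seed = 1)
  expect_identical(res$null_stats, res2$null_stats)
  shuf <- withr::with_seed(9, sample(12))
  res3 <- trajectory_permutation_test(calls[shuf, ], tr, meta, "bari4mg",
                                      B = 200, seed = 1)
  expect_identical(res$p_value, res3$p_value)
  expect_identical(res$observed_stat, res3$observed_stat)
})

test_that("permutation p is super-uniform under exchangeable labels", {
  # null: labels carry no information about trajectories
  n_rep <- 200
  pats <- sprintf("P%02d", 1:20)
  meta <- make_baseline_meta(pats, rep("placebo", 20))
  calls <- tibble::tibble(patient_id = pats,
                          status = rep(c("high", "low"), each = 10))
  pvals <- withr::with_seed(99, {
    vapply(seq_len(n_rep), function(r) {
      tr <- make_trajectories(pats, baseline = 20, changes_by_week = list(
        `4` = round(rnorm(20, 0, 3)), `12` = round(rnorm(20, 0, 3))))
      trajectory_permutation_test(calls, tr, meta, "placebo", B = 400)$p_value
    }, numeric(1))
  })
  rate <- mean(pvals <= 0.05)
  ci <- binom.test(round(0.05 * n_rep), n_rep, conf.level = 0.99)$conf.int
  expect_lte(rate, ci[2])
  expect_gt(mean(pvals), 0.4)
})

test_that("group collapse and bad B are rejected", {
  pats <- sprintf("P%02d", 1:6)
  calls <- tibble::tibble(patient_id = pats,
                          status = c("high", rep("low", 5)))
  tr <- make_trajectories(pats, 20, list(`4` = rep(0, 6)))
  meta <- make_baseline_meta(pats, rep("bari2mg", 6))
  expect_error(trajectory_permutation_test(calls, tr, meta, "bari2mg", B = 10),
               "bari2mg")
  calls2 <- tibble::tibble(patient_id = pats,
                           status = rep(c("high", "low"), 3))
  expect_error(trajectory_permutation_test(calls2, tr, meta, "bari2mg", B = 0),
               "B must be")
})

test_that("LOESS smoothing reproduces linear and constant trajectories", {
  pats <- sprintf("P%02d", 1:8)
  calls <- tibble::tibble(patient_id = pats,
                          status = rep(c("high", "low"), each = 4))
  # change exactly linear in week: -w/2
  tr <- make_trajectories(pats, 30, list(`2` = rep(-1, 8), `4` = rep(-2, 8),
                                         `12` = rep(-6, 8), `24` = rep(-12, 8)))
  sm <- loess_group_trajectories(calls, tr, span = 0.75,
                                 grid = c(0, 2, 4, 12, 24))
  expect_equal(sm$mean_change, -sm$visit_week / 2, tolerance = 1e-6)
  tr0 <- make_trajectories(pats, 30, list(`2` = rep(0, 8), `4` = rep(0, 8),
                                          `12` = rep(0, 8), `24` = rep(0, 8)))
  sm0 <- loess_group_trajectories(calls, tr0, span = 1, grid = c(0, 4, 24))
  expect_equal(sm0$mean_change, rep(0, 6), tolerance = 1e-9)
  expect_error(loess_group_trajectories(calls, tr, span = 1.5), "span")
})

test_that("span-1 smoothing passes near the weekly means", {
  pats <- sprintf("P%02d", 1:6)
  calls <- tibble::tibble(patient_id = pats, status = rep("high", 6))
  withr::with_seed(7, {
    ch2 <- round(rnorm(6, -1, 1)); ch4 <- round(rnorm(6, -2, 1))
    ch12 <- round(rnorm(6, -3, 1)); ch24 <- round(rnorm(6, -4, 1))
  })
  tr <- make_trajectories(pats, 30, list(`2` = ch2, `4` = ch4, `12` = ch12,
                                         `24` = ch24))
  sm <- loess_group_trajectories(calls, tr, span = 1,
                                 grid = c(0, 2, 4, 12, 24))
  weekly <- c(0, mean(ch2), mean(ch4), mean(ch12), mean(ch24))
  expect_lt(max(abs(sm$mean_change - weekly)), 1.5)
})

test_that("percentile classification uses the interpolated 95th percentile strictly", {
  hc <- make_expr(rbind(STAT1 = 1:100, STAT2 = 1:100),
                  samples = sprintf("H%03d", 1:100))
  thr <- quantile(1:100, 0.95, names = FALSE)  # 95.05 by interpolation
  sle <- make_expr(rbind(STAT1 = c(95.05, 95.06, 99, 10),
                         STAT2 = c(99, 10, 99, 10)),
                   samples = sprintf("P%03d", 1:4))
  out <- percentile_classify(sle, hc)
  expect_equal(unname(out$thresholds), c(95.05, 95.05))
  # patient exactly at the threshold is NOT high
  expect_false(out$calls$STAT1_high[1])
  expect_true(out$calls$STAT1_high[2])
  tab <- out$table
  expect_equal(tab$n_both_high, 1)   # P003
  expect_equal(tab$n_a_only, 1)      # P002 (STAT1 only)
  expect_equal(tab$n_b_only, 1)      # P001 (STAT2 only)
  expect_equal(tab$n_both_normal, 1) # P004
  expect_error(percentile_classify(sle, hc, genes = c("STAT1", "STAT9")),
               "STAT9")
})

test_that("the joint-status counts reproduce planted co-elevation", {
  # plant the four joint categories with wide margins around the healthy 95th
  withr::with_seed(15, {
    hc_vals <- matrix(rnorm(2 * 50, 7, 0.3), 2)
  })
  hc <- make_expr(hc_vals, features = c("STAT1", "STAT2"),
                  samples = sprintf("H%03d", 1:50))
  counts <- c(both_normal = 56, a_only = 5, b_only = 34, both_high = 174)
  s1 <- c(rep(6, 56), rep(10, 5), rep(6, 34), rep(10, 174))
  s2 <- c(rep(6, 56), rep(6, 5), rep(10, 34), rep(10, 174))
  sle <- make_expr(rbind(STAT1 = s1, STAT2 = s2),
                   samples = sprintf("P%03d", seq_along(s1)))
  out <- percentile_classify(sle, hc)
  expect_equal(out$table$n_both_normal, 56)
  expect_equal(out$table$n_a_only, 5)
  expect_equal(out$table$n_b_only, 34)
  expect_equal(out$table$n_both_high, 174)
  ft <- fisher_exact_2x2(out$table)
  expect_equal(ft$odds_ratio, (56 * 174) / (5 * 34), tolerance = 1e-12)
})

test_that("Fisher test matches enumeration and the degenerate no-association case", {
  ft <- fisher_exact_2x2(c(10, 10, 10, 10))
  expect_equal(ft$odds_ratio, 1)
  expect_equal(ft$p_two_sided, 1)
  # small tables against both the hand enumeration and stats::fisher.test
  withr::with_seed(8, {
    tables <- replicate(20, rmultinom(1, sample(10:40, 1), rep(0.25, 4))[, 1])
  })
  for (i in seq_len(ncol(tables))) {
    tb <- tables[, i]
    if (any(c(tb[1] + tb[2], tb[3] + tb[4], tb[1] + tb[3], tb[2] + tb[4]) == 0)) next
    got <- fisher_exact_2x2(tb)
    expect_equal(got$p_two_sided, enumerate_fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    ref <- fisher.test(matrix(c(tb[1], tb[3], tb[2], tb[4]), 2, 2))
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(c(0, 0, 5, 5)), "margin")
  inf_or <- fisher_exact_2x2(c(10, 0, 3, 10))
  expect_identical(inf_or$odds_ratio, Inf)
})
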