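make_de_fixture <- function(n_genes = 40, n_sle = 30, n_hc = 20,
                            n_planted = 10, shift = 2, sd = 0.5, seed = 1) {
  n_planted <- min(n_planted, n_genes)
  withr::with_seed(seed, {
    mu <- rnorm(n_genes, 7, 1)
    y <- mu + matrix(rnorm(n_genes * (n_sle + n_hc), 0, sd), n_genes)
    y[seq_len(n_planted), seq_len(n_sle)] <-
      y[seq_len(n_planted), seq_len(n_sle)] + shift
  })
  rownames(y) <- sprintf("G%03d", seq_len(n_genes))
  colnames(y) <- c(sprintf("S%03d", seq_len(n_sle)), sprintf("H%03d", seq_len(n_hc)))
  meta <- make_baseline_meta(colnames(y),
                             rep(c("placebo", "healthy"), c(n_sle, n_hc)))
  list(expr = expr_tibble(y), meta = meta,
       planted = rownames(y)[seq_len(n_planted)])
}

test_that("baseline DE ranks planted elevated genes on top", {
  fx <- make_de_fixture()
  de <- baseline_de(fx$expr, fx$meta)
  expect_setequal(de$feature_id[de$rank <= 10], fx$planted)
  expect_true(all(de$q >= de$p))
  expect_equal(de$q, bh_by_hand(de$p), tolerance = 1e-12)
  top <- top_genes(de, 10)
  expect_identical(top$feature_id, de$feature_id[1:10])
})

test_that("baseline DE agrees with per-gene Welch t-tests", {
  fx <- make_de_fixture(n_genes = 12, seed = 3)
  de <- baseline_de(fx$expr, fx$meta)
  m <- expr_matrix(fx$expr)
  for (g in c("G001", "G007", "G012")) {
    ref <- t.test(m[g, 1:30], m[g, 31:50])
    row <- de[de$feature_id == g, ]
    expect_equal(row$p, ref$p.value, tolerance = 1e-12)
    expect_equal(row$log2_fold_difference,
                 unname(ref$estimate[1] - ref$estimate[2]), tolerance = 1e-12)
  }
})

test_that("a gene with identical group values gets zero fold and p = 1", {
  fx <- make_de_fixture(n_genes = 6, seed = 5)
  m <- expr_matrix(fx$expr)
  m["G003", ] <- 5  # constant everywhere
  de <- baseline_de(expr_tibble(m), fx$meta)
  row <- de[de$feature_id == "G003", ]
  expect_equal(row$log2_fold_difference, 0)
  expect_equal(row$p, 1)
})

test_that("baseline DE null p-values are uniform at the nominal level", {
  fx <- make_de_fixture(n_genes = 1000, n_planted = 0, seed = 8)
  de <- baseline_de(fx$expr, fx$meta)
  rej <- mean(de$p < 0.05)
  ci <- binom.test(round(0.05 * 1000), 1000, conf.level = 0.99)$conf.int
  expect_gt(rej, ci[1] - 1e-9)
  expect_lt(rej, ci[2] + 1e-9)
})

test_that("BH q-values reproduce the step-down formula on hand cases", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.2), 0.2)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(bh_qvalues(p), bh_by_hand(p), tolerance = 1e-12)
  # monotone in p
  withr::with_seed(2, {
    p2 <- runif(50)
  })
  q2 <- bh_qvalues(p2)
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
  expect_error(bh_qvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("MMRM matches OLS when residuals are independent", {
  sim <- simulate_expression(n_per_arm = 20, n_genes = 4,
                             n_signature_genes = 2, intercept_sd = 0,
                             noise_sd = 0.4, seed = 17)
  fits <- fit_mmrm(sim$expression, sim$meta,
                   mmrm_config(covariance = "independence"))
  m <- expr_matrix(sim$expression)
  meta <- sim$meta[sim$meta$group != "healthy", ]
  df <- data.frame(
    y = m[1, meta$sample_id],
    group = factor(meta$group, levels = trial_arms()),
    week_f = factor(meta$visit_week),
    age = meta$age, sex = meta$sex, leucocytes = log(meta$leucocytes)
  )
  ols <- lm(y ~ group * week_f + age + sex + leucocytes, data = df)
  got <- fits$fits[[1]]$coefficients
  expect_equal(unname(got[names(coef(ols))]), unname(coef(ols)),
               tolerance = 1e-6)
  # spatial power on independent data: the estimated rho is small and the
  # within-patient contrasts stay close to OLS
  fits_sp <- fit_mmrm(sim$expression, sim$meta,
                      mmrm_config(covariance = "spatial_power"))
  got_sp <- fits_sp$fits[[1]]$coefficients
  inter <- grep(":", names(coef(ols)), value = TRUE)
  expect_equal(unname(got_sp[inter]), unname(coef(ols)[inter]),
               tolerance = 0.02)
})

test_that("compound symmetry on two balanced visits matches the paired analysis", {
  # two visits, no covariate variation: the treatment-by-week interaction
  # equals the difference in mean within-patient changes, arm vs placebo
  withr::with_seed(23, {
    n <- 24
    pats <- sprintf("P%02d", 1:n)
    arm <- rep(c("placebo", "bari4mg"), each = n / 2)
    b <- rnorm(n, 0, 0.5)
    y0 <- 7 + b + rnorm(n, 0, 0.3)
    y12 <- 7 + b + ifelse(arm == "bari4mg", -0.6, 0) + rnorm(n, 0, 0.3)
  })
  meta <- tibble::tibble(
    sample_id = c(paste0(pats, "_W00"), paste0(pats, "_W12")),
    patient_id = rep(pats, 2), group = rep(arm, 2),
    visit_week = rep(c(0, 12), each = n),
    age = 45, sex = "F", leucocytes = 5.5
  )
  m <- rbind(G1 = c(y0, y12), G2 = c(y0, y12) + 0.1)
  colnames(m) <- meta$sample_id
  fits <- fit_mmrm(expr_tibble(m), meta,
                   mmrm_config(covariance = "compound_symmetry",
                               covariates = character(0),
                               log_covariates = character(0)))
  pd <- pd_contrast(fits, "bari4mg", 12)
  paired <- mean((y12 - y0)[arm == "bari4mg"]) - mean((y12 - y0)[arm == "placebo"])
  expect_equal(pd$estimate[1], paired, tolerance = 1e-6)
  expect_equal(pd$estimate[2], paired, tolerance = 1e-6)
})

test_that("pd_contrast recovers planted effects and nulls out placebo", {
  sim <- simulate_expression(n_per_arm = 40, n_genes = 20,
                             n_signature_genes = 10, pd_effect_log2 = -0.5,
                             seed = 29)
  fits <- fit_mmrm(sim$expression, sim$meta,
                   mmrm_config(covariance = "compound_symmetry"))
  pd <- pd_contrast(fits, "bari4mg", 12)
  block <- sim$truth$genes$ifn_block
  expect_lt(abs(mean(pd$estimate[block]) - (-0.5)), 0.15)
  expect_lt(abs(mean(pd$estimate[!block])), 0.15)
  # self-contrast is exactly zero
  pd0 <- pd_contrast(fits, "placebo", 12)
  expect_true(all(pd0$estimate == 0))
  expect_error(pd_contrast(fits, "bari4mg", 7), "week 7")
  expect_error(pd_contrast(fits, "armX", 12), "armX")
})

test_that("pd_effects q-values equal brute-force BH within each contrast", {
  sim <- simulate_expression(n_per_arm = 15, n_genes = 12,
                             n_signature_genes = 6, seed = 37)
  fits <- fit_mmrm(sim$expression, sim$meta,
                   mmrm_config(covariance = "independence"))
  pd <- pd_effects(fits, arms = "bari4mg", weeks = c(4, 12))
  for (w in c(4, 12)) {
    slice <- pd[pd$week == w, ]
    expect_equal(slice$q, bh_by_hand(slice$p), tolerance = 1e-12)
  }
  # dose ordering of planted effects in the summary
  pd_all <- pd_effects(fits, weeks = 12)
  block <- sim$truth$genes$feature_id[sim$truth$genes$ifn_block]
  m2 <- mean(pd_all$estimate[pd_all$arm == "bari2mg" &
                               pd_all$feature_id %in% block])
  m4 <- mean(pd_all$estimate[pd_all$arm == "bari4mg" &
                               pd_all$feature_id %in% block])
  expect_gt(abs(m4), abs(m2))
})

test_that("fit_mmrm is invariant to sample row order", {
  sim <- simulate_expression(n_per_arm = 10, n_genes = 3,
                             n_signature_genes = 2, seed = 41)
  fits1 <- fit_mmrm(sim$expression, sim$meta)
  withr::with_seed(1, {
    perm <- sample(nrow(sim$meta))
  })
  meta2 <- sim$meta[perm, ]
  expr2 <- sim$expression[c("feature_id", meta2$sample_id)]
  fits2 <- fit_mmrm(expr2, meta2)
  expect_equal(fits1$fits[[1]]$coefficients, fits2$fits[[1]]$coefficients,
               tolerance = 1e-8)
})

test_that("patients without baseline are excluded with a warning", {
  sim <- simulate_expression(n_per_arm = 6, n_genes = 3,
                             n_signature_genes = 2, seed = 43)
  meta <- sim$meta[!(sim$meta$patient_id == "P001" & sim$meta$visit_week == 0), ]
  expr <- sim$expression[c("feature_id", meta$sample_id)]
  expect_warning(fit_mmrm(expr, meta), "P001")
})
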