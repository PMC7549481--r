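# Small fixture builders shared across test files. Everything is generated
# in code; no fixture touches disk except through tempfiles.

# wide expression tibble from a matrix-like spec
make_expr <- function(values, features = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- features %||% rownames(m) %||% sprintf("G%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("S%03d", seq_len(ncol(m)))
  expr_tibble(m)
}

# cohort with planted signature-high/low minorities: n_high patients get
# +shift on the signature genes, n_low get -shift, the rest are unshifted
make_signature_cohort <- function(n_patients = 100, n_high = 15, n_low = 15,
                                  n_genes = 20, shift = 1, noise_sd = 0.5,
                                  intercept_sd = noise_sd / 2, seed = 1) {
  stopifnot(n_high + n_low <= n_patients)
  withr::with_seed(seed, {
    mu <- rnorm(n_genes, 7, 1)
    status <- rep("neither", n_patients)
    status[seq_len(n_high)] <- "high"
    status[n_high + seq_len(n_low)] <- "low"
    status <- sample(status)
    offset <- c(high = shift, low = -shift, neither = 0)[status]
    b <- matrix(rnorm(n_genes * n_patients, 0, intercept_sd), n_genes)
    y <- mu + matrix(rep(offset, each = n_genes), n_genes) + b +
      matrix(rnorm(n_genes * n_patients, 0, noise_sd), n_genes)
    rownames(y) <- sprintf("SIG%03d", seq_len(n_genes))
    colnames(y) <- sprintf("P%03d", seq_len(n_patients))
    list(expr = expr_tibble(y), status = status,
         genes = rownames(y), patients = colnames(y))
  })
}

# minimal metadata for a set of patients in one or more arms at week 0
make_baseline_meta <- function(patients, groups) {
  tibble::tibble(
    sample_id = patients, patient_id = patients, group = groups,
    visit_week = 0,
    age = 45, sex = "F", leucocytes = 5.5
  )
}

# trajectories with specified per-patient changes at post-baseline weeks
make_trajectories <- function(patient_ids, baseline, changes_by_week) {
  purrr::imap(changes_by_week, function(ch, wk) {
    tibble::tibble(patient_id = patient_ids, visit_week = as.numeric(wk),
                   sledai2k = baseline + ch)
  }) |>
    dplyr::bind_rows() |>
    dplyr::bind_rows(tibble::tibble(patient_id = patient_ids, visit_week = 0,
                                    sledai2k = baseline)) |>
    dplyr::arrange(patient_id, visit_week)
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign vectors
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean_w <- n * (n + 1) / 4
  p <- 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs))
  min(1, p)
}

# two-sided Fisher p by direct enumeration over one margin
enumerate_fisher_p <- function(a, b, cc, d) {
  m <- a + cc; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(a, m, nn, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# BH step-down q-values computed literally from the formula
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
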