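---
title: "Models and methods: pathway pharmacodynamics of JAK inhibition in SLE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pathway pharmacodynamics of JAK inhibition in SLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`jakstatpd` analyses a three-arm (placebo, 2 mg, 4 mg once-daily
JAK1/JAK2 inhibitor), 24-week trial design in systemic lupus
erythematosus: whole-blood expression at weeks 0, 2, 4, 12 and 24,
SLEDAI-2K disease-activity scores at the same visits, healthy controls at
week 0 only, and a serum cytokine panel left-censored at analyte-specific
lower limits of quantification (LLOQ). This vignette records the models,
the tunable parameters, the numerical conventions, and the design choices
made where more than one reasonable reading existed.

## Probe preprocessing

Probe intensities are background-corrected, quantile-normalized and
summarized to transcript clusters (TCs).

* **Background.** The default `quantile_floor` method subtracts the
  per-sample 1st-percentile intensity and clamps at `eps = 0.5` so the
  subsequent log2 is defined. Array-chemistry-specific background
  deconvolution is deliberately out of scope: an `identity` option exists
  because synthetic intensities carry no optical background. The clamp
  value only matters for probes at the extreme low end.
* **Quantile normalization** forces every sample's empirical distribution
  onto the across-sample mean of order statistics; ties receive the mean
  of their tied target quantiles. The operation is idempotent and removes
  any global per-sample shift — which is why the synthetic generator does
  not put a coherent all-gene patient offset into the data (see below).
* **Summarization** fits, per TC, `log2 y_ps = mu + probe_p + sample_s + e`
  by iteratively reweighted least squares with Huber weights
  (`k = 1.345` on MAD-standardized residuals, re-estimated each
  iteration; at most 50 iterations, coefficient tolerance `1e-8`). Probe
  effects are constrained to sum to zero, so `mu + sample_s` — the
  reported TC value — carries the level. A very large `k` recovers the
  ordinary least-squares fit exactly, which the tests use as an oracle;
  on outlier-free additive data the robust and OLS fits agree to 1e-6,
  while a single probe corrupted by +10 log2 moves the robust sample
  summary by < 0.05 where OLS is pulled by 2.5. A TC with one probe is
  passed through unchanged (reported); a single sample is an error.

## Baseline disease-vs-control ranking

Per gene, the log2 fold difference of SLE week-0 means over healthy
means, a Welch two-sample t-test, and Benjamini–Hochberg q-values over
all genes. Ranking is by descending fold difference — the reading of
"ranked from high to low" adopted here, with ranking by significance
available as an option (`top_genes(by = "significance")`). Genes with
zero variance in both groups get p = 1 when the means agree and p = 0
otherwise.

## Per-gene MMRM and the PD contrast

For each gene the model is

    y ~ group * factor(week) + age + sex + log(leucocytes)

fit to the SLE samples by generalized least squares maximizing the REML
criterion (`nlme::gls`), with a structured within-patient covariance:

* `spatial_power` (default): correlation `rho^|week_i - week_j|`
  (continuous-time AR(1)), the standard choice for the unequally spaced
  weeks {0, 2, 4, 12, 24};
* `compound_symmetry`: exchangeable correlation;
* `independence`: no correlation (in this limit the fit equals OLS, an
  oracle used by the tests).

Placebo and week 0 are reference levels, so the `group:week` interaction
coefficient *is* the pharmacodynamic effect: the arm's change from
baseline minus the placebo change from baseline at that week. Wald
inference uses the normal reference distribution — per-gene sample sizes
(hundreds of observations) make small-sample degrees-of-freedom
corrections a second-order concern, but this is a documented limitation
rather than a claim of exactness. Cell counts enter log-transformed
because they are positive and right-skewed; missing covariates are an
error, never imputed, since the model includes them unconditionally.
Patients missing the baseline visit are excluded with a warning.
Non-converged genes are flagged, kept in the output, and excluded from
q-value computation (BH within each arm-by-week contrast). No
empirical-Bayes variance moderation is applied.

The MMRM recovery benchmark in the test suite fits with
`compound_symmetry`: the generator induces exchangeable within-patient
correlation through a random intercept, so compound symmetry is the
correctly specified structure for that data, and with it the Wald test
holds its nominal size. Spatial power remains the package default for
real data, where correlation decays with visit distance; fitted to
exchangeable data it over-estimates the variance of long-lag contrasts
and becomes conservative, which is the safe direction but not a
calibration claim.

## N-of-1 signature stratification

For each patient, per-gene differences
`d_g = x_{patient,g} - mean_over_patients(x_{.,g})` are formed over the
signature genes and tested against zero with a two-sided Wilcoxon
signed-rank test; `p < alpha` with positive (negative) median difference
calls the patient signature-high (low), otherwise neither. This
one-sample reading — one difference per gene against the cohort mean — is
the default; a two-sample rank-sum variant (`method = "rank_sum"`) is
available. The cohort mean includes the index patient by default
(`leave_one_out = TRUE` to exclude; with hundreds of patients the
difference is negligible). Exact zero differences are dropped per the
signed-rank convention and reported. At least 5 resolvable signature
genes are required; unresolved gene ids raise a warning naming them
rather than disappearing silently. `stats::wilcox.test` supplies the
p-value and uses the exact null distribution for the gene-set sizes used
here; the tests verify it against a full 2^n sign-flip enumeration for
n ≤ 12.

**The trajectory permutation test.** Within one arm, per-patient
SLEDAI-2K changes from baseline are averaged per visit within the
signature-high and signature-low groups ("neither" patients are
excluded, as only the two strata are compared). The observed statistic is
the unweighted mean over post-baseline visits of (low mean − high mean);
B iterations (default 10 000) shuffle the high/low labels among the same
patients preserving group sizes. The p-value is one-sided — does the high
group improve more? — with the add-one convention
`p = (1 + #{null >= observed}) / (B + 1)`, so p is never zero and the
test is valid at finite B; a two-sided option exists. Averaging rather
than summing across visits is immaterial for a fixed visit count;
averaging was chosen as the simpler estimand. With complete visit data
the statistic reduces to a difference of group means of per-patient
visit-averaged changes, which the implementation exploits for speed (the
general per-visit path handles missing visits). Results are invariant to
input row order and bit-reproducible at a fixed seed.

**LOESS curves** (tricube weights, degree 1, default span 0.75,
`surface = "direct"` for exact small-sample evaluation) are display
only; the permutation statistic never uses them.

**Percentile co-elevation.** The per-gene threshold is the 95th
percentile of healthy controls in the linear-interpolation definition
(R's type-7 quantile — e.g. healthy values 1..100 give 95.05); a patient
is high only if *strictly* above it. Both conventions are pinned because
neither is universal. Fisher's exact test reports the sample odds ratio
`ad/bc` (infinite when a zero appears in the denominator) and a
two-sided p summing hypergeometric probabilities not exceeding the
observed table's probability (with the customary `1 + 1e-7` relative
slack for float ties); fewer than 20 healthy controls triggers a
stability warning.

## Cytokines

Censored measurements are imputed to exactly `0.5 * LLOQ` (idempotent).
Baseline comparisons pool the three SLE arms against healthy controls
with a two-sided Mann–Whitney U on log-imputed concentrations, reporting
detectable fractions per group; if everything is censored in both groups
the test is degenerate and p is reported as 1 with a flag. The
change-from-baseline analysis uses natural-log deltas (the base cancels
in rank statistics; natural log is pinned so reported medians are
reproducible), excludes patients censored at *both* the baseline and the
target visit (counting them), retains patients censored at exactly one
visit with the imputed value, and compares each arm's deltas with
placebo by Mann–Whitney U (Welch's t as an option). Deltas are invariant
to the concentration unit. No multiplicity correction is applied across
analytes by default, matching the per-analyte reporting convention; a BH
option exists. Tobit-style censored regression is a non-goal.

## Network extraction

From the PD effects of one arm/week (canonically 4 mg at week 12), the
selected set is the union of (1) the `n_top = 50` genes with smallest
q-values, (2) genes with `q < 0.05` sharing a transcription-regulation or
phosphorylation edge with JAK1 or JAK2, and (3) the anchors STAT1, STAT2,
JAK1, JAK2, TYK2. Edge qualification treats direction as irrelevant by
default (`directed_rule = TRUE` restricts to edges out of JAK1/JAK2) —
the undirected reading is the generous one and the switch is explicit.
The induced subgraph is then reduced to the connected components (weak
sense) containing at least one anchor; an empty edge table yields the
anchors alone, flagged. Self-loops are dropped with a message. Node
categories come from a user-supplied annotation table (anything
unannotated or unrecognized becomes `other`). No interaction database is
bundled — curated databases of this kind are proprietary — so the module
consumes any SIF/TSV edge table. Output is deterministic under edge-file
row order.

## The synthetic trial generator

The generator is the package's test bed and defines the study conditions
under which every property is validated:

* **Cohort**: 90 SLE patients per arm and 50 healthy controls by default,
  ages ~ N(45, 12²) clipped to [18, 80], 92% female, leucocyte counts
  log-normal around 5.5×10⁹/L — the shape of a phase II lupus trial
  population.
* **Expression**: gene baselines `mu_g ~ N(7, 1)` log2 units; an
  IFN-responsive block (default 50 genes, containing STAT1 and STAT2)
  elevated by `elevation_log2 = 2` in a fraction `frac_ifn_high = 0.625`
  of SLE patients — the midpoint of the 50–75% interferon-signature
  prevalence reported for lupus populations; treatment reduces block
  genes by `pd_effect_log2 = -0.5` log2 in the 4 mg arm at weeks ≥ 2,
  with the 2 mg arm at half that effect (`dose_ratio = 0.5`; the graded
  dose response is qualitatively established, the exact ratio is not, so
  a simple half is used); residual SD 0.5 log2.
* **Within-patient correlation** comes from a random intercept per
  (patient, gene) with SD `noise_sd/2` (intra-class correlation 0.2).
  The intercept is deliberately *not* shared across genes: quantile
  normalization removes coherent all-gene sample shifts from real data,
  and a shared offset would also act as a per-patient confounder of the
  N-of-1 call that preprocessing is designed to remove.
* **Trajectories**: baseline SLEDAI-2K ~ round N(8.8, 3²) floored at 4
  (active disease at entry); change from baseline = placebo drift
  (−0.5 to −1 over the visits) + dose-scaled responder benefit (−1, −2,
  −3, −4 at weeks 2–24) for signature-high patients + N(0, 3²) noise,
  rounded and floored at 0. Effect magnitudes are chosen for
  testability; no published per-visit effect sizes exist to copy. The
  ≥ 0 floor truncates large improvements when the baseline is low —
  faithful to a bounded score — so the generative-mean tests run at a
  high baseline where the floor is inactive.
* **Cytokines**: log-normal concentrations per analyte (panel of IFN-α,
  IFN-γ, IL-6, IL-12p40, IL-10, IL-17A with plausible pg/mL geometric
  means and LLOQs), SLE means elevated over healthy, a −0.4 natural-log
  treatment effect on IL-6 and IL-12p40 in the 4 mg arm from week 12
  (2 mg half), residual `sd_log = 0.8` and a per-(patient, analyte)
  intercept of half that. Censoring below the LLOQ follows from the
  model; its fraction matches the log-normal CDF at log(LLOQ), which the
  tests verify.
* Every draw is recorded in a `truth` object (serialized as TSV + JSON,
  round-trip tested) so recovery can be scored exactly.

**What the generator does not emulate** — and what passing tests
therefore do not establish about real data: probe sequence effects and
spatial array artifacts, batch effects, heavy-tailed or skewed expression
noise, informative dropout, correlated gene-gene noise beyond the planted
block structure, placebo response heterogeneity, and assay drift. The
test suite shows the estimators recover the effects *their models
assume*; robustness to violations of those assumptions is only probed
where stated (outlier probes for the summarization step).

## Benchmark configurations used by the test suite

Problem sizes are chosen so the full suite runs in a few minutes on one
core while keeping Monte Carlo error far from the pass thresholds:

* Permutation-test size: 30 patients/arm, 500 replicates of B = 2000 at
  a null (zero-benefit) configuration; the rejection count at
  alpha = 0.05 must fall inside the exact binomial 99% interval.
* Permutation-test power pattern: default planted benefits, 100
  replicates of B = 1000; median p < 0.05 in the 4 mg arm and > 0.05 in
  placebo.
* MMRM recovery: 200 genes with a planted −0.5 log2 effect plus 200 null
  genes at 90 patients/arm; the mean week-12 contrast must lie within
  ±0.05 of −0.5 and null rejections inside the binomial 99% interval.
* Signature recall: 200 patients of whom 25 are planted high (+1 log2 on
  20 signature genes, noise SD 0.5) and 25 low (−1); recall of the high
  stratum must be ≥ 95%. The planted strata are symmetric minorities so
  the cohort mean stays centred and the nominal +1 offset is the
  effective patient-vs-cohort contrast being tested. At an
  interferon-high fraction of 0.625 the cohort mean absorbs most of a
  +1 elevation — the patient-vs-cohort contrast shrinks to 0.375 log2 —
  and no test of this design can reach 95% recall; recall at the trial
  composition is instead exercised at the generator's default
  `elevation_log2 = 2`, where the contrast is 0.75 log2.

## Known limitations

* Wald normal inference for the MMRM (no Kenward–Roger style df); fine
  at these sample sizes, anti-conservative at small ones.
* The spatial-power MMRM is conservative when the true within-patient
  correlation does not decay with visit distance.
* Quantile normalization assumes approximately exchangeable sample
  distributions; strong global treatment effects are partly absorbed.
* Half-LLOQ imputation biases location estimates of heavily censored
  analytes; rank tests limit, but do not remove, the effect.
* The N-of-1 call treats signature genes as exchangeable evidence;
  correlated genes overstate the effective sample size of the
  signed-rank test.
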