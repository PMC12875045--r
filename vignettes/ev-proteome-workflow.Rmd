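---
title: "Methods: macrophage EV-proteome analysis with evcargo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macrophage EV-proteome analysis with evcargo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcargo)
```

`evcargo` analyzes label-free DIA proteomes of extracellular vesicles (EVs)
released by polarized macrophage subtypes (M1-like, M2-like, and
ascites-reprogrammed TAM-like cells, unpaired donors), plus the particle
and clinical statistics that surround such a study. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Quantification model

The input is a long precursor report in DIA-NN dialect: one row per run,
protein group and precursor, carrying the run-specific protein q-value and
the protein-level MaxLFQ intensity. Three decisions define the protein ×
sample matrix:

* **Detection filter.** A record with q-value at or above `q_max`
  (default 0.01) is treated as undetected in that run. A protein is
  retained in a group when at least `ceiling(min_donor_fraction * donors)`
  donors (default: half, so 2 of 3) show at least `min_precursors`
  (default 3) q-passing precursors. The merged matrix is the union of the
  per-group retained sets. Whether this filter should act per group or
  globally is genuinely open; we chose per group (then union) because it
  preserves subtype-specific detection counts and a meaningful "core"
  intersection, and expose `scope = "global"` for the other reading.
* **Median centering.** Each sample column is shifted so its median over
  observed cells equals the grand median of the pre-centering sample
  medians. This anchors the grand scale (making the operation idempotent)
  while preserving within-sample differences exactly. A column with zero
  observed cells is an error.
* **Imputation.** Missing cells of sample *s* are drawn from
  `Normal(mu_s - shift_sd * sigma_s, (width_sd * sigma_s)^2)` with
  `shift_sd = 1.8` and `width_sd = 0.3` (in units of the sample SD), the
  widely used down-shifted-normal convention for values near the limit of
  detection; both constants are exposed. Samples with fewer than two
  observed values are rejected (no SD). Imputation happens once on the
  whole matrix, before any contrast subsetting, so all contrasts see the
  same data; an analysis wanting per-contrast imputation can simply refit
  from the filtered object.

Intensities are log2 throughout; non-positive intensities are rejected at
parse time.

## Moderated testing

Contrasts are unpaired two-group comparisons on the imputed matrix (imputed
cells included, matching the workflow order above). With per-protein sample
variance $s_g^2$ on $d_g = n_a + n_b - 2$ df, the empirical-Bayes prior
$(d_0, s_0^2)$ is estimated by moment matching on $z_g = \log s_g^2$: under
a scaled-F model, $E[z] = \log\sigma^2 + \psi(d_g/2) - \log(d_g/2)$ and
$\mathrm{Var}[z] = \psi'(d_g/2) + \psi'(d_0/2)$, so the excess dispersion
of $z$ identifies $d_0$ through the inverse trigamma (Newton iteration,
relative tolerance $10^{-12}$) and the mean identifies $s_0^2$. Degenerate
cases: when the observed dispersion does not exceed $\psi'(d_g/2)$ the
variances look homogeneous and we set $d_0 = \infty$ with
$s_0^2 = \bar{s^2}$; variances below $10^{-5}$ times the median are clamped
before taking logs. Forcing `prior_df = 0` recovers the ordinary
equal-variance t-test, `prior_df = Inf` the fully pooled test — both limits
are tested.

The moderated statistic
$t_g = \mathrm{log2FC}_g / (\tilde s_g \sqrt{1/n_a + 1/n_b})$ with
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ is referred to
$t(d_0 + d_g)$, two-sided. BH adjustment uses the standard step-up rule
(ties resolved by the stable sort underlying `p.adjust`), and DAPs are
calls at FDR-adjusted p < 0.05. We deliberately support only single
pairwise contrasts — no covariates, weights, or variance trends: the
three-subtype design needs nothing more, and a shared three-group variance
fit (the other defensible reading) is obtainable by fitting each contrast
on the common matrix; counts from pairwise fits are what the set logic
below consumes.

## MISEV-2023 composition

The ontology is the fixed 12-subcategory code set (1a–5c) with main
categories 1–5; an annotation maps each gene to at most one subcategory.
Two disambiguations are enforced at load time: lipoproteins stay the sole
occupants of 3a while other secreted proteins live in category 5 (the two
categories otherwise overlap by construction), and duplicate gene rows are
an error — one subcategory per gene. Matching against a quantified proteome
is case-insensitive with no alias expansion (alias tables drift; unmatched
genes are reported, not guessed).

Per-sample composition is reported as `%Np`: the percentage of the
sample's total q-passing precursor count attributable to each category.
"Number of precursors" is read literally as *counts* of distinct
precursors; an intensity-share mode is available behind
`mode = "intensity"` for the other reading. Subcategory percentages sum
exactly to their main category, and main categories plus the unannotated
remainder sum to 100. The endosomal-origin ratio divides each sample's
`%Np` of categories 1 ∪ 2a by the **arithmetic mean** of the reference
(TAM) group — mean rather than median because the reference bar is defined
as a group average of three donors; with n = 3 the difference is
immaterial. Marker-panel heatmap values are row z-scores with the
*population* SD (so a displayed row has mean 0, SD 1 exactly); constant
rows get z = 0 with a flag.

## Signature set logic

From the three contrasts, `pro` and `anti` are the up-in-M1 and up-in-M2
DAPs of the M1-vs-M2 contrast; `tam_enriched` is the union of up-in-TAM
DAPs over both TAM contrasts. A protein significant in *opposite*
directions across the two TAM contrasts is contradictory evidence: it is
excluded from `tam_enriched` and reported in `direction_conflict` rather
than silently kept. The remaining sets are pure set algebra, and two
identities are enforced by tests on random inputs: `tam_unique`,
`tam_pro`, `tam_anti` partition `tam_enriched`, and
`|pro| - |tam_pro| = |m1_sig|` (likewise for the anti side). Down-in-TAM
DAPs are reported (`tam_depleted`) but never counted as enrichment.
Hazard-ratio prognosis splits report the median HR per direction with a
95% CI from binomial order statistics — distribution-free and honest at
the small set sizes involved.

## Enrichment and clinical statistics

Over-representation uses the upper hypergeometric tail
$P(X \ge k)$ with set sizes measured *after* intersecting each set with
the user-supplied universe (all detected genes), the size window
[15, 500], BH across tested terms only, and flags at p < 0.05, q < 0.20.
"q-value" here means BH-adjusted p. No ontology graph handling: the
collection is a plain GMT, which keeps results reproducible offline.

Survival screens are univariate Cox fits (Breslow ties by default — ties
are rare in continuous protein levels; Efron available), via the
`survival` package. Kaplan–Meier splits cut at a quantile `q` of the
protein level (default median; the split quantile is a first-class
parameter because published splits vary); the group median survival is the
first time the curve reaches 0.5, flagged undefined if it never does. The
log-rank p is asymptotic chi-square by default, with an exhaustive
permutation option over group labelings that is exact for small cohorts
(enumeration over $\binom{n}{n_{high}}$ labelings; practical to n ≈ 12).
Rank-sum plasma screens use exact enumeration up to 12 total samples
(without ties) and the tie-corrected normal approximation otherwise.

The bootstrap gene-set correlation test draws `n_boot` (default 100,000)
random gene sets of the marker-set size, without replacement within a
draw, and reports the one-sided empirical p as the literal fraction of
draws with correlation at least the observed one — no +1 continuity
correction by default, so a reported p of 0.003 means exactly 300 of
100,000 draws; `add_one = TRUE` gives the conservative convention.
Correlations are Pearson on the supplied (log10-scale) values.

## Particle metrics

Release is `concentration × dilution × volume / cells seeded`. Size
distributions are histogrammed on uniform bins inside the calibrated
40–200 nm instrument window (events outside are rejected with a count) and
fitted with an amplitude–mean–SD Gaussian by Levenberg–Marquardt least
squares, initialized at the sample moments. We fit the *binned relative
frequencies* rather than maximizing the raw-event likelihood because the
published size profiles are binned curves; the sample moments and median
are reported alongside so disagreement is visible. The detergent-lysis
fold change is `(treated - untreated)/untreated`, so complete lysis gives
-1.

## The synthetic-data generator

`sim_config()`/`simulate_report()` emulate the study design: three subtypes
× three unpaired donors, log-normal protein intensities (log2-normal with
`baseline_mean = 14`, `baseline_sd = 2` — typical MaxLFQ dynamic range),
within-group residual SD 0.5 (a realistic run-to-run spread for EV
preparations and the spread used throughout the power checks), planted
group effects of ±2 log2 units on an expected 10% of proteins per contrast,
truncated-Poisson precursor counts (mean 6), 5% of protein-run records
failing the q threshold, and intensity-dependent missingness: a record is
dropped with probability $\sigma(a - b x)$ where $b$ is
`missing_mnar_strength` and $a$ is calibrated by bisection so the overall
missing rate hits `missing_rate` (default 10%). Effects are planted as
"up in exactly one group", so every pairwise contrast sees true log2 fold
changes of exactly 0 or ±2 — this is what makes ground truth bookkeeping
exact.

What it does *not* emulate: real MaxLFQ intensity distributions (log-normal
is asserted, not derived), peptide-level structure (no sequences, spectra
or shared peptides), correlated protein co-regulation, batch effects, or
donor-level pairing. Passing tests therefore demonstrate statistical
correctness of the pipeline under a faithful-but-idealized generative
model, not performance on any particular real dataset. The cohort
generator uses an exponential baseline hazard with log-linear protein
effects and uniform censoring tuned to a target rate; the size generator
is a rejection-truncated Gaussian mixture.

## Problem sizes and tolerances in the test suite

The statistical checks run at sizes chosen to make their bounds sharp while
keeping the suite quick: null uniformity on 5,000 proteins (KS at the 1%
level) and type-I error on 10,000; planted-DAP recovery over 20 seeds of
2,000 proteins (observed ≈ 98% recovery, FDR ≈ 4%); hazard-ratio recovery
over 50 cohorts of n = 400; bootstrap-null uniformity over 200 repetitions
of 2,000 draws; exhaustive oracles (ORA enumeration, log-rank permutation,
Cox grid maximization) only at sizes where enumeration is exact and cheap.
Agreement tolerances are 1e-12 against closed forms, 1e-8 against the
independent empirical-Bayes reference implementation, and 1e-6 against
numerical-optimization oracles.

## Known limitations

* Gene-symbol matching has no alias table; annotation coverage is the
  user's responsibility.
* The moderated test assumes equal group variances and imputed values are
  treated as real observations; heavy MNAR missingness therefore inflates
  variance for affected proteins and costs power (visible in the worked
  example) — by design, since invented values should not create
  confidence.
* The Cox screen is strictly univariate, with no proportionality
  diagnostics or competing risks.
* `%Np` composition depends on the annotation's coverage; the unannotated
  remainder is always reported so this is visible.
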