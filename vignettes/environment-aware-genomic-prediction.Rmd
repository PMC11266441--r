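---
title: "Environment-aware genomic prediction for multi-environment trials: methods and design"
author: "enviroGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environment-aware genomic prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enviroGP)
```

## Overview

`enviroGP` predicts hybrid maize grain yield across multi-environment
trials (MET) by feeding a gradient-boosting learner with engineered
environmental features (envirotyping), genomic relationship matrices,
or both, and evaluates the models under sparse-testing
cross-validation. This vignette explains the statistical machinery,
the defaults and their rationale, what the synthetic-data generator
does and does not emulate, and the numerical choices a maintainer
would want to know.

## Stage 1: single-trial mixed models

Each environment (a location-year) is analyzed separately with

$$Y_{ijklm} = \mu + H_i + R_j + b(R)_{jk} + r_l + c_m + e_{ijklm},$$

where the hybrid effect $H_i$ and replicate effect $R_j$ are fixed
and block-within-replicate, field row and field column are
independent random effects. Variance components are estimated by
REML through `lme4`; the per-hybrid BLUEs are the fixed-effect
predictions averaged over replicate levels, on the Mg/ha data scale.
Assumptions worth stating: row and column effects are i.i.d. (no
AR1-type spatial correlation), and missing plots are missing at
random — hybrids with no surviving plot are dropped from that trial
with a warning.

Two diagnostics summarize trial quality:

* **CV%** $= 100\,\sqrt{\hat\sigma^2_e} / \bar{\hat y}$, using the
  residual variance (the "residual" reading of the CV numerator;
  an alternative reading of the same symbol as the row-effect
  variance would make the statistic insensitive to the error level,
  so the residual interpretation is used).
* **Cullis generalized heritability**
  $H^2 = 1 - \bar V(\Delta) / (2\hat\sigma^2_g)$, from a companion
  refit with hybrid random. $\bar V(\Delta)$ is the mean over all
  hybrid pairs of $\mathrm{var}(\mathrm{BLUP}_i - \mathrm{BLUP}_j)$.
  `lme4` exposes only per-level conditional variances, so the full
  prediction-error-variance matrix is recovered in-package from the
  mixed-model equations at the REML estimates:
  $\mathrm{PEV} = \hat\sigma^2_e\, [C^{-1}]_{gg}$ with
  $C = [X'X, X'Z; Z'X, Z'Z + \mathrm{diag}(\hat\sigma^2_e/\hat\sigma^2_k)]$.
  The result is clamped to $[0,1]$ with a warning, and a zero genetic
  variance returns 0 with a degenerate flag.

Numerical choices: plots are put into a canonical order (replicate,
block, row, column, hybrid) before fitting, which makes every
estimate exactly invariant to input row order — on small trials the
REML surface can have a nearly flat block/row ridge, and without
canonical ordering the optimizer's stopping point would depend on
floating-point summation order. Optimizer tolerances are tightened to
`1e-10`; random terms whose grouping factor has fewer than two levels
or one level per observation (confounded with the residual) are
dropped; a rank-deficient fixed design (hybrid aliased with
replicate) raises an estimability error naming the aliased
coefficients rather than silently dropping them. `force_zero_variance
= TRUE` gives the exact zero-variance limit (ordinary least squares),
used by the tests as an analytic anchor.

## Stage 2: the environmental matrix

Each environment is summarized by 90 features in six declared
categories, recorded in a manifest (name, category, units, recipe) so
any alternative recipe is a drop-in change:

| category | count | default recipe |
|---|---|---|
| weather | 63 | 4 variables x 4 windows x {mean, max, min, sd}, minus one |
| ec_svd | 15 | uncentered truncated SVD of 765 crop-model covariates |
| lagged_yield | 6 | mean, min, p25, p50, p75, max of last year's yield at the location |
| soil | 3 | nitrate ppm, nitrogen lb/acre, calcium % |
| coordinates | 2 | floor-binned latitude (s = 1.2) and longitude (s = 3.6) |
| management | 1 | irrigation flag |

Design notes, where the design was genuinely open:

* **Season windows.** Weather is aggregated over the whole trial
  window plus its intersections with the meteorological seasons
  (spring Mar–May, summer Jun–Aug, autumn Sep–Nov). The 4 x 4 x 4
  grid gives 64 candidate features; the minimum 30-minute rainfall
  over the whole season is identically zero and is dropped, leaving
  63. Windows are config-driven; an empty window produces missing
  features with a single warning.
* **Lagged percentiles.** The six lagged statistics are mean, min,
  quartiles and max — a symmetric, conventional summary. A first-year
  environment has no lag and gets six missing values; the tree
  learner handles missingness natively, and SVD-based constructions
  mean-impute first.
* **Coordinate binning** uses the true floor (toward $-\infty$), so
  $-100.5$ at $s = 3.6$ bins to $-100.8$. Quotients within a few
  ulps of an integer are snapped before flooring so that binning is
  exactly idempotent.
* **EC SVD** is uncentered (scores reproduce $XV$), with a centering
  toggle. Explained-variance ratios are relative to the uncentered
  total sum of squares, so the first component typically captures the
  mean structure.
* **Management** defaults to a categorical irrigation flag — the one
  management descriptor that is routinely known per trial.

Sign ambiguity of every SVD in the package is resolved by making the
largest-magnitude loading of each component positive; ratios and
scores are then reproducible across platforms and row orders (up to
exact ties).

## Stage 3: marker QC and relationship matrices

The QC order is fixed: keep phenotyped individuals, then drop markers
with minor allele frequency below 0.01, then LD-prune — allele
frequencies are always computed on the retained hybrid set. LD
pruning implements pairwise semantics on the squared Pearson
correlation of dosages: within a sliding window of 100 surviving
markers, while any pair exceeds $r^2 = 0.9$, the member of the worst
pair with the higher mean $r^2$ to the rest of the window is removed
(ties: the later position goes); the window then advances by 20
markers and never spans chromosomes. The tie-break is a package
choice made deterministic so results are exactly reproducible.

Relationship matrices use dosage coding 0/1/2 with per-marker
mean imputation of missing calls:

* **Additive (VanRaden):** $Z_{\cdot m} = d_{\cdot m} - 2p_m$,
  $A = ZZ' / (2\sum_m p_m(1-p_m))$.
* **Dominance (Vitezica):** per-marker coding $-2p^2,\ 2pq,\ -2q^2$
  for dosages 0, 1, 2 (zero mean under Hardy–Weinberg proportions),
  $D = WW' / \sum_m (2p_m q_m)^2$.

Monomorphic markers raise a division-guard error instead of
producing NaNs; both matrices are explicitly symmetrized to remove
floating-point asymmetry and validated to $10^{-10}$.

## Stage 4: learner inputs

All four constructions return one row per (Env, Hybrid) BLUE record
with the field location (environment name without the year) as a
categorical column:

* **E** — left join of the environmental matrix by Env. Since all
  features are per-environment, any model fitted on E predicts a
  single value per environment.
* **G** — top-100 SVD scores of the GRM, joined by Hybrid.
* **G+E** — concatenate the env features and the GRM row of each
  record (width about 90 + q) and keep the top-100 SVD scores. No
  explicit interaction: trees form interactions by construction.
* **GEI** — the Kronecker product $X_{nq \times mq} = E \otimes G$.
  At study scale this matrix is enormous, so the package never forms
  it: with $E = U_E S_E V_E'$ and $G = U_G S_G V_G'$,
  $\mathrm{SVD}(E \otimes G) = (U_E \otimes U_G)(S_E \otimes S_G)(V_E \otimes V_G)'$,
  and the score of record (env $i$, hybrid $j$) on the component with
  singular value $s_a t_b$ is $u_{E,ia}\, u_{G,jb}\, s_a t_b$. The
  top-k products are selected in decreasing order (index-ordered on
  ties). A materializing fallback exists behind a size cap purely as
  an oracle for tests; requesting it above the cap raises a memory
  guard.

Feature scaling before the SVDs is deliberately absent (raw
concatenation), with a centering toggle exposed; `k` larger than the
rank bound is reduced with a warning.

## Stage 5: the gradient-boosting learner

The learner is gradient-boosted regression trees via `xgboost` with
leaf-wise (`lossguide`) histogram growth — the same GBM family as the
LightGBM-style tooling common in this literature, configured through
the familiar vocabulary: `num_trees` (100), `learning_rate` (0.1),
`max_leaves` (31), `min_data_in_leaf` (20; for squared loss the
hessian equals the leaf count, so `min_child_weight` implements it
exactly), `feature_fraction` and `bagging_fraction` (1.0), and a
mandatory seed. These defaults are the library family's defaults —
no tuning was attempted, and every value is exposed in the
configuration. Fits are single-threaded, so identical inputs and
seed give bit-identical predictions. The field-location categorical
is one-hot encoded with a level set shared between training and
validation. Note the leaf minimum of 20 means toy data sets with
fewer than 40 rows produce constant predictions (no admissible
split); tests that need splits on toys lower `min_data_in_leaf`.

## Stage 6: cross-validation and metrics

All schemes run 10 repetitions of 5-fold CV; folds partition their
sampling frame with sizes differing by at most one record.

* **CV2** (sparse testing): folds partition the environment-hybrid
  combinations of the last two trial years; 20% are withheld per
  fold.
* **CV1** (new hybrids): folds partition the final-year hybrid set;
  a fold's hybrids contribute their final-year records to validation
  and all their records are removed from training.
* **CV0** (new year): validation is the final-year records of 20% of
  the final-year hybrids that are "known" (have at least one
  earlier-year record); training is those hybrids' earlier-year
  records plus the earlier-year records of an additional 60% sample
  of the remaining earlier-evaluated hybrids. No final-year record
  ever enters training. On a carryover trial design this lands at
  about an 80:20 train:validation proportion; the splitter warns
  with the achieved ratio when the earlier-year pool is too small to
  reach it.

Metrics: Pearson accuracy (with explicit zero-variance and n < 3
errors rather than NaN); the Coincidence Index
$(B - R)/(T - R)$ with $T = \lceil 0.2N \rceil$ and $R = 0.2\,T$ (the
expected overlap when both rankings select the same fraction at
random — the chance-expectation convention adopted here), with ties
broken by a stable sort on the id; the tester-overlap
$\bar p = \frac{1}{kr}\sum |W \cap Z| / |W \cup Z|$ over fold-by-
repetition cells; and the Meng–Rosenthal–Rubin z test for two
overlapping dependent correlations, with the intercorrelation
$r_{12}$ computed from the stored prediction vectors and Bonferroni
correction across the family of model pairs within a scheme. Pooled
comparisons concatenate all validation predictions of a scheme, so
one test per model pair is reported.

## The synthetic-study generator

The generator emulates a three-year parent-by-tester hybrid trial
network so that every stage of the pipeline is testable without any
external data. What it emulates, and the defaults:

* **Population.** Fully inbred parents and testers; each hybrid's
  marker dosage is parent allele + tester allele, so heterozygosity
  (and dominance) is realistic for F1 hybrids. Two main testers in
  year one, four (one carried over) in the later years — 125 parents
  per tester by default (625+ hybrids) — plus a ~1.6% minority of
  hybrids from minor testers in the later years, mirroring the small
  "other tester" share a real program carries. That minority is what
  makes the CV1 tester overlap fall below 100% (a 20% hybrid sample
  can miss a five-hybrid tester) while CV2 overlap stays at 100%.
  Marker MAFs are drawn in [0.05, 0.5]; tester alleles are
  frequency-matched (round(p x n_testers) carriers) because a
  Bernoulli draw over so few testers would let the realized panel
  MAF drift far outside the configured range. Ten percent of markers
  are near-duplicates of a neighbour so LD pruning has work to do.
* **Trial network.** The network grows over the years (7/9/10
  environments by default) with locations nested across years, and
  the year-two cohort carries over fully into year three. This
  carryover structure is what makes the literal CV0 recipe (20%
  validation, 60% earlier top-up) land at the 80:20 proportion; a
  flat network with equal yearly environment counts would land
  nearer 83:17. Each environment samples 60% of its year's cohort
  (incomplete overlap), with every cohort hybrid guaranteed at least
  one environment per year.
* **Phenotypes.** Plot yield = intercept (10.5 Mg/ha) + additive +
  dominance + environment + GxE + block(rep) + row + column +
  residual. Genetic values come from i.i.d. normal marker effects
  rescaled so realized hybrid-level variances hit the configured
  components exactly; default components (Mg/ha)^2 are v_g_add 0.35,
  v_g_dom 0.05, v_env 2.0, v_gxe 0.25, v_block 0.05, v_row 0.03,
  v_col 0.03, v_resid 1.5 — chosen so that single-trial CV% lands in
  the 10–17% band and heritabilities in the 0.3–0.7 band typical of
  maize METs, with environmental variance dominating genetic
  variance as it does in a continent-wide network.
* **Learnable environment signal.** A latent per-environment index
  drives part of the environment main effect (correlation 0.7), the
  temperature level, and the leading factor of the crop-model
  covariate layer; the GxE deviation contains a marker-determined
  reaction norm (hybrid slope x index, weight 0.7) plus i.i.d.
  deviations. This is what gives environment-aware models a
  recoverable advantage; with the correlations at zero the
  environmental features would be pure noise.
* **Layers.** 30-minute weather over a configurable May–September
  window with seasonal and diurnal structure; 765 crop-model
  covariates as mean + rank-12 signal + noise of relative sd 0.01
  (so 15 SVD components capture ≥ 99.9% of the variance);
  coordinates jittered around four regional centers; an irrigation
  flag; and a history table holding the study's own location-year
  plot yields for the lagged features (first-year environments have
  no lag, exercising the missing path).
* **Determinism.** Every stage derives its own seed from the master
  seed, so an identical configuration reproduces the study byte for
  byte, and the realized effects are stored as ground truth — the
  plot value minus the stored effects equals the stored residual
  exactly.

What it does **not** emulate: real maize LD structure (duplication
plus window-local correlation only), real weather climatology or
crop-model mechanics, spatial field trends, and genotype-specific
phenology. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that its qualitative behaviour (environment
features help when GEI and environment signal exist) is reproduced —
not that any particular accuracy level transfers to real data.
Missing-data injection (plots, weather gaps) is off by default and
available through the configuration.

## Problem sizes used by the test suite

The suite exercises the default-scale study (625+ hybrids, 26
environments, 3000 markers) for structural checks, a medium study
(17 environments) for the full 90-feature schema, and toys for the
analytic anchors. Parameter-recovery checks use 200 replicate trials
of 100 hybrids x 2 replicates with all fitted variance components
simulated away from zero — at a zero boundary, REML truncation
biases neighbouring components and the within-3-standard-errors
check would measure that boundary artifact rather than estimator
correctness. The model-comparison check runs two models through 10
repetitions of 5-fold CV2 on an eight-environment study. These sizes
are the package's chosen compromise between statistical resolution
and a test suite that runs in a couple of minutes.

## Known limitations

* No spatial correlation structures (AR1xAR1) in the single-trial
  model; i.i.d. row/column effects only.
* The factor-analytic multiplicative mixed model sometimes used as a
  MET baseline is out of scope; comparisons are among the package's
  own model constructions.
* LD pruning follows pairwise-within-window semantics with a
  documented deterministic tie-break; it is not guaranteed to match
  any external tool's survivor set marker-for-marker.
* The Meng test assumes bivariate normality of the underlying
  scores; with strongly non-normal BLUE distributions its nominal
  error control is approximate (the suite verifies ~5% type-I error
  under a normal null).
* `buildGEI` evaluates scores only at observed (Env, Hybrid) pairs;
  densifying predictions for all conceptual pairs of a large study
  is intentionally unsupported in-memory.
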