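---
title: "Weighted mixed models for therapy-response reversal biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted mixed models for therapy-response reversal biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`dmrev` implements a paired blood-transcriptome analysis for myotonic
dystrophy type 1 (DM1) cohorts sampled before (T0) and after ten months
(T10M) of a behavioural intervention. Its goal is the discovery of
*reversal biomarkers*: genes whose expression is shifted with disease load
(the CTG-repeat expansion length) and shifts back toward normal levels in
patients who respond well to therapy. Because the motivating cohort data
are controlled-access, the package ships a fully replayable synthetic
cohort generator with planted ground truth, and every statistical claim in
the test suite is made against that truth or an independent oracle.

# The models

Let $y_{gps}$ be the log2 counts-per-million of gene $g$ in the sample of
patient $p$ at timepoint $s$, and $w_{gps}$ its precision weight. Three
weighted random-intercept linear mixed models are fitted per gene:

* timepoint model: $y = \beta_0 + \beta_1\,\mathrm{cbt} + u_p + \varepsilon$
* CTG model: $y = \beta_0 + \beta_1\,\mathrm{cbt} + \beta_2\,\mathrm{CTG}_p/100 + u_p + \varepsilon$
* response model: $y = \beta_0 + \beta_1\,\mathrm{cbt} + \beta_2\,r_p\,I(s = \mathrm{T10M}) + u_p + \varepsilon$

with $\mathrm{cbt} = I(s = \mathrm{T10M})$, $u_p \sim N(0, \tau^2)$ a
patient random intercept, and $\varepsilon_i \sim N(0, \sigma^2 / w_i)$.
The CTG covariate is the modal repeat length at trial start divided by
100, identical on both of a patient's rows, so coefficients read "log2
fold change per 100 repeats". The compound response covariate $r_p$ enters
only on T10M rows and is exactly zero at baseline: its coefficient
captures the part of the before/after change that tracks clinical
response, while the shared `cbt` term absorbs global timepoint
differences. The timepoint indicator is kept in every model.

## Estimation and inference

The REML criterion is profiled over $\sigma^2$ and maximised over
$\theta = \tau^2/\sigma^2 \in [0, 10^4]$ by Brent's method, followed by a
bracketed root refinement of the analytic profile-likelihood gradient.
This polish matters: near the optimum the likelihood is numerically flat,
and without it the optimum is located only to about $10^{-7}$ relative
error, which is visible in the Satterthwaite degrees of freedom. With it,
balanced equal-weight fits reproduce the paired $t$-test
($\hat\beta_{cbt}$, se, df, $p$) to machine precision, which the test
suite asserts at $10^{-8}$ against the closed form on 200 simulated
datasets.

For a coefficient $\beta_j$ the Satterthwaite degrees of freedom are
$\mathrm{df} = 2\,(\mathrm{se}_j^2)^2 / \mathrm{Var}(\mathrm{se}_j^2)$,
where $\mathrm{Var}(\mathrm{se}_j^2)$ is the delta-method variance of
$g(\tau^2, \sigma^2) = [\,(X^\top V^{-1} X)^{-1}]_{jj}$ using the inverse
observed information of the REML surface. Both the gradient of $g$ and the
observed information are computed analytically (the Sherman–Morrison
structure of the block-diagonal marginal covariance gives every trace and
quadratic form in $O(np^2)$), so no finite-difference step size enters the
inference. Fits agree with `lmerTest` to six or more digits on weighted,
unbalanced designs.

Boundary policy: when the unconstrained optimum would have $\tau^2 < 0$
(strictly negative REML gradient at $\theta = 0$), the fit is clamped,
flagged `boundary`, and df fall back to the ordinary-least-squares
residual df $n - \mathrm{rank}(X)$ — the exact OLS limit. A vanishing
gradient at $\theta = 0$ (a knife-edge stationary optimum) is treated as
interior, which is required for the paired $t$-test equivalence: a
balanced 3-patient example with pair means on the knife edge must give
df exactly $n - 1 = 2$.

Weights are fixed known precision multipliers and are not re-estimated.
One consequence, shared with `lme4`: splitting an observation into two
half-weight copies preserves every quadratic form but increments the
residual-df count, so the fit moves by $O(1/n)$ rather than being exactly
invariant. The tests document this by asserting agreement with `lmerTest`
on the duplicated data.

Non-converged genes keep their row with missing statistics and are
excluded from the FDR denominator; the count is reported. On generator
data, non-convergence has not been observed.

# Expression preparation

Genes are filtered by the published low-count rule: keep a gene when its
CPM reaches $\mathrm{min.count} / \mathrm{median(lib)} \times 10^6$
(min.count = 50) in at least $n^*$ samples, where $n^*$ equals the
smallest group size $s$ for $s \le 10$ and $10 + 0.7(s - 10)$ beyond, and
its total count reaches 15. The CPM comparison carries a $10^{-10}$
relative slack against float boundaries. The implementation is checked
gene-for-gene against `edgeR::filterByExpr` on random matrices.

Log-CPM is $\log_2((c + 0.5)/(L + 1) \times 10^6)$ on raw column totals —
no TMM scale factors by default, since the motivating analysis names only
the filter and the weighting step; `lib_sizes` is exposed for sensitivity
analyses with effective sizes. Precision weights follow the standard
mean-variance approach: per-gene least squares of log-CPM on intercept +
timepoint, a lowess trend (span 0.5) of the square-root residual sd
against average log2 count, per-observation prediction of the trend at
the fitted log2 count (piecewise-linear, constant extrapolation), and
weight = prediction$^{-4}$. Agreement with `limma::voom` is within 5% on
every weight in the tests; predictions are floored at $10^{-6}$ so weights
stay finite.

# Compound response scoring

Instrument changes are computed as $\mathrm{orientation} \times
(\mathrm{T10M} - \mathrm{T0})$ so that positive always means improved
health; the flagged control instrument (resting activity) is dropped.
Each instrument column is scaled by its uncentred root mean square
($\sqrt{\sum x^2 / (n-1)}$ over non-missing entries), and the compound
response is the per-patient mean of the scaled changes. Missing values
propagate: scaling and averaging use available entries only, and the
number of instruments used is recorded per patient. This is the
minimal-assumption treatment; no imputation is attempted.

One sign-convention note: the prose convention "subtract the 10-month
value from baseline" read literally gives T0 − T10M, which would make
improvements negative for higher-is-better instruments. All downstream
usage associates positive changes with improvement, so the implementation
fixes $\mathrm{orientation} \times (\mathrm{T10M} - \mathrm{T0})$.

# Discovery and validation

Significant sets are built at FDR < 0.05 (Benjamini–Hochberg, delegated to
`stats::p.adjust` and property-tested against a brute-force step-up
implementation). The reversal analysis intersects the CTG and response
sets, reports the Pearson correlation of the two coefficient vectors over
the overlap and over all converged genes (the converged-only universe is
used and its size reported), and the fraction of overlap genes with
opposite coefficient signs. A residualisation check refits the response
covariate on conditional residuals from the CTG model (both stages with a
patient random intercept); planted-truth simulations show correlations
above 0.98 between residualised and full-model response coefficients when
CTG length and response are independent.

Patient heterogeneity is summarised by complete-linkage hierarchical
clustering on per-gene z-scaled expression changes (Euclidean distance,
both axes); leaf order is deterministic given the input order, with ties
broken by the original index, since the original plotting package's leaf
order is not reconstructible. Cross-study validation uses per-gene
two-sample Wilcoxon tests (exact null for combined $n \le 12$ without
ties, else the normal approximation with continuity and tie corrections)
and case-minus-control mean differences on normalized log expression,
correlated with the discovery cohort's CTG coefficients over shared genes.

# The synthetic cohort generator

The generator emulates the study conditions: 27 patients × 2 timepoints,
10,000 expressed genes (matching the ~10,300-gene expressed background),
negative-binomial counts with variance $\mu + \phi\mu^2$, per-gene
dispersions log-uniform on [0.01, 0.3], per-(gene, patient) random
intercepts with sd uniform on [0.1, 0.5] log2 units, and log-normal
library sizes with median $3\times10^7$ read pairs. Expected log2-CPM is

$$\eta_{gps} = \mu_g + u_{gp} + \delta_g I(\mathrm{T10M}) +
\gamma_g \mathrm{CTG}_p / 100 + \rho_g r_p I(\mathrm{T10M})$$

CTG lengths are log-uniform on [120, 900] (the cohort is only described as
spanning a wide range, all expanded alleles); the latent response $r_p$ is
uniform on [−1.5, 2.75], mimicking the reported compound-response display
range. Planted sets default to 500 timepoint genes (|δ| in [0.2, 1.2],
covering the reported 0.64–2.35 fold-change band), 600 CTG genes (|γ| in
[0.1, 0.3] per 100 repeats, within the reported 0.76–1.23 per-100 band),
300 response genes (|ρ| in [0.15, 0.5]), and 100 reversal genes planted in
both sets with $\mathrm{sign}(\rho_g) = -\mathrm{sign}(\gamma_g)$ —
exactly the structure the discovery step is meant to find. The CTG-only
and response-only remainders are disjoint, so the truth-level intersection
equals the reversal set and precision can be measured against it.

The outcome panel has 12 instruments: oriented changes equal
$\lambda_m r_p + \epsilon$ with loadings uniform on [0.5, 1.5] and noise
sd 0.5; four instruments are stored in lower-is-better units (orientation
−1) and must be re-oriented by the scoring module; one pure-noise control
instrument is always emitted and flagged. Stored instrument values are
de-oriented two-timepoint levels, so the scoring module's orientation step
is genuinely exercised round-trip.

`libsize_scale` (default 1/100) shrinks libraries for quick desk-scale
runs. The analysis scripts, the calibration and recovery tests, and
`scripts/acceptance.R` run at `libsize_scale = 1` — full sequencing depth,
the condition under which the min.count = 50 filter retains the expressed
background (~9,850 of 10,000 genes). Negative-binomial draws cost the same
at any depth, so full depth is also the default problem size for all
headline analyses: one complete pipeline run (simulate, filter, weight,
score, three genome-wide model fits, discovery, external validation) takes
a few seconds on one CPU, and the 20-replicate recovery study a few
minutes.

What the generator does *not* emulate: sequencing reads or UMIs, cell-type
composition and its shifts, hemoglobin depletion, interrupted (variant)
repeats beyond an exclusion flag, instrument-specific scoring models,
batch or seasonal effects, and any dependence structure between genes
beyond the shared patient intercepts and library composition. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated generative assumptions, not robustness to the full messiness of
real cohort data.

# Numerical choices

* Brent tolerance ~$\sqrt{\epsilon}\,|\theta| + 10^{-12}$, 300-iteration
  cap; gradient polish by Illinois false position to a $10^{-15}$ relative
  bracket.
* $\theta$ search interval $[0, 10^4]$; an optimum at the upper bound is
  returned as-is (never observed on generated data).
* Boundary classification: clamped when the scaled gradient
  $|\partial l/\partial\tau^2| \cdot \hat\sigma^2 / (n - p) > 10^{-8}$ at
  $\theta = 0$ and negative; otherwise the stationary-point machinery runs
  at $\theta = 0$.
* Singular observed information (never observed on generated data) falls
  back to residual df with a flag rather than failing the gene.
* Lowess span 0.5 and the $-4$ power of the trend are the published
  weighting algorithm's constants; both are arguments.
* RMS scaling uses the $n-1$ denominator, matching the uncentred behaviour
  of the base `scale` routine that defined the compound score.
* Canonical TSV output prints reals at 6 significant digits ("NA" for
  missing), making write–read–write round trips byte-identical.

# Reproducibility

Every stochastic step takes an explicit integer seed, and generators
restore the caller's RNG state. `run_pipeline()` fans a single global seed
out to per-stage child seeds (a fixed hash of the stage name), so stages
are independently reproducible. Two runs with the same configuration and
seed produce identical reports and tables.

# Known limitations

* The compound response covariate is an estimated quantity treated as
  fixed; its sampling noise attenuates response coefficients relative to
  the latent-truth effects (visible in the recovery tests as recall, not
  bias, loss).
* Library-composition effects are real: with a large planted fraction of
  same-sign effects, log-CPM deltas shift globally (no TMM by default);
  at the default planted fraction the shift is well under 0.05 log2 units.
* Satterthwaite inference is slightly liberal at $n = 27$ with estimated
  weights (empirical type-I error near 0.055 at nominal 0.05 for the
  response model), consistent with the behaviour of the standard
  voom + lmerTest stack it mirrors.
* The Wilcoxon exact path is restricted to combined $n \le 12$; larger
  designs use the corrected normal approximation, adequate at the 20 + 20
  sizes used for validation.
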