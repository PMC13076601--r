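---
title: "Methods: case-control lipidomics panel discovery"
author: "lipidpanel"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidpanel)
```

# Scope and model

`lipidpanel` implements the statistical workflow of a two-stage
case-control lipidomics biomarker study. The data model is a wide
feature table: $n$ plasma samples by $p$ lipid species, positive LC-MS
peak-area abundances with a two-level group label (case / control).
Analysis proceeds in five stages, each available as standalone
functions and chained by `discover_panel()`:

1. preprocessing (imputation, log transform, scaling);
2. a supervised OPLS-DA model providing per-lipid VIP scores;
3. the three-criterion differential filter (VIP, univariate p, fold
   change);
4. PCA score-coefficient weighting of the retained lipids and top-$k$
   panel selection;
5. composite scoring and ROC evaluation of the panel.

A parallel, lighter arm screens transcriptome matrices (batch
adjustment, moderated t, preranked GSEA, over-representation) to
motivate the lipid-pathway focus; and a synthetic cohort generator
provides fully specified inputs for every stage.

# Preprocessing

Peak areas are positive and right-skewed, so the default pipeline is
the common metabolomics sequence: drop features missing in more than
`max_missing_fraction` (default 0.5) of samples; impute remaining
missing cells as **half the feature's observed minimum** (the standard
assumption that missingness at the low end reflects the detection
limit); $\log_2$; autoscale (zero mean, unit variance per feature).
Pareto scaling ($\sqrt{SD}$ denominator) and no scaling are available.
Zero-variance features cannot be autoscaled and are dropped with a
warning. Missingness handling assumes MCAR; intensity-dependent
(censoring-type) missingness is *not* modelled, and half-minimum
imputation will bias strongly censored features.

# OPLS-DA

The class vector is coded $+1$ (case) / $-1$ (control) and centered.
With $X$ the scaled data, the fit is the deterministic NIPALS-style
orthogonal projections algorithm:

* candidate predictive weight $w \propto X^\top y$, $\|w\| = 1$;
* X-loading of its score $t = Xw$: $p = X^\top t / t^\top t$;
* orthogonal weight $w_o \propto p - (w^\top p)\,w$, score
  $t_o = X w_o$, loading $p_o$; deflate $X \leftarrow X - t_o p_o^\top$;
* after `n_ortho` deflations (default 1), the final predictive
  component and inner coefficient $b = t^\top y / t^\top t$ are
  extracted from the deflated matrix.

There is no random initialisation, so fits are bit-reproducible.
$R^2Y = 1 - \|y - bt\|^2 / \|y\|^2$. With `n_ortho = 0` the model *is*
1-component PLS regression (verified against an independent closed-form
oracle in the tests). One predictive plus one orthogonal component is
the default because a two-class response admits only one predictive
direction, and a single orthogonal component is what the standard score
plot ($t_1$ vs $t_{o1}$) displays.

**VIP.** With one predictive component,
$\mathrm{VIP}_j = \sqrt{p}\,|w_j| / \|w\|$, the two-class special case
of the general sum-of-squares-weighted formula; $\sum_j \mathrm{VIP}_j^2 = p$
is an algebraic identity and is asserted to $10^{-6}$ on every fixture.
VIP is computed on the predictive component only (some software includes
orthogonal components; that choice would break the link between VIP and
class discrimination that the filter relies on).

**Q².** Stratified $k$-fold cross-validation, default $k = 7$ (the
de-facto chemometrics default). Scaling parameters are re-estimated on
each training fold — estimating them on the full data would leak the
held-out samples into the model and inflate Q². Pooled over folds,
$Q^2 = 1 - \mathrm{PRESS} / \sum (y_{test} - \bar y_{train})^2$; it is
negative when the model predicts worse than the training-class mean,
which is the expected behaviour under label-independent data (mean
Q² ≤ 0 under pure noise is a tested property, as is Q² ≤ R²Y).

**Permutation validation.** The class vector is shuffled `n_perm`
(default 200) times under an explicit seed and Q² recomputed each time;
$p = (\#\{Q^2_{perm} \ge Q^2_{obs}\} + 1)/(n_{perm} + 1)$. Under the
null this p is super-uniform (calibration is a tested property).

# PCA, KMO, Bartlett, Hotelling

PCA is the eigendecomposition of the correlation matrix (equivalently,
PCA of autoscaled data) — the convention for abundances spanning orders
of magnitude; the covariance option exists. Loadings are eigenvectors
scaled by $\sqrt{\lambda}$. Component signs are fixed deterministically
(largest-magnitude loading positive). Rank-deficient directions are
retained with $\lambda \approx 0$ and flagged rather than silently
dropped.

KMO compares squared raw correlations with squared anti-image partials
$a_{ij} = -R^{-1}_{ij}/\sqrt{R^{-1}_{ii} R^{-1}_{jj}}$. Note a limit
worth knowing: as all correlations shrink to zero, raw and partial
correlations vanish at the same rate, so KMO tends to $1/2$, not $0$.
Bartlett's sphericity statistic is
$-(n - 1 - (2p+5)/6)\ln\det R$ on $p(p-1)/2$ df and requires $n > p$.

The Hotelling T² ellipse uses the exact small-sample constant
$c = \frac{2(n-1)}{n-2} F_{1-\alpha;\,2,\,n-2}$; coverage converges to
$1-\alpha$ (tested at $n = 2000$).

# The differential filter and panel weighting

All filter inequalities are **strict**, matching how such thresholds
are printed (VIP > 1, P < 0.05, |log₂FC| > 1): a lipid with VIP exactly
1 is excluded. The validation-stage mode (`abs_log2fc_min = NA`)
applies only the VIP and p criteria. The embedded published tables
(`is_lipid_stats()`) reproduce the printed 19- and 15-lipid counts
under these rules.

Panel weighting follows the stated verbal procedure: retain components
with $\lambda > 1$ (strict); score coefficients
$c_{ij} = \ell_{ij}/\sqrt{\lambda_j}$; per-lipid coefficient
$\sum_j v_j |c_{ij}| / \sum_j v_j$ with $v_j$ the variance-explained
share; weights normalized to sum 1. **Absolute** coefficients are used
because eigenvector entries carry arbitrary signs while the published
coefficients are all positive — averaging signed coefficients across
components would let sign conventions, not structure, set the weights.
The published weight column itself is not numerically reproducible from
the published coefficients (the rounded weights sum to ≈0.476, and no
simple normalization connects the two), so the implementation asserts
the procedure and the resulting panel membership, not the printed
weight values. Ties in panel selection break lexicographically by
feature id, and the tie-break is logged.

# Composite score and ROC

The score is the weight-weighted sum of autoscaled log₂ abundances over
the panel. The weights measure *importance*, not direction, and real
panels mix up- and down-regulated species; a plain weighted sum lets
them cancel. Each lipid therefore enters with its case-like orientation
$d_i = \mathrm{sign}(\bar z_{case,i} - \bar z_{control,i})$ by default.
This was a genuinely open design point: the source study never states
its combination rule, and the literal "weighted sum with a single
global sign flip" reading cannot discriminate when the panel contains
both directions (measurably: on the synthetic validation cohort it
yields AUC ≈ 0.68 versus ≈ 1.0 with per-lipid orientation). The global
rule remains available (`orient = "global"`), as does a logistic
regression combination (`method = "logistic"`).

AUC uses the rank (Mann-Whitney) formulation with ties counted ½, so
AUC ≡ U/(n₁n₂) exactly. The 95% CI is DeLong by default (placement-value
variance), bootstrap optional. The operating point maximizes
J = Se + Sp − 1 with ties resolved to the lowest threshold; a sample is
called a case when its score is at or above the threshold.

# Transcriptome screen

Batch adjustment is a *known-batch location-scale* standardization (per
gene, per batch: standardize, rescale to the pooled mean/SD). This is a
deliberate simplification appropriate when batches are known series
labels; it is not surrogate-variable estimation and will not remove
latent structure that is unlabelled. The moderated t shrinks per-gene
pooled variances toward a prior estimated by moment matching of
$\log s_g^2$ (trigamma-inverse for $d_0$); agreement with the
established empirical-Bayes implementation is close but not exact
(that implementation adds small-sample corrections), which the tests
document with explicit tolerances.

Preranked GSEA uses the classic weighted running sum
(hit increment $|s|^{w}/N_R$, miss decrement $1/(N-N_H)$; default
$w = 1$). The null is the *gene-label* permutation, since the input is
a preranked list. Both NES and the permutation p are computed against
the **same-sign** portion of the permutation null: the observed ES is a
signed extremum, and a tail over the full two-sided null is
anti-conservative by roughly a factor of two (this was caught by the
null-calibration test during development and is asserted there). An
exact mode enumerates all $\binom{N}{N_H}$ hit arrangements when small.
Ranking ties break lexicographically by gene symbol. The ranking metric
is configurable; the moderated t is the default.

# The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated. Log₂ abundance of feature $j$ in sample $s$ is
$\mu_j + \mathbb{1}[case]\,\Delta_j + \varepsilon_s$ with
$\varepsilon \sim N(0, \sigma^2 R)$, abundances $2^{(\cdot)}$
(log-normal: positive, right-skewed, like peak areas). Defaults:

* $\Delta_j$: the 19 published discovery-stage log₂ fold changes
  (|Δ| from 1.034 to 2.52), plus 139 null features (158 species total);
* $\sigma = 0.5$ log₂ units — a moderate biological+technical residual
  spread for targeted lipidomics, chosen once so that the planted
  |Δ| ≥ 1.03 effects are comfortably but not trivially detectable at
  the discovery size n = 15/15;
* $R$: a PE-plasmalogen block with within-block correlation 0.5, a DAG
  block (within 0.5) correlated −0.3 against the PE block, mirroring
  the qualitative correlation structure reported for differential
  lipids; positive semi-definiteness is checked before sampling;
* baseline covariates at the published Table-1 values: ages
  N(64.53, 10.26²) / N(62.95, 8.79²), conventional lipids (TC, TG,
  LDL-C, HDL-C) normal at the printed means/SDs truncated at zero,
  comorbidity flags by a two-stage draw — "any comorbidity" first at
  the published comorbidity-free fractions (111/251 cases, 213/251
  controls), then conditions allocated at $p_{cond}/p_{any}$ — which
  matches both the condition marginals and the subgroup sizes in
  expectation (with the published numbers, every comorbid subject is
  hypertensive, making the allocation exactly consistent).

What the generator does **not** emulate: retention-time drift, batch
trends within a cohort, intensity-dependent missingness, heavy-tailed
or feature-specific variances, and correlated covariate-lipid
confounding. Passing tests therefore demonstrate the *statistical
machinery* is correct under its stated assumptions, not that the
pipeline is robust to every artefact of real LC-MS data.

# Numerical and degenerate-input choices

* All randomness sits behind explicit integer seeds; identical
  spec + seed is bit-identical end to end.
* Correlation-based steps reject singular matrices with instructive
  errors (KMO: reduce variables; Bartlett: needs $n > p$ and positive
  definiteness).
* `normality_gate` is the deterministic moment rule
  (|skewness| < 1 and |excess kurtosis| < 1), n < 8 falls back to the
  rank test with a warning.
* The Mann-Whitney p is the tie-corrected normal approximation; at
  n = 4+4 it deviates from exact enumeration by up to ~0.12 (tested),
  converging by n ≈ 30.
* Strict inequalities throughout the filters; boundary cases are
  tested explicitly.
* The chi-square test is Pearson without continuity correction — with
  Yates' correction the embedded baseline statistics do not reproduce.

# Problem sizes used in validation

The test suite exercises the pipeline at the study's own scales:
discovery-size cohorts (15/15 by 158 features), a validation-size run
(251/251), 200-replicate permutation calibration at 16 samples by 8
features with 99 permutations and 3-fold CV, and 500-replicate null-Q²
sweeps at 20 by 8. These sizes were chosen to make Monte-Carlo bounds
tight enough to be meaningful while keeping a full run fast on a single
CPU.

# Known limitations

* The real study's multivariate values (R²Y = 0.93, Q² = 0.511, KMO,
  AUC 0.917) are not reproducible here because the underlying plasma
  lipidomics data were never deposited; property-based checks and
  synthetic-cohort recovery stand in for them.
* Two-class OPLS-DA only; one predictive component by design.
* The published weight column's normalization could not be recovered
  (see above); panel membership, not printed weights, is the asserted
  output.
* Hypergeometric ORA treats gene sets as flat lists; no ontology
  topology or redundancy trimming.
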