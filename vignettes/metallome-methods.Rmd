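---
title: "Models and methods behind metalloscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metalloscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalloscope)
library(dplyr)
```

metalloscope analyzes multi-organ metallome data — 15 element
concentrations (µg/g dry mass) plus the copper and zinc stable-isotope
compositions δ65Cu and δ66Zn (‰) — measured on mice of several ages,
together with phenotypes, a metabolome and a proteome. This vignette is
the package's own account of the models it fits, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## Isotope-ratio reduction

Isotope compositions are expressed in delta notation against a bracketing
standard, e.g. for copper

$$\delta^{65}\mathrm{Cu} \;(\unicode{x2030}) =
\left[\frac{(^{65}\mathrm{Cu}/^{63}\mathrm{Cu})_{sample}}
{(^{65}\mathrm{Cu}/^{63}\mathrm{Cu})_{standard}} - 1\right] \times 1000 .$$

Two instrumental artifacts must be removed before this ratio is
meaningful:

* **Mass bias.** The mass spectrometer fractionates isotopes
  mass-dependently. We model it with the exponential law
  $r_{meas} = r_{true} \, (m_h/m_l)^{-f}$ and estimate the instantaneous
  exponent $f$ per cycle from a *doped element* of certified isotope
  composition measured in the same solution (Zn doped into Cu solutions
  and vice versa). The correction transfers $f$ to the analyte's own mass
  pair, assuming equal exponent for both elements in a run — the simplest
  reading of elemental doping; the cross-element log–log regression
  variant is out of scope. The sign convention of $f$ is pinned
  operationally, not by formula: `correct_ratio(estimate_mass_bias(...))`
  must return the dopant's certified ratio exactly, so either literature
  convention yields identical corrected ratios.
* **Drift.** Standards are interleaved with every sample
  (STD, SAMPLE, STD, ...). Each sample cycle's delta is computed against
  the **time-linear interpolation** of the corrected ratios of its two
  flanking standards. The unweighted mean of the flanking standards is
  available via `bracket_reduce(..., interpolation = "mean")`; the linear
  rule is the default because it is exact for any drift that is piecewise
  linear in time between standards. Replicates of a label are corrected
  per cycle first and averaged afterwards (mean and 2SD).

Isotope masses are compile-time constants from standard atomic-mass
tables (63Cu 62.929597, 65Cu 64.927790, 64Zn 63.929142, 66Zn 65.926034).
QC compares reference materials against configurable windows; the
defaults are the consensus values for OEP sheep plasma
(δ66Zn +0.76 ± 0.08 ‰, δ65Cu −1.10 ± 0.15 ‰) and bovine liver SRM-1577c
(δ66Zn −0.18 ± 0.05 ‰, δ65Cu +0.43 ± 0.04 ‰), and QC is report-only.

## Preprocessing

* **Outliers** are masked in a single pass by the z-score rule
  $|x - \bar x| / s > z$ within each organ × age group and analyte.
  The default threshold is $z = 3$; it is configurable, and the removed
  fraction is always reported so it can be compared with the expectation
  that well-behaved data lose well under 5% of measurements. Grouping by
  organ × age (not organ alone) prevents genuine age trends from being
  flagged. The pass is deliberately not iterated: re-screening after
  masking would make the removal fraction threshold-history dependent.
* **Normalization** divides concentrations by the sample's Na or by the
  sample's total metal content; isotope deltas are ratios of ratios and
  never enter a denominator. Total normalization makes the concentration
  columns of every sample sum to one — note this induces *closure*
  correlations between analytes (a shared denominator), which is why the
  concordance null calibration below runs unnormalized.
* **Age correction** fits ordinary least squares `value ~ age_months` per
  organ and analyte and keeps intercept + residuals. The output is exactly
  uncorrelated with age within each organ; it is used for visualization
  and rank correlations only — hypothesis tests keep age as a model
  covariate instead, which preserves degrees-of-freedom accounting.
* **PCA fingerprints** use a deterministic SVD on z-scored analytes
  (correlation-matrix scaling, since concentrations span about six orders
  of magnitude across analytes), with concentrations log-transformed
  first. Missing cells are mean-imputed for the decomposition only, with a
  message. Component signs follow a fixed convention (the
  largest-|loading| analyte is positive), so results are bit-reproducible.

## Moderated association statistics

Every hypothesis test in the package is a linear model with empirical-
Bayes variance moderation. For features $g$ sharing a design, the
residual variances $s_g^2$ on $d_g$ degrees of freedom are shrunk toward
a prior $s_0^2$ with prior df $d_0$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
\tilde t_g = \frac{\hat\beta_g}{\tilde s_g \sqrt{v_g}},$$

with two-sided p-values on $d_0 + d_g$ df. The prior is estimated by
moment-matching the distribution of $\log s_g^2$ to a scaled log-F via
the digamma/trigamma equations; the trigamma inverse is solved by
monotone bisection to a tolerance of 1e-8, and $d_0$ is capped at $10^6$
(treated as infinite). When the log-variances show no spread beyond their
own sampling noise the prior is a point mass ($d_0 = \infty$), every
posterior variance equals the common value, and the test becomes a
z-test. Setting $d_0 = 0$ recovers the classical OLS t exactly — a
limiting identity the tests assert — and the whole estimator is
cross-checked against the installed reference implementation (limma) in
the suite.

**Pairwise associations** (`associate_pairwise`) follow the field's
hybrid convention: the reported effect size is the Spearman ρ of the
covariate-residualized values, while significance comes from the
moderated t of the partner term in `a ~ b + covariates`. Moderation and
Benjamini–Hochberg adjustment are shared across an explicit family — per
organ and layer pair, or pooled across organs with organ entering as a
covariate. Two numerical choices matter here:

* Concentrations are log-transformed by default: tissue concentrations
  are log-normal and organ scales differ enormously, so raw-scale pooled
  correlations would be attenuated by heteroscedasticity.
* Each response is standardized by its covariate-residual spread before
  fitting, so null pairs share unit residual variance and moderation
  compares like with like; this also makes the p-values invariant to
  feature rescaling (a property the suite tests).

The default metal–metal family pools organs (with organ as a covariate)
rather than testing per organ. A per-organ family is available
(`group_by = "organ"`), but with ~16 animals per organ × age a complete
within-group clique cannot survive FDR at realistic correlation levels;
the pooled family reflects the view that the metal co-regulation axes are
shared across organs, and it is what the recovery tests exercise.

BH adjustment is implemented directly as the step-up rule
$\tilde p_{(i)} = \min_{j \ge i} m\, p_{(j)} / j$ (NA-aware, capped at
1) and is verified against both a brute-force oracle and
`stats::p.adjust`.

## Set enrichment

Features (metabolites or proteins) are ranked per metal by the signed
evidence metric $-\log_{10}(p) \times r$, with $p$ from the moderated
covariate-adjusted model and $r$ the Pearson correlation; p-values of 0
are floored at 1e-300 and rank ties break lexicographically on the
feature id so the ordering is total and deterministic. The enrichment
score is the weighted Kolmogorov–Smirnov running sum: hits advance by
$|m|^w / \sum_{hits} |m|^w$, misses retreat by $1/(N - n_{set})$, and the
score is the signed maximum deviation (positive on magnitude ties within
1e-12 — R's `cumsum` accumulates in extended precision, so exact ties
must be resolved with a tolerance). The weight default is $w = 1$, the de
facto standard; $w = 0$ gives the classical KS statistic with its
symmetries (monotone-transform invariance, list-reversal antisymmetry),
which the suite tests.

Significance uses a **set-size-preserving permutation null**: random
same-size member draws from the ranked universe, NES = ES divided by the
mean |null ES| of matching sign, and
$p = (1 + \#\{\text{same-sign nulls at least as extreme}\}) /
(1 + \#\{\text{same-sign nulls}\})$. This permutes set membership rather
than sample labels — the ranking is a derived per-feature statistic at
this layer, and sample-level recomputation is out of scope — which is a
documented divergence from the original sample-permutation GSEA. Null
distributions are cached per (ranked list, set size), which is exact
because the null depends on the set only through its size. FDR is BH
within each metal. The permutation p has resolution $\approx 1/n_{perm}$;
with ~34 sets per metal a rank-one set needs the adjusted floor
$n_{sets}/(n_{perm}+1)$ below 0.05, so contexts that must resolve
Adj.P < 0.05 for a single top set (the recovery tests, the acceptance
script) use `n_perm = 2000` rather than the 1000 default.

## Networks and cross-study concordance

Correlation networks draw one edge per association below `edge_alpha`,
weighted by ρ and signed. Layer integration admits a node if it has at
least one association below `node_alpha` and then keeps all edges below
`edge_alpha` among admitted nodes (defaults 0.01 and 0.05, the
caption-style thresholds; a stricter single threshold of 0.005 appears in
some descriptions of this procedure — both are exposed as parameters and
the defaults follow the two-level rule). Networks serialize to GraphML
(typed attributes, via igraph) and to a TSV edge list with a node
companion file so isolated nodes survive the round trip.

Cross-study concordance computes, per organ and under identical
normalization in both studies, either each metal's Spearman ρ with age or
all pairwise metal–metal ρ, pairs them by analyte (pair), and reports the
Pearson/Spearman concordance r plus the OLS regression of study B on
study A with a 95% confidence interval. Whether to correlate raw or
age-corrected values is left to the caller; the default uses raw values
so that shared age responses count as shared structure.

## The synthetic-data generator

`simulate_study()` draws a complete study from an explicit ground truth
so that every downstream stage can be tested against known parameters.
The default emulates the reference design: 49 animals split 17/16/16
across 6, 16 and 24 months, five organs, with each organ assayed in 16
animals per age (the stated total animal count and a per-cell subset size
of 5–6 cannot both hold if organs share animals; we follow the animal
count and the design in which essentially every animal contributes every
organ, since the headline phenotype associations are statistically
unreachable at n ≈ 5 per cell).

Per animal, organ and analyte the generator draws a standardized
biological deviation $z$ from a latent-factor model: each correlation
group contributes a factor with loading $\sqrt{\rho_g}$ on its members
(Group I: S, Mg, P, Rb, K, Cu, Zn, Mn at ρ = 0.75; Group II: Na, Ca;
Group IV: Fe, δ66Zn at ρ = 0.7; Group III is δ65Cu alone), plus
cross-group loadings that set Na, Ca and Fe against the Group I axis and
give Co and Cd moderate structure — mirroring the anticorrelation of Ca
and Fe with other elements seen in organ correlation networks. Se and Mo
carry no structure at all and serve as null analytes for calibration.
Positive definiteness is guaranteed by construction and validated
(total squared loading < 1 per analyte).

Concentrations are log-normal around organ baselines
($x = b\,e^{s\,(\text{age}-6) + cv\,z}$, biological CV 0.12), deltas are
normal (SD 0.08 ‰), age slopes are applied before noise, and measurement
noise is multiplicative 10% (2SD) for concentrations and additive
0.12 ‰ (2SD) for deltas — the stated analytical uncertainties. δ66Zn
additionally receives a small negative coupling to the biological Zn
deviation in liver, brain, muscle and heart (−0.05 ‰ per SD; the
magnitude is a free parameter as no number is reported), echoing the
linear δ66Zn–Zn relation that indicates shared Zn routing in those
organs. Planted age slopes (brain Fe and Cu +0.025 log-units/month, liver
δ65Cu −0.022 ‰/month, kidney Cd, brain Ca/Co, Rb declines) and phenotype
loadings (body weight driven by liver δ65Cu at −0.85 SD, plus fat%,
IPGTT AUC, muscle ROS, complex I/IV, VO2, mtDNA ratio loadings) were
chosen once, by an up-front power calculation, so each headline effect
has >95% power after FDR under the default design — strong but
biologically plausible effects (a 1.5-fold brain Fe increase over 18
months, a −0.4 ‰ lifetime δ65Cu shift, |r| ≈ 0.7 for the top phenotype
association).

Omics layers are standard-normal intensities for 500 features; members
of a planted set are generated as
$\text{strength} \times z(\text{target metal}) + \sqrt{1 -
\text{strength}^2}\,\varepsilon$ (default strength 0.8, one planted set
per analyte plus an equal number of decoy sets on untouched background
features). Isotope runs follow the bracketing layout with a linearly
drifting mass-bias exponent ($f_0 = 1.5$, −2e−5 s⁻¹) and dopant channels
carrying the same exponent; delta-scale noise is applied to the analyte
ratio of sample cycles at the configured 2SD, so that figure is exactly
the per-measurement delta uncertainty, while reference-material cycles
use the better long-term precision of clean standard solutions
(0.06 ‰ 2SD by default) — full sample preparations scatter more than
repeated runs of a pure standard, and the QC windows are calibrated to
the latter.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: batch, cage and litter effects; detection-limit
censoring; non-Gaussian biological tails; organ-specific correlation
structure (the factor loadings are shared across organs, only baselines
and slopes differ); sample-level coupling between the omics layers beyond
the planted metal correlations; and instrument artifacts other than a
smooth exponential mass bias. Recovery of planted effects demonstrates
the statistics are wired correctly, not that real studies of this size
will detect effects of this magnitude.

## Degenerate inputs and tie-breaks (summary)

* Outlier groups with < 3 values or zero spread are skipped with a
  warning, never an error; all-equal groups remove nothing.
* `normalize_metals` masks whole samples whose denominator is missing or
  zero; `age_correct` degrades to the identity (with a warning) for a
  single age level.
* Enrichment: disjoint sets are flagged `"not testable"`, whole-universe
  sets `"degenerate"`; all-zero hit metrics fall back to unweighted
  steps; if no same-sign permutation exists the p-value is guarded at
  $1/(1+0)$ and flagged.
* PCA drops zero-variance analytes and fixes component signs; ranked
  lists break metric ties lexicographically.
* Single-pair association families skip moderation (classical t) since
  there is nothing to pool.

## Problem sizes used in the checks

The recovery and calibration checks run the full pipeline at the default
design (49 animals, 5 organs, ~48 samples per organ) over 20 seeds, with
2000 permutations per enrichment null, 1000-feature null panels for the
type-I calibration, 500-instance brute-force comparisons for the
enrichment score and 200 for the BH step-up. These sizes were chosen so
the complete suite documents each property at tight Monte-Carlo error
while remaining comfortably reproducible on a laptop.

## Known limitations

* The moderated pairwise test treats each (a, b) regression as a
  "feature"; when most pairs in a family are null the estimated prior df
  is effectively infinite and the test reduces to a z-test on the partial
  correlation — conservative for strongly explained responses.
* Membership permutation (not sample permutation) ignores inter-feature
  correlation within sets; planted-set p-values are well calibrated here
  because background features are independent, but correlated real omics
  features make this null anti-conservative.
* Concordance under total normalization includes closure-induced
  correlations that any two compositionally similar studies share; use
  `normalization = "none"` when the question is agreement of biological
  structure rather than agreement of normalized profiles.
* The CSV/GMT/GraphML readers validate schema, not science: units are
  asserted by convention (µg/g, ‰, months), not checked.
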