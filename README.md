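# metalloscope

Tools for studying the **metallome** — the inorganic complement of the
body's omics layers — across organs and age. The package re-builds, as a
tested and reusable R pipeline, the analysis chain used in multi-organ
mouse metallomics with Cu/Zn stable-isotope measurements:

1. **Isotope-ratio data reduction.** Bracketed MC-ICP-MS runs are reduced
   to delta values, e.g. for copper
   `δ65Cu (‰) = [(65Cu/63Cu)_sample / (65Cu/63Cu)_standard − 1] × 1000`,
   with exponential-law instrumental mass-bias correction estimated per
   cycle from a doped element of known isotope composition
   (`r_corrected = r_measured × (m_heavy/m_light)^f`), time-linear
   standard–sample bracketing against the flanking standards, replicate
   means with 2SD, and QC against reference materials (OEP sheep plasma,
   bovine liver SRM-1577c).
2. **Preprocessing** of sample × analyte tables (15 metals in µg/g plus
   δ65Cu/δ66Zn in ‰): single-pass z-score outlier masking within
   organ × age groups, Na/total normalization (deltas never enter a
   denominator), per-organ linear age correction (intercept + residuals),
   and SVD-based PCA fingerprints on z-scored analytes.
3. **Association statistics.** Per-feature linear models with age as a
   covariate; empirical-Bayes **moderated t-statistics** with
   `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)` and the prior `(d₀, s₀²)`
   estimated by moment-matching of log-variances (digamma/trigamma
   equations); Benjamini–Hochberg FDR within explicit families; Spearman
   ρ effect sizes on age-corrected values.
4. **Rank-based set enrichment** (MSEA/GSEA style): features ranked by
   `−log10(p) × Pearson r` against each metal, weighted
   Kolmogorov–Smirnov running-sum enrichment score, set-size-preserving
   permutation NES and p, BH within metal, top-3 summaries.
5. **Networks & concordance.** Threshold-filtered correlation networks,
   multi-layer integration (nodes admitted at Adj.P < 0.01, edges drawn at
   Adj.P < 0.05), GraphML/TSV serialization, and cross-study concordance of
   metal–age and metal–metal Spearman statistics under identical
   normalization.
6. **Synthetic-data generator.** A ground-truth-driven simulator of the
   5-organ × 3-age (6/16/24 months, ~49 animals) design: log-normal
   concentrations with organ baselines, latent-factor metal groups
   (Group I: S, Mg, P, Rb, K, Cu, Zn, Mn; Group II: Na, Ca; Group III:
   δ65Cu; Group IV: Fe, δ66Zn), planted age trends and phenotype loadings,
   omics matrices with planted set enrichments, and raw bracketed isotope
   runs — so every stage is testable against a known truth without any
   download.

Intended users: analysts of ionomics/metallomics studies who need a
reproducible path from raw bracketed isotope intensities and element
tables to moderated association statistics, enrichment results and
integrated networks.

## Worked example

```r
library(metalloscope)

# a complete synthetic study with known ground truth
st <- simulate_study(seed = 1)
m  <- remove_outliers(st$metallome)

# effect of aging, 24 vs 6 months
v <- age_contrast_volcano(m, ages = c(6, 24))
subset(v, organ == "brain" & analyte == "Fe")
#> organ contrast analyte effect effect_type t_mod       p    adj_p  n
#> brain     24v6      Fe  0.687     log2_fc   9.5 7.9e-12 1.34e-10 32
```

Brain iron shows a log2 fold change of +0.69 (≈ 1.6×) between 6 and
24 months with a BH-adjusted moderated-t p-value of 1.3e-10 — the planted
age-dependent brain Fe accumulation, recovered. The liver δ65Cu value
moves by −0.45 ‰ over the same contrast (Adj.P = 3.0e-11; deltas are
reported as plain per-mil differences, `effect_type = "delta_diff"`).

```r
# covariate-adjusted associations and the integrated network
mm  <- associate_pairwise(m, group_by = NULL)            # metal–metal
mp  <- associate_pairwise(m, st$phenotypes)              # metal–phenotype
subset(mp, organ == "liver" & feature_a == "d65Cu" & feature_b == "body_weight_g")
#> rho = -0.774, adj_p = 9.9e-06, n = 48   (negative, as planted)

fa  <- associate_features(st$metabolome, subset(m, organ == "liver"))
er  <- run_enrichment(fa, st$metabolite_sets, n_perm = 2000, seed = 2)
top_enrichment(er, k = 3)                                # top-3 per metal

net <- integrate_layers(mm, mp, er, node_alpha = 0.01, edge_alpha = 0.05)
autoplot(net)

# isotope reduction of a raw bracketed run
dt <- bracket_reduce(st$runs$Cu, mass_bias_model("Cu"))
qc_check(dt)
```

`bracket_reduce` on a noiseless synthetic run returns planted deltas to
better than 1e-9 ‰; with noise at the instrument-typical 0.12 ‰ (2SD) the
replicate 2SD estimate recovers that figure.

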