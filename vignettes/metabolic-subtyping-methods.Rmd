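---
title: "Metabolic subtyping of tumor cohorts: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic subtyping of tumor cohorts: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumors rewire energy metabolism, and two axes dominate in squamous
carcinomas: aerobic glycolysis and cholesterol biosynthesis. `metabosub`
stratifies a bulk RNA-seq cohort into four metabolic subtypes —
**quiescent**, **glycolytic**, **cholesterogenic**, and **mixed** — from
the expression of a glycolysis gene set (29 genes) and a cholesterol
biosynthesis gene set (24 genes), and asks whether the strata differ in
survival, somatic alterations, and protein-level markers.

The method, end to end:

1. **Normalize**: expression is taken to log10(TPM + 1); samples with a
   known tumor purity strictly below 30% are removed; each gene is then
   centered at its cohort median and scaled to unit SD.
2. **Cluster genes**: the pathway genes are consensus-clustered
   (100 subsampling repetitions, 80% of genes per repetition, all samples,
   Euclidean distance, Ward.D2 linkage), and the clustering is cut at
   k = 4. The consensus matrix entry for two genes is the fraction of
   co-sampled repetitions in which they co-clustered; CDF area and
   delta-area diagnostics over k = 2..5 are reported but k is fixed at 4
   for the pipeline.
3. **Select cores**: a cluster is a candidate *core* for a set when at
   least 50% of its members come from that set; among candidates the most
   homogeneous cluster wins (ties: larger cluster, then lower id). The
   core gene list is the winning cluster's members that belong to the set.
4. **Score and classify samples**: a sample's glycolytic
   (cholesterogenic) score is the *median* centered expression over the
   core glycolytic (cholesterogenic) genes, and the quadrant rule assigns
   quiescent (g <= 0, c <= 0), glycolytic (g > 0, c <= 0), cholesterogenic
   (g <= 0, c > 0) or mixed (g > 0, c > 0). Zero lies on the "<= 0" side.
5. **Compare**: Kaplan–Meier curves and a global k-group log-rank test
   after excluding cases with overall survival under 1 month (strict);
   2 x k contingency tests of gene alteration (SNV/INDEL union CNV)
   against subtype; Welch t-tests of immunoreactive scores against a
   control group.

## Tunable parameters

| Parameter | Default | Unit / range | Why this default |
|---|---|---|---|
| `purity_min` | 0.30 | fraction | samples below 30% known tumor content are removed (strict `<`); missing purity is retained |
| log transform | log10(x + 1) | — | zero-preserving, monotone; counts are rescaled per sample to 1e6 first |
| `de_log2fc_min` | 1.0 | log2 units | inclusive `>=` threshold for the optional differential-expression gene filter |
| centering / scaling | median / SD | — | median matches the median-based subtype rule and is robust; SD scaling makes gene weights comparable |
| `reps`, `p_item`, `p_feature` | 100, 0.8, 1.0 | — | the published consensus-clustering parameters |
| distance / inner linkage | Euclidean / Ward.D2 | — | the published choices |
| `k_main` | 4 | clusters | fixed at 4; delta-area is a diagnostic, not a selector |
| `min_composition` | 0.5 | fraction | inclusive candidate-core threshold |
| `homogeneity_min` (pan-cancer) | 0.75 | fraction | cohorts whose winning cores are less than 75% pure are screened out |
| `min_samples` (pan-cancer) | 100 | samples | inclusive: a 100-sample cohort is kept |
| `min_months` | 1 | months | strict exclusion of OS < 1 month |
| CNV segment filter | probes >= 10, \|seg.mean\| > 0.2 | — | probes inclusive, mean strict, exactly as stated |
| copy-status filter | >= 3 amplified, <= 1 deleted | copies | inclusive on both sides; 2 is silent |
| IRS bins | 0–1 / 2–3 / 4–8 / 9–12 | points | negative / mild / moderate / strong |

## The synthetic cohort generator

Real cohorts of this kind are controlled-access, so the package ships a
generator (`generate_cohort()`) that emulates the *statistical structure*
the analysis assumes. Its defaults are the stated world of the analysis,
chosen once:

* **Subtype proportions 0.36 / 0.23 / 0.21 / 0.20** (quiescent largest) —
  the split observed in a ~480-sample head-and-neck cohort, used as a
  realistic default, not a target.
* **Gene blocks**: 29 glycolysis genes with a 12-gene co-expressed core
  and 24 cholesterol genes with a 16-gene core. Core genes are shifted by
  `±effect_size × noise_sd` on the log10(TPM+1) scale according to the
  planted subtype (mixed shifts both blocks up, quiescent both down);
  non-core genes are pure noise. Default `effect_size = 2`, `noise_sd = 1`
  — a clearly separated but noisy regime.
* **Survival**: exponential event times with per-subtype monthly hazards
  (default 0.010 / 0.032 / 0.026 / 0.030, quiescent best — median
  survival ≈ 69 vs 22–27 months), 40% uniform right-censoring.
* **Mutations**: per-(gene, subtype) Bernoulli with TP53 highest overall
  (0.60–0.80) and CDKN2A most differential (0.05–0.45); SNV:INDEL drawn
  4:1. Copy-number spans are drawn per sample over named genes, with some
  spans below the probe filter so the SEG path is exercised.
* **Purity**: uniform on [0.2, 1], so the 30% filter genuinely removes
  samples.

What the generator does **not** emulate: negative-binomial count noise and
library-size effects, linkage between mutations and expression, positional
realism of variants, informative censoring, batch structure. A green
recovery test therefore establishes that the pipeline recovers *this kind*
of planted block/quadrant structure — not that it would denoise a real
cohort with these exact numbers.

With `effect_size = 0` the quadrant rule spreads calls roughly uniformly
over the four quadrants, so chance-level recovery is about
`sum(p_s)/4 = 0.25` — below the largest planted proportion, which would be
the chance level only for a majority-class classifier.

## Numerical choices and degenerate inputs

* **Consensus CDF area** is the exact integral of the step ECDF of the
  upper-triangle consensus values over [0, 1] (equivalently
  `1 - mean(values)`), not a trapezoid across the jumps; with an all-{0,1}
  consensus the area is exactly the fraction of zero pairs. `delta_area(k)`
  is `(auc_k - auc_{k-1}) / auc_{k-1}`, and for the smallest k it is
  `auc_k` itself.
* **Per-repetition seeds** are derived from the master seed and the
  repetition index, so repetitions are order-independent and adding k
  values never changes the subsamples. Gene pairs never co-sampled (rare
  at `p_item = 0.8`, 100 reps) get consensus 0 with a warning.
* **Final labels** come from average-linkage hierarchical clustering of
  `1 - M` (configurable to Ward); with `p_item = p_feature = 1` this
  exactly reproduces the full-data Ward cut.
* **Core-selection ambiguity**: "at least 50% of each gene set" is read as
  the fraction *of the cluster's members* belonging to the set (the
  alternative — fraction of the set captured — is available via
  `composition_of = "set"`). When one cluster is the top candidate for
  both sets it is awarded to the set with no alternative candidate; if
  both sets have alternatives it keeps the set it represents better; if
  neither has an alternative, selection fails.
* **Log-rank** uses the standard hypergeometric (ties-aware) variance and
  a pseudo-inverse fallback for singular covariance. The 4-group test is
  the primary survival comparison; pairwise tests are left to the caller.
* **Cutpoint search** mirrors maximally selected rank statistics with
  `minprop = 0.1`; the reported p-value is deliberately uncorrected for
  the selection and flagged exploratory.
* **Sparse contingency tables** (any expected count < 5) fall back to a
  seeded Monte-Carlo conditional test (10,000 tables with fixed margins);
  q-values are Benjamini–Hochberg across the gene panel. Both raw and
  adjusted values are reported.
* **IRS bins** on a continuous percentage close the printed integer gaps
  as 2: [10, 50], 3: (50, 80], 4: (80, 100]; `proportion_score(0) = 0`.
* **t-tests** default to Welch (unequal variance) rather than classic
  Student's: safer, asymptotically equivalent; `var_equal = TRUE` restores
  the pooled version. Two identical groups return t = 0, p = 1 rather
  than 0/0.
* **Coordinates** are converted to 1-based inclusive once, at the BED
  reader; overlap anywhere (>= 1 bp) with an event marks a gene, with the
  supplied interval standing in for the coding region (no exon model).
* Days-to-months conversion (/30.44) is the caller's responsibility at
  the I/O layer; all internal times are months.

## Open design points resolved

* Whether the original HNSCC analysis centered genes before the quadrant
  rule is stated only for the pan-cancer screen; centering is on by
  default everywhere because the quadrant thresholds at 0 are otherwise
  meaningless on raw log-TPM.
* The per-cohort core derivation is repeated independently for every
  cohort (validation cohorts may legitimately yield different core sizes).
* Silent variants are not excluded: every MAF record of an accepted
  variant type counts.
* The pipeline takes hierarchical (Ward.D2) clustering as the inner loop
  throughout; no k-means variant is implemented.

## Known limitations

* TPM from counts assumes pre-length-normalized input; no gene-length
  model is applied.
* No Cox modeling or multivariable adjustment; survival comparison is
  purely nonparametric.
* Cross-cohort batch correction is per-cohort gene-wise location/scale
  only.
* The shipped gene sets are synthetic stand-ins at the documented sizes
  (29 + 24), not a verbatim MSigDB release; supply your own GMT for real
  analyses.

No empirical claim in this vignette goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.
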