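# metabosub

Metabolic subtyping of bulk RNA-seq tumor cohorts from glycolysis and
cholesterol-biosynthesis gene expression.

## What it does, and for whom

Tumors differ in how far they push aerobic glycolysis and cholesterol
biosynthesis, and that balance tracks prognosis in squamous carcinomas.
`metabosub` is for computational biologists who want to stratify a cohort
(expression TSV + clinical TSV, optionally MAF/SEG/BED somatic data) into
four metabolic subtypes and test what the strata mean clinically:

* **quiescent** — both pathways down (best survival),
* **glycolytic** — glycolysis up, cholesterol synthesis down,
* **cholesterogenic** — the reverse,
* **mixed** — both up.

The core statistic is simple and robust: after log10(TPM + 1) transform,
a strict tumor-purity filter (< 30% removed) and gene-wise median/SD
scaling, the package consensus-clusters the pathway genes (100 reps,
pItem = 0.8, pFeature = 1, Euclidean distance, Ward.D2, cut at k = 4),
selects the *core* co-expressed cluster for each pathway (>= 50% of
members from the set; most homogeneous wins), scores each sample by the
**median centered expression** over each core, and classifies by the
quadrant rule

```
gly <= 0 & chol <= 0  -> quiescent        gly > 0 & chol <= 0 -> glycolytic
gly <= 0 & chol >  0  -> cholesterogenic  gly > 0 & chol >  0 -> mixed
```

Around that sit Kaplan–Meier / k-group log-rank survival comparison (with
the strict OS < 1 month exclusion), CNV calling from copy status (>= 3
amplified, <= 1 deleted) or SEG segments (>= 10 probes, |seg.mean| > 0.2),
2 x k contingency tests of alteration by subtype with BH correction, the
immunoreactive score IRS = proportion score (0–4) x intensity (0–3) with
its negative/mild/moderate/strong bins, a pan-cancer screening loop
(>= 100 samples, >= 75% core homogeneity), and a synthetic-cohort
generator so everything is testable without controlled-access downloads.

## Worked example

```r
library(metabosub)

co  <- generate_cohort(cohort_config(n_samples = 480, seed = 1))
cls <- classify_cohort(co$expression, co$clinical)

cls$core
#> CoreClusters: 12 glycolytic (homogeneity 1.00), 16 cholesterogenic (homogeneity 1.00)
cls$consensus$diagnostics
#>   k       auc delta_area
#> 1 2 0.4296081 0.42960813
#> 2 3 0.6473149 0.50675676
#> 3 4 0.7503973 0.15924607
#> 4 5 0.7883744 0.05060933
table(cls$calls$subtype)
#>       quiescent      glycolytic cholesterogenic           mixed
#>             152             106              90              76
```

The generator planted 12 + 16 core genes; the consensus step recovered
them as perfectly homogeneous clusters, and the 424 samples surviving the
purity filter split across the four quadrants. Survival separates as
planted (quiescent best):

```r
clin <- filter_min_followup(cls$clinical)
clin <- clin[clin$sample_id %in% cls$calls$sample_id, ]
sub  <- cls$calls$subtype[match(clin$sample_id, cls$calls$sample_id)]
logrank_test_by(clin$os_months, clin$os_event, sub)
#> Log-rank: chi-square = 66.12 on 3 df, p = 2.884e-14
```

Mutation frequencies differ by subtype exactly where the generator put
the signal (CDKN2A most differential):

```r
mm  <- build_mutation_matrix(co$mutations,
                             call_cnv_from_segments(co$segments, co$gene_coords),
                             cls$calls$sample_id)
test_gene_by_subtype(mm, cls$calls)[, c("gene", "statistic", "p_value", "q_value")]
#>     gene statistic  p_value  q_value
#> 1   TP53     12.36 6.23e-03 1.04e-02
#> 2 CDKN2A     54.90 7.21e-12 3.60e-11
#> 3 PIK3CA      2.11 5.50e-01 5.50e-01
#> 4  LRP1B      4.58 2.06e-01 2.57e-01
#> 5    FLG     13.45 3.76e-03 9.40e-03
```

And the IHC score of a maximally stained specimen:

```r
irs_score(85, 3)
#>   proportion_score intensity_score irs category
#> 1                4               3  12   strong
```

## Command line

```sh
metabosub simulate   --config cohort.json --out cohort/
metabosub run-all    --in cohort/ --out results/ --config cohort.json
metabosub preprocess --expr expr.tsv --clinical clinical.tsv --out centered.tsv
metabosub cluster    --expr centered.tsv --k 2,3,4,5 --reps 100 --seed 17 --out consensus/
metabosub subtype    --expr centered.tsv --labels consensus/labels_k4.tsv --out subtypes.tsv
metabosub survival   --clinical clinical.tsv --groups subtypes.tsv --out logrank.tsv
metabosub mutations  --maf m.maf --seg s.seg --bed genes.bed --subtypes subtypes.tsv --out contingency.tsv
metabosub irs        --in ihc.tsv --out irs.tsv
metabosub pan-cancer --root cohorts/ --out screen.tsv
```

Configuration is a single JSON file; `run-all` writes every stage artifact
plus a `manifest.json`, and reruns with the same inputs/config are
byte-identical.

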