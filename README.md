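# gastrosubtype

Molecular subtyping and mutation profiling of gastric cancer cohorts from
targeted tumor/normal panel assays.

## The problem

Gastric cancer is molecularly heterogeneous, and histologic systems
(Lauren, WHO) guide patient management poorly. The TCGA framework divides
gastric tumors into four subtypes with distinct therapeutic implications:
EBV-positive, microsatellite-unstable (MSI), chromosomally unstable (CIN),
and genomically stable (GS). This package implements that classification
and the downstream cohort analysis for laboratories working with targeted
panels rather than whole-genome assays: it consumes per-case variant
tables, EBV qPCR results, five-marker MSI allele profiles, and per-target
coverage, and produces subtype labels, gene-by-subtype mutation tables
with exact association tests, copy-number and pathway summaries, and
survival analyses.

## The core method

Each case is classified **serially**:

```
EBV positive?            -> EBV
else >=1 unstable marker -> MSI     (MSS / MSI-L / MSI-H from 5 mononucleotide markers;
else >=1 gene-level CNA  -> CIN      0 / 1 / >=2 unstable; MSI-L counts as MSI subtype)
else                     -> GS
```

Around it:

* **Somatic filter** — tumor VAF > 5%, depth > 50×, exonic, max population
  frequency < 0.005, no germline evidence in the matched normal, seen in
  ≤ 2 cohort normals (panel of normals). **Germline filter** — present in
  both samples, VAF > 30% in each, depth > 50×, population frequency
  < 0.01. All inequalities strict.
* **CNV caller** — median-normalized log2 coverage ratios decoded by a
  3-state Gaussian HMM (state means −1 / 0 / +0.58, Viterbi), gene calls
  requiring ≥ 2 supporting targets; concordance vs reference labels with
  exact Clopper–Pearson intervals.
* **Exact association** — Fisher–Freeman–Halton 2×K enumeration
  (multivariate hypergeometric, Monte Carlo fallback above a 5×10⁶-table
  budget) for each gene × subtype row.
* **Survival** — Kaplan–Meier, log-rank, and Cox proportional hazards
  (Breslow ties) for relapse-free and cancer-specific survival.
* **Synthetic cohorts** — a seeded generator parameterized by the
  published cohort tables, with a deterministic exact-marginal mode for
  table reproduction and a sampling mode for statistical property tests.

## Worked example

Generate the 107-case exact-marginal cohort, run the full pipeline, and
inspect the cohort summary:

```r
library(gastrosubtype)

spec   <- cohort_spec(n_cases = 107, seed = 1, mode = "exact_marginal")
cohort <- generate_cohort(spec)
dir    <- tempfile("cohort"); write_cohort(cohort, dir)
out    <- tempfile("reports")

summary <- run_pipeline(pipeline_config(dir, out))

summary$distribution
#>   subtype  n  pct
#> 1     EBV  7  6.5
#> 2     MSI 19 17.8
#> 3     CIN 46 43.0
#> 4      GS 35 32.7

mutation_rate_per_subtype(summary$gene_table)
#> EBV MSI CIN  GS
#> 2.6 6.6 1.8 1.5

head(summary$tests[order(summary$tests$p_ffh), ], 5)
#>     gene        p_ffh      p_chisq
#> 1   BCOR 3.513674e-06 6.332718e-07
#> 2 PIK3CA 1.355591e-05 7.827034e-06
#> 3 ZBTB20 1.987987e-04 2.169651e-05
#> 4 ARID1A 8.511749e-04 8.785959e-04
#> 5   PGM5 1.060263e-03 7.529116e-04
```

The distribution reproduces the reference cohort split (6.5% EBV, 17.8%
MSI, 43.0% CIN, 32.7% GS) because the exact-marginal generator plants
assay evidence matching the published marginals and the pipeline recovers
every label from the raw assay bundles: qPCR copies, marker histograms,
variant tables, and coverage. The mutation rate row is the mean number of
mutated panel genes per case in each subtype; the hyper-mutated MSI
subtype (6.6 per case) stands out, as expected. The per-gene p-values are
exact tests of mutation-frequency differences across subtypes — e.g.
ZBTB20 mutations are confined to the MSI subtype.

`run_pipeline()` also writes report files into `out`: per-case subtype
labels, the gene × subtype table, mutation rates, recurrent variants,
pathway and germline summaries (JSON), KM coordinates, log-rank results,
filter attrition, and a run manifest. A thin CLI wrapper is available at
`inst/scripts/gastrosubtype.R` (`run --config cfg.yaml`, `simulate --n 107
--out dir/`).

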