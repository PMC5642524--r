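---
title: "Methods: serial molecular subtyping of gastric cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial molecular subtyping of gastric cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastrosubtype)
```

## Overview

`gastrosubtype` re-implements, as a reusable and tested pipeline, a
TCGA-style molecular classification workflow for gastric cancer (GC)
cohorts assayed with targeted tumor/normal panel sequencing, an EBV qPCR
assay, a five-marker microsatellite instability (MSI) assay, and
coverage-based copy-number analysis. The pipeline classifies each tumor
serially into one of four subtypes — EBV-positive, MSI, chromosomal
instability (CIN), or genomically stable (GS) — and then profiles somatic
mutations, copy-number aberrations (CNAs), pathway-level alterations, and
survival by subtype.

Because the cohort this design is drawn from is published only as summary
tables, the package ships a synthetic cohort generator whose parameters are
those tables. Every downstream stage is exercised end to end on generated
assay bundles; the generator is first-class, tested code, not a fixture.

## The serial classification rule

A case is assigned the first matching label in a fixed order:

1. **EBV** — qPCR EBV positivity (any quantifiable amplification above the
   kit's detection limit; the cutoff is configurable).
2. **MSI** — among EBV-negative cases, instability in one or more of the
   five mononucleotide markers BAT-25, BAT-26, NR-21, NR-24, NR-27.
3. **CIN** — among EBV-negative, microsatellite-stable cases, at least one
   gene-level somatic CNA (panel-derived, or externally supplied
   array-derived status, which takes precedence when provided).
4. **GS** — the remainder.

Two deliberate divergences from TCGA proper: MSI-L (exactly one unstable
marker) counts as the MSI subtype — this is required for the reference
cohort's arithmetic, whose MSI subtype of 19 cases is exactly its 15 MSI-H
plus 4 MSI-L cases — and CIN status is decided by a targeted-panel caller
rather than genome-wide SNP arrays, so focal events outside the panel are
invisible (a stated limitation, not a defect).

## Variant filtering

Somatic and germline calls are post-filters over externally produced
variant tables (the package does no alignment, calling, or annotation).
All threshold comparisons are strict inequalities, exactly as the
protocol states them, so a depth of exactly 50 is rejected:

* **Somatic**: tumor VAF > 5%, depth > 50×, exonic (splice-site calls are
  admitted), maximum population frequency across 1000 Genomes / ESP6500 /
  ExAC < 0.005 (absent values treated as 0 — the conservative reading of
  "less than in all three databases"), no germline-level evidence in the
  matched normal (absent, or VAF < 2% — a caller-style trace-evidence
  cutoff the upstream protocol leaves unstated), and seen in at most 2
  distinct non-tumor samples of the cohort panel of normals.
* **Germline**: present in both tumor and matched normal with VAF > 30%
  in each, depth > 50×, all population frequencies < 0.01.

The panel of normals counts distinct cases, never read support. Clinical
significance labels on germline variants are pass-through inputs: the
package counts them and implements no pathogenicity logic.

Recurrence tallies group by gene and normalized protein change; deletions
and duplications at the same residue are pooled by default (the cohort
reports e.g. `p.Gln1334del/dup` as one event), and the pooling is
configurable. Percentages are rounded half away from zero to one decimal,
matching clinical-table convention (R's default half-to-even rounding
differs at .5 boundaries).

## MSI calling

The published assay judged marker instability from capillary
electrophoresis traces without a stated numeric criterion, so the decision
rule here is the package's own construction on allele-length histograms:
a marker is unstable when tumor support at novel lengths — outside a
±1 bp tolerance window around any allele supported in the matched normal —
reaches 20%, or when the modal length shifts by more than 1 bp. The
defaults (tolerance 1 bp, novel fraction 0.2, modal shift 1 bp) are
conservative for mononucleotide markers, where 1 bp stutter is routine
assay noise. Status follows the standard Bethesda-style rule: 0 unstable
markers = MSS, 1 = MSI-L, ≥2 = MSI-H.

## Copy-number calling

Per-target tumor and normal depths are median-normalized within sample and
converted to log2 ratios; zero-depth targets are masked. A three-state
hidden Markov model (deletion / normal / duplication) with Gaussian
emissions is decoded by Viterbi:

* state means −1, 0, +0.58 (single-copy loss and single-copy gain in a
  diploid genome; amplification and gain are not distinguished at the
  gene level),
* a shared emission SD, either supplied or estimated robustly from the
  middle 50% of the observed ratios (IQR/1.349, floored at 0.05 so
  near-constant input cannot degenerate the likelihood),
* transition stay-probability 0.99 and a prior of 0.99 on the normal
  state, which together merge multi-exon evidence and suppress
  single-target outliers.

A gene is called non-normal only when a majority non-normal state is
supported by at least 2 targets (`min_targets`), mirroring the
multi-exon-merging intent of commercial panel CNV tools. Concordance
against binary reference labels (e.g. HER2 immunohistochemistry) is
reported as sensitivity/specificity with exact Clopper–Pearson 95%
intervals.

## Cohort statistics

The gene × subtype table counts cases (not variants): a case with three
ARID1A variants contributes one to its cell. Association per gene row is
tested with an exact Fisher–Freeman–Halton (FFH) test over the 2×K table
of mutated vs wild-type counts: all first-row compositions compatible with
the fixed margins are enumerated and the multivariate-hypergeometric
probabilities of tables no more probable than the observed one are summed.
Numerical choices: a relative tie tolerance of 1e-12 when comparing table
probabilities (the "at most as probable" criterion is ill-defined at exact
floating-point equality); an enumeration budget of 5×10⁶ compositions,
beyond which the test falls back to Monte Carlo with 10⁵ margin-preserving
Patefield draws under a fixed local seed that does not disturb the
caller's RNG stream. A chi-squared test (no continuity correction) is
computed alongside; FFH-exact is primary because small expected cells
dominate gene-level subtype tables. Raw p-values are reported without
multiple-testing correction, as in the reference report.

The per-subtype mutation rate is the column sum of the gene × subtype
counts over the subtype size. Pathway summaries treat a case as altered in
a gene set when it carries a somatic variant or a non-normal CNA in any
member gene (RTK set: ERBB2, EGFR, FGFR2, KDR; RAS/PI3K set: KRAS, BRAF,
PIK3CA, PTEN, MTOR); a case altered in both sets counts once in the
combined figure, and cases carrying both a substitution and a CNA in the
same gene are listed as mutual-exclusivity violations.

## Survival analysis

Relapse-free survival events are loco-regional recurrence, distant
metastasis, or death from any cause; GC-specific survival events are
GC-related deaths (which always imply an RFS event). Estimation is
delegated to the `survival` package behind a thin module surface:
Kaplan–Meier product-limit curves, the log-rank test, and Cox
proportional-hazards regression with Breslow tie handling (the commonest
default; the reference protocol does not state a tie method). Times are
kept in days internally. Zero-variance covariates are reported with
coefficient 0 (hazard ratio 1) and a note rather than being passed to the
optimizer, and coefficients diverging past |β| > 15 are flagged as
possible complete separation. No time-varying covariates, stratification,
or proportionality diagnostics are provided.

## The synthetic cohort generator

The generator's defaults *are* the published study conditions:

* subtype prevalences 7/107, 19/107, 46/107, 35/107;
* per-gene mutation probabilities equal to the published mutated-case
  fraction per subtype (e.g. ARID1A in MSI: 14/19);
* clinical covariates drawn from the published covariate × subtype
  cross-tabs as multinomial parameters;
* all marker instability confined to MSI-subtype cases (the published
  marginals imply every unstable case is EBV-negative), with a per-marker
  instability probability of 0.45, which reproduces the observed ≈15:4
  MSI-H:MSI-L split conditional on at least one unstable marker;
* every CIN case carries one planted gene-level CNA drawn from the genes
  the cohort reported amplified (plus the one reported deletion, PTEN).

Where the source reports no distribution, values were chosen once on
field-typical grounds and not revisited: somatic VAF ~ Beta(2, 5)
truncated to [0.05, 1]; germline VAF ~ Normal(0.5, 0.05) clipped to
[0.30, 0.70]; depth ~ negative binomial (mean 500, size 8) floored at 51×;
coverage CNAs as 1.5× (log2 ≈ +0.58) or 0.5× multiplicative shifts with
log2-normal noise of SD 0.12; unstable MSI markers move 30% of their mass
to 3 bp below the modal allele; EBV load ~ lognormal(9, 1) copies for
positive cases and 0 otherwise. AJCC stage is always derived from the
sampled pT/pN/M via the 7th-edition grid, so stage is consistent with TNM
by construction (consequently the synthetic stage marginals follow the
published ones only through the TNM marginals). Follow-up uses
exponential relapse hazards (4×10⁻⁴/day baseline) scaled by stage group
(0.5/1/2/3 for I–IV) and subtype (MSI best at 0.6, GS worst at 1.2,
qualitatively matching the reported prognosis ordering), with uniform
administrative censoring on [180, 1460] days.

Two modes serve different purposes. **Exact-marginal** mode apportions all
counts deterministically (largest remainder) and disables assay noise —
it exists to reproduce tables, and on it the full pipeline recovers every
true subtype label. **Sampling** mode draws cases i.i.d. with noise
enabled, for statistical property tests; at n = 2000 the per-gene
per-subtype mutation frequencies recover the profile values within three
binomial standard deviations. Mutation indicators are independent across
genes: the source publishes only marginal frequencies, so co-mutation
structure (e.g. the reported KRAS/PIK3CA co-occurrence) is deliberately
not emulated — an assumption, flagged, not asserted as truth. A single
integer seed drives everything through stable per-case sub-seeding;
identical specs yield identical cohorts.

What passing tests on synthetic data do **not** show: robustness to FFPE
artifacts, purity/ploidy distortion of VAFs and coverage ratios, stutter
noise in real electropherograms, panel capture biases, or co-mutation
structure. The generator emulates post-assay summaries, never raw signal.

## Problem sizes used in the test suite

The suite reproduces the 107-case cohort exactly, uses n = 2000 sampled
cases for frequency recovery, 2×K enumeration oracles up to n = 9 per
table plus 2,000 null simulations for the FFH type-I error check, 100
random chains of ≤ 8 targets against a 3ⁿ brute-force path oracle, and
100 replicates of n = 500 for Cox interval coverage at a true hazard
ratio of 3. These sizes make the full suite run in about a minute while
keeping every check at the scale its statistical claim needs.

## Known limitations

* The panel CNV caller approximates, not replicates, array-based CNA
  detection; per-case array-derived CNA status can be supplied instead.
* Exact agreement of FFH p-values with SPSS output beyond three decimals
  is not guaranteed (different exact-test variants exist); agreement is
  asserted to the printed precision only.
* Published multivariate hazard ratios are not reproducible without
  per-case data; the survival module is validated by parameter recovery
  on simulated data instead.
* No ACRG-style (MSS/EMT, MSS/TP53±) classification, no expression or
  methylation subtyping, no ACMG germline classification.
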