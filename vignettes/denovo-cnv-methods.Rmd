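---
title: "Methods: de novo CNV detection in parent-offspring trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo CNV detection in parent-offspring trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovotrio)
```

## The problem

Large copy number variants (CNVs) that arise de novo — present in a child
but in neither biological parent — are strongly enriched in
neurodevelopmental disorders. Detecting them from SNP-array data in
parent-offspring trios is mostly a filtering problem: array CNV callers
(PennCNV-class HMMs over the log R ratio, LRR, and B allele frequency,
BAF) emit many fragmented, noisy calls, and a de novo label is only as
credible as the quality control around it, because a single missed
parental call converts an inherited variant into a false new mutation.

`denovotrio` implements the downstream analysis of such a study: merging
and filtering of caller output, per-sample signal QC, trio transmission
classification, annotation against curated risk loci and gene models, and
cohort mutation-rate statistics. The package ships the summary tables of
a published ADHD trio study (305 trios, 14 de novo CNVs in 13 probands)
as fixtures, so every headline number of that analysis is recomputed by
code rather than quoted.

## Coordinate and length conventions

Calls are stored with coordinates exactly as printed by the caller
(1-based start) and a call's length is defined as `end - start`. This
convention reproduces all fourteen printed event sizes in the packaged
fixture bit-exactly (e.g. the 22q11.21 duplication:
`21460220 - 18892575 = 2567645`), which is why it is preferred over the
1-based-inclusive `end - start + 1` alternative. Exported BED is shifted
to the 0-based half-open convention. Chromosome labels are stored without
a `chr` prefix and emitted with one in BED.

## The pipeline and its thresholds

All thresholds live in `pipeline_config()`; defaults are the published
analysis settings.

1. **Merging** (`merge_adjacent_calls`). Consecutive same-type,
   same-chromosome calls merge when the gap between them is below 50% of
   their *combined length*, read as the sum of the two call lengths (the
   span-inclusive reading is available via `merge_combined = "span"`).
   Merging iterates to a fixed point, so it is idempotent; the merged
   call takes the union span, the summed probe count and the *minimum*
   confidence of its parts — conservative with respect to the downstream
   confidence filter.
2. **CNV-level filters** (`filter_calls`). A call is removed if it has
   fewer than 10 probes, is shorter than 50 kb, has a mean probe spacing
   above 20 kb/probe, or a caller confidence below 10. The density rule
   is directionally interpreted as *removing sparse calls*; the densest
   fixture call has ~0.3 kb/probe spacing and the sparsest ~6.4 kb/probe,
   so all pass. A call with unknown confidence skips the confidence rule
   with a warning (strict mode errors instead).
3. **Sample QC** (`compute_sample_metrics`, `apply_sample_filters`).
   Any sample fails on LRR-SD > 0.3, BAF drift > 0.01 or waviness
   factor > 0.05. Probands are additionally screened for excessive CNV
   load (`n_segments` > 50.8, total length > 16 593 kb) or poor probe
   variance (BAF-SD > 0.063) — parents deliberately are not, so a whole
   trio is not discarded for one parent's mediocre array. The load screen
   can alternatively be recomputed as mean + 4 SD of the proband
   distribution (`outlier_mode = "recompute"`); the fixed printed cutoffs
   are the default because they reproduce the source analysis without its
   cohort. `n_segments` counts calls after CNV-level filtering but before
   the 200 kb retention step.
4. **Retention** (`apply_size_retention`). Only calls strictly longer
   than 200 kb enter the de novo analysis.
5. **Trio classification** (`classify_proband_call`,
   `classify_parental_call`). "Present in a parent" is operationalized as
   the same-type parental call union covering at least 50% of the proband
   call; a proband call is *likely de novo* only when both parents fall
   below that threshold, and a parental call is *transmitted* when the
   proband covers at least 50% of it (inclusive). Dosage type must match:
   a parental duplication never explains a proband deletion. Parents are
   compared at the post-filter 50 kb level, not after 200 kb retention,
   so that small surviving parental evidence still vetoes a de novo
   label.
6. **Annotation** (`annotate_known_loci`, `annotate_genes`). A risk locus
   is hit when the call covers at least 50% *of the locus* (asymmetric,
   per the published wording; a reciprocal mode exists). Gene hits use
   any 1 bp overlap with the gene span for counting, and additionally
   require coding-sequence overlap for curated-list screening.
7. **Rates** (`mutation_rate`, `stratified_rates`, `carrier_table`). The
   mutation rate counts events per trio, the carrier rate probands with
   at least one event; percentages are rounded half-up to one decimal
   only at report emission. Exact Clopper-Pearson 95% intervals (via the
   beta-quantile closed form) accompany every carrier proportion — an
   addition of this package, chosen for exactness at small counts.

## Definitions chosen where the metric is conventionally named but not specified

Three QC statistics are named in the field without a universal formula;
the package fixes fully specified, testable definitions:

* **BAF drift** — the fraction of probes with BAF strictly inside
  (0.20, 0.25) or (0.75, 0.80), i.e. displaced from the canonical bands
  towards positions expected only under abnormal dosage or contamination.
* **Waviness factor** — the population SD of per-1 Mb-window median LRR,
  after trimming 5% of windows from each tail. Window medians resist
  per-probe noise; the trim exists because a genuine multi-megabase CNV
  shifts a handful of window medians, and a wave statistic that fires on
  real copy-number signal would exclude exactly the carriers the study
  is about. The GC-content wave model used by PennCNV itself is not
  reproduced.
* **BAF-SD** — the population SD of BAF restricted to the heterozygous
  band [0.25, 0.75], the standard probe-variance proxy.

All three are approximations to caller-internal metrics and are flagged
as such; their thresholds apply to these definitions.

## The reconstructed cohort pedigree

The fixture tables identify carriers but not the cohort's per-proband
phenotypes, so `study_cohort_trios()` reconstructs a 305-trio pedigree
from the published marginal counts: 13 carriers (3 with intellectual
disability, defined as IQ < 70; one with missing IQ; two female) and 292
non-carriers (26 with ID at the published 9.6% of 271 known-IQ
non-carriers, 21 with missing IQ, 34 further female probands). These
counts make the ID-stratified results auditable: 9 non-ID carriers over
254 known-IQ non-ID probands give 3.5%, and 3 ID carriers among 12
known-IQ carriers give 25.0%. Individual IQ values are placeholders
(65/85/95) encoding only the ID / non-ID / missing partition.

Similarly, real hg19 gene models are not shipped;
`table1_gene_models()` synthesizes one model per printed gene symbol as
an equal slice of its CNV with a central coding interval, reproducing the
printed per-call gene counts under either the gene-span or the
coding-overlap rule. Users supply real gene models for new data.

## The synthetic trio generator

`simulation_config()` fixes the study conditions the generator emulates:

| parameter | default | rationale |
|---|---|---|
| de novo rate / offspring | 0.046 | the published cohort's event rate; drawn as one Bernoulli event so the carrier count is Binomial(n, rate) |
| parental CNV rate | 0.8 / parent / genome (Poisson) | a realistic count of large callable CNVs per individual |
| transmission probability | 0.5 | Mendelian |
| DEL fraction | 10/14 | the observed deletion:duplication split |
| event sizes | log-uniform 200 kb – 4 Mb | the observed size range |
| LRR means (CN 0–4) | −3.5 / −0.66 / 0 / 0.4 / 0.68 | conventional SNP-array emission values |
| LRR noise SD | 0.15 | a mid-quality array (cutoff is 0.3) |
| BAF noise SD | 0.03 | typical het-band width |
| wave | amplitude 0.01, period 8 Mb | mild genomic wave, below the 0.05 screen |
| boundary jitter | 2 probes | caller boundary uncertainty in call-level mode |
| probe spacing | 3 kb | dense-array scale |

The default genome is the 22 autosomes at one tenth of their hg19
lengths, so a full cohort simulates in seconds; full-scale lengths are a
config away. Event boundaries snap to the probe grid, which makes
noise-free segmentation recover them exactly — the basis of the
exactness tests. BAF is drawn from copy-number-appropriate genotype
bands (CN1: 0/1; CN2: 0, ½, 1; CN3: 0, ⅓, ⅔, 1) with noise, clipped to
[0, 1].

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: haplotype-consistent BAF transmission,
mosaicism, GC-driven wave structure, X-chromosome dosage,
genotyping-batch effects, and the saliva-versus-blood quality gradient
real trio studies contend with. A note on scale: at a 1/10-scale genome
the ratio of event length to genome length is tenfold inflated, so
signal-level tests use event sizes proportionate to their simulated
genome; this is a property of the scaled test harness, not of the
method.

`naive_segment()` is a deliberately simple segmentation *test double*
standing in for the external HMM caller (which real analyses consume as
input): running-median smoothing (window 5), thresholds at −0.3 / +0.25
LRR, minimum run 10 probes. Its confidence score is the Gaussian
log-likelihood ratio of the run's mean shift, `n·m̄²/(2σ̂²)`, with σ̂
estimated robustly from probe-to-probe LRR differences (floored at 0.01
so noise-free runs score finitely) — the quantity an HMM caller's
per-call score approximates. A simple `|mean| × length` score was
rejected because noise-induced short fragments of a true event would
score below the confidence cutoff and, through the min-of-parts merge
rule, veto the whole event.

`end_to_end_recovery()` validates the estimator in two modes: `"signal"`
runs probe signals through the segmenter and full sample QC; `"calls"`
derives caller-like calls from truth with boundary jitter and skips the
segmenter, which makes 20-seed × 500-trio recovery studies run in
minutes. In calls mode recovery is exact up to two rare, understood
artifacts: an event drawn within jitter reach of the 200 kb retention
boundary can fall below it, and two nearby transmitted events can merge
into a span neither parent half-covers, producing one false de novo —
both occur at well under one event per 500-trio cohort.

## Numerical choices and degenerate inputs

* Population (divide-by-n) SDs throughout the QC metrics; rounding of
  report percentages is half-up at one decimal, applied only at
  emission.
* Ordering ties in emitted call tables break by (chromosome
  numeric-then-lexical, start, end, type); all outputs are deterministic
  given a seed, with per-trio RNG streams derived from the master seed.
* Copy-neutral (`cn=2`) caller records, zero-length intervals, duplicate
  probands and incomplete trios are errors, not warnings. Empty call
  sets, empty catalogues and missing confidences degrade gracefully with
  warnings.
* The >4 SD proband outlier screen defaults to the published fixed
  cutoffs; the recompute mode applies mean + 4·(sample SD) over the
  proband metric distribution after signal-QC failures are already
  excluded.

## Known limitations

The package does not re-call CNVs from intensities, model CNV genotype
likelihoods, detect mosaicism, assign parent of origin, or lift
coordinates between genome builds; genotype-level array QC (call rate,
sex concordance, Mendelian-error checks) is assumed upstream. The
published analysis's final arbiter — visual inspection of trio traces —
is replaced by `export_trace_window()`, which produces the per-probe
three-member review table that inspection (human or scripted) consumes;
no automated adjudication beyond the documented thresholds is applied.

## Problem sizes used in the shipped tests and scripts

The reproduction path (fixtures over 305 trios) is instantaneous. The
simulation tests use cohorts of 1–50 trios on 2–6 scaled chromosomes for
signal-level checks, a 40-replicate boundary-recovery study, and a
20-seed × 500-trio call-level recovery benchmark; the whole suite runs
in a few minutes on one CPU, and `scripts/acceptance.R` in well under a
minute.
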