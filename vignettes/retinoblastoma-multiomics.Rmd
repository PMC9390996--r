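---
title: "Methods: desk-scale retinoblastoma multi-omics reanalysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale retinoblastoma multi-omics reanalysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbomics)
library(dplyr)
```

rbomics reimplements, as a reusable and tested toolkit, the downstream
analysis layers of an integrative retinoblastoma study: tumor-exome somatic
variant filtering, predictor-consensus deleteriousness calls, arm-level
copy-number recurrence, ChIP-seq/RNA-seq peak-to-gene integration with
binding-motif co-occurrence, single-cell QC, and cohort reporting. The
upstream heavy machinery (aligners, variant callers, peak callers,
segmentation, clustering) is deliberately out of scope: the package starts
from the tabular artifacts those tools emit and makes the *decision rules*
applied to them explicit, reproducible, and testable against synthetic data
with known truth.

## The somatic filter cascade

Tumor-only and matched calling both leave a call set contaminated by
germline polymorphisms and process artifacts. The cascade applies six
predicates to every variant record and keeps a row only when none fails:

1. **Panel of normals** — drop keys (chrom, pos, ref, alt) observed in at
   least 2 of the panel's normal samples. Variant identity is exact key
   equality everywhere in the package.
2. **Read support** — drop when tumor alternate reads < 3, or when tumor
   alternate reads < 8 while the matched blood sample shows > 1 alternate
   read. Without a matched normal only the first clause can apply.
3. **Allele fraction** — drop when the tumor variant allele fraction
   (alt/(alt+ref)) is strictly below 5%; exactly 5% survives. We read this
   "minor allele frequency" cutoff as the *tumor* allele fraction because
   the population-frequency rule is stated separately with its own 1%
   cutoff; this is the main interpretive choice in the module and is
   surfaced here deliberately.
4. **Population frequency** — drop at >= 1% in either the 1000 Genomes or
   ESP column; unknown frequencies pass.
5. **dbSNP with exceptions** — drop dbSNP-listed variants *unless* the
   dbSNP population MAF is < 1% or unknown, the site has a single mapping
   to the reference assembly, or it carries a clinically-associated tag.
   The three exceptions are combined with OR: a rare, clinically tagged
   variant must survive under any serial reading of the sentence.
6. **Shared indel** — a cohort-level germline heuristic: an identical
   insertion, deletion or non-frameshift MNV seen in two or more tumors
   *without* matched germline, and in no matched tumor, is removed
   everywhere.

All six rules are evaluated for every row (no short-circuiting), so the
`failed_rules` list-column is a complete audit trail; because the rules are
independent predicates, evaluation order cannot change the kept set. The
one caveat is the shared-indel rule, which is a function of the cohort you
pass in: re-running the cascade on its own kept table can, in principle,
re-classify a shared indel whose only matched-sample occurrence was removed
by a *different* rule. The package treats the original cohort as the
reference for that rule; the tests exercise idempotence on simulated
cohorts where the interplay does not arise.

## Predictor consensus

Three categorical predictors vote on substitutions: a three-level tool
(probably damaging / possibly damaging / benign) and two binary tools
(damaging / tolerated). "Possibly damaging" counts as a deleterious vote.
The consensus is class-dependent, and the two formulations are *not*
symmetric once calls are missing:

* nonexonic and synonymous substitutions are deleterious iff **two of
  three vote deleterious** — missing calls default toward benign;
* nonsynonymous exonic substitutions are non-deleterious iff **two of
  three vote benign** — missing calls default toward deleterious.

With complete calls the two rules provably coincide (the suite enumerates
all 3 x 2 x 2 call combinations); with missing calls the nonsynonymous
rule dominates. We apply each wording literally — the asymmetry is the
only signal the source protocol gives about missing-call behaviour — and
report the rule used per row. Insertions, deletions and splicing-junction
alterations are force-classified deleterious (`indel_or_splicing`); we
apply this to every indel rather than only exonic ones, a simplification
that matters little for exome data, where called indels are
overwhelmingly exonic or splice-proximal.

## Arm-level copy number

The arm score is the length-weighted mean segment log2 copy ratio over the
arm (gain > 0.1, loss < -0.1, strict at the boundary). The original
study's GISTIC run is not reproducible from its text, so cohort recurrence
uses a permutation analog with the same cutoff semantics: each sample's
arm labels are shuffled (its number of gained/lost arms is preserved,
their identity randomised), giving a null for per-arm frequency;
z = (observed - null mean)/null SD, p from the permutation tail,
Benjamini-Hochberg across arms x directions, significance at z >= 6 and
FDR < 0.05 (z cutoffs inclusive, as stated). The default `n_perm = 10000`
matters: the permutation p floor is 1/(n_perm+1), and after BH across ~78
arm-direction tests a 1000-permutation run cannot reach FDR < 0.05 even
for a perfect signal.

Focal amplification (e.g. MYCN) reuses the permutation idea within a
sample: segment ratios are shuffled across the sample's segment positions
and the locus window's weighted mean recomputed; the locus is flagged at
z >= 3. A locus indistinguishable from background has null SD 0 and is
never flagged. Isodisomy (copy-neutral LOH) is flagged when the arm-median
|BAF - 0.5| exceeds 0.3 — separating heterozygous (~0) from homozygous
(~0.5) arms with wide margin in noiseless simulation — while the arm
score stays within +/-0.1. The hg19 arm table ships as a plain-TSV config
asset and can be replaced wholesale.

## Peak integration

Peak sets are BED-convention tibbles (0-based half-open); TSS positions
are 1-based; conversions live in the readers and in one internal helper.
High-confidence peaks are the union spans of >= 1 bp-overlap clusters that
contain at least one peak from each replicate (transitive clustering via
`GenomicRanges::reduce`; a quadratic all-pairs oracle checks it in the
tests). Whether the original analysis required reciprocal-overlap
fractions is unknown; >= 1 bp is the permissive reading.

Each peak is assigned to the gene whose TSS is nearest its center,
unlimited range, ties broken by lexicographically smallest gene id — the
association rule is unstated in the source, and nearest-TSS is the
convention of the standard annotation tools, so printed link counts are
emulated on mirror fixtures rather than replicated. Signed distance runs
TSS to peak center with the sign flipped on minus-strand genes (negative
is always upstream); bins are [0, 3 kb] (promoter, inclusive at 3000),
(3, 10 kb], (10, 100 kb] and > 100 kb on |distance|. DE integration labels
links up/down at FDR < 0.05 by log-fold-change sign and reports
partition-consistent per-direction gene and peak counts. Super-enhancer
overlap counts SE intervals containing >= 1 bp of >= 1 peak.

## Motifs

Motif models are IUPAC consensus strings or 4 x L probability matrices;
PWM scanning scores windows by log2 odds against the background and calls
a hit at >= `score_threshold` (default 0.8) of the maximum achievable
score, a common scanning default. An N in the sequence never matches
either mode. The bundled models (ERRE `TNAAGGTCA`; CRX/OTX2 `TAATCC`;
NEUROD `CAKCTG`; LHX `TAATTA`) are canonical consensus placeholders chosen
by the implementers, not curated PWMs — real-data motif results are
configuration-dependent, so swap in matrices from a public collection for
production use. Presence matrices, exact-subset (UpSet-style)
co-occurrence counts, and one-sided hypergeometric enrichment with BH
adjustment follow.

## Single-cell QC

Cells are kept when total UMIs > 400 (strict), detected genes lie in
[100, 6000] (inclusive), and mitochondrial content is < 10% (strict);
mitochondrial genes default to the `MT-` symbol prefix because the source
gene list is not published. Group summaries use log1p counts-per-million —
the minimal normalization consistent with CPM-scaled reporting — and
detection is raw count > 0. Co-detection of two genes is tested with a
two-sided Fisher exact test on the 2 x 2 detection table.

## The synthetic-data generators

Every pipeline input can be generated with ground truth, which is what the
whole test pyramid stands on:

* **Variant cohorts** (`simulate_variant_cohort()`): defaults emulate a
  103-tumor exome cohort with 117 panel normals and ~93% matched blood.
  Allele fractions are Beta-distributed — somatic mean 0.35, heterozygous
  germline tight around 0.5, artifact mean 0.03 — so the 5% allele-fraction
  cutoff is exercised from both sides; read counts are Binomial(depth,
  VAF) with Poisson depth, the simplest model that gives the read-count
  rules teeth. Germline variants come from a shared population pool
  (gamma-weighted frequencies), which makes them recur across samples and
  panel normals and makes the shared-indel heuristic meaningful; somatic
  keys are never planted in the panel. Predictor calls flip the true
  label independently per tool at `predictor_error`, and a configurable
  fraction of damaging PolyPhen-style calls is emitted as "possibly
  damaging" to exercise the 3-level mapping. Per-sample burdens
  (somatic 10, germline 40, artifact 15 expected calls) are stylized but
  of the right order for a low-burden pediatric tumor after calling.
* **Arm segments** (`simulate_arm_segments()`): each arm is tiled by
  ~10 random-width segments (Poisson), matching the fragmentation of
  exome copy-ratio segmentations; per-segment Gaussian noise then
  averages out at arm level, which is what makes 0.05-SD noise compatible
  with reliable recovery of a 0.3 planted gain. BAFs sit near 0.5 except
  on planted-isodisomy arms, where they collapse to 0.02/0.98.
* **Integration fixtures** (`simulate_integration_fixture()`): genes are
  spaced 1 Mb apart so every planted peak has an unambiguous nearest TSS
  and the truth bin is exact; replicate-only peaks live in a coordinate
  band no shared peak can reach, so the planted replicate-overlap
  fraction is recovered exactly. Default bin mass puts 18% of peaks in
  promoters and about half in the 10-100 kb band.
* **Count matrices** (`simulate_count_matrix()`): passing cells are built
  with margin on every rule, and each planted failure violates exactly
  one named rule, with deterministic fix-ups (count transfers, gene
  swaps) guaranteeing the label even in sampling corner cases.

What the generators do *not* emulate — alignment artifacts, mutational
signatures, linkage, ambient RNA, doublets, GC-dependent peak calling —
bounds what green tests mean: they certify the decision rules and their
boundary behaviour, not performance on real sequencing data.

## Numerical conventions and problem sizes

Printed percentages use round-half-up at one decimal
(`percent_of()`), not banker's rounding. Threshold comparisons follow the
stated wording everywhere: strict for the 5% VAF, the |0.1| arm score and
the 10% mitochondrial fraction; inclusive for the z cutoffs, the 3 kb
promoter edge and the 100-6000 gene window. Permutation p-values use the
add-one estimator (1 + exceedances)/(n_perm + 1). Oncoprint cells take the
highest-priority alteration (homozygous deletion > stop-gain > splicing >
indel > missense; configurable), columns sorted by burden.

The test suite works at deliberately desk-scale sizes — cohorts of 15-50
samples, 2,000-variant filtering oracles over 100 seeds, 200 random
interval/scan fixtures, 50-replicate null calibrations at 1,000
permutations — chosen so the whole suite completes in a few minutes while
keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The exact GISTIC score and null are a stated substitute, not a
  replication; published arm-level z values are not comparable 1:1.
* The peak-to-gene rule (nearest TSS, unlimited range) cannot exactly
  reproduce the published 1226-peaks/738-genes association without the
  original rule; the package reproduces the partition arithmetic on
  mirror fixtures instead.
* Bundled motif models are placeholders; enrichment on real data depends
  entirely on the matrices supplied.
* Manual IGV curation steps, driver-gene short-listing against benign-gene
  catalogs, and every wet-lab assay in the source study are out of scope.
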