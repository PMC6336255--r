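---
title: "Methods: lncRNA discovery, classification and ceRNA networks with lncflow"
author: "lncflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery, classification and ceRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncflow)
```

# Scope and model

`lncflow` implements the downstream analysis that turns assembled
transcript models from a multi-tissue, strand-specific RNA-seq design
into a characterized long non-coding RNA (lncRNA) catalogue and a
competing endogenous RNA (ceRNA) network.  Upstream steps — read
alignment, transcript assembly, coding-potential scoring (CPC), protein
domain search (Pfam), BLAST similarity, and miRNA target prediction —
are deliberately out of scope: their outputs are consumed as tables, so
the package isolates the *decision logic* of the analysis from
third-party scorers.

The stages, in pipeline order:

1. **Novelty filter cascade** (`runFilterCascade`).  After removing
   redundant transcript models (`deduplicateTranscripts`: identical
   chromosome, strand, exon coordinates), assembled transcripts are
   screened in a fixed order: spliced length ≥ 200 bp; read coverage
   ≥ 3; not overlapping a known coding gene; not > 90% identical to a
   known lncRNA; coding-potential score < 0 *and* no protein-domain
   hit.  Survivors are the novel lncRNA set.  Each failure is
   attributed to the *first* violated step, so drop counts decompose
   the loss exactly.  Boundaries follow the inequalities literally:
   length exactly 200 and coverage exactly 3 and identity exactly 90%
   survive their steps; a coding-potential score of exactly 0 does not.
2. **Positional classification** (`assignPartners`, `classifyPosition`).
   Every lncRNA is paired with an RNA partner gene — the gene with
   maximal span overlap, or the nearest gene within 100 kb — and
   assigned one of six classes: genic lncRNAs are `containing`,
   `nested` or `overlapping` by containment geometry of the transcript
   spans; intergenic lncRNAs are `same_strand`, `convergent` or
   `divergent` by strand configuration relative to the gap.
3. **Quantification** (`computeRpkm`, `expressedSets`,
   `vennPartition`).  RPKM = 10⁹·C/(N·L) with C the feature's count in
   a sample, N the sample's total assigned reads and L the feature
   length.  A feature counts as expressed in a tissue when its mean
   RPKM across that tissue's replicates is ≥ 1; per-tissue sets feed a
   Venn partition and tissue-specific lists.
4. **Differential expression screen** (`deTest`, `bhAdjust`).  A
   feature is differentially expressed in a tissue pair when its fold
   change is ≥ 2 (|log₂FC| ≥ 1) *and* its Benjamini–Hochberg q-value is
   ≤ 0.01.
5. **Cis-target prediction** (`predictCisTargets`).  A gene is a
   cis-target candidate of an lncRNA when both are differentially
   expressed, the gene overlaps the lncRNA span or lies within 100 kb
   of it, and their expression profiles correlate (Pearson p < 0.01
   across all samples).
6. **Term enrichment** (`enrichTerms`, `hyperTailP`).  Exact
   hypergeometric upper tail
   P = 1 − Σᵢ₌₀^{m−1} C(M,i)·C(N−M,n−i)/C(N,n) over a gene→term table,
   BH-adjusted across terms.
7. **ceRNA network** (`buildTrends`, `buildCernaNetwork`,
   `exportNetwork`).  A candidate triplet is any (lncRNA, miRNA, mRNA)
   where the miRNA targets both (a shared miRNA response element); it
   is accepted when at least one tissue contrast shows the lncRNA
   differentially expressed with the mRNA trending the same way and
   the miRNA trending opposite.  Accepted triplets export as SIF +
   node attributes for network viewers.

# Coordinate and container conventions

Intervals live in `GenomicRanges` objects (1-based, closed), the
Bioconductor convention; all overlap, gap and containment semantics are
defined on that representation.  "Overlap" means shared bases: adjacent
(bookended) spans have `overlapBp = 0` *and* `gapDistance = 0` and
classify as intergenic.  Positional comparisons use whole-transcript
spans, not exon unions; an exon-union mode is intentionally not
provided.  Expression matrices travel as `SummarizedExperiment`s with
`tissue`/`replicate` column data; transcript models as a `TranscriptSet`
(a `GRangesList` of exons plus a transcript table) whose validity
method enforces sorted, non-overlapping, single-chromosome,
single-strand exon sets.

# Tunable parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `minLength` | 200 | bp | minimum spliced transcript length |
| `minCoverage` | 3 | assembler units | minimum read coverage (opaque real) |
| `maxKnownIdentity` | 90 | % | maximum identity to a known lncRNA |
| `cpcCutoff` | 0 | score | coding-potential threshold (must be below) |
| `rpkmCutoff` | 1 | RPKM | expression-presence cutoff (mean of replicates) |
| `fcCutoff` | 2 | fold | DE screen fold-change bound (inclusive) |
| `qCutoff` | 0.01 | FDR | DE screen BH q bound (inclusive) |
| `cisWindow` | 100000 | bp | cis search window and partner `maxGap` |
| `cisAlpha` | 0.01 | p | correlation cutoff for cis candidates |

"Read coverage" is treated as an opaque real compared against 3; its
units are whatever the upstream assembler reports.

# Design choices where the design was open

**Partner selection.** When several genes overlap or flank an lncRNA,
the partner is the gene with maximal span overlap, else nearest gap;
ties break to the smaller start coordinate, then lexicographic id.
This makes classification a deterministic function of the annotation.
Genic subtypes ignore strand (an antisense overlap is still genic by
geometry); exact span equality classifies as `containing` (containment
read inclusively, with the `nested` tie broken for determinism).
Convergence is decided by the strand of the left-hand feature of the
pair: `+` on the left means both transcribe toward the gap.

**Replicate aggregation for expression presence.** The RPKM < 1 rule is
applied to the replicate *mean* per tissue (a `max` rule is available
by flag).  The comparison is inclusive at the cutoff.

**The DE statistic.** The screen (fold change ≥ 2, Q ≤ 0.01) is the
contract; the p-value generator is pluggable.  The default, `nbz`, is a
two-sided Wald z-test on the log-ratio of pooled
library-size-normalized group means whose variance follows a
negative-binomial model with a single common dispersion estimated from
all features by moments (a ratio-of-sums estimator, so high-count
features dominate).  A pure Poisson z-statistic is badly
anticonservative as soon as replicates are overdispersed; borrowing one
common dispersion across a few thousand features costs almost no power
at n = 3 + 3 and restores type-I control, and at zero dispersion the
statistic reduces to the Poisson z.  `poisson` provides the exact
conditional binomial (two-sample Poisson) alternative.  Fold changes
use a pseudo-count of 1 normalized count.  How multiple DE callers
would be reconciled is not modeled; one statistic runs at a time.

**Correlation for cis-targets** is computed across all 9 samples
(3 tissues × 3 replicates), not across 3 tissue means — three points
give essentially no power at p < 0.01.  Both correlation signs are
accepted by default (`positiveOnly` restricts to positive).  Window
distance is measured between transcript spans, not TSS anchors.

**ceRNA quantifiers.** The trend rule requires at least one contrast in
which the lncRNA is itself differentially expressed and the
mRNA/miRNA trends qualify; a strict mode requires every lncRNA-DE
contrast to qualify.  Target tables from multiple predictors are
unioned by default (intersection by flag).  The rule depends only on
relative signs, so a global sign flip leaves the network unchanged.

**Numerics.** The hypergeometric tail is computed as the complementary
(upper) tail sum — mathematically identical to one minus the printed
lower sum, numerically stable — with log-space binomial coefficients.
Correlation p-values guard |r| = 1 against division by zero.  Rows with
zero variance get correlation distance 1 in clustering instead of NA.

# The synthetic study generator

`simulateStudy` emulates the study design this pipeline targets: three
tissues (flower, leaf, root) × three biological replicates, a toy
two-chromosome genome, and every downstream input with planted ground
truth:

* **Geometry.** Features are laid out in blocks spaced 250 kb apart so
  features of different blocks are always farther apart than the
  100-kb window.  Each planted lncRNA sits in a block with its partner
  gene in one of the six class geometries, so the classifier's output
  on the generated annotation must reproduce the planted label.  The
  first lncRNA of each class is annotated known, the rest are novel.
* **Counts.** Negative-binomial with common dispersion (default 0.1,
  the typical biological-replicate scale for bulk RNA-seq; 0 gives the
  Poisson limit), means = per-feature baseline × tissue multiplier.
  Planted differentially expressed features have an exact mean ratio
  of 2^`deLog2fc` (default 2) between their up-tissue and the others.
  Planted up-tissues rotate across features so no tissue dominates the
  library composition — with one-sided planting, library-size
  normalization would otherwise absorb part of every planted fold
  change into a composition artifact.
* **Cascade decoys** each violate exactly one filter step (short
  length is violated geometrically; the others through the evidence
  table the generator writes), so step attribution is testable
  per decoy.
* **Cis pairs** share their tissue pattern *and* a per-sample latent
  log-normal factor (log-sd 0.4), the co-regulation signal the
  correlation step detects; negative controls are block pairs whose
  members are both differentially expressed but in orthogonal tissue
  patterns with independent jitter (population correlation ≈ −0.5,
  p ≈ 0.17 at n = 9 — detectably *not* cis).
* **ceRNA triplets** wire a miRNA to one planted lncRNA and one mRNA
  in both target tables with opposite expression trend; each true
  triplet is mirrored by a decoy miRNA sharing both targets but
  trending *with* them, which the network rule must reject.  miRNA
  expression is simulated directly as its own matrix.
* **Term map.** A gene→pathway table with one pathway collecting the
  planted DE genes plus background stripes, so the enrichment stage
  has a planted answer.

All randomness derives from the single config seed; the same
configuration yields byte-identical outputs, which the determinism
checks exploit.

What the generator does *not* emulate: sequence-level realism (random
nucleotides; homology and GC structure absent), read-level data (no
FASTQ), gene-length biases in enrichment, batch effects, and the
long-tailed mean-dispersion relationships of real libraries.  Passing
tests therefore demonstrate that the decision logic is correct under
its stated model, not that the thresholds are optimal for any real
tissue panel.

# Verification strategy and problem sizes

Every operation with a closed form is tested against an independent
oracle: exhaustive draw enumeration for the hypergeometric tail (all
N ≤ 12), a definitional step-up oracle for BH (10,000 random vectors of
length ≤ 8), an exhaustive start-position scan for ORFs, a naive O(n³)
agglomeration for clustering, brute-force geometry for classification
(1,000 random span pairs per run), triple-loop enumeration for the
ceRNA rule, and the planted truth of the generator for the end-to-end
stages (a 500-decoy study for cascade attribution).  Error-control
checks use 2,000-feature null and power simulations at 3 + 3
replicates, with the 200 planted changes split 100 up / 100 down so
that power is measured free of composition bias.  Exact-recovery checks
for cis pairs and ceRNA triplets run in the zero-noise limit (zero
dispersion, planted log₂ fold change 3); at realistic noise the
correlation step's recall is bounded by the 9-sample design (~0.8 at
dispersion 0.1), which is the expected behaviour of the method, not a
defect.  These sizes keep the full suite under a minute on one CPU
while leaving each property's margin wide.

# Known limitations

* Classification depends on the partner-selection rule where the
  annotation offers several candidates; other choices (e.g. all
  overlapping genes) would multiply assignments.
* The plain hypergeometric test carries no gene-length bias
  correction.
* RPKM is the only normalization; no TPM or between-sample methods.
* The ceRNA step consumes predictor tables and miRNA expression as
  given; no binding-site prediction from sequence.
* ORFs are sought on the sense strand only, which assumes oriented
  (strand-specific) transcript sequences.
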