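---
title: "Detecting and analysing circular RNAs with circSplice"
author: "circSplice maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing circular RNAs with circSplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circSplice)
```

## The problem

Circular RNAs (circRNAs) arise from back-splicing: a downstream splice
donor is joined to an upstream acceptor, producing a covalently closed
circle whose diagnostic signature in RNA-seq is a head-to-tail junction
read — a read whose left part matches the 3' end of a downstream exon and
whose right part matches the 5' start of an upstream exon. circSplice
implements a complete desk-scale analysis of this signal for a two-condition
design with biological replicates, modelled on the study of circRNA
regulation by the ALS-associated RNA-binding protein FUS in motor neurons:

1. anchor-based back-splice junction discovery with a GT/AG splice-signal
   constraint and the published support filters;
2. joint circular/linear differential expression with a negative-binomial
   GLM likelihood-ratio test;
3. a faux-circRNA permutation test for positional bias of circRNAs within
   protein-coding transcripts;
4. a CLIP-peak flanking-intron enrichment analysis relating binding to
   deregulation.

Every stage is testable without external downloads through the bundled
synthetic-data generator, which plants circles with known coordinates,
fold changes and binding flags.

## Coordinates and containers

All intervals are 1-based closed `GRanges` (the Bioconductor convention);
GTF input/output is 1-based closed, BED input/output 0-based half-open,
with conversion only at the I/O boundary. Splice sites are stored as the
genomic coordinate of the exon-terminal base: the donor is the last exonic
base of the upstream exon in transcription order, the acceptor the first
base of the downstream exon. A junction is circular exactly when its
acceptor lies upstream of its donor in transcription order. Sequences and
gene models live in a `GenomeBundle`; circular and cognate linear counts in
a `CircCountSet`, a `SummarizedExperiment` whose library sizes are defined
as column sums over all features.

## Junction detection

Reads are prefiltered in two stages mirroring the published pipeline:
pairs matching abundant non-coding RNA contaminants are removed, then any
mate that maps contiguously (full length, either strand) anywhere in the
genome is discarded — what survives must span a junction. Both prefilters
use exact seed-and-verify matching; the package deliberately ships a
toy-scale exact aligner rather than a production short-read mapper.

From each candidate mate, 20-nt anchors are taken from both ends and
aligned exactly to the genome on both strands. For each compatible anchor
placement pair, every split of the unanchored middle is scored; a
breakpoint is accepted when both pieces match the genome adjacent to their
anchors with at most `maxMismatch` (default 2) substitutions **and** the
genomic dinucleotides flanking the junction are GT (donor side) and AG
(acceptor side) on the read's strand. Among equal-mismatch candidates the
genomically leftmost breakpoint is chosen, making calls deterministic.
Genomic positions outside the sequence read as a pad byte that can never
match a base or a signal, so junctions near sequence ends remain scorable.

The published per-sample filters are applied at aggregation: at least two
unique supporting read sequences, span below 100 kb, both anchors uniquely
placed (the package's realisation of the MAPQ >= 35 cutoff — in an
exact-match aligner a placement is either unique or it is not), and no
junction spanning two mutually non-overlapping genes (a mapping-error
signature). Junctions passing in at least one sample are kept, and linear
reads across the two back-splice coordinates are summed to quantify the
cognate linear transcript.

## Differential expression

Counts of each circular junction and its cognate linear junction are
modelled as negative binomial with a log link and library-size offsets;
the per-feature test is a likelihood ratio between per-condition means and
a shared mean, referred to chi-squared with one degree of freedom.
Significance uses the raw p-value at 0.05 (a deliberate choice for
low-count features, matching the published analysis); a Benjamini-Hochberg
column is provided for reference.

Dispersion is estimated from all features by maximising the Cox-Reid
adjusted profile likelihood (half the log-determinant of the per-group
Fisher information is subtracted before profiling out the means). The
adjustment matters at this design size: with three replicates per
condition the naive profile likelihood underestimates the dispersion by
roughly 40% and inflates the type-I error of the LRT to about 0.11; with
the adjustment the empirical type-I error at nominal 0.05 is about 0.05.
Per-feature dispersions maximise the feature's own adjusted profile
likelihood plus `priorWeight` (default 10) times the average across
features, on a dispersion grid; an infinite prior weight collapses to the
common value. The default test uses the shrunken per-feature values.

Library sizes are plain column sums of the combined circular+linear
matrix, with no trimmed-mean normalisation — the published run supplied
both event types to the testing software together and says nothing about
extra normalisation, so none is added. A consequence worth knowing: if
circular counts were a large fraction of the library, strong circular
deregulation would shift the offsets (composition bias). In real data
linear junction reads exceed back-splice reads by orders of magnitude, so
the generator's defaults and the package's validation designs keep linear
counts dominant.

Fold-change estimates are plain maximum likelihood. At the package's
validation design (three replicates per condition, mean 50, dispersion
0.2) the sampling standard deviation of a per-feature log2 fold change is
about 0.55 in log2 units — this is the information bound, not an
implementation artefact, and no unbiased estimator can do better at this
depth. Users needing tighter per-feature estimates need more replicates or
deeper junction coverage; the package does not shrink fold changes toward
zero, keeping estimates unbiased for downstream sign-based analyses.

Circles where both the circular and linear features are significant with
fold changes of the same sign are flagged *parallel* — their change is
plausibly transcriptional rather than post-transcriptional — and excluded
from the positional and binding analyses. Sign agreement is this package's
operationalisation of "significantly paralleling"; the rule is documented
here because the boundary case (both significant, opposite signs) is
genuinely ambiguous and we keep such circles.

A one-sample two-sided t-test on the vector of circular log2 fold changes
summarises global shifts (the cognate linear vector should stay centred
at zero).

## Positional bias: the faux-circRNA permutation test

Circles whose junctions fall in introns or outside genes are excluded;
the rest are resolved against protein-coding transcripts and flagged for
overlap (>= 1 bp) of their exonic span with the 5' UTR, CDS and 3' UTR.
When several coding isoforms host a circle, flags come from the longest
coding isoform (a switch selects the shortest instead) and the exon count
spanned is the mean across isoforms rounded to the nearest integer, halves
away from zero — the tie direction is fixed so results are identical
across platforms.

The null model draws 5,000 faux circles: each draw samples an exon-run
size from the observed distribution, a uniform-random hosting transcript
that can accommodate it, and a uniform-random run of consecutive
*internal* exons (terminal exons are never used, matching how real circles
avoid transcript ends). Observed category counts over the partition
{5' UTR only, CDS only, 3' UTR only, both UTRs} are tested against the
faux frequencies with a Pearson goodness-of-fit chi-squared; categories
with zero expectation are merged into the rarest populated category with a
warning. Because the expected proportions come from a finite faux sample,
the p-value is taken from the finite-reference null (the statistic is
scaled by nF/(nF + nR)); treating a 5,000-draw reference as exact is
anti-conservative once the real set reaches several hundred circles, and
an option restores that naive behaviour for comparison. Calibration is checked by drawing "real" circles from the faux
process itself with a fresh faux reference per repeat — the unconditional
type-I error of the whole procedure, including the reference's own
sampling error, at the scale of the real localization analysis (1,000
circles per repeat; rejection at nominal 0.05 lands in [0.03, 0.07] over
500 repeats) — and power by planting circles at twice the baseline 5'-UTR
overlap rate (the run weight realising a doubled rate for baseline
frequency f is 2(1-f)/(1-2f)).

## CLIP binding enrichment

Peak replicates arrive as BED6 plus a p-value column; per replicate only
peaks with p strictly below 1e-4 are kept. Pooled peaks are merged when
separated by at most 50 nt (the interval-merge semantics of
`bedtools merge -d 50`; a gap of exactly 51 stays unmerged) and a merged
site is a binding site only when its constituents come from at least two
distinct replicates. Merging is strand-aware by default since the
upstream CLIP processing is stranded; unstranded peaks match either
strand.

Eligible circles must have both back-splice sites on annotated splice
sites, flanking introns of at least 1,500 nt on both sides, and must not
be in the parallel-exclusion list. For each eligible circle two windows
are built: up to *w* nt of the upstream flanking intron immediately 5' of
the acceptor and up to *w* nt of the downstream intron immediately 3' of
the donor (strand-aware, clipped to the intron), with *w* in {500, 1000}
by default and arbitrary widths supported to trace the distance decay of
the effect. A circle is bound when any binding site overlaps either
window by at least one base.

The 2x2 test crosses bound/unbound with deregulated/unaffected
(deregulated = raw DE p below the cutoff; the cutoff is stratified over
{0.05, 0.005, 0.001}) and uses a Pearson chi-squared without continuity
correction by default; the Yates-corrected variant is a flag, since the
original report does not state which was used and the full width-by-cutoff
grid makes every variant inspectable.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions every calibration result refers to: 50 genes (4-8 exons of
100-250 nt, introns 1,600-2,600 nt beginning GT and ending AG on the
coding strand, both strands, 90% protein-coding with the CDS placed so
early exon runs span the 5' UTR), 20 planted circles over 2-3 consecutive
internal exons, three replicates in each of two conditions, 100-nt
stranded paired reads, NB counts with dispersion 0.1 around a circular
baseline mean of 30 and a linear baseline of 60, 40% of circles
deregulated (80% of those down, magnitudes uniform in [1, 2.5] log2
units — mirroring the direction balance reported in the motivating study),
and CLIP peaks planted in a flanking intron within 1-500 nt of a
back-splice site for 35% of deregulated and 24% of unaffected circles,
replicated threefold with <= 10 nt jitter.

Two generator properties are deliberate:

* **Unique breakpoints.** Exon terminal bases never equal G, so the
  zero-mismatch GT/AG-consistent breakpoint of every planted junction is
  unique and exact-coordinate recovery is well-defined. Real genomes
  contain junction-adjacent repeats that make the breakpoint ambiguous by
  a few bases; resolving that ambiguity is an aligner concern outside this
  package's scope, so passing tests demonstrate correctness of the
  breakpoint logic, not robustness to repeat-induced ambiguity.
* **Clean reads by default.** Sequencing errors default to zero (a uniform
  substitution rate is available) because the object under test is the
  filter chain, not alignment robustness.

What the simulation does *not* emulate: fragment-length and coverage
biases, quality-score structure, intron-retaining circles, multi-isoform
hosts (one transcript per gene by default; multi-isoform behaviour is
exercised with hand-built annotations in the test suite), and
repeat-driven multi-mapping beyond the explicit duplicated-segment
fixtures. Conclusions about real libraries should be drawn accordingly.

## Reproducibility and problem sizes

Every stage derives its RNG stream from one master seed; reruns with an
identical configuration produce byte-identical artifacts, and the pipeline
writes a manifest of all parameters alongside its outputs. The validation
suite uses desk-scale designs chosen to estimate each property precisely
enough while staying quick: 2,000 features for null calibration, 500 for
fold-change recovery, 500/200 Monte-Carlo repeats for the permutation and
enrichment checks, and 20 random toy genomes for the brute-force
breakpoint cross-check.

## A worked run

```{r, eval = FALSE}
res <- runPipeline(list(nGenes = 30L, nCirc = 12L, seed = 1L),
                   outDir = "circ_run")
res$summary
res$enrichment
```

`res$summary` reports the junction counts surviving each published filter,
the robustly expressed set, and the significant/downregulated tallies;
`res$enrichment` is the width-by-cutoff grid of bound fractions and
chi-squared p-values. All artifacts (junction tables, DE table,
localization and faux tables, merged binding sites, run report, manifest)
are written under `outDir`.

## Known limitations

* The aligner is exact-match and toy-scale by design; genome-scale FASTQ
  input is out of scope.
* Dispersion shrinkage uses a grid-based weighted-likelihood scheme, not
  the full Cox-Reid tagwise machinery of production DE packages; its
  behaviour is validated by calibration, not by numerical identity to any
  other implementation.
* Per-feature fold-change precision is bounded by the information in six
  samples of junction counts (see above); global summaries (shift tests,
  bound fractions, category counts) are the quantities this depth
  estimates well.
* GFF3 dialects, annotation liftover and multi-factor designs are not
  supported.
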