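# circSplice

Back-splice junction detection and differential analysis of circular RNAs
(circRNAs) from stranded paired-end RNA-seq, for two-condition designs with
biological replicates — the computational workflow used to study how an
RNA-binding protein (such as FUS, mutated in familial ALS) regulates
back-splicing in neurons.

A circRNA betrays itself through head-to-tail junction reads: a read whose
left part matches the 3' end of a downstream exon and whose right part
matches the 5' start of an upstream exon. circSplice finds these reads with
20-nt terminal anchors and breakpoint extension under a GT/AG splice-signal
constraint, applies the published support filters (two unique reads per
sample, span < 100 kb, uniquely placed anchors, no junctions across
non-overlapping genes), counts reads on each back-splice junction and on its
cognate linear junctions, and then:

* tests differential expression jointly for circular and linear features
  with a negative-binomial GLM likelihood-ratio test
  (log link, library-size offsets, Cox–Reid-adjusted dispersion estimation;
  significance on raw p < 0.05), flagging circles whose change merely
  parallels the host transcript;
* tests whether circRNAs sit preferentially over the 5' UTR / CDS / 3' UTR
  of their host transcripts against a null of 5,000 *faux* circRNAs — random
  runs of consecutive internal exons — with a Pearson goodness-of-fit
  chi-squared;
* asks whether deregulated circRNAs are enriched for CLIP-seq binding sites
  (replicate peaks filtered at p < 1e-4, merged at 50 nt with two-replicate
  support) in the 1–500 / 1–1000 nt of flanking intron next to their
  back-splice sites, with a 2×2 chi-squared stratified over DE cutoffs.

Everything runs end-to-end on a bundled synthetic-data generator that plants
circles with known coordinates, fold changes and binding flags, so every
stage is validated against ground truth without any downloads.

## A worked example

```r
library(circSplice)
res <- runPipeline(list(nGenes = 30L, genesPerChrom = 10L, nCirc = 12L,
                        nFaux = 1000L, seed = 1L),
                   outDir = "circ_run")
res$summary
#> backsplice_junctions_total         circ_after_filters
#>                         12                         12
#>    circ_robustly_expressed           circ_significant
#>                         12                          5
#>      circ_significant_down     circ_parallel_excluded
#>                          4                          0
res$counts
#> CircCountSet: 12 circular + 12 linear features x 6 samples
#>   conditions: cond1 vs cond2
head(as.data.frame(res$de[res$de$kind == "circular",
                          c("log2fc", "lr", "pvalue", "padj")]), 5)
#>                       log2fc      lr pvalue   padj
#> chr1:-:82890:80617   -2.2570 18.3115 0.0000 0.0002
#> chr1:+:128758:131133  0.5962  1.7375 0.1875 0.4499
#> chr1:+:17810:20026    0.2814  0.3868 0.5340 0.8134
#> chr1:+:66763:69634    0.0899  0.0413 0.8390 0.9035
#> chr2:-:13378:8820    -1.7167 12.3471 0.0004 0.0027
```

All 12 planted circles are recovered with exact coordinates and survive the
published filters; 5 are called deregulated at p < 0.05, 4 of them down —
matching the planted truth for this seed. `res$de` lists each junction's
log2 fold change (condition 2 vs 1), likelihood-ratio statistic, raw p-value
and BH-adjusted q; `res$enrichment` holds the width-by-cutoff grid of bound
fractions and chi-squared p-values; `res$locTest` the positional-bias test.
Artifacts (junction tables, DE table, localization and faux tables, merged
binding-site BED, per-sample read-accounting report, parameter manifest) are
written under `outDir`, byte-identically on rerun with the same seed.

The methods vignette (`vignettes/circSplice-methods.Rmd`) documents the
model, the parameter defaults and the generator's scope.

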