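mkBed <- function(rows) {
    f <- tempfile(fileext = ".bed")
    writeLines(vapply(rows, paste, "", collapse = "\t"), f)
    f
}

test_that("peak ingestion applies the strict p-value cutoff per replicate", {
    f <- mkBed(list(c("chr1", 100, 130, "p1", 0, "+", 5e-5),
                    c("chr1", 500, 530, "p2", 0, "+", 2e-4)))
    pk <- readClipPeaks(c(rep1 = f), circParams())
    expect_identical(length(pk$rep1), 1L)
    expect_identical(pk$rep1$name, "p1")
    expect_identical(start(pk$rep1), 101L)   # BED is 0-based half-open
    expect_identical(end(pk$rep1), 130L)
})

test_that("malformed BED lines are rejected with their line number", {
    f <- mkBed(list(c("chr1", 100, 130, "p1", 0, "+", 5e-5),
                    c("chr1", "oops", 130, "p2", 0, "+", 5e-5)))
    expect_error(readClipPeaks(c(r = f), circParams()), "line 2")
    f2 <- mkBed(list(c("chr1", 100, 130, "p1", 0, "+")))
    expect_error(readClipPeaks(c(r = f2), circParams()), ">= 7 fields")
})

test_that("a replicate emptied by the filter still counts for support", {
    f1 <- mkBed(list(c("chr1", 100, 130, "a", 0, "+", 5e-5)))
    f2 <- mkBed(list(c("chr1", 110, 140, "b", 0, "+", 5e-3)))
    expect_warning(pk <- readClipPeaks(c(r1 = f1, r2 = f2), circParams()),
                   "no peaks")
    expect_identical(length(pk), 2L)
    expect_identical(length(pk$r2), 0L)
    sites <- mergeReplicatePeaks(pk, circParams())
    expect_identical(length(sites), 0L)   # single-replicate support only
})

test_that("replicate merging follows the -d 50 and two-replicate rules", {
    p <- circParams()
    mk <- function(s, e) GenomicRanges::GRanges("chr1",
        IRanges::IRanges(s, e), strand = "+", pvalue = 1e-5)
    # gap of 20 nt between replicates: merged and kept
    sites <- mergeReplicatePeaks(list(r1 = mk(101L, 130L),
                                      r2 = mk(151L, 180L)), p)
    expect_identical(length(sites), 1L)
    expect_identical(c(start(sites), end(sites)), c(101L, 180L))
    expect_identical(sites$n_replicates, 2L)
    # two peaks from the same replicate only: merged but discarded
    sites2 <- mergeReplicatePeaks(
        list(r1 = c(mk(101L, 130L), mk(151L, 180L)),
             r2 = mk(9000L, 9030L)), p)
    expect_false(any(start(sites2) == 101L))
    # gap of exactly 50 merges, 51 does not
    at50 <- mergeReplicatePeaks(list(r1 = mk(101L, 130L),
                                     r2 = mk(181L, 210L)), p)
    expect_identical(length(at50), 1L)
    at51 <- mergeReplicatePeaks(list(r1 = mk(101L, 130L),
                                     r2 = mk(182L, 210L)), p)
    expect_identical(length(at51), 0L)   # two singleton-replicate sites
    expect_error(mergeReplicatePeaks(list(r1 = mk(1L, 10L)), p),
                 "two replicates")
})

test_that("merging is idempotent", {
    p <- circParams()
    set.seed(20)
    mk <- function(n) GenomicRanges::GRanges("chr1",
        IRanges::IRanges(sort(sample.int(5000, n)), width = 30),
        strand = "+", pvalue = 1e-5)
    sites <- mergeReplicatePeaks(list(r1 = mk(30), r2 = mk(30)), p)
    again <- GenomicRanges::reduce(sites,
                                   min.gapwidth = p@peakMergeDist + 1L)
    expect_identical(length(again), length(sites))
    expect_identical(start(again), start(sites))
    expect_identical(end(again), end(sites))
})

test_that("circle eligibility applies the three published filters", {
    ss <- smallSim()
    tt <- ss$truth@circles
    df <- data.frame(id = tt$circ_id, chrom = tt$chrom, strand = tt$strand,
                     acceptor = tt$acceptor, donor = tt$donor,
                     stringsAsFactors = FALSE)
    p <- circParams()
    elig <- filterCirclesForClip(df, ss$bundle, p)
    # planted circles sit on annotated internal exons with long introns
    expect_true(all(elig$eligible))
    # exclusion list removes the parallel circle
    elig2 <- filterCirclesForClip(df, ss$bundle, p,
                                  exclude = tt$circ_id[1])
    expect_false(elig2$eligible[1])
    expect_identical(elig2$reason[1], "parallel_linear")
    # a junction not on annotated sites is excluded
    df2 <- df; df2$acceptor[2] <- df2$acceptor[2] + 1L
    elig3 <- filterCirclesForClip(df2, ss$bundle, p)
    expect_identical(elig3$reason[2], "not_annotated")
    # short flanking introns are excluded
    p2 <- circParams(minFlankIntron = 100000L)
    elig4 <- filterCirclesForClip(df, ss$bundle, p2)
    expect_true(all(elig4$reason == "short_flanking_intron"))
})

test_that("flanking windows are intronic, clipped, strand-aware and nested", {
    ss <- smallSim()
    tt <- ss$truth@circles
    df <- data.frame(id = tt$circ_id, chrom = tt$chrom, strand = tt$strand,
                     acceptor = tt$acceptor, donor = tt$donor,
                     stringsAsFactors = FALSE)
    elig <- filterCirclesForClip(df, ss$bundle, circParams())
    w500 <- flankingWindows(elig, 500L)
    w1000 <- flankingWindows(elig, 1000L)
    expect_identical(length(w500), 2L * sum(elig$eligible))
    expect_true(all(width(w500) == 500L))
    # windows touch the back-splice sites from the intron side
    for (k in which(elig$eligible)) {
        ci <- df[df$id == elig$id[k], ]
        up <- w500[w500$circ_id == ci$id & w500$side == "up"]
        if (ci$strand == "+")
            expect_identical(end(up), ci$acceptor - 1L)
        else expect_identical(start(up), ci$acceptor + 1L)
    }
    # nesting: every 500-nt window is inside the 1000-nt window
    ov <- GenomicRanges::findOverlaps(w500, w1000, type = "within")
    expect_true(all(seq_along(w500) %in% S4Vectors::queryHits(ov)))
    # clipping: windows wider than the intron are truncated to it
    wBig <- flankingWindows(elig, 10000L)
    expect_true(all(width(wBig) <= 10000L))
    expect_true(any(width(wBig) < 10000L))
})

test_that("bound calls need a one-base same-strand window overlap", {
    win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1500),
                                  strand = "+", circ_id = "c1",
                                  side = "up")
    siteIn <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1600),
                                     strand = "+")
    expect_true(boundCall(win, siteIn)[["c1"]])
    siteOut <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1501, 1600),
                                      strand = "+")
    expect_false(boundCall(win, siteOut)[["c1"]])
    siteMinus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1400, 1450),
                                        strand = "-")
    expect_false(boundCall(win, siteMinus)[["c1"]])
    expect_true(boundCall(win, siteMinus, strandAware = FALSE)[["c1"]])
    # unstranded sites match either strand
    siteStar <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1400, 1450),
                                       strand = "*")
    expect_true(boundCall(win, siteStar)[["c1"]])
})

test_that("planted peaks produce bound calls equal to truth flags", {
    cfg <- simulationConfig(nGenes = 20L, genesPerChrom = 10L, nCirc = 10L,
                            pDereg = 1, pUnaff = 0,
                            backgroundPeaksPerReplicate = 0L,
                            weakPeaksPerReplicate = 0L, seed = 12L)
    b0 <- simulateGenome(cfg)
    pc <- plantCircles(b0, cfg)
    tr <- simulateCounts(pc$truth, cfg)
    cp <- simulateClipPeaks(tr, pc$bundle, cfg)
    tt <- cp$truth@circles
    p <- circParams()
    sites <- mergeReplicatePeaks(readClipPeaks(cp$peaks, p), p)
    df <- data.frame(id = tt$circ_id, chrom = tt$chrom, strand = tt$strand,
                     acceptor = tt$acceptor, donor = tt$donor,
                     stringsAsFactors = FALSE)
    elig <- filterCirclesForClip(df, pc$bundle, p)
    bnd <- boundCall(flankingWindows(elig, 500L), sites)
    expect_identical(unname(bnd[tt$circ_id]), tt$bound)
    # window nesting implies bound at 500 => bound at 1000
    bnd1k <- boundCall(flankingWindows(elig, 1000L), sites)
    expect_true(all(bnd1k[bnd]))
})

test_that("the 2x2 enrichment test matches the hand Pearson formula", {
    deP <- setNames(c(rep(0.01, 134), rep(0.5, 804)),
                    paste0("c", 1:938))
    bound <- setNames(c(rep(TRUE, 47), rep(FALSE, 87),
                        rep(TRUE, 193), rep(FALSE, 611)),
                      paste0("c", 1:938))
    r <- enrichmentTest(deP, bound, 0.05)
    expect_identical(c(r$n_dereg, r$n_unaff), c(134L, 804L))
    expect_identical(c(r$bound_dereg, r$bound_unaff), c(47L, 193L))
    stat <- oraclePearson2x2(47, 87, 193, 611)
    expect_equal(r$statistic, stat, tolerance = 1e-12)
    expect_equal(r$pvalue, oracleChisq1Surv(stat), tolerance = 1e-12)
    # identical fractions: p near 1
    bEq <- setNames(rep(c(TRUE, FALSE), length.out = 938), names(deP))
    rEq <- enrichmentTest(deP, bEq, 0.05)
    expect_gt(rEq$pvalue, 0.5)
    # empty stratum reports NA with a warning
    expect_warning(rNA <- enrichmentTest(deP, bound, 1e-9), "empty stratum")
    expect_true(is.na(rNA$pvalue))
    # Yates variant is more conservative
    rY <- enrichmentTest(deP, bound, 0.05, yates = TRUE)
    expect_gt(rY$pvalue, r$pvalue)
})

test_that("the enrichment grid spans widths and stratification cutoffs", {
    ss <- smallSim()
    tt <- ss$truth@circles
    df <- data.frame(id = tt$circ_id, chrom = tt$chrom, strand = tt$strand,
                     acceptor = tt$acceptor, donor = tt$donor,
                     stringsAsFactors = FALSE)
    p <- circParams()
    elig <- filterCirclesForClip(df, ss$bundle, p)
    sites <- GenomicRanges::GRanges()
    deP <- setNames(runif(nrow(df)), df$id)
    g <- suppressWarnings(enrichmentGrid(elig, sites, deP, p))
    expect_identical(nrow(g), length(p@windowWidths) *
                         length(p@stratCutoffs))
    expect_identical(sort(unique(g$width)), sort(p@windowWidths))
    expect_identical(sum(g$bound_dereg) + sum(g$bound_unaff), 0L)
})
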