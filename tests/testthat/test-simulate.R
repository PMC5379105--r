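test_that("genome generation is byte-identical under one seed", {
    cfg <- simulationConfig(nGenes = 5L, nCirc = 2L, seed = 1L)
    d1 <- tempfile(); d2 <- tempfile()
    for (d in c(d1, d2)) {
        b <- simulateGenome(cfg)
        dir.create(d)
        Biostrings::writeXStringSet(genomeSeqs(b), file.path(d, "g.fa"))
        writeAnnotationGtf(b, file.path(d, "a.gtf"))
    }
    expect_identical(readLines(file.path(d1, "g.fa")),
                     readLines(file.path(d2, "g.fa")))
    expect_identical(readLines(file.path(d1, "a.gtf")),
                     readLines(file.path(d2, "a.gtf")))
})

test_that("intron totals follow the exon-count range", {
    cfg <- simulationConfig(nGenes = 5L, nCirc = 0L,
                            exonCountRange = c(3L, 5L),
                            circExonRange = c(1L, 1L), seed = 2L)
    b <- simulateGenome(cfg)
    gtf <- tempfile(); writeAnnotationGtf(b, gtf)
    lines <- readLines(gtf)
    nExon <- sum(grepl("\texon\t", lines))
    nIntron <- nExon - 5L            # one transcript per gene
    expect_gte(nIntron, 10L)
    expect_lte(nIntron, 20L)
    expect_identical(length(intronRanges(b)), nIntron)
})

test_that("infeasible structural ranges are rejected", {
    expect_error(simulationConfig(intronLenRange = c(2L, 3L)), "GT")
    expect_error(simulationConfig(exonLenRange = c(50L, 80L)), "readLen")
    expect_error(simulationConfig(nCirc = 99L, nGenes = 10L), "nCirc")
    expect_error(simulationConfig(pDereg = 1.2), "probabilities")
    expect_error(simulationConfig(bogusKnob = 1), "unknown")
})

test_that("planted circles sit on annotated splice sites of internal exons", {
    ss <- smallSim()
    circles <- ss$truth@circles
    cat <- spliceSiteCatalog(ss$bundle)
    for (k in seq_len(nrow(circles))) {
        ci <- circles[k, ]
        expect_true(any(cat$acceptors$chrom == ci$chrom &
                        cat$acceptors$pos == ci$acceptor &
                        cat$acceptors$strand == ci$strand))
        expect_true(any(cat$donors$chrom == ci$chrom &
                        cat$donors$pos == ci$donor &
                        cat$donors$strand == ci$strand))
        expect_gte(ci$exon_from, 2L)
    }
})

test_that("zero circles give an empty truth and excess circles error", {
    cfg <- simulationConfig(nGenes = 5L, nCirc = 0L, seed = 3L)
    b <- simulateGenome(cfg)
    pc <- plantCircles(b, cfg)
    expect_identical(nrow(pc$truth@circles), 0L)
    cfg2 <- simulationConfig(nGenes = 5L, nCirc = 5L,
                             exonCountRange = c(3L, 3L),
                             circExonRange = c(2L, 2L), seed = 3L)
    # 3-exon genes cannot host a 2-exon internal run
    b2 <- simulateGenome(cfg2)
    expect_error(plantCircles(b2, cfg2), "eligible")
})

test_that("count simulation applies the fold change to circles only", {
    cfg <- simulationConfig(nGenes = 10L, genesPerChrom = 5L, nCirc = 4L,
                            fracDereg = 1, fracDeregDown = 1,
                            deregLog2FCRange = c(2, 2),
                            circBaseMean = 40, dispersion = 0, seed = 4L,
                            samplesPerCondition = 300L)
    b <- simulateGenome(cfg)
    pc <- plantCircles(b, cfg)
    tr <- simulateCounts(pc$truth, cfg)
    cond2 <- tr@samples$condition == "cond2"
    m1 <- rowMeans(tr@circCounts[, !cond2])
    m2 <- rowMeans(tr@circCounts[, cond2])
    # log2FC = -2 at mean 40: condition-2 circular means near 10
    expect_true(all(abs(m2 - 10) < 2))
    expect_true(all(abs(m1 - 40) < 4))
    l1 <- rowMeans(tr@linCounts[, !cond2]); l2 <- rowMeans(tr@linCounts[, cond2])
    expect_true(all(abs(l1 - l2) < 6))   # linear means equal across conditions
})

test_that("Poisson-limit counts have the configured mean within 1%", {
    cfg <- simulationConfig(nGenes = 5L, nCirc = 1L, dispersion = 0,
                            circBaseMean = 50, fracDereg = 0,
                            samplesPerCondition = 5000L, seed = 5L)
    b <- simulateGenome(cfg)
    tr <- simulateCounts(plantCircles(b, cfg)$truth, cfg)
    expect_lt(abs(mean(tr@circCounts) - 50) / 50, 0.01)
})

test_that("count tables are identical under the same seed", {
    cfg <- simulationConfig(nGenes = 5L, nCirc = 2L, seed = 6L)
    b <- simulateGenome(cfg)
    t1 <- simulateCounts(plantCircles(b, cfg)$truth, cfg)
    t2 <- simulateCounts(plantCircles(b, cfg)$truth, cfg)
    expect_identical(t1@circCounts, t2@circCounts)
    expect_identical(t1@linCounts, t2@linCounts)
})

test_that("emitted back-splice mates are head-to-tail by construction", {
    ss <- smallSim()
    r1 <- ss$er$reads[[1]]$R1
    bs <- r1[grepl("\\|bs\\|", names(r1))]
    circles <- ss$truth@circles
    # per-circle counts match the count matrix exactly
    circOf <- sub("\\|.*", "", names(bs))
    tab <- table(circOf)
    for (k in seq_len(nrow(circles))) {
        expected <- ss$truth@circCounts[k, 1]
        got <- if (circles$circ_id[k] %in% names(tab))
            as.integer(tab[[circles$circ_id[k]]]) else 0L
        expect_identical(got, expected)
    }
    # sequence structure: suffix of the circle segment then its prefix
    ci <- circles[1, ]
    seg <- character()
    ex <- exonRanges(ss$bundle)
    exi <- ex[ex$transcript_id == ci$transcript_id]
    exi <- exi[order(exi$exon_rank)]
    for (e in ci$exon_from:ci$exon_to) {
        s <- Biostrings::subseq(genomeSeqs(ss$bundle)[[ci$chrom]],
                                start(exi)[e], end(exi)[e])
        if (ci$strand == "-") s <- Biostrings::reverseComplement(s)
        seg <- paste0(seg, as.character(s))
    }
    one <- as.character(bs[circOf == ci$circ_id][[1]])
    R <- nchar(one)
    okSomeSplit <- any(vapply(20:(R - 20), function(b)
        identical(one, paste0(substr(seg, nchar(seg) - b + 1, nchar(seg)),
                              substr(seg, 1, R - b))), TRUE))
    expect_true(okSomeSplit)
})

test_that("reads shorter than two anchors are refused", {
    cfg <- simulationConfig(nGenes = 5L, nCirc = 1L, readLen = 100L,
                            seed = 7L)
    b <- simulateGenome(cfg)
    tr <- simulateCounts(plantCircles(b, cfg)$truth, cfg)
    expect_error(emitReads(tr, b, cfg, anchorLen = 60L), "undetectable")
})

test_that("cryptic circles fail the annotated-splice-site filter downstream", {
    cfg <- simulationConfig(nGenes = 20L, genesPerChrom = 10L, nCirc = 10L,
                            fracNonAnnotated = 0.2, seed = 8L)
    b <- simulateGenome(cfg)
    pc <- plantCircles(b, cfg)
    circles <- pc$truth@circles
    expect_identical(sum(!circles$annotated), 2L)
    df <- data.frame(id = circles$circ_id, chrom = circles$chrom,
                     strand = circles$strand, acceptor = circles$acceptor,
                     donor = circles$donor, stringsAsFactors = FALSE)
    elig <- filterCirclesForClip(df, pc$bundle, circParams())
    expect_identical(sum(elig$reason %in% "not_annotated"), 2L)
    expect_identical(elig$id[elig$reason %in% "not_annotated"],
                     circles$circ_id[!circles$annotated])
})

test_that("cryptic junctions still carry GT/AG and are detectable", {
    cfg <- simulationConfig(nGenes = 10L, genesPerChrom = 5L, nCirc = 5L,
                            fracNonAnnotated = 1, seed = 9L)
    b <- simulateGenome(cfg)
    pc <- plantCircles(b, cfg)
    tr <- simulateCounts(pc$truth, cfg)
    er <- emitReads(tr, pc$bundle, cfg)
    p <- circParams()
    det <- detectSample(er$reads[[1]], pc$bundle, p,
                        contaminants = er$contaminants)
    ev <- det$events; ev$sample <- "s"
    agg <- aggregateJunctions(ev, pc$bundle, p)
    keys <- truthKeys(tr)
    expect_true(all(keys %in% agg$circular$junction_id))
})

test_that("clip peak planting matches truth labels at extreme probabilities", {
    cfg <- simulationConfig(nGenes = 20L, genesPerChrom = 10L, nCirc = 10L,
                            pDereg = 1, pUnaff = 0,
                            backgroundPeaksPerReplicate = 0L,
                            weakPeaksPerReplicate = 0L, seed = 10L)
    b <- simulateGenome(cfg)
    pc <- plantCircles(b, cfg)
    tr <- simulateCounts(pc$truth, cfg)
    cp <- simulateClipPeaks(tr, pc$bundle, cfg)
    circles <- cp$truth@circles
    expect_identical(circles$bound, circles$log2fc != 0)
    # every planted peak has a p-value below the retention cutoff
    for (r in names(cp$peaks))
        expect_true(all(cp$peaks[[r]]$pvalue < 1e-4))
})

test_that("replicate jitter within merge distance recovers one site per peak", {
    cfg <- simulationConfig(nGenes = 20L, genesPerChrom = 10L, nCirc = 10L,
                            pDereg = 1, pUnaff = 1, peakJitter = 10L,
                            backgroundPeaksPerReplicate = 0L,
                            weakPeaksPerReplicate = 0L, seed = 11L)
    b <- simulateGenome(cfg)
    pc <- plantCircles(b, cfg)
    tr <- simulateCounts(pc$truth, cfg)
    cp <- simulateClipPeaks(tr, pc$bundle, cfg)
    peaks <- readClipPeaks(cp$peaks, circParams())
    sites <- mergeReplicatePeaks(peaks, circParams())
    expect_identical(length(sites), sum(cp$truth@circles$bound))
    expect_true(all(sites$n_replicates == cfg$nClipReplicates))
})
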