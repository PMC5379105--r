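test_that("anchors are the terminal 20 nt and short reads are skipped", {
    reads <- Biostrings::DNAStringSet(c(
        r100 = paste(rep("ACGT", 25), collapse = ""),
        r40 = paste(rep("AC", 20), collapse = ""),
        r39 = paste(rep("A", 39), collapse = "")))
    expect_message(an <- makeAnchors(reads), "skipped")
    expect_identical(an$kept, c(1L, 2L))
    expect_identical(as.character(an$anchor5[[1]]),
                     substr(as.character(reads[[1]]), 1, 20))
    expect_identical(as.character(an$anchor3[[1]]),
                     substr(as.character(reads[[1]]), 81, 100))
    # a 40-nt read is exactly partitioned by its two anchors
    expect_identical(paste0(as.character(an$anchor5[[2]]),
                            as.character(an$anchor3[[2]])),
                     as.character(reads[[2]]))
})

test_that("anchor alignment reports all placements on both strands", {
    set.seed(42)
    core <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
    filler <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                                collapse = "")
    # core planted twice on chrA, once (reverse complement) on chrB
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">chrA", paste0(filler(30), core, filler(25), core,
                                 filler(30)),
                 ">chrB", paste0(filler(40),
                                 as.character(Biostrings::reverseComplement(
                                     Biostrings::DNAString(core))),
                                 filler(40))), fa)
    b <- readGenomeFasta(fa)
    aln <- alignAnchors(b, Biostrings::DNAStringSet(core))
    h <- aln$hits[[core]]
    expect_identical(aln$mult, 3L)
    expect_identical(sum(h$strand == "+"), 2L)
    expect_identical(h$start[h$strand == "+"], c(31L, 76L))
    expect_identical(h$chrom[h$strand == "-"], "chrB")
    expect_identical(h$start[h$strand == "-"], 41L)
})

test_that("contaminant pairs are removed and accounting is conserved", {
    ss <- smallSim()
    rep <- smallEvents()$report
    expect_identical(rep[["contaminant_pairs"]], 20L)
    expect_identical(rep[["input_pairs"]],
                     rep[["contaminant_pairs"]] +
                         rep[["pairs_after_contaminant"]])
    expect_identical(rep[["mates_in"]],
                     rep[["linear_mapper_mates"]] +
                         rep[["candidate_mates"]])
    # empty contaminant set is the identity
    pairs <- ss$er$reads[[1]]
    fc <- filterContaminants(pairs, Biostrings::DNAStringSet())
    expect_identical(length(fc$pairs$R1), length(pairs$R1))
    expect_identical(fc$removed, 0L)
    # a read that is an exact contaminant substring is dropped
    contam <- ss$er$contaminants
    sub <- Biostrings::DNAStringSet(
        as.character(Biostrings::subseq(contam[[1]], 51, 150)))
    names(sub) <- "planted"
    fc2 <- filterContaminants(list(R1 = sub, R2 = sub), contam)
    expect_identical(fc2$removed, 1L)
})

test_that("linear-mapper prefilter keeps only junction-spanning mates", {
    ss <- smallSim()
    b <- ss$bundle
    ex <- exonRanges(b)[1]
    exonic <- Biostrings::DNAStringSet(as.character(Biostrings::subseq(
        genomeSeqs(b)[[as.character(seqnames(ex))]],
        start(ex), start(ex) + 99L)))
    names(exonic) <- "exonic"
    fl <- filterLinearMappers(exonic, b)
    expect_identical(fl$removed, 1L)
    bsReads <- ss$er$reads[[1]]$R1[grepl("\\|bs\\|",
                                         names(ss$er$reads[[1]]$R1))]
    fl2 <- filterLinearMappers(bsReads, b)
    expect_identical(fl2$removed, 0L)   # back-splice mates cannot map
    # planted junction mates survive in full
    keepPair <- !grepl("contam", names(ss$er$reads[[1]]$R1))
    mates <- c(ss$er$reads[[1]]$R1[keepPair], ss$er$reads[[1]]$R2[keepPair])
    fl3 <- filterLinearMappers(mates, b)
    # survivors are exactly the junction-spanning first mates
    expect_identical(length(fl3$mates), sum(keepPair))
})

test_that("breakpoint extension recovers planted coordinates exactly", {
    ss <- smallSim()
    ev <- smallEvents()$events
    keys <- truthKeys(ss$truth)
    circEv <- ev[ev$kind == "circular", ]
    evKeys <- unique(paste(circEv$chrom, circEv$strand, circEv$acceptor,
                           circEv$donor, sep = ":"))
    expect_true(all(evKeys %in% keys))
    expect_true(all(circEv$mismatches == 0L))
    # linear events land on annotated donor/acceptor pairs
    cat <- spliceSiteCatalog(ss$bundle)
    linEv <- unique(ev[ev$kind == "linear",
                       c("chrom", "strand", "acceptor", "donor")])
    for (i in seq_len(nrow(linEv))) {
        expect_true(any(cat$donors$chrom == linEv$chrom[i] &
                        cat$donors$pos == linEv$donor[i] &
                        cat$donors$strand == linEv$strand[i]))
        expect_true(any(cat$acceptors$chrom == linEv$chrom[i] &
                        cat$acceptors$pos == linEv$acceptor[i] &
                        cat$acceptors$strand == linEv$strand[i]))
    }
})

test_that("breakpoints without the acceptor signal are rejected", {
    # two "exons" joined head-to-tail, but no AG before the acceptor
    set.seed(7)
    base <- function(n) paste(sample(c("A", "C", "T"), n, replace = TRUE),
                              collapse = "")
    e1 <- base(60); e2 <- base(60)
    chromOK <- paste0(base(20), "AG", e1, "GT", base(40), "AG", e2, "GT",
                      base(20))
    chromBad <- sub("AG", "CC", chromOK)  # first AG (before e1) destroyed
    read <- paste0(substr(e2, 21, 60), substr(e1, 1, 60))  # 100 nt, b = 40
    p <- circParams()
    mkBundle <- function(seqChar) {
        fa <- tempfile(fileext = ".fa")
        writeLines(c(">c", seqChar), fa)
        readGenomeFasta(fa)
    }
    bOK <- mkBundle(chromOK)
    leftStart <- as.integer(regexpr(substr(read, 1, 20), chromOK))
    rightStart <- as.integer(regexpr(substr(read, 81, 100), chromOK))
    ev <- extendBreakpoint(read, leftStart, rightStart,
                           genomeSeqs(bOK)[["c"]], "c", "+", p)
    expect_identical(ev$kind, "circular")
    bBad <- mkBundle(chromBad)
    leftStart <- as.integer(regexpr(substr(read, 1, 20), chromBad))
    rightStart <- as.integer(regexpr(substr(read, 81, 100), chromBad))
    expect_null(extendBreakpoint(read, leftStart, rightStart,
                                 genomeSeqs(bBad)[["c"]], "c", "+", p))
})

test_that("swapping the junction order flips circular and linear", {
    # genome: AG e1 GT ... AG e2 GT  — both orders are signal-consistent
    set.seed(8)
    base <- function(n) paste(sample(c("A", "C", "T"), n, replace = TRUE),
                              collapse = "")
    e1 <- base(60); e2 <- base(60)
    chrom <- paste0(base(20), "AG", e1, "GT", base(40), "AG", e2, "GT",
                    base(20))
    fa <- tempfile(fileext = ".fa"); writeLines(c(">c", chrom), fa)
    b <- readGenomeFasta(fa)
    p <- circParams()
    linRead <- paste0(substr(e1, 21, 60), substr(e2, 1, 60))
    circRead <- paste0(substr(e2, 21, 60), substr(e1, 1, 60))
    ev <- function(r) {
        ls <- as.integer(regexpr(substr(r, 1, 20), chrom))
        rs <- as.integer(regexpr(substr(r, 81, 100), chrom))
        extendBreakpoint(r, ls, rs, genomeSeqs(b)[["c"]], "c", "+", p)
    }
    evLin <- ev(linRead); evCirc <- ev(circRead)
    expect_identical(evLin$kind, "linear")
    expect_identical(evCirc$kind, "circular")
    # layout check: linear joins end(e1)->start(e2); circular joins
    # end(e2) back to start(e1) (head-to-tail, acceptor upstream of donor)
    expect_identical(c(evLin$donor, evLin$acceptor), c(82L, 127L))
    expect_identical(c(evCirc$donor, evCirc$acceptor), c(186L, 23L))
    expect_lt(evCirc$acceptor, evCirc$donor)
    expect_gt(evLin$acceptor, evLin$donor)
})

test_that("published per-sample junction filters behave on fixtures", {
    ss <- smallSim()
    p <- circParams()
    base <- data.frame(read = "r", seq = "X", chrom = "chr1", strand = "+",
                       acceptor = 100L, donor = 5000L, kind = "circular",
                       mismatches = 0L, qual = TRUE, sample = "s1",
                       stringsAsFactors = FALSE)
    mk <- function(...) {
        rows <- list(...)
        do.call(rbind, lapply(seq_along(rows), function(i) {
            r <- base
            for (nm in names(rows[[i]])) r[[nm]] <- rows[[i]][[nm]]
            r$read <- paste0("r", i)
            r
        }))
    }
    # one unique read only -> removed
    ev <- mk(list(seq = "AAA"), list(seq = "AAA"))
    agg <- aggregateJunctions(ev, ss$bundle, p)
    expect_false(agg$circular$kept)
    expect_identical(attr(agg$circular, "uniq")[1, "s1"], 1L)
    # two unique reads -> kept
    ev <- mk(list(seq = "AAA"), list(seq = "AAC"))
    expect_true(aggregateJunctions(ev, ss$bundle, p)$circular$kept)
    # span 150,000 -> removed (two unique reads otherwise fine)
    ev <- mk(list(seq = "AAA", donor = 150100L),
             list(seq = "AAC", donor = 150100L))
    agg <- aggregateJunctions(ev, ss$bundle, p)
    expect_false(agg$circular$kept)
    expect_identical(agg$circular$span, 150000L)
    # non-unique anchors -> removed
    ev <- mk(list(seq = "AAA", qual = FALSE), list(seq = "AAC", qual = FALSE))
    expect_false(aggregateJunctions(ev, ss$bundle, p)$circular$kept)
})

test_that("junctions spanning two non-overlapping genes are excluded", {
    fa <- toyAnnotation()$fa
    gtf <- tempfile(fileext = ".gtf")
    mk <- function(g, t, s, e) c(
        paste("chrT", "toy", "gene", s, e, ".", "+", ".",
              sprintf('gene_id "%s";', g), sep = "\t"),
        paste("chrT", "toy", "exon", s, e, ".", "+", ".",
              sprintf('gene_id "%s"; transcript_id "%s";', g, t), sep = "\t"))
    # g1 and g2 disjoint; g2 and g3 overlap
    writeLines(c(mk("g1", "t1", 101, 300), mk("g2", "t2", 500, 800),
                 mk("g3", "t3", 700, 1000)), gtf)
    b <- readAnnotationGtf(gtf, readGenomeFasta(fa))
    p <- circParams()
    ev <- data.frame(read = c("r1", "r2", "r1b", "r2b"),
                     seq = c("A", "B", "C", "D"),
                     chrom = "chrT", strand = "+",
                     acceptor = c(150L, 550L, 150L, 550L),
                     donor = c(550L, 950L, 550L, 950L),
                     kind = "circular", mismatches = 0L, qual = TRUE,
                     sample = "s1", stringsAsFactors = FALSE)
    agg <- aggregateJunctions(ev, b, p)
    tab <- agg$circular
    spansDisjoint <- tab$acceptor == 150L
    expect_true(all(tab$multi_locus[spansDisjoint]))
    expect_false(any(tab$kept[spansDisjoint]))
    expect_true(all(tab$kept[!spansDisjoint]))   # overlapping genes: kept
})

test_that("a duplicated segment voids the anchor-quality flag", {
    ss <- smallSim()
    b <- ss$bundle
    ci <- ss$truth@circles[1, ]
    reads <- ss$er$reads[[1]]$R1
    circReads <- reads[grepl(paste0(ci$circ_id, "\\|"), names(reads)) &
                       grepl("\\|bs\\|", names(reads))]
    # duplicate the genomic neighbourhood of the circle's junction into a
    # new chromosome so every anchor of its reads has two placements
    lo <- min(ci$acceptor, ci$donor); hi <- max(ci$acceptor, ci$donor)
    dupRegion <- Biostrings::subseq(genomeSeqs(b)[[ci$chrom]],
                                    max(1L, lo - 200L), hi + 200L)
    fa <- tempfile(fileext = ".fa")
    dupSet <- Biostrings::DNAStringSet(dupRegion)
    names(dupSet) <- "dup"
    Biostrings::writeXStringSet(c(genomeSeqs(b), dupSet), fa)
    gtf <- tempfile(fileext = ".gtf"); writeAnnotationGtf(b, gtf)
    b2 <- readAnnotationGtf(gtf, readGenomeFasta(fa))
    p <- circParams()
    ev <- callJunctions(circReads, b2, p)
    expect_true(nrow(ev) > 0)
    expect_true(all(!ev$qual))
    ev$sample <- "s1"
    agg <- aggregateJunctions(ev, b2, p)
    expect_false(any(agg$circular$kept))
    # same reads on the original genome pass
    ev0 <- callJunctions(circReads, b, p)
    expect_true(all(ev0$qual))
})

test_that("identical read copies collapse to one unique read", {
    ss <- smallSim()
    reads <- ss$er$reads[[1]]$R1
    bs <- reads[grepl("\\|bs\\|", names(reads))][1]
    copies <- rep(bs, 5)
    names(copies) <- paste0("copy", 1:5)
    p <- circParams()
    ev <- callJunctions(copies, ss$bundle, p)
    ev$sample <- "s1"
    agg <- aggregateJunctions(ev, ss$bundle, p)
    expect_identical(unname(attr(agg$circular, "counts")[1, "s1"]), 5L)
    expect_identical(unname(attr(agg$circular, "uniq")[1, "s1"]), 1L)
    expect_false(agg$circular$kept)   # below the unique-read threshold
})

test_that("linear reads across both back-splice coordinates are summed", {
    circTab <- data.frame(junction_id = "j", chrom = "c", strand = "+",
                          acceptor = 1000L, donor = 5000L,
                          stringsAsFactors = FALSE)
    attr(circTab, "counts") <- matrix(0L, 1, 1,
                                      dimnames = list("j", "s1"))
    linTab <- data.frame(chrom = "c", strand = "+",
                         acceptor = c(1000L, 9000L, 8000L),
                         donor = c(500L, 5000L, 7000L),
                         stringsAsFactors = FALSE)
    attr(linTab, "counts") <- matrix(c(3L, 4L, 9L), 3, 1,
                                     dimnames = list(NULL, "s1"))
    out <- countLinearAtBacksplice(circTab, linTab)
    expect_identical(unname(out[1, 1]), 7L)   # 3 across acceptor + 4 donor
    # no linear evidence -> zero
    attr(linTab, "counts") <- matrix(0L, 3, 1,
                                     dimnames = list(NULL, "s1"))
    expect_identical(unname(countLinearAtBacksplice(circTab, linTab)[1, 1]),
                     0L)
})

test_that("breakpoint extension agrees with the brute-force enumerator", {
    ss <- smallSim()
    p <- circParams()
    b <- ss$bundle
    chromChar <- lapply(as.character(genomeSeqs(b)), identity)
    reads <- c(ss$er$reads[[1]]$R1, ss$er$reads[[2]]$R1)
    reads <- reads[!grepl("contam", names(reads))]
    reads <- reads[seq_len(min(100, length(reads)))]
    checked <- 0L
    for (i in seq_along(reads)) {
        r <- as.character(reads[[i]])
        for (orient in c("+", "-")) {
            os <- if (orient == "+") r else oracleRevComp(r)
            for (chrom in names(chromChar)) {
                ls <- as.integer(regexpr(substr(os, 1, 20),
                                         chromChar[[chrom]], fixed = TRUE))
                rs <- as.integer(regexpr(substr(os, 81, 100),
                                         chromChar[[chrom]], fixed = TRUE))
                if (ls < 0 || rs < 0) next
                fast <- extendBreakpoint(os, ls, rs,
                                         genomeSeqs(b)[[chrom]], chrom,
                                         orient, p)
                slow <- oracleBreakpoint(os, ls, rs, chromChar[[chrom]],
                                         orient, 20L, p@maxMismatch)
                if (is.null(slow)) expect_null(fast)
                else {
                    expect_identical(fast$acceptor, slow$acceptor)
                    expect_identical(fast$donor, slow$donor)
                    expect_identical(fast$kind, slow$kind)
                    expect_identical(fast$mismatches, slow$mismatches)
                }
                checked <- checked + 1L
            }
        }
    }
    expect_gte(checked, 100L)
})
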