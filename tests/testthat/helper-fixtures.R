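# Shared fixtures, built in code.  Expensive simulations are cached per
# session so several test files can reuse them.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, force(expr), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# small simulated experiment used across caller/DE tests
smallSim <- function() cachedFixture("smallSim", {
    cfg <- simulationConfig(nGenes = 12L, genesPerChrom = 6L, nCirc = 6L,
                            seed = 101L)
    bundle <- simulateGenome(cfg)
    pc <- plantCircles(bundle, cfg)
    truth <- simulateCounts(pc$truth, cfg)
    er <- emitReads(truth, pc$bundle, cfg)
    list(cfg = cfg, bundle = pc$bundle, truth = truth, er = er)
})

# detection events for sample 1 of smallSim
smallEvents <- function() cachedFixture("smallEvents", {
    ss <- smallSim()
    p <- circParams()
    det <- detectSample(ss$er$reads[[1]], ss$bundle, p,
                        contaminants = ss$er$contaminants)
    ev <- det$events
    ev$sample <- ss$truth@samples$sample[1]
    list(events = ev, report = det$report, params = p)
})

truthKeys <- function(truth)
    paste(truth@circles$chrom, truth@circles$strand,
          truth@circles$acceptor, truth@circles$donor, sep = ":")

# a hand-built two-gene annotation on a synthetic chromosome, written as
# FASTA + GTF and loaded through the package readers.
# Layout (1-based), all plus strand unless noted:
#   geneA (+): exons [101,200], [301,400], [501,600]; introns GT..AG;
#              CDS [151,550] (so exon1+half of exon2's start region is UTR)
#   geneB (-): exons [801,900], [1101,1200]; intron GT..AG on minus strand
toyAnnotation <- function() cachedFixture("toyAnnotation", {
    set.seed(77)
    base <- sample(c("A", "C", "T"), 1500, replace = TRUE)  # no G background
    seq <- base
    put <- function(seq, at, s) {
        seq[at:(at + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
        seq
    }
    randEx <- function(n) paste(sample(c("A", "C", "T"), n, replace = TRUE),
                                collapse = "")
    seq <- put(seq, 101, randEx(100))
    seq <- put(seq, 301, randEx(100))
    seq <- put(seq, 501, randEx(100))
    # plus-strand introns: GT..AG
    seq <- put(seq, 201, "GT"); seq <- put(seq, 299, "AG")
    seq <- put(seq, 401, "GT"); seq <- put(seq, 499, "AG")
    # minus-strand gene: forward shows CT..AC
    seq <- put(seq, 801, randEx(100))
    seq <- put(seq, 1101, randEx(100))
    seq <- put(seq, 901, "CT"); seq <- put(seq, 1099, "AC")
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">chrT", paste(seq, collapse = "")), fa)
    gtf <- tempfile(fileext = ".gtf")
    at <- function(k, v) sprintf('%s "%s";', k, v)
    lines <- c(
        paste("chrT", "toy", "gene", 101, 600, ".", "+", ".",
              paste(at("gene_id", "geneA"),
                    at("gene_biotype", "protein_coding")), sep = "\t"),
        paste("chrT", "toy", "transcript", 101, 600, ".", "+", ".",
              paste(at("gene_id", "geneA"), at("transcript_id", "txA")),
              sep = "\t"),
        paste("chrT", "toy", "exon", 101, 200, ".", "+", ".",
              paste(at("gene_id", "geneA"), at("transcript_id", "txA")),
              sep = "\t"),
        paste("chrT", "toy", "exon", 301, 400, ".", "+", ".",
              paste(at("gene_id", "geneA"), at("transcript_id", "txA")),
              sep = "\t"),
        paste("chrT", "toy", "exon", 501, 600, ".", "+", ".",
              paste(at("gene_id", "geneA"), at("transcript_id", "txA")),
              sep = "\t"),
        paste("chrT", "toy", "CDS", 151, 550, ".", "+", "0",
              paste(at("gene_id", "geneA"), at("transcript_id", "txA")),
              sep = "\t"),
        paste("chrT", "toy", "gene", 801, 1200, ".", "-", ".",
              paste(at("gene_id", "geneB"), at("gene_biotype", "lincRNA")),
              sep = "\t"),
        paste("chrT", "toy", "transcript", 801, 1200, ".", "-", ".",
              paste(at("gene_id", "geneB"), at("transcript_id", "txB")),
              sep = "\t"),
        paste("chrT", "toy", "exon", 801, 900, ".", "-", ".",
              paste(at("gene_id", "geneB"), at("transcript_id", "txB")),
              sep = "\t"),
        paste("chrT", "toy", "exon", 1101, 1200, ".", "-", ".",
              paste(at("gene_id", "geneB"), at("transcript_id", "txB")),
              sep = "\t"))
    writeLines(lines, gtf)
    bundle <- readAnnotationGtf(gtf, readGenomeFasta(fa))
    list(bundle = bundle, fa = fa, gtf = gtf)
})
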