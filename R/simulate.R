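#' Simulation configuration
#'
#' Returns the default configuration of the synthetic-data generator, with
#' any argument overridden.  The defaults emulate the study design the
#' pipeline targets: two conditions with three biological replicates each,
#' 100-nt paired-end stranded reads, negative-binomial junction counts with a
#' condition-specific log2 fold change applied to back-splice counts only
#' (host linear transcripts unchanged), a deregulated fraction that is mostly
#' downregulated, and CLIP peaks planted preferentially in the introns
#' flanking deregulated circles (35\% vs 24\%).
#'
#' @param ... named overrides of the defaults listed below.
#' @return a validated configuration list of class \code{circSimConfig}.
#' @details Fields:
#' \describe{
#'   \item{nGenes, genesPerChrom}{number of simulated genes and packing per
#'     chromosome.}
#'   \item{exonCountRange, exonLenRange, intronLenRange, intergenicRange}{
#'     structural ranges in nt; every intron begins GT and ends AG on the
#'     coding strand; exon terminal bases avoid G so each planted junction
#'     has a unique zero-mismatch GT/AG-consistent breakpoint.}
#'   \item{fracCoding}{fraction of genes that are protein-coding, with the
#'     CDS starting inside exon 2 and ending inside the penultimate exon so
#'     circles over early exon runs span the 5' UTR.}
#'   \item{nCirc, circExonRange, fracNonAnnotated}{planted circles: number,
#'     exons per circle, and the fraction placed on exon-internal
#'     (non-annotated) GT/AG pairs to exercise the annotated-splice-site
#'     filter.}
#'   \item{readLen, samplesPerCondition, conditions}{read geometry and
#'     design.}
#'   \item{dispersion, circBaseMean, linearBaseMean}{NB dispersion phi and
#'     baseline junction-read means.}
#'   \item{fracDereg, fracDeregDown, deregLog2FCRange}{fraction of circles
#'     with nonzero true log2FC, fraction of those downregulated, and the
#'     magnitude range.}
#'   \item{errorRate}{uniform substitution rate in reads (default 0).}
#'   \item{nContamPairs, nContamSeqs, contamLen}{read pairs per sample drawn
#'     from abundant-ncRNA-like contaminant sequences.}
#'   \item{pDereg, pUnaff}{probability that a deregulated / unaffected circle
#'     carries a planted CLIP peak in a flanking intron.}
#'   \item{peakWidth, peakJitter, nClipReplicates, backgroundPeaksPerReplicate,
#'     weakPeaksPerReplicate, clipWindowMax}{CLIP peak geometry: planted
#'     peaks lie within 1-\code{clipWindowMax} nt of a back-splice site, are
#'     replicated with jittered ends, and are accompanied by random
#'     background peaks and by peaks failing the p-value cutoff.}
#'   \item{seed}{master seed; every stage derives its own deterministic
#'     stream from it.}
#' }
#' @export
simulationConfig <- function(...) {
    cfg <- list(
        nGenes = 50L, genesPerChrom = 10L,
        exonCountRange = c(4L, 8L), exonLenRange = c(100L, 250L),
        intronLenRange = c(1600L, 2600L), intergenicRange = c(500L, 1500L),
        fracCoding = 0.9,
        nCirc = 20L, circExonRange = c(2L, 3L), fracNonAnnotated = 0,
        readLen = 100L,
        samplesPerCondition = 3L, conditions = c("cond1", "cond2"),
        dispersion = 0.1, circBaseMean = 30, linearBaseMean = 60,
        fracDereg = 0.4, fracDeregDown = 0.8, deregLog2FCRange = c(1, 2.5),
        errorRate = 0,
        nContamPairs = 20L, nContamSeqs = 2L, contamLen = 1500L,
        pDereg = 0.35, pUnaff = 0.24,
        peakWidth = 30L, peakJitter = 10L, nClipReplicates = 3L,
        backgroundPeaksPerReplicate = 5L, weakPeaksPerReplicate = 5L,
        clipWindowMax = 500L,
        seed = 1L)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown simulation config keys: ",
             paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    .validateSimConfig(cfg)
    class(cfg) <- "circSimConfig"
    cfg
}

.validateSimConfig <- function(cfg) {
    bad <- character()
    prob <- c(fracCoding = cfg$fracCoding, fracNonAnnotated =
                  cfg$fracNonAnnotated, fracDereg = cfg$fracDereg,
              fracDeregDown = cfg$fracDeregDown, errorRate = cfg$errorRate,
              pDereg = cfg$pDereg, pUnaff = cfg$pUnaff)
    if (any(prob < 0 | prob > 1))
        bad <- c(bad, paste("probabilities outside [0,1]:",
                            paste(names(prob)[prob < 0 | prob > 1],
                                  collapse = ", ")))
    if (cfg$intronLenRange[1L] < 4L)
        bad <- c(bad, "intronLenRange minimum must be >= 4 (room for GT..AG)")
    if (cfg$nCirc > cfg$nGenes)
        bad <- c(bad, "nCirc exceeds nGenes")
    if (cfg$exonCountRange[1L] < 3L)
        bad <- c(bad, "genes need at least 3 exons")
    if (cfg$exonLenRange[1L] < cfg$readLen)
        bad <- c(bad, "exonLenRange minimum must be >= readLen")
    if (cfg$circBaseMean < 0 || cfg$linearBaseMean < 0)
        bad <- c(bad, "negative baseline means")
    if (length(bad))
        stop("invalid simulation config:\n  ", paste(bad, collapse = "\n  "))
    invisible(TRUE)
}

## sample one element of a vector (safe for length-1 vectors)
.sampleOne <- function(v) v[sample.int(length(v), 1L)]

## per-stage RNG streams derived from the master seed (kept below 2^31)
.stageSeed <- function(cfg, stage)
    (as.integer(cfg$seed) %% 100000000L) * 13L + stage

.randDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

## exon sequence whose terminal bases avoid the intron-boundary base G,
## keeping the zero-mismatch GT/AG breakpoint of planted junctions unique
.randExon <- function(n) {
    s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    s[c(1L, n)] <- sample(c("A", "C", "T"), 2L, replace = TRUE)
    paste(s, collapse = "")
}

.randIntron <- function(n)
    paste0("GT", .randDNA(n - 4L), "AG")

#' Simulate a genome with spliced gene models
#'
#' Generates random multi-exon genes on both strands, every intron beginning
#' GT and ending AG on the coding strand, a configurable fraction
#' protein-coding with the CDS placed so that circles over early exon runs
#' span the 5' UTR boundary.  Byte-identical output under the same seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return an annotated \linkS4class{GenomeBundle}.
#' @export
simulateGenome <- function(config) {
    set.seed(.stageSeed(config, 1L))
    nG <- config$nGenes
    geneTbl <- vector("list", nG)
    chromSeqs <- list()
    curChrom <- 0L
    chromParts <- character()
    chromPos <- 0L
    exonRows <- list(); cdsRows <- list(); geneRows <- list()
    newChrom <- function() {
        curChrom <<- curChrom + 1L
        chromParts <<- character()
        chromPos <<- 0L
    }
    flushChrom <- function() {
        if (length(chromParts))
            chromSeqs[[paste0("chr", curChrom)]] <<-
                paste(chromParts, collapse = "")
    }
    newChrom()
    for (g in seq_len(nG)) {
        if ((g - 1L) %% config$genesPerChrom == 0L && g > 1L) {
            flushChrom(); newChrom()
        }
        gid <- sprintf("gene_%03d", g)
        tid <- sprintf("tx_%03d", g)
        strand <- .sampleOne(c("+", "-"))
        coding <- runif(1L) < config$fracCoding
        nEx <- .sampleOne(seq(config$exonCountRange[1L],
                              config$exonCountRange[2L]))
        exLen <- sample(seq(config$exonLenRange[1L],
                            config$exonLenRange[2L]), nEx, replace = TRUE)
        inLen <- sample(seq(config$intronLenRange[1L],
                            config$intronLenRange[2L]), nEx - 1L,
                        replace = TRUE)
        exSeq <- vapply(exLen, .randExon, "")
        inSeq <- vapply(inLen, .randIntron, "")
        parts <- character(2L * nEx - 1L)
        parts[seq(1L, 2L * nEx - 1L, by = 2L)] <- exSeq
        if (nEx > 1L) parts[seq(2L, 2L * nEx - 2L, by = 2L)] <- inSeq
        txSeq <- paste(parts, collapse = "")   # transcript orientation
        geneLen <- nchar(txSeq)
        # transcript-oriented exon offsets within the gene
        segLen <- c(rbind(exLen, c(inLen, 0L)))[seq_len(2L * nEx - 1L)]
        offEnd <- cumsum(segLen)
        exOffStart <- c(1L, offEnd[seq(2L, length(offEnd), by = 2L)] + 1L)[
            seq_len(nEx)]
        exOffEnd <- offEnd[seq(1L, 2L * nEx - 1L, by = 2L)]

        gap <- .sampleOne(seq(config$intergenicRange[1L],
                              config$intergenicRange[2L]))
        chromParts[length(chromParts) + 1L] <- .randDNA(gap)
        geneStart <- chromPos + gap + 1L
        fwd <- if (strand == "+") txSeq else
            as.character(reverseComplement(Biostrings::DNAString(txSeq)))
        chromParts[length(chromParts) + 1L] <- fwd
        chromPos <- chromPos + gap + geneLen
        geneEnd <- geneStart + geneLen - 1L
        chrom <- paste0("chr", curChrom)

        # genomic exon coordinates
        if (strand == "+") {
            gs <- geneStart + exOffStart - 1L
            ge <- geneStart + exOffEnd - 1L
        } else {
            gs <- geneEnd - exOffEnd + 1L
            ge <- geneEnd - exOffStart + 1L
        }
        exonRows[[g]] <- data.frame(chrom = chrom, start = gs, end = ge,
                                    strand = strand, transcript_id = tid,
                                    gene_id = gid, stringsAsFactors = FALSE)
        if (coding && nEx >= 3L) {
            cdsStartT <- exOffStart[2L] + exLen[2L] %/% 2L
            cdsEndT <- exOffStart[nEx - 1L] + exLen[nEx - 1L] %/% 2L
            if (cdsEndT > cdsStartT) {
                gc1 <- if (strand == "+") geneStart + cdsStartT - 1L else
                    geneEnd - cdsEndT + 1L
                gc2 <- if (strand == "+") geneStart + cdsEndT - 1L else
                    geneEnd - cdsStartT + 1L
                cdsRows[[g]] <- data.frame(chrom = chrom, start = gc1,
                                           end = gc2, strand = strand,
                                           transcript_id = tid,
                                           stringsAsFactors = FALSE)
            }
        }
        geneRows[[g]] <- data.frame(chrom = chrom, start = geneStart,
                                    end = geneEnd, strand = strand,
                                    gene_id = gid, gene_name = gid,
                                    gene_biotype = if (coding)
                                        "protein_coding" else "lincRNA",
                                    stringsAsFactors = FALSE)
        geneTbl[[g]] <- list(tid = tid, strand = strand,
                             geneStart = geneStart, geneEnd = geneEnd,
                             nEx = nEx)
    }
    chromParts[length(chromParts) + 1L] <-
        .randDNA(.sampleOne(seq(config$intergenicRange[1L],
                                config$intergenicRange[2L])))
    flushChrom()

    seqs <- DNAStringSet(unlist(chromSeqs))
    exdf <- do.call(rbind, exonRows)
    exons <- GRanges(exdf$chrom, IRanges(exdf$start, exdf$end),
                     strand = exdf$strand, transcript_id = exdf$transcript_id,
                     gene_id = exdf$gene_id)
    cdsParts <- GRanges()
    keep <- !vapply(cdsRows, is.null, TRUE)
    if (any(keep)) {
        cdf <- do.call(rbind, cdsRows[keep])
        cdsParts <- GRanges(cdf$chrom, IRanges(cdf$start, cdf$end),
                            strand = cdf$strand,
                            transcript_id = cdf$transcript_id)
    }
    gdf <- do.call(rbind, geneRows)
    geneMeta <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                        strand = gdf$strand, gene_id = gdf$gene_id,
                        gene_name = gdf$gene_name,
                        gene_biotype = gdf$gene_biotype)
    bundle <- new("GenomeBundle", seqs = seqs,
                  genes = GRanges(), transcripts = GRanges(),
                  exons = GRanges(), cds = GRanges(), introns = GRanges(),
                  utr5 = GRanges(), utr3 = GRanges())
    .attachModels(bundle, exons, cdsParts, geneMeta)
}

## exons of one transcript in transcription order
.txExons <- function(bundle, tid) {
    ex <- bundle@exons[bundle@exons$transcript_id == tid]
    ex[order(ex$exon_rank)]
}

## spliced sequence of exon run i..j (transcription order), as character
.exonRunSeq <- function(bundle, tid, i, j) {
    ex <- .txExons(bundle, tid)
    chrom <- as.character(seqnames(ex))[1L]
    minus <- as.character(strand(ex))[1L] == "-"
    seqs <- vapply(i:j, function(k) {
        s <- subseq(bundle@seqs[[chrom]], start(ex)[k], end(ex)[k])
        if (minus) s <- reverseComplement(s)
        as.character(s)
    }, "")
    paste(seqs, collapse = "")
}

#' Plant circRNAs on a simulated genome
#'
#' Each circle is a run of consecutive internal exons of one transcript: the
#' back-splice acceptor is the first base of the 5'-most exon of the run and
#' the donor the last base of the 3'-most exon (transcription order), both
#' annotated splice sites.  A configurable fraction of circles is instead
#' placed on exon-internal GT/AG pairs that are not annotated splice sites
#' (the genome sequence is edited to carry the signal), to exercise the
#' annotated-splice-site filter downstream.  True log2 fold changes
#' (condition 2 vs 1) are assigned here: a \code{fracDereg} fraction is
#' deregulated, of which \code{fracDeregDown} downregulated.
#'
#' @param bundle a simulated \linkS4class{GenomeBundle}.
#' @param config a \code{\link{simulationConfig}}.
#' @return list with the (possibly sequence-edited) \code{bundle} and
#'   \code{truth}, a \linkS4class{SimulationTruth} skeleton (no counts yet).
#' @export
plantCircles <- function(bundle, config) {
    set.seed(.stageSeed(config, 2L))
    nC <- config$nCirc
    samples <- DataFrame(
        sample = paste0(rep(config$conditions,
                            each = config$samplesPerCondition), "_",
                        rep(seq_len(config$samplesPerCondition), 2L)),
        condition = rep(config$conditions, each = config$samplesPerCondition))
    if (nC == 0L)
        return(list(bundle = bundle,
                    truth = new("SimulationTruth", circles = DataFrame(),
                                circCounts = matrix(0L, 0L, nrow(samples)),
                                linCounts = matrix(0L, 0L, nrow(samples)),
                                samples = samples)))
    tx <- bundle@transcripts
    nExPerTx <- table(as.character(bundle@exons$transcript_id))
    # a circle over internal exons needs >= circExonRange[1] + 2 exons
    eligible <- names(nExPerTx)[as.integer(nExPerTx) >=
                                    config$circExonRange[1L] + 2L]
    if (nC > length(eligible))
        stop("requesting more circles than eligible transcripts (",
             length(eligible), ")")
    hostTx <- sample(eligible, nC)
    nCryptic <- round(config$fracNonAnnotated * nC)
    cryptic <- rep(c(TRUE, FALSE), c(nCryptic, nC - nCryptic))

    rows <- vector("list", nC)
    for (k in seq_len(nC)) {
        tid <- hostTx[k]
        ex <- .txExons(bundle, tid)
        n <- length(ex)
        Lmax <- min(config$circExonRange[2L], n - 2L)
        L <- .sampleOne(seq(config$circExonRange[1L], Lmax))
        i <- .sampleOne(seq(2L, n - L))
        j <- i + L - 1L
        minus <- as.character(strand(ex))[1L] == "-"
        chrom <- as.character(seqnames(ex))[1L]
        if (!cryptic[k]) {
            acceptor <- if (minus) end(ex)[i] else start(ex)[i]
            donor <- if (minus) start(ex)[j] else end(ex)[j]
            accOff <- 0L; donOff <- 0L
        } else {
            # exon-internal GT/AG pair: acceptor accOff bases into exon i,
            # donor donOff bases before the end of exon j
            wi <- width(ex)[i]; wj <- width(ex)[j]
            accOff <- .sampleOne(4L:min(20L, wi - 4L))
            donOff <- .sampleOne(4L:min(20L, wj - 4L))
            bundle <- .plantCrypticSignals(bundle, ex, i, j, accOff, donOff)
            if (minus) {
                acceptor <- end(ex)[i] - accOff
                donor <- start(ex)[j] + donOff
            } else {
                acceptor <- start(ex)[i] + accOff
                donor <- end(ex)[j] - donOff
            }
        }
        rows[[k]] <- data.frame(
            circ_id = sprintf("circ_%03d", k), transcript_id = tid,
            gene_id = as.character(tx$gene_id)[
                match(tid, tx$transcript_id)],
            chrom = chrom, strand = if (minus) "-" else "+",
            acceptor = acceptor, donor = donor,
            exon_from = i, exon_to = j,
            acc_off = accOff, don_off = donOff,
            annotated = !cryptic[k], stringsAsFactors = FALSE)
    }
    circles <- DataFrame(do.call(rbind, rows))
    nDereg <- round(config$fracDereg * nC)
    lfc <- numeric(nC)
    if (nDereg > 0L) {
        who <- sample(nC, nDereg)
        mag <- runif(nDereg, config$deregLog2FCRange[1L],
                     config$deregLog2FCRange[2L])
        sgn <- ifelse(runif(nDereg) < config$fracDeregDown, -1, 1)
        lfc[who] <- sgn * mag
    }
    circles$log2fc <- lfc
    circles$bound <- NA
    truth <- new("SimulationTruth", circles = circles,
                 circCounts = matrix(0L, nC, nrow(samples),
                                     dimnames = list(circles$circ_id,
                                                     samples$sample)),
                 linCounts = matrix(0L, nC, nrow(samples),
                                    dimnames = list(circles$circ_id,
                                                    samples$sample)),
                 samples = samples)
    list(bundle = bundle, truth = truth)
}

## write GT after the cryptic donor and AG before the cryptic acceptor, in
## transcript orientation, and keep the segment's terminal bases != G
.plantCrypticSignals <- function(bundle, ex, i, j, accOff, donOff) {
    chrom <- as.character(seqnames(ex))[1L]
    minus <- as.character(strand(ex))[1L] == "-"
    seqChr <- bundle@seqs[[chrom]]
    setT <- function(exIdx, off, base) {
        # set the transcript-oriented base at 1-based offset `off` of exon
        pos <- if (minus) end(ex)[exIdx] - off + 1L else
            start(ex)[exIdx] + off - 1L
        b <- if (minus)
            as.character(reverseComplement(Biostrings::DNAString(base)))
        else base
        subseq(seqChr, pos, pos) <<- Biostrings::DNAString(b)
    }
    wi <- Biostrings::width(ex)[i]  # unused; clarity
    # acceptor at exon i offset accOff+1: AG just before, first base not G
    setT(i, accOff - 1L, "A"); setT(i, accOff, "G")
    setT(i, accOff + 1L, "C")
    # donor at exon j offset width-donOff: GT just after, last base not G
    wj <- width(ex)[j]
    setT(j, wj - donOff, "C")
    setT(j, wj - donOff + 1L, "G"); setT(j, wj - donOff + 2L, "T")
    bundle@seqs[[chrom]] <- seqChr
    bundle
}

#' Simulate circular and linear junction counts
#'
#' Counts are negative binomial with dispersion \code{phi}: circular means in
#' condition 2 are scaled by \code{2^log2fc}; cognate linear means are equal
#' across conditions (the dominant regime in the data modelled: host linear
#' transcripts unchanged).  \code{phi = 0} gives the Poisson limit.
#'
#' @param truth a \linkS4class{SimulationTruth} from \code{\link{plantCircles}}.
#' @param config a \code{\link{simulationConfig}}.
#' @return the truth object with count matrices filled in.
#' @export
simulateCounts <- function(truth, config) {
    set.seed(.stageSeed(config, 3L))
    if (config$circBaseMean < 0 || config$linearBaseMean < 0)
        stop("negative means")
    nC <- nrow(truth@circles)
    samp <- truth@samples
    nS <- nrow(samp)
    cond2 <- samp$condition == config$conditions[2L]
    rnb <- function(n, mu) {
        if (config$dispersion == 0) rpois(n, mu)
        else rnbinom(n, mu = mu, size = 1 / config$dispersion)
    }
    circ <- matrix(0L, nC, nS,
                   dimnames = list(truth@circles$circ_id, samp$sample))
    lin <- circ
    for (s in seq_len(nS)) {
        muC <- if (cond2[s]) config$circBaseMean * 2^truth@circles$log2fc
               else rep(config$circBaseMean, nC)
        circ[, s] <- as.integer(rnb(nC, muC))
        lin[, s] <- as.integer(rnb(nC, rep(config$linearBaseMean, nC)))
    }
    truth@circCounts <- circ
    truth@linCounts <- lin
    truth
}

.mutateReads <- function(seqs, rate) {
    if (rate <= 0) return(seqs)
    vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1L]]
        hit <- runif(length(ch)) < rate
        if (any(hit))
            ch[hit] <- vapply(ch[hit], function(b)
                sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
}

#' Emit paired-end reads
#'
#' For every circular junction count, that many read pairs are produced whose
#' first mate crosses the head-to-tail junction: the mate is a suffix of the
#' circle's 3' end followed by a prefix of its 5' start (transcript
#' orientation), with the breakpoint at a uniform-random offset leaving at
#' least \code{anchorLen} bases on each side.  Linear counts produce mates
#' spanning one of the two annotated linear junctions at the back-splice
#' coordinates.  Second mates are contiguous exonic (antisense) segments.
#' Contaminant pairs are drawn from generated abundant-ncRNA-like sequences.
#' Read ids encode the originating circle, sample and read type.
#'
#' @param truth a counted \linkS4class{SimulationTruth}.
#' @param bundle the (possibly circle-edited) \linkS4class{GenomeBundle}.
#' @param config a \code{\link{simulationConfig}}.
#' @param anchorLen anchor length the downstream caller will use; read
#'   length must be at least twice this.
#' @return list with \code{reads} (per sample, \code{R1}/\code{R2}
#'   \code{DNAStringSet}s) and \code{contaminants} (\code{DNAStringSet}).
#' @export
emitReads <- function(truth, bundle, config, anchorLen = 20L) {
    set.seed(.stageSeed(config, 4L))
    R <- config$readLen
    if (R < 2L * anchorLen)
        stop("read length ", R, " < 2 x anchor length ", anchorLen,
             ": breakpoints would be undetectable")
    contam <- DNAStringSet(vapply(seq_len(config$nContamSeqs), function(i)
        .randDNA(config$contamLen), ""))
    names(contam) <- paste0("ncRNA_", seq_along(contam))

    circles <- truth@circles
    nC <- nrow(circles)
    segSeq <- character(nC)
    exSeqUp <- character(nC)   # exon upstream of the acceptor (i - 1)
    exSeqDn <- character(nC)   # exon downstream of the donor (j + 1)
    exSeqIn <- character(nC)   # first full exon inside the circle
    for (k in seq_len(nC)) {
        ci <- circles[k, ]
        full <- .exonRunSeq(bundle, ci$transcript_id, ci$exon_from,
                            ci$exon_to)
        ex <- .txExons(bundle, ci$transcript_id)
        wFrom <- width(ex)[ci$exon_from]
        if (ci$annotated) segSeq[k] <- full
        else {
            # trim to the cryptic acceptor/donor offsets
            from <- ci$acc_off + 1L
            to <- nchar(full) - ci$don_off
            segSeq[k] <- substr(full, from, to)
        }
        exSeqUp[k] <- .exonRunSeq(bundle, ci$transcript_id,
                                  ci$exon_from - 1L, ci$exon_from - 1L)
        exSeqDn[k] <- .exonRunSeq(bundle, ci$transcript_id,
                                  ci$exon_to + 1L, ci$exon_to + 1L)
        exSeqIn[k] <- .exonRunSeq(bundle, ci$transcript_id, ci$exon_from,
                                  ci$exon_from)
    }
    exSeqNext <- vapply(seq_len(nC), function(k)
        .exonRunSeq(bundle, circles$transcript_id[k], circles$exon_to[k],
                    circles$exon_to[k]), "")

    rc <- .rcChar
    samples <- truth@samples$sample
    reads <- vector("list", length(samples))
    names(reads) <- samples
    for (s in seq_along(samples)) {
        ids <- character(); r1 <- character(); r2 <- character()
        for (k in seq_len(nC)) {
            nBS <- truth@circCounts[k, s]
            seg <- segSeq[k]
            if (nBS > 0L) {
                off <- sample(anchorLen:(R - anchorLen), nBS, replace = TRUE)
                m1 <- vapply(off, function(b) paste0(
                    substr(seg, nchar(seg) - b + 1L, nchar(seg)),
                    substr(seg, 1L, R - b)), "")
                inEx <- exSeqIn[k]
                p2 <- sample(seq_len(nchar(inEx) - R + 1L), nBS,
                             replace = TRUE)
                m2 <- rc(substring(inEx, p2, p2 + R - 1L))
                ids <- c(ids, sprintf("%s|%s|bs|r%04d", circles$circ_id[k],
                                      samples[s], seq_len(nBS)))
                r1 <- c(r1, m1); r2 <- c(r2, m2)
            }
            nLin <- truth@linCounts[k, s]
            if (nLin > 0L) {
                up <- sample(c(TRUE, FALSE), nLin, replace = TRUE)
                off <- sample(anchorLen:(R - anchorLen), nLin, replace = TRUE)
                m1 <- character(nLin); m2 <- character(nLin)
                for (q in seq_len(nLin)) {
                    if (up[q]) { left <- exSeqUp[k]; right <- exSeqIn[k] }
                    else { left <- exSeqNext[k]; right <- exSeqDn[k] }
                    b <- off[q]
                    m1[q] <- paste0(
                        substr(left, nchar(left) - b + 1L, nchar(left)),
                        substr(right, 1L, R - b))
                    p2 <- .sampleOne(seq_len(nchar(right) - R + 1L))
                    m2[q] <- rc(substr(right, p2, p2 + R - 1L))
                }
                ids <- c(ids, sprintf("%s|%s|lin%s|r%04d",
                                      circles$circ_id[k], samples[s],
                                      ifelse(up, "up", "dn"), seq_len(nLin)))
                r1 <- c(r1, m1); r2 <- c(r2, m2)
            }
        }
        if (config$nContamPairs > 0L && length(contam)) {
            src <- sample(seq_along(contam), config$nContamPairs,
                          replace = TRUE)
            p <- vapply(src, function(i)
                .sampleOne(seq_len(config$contamLen - R + 1L)), 0L)
            cs <- as.character(contam)
            m1 <- substring(cs[src], p, p + R - 1L)
            m2 <- rc(substring(cs[src], pmax(1L, p - 50L),
                               pmax(1L, p - 50L) + R - 1L))
            ids <- c(ids, sprintf("contam|%s|ct|r%04d", samples[s],
                                  seq_len(config$nContamPairs)))
            r1 <- c(r1, m1); r2 <- c(r2, m2)
        }
        r1 <- .mutateReads(r1, config$errorRate)
        r2 <- .mutateReads(r2, config$errorRate)
        R1 <- DNAStringSet(r1); names(R1) <- ids
        R2 <- DNAStringSet(r2); names(R2) <- ids
        reads[[s]] <- list(R1 = R1, R2 = R2)
    }
    list(reads = reads, contaminants = contam)
}

#' Simulate CLIP-seq peak replicates
#'
#' Each annotated circle carries a planted binding site with probability
#' \code{pDereg} (true log2FC != 0) or \code{pUnaff} (log2FC == 0): a peak of
#' \code{peakWidth} nt placed in one of the two flanking introns within
#' 1-\code{clipWindowMax} nt of the back-splice site, replicated into every
#' replicate file with jittered ends and a p-value below the retention
#' cutoff.  Background peaks (uniform placement) and deliberately weak peaks
#' (p-value above the cutoff) are added per replicate.
#'
#' @param truth a \linkS4class{SimulationTruth} with log2FC labels.
#' @param bundle the annotated \linkS4class{GenomeBundle}.
#' @param config a \code{\link{simulationConfig}}.
#' @param peakPMax per-replicate peak p-value cutoff the pipeline will apply.
#' @return list with \code{peaks} (list of \code{GRanges}, one per
#'   replicate, metadata \code{name}, \code{score}, \code{pvalue}) and
#'   \code{truth} with the \code{bound} flag filled in.
#' @export
simulateClipPeaks <- function(truth, bundle, config, peakPMax = 1e-4) {
    set.seed(.stageSeed(config, 5L))
    circles <- truth@circles
    nC <- nrow(circles)
    w <- config$peakWidth
    nRep <- config$nClipReplicates
    repPeaks <- replicate(nRep, list(chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     name = character(), p = numeric()),
                          simplify = FALSE)
    bound <- logical(nC)
    introns <- bundle@introns
    for (k in seq_len(nC)) {
        ci <- circles[k, ]
        if (!ci$annotated) next
        pBind <- if (ci$log2fc != 0) config$pDereg else config$pUnaff
        if (runif(1L) >= pBind) next
        bound[k] <- TRUE
        side <- .sampleOne(c("up", "dn"))
        minus <- ci$strand == "-"
        d <- sample.int(config$clipWindowMax - w, 1L)
        if (side == "up") {
            # intron upstream of the acceptor (rank exon_from - 1)
            if (!minus) { e <- ci$acceptor - d; s <- e - w + 1L }
            else { s <- ci$acceptor + d; e <- s + w - 1L }
        } else {
            if (!minus) { s <- ci$donor + d; e <- s + w - 1L }
            else { e <- ci$donor - d; s <- e - w + 1L }
        }
        for (r in seq_len(nRep)) {
            js <- s + .sampleOne(-config$peakJitter:config$peakJitter)
            je <- e + .sampleOne(-config$peakJitter:config$peakJitter)
            if (je <= js) je <- js + 1L
            repPeaks[[r]]$chrom <- c(repPeaks[[r]]$chrom, ci$chrom)
            repPeaks[[r]]$start <- c(repPeaks[[r]]$start, js)
            repPeaks[[r]]$end <- c(repPeaks[[r]]$end, je)
            repPeaks[[r]]$strand <- c(repPeaks[[r]]$strand, ci$strand)
            repPeaks[[r]]$name <- c(repPeaks[[r]]$name,
                                    paste0(ci$circ_id, "_", side))
            repPeaks[[r]]$p <- c(repPeaks[[r]]$p,
                                 runif(1L, 0, peakPMax * 0.9))
        }
    }
    chromLen <- width(bundle@seqs)
    names(chromLen) <- names(bundle@seqs)
    for (r in seq_len(nRep)) {
        nBg <- config$backgroundPeaksPerReplicate
        nWk <- config$weakPeaksPerReplicate
        for (grp in c("bg", "weak")) {
            n <- if (grp == "bg") nBg else nWk
            if (n == 0L) next
            chr <- sample(names(chromLen), n, replace = TRUE)
            st <- vapply(chr, function(cc)
                sample.int(chromLen[[cc]] - w, 1L), 0L)
            pv <- if (grp == "bg") runif(n, 0, peakPMax * 0.9)
            else runif(n, peakPMax * 2, 1e-2)
            repPeaks[[r]]$chrom <- c(repPeaks[[r]]$chrom, chr)
            repPeaks[[r]]$start <- c(repPeaks[[r]]$start, st)
            repPeaks[[r]]$end <- c(repPeaks[[r]]$end, st + w - 1L)
            repPeaks[[r]]$strand <- c(repPeaks[[r]]$strand,
                                      sample(c("+", "-"), n, replace = TRUE))
            repPeaks[[r]]$name <- c(repPeaks[[r]]$name,
                                    paste0(grp, "_", seq_len(n)))
            repPeaks[[r]]$p <- c(repPeaks[[r]]$p, pv)
        }
    }
    peaks <- lapply(repPeaks, function(pp) {
        if (length(pp$chrom) == 0L) return(GRanges())
        GRanges(pp$chrom, IRanges(pp$start, pp$end), strand = pp$strand,
                name = pp$name, score = 0L, pvalue = pp$p)
    })
    names(peaks) <- paste0("rep", seq_len(nRep))
    truth@circles$bound <- bound
    list(peaks = peaks, truth = truth)
}

#' Write a DNAStringSet as FASTQ
#'
#' @param seqs named \code{DNAStringSet}.
#' @param path output file (uncompressed).
#' @param qualChar constant base-quality character (default "I", Q40).
#' @export
writeFastq <- function(seqs, path, qualChar = "I") {
    s <- as.character(seqs)
    lines <- as.vector(rbind(paste0("@", names(seqs)), s, "+",
                             vapply(nchar(s), function(n)
                                 strrep(qualChar, n), "")))
    writeLines(lines, path)
    invisible(path)
}

#' Write all simulation artifacts to a directory
#'
#' Emits \code{genome.fa}, \code{annotation.gtf}, per-sample
#' \code{<sample>_R1.fastq}/\code{_R2.fastq}, per-replicate
#' \code{clip_<rep>.bed} (BED6 + p-value column), \code{contaminants.fa} and
#' the ground-truth manifest \code{truth.tsv}.
#'
#' @param bundle,truth,reads,peaks simulation outputs.
#' @param dir output directory (created if missing).
#' @export
writeSimulation <- function(bundle, truth, reads, peaks, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(bundle@seqs, file.path(dir, "genome.fa"))
    writeAnnotationGtf(bundle, file.path(dir, "annotation.gtf"))
    Biostrings::writeXStringSet(reads$contaminants,
                                file.path(dir, "contaminants.fa"))
    for (s in names(reads$reads)) {
        writeFastq(reads$reads[[s]]$R1,
                   file.path(dir, paste0(s, "_R1.fastq")))
        writeFastq(reads$reads[[s]]$R2,
                   file.path(dir, paste0(s, "_R2.fastq")))
    }
    for (r in names(peaks))
        writeBed(peaks[[r]], file.path(dir, paste0("clip_", r, ".bed")),
                 extra = "pvalue")
    utils::write.table(as.data.frame(truth@circles),
                       file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}
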