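#' Read a genome FASTA
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet.
#'
#' @param fasta path to a FASTA file.
#' @return a \linkS4class{GenomeBundle} with sequences only (empty gene
#'   models); attach annotation with \code{\link{readAnnotationGtf}}.
#' @export
readGenomeFasta <- function(fasta) {
    seqs <- Biostrings::readBStringSet(fasta)
    if (length(seqs) == 0L)
        stop("FASTA contains no sequences: ", fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stop("duplicate sequence name in FASTA: ",
             names(seqs)[duplicated(names(seqs))][1L])
    if (any(width(seqs) == 0L))
        stop("empty sequence in FASTA: ", names(seqs)[width(seqs) == 0L][1L])
    up <- Biostrings::BStringSet(toupper(as.character(seqs)))
    letters <- Biostrings::uniqueLetters(up)
    bad <- setdiff(letters, c("A", "C", "G", "T", "N"))
    if (length(bad))
        stop("sequence contains characters outside A/C/G/T/N: ",
             paste(bad, collapse = ", "))
    names(up) <- names(seqs)
    emptyGR <- GRanges()
    new("GenomeBundle", seqs = DNAStringSet(up),
        genes = emptyGR, transcripts = emptyGR, exons = emptyGR,
        cds = emptyGR, introns = emptyGR, utr5 = emptyGR, utr3 = emptyGR)
}

#' Attach gene models from a GTF file
#'
#' Reads an Ensembl-dialect GTF (gene/transcript/exon and optional CDS
#' features with \code{gene_id}/\code{transcript_id} attributes), orders
#' exons in transcription order (first exon = 5'-most), and derives introns
#' and, where a CDS is present, 5' and 3' UTR intervals.  GTF coordinates are
#' 1-based closed, matching the internal convention, so no shifting occurs.
#'
#' @param gtf path to a GTF file.
#' @param bundle a \linkS4class{GenomeBundle} holding the sequences.
#' @return the bundle with gene models attached.
#' @export
readAnnotationGtf <- function(gtf, bundle) {
    gr <- rtracklayer::import(gtf, format = "gtf")
    exons <- gr[gr$type == "exon"]
    if (length(exons) == 0L)
        stop("GTF has no exon features: ", gtf)
    if (is.null(exons$transcript_id) || any(is.na(exons$transcript_id)))
        stop("exon feature without transcript_id")
    .attachModels(bundle,
        exons = GRanges(seqnames(exons), IRanges(start(exons), end(exons)),
                        strand = strand(exons),
                        transcript_id = exons$transcript_id,
                        gene_id = exons$gene_id),
        cdsParts = gr[gr$type == "CDS"],
        geneMeta = gr[gr$type == "gene"])
}

## Shared by the GTF reader and the simulator: sorts exons, derives
## transcript/gene extents, introns and UTRs; validates per-transcript
## exon disjointness.
.attachModels <- function(bundle, exons, cdsParts = GRanges(),
                          geneMeta = GRanges()) {
    ord <- order(as.character(exons$transcript_id), start(exons))
    exons <- exons[ord]
    txs <- as.character(exons$transcript_id)
    txSplit <- split(seq_along(exons), txs)

    txIds <- names(txSplit)
    exStrand <- as.character(strand(exons))
    rank <- integer(length(exons))
    intronList <- vector("list", length(txIds))
    txRow <- integer(length(txIds))
    for (k in seq_along(txIds)) {
        idx <- txSplit[[k]]
        s <- start(exons)[idx]; e <- end(exons)[idx]
        if (length(idx) > 1L && any(s[-1L] <= e[-length(e)]))
            stop("overlapping exons within transcript ", txIds[k])
        minus <- exStrand[idx[1L]] == "-"
        rank[idx] <- if (minus) rev(seq_along(idx)) else seq_along(idx)
        txRow[k] <- idx[1L]
        if (length(idx) > 1L) {
            is <- e[-length(e)] + 1L
            ie <- s[-1L] - 1L
            ir <- if (minus) rev(seq_along(is)) else seq_along(is)
            intronList[[k]] <- GRanges(
                seqnames(exons)[idx[1L]], IRanges(is, ie),
                strand = exStrand[idx[1L]],
                transcript_id = txIds[k], intron_rank = ir)
        }
    }
    exons$exon_rank <- rank
    introns <- if (any(!vapply(intronList, is.null, TRUE)))
        do.call(c, intronList[!vapply(intronList, is.null, TRUE)])
    else GRanges()

    txRanges <- unlist(range(split(exons, txs), ignore.strand = FALSE))
    txRanges <- txRanges[txIds]
    mcols(txRanges) <- DataFrame(
        transcript_id = txIds,
        gene_id = as.character(exons$gene_id)[txRow])
    names(txRanges) <- NULL

    gid <- as.character(txRanges$gene_id)
    geneRangesGR <- unlist(range(split(txRanges, gid), ignore.strand = FALSE))
    geneIds <- names(geneRangesGR)
    names(geneRangesGR) <- NULL
    biotype <- rep(NA_character_, length(geneIds))
    gname <- geneIds
    if (length(geneMeta)) {
        m <- match(geneIds, geneMeta$gene_id)
        if (!is.null(geneMeta$gene_biotype))
            biotype <- as.character(geneMeta$gene_biotype)[m]
        if (!is.null(geneMeta$gene_name)) {
            nm <- as.character(geneMeta$gene_name)[m]
            gname <- ifelse(is.na(nm), geneIds, nm)
        }
    }
    mcols(geneRangesGR) <- DataFrame(gene_id = geneIds, gene_name = gname,
                                     gene_biotype = biotype)

    cds <- GRanges()
    utr5 <- GRanges()
    utr3 <- GRanges()
    if (length(cdsParts)) {
        ctx <- as.character(cdsParts$transcript_id)
        spans <- unlist(range(split(cdsParts, ctx), ignore.strand = FALSE))
        cdsTx <- names(spans)
        names(spans) <- NULL
        mcols(spans) <- DataFrame(transcript_id = cdsTx)
        cds <- spans
        u5 <- vector("list", length(cdsTx))
        u3 <- vector("list", length(cdsTx))
        for (k in seq_along(cdsTx)) {
            idx <- txSplit[[cdsTx[k]]]
            if (is.null(idx)) next
            ex <- exons[idx]
            minus <- as.character(strand(ex))[1L] == "-"
            cs <- start(cds)[k]; ce <- end(cds)[k]
            left <- .clipToRegion(ex, 1L, cs - 1L)
            right <- .clipToRegion(ex, ce + 1L, .Machine$integer.max)
            if (minus) { tmp <- left; left <- right; right <- tmp }
            if (length(left)) {
                mcols(left) <- DataFrame(transcript_id = cdsTx[k])
                u5[[k]] <- left
            }
            if (length(right)) {
                mcols(right) <- DataFrame(transcript_id = cdsTx[k])
                u3[[k]] <- right
            }
        }
        keep5 <- !vapply(u5, is.null, TRUE)
        keep3 <- !vapply(u3, is.null, TRUE)
        if (any(keep5)) utr5 <- do.call(c, u5[keep5])
        if (any(keep3)) utr3 <- do.call(c, u3[keep3])
    }

    bundle@exons <- exons
    bundle@transcripts <- txRanges
    bundle@genes <- geneRangesGR
    bundle@cds <- cds
    bundle@introns <- introns
    bundle@utr5 <- utr5
    bundle@utr3 <- utr3
    validObject(bundle)
    bundle
}

## exonic pieces of `ex` falling inside the genomic region [lo, hi]
.clipToRegion <- function(ex, lo, hi) {
    s <- pmax(start(ex), lo)
    e <- pmin(end(ex), hi)
    keep <- s <= e
    if (!any(keep)) return(GRanges())
    GRanges(seqnames(ex)[keep], IRanges(s[keep], e[keep]),
            strand = strand(ex)[keep])
}

#' Catalog of annotated splice sites
#'
#' Donors are the genomic coordinate of the last base (transcription order)
#' of every non-terminal exon; acceptors the first base of every non-initial
#' exon.  Sites shared between isoforms appear once.
#'
#' @param bundle an annotated \linkS4class{GenomeBundle}.
#' @return list of two data.frames (\code{donors}, \code{acceptors}) with
#'   columns \code{chrom}, \code{pos}, \code{strand}.
#' @export
spliceSiteCatalog <- function(bundle) {
    ex <- bundle@exons
    if (length(ex) == 0L)
        return(list(donors = .siteDF(), acceptors = .siteDF()))
    nEx <- table(as.character(ex$transcript_id))
    n <- as.integer(nEx[as.character(ex$transcript_id)])
    minus <- as.character(strand(ex)) == "-"
    rank <- ex$exon_rank
    isDonor <- rank < n           # has a downstream intron
    isAcceptor <- rank > 1L       # has an upstream intron
    donorPos <- ifelse(minus, start(ex), end(ex))
    accPos <- ifelse(minus, end(ex), start(ex))
    chrom <- as.character(seqnames(ex))
    str <- as.character(strand(ex))
    donors <- unique(data.frame(chrom = chrom[isDonor],
                                pos = donorPos[isDonor],
                                strand = str[isDonor],
                                stringsAsFactors = FALSE))
    acceptors <- unique(data.frame(chrom = chrom[isAcceptor],
                                   pos = accPos[isAcceptor],
                                   strand = str[isAcceptor],
                                   stringsAsFactors = FALSE))
    list(donors = donors, acceptors = acceptors)
}

.siteDF <- function()
    data.frame(chrom = character(), pos = integer(), strand = character(),
               stringsAsFactors = FALSE)

#' Genes overlapping an interval
#'
#' @param bundle an annotated \linkS4class{GenomeBundle}.
#' @param interval a \code{GRanges} of length 1.
#' @param strandAware match gene strand (default TRUE; the sequencing
#'   protocol modelled here is stranded).
#' @return the overlapping genes as a \code{GRanges}; the attribute
#'   \code{mutuallyOverlapping} reports whether every returned pair of genes
#'   overlaps each other.
#' @export
genesOverlapping <- function(bundle, interval, strandAware = TRUE) {
    stopifnot(is(interval, "GRanges"), length(interval) == 1L)
    if (!(as.character(seqnames(interval)) %in% names(bundle@seqs)))
        stop("unknown chromosome: ", as.character(seqnames(interval)))
    hits <- GenomicRanges::findOverlaps(interval, bundle@genes,
                                        ignore.strand = !strandAware)
    g <- bundle@genes[subjectHits(hits)]
    mutual <- TRUE
    if (length(g) > 1L) {
        selfHits <- GenomicRanges::findOverlaps(g, g,
                                                ignore.strand = !strandAware)
        nPairs <- length(selfHits)  # includes self-hits
        mutual <- nPairs == length(g)^2
    }
    attr(mutual, "names") <- NULL
    S4Vectors::metadata(g)$mutuallyOverlapping <- mutual
    g
}

## TRUE for junctions whose span touches two genes that do not overlap each
## other (the published mapping-error exclusion).  `acceptor`/`donor` are
## genomic coordinates; evaluation is strand-aware by default.
.spansNonOverlappingGenes <- function(bundle, chrom, strand, acceptor, donor,
                                      strandAware = TRUE) {
    n <- length(chrom)
    out <- logical(n)
    if (length(bundle@genes) == 0L || n == 0L) return(out)
    pts <- GRanges(rep(chrom, 2L),
                   IRanges(c(acceptor, donor), width = 1L),
                   strand = rep(strand, 2L))
    hits <- GenomicRanges::findOverlaps(pts, bundle@genes,
                                        ignore.strand = !strandAware)
    byPt <- split(subjectHits(hits), factor(queryHits(hits),
                                            levels = seq_len(2L * n)))
    for (i in seq_len(n)) {
        gA <- byPt[[i]]
        gD <- byPt[[i + n]]
        if (length(gA) == 0L || length(gD) == 0L) next
        if (length(intersect(gA, gD))) next
        ga <- bundle@genes[gA]; gd <- bundle@genes[gD]
        ov <- GenomicRanges::findOverlaps(ga, gd,
                                          ignore.strand = !strandAware)
        out[i] <- length(ov) == 0L
    }
    out
}

#' Write gene models as Ensembl-dialect GTF
#'
#' Emits gene, transcript, exon and CDS lines with \code{gene_id},
#' \code{transcript_id} and \code{gene_biotype} attributes; coordinates are
#' written 1-based closed so a read/write round trip preserves them exactly.
#'
#' @param bundle an annotated \linkS4class{GenomeBundle}.
#' @param path output file.
#' @export
writeAnnotationGtf <- function(bundle, path) {
    lines <- character()
    attrs <- function(...) {
        kv <- list(...)
        paste(vapply(names(kv), function(k)
            sprintf('%s "%s";', k, kv[[k]]), ""), collapse = " ")
    }
    g <- bundle@genes
    gline <- sprintf("%s\tcircSplice\tgene\t%d\t%d\t.\t%s\t.\t%s",
                     as.character(seqnames(g)), start(g), end(g),
                     as.character(strand(g)),
                     mapply(function(id, nm, bt)
                         attrs(gene_id = id, gene_name = nm,
                               gene_biotype = ifelse(is.na(bt), "NA", bt)),
                         g$gene_id, g$gene_name, g$gene_biotype))
    tx <- bundle@transcripts
    tline <- sprintf("%s\tcircSplice\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                     as.character(seqnames(tx)), start(tx), end(tx),
                     as.character(strand(tx)),
                     mapply(function(t, gid) attrs(gene_id = gid,
                                                   transcript_id = t),
                            tx$transcript_id, tx$gene_id))
    ex <- bundle@exons
    eline <- sprintf("%s\tcircSplice\texon\t%d\t%d\t.\t%s\t.\t%s",
                     as.character(seqnames(ex)), start(ex), end(ex),
                     as.character(strand(ex)),
                     mapply(function(t, gid, r)
                         attrs(gene_id = gid, transcript_id = t,
                               exon_number = r),
                            ex$transcript_id, ex$gene_id, ex$exon_rank))
    cline <- character()
    if (length(bundle@cds)) {
        cd <- bundle@cds
        gid <- bundle@transcripts$gene_id[
            match(cd$transcript_id, bundle@transcripts$transcript_id)]
        cline <- sprintf("%s\tcircSplice\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                         as.character(seqnames(cd)), start(cd), end(cd),
                         as.character(strand(cd)),
                         mapply(function(t, g) attrs(gene_id = g,
                                                     transcript_id = t),
                                cd$transcript_id, gid))
    }
    writeLines(c(gline, tline, eline, cline), path)
    invisible(path)
}

#' Write junctions or peaks as BED6(+)
#'
#' Internal 1-based closed intervals are converted to BED's 0-based
#' half-open convention at this boundary.
#'
#' @param gr a \code{GRanges}; the \code{name} and \code{score} metadata
#'   columns, when present, fill BED columns 4-5.  Any \code{extra} columns
#'   are appended after column 6.
#' @param path output file.
#' @param extra character vector of metadata column names to append.
#' @export
writeBed <- function(gr, path, extra = character()) {
    name <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
    score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     name, score, str, stringsAsFactors = FALSE)
    for (col in extra) df[[col]] <- mcols(gr)[[col]]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
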