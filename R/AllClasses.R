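#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay rowData colData
#' @importFrom stats rnbinom rpois runif
NULL

#' Genome plus gene models in one object
#'
#' A \code{GenomeBundle} holds chromosome sequences together with gene,
#' transcript, exon, CDS, intron and UTR intervals, all as 1-based closed
#' \link[GenomicRanges]{GRanges} on the same sequence namespace.  External
#' formats are converted at the boundary: GTF is read/written 1-based closed,
#' BED 0-based half-open.  Splice sites are represented by the genomic
#' coordinate of the exon-terminal base: the donor is the last exonic base of
#' the upstream exon (in transcription order), the acceptor the first exonic
#' base of the downstream exon.
#'
#' @slot seqs \code{DNAStringSet} of uppercase chromosome sequences (A/C/G/T/N).
#' @slot genes \code{GRanges} with \code{gene_id}, \code{gene_name},
#'   \code{gene_biotype}.
#' @slot transcripts \code{GRanges} with \code{transcript_id}, \code{gene_id}.
#' @slot exons \code{GRanges} with \code{transcript_id}, \code{gene_id} and
#'   \code{exon_rank} (1 = 5'-most exon in transcription order).
#' @slot cds \code{GRanges}, one genomic CDS span per coding transcript.
#' @slot introns \code{GRanges} with \code{transcript_id} and
#'   \code{intron_rank} (gap after the exon of the same rank).
#' @slot utr5,utr3 \code{GRanges} with \code{transcript_id}; exonic sequence
#'   outside the CDS span, 5' or 3' of it in transcription order.
#'
#' @export
setClass("GenomeBundle",
    representation(
        seqs        = "DNAStringSet",
        genes       = "GRanges",
        transcripts = "GRanges",
        exons       = "GRanges",
        cds         = "GRanges",
        introns     = "GRanges",
        utr5        = "GRanges",
        utr3        = "GRanges"
    )
)

setValidity("GenomeBundle", function(object) {
    msg <- character()
    if (length(object@seqs) == 0L)
        msg <- c(msg, "no sequences")
    nm <- names(object@seqs)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "sequence names must be unique and non-NULL")
    if (length(object@exons)) {
        chr <- as.character(seqnames(object@exons))
        bad <- !(chr %in% nm)
        if (any(bad))
            msg <- c(msg, "exon on unknown chromosome")
        else {
            len <- width(object@seqs)[match(chr, nm)]
            if (any(end(object@exons) > len) || any(start(object@exons) < 1L))
                msg <- c(msg, "exon outside chromosome bounds")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn GenomeBundle-class chromosome sequences
#' @param x a \code{GenomeBundle}
#' @export
genomeSeqs <- function(x) x@seqs
#' @describeIn GenomeBundle-class gene extents
#' @export
geneRanges <- function(x) x@genes
#' @describeIn GenomeBundle-class transcript extents
#' @export
transcriptRanges <- function(x) x@transcripts
#' @describeIn GenomeBundle-class exon intervals
#' @export
exonRanges <- function(x) x@exons
#' @describeIn GenomeBundle-class derived introns
#' @export
intronRanges <- function(x) x@introns
#' @describeIn GenomeBundle-class CDS genomic spans
#' @export
cdsRanges <- function(x) x@cds
#' @describeIn GenomeBundle-class derived 5' UTR intervals
#' @export
utr5Ranges <- function(x) x@utr5
#' @describeIn GenomeBundle-class derived 3' UTR intervals
#' @export
utr3Ranges <- function(x) x@utr3

setMethod("show", "GenomeBundle", function(object) {
    cat("GenomeBundle with", length(object@seqs), "sequences (",
        sum(width(object@seqs)), "bp ),",
        length(object@genes), "genes,",
        length(object@transcripts), "transcripts,",
        length(object@exons), "exons\n")
})

#' Analysis parameter set
#'
#' Bundles every tunable threshold of the detection, differential-expression,
#' localization and CLIP-enrichment stages.  Defaults reproduce the published
#' analysis settings: 20-nt anchors, a 100-kb maximum back-splice span,
#' at least two unique supporting reads per junction and sample, the
#' two-reads-in-three-samples expression filter, raw-p significance at 0.05,
#' 5,000 faux-circRNA draws, peak retention at p < 1e-4, replicate merging at
#' 50 nt with two-replicate support, 1,500-nt minimum flanking introns, and
#' 1-500 / 1-1000 nt binding windows.
#'
#' The published anchor mapping-quality cutoff (MAPQ >= 35) is realised in
#' this package's exact-match aligner as "both anchors have exactly one
#' genomic placement" (\code{minAnchorQuality} is kept for documentation).
#'
#' @slot anchorLen integer, anchor length in nt.
#' @slot maxSpan integer, maximum donor-acceptor distance in nt.
#' @slot minAnchorQuality integer, nominal MAPQ cutoff (realised as uniqueness).
#' @slot minUniqReads integer, minimum distinct read sequences per circular
#'   junction and sample.
#' @slot exprMinReads,exprMinSamples integers, the expression filter: keep
#'   features with >= exprMinReads reads in >= exprMinSamples samples.
#' @slot deAlpha numeric, raw-p significance threshold for DE calls.
#' @slot nFaux integer, number of faux-circRNA draws for the positional test.
#' @slot peakPMax numeric, per-replicate CLIP peak p-value cutoff (strict <).
#' @slot peakMergeDist integer, maximum gap (nt) merged between pooled peaks.
#' @slot peakMinReplicates integer, distinct replicates required per site.
#' @slot minFlankIntron integer, minimum flanking intron length (nt).
#' @slot windowWidths integer vector, flanking window widths (nt).
#' @slot stratCutoffs numeric vector, DE p-value cutoffs for stratified
#'   enrichment.
#' @slot donorSignal,acceptorSignal splice signals on the coding strand.
#' @slot maxMismatch integer, mismatch tolerance in breakpoint extension.
#' @slot strandAwareGenes logical, evaluate the non-overlapping-genes
#'   exclusion strand-aware.
#' @slot yatesCorrection logical, continuity-correct the enrichment test.
#' @slot priorWeight numeric, shrinkage weight for tagwise dispersion.
#' @slot rngSeed integer or NA, seed recorded by the pipeline.
#'
#' @export
setClass("CircParams",
    representation(
        anchorLen         = "integer",
        maxSpan           = "integer",
        minAnchorQuality  = "integer",
        minUniqReads      = "integer",
        exprMinReads      = "integer",
        exprMinSamples    = "integer",
        deAlpha           = "numeric",
        nFaux             = "integer",
        peakPMax          = "numeric",
        peakMergeDist     = "integer",
        peakMinReplicates = "integer",
        minFlankIntron    = "integer",
        windowWidths      = "integer",
        stratCutoffs      = "numeric",
        donorSignal       = "character",
        acceptorSignal    = "character",
        maxMismatch       = "integer",
        strandAwareGenes  = "logical",
        yatesCorrection   = "logical",
        priorWeight       = "numeric",
        rngSeed           = "integer"
    )
)

setValidity("CircParams", function(object) {
    msg <- character()
    pos <- c(anchorLen = object@anchorLen, maxSpan = object@maxSpan,
             minUniqReads = object@minUniqReads,
             exprMinReads = object@exprMinReads,
             exprMinSamples = object@exprMinSamples,
             nFaux = object@nFaux, peakMergeDist = object@peakMergeDist,
             peakMinReplicates = object@peakMinReplicates,
             minFlankIntron = object@minFlankIntron)
    if (any(pos <= 0L))
        msg <- c(msg, paste("must be positive:",
                            paste(names(pos)[pos <= 0L], collapse = ", ")))
    if (any(object@windowWidths <= 0L))
        msg <- c(msg, "windowWidths must be positive")
    cut01 <- c(object@deAlpha, object@peakPMax, object@stratCutoffs)
    if (any(cut01 <= 0) || any(cut01 > 1))
        msg <- c(msg, "p-value cutoffs must lie in (0, 1]")
    if (nchar(object@donorSignal) != 2L || nchar(object@acceptorSignal) != 2L)
        msg <- c(msg, "splice signals must be dinucleotides")
    if (object@maxMismatch < 0L)
        msg <- c(msg, "maxMismatch must be >= 0")
    if (object@priorWeight < 0)
        msg <- c(msg, "priorWeight must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a parameter set
#'
#' @param anchorLen,maxSpan,minAnchorQuality,minUniqReads,exprMinReads,exprMinSamples,deAlpha,nFaux,peakPMax,peakMergeDist,peakMinReplicates,minFlankIntron,windowWidths,stratCutoffs,donorSignal,acceptorSignal,maxMismatch,strandAwareGenes,yatesCorrection,priorWeight,rngSeed
#'   see the slot documentation in \linkS4class{CircParams}.
#' @return a validated \linkS4class{CircParams} object.
#' @examples
#' p <- circParams()
#' p@anchorLen
#' @export
circParams <- function(anchorLen = 20L, maxSpan = 100000L,
                       minAnchorQuality = 35L, minUniqReads = 2L,
                       exprMinReads = 2L, exprMinSamples = 3L,
                       deAlpha = 0.05, nFaux = 5000L, peakPMax = 1e-4,
                       peakMergeDist = 50L, peakMinReplicates = 2L,
                       minFlankIntron = 1500L,
                       windowWidths = c(500L, 1000L),
                       stratCutoffs = c(0.05, 0.005, 0.001),
                       donorSignal = "GT", acceptorSignal = "AG",
                       maxMismatch = 2L, strandAwareGenes = TRUE,
                       yatesCorrection = FALSE, priorWeight = 10,
                       rngSeed = NA_integer_) {
    new("CircParams",
        anchorLen = as.integer(anchorLen), maxSpan = as.integer(maxSpan),
        minAnchorQuality = as.integer(minAnchorQuality),
        minUniqReads = as.integer(minUniqReads),
        exprMinReads = as.integer(exprMinReads),
        exprMinSamples = as.integer(exprMinSamples),
        deAlpha = deAlpha, nFaux = as.integer(nFaux), peakPMax = peakPMax,
        peakMergeDist = as.integer(peakMergeDist),
        peakMinReplicates = as.integer(peakMinReplicates),
        minFlankIntron = as.integer(minFlankIntron),
        windowWidths = as.integer(windowWidths),
        stratCutoffs = stratCutoffs,
        donorSignal = toupper(donorSignal),
        acceptorSignal = toupper(acceptorSignal),
        maxMismatch = as.integer(maxMismatch),
        strandAwareGenes = strandAwareGenes,
        yatesCorrection = yatesCorrection,
        priorWeight = priorWeight,
        rngSeed = as.integer(rngSeed))
}

setMethod("show", "CircParams", function(object) {
    cat("CircParams: anchor", object@anchorLen, "nt; span <", object@maxSpan,
        "nt; >=", object@minUniqReads, "unique reads;",
        "expr filter >=", object@exprMinReads, "reads in >=",
        object@exprMinSamples, "samples; alpha =", object@deAlpha, "\n")
})

#' Ground truth of a simulated circRNA experiment
#'
#' @slot circles \code{DataFrame}, one row per planted circle: identifiers,
#'   host gene/transcript, back-splice acceptor/donor coordinates, exon run,
#'   whether the junction uses annotated splice sites, the true log2 fold
#'   change (condition 2 vs 1) and the true CLIP-bound flag.
#' @slot circCounts,linCounts integer matrices (circles x samples) of true
#'   back-splice and cognate linear junction read counts.
#' @slot samples \code{DataFrame} with \code{sample} and \code{condition}.
#'
#' @export
setClass("SimulationTruth",
    representation(
        circles    = "DataFrame",
        circCounts = "matrix",
        linCounts  = "matrix",
        samples    = "DataFrame"
    )
)

setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth:", nrow(object@circles), "planted circles,",
        nrow(object@samples), "samples\n")
    if (nrow(object@circles)) {
        nd <- sum(object@circles$log2fc != 0)
        cat("  deregulated:", nd, " unaffected:",
            nrow(object@circles) - nd, "\n")
    }
})

#' Circular and cognate linear junction counts
#'
#' A \code{CircCountSet} extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: the \code{counts} assay
#' holds integer junction read counts; \code{rowData} carries \code{kind}
#' (\code{"circular"} or \code{"linear"}), \code{pair_id} (the cognate
#' feature) and \code{host_gene}; \code{colData} carries \code{condition}.
#' Library sizes are defined as the per-sample column sums over all features
#' in the object (circular plus linear), and c.p.m. as count / library size
#' x 1e6.
#'
#' @export
setClass("CircCountSet", contains = "SummarizedExperiment")

#' Build a circular+linear count matrix
#'
#' @param circCounts integer matrix, circular junction counts (features x
#'   samples); rownames are circle ids.
#' @param linCounts integer matrix of the cognate linear junction counts,
#'   same dimensions and row order as \code{circCounts}.
#' @param condition factor or character, one condition label per sample
#'   (exactly two levels).
#' @param hostGene optional character vector of host gene ids per circle.
#' @return a \linkS4class{CircCountSet} with circular features first.
#' @examples
#' cc <- matrix(rpois(12, 20), 2, 6,
#'              dimnames = list(c("circ_1", "circ_2"), paste0("s", 1:6)))
#' ll <- matrix(rpois(12, 50), 2, 6, dimnames = dimnames(cc))
#' x <- buildCountMatrix(cc, ll, rep(c("cond1", "cond2"), each = 3))
#' librarySizes(x)
#' @export
buildCountMatrix <- function(circCounts, linCounts, condition,
                             hostGene = NULL) {
    stopifnot(all(dim(circCounts) == dim(linCounts)))
    if (any(circCounts < 0) || any(linCounts < 0))
        stop("counts must be non-negative")
    ids <- rownames(circCounts)
    if (is.null(ids)) ids <- paste0("circ_", seq_len(nrow(circCounts)))
    linIds <- sub("^circ", "lin", ids)
    dup <- linIds == ids
    linIds[dup] <- paste0(ids[dup], "_lin")
    counts <- rbind(circCounts, linCounts)
    rownames(counts) <- c(ids, linIds)
    if (is.null(hostGene)) hostGene <- rep(NA_character_, length(ids))
    rd <- DataFrame(
        kind = rep(c("circular", "linear"), each = length(ids)),
        pair_id = c(linIds, ids),
        host_gene = rep(hostGene, 2L),
        row.names = rownames(counts))
    condition <- factor(condition)
    if (nlevels(condition) != 2L)
        stop("condition must have exactly two levels")
    cd <- DataFrame(condition = condition,
                    row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = round(as.matrix(counts))),
        rowData = rd, colData = cd)
    new("CircCountSet", se)
}

#' @describeIn CircCountSet-class per-sample library sizes (column sums over
#'   circular plus linear features).
#' @param x a \code{CircCountSet}
#' @export
librarySizes <- function(x) colSums(SummarizedExperiment::assay(x, "counts"))

#' @describeIn CircCountSet-class counts-per-million matrix; every column
#'   sums to 1e6 over all features.
#' @export
junctionCPM <- function(x) {
    cnt <- SummarizedExperiment::assay(x, "counts")
    t(t(cnt) / librarySizes(x)) * 1e6
}

setMethod("show", "CircCountSet", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    cat("CircCountSet:", sum(rd$kind == "circular"), "circular +",
        sum(rd$kind == "linear"), "linear features x",
        ncol(object), "samples\n")
    cat("  conditions:",
        paste(levels(SummarizedExperiment::colData(object)$condition),
              collapse = " vs "), "\n")
})
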