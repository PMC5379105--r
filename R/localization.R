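## per-transcript exon table in transcription order, with per-exon overlap
## flags against the same transcript's 5'UTR / CDS / 3'UTR intervals
.txFlagIndex <- function(bundle, txIds = NULL) {
    ex <- bundle@exons
    if (is.null(txIds))
        txIds <- unique(as.character(ex$transcript_id))
    cdsTx <- as.character(bundle@cds$transcript_id)
    out <- vector("list", length(txIds))
    names(out) <- txIds
    for (t in txIds) {
        exi <- ex[ex$transcript_id == t]
        exi <- exi[order(exi$exon_rank)]
        ci <- match(t, cdsTx)
        u5 <- bundle@utr5[as.character(bundle@utr5$transcript_id) == t]
        u3 <- bundle@utr3[as.character(bundle@utr3$transcript_id) == t]
        flag <- function(gr) if (length(gr) == 0L) rep(FALSE, length(exi))
            else GenomicRanges::countOverlaps(exi, gr,
                                              ignore.strand = TRUE) > 0L
        out[[t]] <- list(
            exons = exi,
            coding = !is.na(ci),
            exonLen = sum(width(exi)),
            u5 = flag(u5),
            cds = if (is.na(ci)) rep(FALSE, length(exi))
                  else flag(bundle@cds[ci]),
            u3 = flag(u3))
    }
    out
}

## flags of an exon run [i, j] (transcription order) in one indexed tx
.runFlags <- function(idx, i, j)
    c(u5 = any(idx$u5[i:j]), cds = any(idx$cds[i:j]),
      u3 = any(idx$u3[i:j]))

#' Classify circRNA localization within protein-coding transcripts
#'
#' Each circle's back-splice acceptor and donor are resolved against the
#' exons of same-strand transcripts; circles whose junctions fall in an
#' intron or outside any gene are excluded with a reason, as are circles
#' with no protein-coding host.  Localization flags (overlap of the circle's
#' exonic span with the 5' UTR, CDS and 3' UTR by at least one base) are
#' taken from the chosen host isoform: the longest protein-coding isoform by
#' exonic length (switchable to the shortest via \code{host}).  The exon
#' count spanned is averaged over all protein-coding host isoforms and
#' rounded to the nearest integer, half away from zero.
#'
#' @param circles data.frame with columns \code{id}, \code{chrom},
#'   \code{strand}, \code{acceptor}, \code{donor}.
#' @param bundle an annotated \linkS4class{GenomeBundle}.
#' @param host \code{"longest"} (default) or \code{"shortest"} coding
#'   isoform.
#' @return \code{DataFrame}: id, included flag, reason, host transcript,
#'   number of candidate coding isoforms, exon_count, overlaps_5utr,
#'   overlaps_cds, overlaps_3utr.
#' @export
assignLocalization <- function(circles, bundle, host = c("longest",
                                                         "shortest")) {
    host <- match.arg(host)
    idx <- .txFlagIndex(bundle)
    ex <- bundle@exons
    n <- nrow(circles)
    out <- data.frame(id = circles$id, included = FALSE,
                      reason = NA_character_, host_tx = NA_character_,
                      n_hosts = 0L, exon_count = NA_integer_,
                      overlaps_5utr = NA, overlaps_cds = NA,
                      overlaps_3utr = NA, stringsAsFactors = FALSE)
    geneHit <- function(chrom, pos, strand) {
        g <- bundle@genes
        any(as.character(seqnames(g)) == chrom & start(g) <= pos &
                end(g) >= pos & as.character(strand(g)) == strand)
    }
    for (k in seq_len(n)) {
        ci <- circles[k, ]
        lo <- min(ci$acceptor, ci$donor); hi <- max(ci$acceptor, ci$donor)
        hosts <- character(); counts <- integer(); lens <- numeric()
        flagsPer <- list()
        for (t in names(idx)) {
            exi <- idx[[t]]$exons
            if (length(exi) == 0L) next
            if (as.character(seqnames(exi))[1L] != ci$chrom ||
                as.character(strand(exi))[1L] != ci$strand) next
            inExA <- which(start(exi) <= ci$acceptor &
                               end(exi) >= ci$acceptor)
            inExD <- which(start(exi) <= ci$donor & end(exi) >= ci$donor)
            if (length(inExA) == 0L || length(inExD) == 0L) next
            if (!idx[[t]]$coding) next
            span <- which(start(exi) <= hi & end(exi) >= lo)
            hosts <- c(hosts, t)
            counts <- c(counts, length(span))
            lens <- c(lens, idx[[t]]$exonLen)
            flagsPer[[t]] <- .runFlags(idx[[t]], min(span), max(span))
        }
        if (length(hosts) == 0L) {
            # distinguish intronic / outside-gene / non-coding host
            inGeneA <- geneHit(ci$chrom, ci$acceptor, ci$strand)
            inGeneD <- geneHit(ci$chrom, ci$donor, ci$strand)
            out$reason[k] <- if (!inGeneA || !inGeneD) "outside_gene"
            else {
                anyExonic <- any(vapply(idx, function(ix) {
                    exi <- ix$exons
                    length(exi) &&
                        as.character(seqnames(exi))[1L] == ci$chrom &&
                        as.character(strand(exi))[1L] == ci$strand &&
                        any(start(exi) <= ci$acceptor &
                                end(exi) >= ci$acceptor) &&
                        any(start(exi) <= ci$donor & end(exi) >= ci$donor)
                }, TRUE))
                if (anyExonic) "non_coding_host" else "intronic"
            }
            next
        }
        pick <- if (host == "longest") which.max(lens) else which.min(lens)
        mn <- mean(counts)
        out$included[k] <- TRUE
        out$host_tx[k] <- hosts[pick]
        out$n_hosts[k] <- length(hosts)
        out$exon_count[k] <- .roundHalfAway(mn)
        fl <- flagsPer[[hosts[pick]]]
        out$overlaps_5utr[k] <- fl["u5"]
        out$overlaps_cds[k] <- fl["cds"]
        out$overlaps_3utr[k] <- fl["u3"]
    }
    DataFrame(out)
}

## round to nearest integer, halves away from zero (platform-stable)
.roundHalfAway <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Distribution of exon counts spanned by circles
#'
#' @param loc localization table from \code{\link{assignLocalization}}
#'   (only included circles contribute).
#' @return named integer vector: exon count -> number of circles.
#' @export
exonCountDistribution <- function(loc) {
    counts <- loc$exon_count[loc$included]
    if (length(counts) == 0L) stop("no included circles")
    if (any(counts < 1L)) stop("malformed circle with zero exons")
    tab <- table(counts)
    stats::setNames(as.integer(tab), names(tab))
}

#' Sample faux circRNAs from hosting transcripts
#'
#' Draws \code{n} groups of consecutive \emph{internal} exons (never the
#' first or last exon of a transcript): each draw samples a group size from
#' the supplied distribution, then a uniform-random hosting transcript able
#' to accommodate it, then a uniform-random run position.  Group sizes no
#' transcript can host are resampled (count reported in the
#' \code{resampled} attribute).  Sampling is with replacement.
#'
#' @param bundle an annotated \linkS4class{GenomeBundle}.
#' @param txIds hosting transcript ids (each should have >= 3 exons).
#' @param dist named vector, exon-count distribution (weights).
#' @param n number of draws (published analysis: 5,000).
#' @param seed optional seed for a self-contained deterministic draw.
#' @param bias5utr optional multiplicative weight applied to runs that
#'   overlap the 5' UTR (used for power checks; default 1 = unbiased).
#' @param index optional precomputed transcript index (from the internal
#'   flag indexer) to amortise repeated draws over one annotation.
#' @return \code{DataFrame}: transcript, start exon (transcription order),
#'   size, overlaps_5utr, overlaps_cds, overlaps_3utr.
#' @export
sampleFauxCircles <- function(bundle, txIds, dist, n, seed = NULL,
                              bias5utr = 1, index = NULL) {
    if (!is.null(seed)) set.seed(seed)
    idx <- if (is.null(index)) .txFlagIndex(bundle, unique(txIds)) else index
    nEx <- vapply(idx, function(ix) length(ix$exons), 0L)
    # per-transcript cumulative flag counts over transcription-ordered exons
    cum <- lapply(idx, function(ix)
        list(u5 = cumsum(c(0L, ix$u5)), cds = cumsum(c(0L, ix$cds)),
             u3 = cumsum(c(0L, ix$u3))))
    sizes <- as.integer(names(dist))
    w <- as.numeric(dist)
    feasible <- vapply(sizes, function(L) any(nEx >= L + 2L), TRUE)
    if (!any(feasible)) stop("no transcript can host any sampled size")
    resampled <- 0L
    L <- sizes[sample.int(length(sizes), n, replace = TRUE, prob = w)]
    bad <- !L %in% sizes[feasible]
    while (any(bad)) {   # resample infeasible sizes (logged)
        resampled <- resampled + sum(bad)
        L[bad] <- sizes[sample.int(length(sizes), sum(bad), replace = TRUE,
                                   prob = w)]
        bad <- !L %in% sizes[feasible]
    }
    outTx <- character(n); outS <- integer(n)
    f5 <- logical(n); fc <- logical(n); f3 <- logical(n)
    for (Lu in unique(L)) {
        qs <- which(L == Lu)
        elig <- names(nEx)[nEx >= Lu + 2L]
        outTx[qs] <- elig[sample.int(length(elig), length(qs),
                                     replace = TRUE)]
        for (t in unique(outTx[qs])) {
            qt <- qs[outTx[qs] == t]
            ne <- nEx[[t]]
            starts <- seq(2L, ne - Lu)   # runs within internal exons
            if (bias5utr != 1) {
                cs5 <- cum[[t]]$u5
                wts <- ifelse(cs5[starts + Lu] - cs5[starts] > 0L,
                              bias5utr, 1)
                pick <- starts[sample.int(length(starts), length(qt),
                                          replace = TRUE, prob = wts)]
            } else
                pick <- starts[sample.int(length(starts), length(qt),
                                          replace = TRUE)]
            outS[qt] <- pick
            f5[qt] <- cum[[t]]$u5[pick + Lu] - cum[[t]]$u5[pick] > 0L
            fc[qt] <- cum[[t]]$cds[pick + Lu] - cum[[t]]$cds[pick] > 0L
            f3[qt] <- cum[[t]]$u3[pick + Lu] - cum[[t]]$u3[pick] > 0L
        }
    }
    res <- DataFrame(transcript = outTx, start_exon = outS, size = L,
                     overlaps_5utr = f5, overlaps_cds = fc,
                     overlaps_3utr = f3)
    attr(res, "resampled") <- resampled
    res
}

#' Localization category of flag triples
#'
#' Minimal faithful partition of the UTR/CDS overlap structure:
#' \code{utr5} (overlaps the 5' UTR only), \code{utr3}, \code{bothUTR}
#' (overlaps both UTRs), \code{cdsOnly}.
#'
#' @param flags data.frame-like with \code{overlaps_5utr},
#'   \code{overlaps_3utr}.
#' @return factor with the four levels.
#' @export
localizationCategories <- function(flags) {
    u5 <- flags$overlaps_5utr; u3 <- flags$overlaps_3utr
    cat <- ifelse(u5 & u3, "bothUTR",
           ifelse(u5, "utr5", ifelse(u3, "utr3", "cdsOnly")))
    factor(cat, levels = c("utr5", "cdsOnly", "utr3", "bothUTR"))
}

#' Chi-squared test of positional bias against the faux-circRNA null
#'
#' Observed counts are the real circles' category counts; expected
#' proportions are the faux circles' category frequencies.  Categories with
#' zero expected count are merged into the rarest non-empty category with a
#' warning.  The statistic is the Pearson goodness-of-fit statistic with
#' (categories - 1) degrees of freedom.  Because the expected proportions
#' are themselves estimated from a finite faux sample, the p-value is
#' computed against the finite-reference null: the statistic is scaled by
#' nF / (nF + nR) (faux and real sample sizes) before the chi-squared
#' tail, which keeps the test calibrated for any real-set size; with an
#' infinite reference this reduces to the plain goodness of fit
#' (\code{referenceKnown = TRUE} forces that behaviour).
#'
#' @param real,faux tables with localization flag columns (real: included
#'   circles from \code{\link{assignLocalization}}; faux: from
#'   \code{\link{sampleFauxCircles}}).
#' @param referenceKnown treat the faux frequencies as exact proportions
#'   (no finite-reference correction).
#' @return list: statistic, df, pvalue, observed, expected, categories.
#' @export
localizationChisq <- function(real, faux, referenceKnown = FALSE) {
    rc <- localizationCategories(real)
    fc <- localizationCategories(faux)
    obs <- table(rc)
    exp0 <- table(fc)
    # categories observed in neither set are simply dropped
    empty <- obs == 0L & exp0 == 0L
    obs <- obs[!empty]; exp0 <- exp0[!empty]
    if (any(exp0 == 0L)) {
        zero <- names(exp0)[exp0 == 0L]
        nz <- names(exp0)[exp0 > 0L]
        sink <- nz[which.min(exp0[nz])]
        warning("merging zero-expectation categories (",
                paste(zero, collapse = ", "), ") into ", sink)
        merged <- c(zero, sink)
        obs <- c(obs[setdiff(names(obs), merged)],
                 stats::setNames(sum(obs[merged]), sink))
        exp0 <- c(exp0[setdiff(names(exp0), merged)],
                  stats::setNames(sum(exp0[merged]), sink))
        obs <- obs[names(exp0)]
    }
    p <- as.numeric(exp0) / sum(exp0)
    n <- sum(obs)
    expected <- n * p
    stat <- sum((as.numeric(obs) - expected)^2 / expected)
    df <- length(expected) - 1L
    shrink <- if (referenceKnown) 1 else sum(exp0) / (sum(exp0) + n)
    list(statistic = stat, df = df,
         pvalue = stats::pchisq(stat * shrink, df, lower.tail = FALSE),
         observed = obs, expected = stats::setNames(expected, names(exp0)),
         categories = names(exp0))
}
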