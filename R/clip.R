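#' Ingest CLIP peak replicates from BED files
#'
#' Reads BED6+1 files (chrom, start, end, name, score, strand, p-value),
#' converting the 0-based half-open BED coordinates to the internal 1-based
#' closed convention, and retains per replicate only peaks with p-value
#' strictly below \code{peakPMax}.  A replicate left empty by the filter is
#' kept (with a warning) so it still counts towards the replicate-support
#' rule.
#'
#' @param sources character vector of BED paths, or a named list of
#'   \code{GRanges} with a \code{pvalue} metadata column (already 1-based).
#' @param params a \linkS4class{CircParams}.
#' @return named list of \code{GRanges}, one per replicate.
#' @export
readClipPeaks <- function(sources, params = circParams()) {
    parseOne <- function(path) {
        lines <- readLines(path)
        lines <- lines[nzchar(lines)]
        parts <- strsplit(lines, "\t", fixed = TRUE)
        nf <- lengths(parts)
        if (any(nf < 7L))
            stop("malformed BED line ", which(nf < 7L)[1L], " in ", path,
                 ": expected >= 7 fields (BED6 + p-value)")
        m <- matrix(unlist(lapply(parts, `[`, 1:7)), ncol = 7L,
                    byrow = TRUE)
        st <- suppressWarnings(as.integer(m[, 2L]))
        en <- suppressWarnings(as.integer(m[, 3L]))
        pv <- suppressWarnings(as.numeric(m[, 7L]))
        bad <- which(is.na(st) | is.na(en) | is.na(pv) | en <= st)
        if (length(bad))
            stop("malformed BED line ", bad[1L], " in ", path)
        str <- m[, 6L]
        str[!str %in% c("+", "-")] <- "*"
        GRanges(m[, 1L], IRanges(st + 1L, en), strand = str,
                name = m[, 4L], score = m[, 5L], pvalue = pv)
    }
    peaks <- if (is.character(sources)) {
        out <- lapply(sources, parseOne)
        names(out) <- if (!is.null(names(sources))) names(sources)
                      else sub("\\.bed$", "", basename(sources))
        out
    } else sources
    lapply(stats::setNames(names(peaks), names(peaks)), function(r) {
        p <- peaks[[r]]
        kept <- p[!is.na(p$pvalue) & p$pvalue < params@peakPMax]
        if (length(kept) == 0L)
            warning("replicate ", r, " has no peaks below p < ",
                    params@peakPMax, " (still counted for replicate support)")
        kept
    })
}

#' Merge peak replicates into binding sites
#'
#' Pools peaks from all replicates and merges runs separated by at most
#' \code{peakMergeDist} nt (the interval-merge semantics of
#' \command{bedtools merge -d}); merged sites are retained only when their
#' constituent peaks come from at least \code{peakMinReplicates} distinct
#' replicates.
#'
#' @param peakSets named list of \code{GRanges}, one per replicate.
#' @param params a \linkS4class{CircParams}.
#' @param strandAware merge within strand (default TRUE; peaks with
#'   \code{*} strand merge with either).
#' @return \code{GRanges} of binding sites with \code{n_replicates} and
#'   \code{n_peaks} metadata.
#' @export
mergeReplicatePeaks <- function(peakSets, params = circParams(),
                                strandAware = TRUE) {
    if (length(peakSets) < 2L)
        stop("need at least two replicates")
    rep_id <- rep(names(peakSets), lengths(peakSets))
    pooled <- suppressWarnings(do.call(c, unname(peakSets)))
    if (length(pooled) == 0L)
        return(GRanges(n_replicates = integer(), n_peaks = integer()))
    red <- GenomicRanges::reduce(pooled,
                                 min.gapwidth = params@peakMergeDist + 1L,
                                 with.revmap = TRUE,
                                 ignore.strand = !strandAware)
    nRep <- vapply(red$revmap, function(ii)
        length(unique(rep_id[ii])), 0L)
    nPk <- lengths(red$revmap)
    red$revmap <- NULL
    red$n_replicates <- nRep
    red$n_peaks <- nPk
    sort(red[nRep >= params@peakMinReplicates])
}

#' Select circles eligible for the binding analysis
#'
#' Keeps circles whose acceptor and donor both coincide with annotated
#' splice sites, whose upstream and downstream flanking introns are each at
#' least \code{minFlankIntron} nt, and that are not in the exclusion list
#' (circles whose deregulation parallels the host transcript).  Circles on
#' terminal exons (no flanking intron) are excluded with a reason.
#'
#' @param circles data.frame with \code{id}, \code{chrom}, \code{strand},
#'   \code{acceptor}, \code{donor}.
#' @param bundle an annotated \linkS4class{GenomeBundle}.
#' @param params a \linkS4class{CircParams}.
#' @param exclude character vector of circle ids to drop (parallel set).
#' @return \code{DataFrame}: id, eligible, reason, host transcript and the
#'   flanking intron coordinates (up_start/up_end/dn_start/dn_end) used for
#'   window construction.
#' @export
filterCirclesForClip <- function(circles, bundle, params = circParams(),
                                 exclude = character()) {
    ex <- bundle@exons
    nExPerTx <- table(as.character(ex$transcript_id))
    cdsTx <- as.character(bundle@cds$transcript_id)
    n <- nrow(circles)
    out <- data.frame(id = circles$id, eligible = FALSE,
                      reason = NA_character_, host_tx = NA_character_,
                      up_start = NA_integer_, up_end = NA_integer_,
                      dn_start = NA_integer_, dn_end = NA_integer_,
                      stringsAsFactors = FALSE)
    exChrom <- as.character(seqnames(ex))
    exStrand <- as.character(strand(ex))
    exTx <- as.character(ex$transcript_id)
    for (k in seq_len(n)) {
        ci <- circles[k, ]
        if (ci$id %in% exclude) { out$reason[k] <- "parallel_linear"; next }
        minus <- ci$strand == "-"
        accHit <- which(exChrom == ci$chrom & exStrand == ci$strand &
                        (if (minus) end(ex) == ci$acceptor
                         else start(ex) == ci$acceptor))
        donHit <- which(exChrom == ci$chrom & exStrand == ci$strand &
                        (if (minus) start(ex) == ci$donor
                         else end(ex) == ci$donor))
        hostTx <- intersect(exTx[accHit], exTx[donHit])
        if (length(hostTx) == 0L) {
            out$reason[k] <- "not_annotated"; next
        }
        # prefer the longest coding isoform, consistent with localization
        lens <- vapply(hostTx, function(t)
            sum(width(ex[exTx == t])), 0)
        coding <- hostTx %in% cdsTx
        ord <- order(!coding, -lens)
        picked <- FALSE
        for (t in hostTx[ord]) {
            accRank <- ex$exon_rank[accHit[exTx[accHit] == t]][1L]
            donRank <- ex$exon_rank[donHit[exTx[donHit] == t]][1L]
            nE <- as.integer(nExPerTx[[t]])
            if (accRank <= 1L || donRank >= nE) next  # terminal exon
            up <- bundle@introns[bundle@introns$transcript_id == t &
                                     bundle@introns$intron_rank ==
                                     accRank - 1L]
            dn <- bundle@introns[bundle@introns$transcript_id == t &
                                     bundle@introns$intron_rank == donRank]
            if (length(up) != 1L || length(dn) != 1L) next
            out$host_tx[k] <- t
            out$up_start[k] <- start(up); out$up_end[k] <- end(up)
            out$dn_start[k] <- start(dn); out$dn_end[k] <- end(dn)
            picked <- TRUE
            break
        }
        if (!picked) { out$reason[k] <- "terminal_exon"; next }
        if ((out$up_end[k] - out$up_start[k] + 1L) < params@minFlankIntron ||
            (out$dn_end[k] - out$dn_start[k] + 1L) < params@minFlankIntron) {
            out$reason[k] <- "short_flanking_intron"; next
        }
        out$eligible[k] <- TRUE
    }
    res <- DataFrame(out)
    S4Vectors::metadata(res)$circles <- circles
    res
}

#' Flanking intronic windows around a circle's back-splice sites
#'
#' Window 1 covers up to \code{width} nt of the upstream flanking intron
#' immediately 5' of the acceptor (transcription order); window 2 up to
#' \code{width} nt of the downstream intron immediately 3' of the donor.
#' Windows are clipped to their intron and are strand-aware (on the minus
#' strand, "upstream" is genomically rightward).
#'
#' @param elig eligibility table from \code{\link{filterCirclesForClip}}
#'   (eligible rows only are used).
#' @param width window width in nt.
#' @return \code{GRanges} with metadata \code{circ_id} and \code{side}
#'   (\code{"up"}/\code{"dn"}), two rows per eligible circle.
#' @export
flankingWindows <- function(elig, width) {
    circles <- S4Vectors::metadata(elig)$circles
    rows <- which(elig$eligible)
    if (length(rows) == 0L)
        return(GRanges(circ_id = character(), side = character()))
    chrom <- character(); st <- integer(); en <- integer()
    str <- character(); cid <- character(); side <- character()
    for (k in rows) {
        ci <- circles[match(elig$id[k], circles$id), ]
        minus <- ci$strand == "-"
        if (!minus) {
            up <- c(max(elig$up_start[k], ci$acceptor - width),
                    ci$acceptor - 1L)
            dn <- c(ci$donor + 1L,
                    min(elig$dn_end[k], ci$donor + width))
        } else {
            up <- c(ci$acceptor + 1L,
                    min(elig$up_end[k], ci$acceptor + width))
            dn <- c(max(elig$dn_start[k], ci$donor - width),
                    ci$donor - 1L)
        }
        chrom <- c(chrom, rep(ci$chrom, 2L))
        st <- c(st, up[1L], dn[1L]); en <- c(en, up[2L], dn[2L])
        str <- c(str, rep(ci$strand, 2L))
        cid <- c(cid, rep(elig$id[k], 2L)); side <- c(side, "up", "dn")
    }
    GRanges(chrom, IRanges(st, en), strand = str, circ_id = cid,
            side = side)
}

#' Call circles bound by a binding site
#'
#' A circle is bound when at least one merged binding site overlaps (by at
#' least one base, same strand when both carry strand) at least one of its
#' two flanking windows.
#'
#' @param windows \code{GRanges} from \code{\link{flankingWindows}}.
#' @param sites merged binding sites from \code{\link{mergeReplicatePeaks}}.
#' @param strandAware require strand match (default TRUE; \code{*} matches
#'   either).
#' @return named logical vector over the circle ids present in
#'   \code{windows}.
#' @export
boundCall <- function(windows, sites, strandAware = TRUE) {
    ids <- unique(windows$circ_id)
    if (length(ids) == 0L) return(stats::setNames(logical(), character()))
    ov <- GenomicRanges::countOverlaps(windows, sites,
                                       ignore.strand = !strandAware) > 0L
    hit <- tapply(ov, windows$circ_id, any)
    stats::setNames(as.logical(hit[ids]), ids)
}

#' Binding enrichment in deregulated versus unaffected circles
#'
#' Splits the eligible circles into deregulated (DE p-value below
#' \code{deCutoff}) and unaffected (the rest), crosses with the bound call,
#' and tests the 2x2 table with a Pearson chi-squared (1 df), by default
#' without continuity correction.
#'
#' @param deP named numeric, DE p-values for the eligible circles.
#' @param bound named logical, bound calls for the same circles.
#' @param deCutoff deregulation p-value cutoff.
#' @param yates apply the continuity correction.
#' @return one-row data.frame: cutoff, group sizes, bound counts and
#'   fractions, statistic and p-value (NA with a warning when a stratum is
#'   empty).
#' @export
enrichmentTest <- function(deP, bound, deCutoff, yates = FALSE) {
    ids <- intersect(names(deP), names(bound))
    deP <- deP[ids]; bound <- bound[ids]
    ok <- !is.na(deP) & !is.na(bound)
    deP <- deP[ok]; bound <- bound[ok]
    dereg <- deP < deCutoff
    row <- data.frame(cutoff = deCutoff,
                      n_dereg = sum(dereg), n_unaff = sum(!dereg),
                      bound_dereg = sum(bound[dereg]),
                      bound_unaff = sum(bound[!dereg]),
                      frac_dereg = NA_real_, frac_unaff = NA_real_,
                      statistic = NA_real_, pvalue = NA_real_)
    if (row$n_dereg == 0L || row$n_unaff == 0L) {
        warning("empty stratum at DE cutoff ", deCutoff)
        return(row)
    }
    row$frac_dereg <- row$bound_dereg / row$n_dereg
    row$frac_unaff <- row$bound_unaff / row$n_unaff
    tab <- matrix(c(row$bound_dereg, row$n_dereg - row$bound_dereg,
                    row$bound_unaff, row$n_unaff - row$bound_unaff),
                  nrow = 2L)
    if (any(rowSums(tab) == 0L)) {
        warning("degenerate 2x2 table at DE cutoff ", deCutoff)
        return(row)
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    row$statistic <- unname(ct$statistic)
    row$pvalue <- ct$p.value
    row
}

#' Enrichment grid over window widths and DE cutoffs
#'
#' Recomputes flanking windows and bound calls for every width in
#' \code{windowWidths} and runs \code{\link{enrichmentTest}} at every
#' cutoff in \code{stratCutoffs}.
#'
#' @param elig eligibility table from \code{\link{filterCirclesForClip}}.
#' @param sites merged binding sites.
#' @param deP named numeric DE p-values for circles.
#' @param params a \linkS4class{CircParams}.
#' @param strandAware strand-aware bound calls.
#' @return data.frame, one row per width x cutoff.
#' @export
enrichmentGrid <- function(elig, sites, deP, params = circParams(),
                           strandAware = TRUE) {
    rows <- lapply(params@windowWidths, function(w) {
        win <- flankingWindows(elig, w)
        bnd <- boundCall(win, sites, strandAware)
        do.call(rbind, lapply(params@stratCutoffs, function(cut) {
            r <- enrichmentTest(deP, bnd, cut, params@yatesCorrection)
            cbind(width = w, r)
        }))
    })
    do.call(rbind, rows)
}
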