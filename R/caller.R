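#' Remove contaminant read pairs
#'
#' Read pairs with either mate matching a contaminant sequence end-to-end
#' (either strand, at most \code{maxMismatch} substitutions) are removed,
#' emulating the abundant-ncRNA prefilter applied before circRNA detection.
#'
#' @param pairs list with \code{R1} and \code{R2} \code{DNAStringSet}s of
#'   equal length and matching names.
#' @param contaminants \code{DNAStringSet} of contaminant sequences (may be
#'   empty, in which case the input is returned unchanged).
#' @param maxMismatch substitution tolerance (default 0 = exact).
#' @return list with filtered \code{pairs} and \code{removed}, the number of
#'   pairs dropped.
#' @export
filterContaminants <- function(pairs, contaminants, maxMismatch = 0L) {
    n <- length(pairs$R1)
    if (length(contaminants) == 0L || n == 0L)
        return(list(pairs = pairs, removed = 0L))
    hit1 <- .mapsContiguously(pairs$R1, contaminants, maxMismatch)
    hit2 <- .mapsContiguously(pairs$R2, contaminants, maxMismatch)
    drop <- hit1 | hit2
    list(pairs = list(R1 = pairs$R1[!drop], R2 = pairs$R2[!drop]),
         removed = sum(drop))
}

#' Remove mates that map contiguously to the genome
#'
#' Mates aligning full-length (either strand, at most \code{maxMismatch}
#' substitutions) anywhere in the genome are discarded; the survivors are
#' the candidate junction-spanning reads.
#'
#' @param mates \code{DNAStringSet} of reads (both mates pooled; names keep
#'   their identity).
#' @param bundle a \linkS4class{GenomeBundle}.
#' @param maxMismatch substitution tolerance (default 0 = exact).
#' @return list with \code{mates} (survivors) and \code{removed} count.
#' @export
filterLinearMappers <- function(mates, bundle, maxMismatch = 0L) {
    if (length(mates) == 0L)
        return(list(mates = mates, removed = 0L))
    hit <- .mapsContiguously(mates, bundle@seqs, maxMismatch)
    list(mates = mates[!hit], removed = sum(hit))
}

## TRUE for each read with a full-length match (either strand) in any
## subject.  Seed-and-verify at toy scale: exact seed hits of the read's
## first bases locate candidates, which are verified full-length with at
## most maxMismatch substitutions (exact matching when maxMismatch = 0).
.mapsContiguously <- function(reads, subjects, maxMismatch = 0L,
                              seedLen = 20L) {
    n <- length(reads)
    hit <- logical(n)
    if (n == 0L || length(subjects) == 0L) return(hit)
    subjRaw <- lapply(as.character(subjects), charToRaw)
    orientations <- list(as.character(reads),
                         .rcChar(as.character(reads)))
    for (ori in orientations) {
        todo <- which(!hit & nchar(ori) >= seedLen)
        if (length(todo) == 0L) next
        seeds <- substr(ori[todo], 1L, seedLen)
        useeds <- unique(seeds)
        pd <- Biostrings::PDict(DNAStringSet(useeds))
        seedIdx <- match(seeds, useeds)
        byseed <- split(todo, seedIdx)
        for (s in seq_along(subjRaw)) {
            m <- Biostrings::matchPDict(pd, subjects[[s]])
            st <- Biostrings::startIndex(m)
            slen <- length(subjRaw[[s]])
            for (u in seq_along(useeds)) {
                pos <- st[[u]]
                if (is.null(pos) || length(pos) == 0L) next
                ri <- byseed[[as.character(u)]]
                if (is.null(ri)) next
                for (i in ri) {
                    if (hit[i]) next
                    w <- nchar(ori[i])
                    rRaw <- charToRaw(ori[i])
                    for (p in pos) {
                        if (p + w - 1L > slen) next
                        mm <- sum(rRaw != subjRaw[[s]][p:(p + w - 1L)])
                        if (mm <= maxMismatch) { hit[i] <- TRUE; break }
                    }
                }
            }
        }
    }
    hit
}

## fast character-level reverse complement
.rcChar <- function(x)
    vapply(x, function(s)
        rawToChar(rev(charToRaw(chartr("ACGTNacgtn", "TGCANtgcan", s)))),
        "", USE.NAMES = FALSE)

#' Produce terminal anchors from reads
#'
#' @param reads \code{DNAStringSet}; reads shorter than
#'   \code{2 * anchorLen} are skipped (their index is reported in the
#'   \code{skipped} attribute).
#' @param anchorLen anchor length in nt (default 20).
#' @return list with \code{anchor5} (first \code{anchorLen} bases),
#'   \code{anchor3} (last \code{anchorLen} bases) and \code{kept} indices.
#' @export
makeAnchors <- function(reads, anchorLen = 20L) {
    keep <- width(reads) >= 2L * anchorLen
    if (any(!keep))
        message(sum(!keep), " reads shorter than 2 x anchor length skipped")
    r <- reads[keep]
    list(anchor5 = subseq(r, 1L, anchorLen),
         anchor3 = subseq(r, width(r) - anchorLen + 1L, width(r)),
         kept = which(keep))
}

#' Align anchors exactly to the genome
#'
#' Returns every exact placement of each anchor on both strands.  A minus
#' hit at position p means the reverse complement of the anchor matches the
#' forward sequence starting at p.  Placement multiplicity (total over both
#' strands) downstream stands in for mapping quality: an anchor is
#' "high quality" when it has exactly one placement.
#'
#' @param bundle a \linkS4class{GenomeBundle}.
#' @param anchors \code{DNAStringSet} of equal-width anchors.
#' @return list with \code{hits}, a per-unique-sequence list of
#'   data.frames (\code{chrom}, \code{start}, \code{strand}), \code{key},
#'   mapping each input anchor to its entry in \code{hits}, and \code{mult},
#'   the per-unique-sequence total placement count.
#' @export
alignAnchors <- function(bundle, anchors) {
    useq <- unique(as.character(anchors))
    rcseq <- .rcChar(useq)
    idx <- .anchorIndex(bundle, unique(c(useq, rcseq)))
    hits <- vector("list", length(useq))
    mult <- integer(length(useq))
    for (k in seq_along(useq)) {
        fw <- .anchorHits(idx, useq[k])
        rv <- .anchorHits(idx, rcseq[k])
        h <- data.frame(
            chrom = c(fw$chrom, rv$chrom),
            start = c(fw$start, rv$start),
            strand = rep(c("+", "-"), c(length(fw$start),
                                        length(rv$start))),
            stringsAsFactors = FALSE)
        hits[[k]] <- if (nrow(h)) h else NULL
        mult[k] <- nrow(h)
    }
    names(hits) <- useq
    list(hits = hits, key = match(as.character(anchors), useq), mult = mult)
}

## forward-strand exact placement index for a set of equal-width sequences:
## parallel chrom/start vectors per sequence, assembled without per-pattern
## data frames (the hot path of the caller)
.anchorIndex <- function(bundle, seqs) {
    pd <- Biostrings::PDict(DNAStringSet(seqs))
    chromAll <- character(); startAll <- integer(); idxAll <- integer()
    for (chrom in names(bundle@seqs)) {
        m <- Biostrings::matchPDict(pd, bundle@seqs[[chrom]])
        st <- Biostrings::startIndex(m)
        ln <- vapply(st, length, 0L)
        if (sum(ln) == 0L) next
        idxAll <- c(idxAll, rep(seq_along(seqs), ln))
        startAll <- c(startAll, unlist(st[ln > 0L], use.names = FALSE))
        chromAll <- c(chromAll, rep(chrom, sum(ln)))
    }
    grp <- factor(idxAll, levels = seq_along(seqs))
    list(seqs = seqs,
         chrom = split(chromAll, grp),
         start = split(startAll, grp),
         count = as.integer(table(grp)))
}

.anchorHits <- function(idx, s) {
    k <- match(s, idx$seqs)
    if (is.na(k)) return(list(chrom = character(), start = integer()))
    list(chrom = idx$chrom[[k]], start = idx$start[[k]])
}

#' Extend anchors across a putative splice breakpoint
#'
#' Given one oriented read (the read itself for a plus-strand candidate, its
#' reverse complement for minus) whose terminal anchors matched the forward
#' genome at \code{leftStart} and \code{rightStart}, every split of the
#' unanchored middle is scored: a breakpoint is accepted when both pieces
#' match the genome adjacent to their anchors with minimal mismatches
#' (\code{<= maxMismatch}) and the genomic dinucleotides flanking the
#' junction are the donor/acceptor signals (GT/AG) on the read's strand.
#' Among equal-mismatch signal-consistent breakpoints the genomically
#' leftmost is chosen.  The junction is circular when the acceptor lies
#' upstream of the donor in transcription order (head-to-tail), linear
#' otherwise.
#'
#' @param orientedRead character or \code{DNAString}, the oriented read.
#' @param leftStart,rightStart forward-genome start positions of the
#'   oriented read's first and last anchor.
#' @param chromSeq \code{DNAString} of the chromosome.
#' @param chrom chromosome name.
#' @param strandLabel \code{"+"} or \code{"-"}.
#' @param params a \linkS4class{CircParams}.
#' @return one-row data.frame (chrom, strand, acceptor, donor, kind,
#'   mismatches) or \code{NULL} when no signal-consistent breakpoint exists.
#' @export
extendBreakpoint <- function(orientedRead, leftStart, rightStart, chromSeq,
                             chrom, strandLabel, params) {
    sRaw <- charToRaw(as.character(orientedRead))
    chromRaw <- charToRaw(as.character(chromSeq))
    sig <- .signalBytes(params)
    hit <- .extendFast(sRaw, params@anchorLen, leftStart, rightStart,
                       chromRaw, strandLabel, sig, params@maxMismatch)
    if (is.null(hit)) return(NULL)
    data.frame(chrom = chrom, strand = strandLabel,
               acceptor = hit$acceptor, donor = hit$donor, kind = hit$kind,
               mismatches = hit$mismatches, stringsAsFactors = FALSE)
}

## splice-signal bytes: donor/acceptor and their reverse complements
.signalBytes <- function(params) {
    rc <- function(x) as.character(reverseComplement(
        Biostrings::DNAString(x)))
    list(don = charToRaw(params@donorSignal),
         acc = charToRaw(params@acceptorSignal),
         rcDon = charToRaw(rc(params@donorSignal)),
         rcAcc = charToRaw(rc(params@acceptorSignal)))
}

## raw-byte breakpoint scorer; see extendBreakpoint for the contract
.extendFast <- function(sRaw, a, leftStart, rightStart, chromRaw,
                        strandLabel, sig, maxMismatch) {
    L <- length(sRaw)
    M <- L - 2L * a
    if (M < 0L) return(NULL)
    leftEnd <- leftStart + a - 1L
    clen <- length(chromRaw)
    # out-of-bounds genomic positions read as a 0x00 pad byte, which can
    # never match a base or a splice signal; negative positions are mapped
    # onto the pad as well, so breakpoints near sequence ends stay scorable
    at <- function(pos) {
        pos[pos < 1L] <- clen + 1L
        chromRaw[pos]
    }
    if (M > 0L) {
        mid <- sRaw[(a + 1L):(a + M)]
        leftG <- at((leftEnd + 1L):(leftEnd + M))
        rightG <- at((rightStart - M):(rightStart - 1L))
        dl <- as.integer(mid != leftG)
        dr <- as.integer(mid != rightG)
        mm <- c(0L, cumsum(dl)) + rev(c(0L, cumsum(rev(dr))))
    } else mm <- 0L
    b <- 0:M
    leftBound <- leftEnd + b            # last genomic base, left piece
    rightBound <- rightStart - (M - b)  # first genomic base, right piece
    after1 <- at(leftBound + 1L)
    after2 <- at(leftBound + 2L)
    before1 <- at(rightBound - 2L)
    before2 <- at(rightBound - 1L)
    if (strandLabel == "+") {
        ok <- after1 == sig$don[1L] & after2 == sig$don[2L] &
            before1 == sig$acc[1L] & before2 == sig$acc[2L]
        donor <- leftBound
        acceptor <- rightBound
    } else {
        # on the minus strand the forward genome shows the reverse
        # complements, with the acceptor on the left side of the match
        ok <- after1 == sig$rcAcc[1L] & after2 == sig$rcAcc[2L] &
            before1 == sig$rcDon[1L] & before2 == sig$rcDon[2L]
        acceptor <- leftBound
        donor <- rightBound
    }
    ok <- ok & mm <= maxMismatch
    if (!any(ok)) return(NULL)
    cand <- which(ok)
    best <- cand[which.min(mm[cand])]
    A <- acceptor[best]; D <- donor[best]
    circular <- if (strandLabel == "+") A < D else A > D
    list(acceptor = A, donor = D,
         kind = if (circular) "circular" else "linear",
         mismatches = mm[best])
}

#' Call junctions from candidate reads of one sample
#'
#' Runs anchor production, exact anchor alignment and breakpoint extension
#' for every surviving mate, trying both orientations (the read as given =
#' plus strand, its reverse complement = minus).  For each mate the
#' minimal-mismatch junction across all compatible anchor placements is
#' reported; ties prefer the plus orientation and then genomic order of the
#' placements.
#'
#' @param mates \code{DNAStringSet} of candidate junction-spanning reads.
#' @param bundle a \linkS4class{GenomeBundle}.
#' @param params a \linkS4class{CircParams}.
#' @param maxPlacements anchors with more placements than this are not
#'   paired exhaustively (the read is skipped; multiplicity still recorded).
#' @return data.frame of junction events: read, seq, chrom, strand,
#'   acceptor, donor, kind, mismatches, qual (both anchors uniquely placed).
#' @export
callJunctions <- function(mates, bundle, params, maxPlacements = 8L) {
    if (length(mates) == 0L) return(.emptyEvents())
    a <- params@anchorLen
    anch <- makeAnchors(mates, a)
    mates <- mates[anch$kept]
    if (length(mates) == 0L) return(.emptyEvents())
    rcMates <- reverseComplement(mates)
    readSeqs <- as.character(mates)
    rcSeqs <- as.character(rcMates)
    # oriented reads: plus = read, minus = revcomp(read); the left/right
    # anchors of each oriented read are aligned to the forward genome
    a5 <- substr(readSeqs, 1L, a)
    a3 <- substr(readSeqs, nchar(readSeqs) - a + 1L, nchar(readSeqs))
    rc5 <- substr(rcSeqs, 1L, a)                      # = revcomp(a3)
    rc3 <- substr(rcSeqs, nchar(rcSeqs) - a + 1L, nchar(rcSeqs))
    # forward-strand placements of every oriented anchor (minus-strand
    # hits of an anchor are the forward hits of its reverse complement,
    # already in the set); multiplicity = both-strand placement count
    allAnch <- unique(c(a5, a3, rc5, rc3))
    idx <- .anchorIndex(bundle, allAnch)
    i5 <- match(a5, allAnch); i3 <- match(a3, allAnch)
    j5 <- match(rc5, allAnch); j3 <- match(rc3, allAnch)
    mult <- idx$count + idx$count[match(.rcChar(allAnch), allAnch)]
    qual <- mult[i5] == 1L & mult[i3] == 1L

    chromRaw <- lapply(as.character(bundle@seqs), charToRaw)
    sig <- .signalBytes(params)
    n <- length(mates)
    rChrom <- character(n); rStrand <- character(n)
    rAcc <- integer(n); rDon <- integer(n); rKind <- character(n)
    rMM <- integer(n); found <- logical(n)
    for (i in seq_len(n)) {
        bestMM <- params@maxMismatch + 1L
        for (orient in c("+", "-")) {
            if (orient == "+") {
                os <- readSeqs[i]; kl <- i5[i]; kr <- i3[i]
            } else {
                os <- rcSeqs[i]; kl <- j5[i]; kr <- j3[i]
            }
            hlChrom <- idx$chrom[[kl]]; hlStart <- idx$start[[kl]]
            hrChrom <- idx$chrom[[kr]]; hrStart <- idx$start[[kr]]
            nl <- length(hlStart); nr <- length(hrStart)
            if (nl == 0L || nr == 0L) next
            if (nl > maxPlacements || nr > maxPlacements) next
            osRaw <- charToRaw(os)
            for (p in seq_len(nl)) for (q in seq_len(nr)) {
                if (hlChrom[p] != hrChrom[q]) next
                ev <- .extendFast(osRaw, a, hlStart[p], hrStart[q],
                                  chromRaw[[hlChrom[p]]], orient, sig,
                                  params@maxMismatch)
                if (!is.null(ev) && ev$mismatches < bestMM) {
                    bestMM <- ev$mismatches
                    found[i] <- TRUE
                    rChrom[i] <- hlChrom[p]; rStrand[i] <- orient
                    rAcc[i] <- ev$acceptor; rDon[i] <- ev$donor
                    rKind[i] <- ev$kind; rMM[i] <- ev$mismatches
                }
            }
        }
    }
    if (!any(found)) return(.emptyEvents())
    data.frame(read = names(mates)[found], seq = readSeqs[found],
               chrom = rChrom[found], strand = rStrand[found],
               acceptor = rAcc[found], donor = rDon[found],
               kind = rKind[found], mismatches = rMM[found],
               qual = qual[found], stringsAsFactors = FALSE)
}

.emptyEvents <- function()
    data.frame(read = character(), seq = character(), chrom = character(),
               strand = character(), acceptor = integer(),
               donor = integer(), kind = character(),
               mismatches = integer(), qual = logical(),
               stringsAsFactors = FALSE)

#' Aggregate junction events and apply the published per-sample filters
#'
#' Events (possibly from several samples; column \code{sample} required)
#' are grouped by (chrom, strand, acceptor, donor, kind); per sample the
#' read count and the unique-read count (distinct mate sequences) are
#' computed.  A circular junction passes in a sample when it has at least
#' \code{minUniqReads} unique reads there, its span is below \code{maxSpan},
#' every supporting read has both anchors uniquely placed, and it does not
#' span two non-overlapping genes; junctions passing in at least one sample
#' are retained (per-sample filtering, then merging, as published).  Linear
#' junctions are aggregated without filtering.
#'
#' @param events data.frame from \code{\link{callJunctions}} with an added
#'   \code{sample} column.
#' @param bundle a \linkS4class{GenomeBundle}.
#' @param params a \linkS4class{CircParams}.
#' @return list with \code{circular} and \code{linear} data.frames (one row
#'   per junction; count and unique-count matrices in attributes
#'   \code{counts} and \code{uniq} keyed by junction id), where
#'   \code{circular} carries the filter columns and \code{kept} flag.
#' @export
aggregateJunctions <- function(events, bundle, params) {
    stopifnot("sample" %in% names(events))
    samples <- sort(unique(events$sample))
    build <- function(ev) {
        if (nrow(ev) == 0L)
            return(list(tab = data.frame(), counts = NULL, uniq = NULL))
        key <- paste(ev$chrom, ev$strand, ev$acceptor, ev$donor, sep = ":")
        ids <- sort(unique(key))
        cnt <- matrix(0L, length(ids), length(samples),
                      dimnames = list(ids, samples))
        unq <- cnt
        spl <- split(seq_len(nrow(ev)), key)
        qualAll <- logical(length(ids))
        names(qualAll) <- ids
        for (id in ids) {
            rows <- spl[[id]]
            qualAll[id] <- all(ev$qual[rows])
            bySample <- split(rows, ev$sample[rows])
            for (s in names(bySample)) {
                cnt[id, s] <- length(bySample[[s]])
                unq[id, s] <- length(unique(ev$seq[bySample[[s]]]))
            }
        }
        first <- ev[match(ids, key), c("chrom", "strand", "acceptor",
                                       "donor", "kind")]
        first$junction_id <- ids
        first$span <- abs(first$donor - first$acceptor)
        first$qual <- qualAll
        rownames(first) <- NULL
        list(tab = first, counts = cnt, uniq = unq)
    }
    circ <- build(events[events$kind == "circular", , drop = FALSE])
    lin <- build(events[events$kind == "linear", , drop = FALSE])
    if (nrow(circ$tab)) {
        tab <- circ$tab
        tab$multi_locus <- .spansNonOverlappingGenes(
            bundle, tab$chrom, tab$strand,
            pmin(tab$acceptor, tab$donor), pmax(tab$acceptor, tab$donor),
            strandAware = params@strandAwareGenes)
        passSample <- circ$uniq >= params@minUniqReads
        tab$n_samples_pass <- as.integer(rowSums(passSample))
        tab$kept <- tab$n_samples_pass >= 1L &
            tab$span < params@maxSpan &
            tab$qual &
            !tab$multi_locus
        circ$tab <- tab
    }
    circTab <- circ$tab
    attr(circTab, "counts") <- circ$counts
    attr(circTab, "uniq") <- circ$uniq
    linTab <- lin$tab
    attr(linTab, "counts") <- lin$counts
    attr(linTab, "uniq") <- lin$uniq
    list(circular = circTab, linear = linTab)
}

#' Count linear reads across the two back-splice coordinates
#'
#' For each circular junction, sums the reads supporting linear splicing
#' across the back-splice acceptor (linear junctions sharing that acceptor)
#' and across the back-splice donor (linear junctions sharing that donor);
#' optional contiguous alignments spanning either coordinate are added.
#'
#' @param circTab circular junction table from
#'   \code{\link{aggregateJunctions}}.
#' @param linTab linear junction table from the same call.
#' @param alignments optional \code{GRanges} of contiguous alignments (with
#'   a \code{sample} metadata column) counted when they cover a coordinate
#'   with at least \code{minOverhang} bases on each side.
#' @param minOverhang minimum overhang for contiguous coverage (default 5).
#' @return integer matrix, circular junctions x samples.
#' @export
countLinearAtBacksplice <- function(circTab, linTab, alignments = NULL,
                                    minOverhang = 5L) {
    linCounts <- attr(linTab, "counts")
    samples <- colnames(attr(circTab, "counts"))
    if (is.null(samples)) samples <- colnames(linCounts)
    out <- matrix(0, nrow(circTab), length(samples),
                  dimnames = list(circTab$junction_id, samples))
    if (nrow(circTab) == 0L) {
        storage.mode(out) <- "integer"
        return(out)
    }
    for (i in seq_len(nrow(circTab))) {
        if (nrow(linTab)) {
            sameAcc <- linTab$chrom == circTab$chrom[i] &
                linTab$strand == circTab$strand[i] &
                linTab$acceptor == circTab$acceptor[i]
            sameDon <- linTab$chrom == circTab$chrom[i] &
                linTab$strand == circTab$strand[i] &
                linTab$donor == circTab$donor[i]
            sel <- sameAcc | sameDon
            if (any(sameAcc))
                out[i, ] <- out[i, ] +
                    colSums(linCounts[sameAcc, , drop = FALSE])
            if (any(sameDon))
                out[i, ] <- out[i, ] +
                    colSums(linCounts[sameDon, , drop = FALSE])
        }
        if (!is.null(alignments) && length(alignments)) {
            for (coord in c(circTab$acceptor[i], circTab$donor[i])) {
                cov <- as.character(seqnames(alignments)) ==
                    circTab$chrom[i] &
                    start(alignments) <= coord - minOverhang &
                    end(alignments) >= coord + minOverhang
                if (any(cov)) {
                    tt <- table(alignments$sample[cov])
                    out[i, names(tt)] <- out[i, names(tt)] +
                        as.integer(tt)
                }
            }
        }
    }
    storage.mode(out) <- "integer"
    out
}

#' Detect junctions in one sample end to end
#'
#' Applies the contaminant prefilter to read pairs, pools the mates, removes
#' contiguously mapping mates, and calls junction events on the survivors.
#' Per-stage read accounting is returned for the run report.
#'
#' @param pairs list with \code{R1}/\code{R2} \code{DNAStringSet}s.
#' @param bundle a \linkS4class{GenomeBundle}.
#' @param params a \linkS4class{CircParams}.
#' @param contaminants optional \code{DNAStringSet}.
#' @param prefilterMismatch substitution tolerance of both prefilters.
#' @return list with \code{events} (data.frame) and \code{report} (named
#'   integer vector of stage counts).
#' @export
detectSample <- function(pairs, bundle, params, contaminants = NULL,
                         prefilterMismatch = 0L) {
    nIn <- length(pairs$R1)
    if (is.null(contaminants)) contaminants <- DNAStringSet()
    fc <- filterContaminants(pairs, contaminants, prefilterMismatch)
    mates <- c(fc$pairs$R1, fc$pairs$R2)
    names(mates) <- c(paste0(names(fc$pairs$R1), "/1"),
                      paste0(names(fc$pairs$R2), "/2"))
    fl <- filterLinearMappers(mates, bundle, prefilterMismatch)
    events <- callJunctions(fl$mates, bundle, params)
    report <- c(input_pairs = nIn,
                contaminant_pairs = fc$removed,
                pairs_after_contaminant = nIn - fc$removed,
                mates_in = length(mates),
                linear_mapper_mates = fl$removed,
                candidate_mates = length(fl$mates),
                backsplice_reads = sum(events$kind == "circular"),
                linear_splice_reads = sum(events$kind == "linear"))
    list(events = events, report = report)
}
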