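# Independent oracles: deliberately naive implementations used to check the
# package's optimised code paths.

# reverse complement by explicit lookup
oracleRevComp <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force breakpoint scorer: enumerates every split of the unanchored
# middle, counts mismatches character by character, applies the GT/AG rule
# literally, and picks minimal mismatches with the leftmost tie-break.
oracleBreakpoint <- function(orientedRead, leftStart, rightStart, chromChar,
                             strandLabel, anchorLen = 20L, maxMismatch = 2L) {
    L <- nchar(orientedRead)
    M <- L - 2L * anchorLen
    leftEnd <- leftStart + anchorLen - 1L
    if (leftEnd + M + 2L > nchar(chromChar) || rightStart - M - 2L < 1L)
        return(NULL)
    best <- NULL
    for (b in 0:M) {
        mm <- 0L
        if (b > 0) {
            readPart <- substr(orientedRead, anchorLen + 1L, anchorLen + b)
            genomePart <- substr(chromChar, leftEnd + 1L, leftEnd + b)
            mm <- mm + sum(strsplit(readPart, "")[[1]] !=
                               strsplit(genomePart, "")[[1]])
        }
        if (b < M) {
            readPart <- substr(orientedRead, anchorLen + b + 1L, L - anchorLen)
            genomePart <- substr(chromChar, rightStart - (M - b),
                                 rightStart - 1L)
            mm <- mm + sum(strsplit(readPart, "")[[1]] !=
                               strsplit(genomePart, "")[[1]])
        }
        if (mm > maxMismatch) next
        leftBound <- leftEnd + b
        rightBound <- rightStart - (M - b)
        after <- substr(chromChar, leftBound + 1L, leftBound + 2L)
        before <- substr(chromChar, rightBound - 2L, rightBound - 1L)
        if (strandLabel == "+") {
            if (after != "GT" || before != "AG") next
            donor <- leftBound; acceptor <- rightBound
        } else {
            if (after != oracleRevComp("AG") ||
                before != oracleRevComp("GT")) next
            acceptor <- leftBound; donor <- rightBound
        }
        if (is.null(best) || mm < best$mismatches) {
            circular <- if (strandLabel == "+") acceptor < donor
                        else acceptor > donor
            best <- list(acceptor = acceptor, donor = donor,
                         kind = if (circular) "circular" else "linear",
                         mismatches = mm)
        }
    }
    best
}

# dense 1-D grid search for the NB group-mean MLE (groups are separable)
oracleNbGroupLogLik <- function(y, N, phi) {
    if (sum(y) == 0) return(0)
    center <- log(sum(y) / sum(N))
    betas <- seq(center - 0.3, center + 0.3, length.out = 20001L)
    ll <- vapply(betas, function(b) {
        mu <- exp(b) * N
        if (phi == 0) sum(dpois(y, mu, log = TRUE))
        else sum(dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
    }, 0)
    max(ll)
}

# chi-squared(1) survival function via the normal tail (erfc identity)
oracleChisq1Surv <- function(x) 2 * pnorm(-sqrt(x))

# Pearson statistic of a 2x2 table by the closed-form identity
oraclePearson2x2 <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
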