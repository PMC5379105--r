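## Negative-binomial log-likelihood with mean mu and dispersion phi
## (phi = 0 is the Poisson limit).  Vectorised over matrices.
.nbLogLik <- function(y, mu, phi) {
    if (phi == 0) return(sum(stats::dpois(y, pmax(mu, 1e-300), log = TRUE)))
    sum(stats::dnbinom(y, mu = pmax(mu, 1e-300), size = 1 / phi, log = TRUE))
}

## Maximum-likelihood group means for an NB GLM with log link and
## library-size offsets, vectorised over features (rows).
## Model: mu_ij = m_i * N_j for the columns `cols`; Fisher scoring on
## beta = log m.  Features whose selected counts are all zero get m = 0.
.fitGroupMeans <- function(Y, N, cols, phi, iter = 50L, tol = 1e-10) {
    Ys <- Y[, cols, drop = FALSE]
    Ns <- N[cols]
    rs <- rowSums(Ys)
    m <- rs / sum(Ns)
    zero <- rs == 0
    beta <- log(pmax(m, 1e-8))
    Nm <- matrix(Ns, nrow(Ys), length(Ns), byrow = TRUE)
    for (it in seq_len(iter)) {
        mu <- exp(beta) * Nm
        wden <- 1 + phi * mu
        U <- rowSums((Ys - mu) / wden)
        I <- rowSums(mu / wden)
        step <- U / pmax(I, 1e-12)
        step <- pmin(pmax(step, -5), 5)
        beta <- beta + step
        if (max(abs(step[!zero]), 0) < tol) break
    }
    m <- exp(beta)
    m[zero] <- 0
    m
}

## per-feature log-likelihood at the fitted group means
.rowLogLik <- function(Y, N, mu_per_sample, phi) {
    if (phi == 0)
        ll <- stats::dpois(Y, pmax(mu_per_sample, 1e-300), log = TRUE)
    else
        ll <- stats::dnbinom(Y, mu = pmax(mu_per_sample, 1e-300),
                             size = 1 / phi, log = TRUE)
    ll[Y == 0 & mu_per_sample == 0] <- 0
    rowSums(ll)
}

## full (per-condition means) and null (shared mean) profile log-likelihoods
## for all features at a given phi
.profileLogLik <- function(Y, N, cond, phi) {
    g1 <- which(cond == levels(cond)[1L])
    g2 <- which(cond == levels(cond)[2L])
    m1 <- .fitGroupMeans(Y, N, g1, phi)
    m2 <- .fitGroupMeans(Y, N, g2, phi)
    m0 <- .fitGroupMeans(Y, N, seq_along(N), phi)
    Nm <- matrix(N, nrow(Y), length(N), byrow = TRUE)
    muFull <- Nm
    muFull[, g1] <- m1 * Nm[, g1, drop = FALSE]
    muFull[, g2] <- m2 * Nm[, g2, drop = FALSE]
    muNull <- m0 * Nm
    # Cox-Reid adjustment: 0.5 log det of the per-group Fisher information
    # at the full-model fit, used when profiling out the means to estimate
    # the dispersion (restricted-likelihood analogue)
    info <- muFull / (1 + phi * muFull)
    crAdj <- 0.5 * (log(pmax(rowSums(info[, g1, drop = FALSE]), 1e-8)) +
                    log(pmax(rowSums(info[, g2, drop = FALSE]), 1e-8)))
    list(m1 = m1, m2 = m2, m0 = m0,
         llFull = .rowLogLik(Y, N, muFull, phi),
         llNull = .rowLogLik(Y, N, muNull, phi),
         crAdj = crAdj)
}

#' Fit a two-group negative-binomial GLM for one feature
#'
#' Maximum-likelihood per-condition means under a log link with
#' library-size offsets, at fixed dispersion \code{phi} (\code{phi = 0} is
#' the Poisson limit).  The null model shares one mean across conditions.
#'
#' @param counts integer vector of counts for one feature.
#' @param condition two-level factor over the samples.
#' @param libSizes library sizes (offsets), same length as \code{counts}.
#' @param phi NB dispersion (>= 0).
#' @return list with per-condition fitted means (\code{mu1}, \code{mu2},
#'   per unit library size), the shared null mean \code{mu0},
#'   \code{log2fc} (condition 2 vs 1), and log-likelihoods \code{llFull},
#'   \code{llNull}.  All-zero features are flagged with
#'   \code{allZero = TRUE}.
#' @examples
#' fitNbGlm(c(40, 40, 40, 10, 10, 10),
#'          factor(rep(c("a", "b"), each = 3)), rep(1, 6), phi = 0.1)
#' @export
fitNbGlm <- function(counts, condition, libSizes, phi) {
    stopifnot(phi >= 0, length(counts) == length(condition),
              length(libSizes) == length(counts))
    condition <- factor(condition)
    stopifnot(nlevels(condition) == 2L)
    Y <- matrix(as.numeric(counts), nrow = 1L)
    pr <- .profileLogLik(Y, libSizes, condition, phi)
    list(mu1 = pr$m1, mu2 = pr$m2, mu0 = pr$m0,
         log2fc = log2(pmax(pr$m2, 1e-8) / pmax(pr$m1, 1e-8)),
         llFull = pr$llFull, llNull = pr$llNull,
         allZero = sum(counts) == 0)
}

#' Likelihood-ratio test from full and null fits
#'
#' LR = 2 (llFull - llNull), referred to a chi-squared distribution with
#' one degree of freedom.  Significance calls downstream use the raw
#' p-value (not FDR), matching the published analysis choice.
#'
#' @param llFull,llNull log-likelihoods of the full and null fits.
#' @param tol negative LR beyond this tolerance raises an error (failed
#'   optimisation); small negatives are clamped to zero.
#' @return list with \code{lr} and \code{pvalue}.
#' @export
lrtPvalue <- function(llFull, llNull, tol = 1e-4) {
    lr <- 2 * (llFull - llNull)
    if (any(lr < -tol))
        stop("likelihood-ratio statistic negative beyond tolerance: ",
             "numerical optimisation failure")
    lr <- pmax(lr, 0)
    list(lr = lr, pvalue = stats::pchisq(lr, df = 1L, lower.tail = FALSE))
}

#' Estimate NB dispersion: common and shrunken per-feature
#'
#' The common dispersion maximises the summed profile log-likelihood over
#' features (group means refitted at every candidate dispersion).  The
#' per-feature dispersion maximises the feature's own profile log-likelihood
#' plus \code{priorWeight} times the average profile log-likelihood across
#' features, evaluated on a dispersion grid: an infinite prior weight
#' returns the common value for every feature.
#'
#' @param counts integer matrix (features x samples).
#' @param condition two-level factor over samples.
#' @param libSizes library sizes; defaults to column sums of \code{counts}.
#' @param priorWeight shrinkage weight (default 10).
#' @param gridSize dispersion grid resolution for the per-feature step.
#' @return list with \code{common} (scalar) and \code{tagwise} (per-feature
#'   vector).  All-constant data yield dispersion 0 with a warning.
#' @export
estimateDispersion <- function(counts, condition,
                               libSizes = colSums(counts),
                               priorWeight = 10, gridSize = 21L) {
    Y <- as.matrix(counts)
    if (nrow(Y) < 2L)
        stop("need at least two features to estimate dispersion")
    condition <- factor(condition)
    keep <- rowSums(Y) > 0
    if (!any(keep)) {
        warning("all features zero; dispersion set to 0")
        return(list(common = 0, tagwise = rep(0, nrow(Y))))
    }
    Yk <- Y[keep, , drop = FALSE]
    N <- libSizes / mean(libSizes)
    apl <- function(phi) {
        pr <- .profileLogLik(Yk, N, condition, phi)
        pr$llFull - pr$crAdj
    }
    opt <- stats::optimize(function(lp) sum(apl(exp(lp))),
                           c(log(1e-4), log(4)), maximum = TRUE, tol = 1e-3)
    common <- exp(opt$maximum)
    if (sum(apl(1e-4)) >= opt$objective) common <- 0
    if (common == 0) {
        warning("no evidence of overdispersion; common dispersion 0")
        return(list(common = 0, tagwise = rep(0, nrow(Y))))
    }
    grid <- exp(seq(log(max(common / 10, 1e-4)), log(common * 10),
                    length.out = gridSize))
    llMat <- vapply(grid, apl, numeric(nrow(Yk)))
    shape <- colMeans(llMat)
    if (is.infinite(priorWeight)) {
        tw <- rep(common, nrow(Yk))
    } else {
        obj <- llMat + matrix(priorWeight * shape, nrow(Yk),
                              length(grid), byrow = TRUE)
        tw <- grid[max.col(obj, ties.method = "first")]
    }
    tagwise <- rep(common, nrow(Y))
    tagwise[keep] <- tw
    list(common = common, tagwise = tagwise)
}

#' Differential expression of circular and linear junction features
#'
#' Negative-binomial GLM likelihood-ratio test per feature, condition 2
#' versus condition 1, with library-size offsets taken from the column sums
#' of the full (circular + linear) count matrix.  Dispersion is estimated
#' from all features (common + shrunken per-feature; see
#' \code{\link{estimateDispersion}}).  Significance is intended to be judged
#' on the raw p-value at \code{deAlpha}; a Benjamini-Hochberg column is also
#' provided.
#'
#' @param x a \linkS4class{CircCountSet} (after
#'   \code{\link{expressionFilter}}).
#' @param params a \linkS4class{CircParams}.
#' @param dispersion \code{"tagwise"} (default) or \code{"common"}.
#' @return \code{DataFrame}: id, kind, pair_id, host_gene, log2fc, lr,
#'   pvalue, padj, mean c.p.m. per condition, phi.  All-zero features get
#'   NA statistics.
#' @export
testDifferentialExpression <- function(x, params = circParams(),
                                       dispersion = c("tagwise", "common")) {
    dispersion <- match.arg(dispersion)
    Y <- SummarizedExperiment::assay(x, "counts")
    rd <- SummarizedExperiment::rowData(x)
    cond <- SummarizedExperiment::colData(x)$condition
    libs <- librarySizes(x)
    N <- libs / mean(libs)
    disp <- estimateDispersion(Y, cond, libSizes = libs,
                               priorWeight = params@priorWeight)
    phis <- if (dispersion == "common") rep(disp$common, nrow(Y))
            else disp$tagwise
    cpm <- junctionCPM(x)
    g1 <- cond == levels(factor(cond))[1L]
    res <- data.frame(id = rownames(Y), kind = rd$kind,
                      pair_id = rd$pair_id, host_gene = rd$host_gene,
                      log2fc = NA_real_, lr = NA_real_, pvalue = NA_real_,
                      cpm1 = rowMeans(cpm[, g1, drop = FALSE]),
                      cpm2 = rowMeans(cpm[, !g1, drop = FALSE]),
                      phi = phis, stringsAsFactors = FALSE)
    allZero <- rowSums(Y) == 0
    for (phi in unique(phis)) {
        sel <- which(phis == phi & !allZero)
        if (!length(sel)) next
        pr <- .profileLogLik(Y[sel, , drop = FALSE], N, factor(cond), phi)
        lt <- lrtPvalue(pr$llFull, pr$llNull)
        res$log2fc[sel] <- log2(pmax(pr$m2, 1e-8) / pmax(pr$m1, 1e-8))
        res$lr[sel] <- lt$lr
        res$pvalue[sel] <- lt$pvalue
    }
    res$padj <- stats::p.adjust(res$pvalue, method = "BH")
    DataFrame(res, row.names = res$id)
}

#' Filter features by expression before testing
#'
#' Keeps features with at least \code{exprMinReads} reads in at least
#' \code{exprMinSamples} samples; a circular feature's cognate linear
#' feature is retained alongside it (and vice versa is not: linear features
#' are only carried by their circle).
#'
#' @param x a \linkS4class{CircCountSet}.
#' @param params a \linkS4class{CircParams}.
#' @return the filtered \linkS4class{CircCountSet}.
#' @export
expressionFilter <- function(x, params = circParams()) {
    Y <- SummarizedExperiment::assay(x, "counts")
    rd <- SummarizedExperiment::rowData(x)
    pass <- rowSums(Y >= params@exprMinReads) >= params@exprMinSamples
    circPass <- pass & rd$kind == "circular"
    carried <- rownames(Y) %in% rd$pair_id[circPass]
    x[circPass | carried, ]
}

#' Classify circular/linear concordance
#'
#' Applies the four-way classification of circular versus cognate linear
#' differential-expression verdicts at \code{deAlpha}; circles where both
#' are significant with fold changes of the same sign are marked
#' \emph{parallel} (the circle's change plausibly reflects host-gene
#' transcription) and listed for exclusion from downstream positional and
#' binding analyses.
#'
#' @param de DE table from \code{\link{testDifferentialExpression}}.
#' @param params a \linkS4class{CircParams}.
#' @return list with \code{records} (\code{DataFrame}: circ id, category,
#'   parallel flag) and \code{excluded} (character vector of parallel circ
#'   ids).
#' @export
classifyConcordance <- function(de, params = circParams()) {
    circ <- de[de$kind == "circular", , drop = FALSE]
    lin <- de[match(circ$pair_id, de$id), , drop = FALSE]
    if (any(is.na(lin$id)))
        stop("unpaired circular feature: ",
             circ$id[is.na(lin$id)][1L])
    a <- params@deAlpha
    cs <- !is.na(circ$pvalue) & circ$pvalue < a
    ls <- !is.na(lin$pvalue) & lin$pvalue < a
    category <- ifelse(cs & ls, "both",
                ifelse(cs, "circ-only", ifelse(ls, "linear-only", "neither")))
    parallel <- cs & ls & sign(circ$log2fc) == sign(lin$log2fc)
    rec <- DataFrame(circ_id = circ$id, circ_p = circ$pvalue,
                     linear_p = lin$pvalue, circ_log2fc = circ$log2fc,
                     linear_log2fc = lin$log2fc, category = category,
                     parallel = parallel)
    list(records = rec, excluded = circ$id[parallel])
}

#' One-sample t-test for a global fold-change shift
#'
#' Tests whether the mean of a log2 fold-change vector differs from zero
#' (two-sided), the summary used to show a general reduction of circRNA
#' expression while cognate linear transcripts stay centred.
#'
#' @param log2fc numeric vector (length >= 2, non-degenerate).
#' @return list with \code{statistic}, \code{pvalue}, \code{mean}, \code{n}.
#' @export
logfcShiftTest <- function(log2fc) {
    log2fc <- log2fc[is.finite(log2fc)]
    if (length(log2fc) < 2L)
        stop("need at least two finite fold changes")
    if (stats::sd(log2fc) == 0)
        stop("zero variance in fold changes")
    tt <- stats::t.test(log2fc, mu = 0)
    list(statistic = unname(tt$statistic), pvalue = tt$p.value,
         mean = mean(log2fc), n = length(log2fc))
}
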