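#' Validate and normalise a pipeline configuration
#'
#' Accepts a named list or a YAML file path.  Keys are either
#' \code{\link{simulationConfig}} fields or \linkS4class{CircParams}
#' constructor arguments; unknown keys are rejected and all out-of-range
#' values are reported together.  The shared \code{seed} drives every
#' source of randomness in a run.
#'
#' @param config named list or YAML path (default: all defaults).
#' @return list with \code{sim} (simulation config), \code{params}
#'   (\linkS4class{CircParams}) and \code{seed}.
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
    stopifnot(is.list(config))
    simKeys <- names(simulationConfig())
    parKeys <- names(formals(circParams))
    unknown <- setdiff(names(config), c(simKeys, parKeys))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    errors <- character()
    sim <- tryCatch(
        do.call(simulationConfig, config[intersect(names(config), simKeys)]),
        error = function(e) { errors <<- c(errors, conditionMessage(e))
                              NULL })
    params <- tryCatch({
        p <- do.call(circParams,
                     config[intersect(names(config), parKeys)])
        validObject(p)
        p
    }, error = function(e) { errors <<- c(errors, conditionMessage(e))
                             NULL })
    if (length(errors))
        stop("invalid configuration:\n", paste(errors, collapse = "\n"))
    if (!is.null(config$seed))
        params@rngSeed <- as.integer(config$seed)
    else params@rngSeed <- as.integer(sim$seed)
    list(sim = sim, params = params, seed = as.integer(sim$seed))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a genome with planted circles, counts, reads and CLIP peaks;
#' detects junctions per sample (contaminant prefilter, linear-mapper
#' prefilter, anchor-based breakpoint extension); applies the per-sample
#' circular-junction filters and merges samples; builds the circular+linear
#' count matrix; filters by expression and tests differential expression
#' with the NB GLM likelihood-ratio test; classifies circular/linear
#' concordance and tests the global fold-change shift; runs the
#' faux-circRNA localization test; and computes the CLIP binding enrichment
#' grid.  All artifacts are written under \code{outDir} with fixed names;
#' reruns with an identical configuration produce byte-identical outputs.
#'
#' @param config named list or YAML path (see \code{\link{validateConfig}}).
#' @param outDir output directory, or \code{NULL} to skip writing.
#' @return (invisibly) a list with every intermediate: bundle, truth,
#'   junctions, counts (\linkS4class{CircCountSet}), de, concordance,
#'   shift tests, localization, faux set, localization test, clip
#'   (sites, eligibility, grid) and the per-sample run \code{report}.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
    cfg <- validateConfig(config)
    sim <- cfg$sim
    params <- cfg$params

    bundle <- simulateGenome(sim)
    pc <- plantCircles(bundle, sim)
    bundle <- pc$bundle
    truth <- simulateCounts(pc$truth, sim)
    er <- emitReads(truth, bundle, sim, anchorLen = params@anchorLen)
    cp <- simulateClipPeaks(truth, bundle, sim, peakPMax = params@peakPMax)
    truth <- cp$truth

    samples <- truth@samples$sample
    events <- vector("list", length(samples))
    report <- vector("list", length(samples))
    for (s in seq_along(samples)) {
        det <- detectSample(er$reads[[samples[s]]], bundle, params,
                            contaminants = er$contaminants)
        ev <- det$events
        if (nrow(ev)) ev$sample <- samples[s]
        events[[s]] <- ev
        report[[s]] <- det$report
    }
    events <- do.call(rbind, events[vapply(events, nrow, 0L) > 0L])
    if (is.null(events)) {
        events <- cbind(.emptyEvents(), sample = character())
    }
    agg <- aggregateJunctions(events, bundle, params)
    circTab <- agg$circular
    kept <- if (nrow(circTab)) circTab[circTab$kept, , drop = FALSE]
            else circTab
    circCounts <- attr(agg$circular, "counts")
    circCounts <- circCounts[kept$junction_id, , drop = FALSE]
    keptAttr <- kept
    attr(keptAttr, "counts") <- circCounts
    linAtBs <- countLinearAtBacksplice(keptAttr, agg$linear)

    hostGenes <- vapply(seq_len(nrow(kept)), function(i) {
        g <- genesOverlapping(bundle, GRanges(
            kept$chrom[i],
            IRanges(pmin(kept$acceptor[i], kept$donor[i]),
                    pmax(kept$acceptor[i], kept$donor[i])),
            strand = kept$strand[i]),
            strandAware = params@strandAwareGenes)
        if (length(g)) as.character(g$gene_id)[1L] else NA_character_
    }, "")

    rownames(circCounts) <- kept$junction_id
    cset <- buildCountMatrix(circCounts, linAtBs,
                             truth@samples$condition, hostGene = hostGenes)
    cexpr <- expressionFilter(cset, params)
    de <- testDifferentialExpression(cexpr, params)
    conc <- classifyConcordance(de, params)
    circDE <- de[de$kind == "circular", , drop = FALSE]
    linDE <- de[de$kind == "linear", , drop = FALSE]
    shiftCirc <- tryCatch(logfcShiftTest(circDE$log2fc),
                          error = function(e) NULL)
    shiftLin <- tryCatch(logfcShiftTest(linDE$log2fc),
                         error = function(e) NULL)

    analysisIds <- setdiff(circDE$id, conc$excluded)
    circDF <- data.frame(id = analysisIds, stringsAsFactors = FALSE)
    m <- match(analysisIds, kept$junction_id)
    circDF$chrom <- kept$chrom[m]; circDF$strand <- kept$strand[m]
    circDF$acceptor <- kept$acceptor[m]; circDF$donor <- kept$donor[m]

    loc <- assignLocalization(circDF, bundle)
    locTest <- NULL; faux <- NULL
    locIncluded <- loc[loc$included, , drop = FALSE]
    if (nrow(locIncluded) > 0L) {
        dist <- exonCountDistribution(loc)
        faux <- sampleFauxCircles(bundle, unique(locIncluded$host_tx),
                                  dist, params@nFaux)
        locTest <- localizationChisq(locIncluded, faux)
    }

    peaks <- readClipPeaks(cp$peaks, params)
    sites <- mergeReplicatePeaks(peaks, params)
    elig <- filterCirclesForClip(circDF, bundle, params,
                                 exclude = conc$excluded)
    deP <- stats::setNames(circDE$pvalue, circDE$id)
    grid <- enrichmentGrid(elig, sites, deP, params)

    reportTab <- do.call(rbind, report)
    rownames(reportTab) <- samples
    summaryRow <- c(
        backsplice_junctions_total = nrow(agg$circular),
        circ_after_filters = nrow(kept),
        circ_robustly_expressed =
            sum(SummarizedExperiment::rowData(cexpr)$kind == "circular"),
        circ_significant = sum(circDE$pvalue < params@deAlpha,
                               na.rm = TRUE),
        circ_significant_down = sum(circDE$pvalue < params@deAlpha &
                                        circDE$log2fc < 0, na.rm = TRUE),
        circ_parallel_excluded = length(conc$excluded))

    res <- list(bundle = bundle, truth = truth, events = events,
                junctions = agg, kept = kept, counts = cset,
                countsFiltered = cexpr, de = de, concordance = conc,
                shiftCirc = shiftCirc, shiftLin = shiftLin,
                localization = loc, faux = faux, locTest = locTest,
                clipSites = sites, clipEligibility = elig,
                enrichment = grid, report = reportTab,
                summary = summaryRow, params = params, sim = sim)
    if (!is.null(outDir)) .writePipeline(res, er, cp, outDir)
    invisible(res)
}

.writePipeline <- function(res, er, cp, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeSimulation(res$bundle, res$truth, er, cp$peaks,
                    file.path(outDir, "sim"))
    wt <- function(x, f) utils::write.table(
        as.data.frame(x), file.path(outDir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
    circ <- res$kept
    cnts <- attr(res$junctions$circular, "counts")
    if (nrow(circ)) {
        tab <- cbind(circ, cnts[circ$junction_id, , drop = FALSE])
        wt(tab, "circular_junctions.tsv")
        bed <- GRanges(circ$chrom,
                       IRanges(pmin(circ$acceptor, circ$donor),
                               pmax(circ$acceptor, circ$donor)),
                       strand = circ$strand, name = circ$junction_id,
                       score = circ$n_samples_pass)
        writeBed(bed, file.path(outDir, "circular_junctions.bed"))
    }
    if (nrow(res$junctions$linear))
        wt(res$junctions$linear, "linear_junctions.tsv")
    wt(res$de, "differential_expression.tsv")
    wt(res$concordance$records, "concordance.tsv")
    wt(res$localization, "localization.tsv")
    if (!is.null(res$faux)) wt(res$faux, "faux_circles.tsv")
    if (length(res$clipSites))
        writeBed(res$clipSites, file.path(outDir, "binding_sites.bed"))
    wt(res$clipEligibility, "clip_eligibility.tsv")
    wt(res$enrichment, "enrichment_grid.tsv")
    rep <- cbind(sample = rownames(res$report),
                 as.data.frame(res$report))
    wt(rep, "run_report.tsv")
    manifest <- list(
        seed = res$sim$seed,
        parameters = list(
            anchorLen = res$params@anchorLen,
            maxSpan = res$params@maxSpan,
            minUniqReads = res$params@minUniqReads,
            exprMinReads = res$params@exprMinReads,
            exprMinSamples = res$params@exprMinSamples,
            deAlpha = res$params@deAlpha,
            nFaux = res$params@nFaux,
            peakPMax = res$params@peakPMax,
            peakMergeDist = res$params@peakMergeDist,
            peakMinReplicates = res$params@peakMinReplicates,
            minFlankIntron = res$params@minFlankIntron,
            windowWidths = res$params@windowWidths,
            stratCutoffs = res$params@stratCutoffs),
        simulation = res$sim[setdiff(names(res$sim), "conditions")])
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    invisible(outDir)
}
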