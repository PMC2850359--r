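#' Pipeline configuration
#'
#' Builds the declarative configuration for [runPipeline()]. Every screening,
#' model and rhythm default is the value used throughout the analysis: 0.7
#' missingness cut, 2.6x background detection, ANOVA P < 1e-3, harmonics
#' \code{{1,3,6,9}} with the constant term, THR cuts 0.4 / 0.6. The
#' configuration round-trips losslessly through YAML via
#' [readPipelineConfig()] / [writePipelineConfig()].
#'
#' @param expression path to the expression TSV (ignored when \code{de} is
#'   passed to [runPipeline()] directly).
#' @param sampleSheet path to the sample sheet TSV.
#' @param outputDir directory for run artifacts.
#' @param maxMissingFrac,detectionFactor,alpha,nSelect screening thresholds
#'   (see [screenGenes()]; \code{nSelect = NULL} keeps 30\% of the
#'   ANOVA-selected genes).
#' @param harmonics,period Fourier basis settings (see [fourierBasis()]).
#' @param m0,v0,a0,b0 prior hyperparameters (see [nigPrior()]).
#' @param partitionPrior,alphaCohesion,poolSize clustering settings; pooling
#'   is off when \code{poolSize} is \code{NULL}.
#' @param rhythmicCut,robustCut THR classification cuts.
#' @param seed top-level seed; all randomness flows from it.
#' @param makePlot write the polar plot (SVG) among the artifacts.
#' @return a named list of class \code{"dielBFCConfig"}.
#' @export
pipelineConfig <- function(expression = NULL, sampleSheet = NULL,
                           outputDir = "dielbfc_out",
                           maxMissingFrac = 0.7, detectionFactor = 2.6,
                           alpha = 1e-3, nSelect = NULL,
                           harmonics = c(1L, 3L, 6L, 9L), period = NULL,
                           m0 = 0, v0 = 100, a0 = 0.001, b0 = 0.001,
                           partitionPrior = "uniform", alphaCohesion = 1,
                           poolSize = NULL,
                           rhythmicCut = 0.4, robustCut = 0.6,
                           seed = 1, makePlot = TRUE) {
    cfg <- list(expression = expression, sampleSheet = sampleSheet,
                outputDir = outputDir, maxMissingFrac = maxMissingFrac,
                detectionFactor = detectionFactor, alpha = alpha,
                nSelect = nSelect, harmonics = as.integer(harmonics),
                period = period, m0 = m0, v0 = v0, a0 = a0, b0 = b0,
                partitionPrior = partitionPrior,
                alphaCohesion = alphaCohesion, poolSize = poolSize,
                rhythmicCut = rhythmicCut, robustCut = robustCut,
                seed = seed, makePlot = makePlot)
    validatePipelineConfig(cfg)
    class(cfg) <- "dielBFCConfig"
    cfg
}

validatePipelineConfig <- function(cfg) {
    stopIfNot(cfg$maxMissingFrac >= 0 && cfg$maxMissingFrac < 1,
              "maxMissingFrac must lie in [0, 1)")
    stopIfNot(cfg$detectionFactor > 0, "detectionFactor must be positive")
    stopIfNot(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
    stopIfNot(cfg$v0 > 0 && cfg$a0 > 0 && cfg$b0 > 0,
              "v0, a0, b0 must be positive")
    stopIfNot(cfg$rhythmicCut >= 0 && cfg$rhythmicCut < cfg$robustCut &&
              cfg$robustCut <= 1, "need 0 <= rhythmicCut < robustCut <= 1")
    stopIfNot(cfg$partitionPrior %in% c("uniform", "cohesion"),
              "partitionPrior must be 'uniform' or 'cohesion'")
    invisible(TRUE)
}

#' Read and write pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a configuration from [pipelineConfig()].
#' @return `readPipelineConfig()` returns the configuration list;
#'   `writePipelineConfig()` invisibly returns \code{path}.
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}

#' Validate expression and sample-sheet inputs
#'
#' Checks header/sample-id agreement between the two files, duplicate gene
#' ids, NA encoding (non-numeric expression entries), background positivity
#' and time-of-day ranges. Diagnostics with level \code{"fatal"} make the
#' input unusable.
#'
#' @param expressionFile path to the expression TSV.
#' @param sampleFile path to the sample sheet TSV.
#' @return a data.frame of diagnostics (\code{level}, \code{message}), with
#'   attribute \code{n_fatal}.
#' @export
validateInputs <- function(expressionFile, sampleFile) {
    diag <- data.frame(level = character(), message = character(),
                       stringsAsFactors = FALSE)
    note <- function(level, msg)
        rbind(diag, data.frame(level = level, message = msg,
                               stringsAsFactors = FALSE))
    for (f in c(expressionFile, sampleFile))
        if (!file.exists(f))
            stop("I/O error: cannot read ", f)

    ex <- utils::read.table(expressionFile, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ss <- utils::read.table(sampleFile, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)

    exprSamples <- colnames(ex)[-1]
    missingCols <- setdiff(ss$sample_id, exprSamples)
    extraCols <- setdiff(exprSamples, ss$sample_id)
    if (length(missingCols))
        diag <- note("fatal", paste0("expression matrix lacks sample ",
                                     "column(s): ",
                                     paste(missingCols, collapse = ", ")))
    if (length(extraCols))
        diag <- note("fatal", paste0("sample sheet lacks sample(s): ",
                                     paste(extraCols, collapse = ", ")))
    dup <- ex[[1]][duplicated(ex[[1]])]
    if (length(dup))
        diag <- note("fatal", paste0("duplicate gene_id: ",
                                     paste(unique(dup), collapse = ", ")))
    vals <- ex[, -1, drop = FALSE]
    nonNum <- !vapply(vals, is.numeric, TRUE)
    if (any(nonNum))
        diag <- note("fatal", paste0("non-numeric expression column(s) ",
                                     "(check NA encoding): ",
                                     paste(names(vals)[nonNum],
                                           collapse = ", ")))
    if (!is.null(ss$background) && any(ss$background <= 0))
        diag <- note("fatal", "background must be positive for all samples")
    if (!is.null(ss$tod) && any(ss$tod < 0 | ss$tod >= 24))
        diag <- note("fatal", "tod out of [0, 24)")
    attr(diag, "n_fatal") <- sum(diag$level == "fatal")
    diag
}

.writeTSV <- function(x, path)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")

#' Run the full diel analysis pipeline
#'
#' Executes screening (missingness, detection, ANOVA, PCA), Bayesian Fourier
#' Clustering and rhythm scoring in order, and writes all artifacts to the
#' configured output directory: screen results, the amplitude histogram,
#' cluster assignments, the merge trajectory, the rhythm and polar summaries,
#' a per-stage count summary, a run log (package version, config hash, seed)
#' and optionally the polar plot (SVG). Reruns with identical configuration
#' and seed produce byte-identical tabular outputs.
#'
#' @param cfg a configuration from [pipelineConfig()].
#' @param de optionally, an in-memory \linkS4class{DielExperiment}; when
#'   omitted the expression and sample-sheet paths in \code{cfg} are read and
#'   validated first.
#' @return invisibly, a list with the screen output, the partition (or pooled
#'   partitions), the rhythm and polar summaries, the per-stage \code{counts}
#'   and the written \code{paths}.
#' @examples
#' de <- simulateDielData(nClusters = 2, genesPerCluster = 5, seed = 1)
#' cfg <- pipelineConfig(outputDir = tempfile(), makePlot = FALSE)
#' res <- runPipeline(cfg, de)
#' res$counts
#' @export
runPipeline <- function(cfg, de = NULL) {
    validatePipelineConfig(cfg)
    if (is.null(de)) {
        diag <- validateInputs(cfg$expression, cfg$sampleSheet)
        if (attr(diag, "n_fatal") > 0)
            stop("stage validate: fatal input diagnostics:\n",
                 paste(diag$message[diag$level == "fatal"], collapse = "\n"))
        de <- readDielData(cfg$expression, cfg$sampleSheet)
    }
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)

    scr <- tryCatch(
        screenGenes(de, cfg$maxMissingFrac, cfg$detectionFactor,
                    cfg$alpha, cfg$nSelect),
        error = function(e) stop("stage screen: ", conditionMessage(e)))
    sel <- scr$selected
    if (nrow(sel) == 0)
        stop("stage screen: no genes selected")

    basis <- fourierBasis(sel, harmonics = cfg$harmonics, period = cfg$period)
    prior <- nigPrior(cfg$m0, cfg$v0, cfg$a0, cfg$b0)
    if (is.null(cfg$poolSize)) {
        partition <- tryCatch(
            runBFC(sel, basis, prior, cfg$partitionPrior, cfg$alphaCohesion),
            error = function(e) stop("stage cluster: ", conditionMessage(e)))
        partitions <- list(pool1 = partition)
    } else {
        partitions <- tryCatch(
            pooledBFC(sel, cfg$poolSize, cfg$seed, basis, prior,
                      cfg$partitionPrior, cfg$alphaCohesion),
            error = function(e) stop("stage cluster: ", conditionMessage(e)))
    }

    summaries <- lapply(partitions, rhythmSummary,
                        rhythmicCut = cfg$rhythmicCut,
                        robustCut = cfg$robustCut)
    rhythm <- do.call(rbind, lapply(seq_along(summaries), function(i) {
        s <- summaries[[i]]
        s$cluster_id <- paste0(names(summaries)[i], "_", s$cluster_id)
        s$pool <- names(summaries)[i]
        s
    }))
    polar <- polarSummary(rhythm)

    assignments <- do.call(rbind, lapply(seq_along(partitions), function(i) {
        a <- clusterAssignments(partitions[[i]])
        data.frame(gene_id = names(a),
                   cluster_id = sprintf("%s_c%03d", names(partitions)[i], a),
                   stringsAsFactors = FALSE)
    }))
    trajectory <- do.call(rbind, lapply(seq_along(partitions), function(i) {
        h <- mergeHistory(partitions[[i]])
        h$pool <- names(partitions)[i]
        h
    }))

    counts <- c(scr$counts,
                clusters = nrow(rhythm),
                rhythmic_clusters = sum(rhythm$rhythm_class != "arrhythmic"),
                robust_clusters = sum(rhythm$rhythm_class == "robust"))

    paths <- c(
        screen = file.path(cfg$outputDir, "screen_results.tsv"),
        histogram = file.path(cfg$outputDir, "amplitude_histogram.tsv"),
        assignments = file.path(cfg$outputDir, "cluster_assignments.tsv"),
        trajectory = file.path(cfg$outputDir, "merge_trajectory.tsv"),
        rhythm = file.path(cfg$outputDir, "rhythm_summary.tsv"),
        polar = file.path(cfg$outputDir, "polar_summary.tsv"),
        summary = file.path(cfg$outputDir, "run_summary.tsv"),
        log = file.path(cfg$outputDir, "run_log.yaml"))
    .writeTSV(scr$result, paths[["screen"]])
    if (!is.null(scr$histogram)) .writeTSV(scr$histogram, paths[["histogram"]])
    .writeTSV(assignments, paths[["assignments"]])
    .writeTSV(trajectory, paths[["trajectory"]])
    .writeTSV(rhythm, paths[["rhythm"]])
    .writeTSV(polar, paths[["polar"]])
    .writeTSV(data.frame(stage = names(counts),
                         count = unlist(counts, use.names = FALSE)),
              paths[["summary"]])
    cfgYaml <- yaml::as.yaml(unclass(cfg))
    yaml::write_yaml(list(package = "dielBFC",
                          version = as.character(
                              utils::packageVersion("dielBFC")),
                          config_hash = contentHash(cfgYaml),
                          seed = cfg$seed),
                     paths[["log"]])
    if (isTRUE(cfg$makePlot) && nrow(polar) > 0) {
        plotPath <- file.path(cfg$outputDir, "polar_plot.svg")
        lightOn <- if (any(lightPhase(de)))
            min(timeOfDay(de)[lightPhase(de)]) else 9
        lightOff <- if (any(!lightPhase(de)))
            min(timeOfDay(de)[!lightPhase(de) & timeOfDay(de) > lightOn])
            else 21
        p <- plotPolarClusters(polar, lightOn, lightOff)
        grDevices::svg(plotPath, width = 6, height = 6)
        print(p)
        grDevices::dev.off()
        paths <- c(paths, plot = plotPath)
    }

    invisible(list(screen = scr, partitions = partitions, rhythm = rhythm,
                   polar = polar, counts = counts, paths = paths))
}
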