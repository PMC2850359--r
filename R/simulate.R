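#' Simulate a diel expression experiment with ground truth
#'
#' Generates a gene x sample log2 expression matrix with the statistical
#' structure the downstream analysis assumes, plus per-gene truth labels for
#' recovery benchmarks. Rhythmic genes in cluster \code{c} follow
#' \code{baseline + (amplitude_c / 2) * cos(2*pi*(tod - phase_c)/24)} with
#' i.i.d. Gaussian noise; arrhythmic genes are noise around the baseline;
#' unexpressed genes are drawn uniformly below the detection limit
#' (\code{detectionFactor * background}) on the linear scale. Missing entries
#' are masked completely at random. Fully reproducible from \code{seed}.
#'
#' @param design sample design as returned by [makeDielDesign()] (default:
#'   the default 3-kinetic, 27-sample design).
#' @param nClusters number of rhythmic clusters (default 6).
#' @param genesPerCluster rhythmic genes per cluster (default 20).
#' @param phases peak times of day (hours) per cluster; default evenly spaced
#'   over the 24-h cycle.
#' @param amplitudes peak-to-trough amplitudes (delta log2) per cluster;
#'   default evenly spans 1.5 to 9, the range observed for cycling genes.
#' @param nArrhythmic number of expressed but arrhythmic genes (default 20).
#' @param nUnexpressed number of genes below the detection limit (default 20).
#' @param noiseSd Gaussian noise standard deviation, log2 units (default 0.3).
#' @param missingFrac fraction of entries masked as missing, in [0,1)
#'   (default 0.02).
#' @param seed integer RNG seed (default 1).
#' @param baselineLog2 baseline log2 level for expressed genes; default
#'   \code{log2(detectionFactor * max(background)) + 2}, comfortably above
#'   detection.
#' @param detectionFactor linear detection multiple of background used to
#'   bound unexpressed genes (default 2.6).
#' @return a \linkS4class{DielExperiment} whose \code{rowData} holds the truth
#'   labels: \code{class} (rhythmic/arrhythmic/unexpressed),
#'   \code{true_cluster}, \code{phase_h} and \code{amplitude}.
#' @examples
#' de <- simulateDielData(nClusters = 2, genesPerCluster = 5, seed = 1)
#' table(truthLabels(de)$class)
#' @export
simulateDielData <- function(design = makeDielDesign(),
                             nClusters = 6, genesPerCluster = 20,
                             phases = NULL, amplitudes = NULL,
                             nArrhythmic = 20, nUnexpressed = 20,
                             noiseSd = 0.3, missingFrac = 0.02,
                             seed = 1, baselineLog2 = NULL,
                             detectionFactor = 2.6) {
    if (is.null(phases))
        phases <- seq(0, 24, length.out = nClusters + 1)[seq_len(nClusters)]
    if (is.null(amplitudes))
        amplitudes <- if (nClusters > 1)
            seq(1.5, 9, length.out = nClusters) else 3
    if (length(phases) != nClusters || length(amplitudes) != nClusters)
        stop("invalid spec: 'phases' and 'amplitudes' must each have ",
             "length nClusters")
    stopIfNot(noiseSd >= 0, "noiseSd must be nonnegative")
    stopIfNot(missingFrac >= 0 && missingFrac < 1,
              "missingFrac must lie in [0, 1)")

    n <- nrow(design)
    bg <- design$background
    if (is.null(baselineLog2))
        baselineLog2 <- log2(detectionFactor * max(bg)) + 2

    nRhythmic <- nClusters * genesPerCluster
    G <- nRhythmic + nArrhythmic + nUnexpressed
    stopIfNot(G >= 1, "at least one gene must be simulated")

    withSeed(seed, {
        vals <- matrix(NA_real_, G, n)
        cls <- rep(c("rhythmic", "arrhythmic", "unexpressed"),
                   c(nRhythmic, nArrhythmic, nUnexpressed))
        trueCluster <- rep(NA_integer_, G)
        phaseH <- rep(NA_real_, G)
        amp <- rep(0, G)
        row <- 0L
        for (c in seq_len(nClusters)) {
            mu <- baselineLog2 +
                (amplitudes[c] / 2) * cos(2 * pi * (design$tod - phases[c]) / 24)
            for (g in seq_len(genesPerCluster)) {
                row <- row + 1L
                vals[row, ] <- mu + rnorm(n, 0, noiseSd)
                trueCluster[row] <- c
                phaseH[row] <- phases[c]
                amp[row] <- amplitudes[c]
            }
        }
        for (g in seq_len(nArrhythmic)) {
            row <- row + 1L
            vals[row, ] <- baselineLog2 + rnorm(n, 0, noiseSd)
        }
        for (g in seq_len(nUnexpressed)) {
            row <- row + 1L
            vals[row, ] <- log2(pmax(runif(n, 0, detectionFactor * bg), 1e-12))
        }
        if (missingFrac > 0)
            vals[matrix(runif(G * n) < missingFrac, G, n)] <- NA_real_
    })

    ids <- sprintf("gene%04d", seq_len(G))
    rownames(vals) <- ids
    colnames(vals) <- design$sample_id
    truth <- data.frame(gene_id = ids, class = cls,
                        true_cluster = trueCluster, phase_h = phaseH,
                        amplitude = amp, stringsAsFactors = FALSE)
    DielExperiment(vals, design, rowData = truth)
}

#' Read and write diel expression data as TSV
#'
#' `writeDielData()` writes the expression matrix (first column
#' \code{gene_id}, one column per sample), the sample sheet and, when truth
#' labels are present, a truth table, all tab-separated with missing values
#' encoded as \code{"NA"}. `readDielData()` reads the pair back into a
#' \linkS4class{DielExperiment}.
#'
#' @param de a \linkS4class{DielExperiment}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"diel"}).
#' @return `writeDielData()` invisibly returns the written paths;
#'   `readDielData()` returns a \linkS4class{DielExperiment}.
#' @examples
#' de <- simulateDielData(nClusters = 1, genesPerCluster = 2, seed = 1)
#' paths <- writeDielData(de, tempdir())
#' de2 <- readDielData(paths[["expression"]], paths[["samples"]])
#' @export
writeDielData <- function(de, dir, prefix = "diel") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    exprPath <- file.path(dir, paste0(prefix, "_expression.tsv"))
    samplePath <- file.path(dir, paste0(prefix, "_samples.tsv"))
    m <- assay(de, "exprs")
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.table(sampleDesign(de), samplePath, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    paths <- c(expression = exprPath, samples = samplePath)
    truth <- truthLabels(de)
    if (ncol(truth) > 0) {
        truthPath <- file.path(dir, paste0(prefix, "_truth.tsv"))
        utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
        paths <- c(paths, truth = truthPath)
    }
    invisible(paths)
}

#' @param expressionFile path to the expression TSV.
#' @param sampleFile path to the sample sheet TSV.
#' @param truthFile optional path to a truth TSV (attached as rowData).
#' @rdname writeDielData
#' @export
readDielData <- function(expressionFile, sampleFile, truthFile = NULL) {
    ex <- utils::read.table(expressionFile, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    design <- utils::read.table(sampleFile, header = TRUE, sep = "\t",
                                check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(ex[, -1, drop = FALSE])
    rownames(m) <- ex[[1]]
    storage.mode(m) <- "double"
    truth <- if (!is.null(truthFile))
        utils::read.table(truthFile, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE) else NULL
    DielExperiment(m, design, rowData = truth)
}
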