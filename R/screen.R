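#' Drop genes with too many missing values
#'
#' Removes genes whose fraction of missing samples strictly exceeds
#' \code{maxMissingFrac} (default 0.7: genes missing on more than 70\% of
#' time points are removed). The order of surviving genes is preserved.
#'
#' @param de a \linkS4class{DielExperiment}.
#' @param maxMissingFrac maximum tolerated missing fraction, in [0,1).
#' @return the filtered \linkS4class{DielExperiment}.
#' @export
filterMissingness <- function(de, maxMissingFrac = 0.7) {
    stopIfNot(maxMissingFrac >= 0 && maxMissingFrac < 1,
              "maxMissingFrac must lie in [0, 1)")
    frac <- rowMeans(is.na(assay(de, "exprs")))
    de[frac <= maxMissingFrac, ]
}

#' Detect expressed genes against a background level
#'
#' A gene is called expressed if its linear-scale signal (\code{2^log2value})
#' reaches \code{factor} times the per-sample background in at least one
#' sample (ties at exactly \code{factor * background} count as expressed;
#' missing entries are ignored). Genes with no observed values are flagged
#' not expressed, with a warning.
#'
#' @param de a \linkS4class{DielExperiment}; per-sample backgrounds are taken
#'   from the design and must be positive.
#' @param factor detection multiple of background (default 2.6).
#' @return a named logical vector, one entry per gene.
#' @export
detectExpressed <- function(de, factor = 2.6) {
    bg <- backgroundLevel(de)
    stopIfNot(all(bg > 0), "per-sample background must be positive")
    m <- 2^assay(de, "exprs")
    thr <- matrix(factor * bg, nrow(m), ncol(m), byrow = TRUE)
    hit <- m >= thr
    allMissing <- rowSums(!is.na(m)) == 0
    expressed <- rowSums(hit, na.rm = TRUE) > 0
    expressed[allMissing] <- FALSE
    if (any(allMissing))
        warning(sum(allMissing),
                " gene(s) with no observed values flagged not expressed")
    stats::setNames(expressed, rownames(de))
}

# residual sum of squares of each row of Y under the projection residual-maker
.rowRSS <- function(Y, M) rowSums((Y %*% M) * Y)

#' Per-gene ANOVA screen for differential expression over the diel cycle
#'
#' Fits, for every gene, a two-way fixed-effects ANOVA with factors time of
#' day and kinetic (no interaction) and tests the time-of-day effect; a gene
#' is selected when its p-value falls strictly below \code{alpha} (default
#' 1e-3). Genes with zero residual variance get p = 0 when the between-time
#' variance is positive and p = 1 otherwise (constant genes: F = 0). Genes
#' with missing values are fitted on their complete cases.
#'
#' @param de a \linkS4class{DielExperiment}; every time-of-day level must be
#'   observed in at least two kinetics and there must be at least two levels.
#' @param alpha selection threshold on the raw p-value (default 1e-3; no
#'   multiplicity correction, by design).
#' @return a data.frame with columns \code{gene_id}, \code{F}, \code{p},
#'   \code{selected}.
#' @export
anovaScreen <- function(de, alpha = 1e-3) {
    tod <- factor(timeOfDay(de))
    kin <- factor(kineticOf(de))
    if (nlevels(tod) < 2)
        stop("need at least two time-of-day levels")
    cov2 <- rowSums(table(tod, kin) > 0)
    if (any(cov2 < 2))
        stop("degrees-of-freedom error: time-of-day level(s) ",
             paste(names(cov2)[cov2 < 2], collapse = ", "),
             " observed in fewer than two kinetics")

    Y <- assay(de, "exprs")
    G <- nrow(Y)
    Fv <- rep(NA_real_, G)
    pv <- rep(NA_real_, G)

    fitF <- function(y, todf, kinf) {
        # drop unused levels for complete-case fits
        todf <- droplevels(todf); kinf <- droplevels(kinf)
        Xf <- stats::model.matrix(~ todf + kinf)
        Xr <- stats::model.matrix(~ kinf)
        qf <- qr(Xf); qr_ <- qr(Xr)
        rssF <- sum(stats::resid(stats::lm.fit(Xf, y))^2)
        rssR <- sum(stats::resid(stats::lm.fit(Xr, y))^2)
        df1 <- qf$rank - qr_$rank
        df2 <- length(y) - qf$rank
        tol <- 1e-12 * (sum(y^2) + 1)
        if (df1 < 1 || df2 < 1) return(c(NA_real_, NA_real_))
        if (rssF < tol) {
            if (rssR - rssF > tol) return(c(Inf, 0))
            return(c(0, 1))
        }
        Fstat <- ((rssR - rssF) / df1) / (rssF / df2)
        c(Fstat, stats::pf(Fstat, df1, df2, lower.tail = FALSE))
    }

    complete <- rowSums(is.na(Y)) == 0
    if (any(complete)) {
        # shared-design fast path via residual-maker quadratic forms
        Xf <- stats::model.matrix(~ tod + kin)
        Xr <- stats::model.matrix(~ kin)
        Mf <- diag(ncol(Y)) - Xf %*% solve(crossprod(Xf), t(Xf))
        Mr <- diag(ncol(Y)) - Xr %*% solve(crossprod(Xr), t(Xr))
        Yc <- Y[complete, , drop = FALSE]
        rssF <- .rowRSS(Yc, Mf)
        rssR <- .rowRSS(Yc, Mr)
        df1 <- qr(Xf)$rank - qr(Xr)$rank
        df2 <- ncol(Y) - qr(Xf)$rank
        tol <- 1e-12 * (rowSums(Yc^2) + 1)
        Fstat <- ((rssR - rssF) / df1) / (rssF / df2)
        p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
        zeroRes <- rssF < tol
        Fstat[zeroRes] <- ifelse(rssR[zeroRes] - rssF[zeroRes] > tol[zeroRes],
                                 Inf, 0)
        p[zeroRes] <- ifelse(is.infinite(Fstat[zeroRes]), 0, 1)
        Fv[complete] <- Fstat
        pv[complete] <- p
    }
    for (g in which(!complete)) {
        obs <- !is.na(Y[g, ])
        if (!any(obs)) next
        r <- fitF(Y[g, obs], tod[obs], kin[obs])
        Fv[g] <- r[1]; pv[g] <- r[2]
    }
    data.frame(gene_id = rownames(Y), F = Fv, p = pv,
               selected = !is.na(pv) & pv < alpha,
               stringsAsFactors = FALSE)
}

#' Select genes with best dispersion by PCA
#'
#' Runs a principal component analysis with genes as observations over the
#' sample dimensions, after per-gene centering (missing entries are
#' mean-imputed, i.e. set to the gene mean). Each gene's dispersion score is
#' its squared projection length onto the first two principal axes; the
#' \code{nSelect} genes with the largest score are retained, with a
#' deterministic tie-break by input gene order.
#'
#' @param de a \linkS4class{DielExperiment}.
#' @param nSelect number of genes to retain (1..number of genes).
#' @return a list with \code{experiment} (the selected genes, input order
#'   preserved) and \code{score} (named per-gene dispersion scores for all
#'   input genes).
#' @export
pcaSelect <- function(de, nSelect) {
    G <- nrow(de)
    if (length(nSelect) != 1 || is.na(nSelect) || nSelect <= 0)
        stop("invalid argument: nSelect must be a positive count")
    stopIfNot(nSelect <= G, "nSelect exceeds the number of genes")
    Y <- assay(de, "exprs")
    Yc <- Y - rowMeans(Y, na.rm = TRUE)
    Yc[is.na(Yc)] <- 0
    k <- min(2, dim(Yc))
    sv <- svd(Yc, nu = k, nv = 0)
    proj <- sv$u[, seq_len(k), drop = FALSE] %*%
        diag(sv$d[seq_len(k)], k)
    score <- stats::setNames(rowSums(proj^2), rownames(Y))
    keep <- sort(order(-score, seq_len(G))[seq_len(nSelect)])
    list(experiment = de[keep, ], score = score)
}

.AMP_BIN_LABELS <- paste(0:8, 1:9, sep = "-")

#' Peak-to-trough amplitudes and Table-style amplitude histogram
#'
#' For each gene, computes the median profile over time of day (pooling
#' kinetics and overlapping time points) and its peak-to-trough range
#' \code{max - min} in delta log2 units, then tallies genes into the nine
#' unit-width bins 0-1, 1-2, ..., 8-9 (right-open except the last; amplitudes
#' above 9 are counted in the top bin).
#'
#' @param de a \linkS4class{DielExperiment}.
#' @return a list with \code{amplitude} (named per-gene vector) and
#'   \code{histogram} (data.frame with columns \code{bin}, \code{count}).
#' @export
amplitudeBins <- function(de) {
    Y <- assay(de, "exprs")
    tod <- timeOfDay(de)
    levelsT <- sort(unique(tod))
    prof <- vapply(levelsT, function(tt)
        apply(Y[, tod == tt, drop = FALSE], 1, stats::median, na.rm = TRUE),
        numeric(nrow(Y)))
    if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
    amp <- apply(prof, 1, function(x) {
        x <- x[is.finite(x)]
        if (!length(x)) NA_real_ else max(x) - min(x)
    })
    names(amp) <- rownames(Y)
    bin <- pmin(floor(pmax(amp, 0)) + 1, 9)
    counts <- tabulate(bin[!is.na(bin)], nbins = 9)
    list(amplitude = amp,
         histogram = data.frame(bin = .AMP_BIN_LABELS, count = counts,
                                stringsAsFactors = FALSE))
}

#' Full gene-screening cascade
#'
#' Applies, in order: the missingness filter, the background detection filter,
#' the per-gene ANOVA selection and the PCA dispersion selection, and computes
#' per-gene amplitudes. Mirrors the screening used ahead of curve clustering:
#' genes are only eligible for a later stage if they survived the earlier
#' ones.
#'
#' @param de a \linkS4class{DielExperiment}.
#' @param maxMissingFrac missingness cut (default 0.7).
#' @param detectionFactor detection multiple of background (default 2.6).
#' @param alpha ANOVA selection threshold (default 1e-3).
#' @param nSelect number of genes kept by PCA; default 30\% of the
#'   ANOVA-selected genes (at least 1).
#' @return a list with \code{result} (per-gene data.frame: \code{gene_id},
#'   \code{n_missing}, \code{expressed}, \code{F}, \code{p},
#'   \code{pca_score}, \code{amplitude}, \code{selected_anova},
#'   \code{selected_pca}), \code{selected} (the post-cascade
#'   \linkS4class{DielExperiment}), \code{histogram} (amplitude histogram of
#'   the ANOVA-selected genes) and \code{counts} (per-stage totals).
#' @export
screenGenes <- function(de, maxMissingFrac = 0.7, detectionFactor = 2.6,
                        alpha = 1e-3, nSelect = NULL) {
    res <- data.frame(gene_id = rownames(de),
                      n_missing = rowSums(is.na(assay(de, "exprs"))),
                      expressed = FALSE, F = NA_real_, p = NA_real_,
                      pca_score = NA_real_, amplitude = NA_real_,
                      selected_anova = FALSE, selected_pca = FALSE,
                      stringsAsFactors = FALSE)
    rownames(res) <- res$gene_id

    kept <- filterMissingness(de, maxMissingFrac)
    expressed <- detectExpressed(kept, detectionFactor)
    res[names(expressed), "expressed"] <- expressed
    exprSet <- kept[expressed, ]

    counts <- list(genes_in = nrow(de),
                   dropped_missingness = nrow(de) - nrow(kept),
                   expressed = nrow(exprSet))
    if (nrow(exprSet) == 0)
        return(list(result = res, selected = exprSet,
                    histogram = NULL,
                    counts = c(counts, anova_selected = 0, pca_selected = 0)))

    av <- anovaScreen(exprSet, alpha)
    res[av$gene_id, c("F", "p")] <- av[, c("F", "p")]
    res[av$gene_id, "selected_anova"] <- av$selected
    anovaSet <- exprSet[av$selected, ]
    counts$anova_selected <- nrow(anovaSet)

    ampAll <- amplitudeBins(kept)
    res[names(ampAll$amplitude), "amplitude"] <- ampAll$amplitude
    hist <- if (nrow(anovaSet)) amplitudeBins(anovaSet)$histogram else NULL

    if (nrow(anovaSet) == 0)
        return(list(result = res, selected = anovaSet, histogram = hist,
                    counts = c(counts, pca_selected = 0)))

    if (is.null(nSelect))
        nSelect <- max(1L, round(0.3 * nrow(anovaSet)))
    nSelect <- min(nSelect, nrow(anovaSet))
    pca <- pcaSelect(anovaSet, nSelect)
    res[names(pca$score), "pca_score"] <- pca$score
    res[rownames(pca$experiment), "selected_pca"] <- TRUE
    counts$pca_selected <- nrow(pca$experiment)

    list(result = res, selected = pca$experiment, histogram = hist,
         counts = counts)
}
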