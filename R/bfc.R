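# Bayesian Fourier Clustering: greedy agglomerative search over partitions
# scored by the sum of member-cluster log evidences (optionally plus a
# Crowley/DP-style cohesion term). "Most similar in covariance structure" is
# operationalized as the merge with maximal evidence gain, the only similarity
# consistent with the partition score.

.logPartitionPrior <- function(sizes, type, alpha) {
    if (type == "uniform") return(0)
    length(sizes) * log(alpha) + sum(lgamma(sizes))
}

.mergePriorDelta <- function(n1, n2, type, alpha) {
    if (type == "uniform") return(0)
    -log(alpha) + lgamma(n1 + n2) - lgamma(n1) - lgamma(n2)
}

.pairDelta <- function(si, sj, ei, ej, prior, type, alpha, nGenesI, nGenesJ) {
    em <- .nigFit(.addStats(si, sj), prior)$logEvidence
    em - ei - ej + .mergePriorDelta(nGenesI, nGenesJ, type, alpha)
}

.partitionFromState <- function(members, geneStats, geneIds, basis, prior,
                                partitionPrior, alpha, history) {
    clusters <- lapply(members, function(ms) {
        stats <- Reduce(.addStats, geneStats[ms])
        .makePosterior(ms, .nigFit(stats, prior), basis@harmonics)
    })
    score <- sum(vapply(clusters, slot, numeric(1), "logEvidence")) +
        .logPartitionPrior(lengths(members), partitionPrior, alpha)
    new("DielPartition", clusters = clusters, score = score,
        history = history, geneIds = geneIds, basis = basis, prior = prior,
        partitionPrior = partitionPrior, alpha = alpha,
        geneStats = geneStats)
}

.emptyHistory <- function() {
    data.frame(step = integer(), cluster_i = integer(), cluster_j = integer(),
               score = numeric())
}

#' Initial all-singletons partition
#'
#' Assigns every gene expression profile to its own cluster, with evidence and
#' posterior computed per gene. The partition score is the sum of singleton
#' log evidences plus the log partition-prior term.
#'
#' @param de a \linkS4class{DielExperiment} with at least one gene.
#' @param basis a \linkS4class{FourierBasis}; default built from the design
#'   with harmonics \code{c(1,3,6,9)}.
#' @param prior an \linkS4class{NIGPrior}.
#' @param partitionPrior \code{"uniform"} (score is the plain evidence sum) or
#'   \code{"cohesion"} (adds \code{K log(alpha) + sum(lgamma(n_c))}).
#' @param alpha cohesion concentration (default 1).
#' @return a \linkS4class{DielPartition} of singletons.
#' @export
initPartition <- function(de, basis = NULL, prior = nigPrior(),
                          partitionPrior = c("uniform", "cohesion"),
                          alpha = 1) {
    partitionPrior <- match.arg(partitionPrior)
    if (nrow(de) < 1) stop("invalid input: empty expression matrix")
    if (is.null(basis)) basis <- fourierBasis(de)
    Y <- assay(de, "exprs")
    geneIds <- rownames(Y)
    geneStats <- lapply(seq_len(nrow(Y)),
                        function(g) .geneStats(Y[g, ], basis@matrix))
    names(geneStats) <- geneIds
    members <- as.list(geneIds)
    history <- .emptyHistory()
    p <- .partitionFromState(members, geneStats, geneIds, basis, prior,
                             partitionPrior, alpha, history)
    p@history <- data.frame(step = 0L, cluster_i = NA_integer_,
                            cluster_j = NA_integer_, score = p@score)
    p
}

#' Best single merge of a partition
#'
#' Evaluates every pair of clusters and returns the pair whose merge maximizes
#' the score gain \code{evidence(merged) - evidence(i) - evidence(j)} (plus the
#' partition-prior delta). Ties are broken by the lexicographically smallest
#' \code{(i, j)} pair of cluster indices.
#'
#' @param p a \linkS4class{DielPartition} with at least two clusters.
#' @return a list with \code{pair} (integer cluster indices) and
#'   \code{deltaScore}.
#' @export
bestMerge <- function(p) {
    K <- length(p@clusters)
    if (K < 2) stop("no merge possible: fewer than two clusters")
    stats <- lapply(p@clusters, function(cl)
        Reduce(.addStats, p@geneStats[cl@members]))
    ev <- vapply(p@clusters, slot, numeric(1), "logEvidence")
    sizes <- clusterSizes(p)
    best <- NULL
    bestDelta <- -Inf
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
        d <- .pairDelta(stats[[i]], stats[[j]], ev[i], ev[j], p@prior,
                        p@partitionPrior, p@alpha, sizes[i], sizes[j])
        if (d > bestDelta) { bestDelta <- d; best <- c(i, j) }
    }
    list(pair = best, deltaScore = bestDelta)
}

#' Agglomerative Bayesian Fourier Clustering
#'
#' Starts from singleton clusters and greedily applies the best available
#' merge until all genes lie in a single cluster, scoring the partition at
#' initialization and after every merge; the partition attaining the maximum
#' recorded score is returned. Candidate merge gains are cached pairwise and
#' invalidated only for pairs touching the last merge.
#'
#' @inheritParams initPartition
#' @param verbose print progress every 50 merges.
#' @return the best-scoring \linkS4class{DielPartition}; its
#'   \code{mergeHistory()} records the full greedy trajectory.
#' @examples
#' de <- simulateDielData(nClusters = 3, genesPerCluster = 5,
#'                        nArrhythmic = 0, nUnexpressed = 0, seed = 1)
#' p <- runBFC(de)
#' clusterSizes(p)
#' @export
runBFC <- function(de, basis = NULL, prior = nigPrior(),
                   partitionPrior = c("uniform", "cohesion"), alpha = 1,
                   verbose = FALSE) {
    partitionPrior <- match.arg(partitionPrior)
    if (nrow(de) < 1) stop("invalid input: empty expression matrix")
    if (is.null(basis)) basis <- fourierBasis(de)
    Y <- assay(de, "exprs")
    G <- nrow(Y)
    geneIds <- rownames(Y)
    geneStats <- lapply(seq_len(G), function(g) .geneStats(Y[g, ], basis@matrix))
    names(geneStats) <- geneIds

    stats <- geneStats
    ev <- vapply(stats, function(s) .nigFit(s, prior)$logEvidence, numeric(1))
    sizes <- rep(1L, G)
    active <- rep(TRUE, G)
    assign <- seq_len(G)          # gene -> slot
    score <- sum(ev) + .logPartitionPrior(sizes, partitionPrior, alpha)
    bestScore <- score
    bestAssign <- assign

    hStep <- integer(G); hI <- integer(G); hJ <- integer(G); hS <- numeric(G)
    hStep[1] <- 0L; hI[1] <- NA_integer_; hJ[1] <- NA_integer_; hS[1] <- score

    D <- matrix(NA_real_, G, G)
    if (G > 1) {
        for (i in seq_len(G - 1)) for (j in (i + 1):G)
            D[i, j] <- .pairDelta(stats[[i]], stats[[j]], ev[i], ev[j],
                                  prior, partitionPrior, alpha, 1L, 1L)
    }

    for (step in seq_len(max(G - 1, 0))) {
        maxd <- max(D, na.rm = TRUE)
        cand <- which(D == maxd, arr.ind = TRUE)
        cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
        i <- cand[1, 1]; j <- cand[1, 2]

        stats[[i]] <- .addStats(stats[[i]], stats[[j]])
        ev[i] <- .nigFit(stats[[i]], prior)$logEvidence
        sizes[i] <- sizes[i] + sizes[j]
        active[j] <- FALSE
        assign[assign == j] <- i
        score <- score + maxd
        D[j, ] <- NA_real_; D[, j] <- NA_real_
        for (k in which(active)) {
            if (k == i) next
            a <- min(i, k); b <- max(i, k)
            D[a, b] <- .pairDelta(stats[[i]], stats[[k]], ev[i], ev[k],
                                  prior, partitionPrior, alpha,
                                  sizes[i], sizes[k])
        }
        hStep[step + 1] <- step; hI[step + 1] <- i; hJ[step + 1] <- j
        hS[step + 1] <- score
        if (score > bestScore) { bestScore <- score; bestAssign <- assign }
        if (verbose && step %% 50 == 0)
            message("merge ", step, "/", G - 1, " score ", format(score))
    }

    history <- data.frame(step = hStep, cluster_i = hI, cluster_j = hJ,
                          score = hS)
    slots <- sort(unique(bestAssign))
    members <- lapply(slots, function(s) geneIds[bestAssign == s])
    p <- .partitionFromState(members, geneStats, geneIds, basis, prior,
                             partitionPrior, alpha, history)
    # from-scratch rescoring must agree with the incremental trajectory
    if (abs(p@score - bestScore) > 1e-6 * (1 + abs(bestScore)))
        warning("incremental score drifted from the from-scratch score by ",
                format(abs(p@score - bestScore)))
    p
}

#' Pooled clustering for large gene sets
#'
#' Shuffles the genes with \code{seed}, splits them into
#' \code{ceiling(G / poolSize)} pools, and clusters each pool independently
#' with [runBFC()]. Pools are the memory-saving device used when a direct run
#' over all genes is not feasible; no cross-pool reconciliation is attempted.
#'
#' @inheritParams runBFC
#' @param poolSize maximum genes per pool (>= 2).
#' @param seed integer seed for the shuffle.
#' @return a named list of \linkS4class{DielPartition}, one per pool, with the
#'   pool assignment attached as attribute \code{"poolAssignments"} (a named
#'   integer vector over gene ids).
#' @export
pooledBFC <- function(de, poolSize, seed = 1, basis = NULL,
                      prior = nigPrior(),
                      partitionPrior = c("uniform", "cohesion"), alpha = 1) {
    if (length(poolSize) != 1 || is.na(poolSize) || poolSize < 2)
        stop("invalid argument: poolSize must be >= 2")
    partitionPrior <- match.arg(partitionPrior)
    G <- nrow(de)
    perm <- withSeed(seed, sample.int(G))
    poolOf <- integer(G)
    poolOf[perm] <- ceiling(seq_len(G) / poolSize)
    names(poolOf) <- rownames(de)
    nPools <- max(poolOf)
    out <- lapply(seq_len(nPools), function(pl) {
        idx <- which(poolOf == pl)   # original gene order within each pool
        runBFC(de[idx, ], basis = basis, prior = prior,
               partitionPrior = partitionPrior, alpha = alpha)
    })
    names(out) <- paste0("pool", seq_len(nPools))
    attr(out, "poolAssignments") <- poolOf
    out
}
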