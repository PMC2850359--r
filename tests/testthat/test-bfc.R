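toyExperiment <- function(m, design = makeDielDesign(),
                          ids = sprintf("g%02d", seq_len(nrow(m)))) {
    rownames(m) <- ids
    colnames(m) <- design$sample_id
    DielExperiment(m, design)
}

test_that("initial partition is all singletons scored by summed evidence", {
    d <- makeDielDesign()
    set.seed(71)
    de <- toyExperiment(matrix(rnorm(5 * 27), 5, 27) + 7, d)
    p <- initPartition(de)
    expect_equal(length(clusters(p)), 5)
    expect_equal(clusterSizes(p), rep(1L, 5))
    b <- fourierBasis(de)
    singles <- vapply(seq_len(5), function(g)
        logEvidence(assay(de, "exprs")[g, ], b), numeric(1))
    expect_equal(partitionScore(p), sum(singles), tolerance = 1e-8)
    expect_error(initPartition(de[0, ]), "empty")
})

test_that("a single gene terminates immediately", {
    de <- simulateDielData(nClusters = 1, genesPerCluster = 1,
                           nArrhythmic = 0, nUnexpressed = 0, seed = 1)
    p <- runBFC(de)
    expect_equal(length(clusters(p)), 1)
    expect_equal(nrow(mergeHistory(p)), 1)   # step 0 only
})

test_that("bestMerge maximizes evidence gain over the exhaustive pair oracle", {
    d <- makeDielDesign()
    set.seed(72)
    base <- function(ph) 7 + 1.5 * cos(2 * pi * (d$tod - ph) / 24)
    g1 <- base(3) + rnorm(27, sd = 0.2)
    m <- rbind(g1, g1, base(11) + rnorm(27, sd = 0.2),
               base(19) + rnorm(27, sd = 0.2))
    de <- toyExperiment(m, d)
    p <- initPartition(de)
    bm <- bestMerge(p)
    expect_equal(bm$pair, c(1, 2))   # the identical pair merges first

    b <- fourierBasis(de)
    Y <- assay(de, "exprs")
    deltas <- combn(4, 2, function(ij) {
        logEvidence(Y[ij, ], b) -
            logEvidence(Y[ij[1], ], b) - logEvidence(Y[ij[2], ], b)
    })
    expect_equal(bm$deltaScore, max(deltas), tolerance = 1e-8)
    expect_error(bestMerge(runBFC(de[1, ])), "fewer than two")
})

test_that("two genes sharing generating coefficients merge first", {
    d <- makeDielDesign()
    set.seed(73)
    shared <- 6 + 2 * cos(2 * pi * (d$tod - 8) / 24)
    m <- rbind(shared + rnorm(27, 0.0, 0.25),
               shared + rnorm(27, 0.0, 0.25),
               6 + 2 * cos(2 * pi * (d$tod - 20) / 24) + rnorm(27, 0, 0.25))
    p <- initPartition(toyExperiment(m, d))
    expect_equal(bestMerge(p)$pair, c(1, 2))
})

test_that("exact merge ties break to the lexicographically smallest pair", {
    d <- makeDielDesign()
    set.seed(74)
    a <- 1.5 * cos(2 * pi * (d$tod - 5) / 24) + rnorm(27, sd = 0.1)
    # genes 3,4 are the sign-flipped copies of 1,2: identical evidence
    # structure, so delta(1,2) == delta(3,4) exactly
    de <- toyExperiment(rbind(a, a, -a, -a), d)
    p <- initPartition(de)
    bm <- bestMerge(p)
    expect_equal(bm$pair, c(1, 2))
})

test_that("two identical genes end up merged", {
    d <- makeDielDesign()
    set.seed(75)
    a <- 7 + 2 * cos(2 * pi * d$tod / 24) + rnorm(27, sd = 0.2)
    de <- toyExperiment(rbind(a, a), d)
    p <- runBFC(de)
    expect_equal(length(clusters(p)), 1)
    expect_gt(bestMerge(initPartition(de))$deltaScore, 0)
})

test_that("three well-separated clusters are recovered exactly", {
    de <- simulateDielData(nClusters = 3, genesPerCluster = 10,
                           phases = c(3, 11, 19), amplitudes = rep(3, 3),
                           nArrhythmic = 0, nUnexpressed = 0,
                           noiseSd = 0.3, missingFrac = 0, seed = 1)
    p <- runBFC(de)
    expect_equal(length(clusters(p)), 3)
    truth <- truthLabels(de)
    expect_equal(ari(clusterAssignments(p)[truth$gene_id],
                     truth$true_cluster), 1.0)
})

test_that("the trajectory score matches from-scratch rescoring at every step", {
    d <- makeDielDesign()
    set.seed(76)
    de <- toyExperiment(matrix(rnorm(8 * 27, sd = 0.5), 8, 27) + 6, d)
    b <- fourierBasis(de)
    pr <- nigPrior()
    p <- runBFC(de, b, pr)
    h <- mergeHistory(p)
    Y <- assay(de, "exprs")
    # replay the merges, rescoring each partition from raw data
    slots <- as.list(seq_len(8))
    for (r in seq_len(nrow(h))) {
        if (r > 1) {
            i <- h$cluster_i[r]; j <- h$cluster_j[r]
            slots[[i]] <- c(slots[[i]], slots[[j]])
            slots[[j]] <- integer()
        }
        blocks <- Filter(length, slots)
        fresh <- sum(vapply(blocks, function(bk)
            logEvidence(Y[bk, , drop = FALSE], b, pr), numeric(1)))
        expect_equal(h$score[r], fresh, tolerance = 1e-8)
    }
    # coverage conservation: the best partition covers the gene set exactly
    expect_setequal(names(clusterAssignments(p)), rownames(de))
})

test_that("greedy search matches exhaustive enumeration on separated toys", {
    d <- makeDielDesign()
    set.seed(77)
    base <- function(ph) 6 + 2.5 * cos(2 * pi * (d$tod - ph) / 24)
    m <- rbind(base(3) + rnorm(27, sd = 0.25),
               base(3) + rnorm(27, sd = 0.25),
               base(3) + rnorm(27, sd = 0.25),
               base(15) + rnorm(27, sd = 0.25),
               base(15) + rnorm(27, sd = 0.25),
               base(15) + rnorm(27, sd = 0.25))
    de <- toyExperiment(m, d)
    b <- fourierBasis(de); pr <- nigPrior()
    p <- runBFC(de, b, pr)

    Y <- assay(de, "exprs")
    memo <- new.env()
    blockEv <- function(bk) {
        key <- paste(bk, collapse = ",")
        if (is.null(memo[[key]]))
            memo[[key]] <- logEvidence(Y[bk, , drop = FALSE], b, pr)
        memo[[key]]
    }
    scores <- vapply(allSetPartitions(6), function(blocks)
        sum(vapply(blocks, blockEv, numeric(1))), numeric(1))
    expect_equal(partitionScore(p), max(scores), tolerance = 1e-8)
    # greedy dominates nearly all partitions by construction
    expect_gte(mean(partitionScore(p) >= scores - 1e-8), 0.99)
})

test_that("a strong cohesion prior coarsens noise-only data", {
    d <- makeDielDesign()
    set.seed(78)
    de <- toyExperiment(matrix(rnorm(6 * 27, sd = 0.3), 6, 27) + 7, d)
    p <- runBFC(de, partitionPrior = "cohesion", alpha = 1e-8)
    expect_lt(length(clusters(p)), 6)
})

test_that("cluster recovery holds across cluster counts and seeds", {
    for (C in c(2, 3, 4, 5)) {
        hits <- 0
        for (seed in 1:5) {
            de <- simulateDielData(
                nClusters = C, genesPerCluster = 40,
                phases = seq(0, 24, length.out = C + 1)[seq_len(C)],
                amplitudes = rep(2, C), nArrhythmic = 0, nUnexpressed = 0,
                noiseSd = 0.3, missingFrac = 0, seed = seed)
            p <- runBFC(de)
            truth <- truthLabels(de)
            if (ari(clusterAssignments(p)[truth$gene_id],
                    truth$true_cluster) >= 0.9) hits <- hits + 1
        }
        expect_gte(hits, 4)
    }
})

test_that("pooled clustering splits deterministically and degenerates to one run", {
    de <- simulateDielData(nClusters = 2, genesPerCluster = 5,
                           nArrhythmic = 0, nUnexpressed = 0, seed = 79)
    pools <- pooledBFC(de, poolSize = 4, seed = 2)
    asg <- attr(pools, "poolAssignments")
    expect_equal(sort(as.vector(table(asg)), decreasing = TRUE), c(4, 4, 2))
    expect_setequal(names(asg), rownames(de))
    # same seed, same split
    asg2 <- attr(pooledBFC(de, poolSize = 4, seed = 2), "poolAssignments")
    expect_identical(asg, asg2)

    # pool at least as large as the gene set: one pool, same partition
    one <- pooledBFC(de, poolSize = 100, seed = 2)
    expect_equal(length(one), 1)
    direct <- runBFC(de)
    expect_equal(partitionScore(one[[1]]), partitionScore(direct))
    expect_equal(clusterAssignments(one[[1]]), clusterAssignments(direct))

    expect_error(pooledBFC(de, poolSize = 1), "invalid argument")
})
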