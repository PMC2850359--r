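makeToyExperiment <- function(values, design = makeDielDesign(),
                              ids = NULL) {
    if (is.null(ids)) ids <- sprintf("g%02d", seq_len(nrow(values)))
    rownames(values) <- ids
    colnames(values) <- design$sample_id
    DielExperiment(values, design)
}

test_that("missingness filter drops genes strictly above the cut", {
    d <- makeDielDesign()
    m <- matrix(5, 3, 27)
    m[1, 1:20] <- NA   # 74% missing -> dropped at 0.7
    m[2, 1:18] <- NA   # 66.7% -> kept
    de <- makeToyExperiment(m, d)
    kept <- filterMissingness(de)
    expect_equal(rownames(kept), c("g02", "g03"))

    # boundary: any missing value is fatal at maxMissingFrac = 0
    m2 <- matrix(5, 2, 27)
    m2[1, 1] <- NA
    expect_equal(rownames(filterMissingness(makeToyExperiment(m2, d), 0)),
                 "g02")
    # empty matrix passes through without error
    expect_equal(nrow(filterMissingness(de[0, ])), 0)
})

test_that("filters commute with gene reordering", {
    de <- simulateDielData(nClusters = 2, genesPerCluster = 5,
                           missingFrac = 0.3, seed = 21)
    perm <- rev(seq_len(nrow(de)))
    a <- rownames(filterMissingness(de, 0.2))
    b <- rownames(filterMissingness(de[perm, ], 0.2))
    expect_setequal(a, b)
    expect_equal(b, intersect(rownames(de)[perm], b))  # order preserved
})

test_that("detection filter uses >= factor x background on at least one sample", {
    d <- makeDielDesign()   # background 100
    m <- matrix(log2(50), 4, 27)
    m[1, 5] <- log2(3 * 100)       # one sample at 3x background
    m[2, ] <- log2(1.0 * 100)      # at background everywhere
    m[3, 12] <- log2(2.6 * 100)    # tie at exactly 2.6x
    m[4, ] <- NA                   # no observed values
    de <- makeToyExperiment(m, d)
    expect_warning(expressed <- detectExpressed(de), "no observed values")
    expect_equal(unname(expressed), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("ANOVA screen matches the lm oracle, including missing-value genes", {
    d <- makeDielDesign()
    set.seed(31)
    m <- matrix(rnorm(6 * 27), 6, 27) + 8
    m[2, d$tod >= 12] <- m[2, d$tod >= 12] + 6   # strong time effect
    m[3, ] <- 4                                  # constant gene
    m[4, c(2, 9, 20)] <- NA                      # complete-case path
    de <- makeToyExperiment(m, d)
    res <- anovaScreen(de)

    for (g in c(1, 2, 5, 6)) {
        o <- oracleAnovaF(m[g, ], d$tod, d$kinetic)
        expect_equal(res$F[g], unname(o["F"]), tolerance = 1e-10)
        expect_equal(res$p[g], unname(o["p"]), tolerance = 1e-10)
    }
    obs <- !is.na(m[4, ])
    o4 <- oracleAnovaF(m[4, obs], d$tod[obs], d$kinetic[obs])
    expect_equal(res$F[4], unname(o4["F"]), tolerance = 1e-10)

    expect_lt(res$p[2], 1e-3)
    expect_true(res$selected[2])
    expect_equal(res$F[3], 0)
    expect_equal(res$p[3], 1)
    expect_false(res$selected[3])
})

test_that("ANOVA screen rejects designs without replicated time levels", {
    d1 <- makeDielDesign(nKinetics = 1)
    de <- makeToyExperiment(matrix(rnorm(18), 2, 9), d1)
    expect_error(anovaScreen(de), "fewer than two kinetics")
})

test_that("null ANOVA p-values are uniform (KS) and calibrated at 1e-3", {
    d <- makeDielDesign()
    set.seed(41)
    m <- matrix(rnorm(2000 * 27), 2000, 27)
    de <- makeToyExperiment(m, d, ids = sprintf("g%04d", 1:2000))
    res <- anovaScreen(de)
    ks <- max(abs(sort(res$p) - (seq_len(2000) - 0.5) / 2000))
    expect_lt(ks, 0.05)
    expect_lte(sum(res$selected), stats::qbinom(0.995, 2000, 1e-3))
})

test_that("PCA dispersion selection behaves on constructed cohorts", {
    d <- makeDielDesign()
    set.seed(51)
    flat <- matrix(rnorm(90 * 27, sd = 0.3), 90, 27)
    sinus <- t(vapply(seq_len(10), function(i)
        3 * cos(2 * pi * (d$tod - 2 * i) / 24) + rnorm(27, sd = 0.3),
        numeric(27)))
    de <- makeToyExperiment(rbind(sinus, flat), d,
                            ids = sprintf("g%03d", 1:100))
    sel <- pcaSelect(de, 10)
    expect_setequal(rownames(sel$experiment), sprintf("g%03d", 1:10))

    # zero-variance gene scores 0 and loses to any varying gene
    m <- rbind(rep(3, 27), sinus[1, ], sinus[1, ])
    de2 <- makeToyExperiment(m, d)
    sel2 <- pcaSelect(de2, 2)
    expect_equal(unname(sel2$score["g01"]), 0)
    expect_false("g01" %in% rownames(sel2$experiment))
    # duplicated genes score identically
    expect_equal(unname(sel2$score["g02"]), unname(sel2$score["g03"]))

    # selecting all genes is the identity on the gene set
    expect_equal(rownames(pcaSelect(de, 100)$experiment), rownames(de))
    expect_error(pcaSelect(de, 0), "invalid argument")
})

test_that("amplitudes bin into the nine unit-width strata", {
    d <- makeDielDesign()
    m <- rbind(8 + 5.5 / 2 * cos(2 * pi * d$tod / 24),  # amplitude 5.5
               rep(8, 27))                               # constant
    de <- makeToyExperiment(m, d)
    ab <- amplitudeBins(de)
    expect_equal(unname(ab$amplitude), c(5.5, 0), tolerance = 1e-12)
    expect_equal(ab$histogram$count[ab$histogram$bin == "5-6"], 1)
    expect_equal(ab$histogram$count[ab$histogram$bin == "0-1"], 1)

    # a noiseless cohort reproduces its prescribed strata exactly
    de2 <- simulateDielData(nClusters = 9, genesPerCluster = 3,
                            phases = rep(0, 9),
                            amplitudes = seq(0.5, 8.5, by = 1),
                            nArrhythmic = 0, nUnexpressed = 0,
                            noiseSd = 0, missingFrac = 0, seed = 1)
    expect_equal(amplitudeBins(de2)$histogram$count, rep(3, 9))
})

test_that("screening cascade enforces the stage nesting invariants", {
    de <- simulateDielData(seed = 2)
    scr <- screenGenes(de)
    r <- scr$result
    expect_true(all(!r$selected_anova | r$expressed))
    expect_true(all(!r$selected_anova | (r$p < 1e-3)))
    expect_true(all(!r$selected_pca | r$selected_anova))
    cnt <- scr$counts
    expect_true(cnt$genes_in >= cnt$expressed &&
                cnt$expressed >= cnt$anova_selected &&
                cnt$anova_selected >= cnt$pca_selected)
    expect_equal(sum(r$selected_pca), nrow(scr$selected))
})
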