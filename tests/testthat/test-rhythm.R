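# least-squares coefficients realized through an effectively flat prior
flatFit <- function(y, b) posteriorProfile(y, b, nigPrior(v0 = 1e8))

test_that("THR separates pure 24-h, pure 12-h and mixed waveforms", {
    b <- fourierBasis(makeDielDesign())
    t <- b@times
    expect_equal(thr(flatFit(cos(2 * pi * t / 24), b)), 1.0,
                 tolerance = 1e-9)
    expect_lte(thr(flatFit(cos(2 * pi * t / 12), b)), 1e-9)
    mix <- cos(2 * pi * t / 24) + cos(2 * pi * t / 12)
    expect_equal(thr(flatFit(mix, b)), 0.5, tolerance = 1e-6)
})

test_that("THR is amplitude-free and bounded", {
    b <- fourierBasis(makeDielDesign())
    set.seed(81)
    y <- rnorm(27) + 2 * cos(2 * pi * b@times / 24)
    p1 <- posteriorProfile(y, b)
    p2 <- posteriorProfile(10 * y, b)
    expect_equal(thr(p1), thr(p2), tolerance = 1e-10)
    expect_gte(thr(p1), 0); expect_lte(thr(p1), 1)
})

test_that("flat clusters get THR 0 with a flag; missing harmonic errors", {
    b <- fourierBasis(makeDielDesign())
    flat <- posteriorProfile(rep(0, 27), b)
    v <- thr(flat)
    expect_equal(as.numeric(v), 0)
    expect_true(attr(v, "flat"))

    b1 <- fourierBasis(makeDielDesign(), harmonics = c(1L, 6L))
    post <- posteriorProfile(rep(1, 27), b1)
    expect_error(thr(post), "configuration error")
})

test_that("rhythm classes use strict cuts", {
    expect_equal(classifyRhythm(c(0.41, 0.4, 0.75, 0.6)),
                 c("rhythmic", "arrhythmic", "robust", "rhythmic"))
    expect_error(classifyRhythm(0.5, rhythmicCut = 0.7, robustCut = 0.6),
                 "invalid argument")
})

test_that("phase lands where the diurnal component peaks", {
    b <- fourierBasis(makeDielDesign())
    t <- b@times
    p15 <- flatFit(cos(2 * pi * (t - 15) / 24), b)
    expect_equal(phaseEstimate(p15), 15, tolerance = 0.01)

    psin <- flatFit(sin(2 * pi * t / 24), b)
    expect_equal(phaseEstimate(psin), 6, tolerance = 0.01)

    flat <- posteriorProfile(rep(0, 27), b)
    expect_warning(ph <- phaseEstimate(flat), "undefined phase")
    expect_true(is.na(ph))
})

test_that("phase is equivariant under time shifts", {
    d <- makeDielDesign()
    y <- cos(2 * pi * (d$t - 10) / 24)
    for (delta in c(3, 7.5, 13)) {
        b0 <- fourierBasis(d$t, harmonics = c(1L, 3L, 6L, 9L), period = 72)
        bS <- fourierBasis(d$t + delta, harmonics = c(1L, 3L, 6L, 9L),
                           period = 72)
        ph0 <- phaseEstimate(flatFit(y, b0))
        phS <- phaseEstimate(flatFit(y, bS))
        expect_equal((phS - ph0) %% 24, delta %% 24, tolerance = 0.01)
    }
})

test_that("polar summary encodes phase, THR and size", {
    s <- data.frame(cluster_id = c("a", "b", "c"),
                    size = c(10, 50, 4),
                    thr = c(1, 0.5, 0.2),
                    phase_h = c(0, 12, NA),
                    rhythm_class = c("robust", "rhythmic", "arrhythmic"))
    pol <- polarSummary(s)
    expect_equal(nrow(pol), 2)
    expect_equal(attr(pol, "n_omitted"), 1)
    expect_equal(pol$angle[1], 0)
    expect_equal(pol$radius[1], 1)
    expect_equal(pol$dot_size[2] / pol$dot_size[1], 5)

    p <- plotPolarClusters(pol)
    expect_s3_class(p, "ggplot")
})

test_that("six evenly phased clusters land at evenly spaced angles", {
    de <- simulateDielData(nClusters = 6, genesPerCluster = 3,
                           amplitudes = rep(3, 6),
                           nArrhythmic = 0, nUnexpressed = 0,
                           noiseSd = 0, missingFrac = 0, seed = 1)
    p <- runBFC(de)
    pol <- polarSummary(rhythmSummary(p))
    expect_equal(nrow(pol), 6)
    gaps <- diff(sort(pol$angle))
    expect_true(all(abs(gaps - 2 * pi / 6) < 0.05))
})

test_that("clustered rhythmic genes score rhythmic; summaries are consistent", {
    de <- simulateDielData(nClusters = 3, genesPerCluster = 8,
                           amplitudes = rep(2.5, 3),
                           nArrhythmic = 0, nUnexpressed = 0,
                           noiseSd = 0.3, missingFrac = 0, seed = 82)
    p <- runBFC(de)
    rs <- rhythmSummary(p)
    expect_equal(sum(rs$size), 24)
    expect_true(all(rs$thr >= 0 & rs$thr <= 1))
    expect_true(all(rs$rhythm_class[rs$thr > 0.6] == "robust"))
    expect_true(all(rs$thr[rs$rhythm_class == "rhythmic"] > 0.4))
})
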