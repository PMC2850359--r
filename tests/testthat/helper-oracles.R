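# Independent oracles used by the tests. These deliberately take different
# routes than the package internals: the evidence oracle integrates the noise
# variance numerically against the exact Gaussian beta-marginal density
# (an N x N covariance route, vs the package's p x p normal-equations route),
# and is itself cross-checked by brute-force 2-D grid quadrature on scalar-beta
# cases; the ANOVA oracle is a permutation test; the partition oracle
# enumerates all set partitions.

# log density of y ~ N(mu, sigma2 * (I + v0 * X X'))   (beta integrated out)
.oracleLogMarginalGivenSigma2 <- function(y, X, prior, sigma2) {
    N <- length(y)
    m0 <- rep(prior@m0, length.out = ncol(X))
    S <- sigma2 * (diag(N) + prior@v0 * tcrossprod(X))
    R <- chol(S)
    z <- forwardsolve(t(R), y - drop(X %*% m0))
    -N / 2 * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# evidence by adaptive quadrature over sigma2 (integrand maximum rescaled
# out for numerical stability)
oracleLogEvidence <- function(y, X, prior) {
    a0 <- prior@a0; b0 <- prior@b0
    logIntegrand <- function(s2)
        .oracleLogMarginalGivenSigma2(y, X, prior, s2) +
        a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(s2) - b0 / s2
    # locate the peak on a log grid, then integrate the rescaled integrand
    grid <- exp(seq(log(1e-6), log(1e6), length.out = 200))
    lg <- vapply(grid, logIntegrand, numeric(1))
    M <- max(lg)
    f <- function(s2) exp(vapply(s2, logIntegrand, numeric(1)) - M)
    val <- stats::integrate(f, 0, Inf, rel.tol = 1e-10,
                            subdivisions = 2000L)$value
    M + log(val)
}

# brute-force 2-D grid quadrature over (beta, sigma2); scalar beta only
oracleLogEvidence2D <- function(y, X, prior, nBeta = 4001, nS2 = 4001) {
    stopifnot(ncol(X) == 1)
    m0 <- prior@m0; v0 <- prior@v0; a0 <- prior@a0; b0 <- prior@b0
    bGrid <- seq(m0 - 40, m0 + 40, length.out = nBeta)
    s2Grid <- exp(seq(log(1e-5), log(1e5), length.out = nS2))
    db <- diff(bGrid[1:2])
    logRows <- vapply(s2Grid, function(s2) {
        ll <- -length(y) / 2 * log(2 * pi * s2) -
            colSums((y - outer(drop(X), bGrid))^2) / (2 * s2)
        lp <- -0.5 * log(2 * pi * s2 * v0) - (bGrid - m0)^2 / (2 * s2 * v0)
        li <- a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(s2) - b0 / s2
        m <- max(ll + lp)
        m + log(sum(exp(ll + lp - m)) * db) + li
    }, numeric(1))
    # trapezoid in log-sigma2 space: ds2 = s2 d(log s2)
    dls <- diff(log(s2Grid[1:2]))
    lr <- logRows + log(s2Grid) + log(dls)
    m <- max(lr)
    m + log(sum(exp(lr - m)))
}

# two-way (time-of-day + kinetic, no interaction) F statistic for the
# time-of-day effect, straight from lm residuals
oracleAnovaF <- function(y, tod, kin) {
    full <- stats::lm(y ~ factor(tod) + factor(kin))
    red <- stats::lm(y ~ factor(kin))
    a <- stats::anova(red, full)
    c(F = a$F[2], p = a$`Pr(>F)`[2])
}

# permutation p-value of the time-of-day F statistic, vectorized over
# permutations through residual-maker quadratic forms
oraclePermutationP <- function(y, tod, kin, nPerm = 10000, seed = 99) {
    Xf <- stats::model.matrix(~ factor(tod) + factor(kin))
    Xr <- stats::model.matrix(~ factor(kin))
    Mf <- diag(length(y)) - Xf %*% solve(crossprod(Xf), t(Xf))
    Mr <- diag(length(y)) - Xr %*% solve(crossprod(Xr), t(Xr))
    fstat <- function(Y) {
        rf <- colSums((Mf %*% Y) * Y)
        rr <- colSums((Mr %*% Y) * Y)
        (rr - rf) / rf    # monotone in F (common df factored out)
    }
    obs <- fstat(matrix(y))
    set.seed(seed)
    perms <- replicate(nPerm, sample(y))
    mean(fstat(perms) >= obs)
}

# all set partitions of 1..n as lists of member-index vectors
# (restricted growth strings)
allSetPartitions <- function(n) {
    out <- list()
    rec <- function(s, k) {
        i <- length(s) + 1
        if (i > n) {
            blocks <- split(seq_len(n), s)
            out[[length(out) + 1]] <<- unname(blocks)
            return(invisible())
        }
        for (v in seq_len(k + 1)) rec(c(s, v), max(k, v))
    }
    rec(integer(), 0L)
    out
}

# partition score = sum of block evidences (uniform partition prior),
# computed from the public evidence function over raw data blocks
oraclePartitionScore <- function(Y, basis, prior, blocks) {
    sum(vapply(blocks, function(b)
        dielBFC::logEvidence(Y[b, , drop = FALSE], basis, prior), numeric(1)))
}

# adjusted Rand index between two labelings (via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

defaultBasisDesign <- function() makeDielDesign()
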