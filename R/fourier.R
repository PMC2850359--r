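#' Build a Fourier design matrix
#'
#' Constructs the harmonic regression basis over the concatenated time axis:
#' a constant column followed by \code{cos(2*pi*h*t/period)},
#' \code{sin(2*pi*h*t/period)} pairs for each harmonic \code{h} in ascending
#' order. With the default 3-kinetic design the fundamental period is the full
#' 72-h concatenated span, so harmonic 3 is the 24-h diurnal component; the
#' default harmonic set \code{{1,3,6,9}} plus the constant yields 9 columns.
#'
#' @param design a \linkS4class{DielExperiment}, a design data.frame (see
#'   [makeDielDesign()]), or a numeric vector of times in hours.
#' @param harmonics distinct positive integers (default \code{c(1,3,6,9)}).
#' @param period fundamental period in hours. Default: the concatenated span
#'   \code{24 * max(kinetic)} when the design carries kinetics, otherwise the
#'   time span rounded up to a whole day.
#' @return a \linkS4class{FourierBasis}.
#' @examples
#' b <- fourierBasis(makeDielDesign())
#' dim(b@matrix)  # 27 x 9
#' @export
fourierBasis <- function(design, harmonics = c(1L, 3L, 6L, 9L),
                         period = NULL) {
    if (is(design, "DielExperiment")) {
        times <- sampleTimes(design)
        kin <- kineticOf(design)
    } else if (is.data.frame(design) || is(design, "DataFrame")) {
        times <- design$t
        kin <- design$kinetic
    } else {
        times <- as.numeric(design)
        kin <- NULL
    }
    if (length(times) == 0) stop("design must be nonempty")
    harmonics <- as.integer(harmonics)
    if (length(harmonics) == 0 || any(harmonics < 1))
        stop("harmonics must be a nonempty set of positive integers")
    if (anyDuplicated(harmonics))
        stop("invalid argument: duplicate harmonic values")
    if (is.null(period))
        period <- if (!is.null(kin)) 24 * max(kin)
                  else 24 * max(1, ceiling((max(times) - min(times)) / 24))
    stopIfNot(period > 0, "period must be positive")

    H <- length(harmonics)
    m <- matrix(0, length(times), 2 * H + 1)
    m[, 1] <- 1
    for (i in seq_len(H)) {
        w <- 2 * pi * harmonics[i] * times / period
        m[, 2 * i] <- cos(w)
        m[, 2 * i + 1] <- sin(w)
    }
    colnames(m) <- c("const",
                     as.vector(rbind(paste0("cos", harmonics),
                                     paste0("sin", harmonics))))
    new("FourierBasis", times = times, harmonics = harmonics,
        period = period, matrix = m)
}

# ---- sufficient statistics --------------------------------------------------
# A cluster's evidence depends on its stacked rows only through
# (X'X, X'y, y'y, n), which are additive over genes; all clustering math runs
# on these so merges cost O(p^2) + one O(p^3) factorization.

# per-gene stats; y is the gene's row aligned with the basis rows, NAs dropped
.geneStats <- function(y, B) {
    obs <- !is.na(y)
    X <- B[obs, , drop = FALSE]
    list(XtX = crossprod(X), Xty = drop(crossprod(X, y[obs])),
         yty = sum(y[obs]^2), n = sum(obs))
}

.addStats <- function(s1, s2) {
    list(XtX = s1$XtX + s2$XtX, Xty = s1$Xty + s2$Xty,
         yty = s1$yty + s2$yty, n = s1$n + s2$n)
}

.expandM0 <- function(prior, p) {
    m0 <- prior@m0
    if (length(m0) == 1) rep(m0, p)
    else if (length(m0) == p) m0
    else stop("prior m0 must be scalar or one value per basis column")
}

# closed-form NIG posterior/evidence from sufficient statistics
.nigFit <- function(stats, prior) {
    if (stats$n < 1)
        stop("undefined evidence: no observed values in cluster")
    p <- nrow(stats$XtX)
    m0 <- .expandM0(prior, p)
    v0 <- prior@v0
    Kn <- stats$XtX + diag(1 / v0, p)
    R <- chol(Kn)
    rhs <- stats$Xty + m0 / v0
    mn <- backsolve(R, forwardsolve(t(R), rhs))
    quad <- max(stats$yty + sum(m0^2) / v0 - sum(rhs * mn), 0)
    an <- prior@a0 + stats$n / 2
    bn <- prior@b0 + quad / 2
    logev <- -stats$n / 2 * log(2 * pi) -
        0.5 * p * log(v0) - sum(log(diag(R))) +
        prior@a0 * log(prior@b0) - an * log(bn) +
        lgamma(an) - lgamma(prior@a0)
    list(betaHat = drop(mn), an = an, bn = bn, logEvidence = logev)
}

.asGeneMatrix <- function(Y, basis) {
    nT <- nrow(basis@matrix)
    if (is.null(dim(Y))) {
        if (length(Y) %% nT != 0)
            stop("Y length must be a multiple of the number of basis rows")
        Y <- matrix(Y, ncol = nT, byrow = TRUE)
    }
    if (ncol(Y) != nT)
        stop("Y columns must align with the basis rows")
    Y
}

.clusterStats <- function(Y, basis) {
    Y <- .asGeneMatrix(Y, basis)
    stats <- .geneStats(Y[1, ], basis@matrix)
    for (g in seq_len(nrow(Y))[-1])
        stats <- .addStats(stats, .geneStats(Y[g, ], basis@matrix))
    stats
}

# ---- public model core ------------------------------------------------------

#' Log marginal likelihood of a cluster of curves
#'
#' Evaluates, in closed form, the log evidence
#' \deqn{\log \int\!\!\int N(Y \mid B\beta, \sigma^2 I)\,
#'   N(\beta \mid m_0, \sigma^2 v_0 I)\,
#'   \mathrm{InvGamma}(\sigma^2 \mid a_0, b_0)\, d\beta\, d\sigma^2,}
#' the probability of the cluster's stacked observations with coefficients and
#' variance integrated out. All genes in the cluster share one
#' \eqn{(\beta, \sigma^2)}; each contributes its own copy of the basis rows,
#' and missing entries are dropped row-wise.
#'
#' @param Y a numeric matrix (genes x times, columns aligned with the basis
#'   rows) or a stacked numeric vector whose length is a multiple of the
#'   number of basis rows. \code{NA} marks missing values.
#' @param basis a \linkS4class{FourierBasis}.
#' @param prior an \linkS4class{NIGPrior}.
#' @return the log evidence (a finite scalar).
#' @examples
#' b <- fourierBasis(makeDielDesign())
#' y <- cos(2 * pi * b@times / 24)
#' logEvidence(y, b, nigPrior())
#' @export
logEvidence <- function(Y, basis, prior = nigPrior()) {
    .nigFit(.clusterStats(Y, basis), prior)$logEvidence
}

#' Conjugate posterior profile of a cluster
#'
#' Computes the normal-inverse-gamma posterior for a cluster's shared
#' coefficients and noise variance:
#' \code{betaHat = (B'B + v0^-1 I)^-1 (B'Y + v0^-1 m0)} (summed over member
#' genes), the updated inverse-gamma parameters for \eqn{\sigma^2}, the
#' per-harmonic (a, b) cosine/sine coefficient pairs read from \code{betaHat},
#' and the log evidence. The fitted mean curve is \code{basis matrix \%*\%
#' betaHat} (see [fittedProfile()]).
#'
#' @inheritParams logEvidence
#' @param members optional gene ids (defaults to rownames of \code{Y}).
#' @return a \linkS4class{ClusterPosterior}.
#' @examples
#' b <- fourierBasis(makeDielDesign())
#' post <- posteriorProfile(cos(2 * pi * b@times / 24), b)
#' harmonicCoefficients(post)
#' @export
posteriorProfile <- function(Y, basis, prior = nigPrior(), members = NULL) {
    Ym <- .asGeneMatrix(Y, basis)
    if (is.null(members))
        members <- if (!is.null(rownames(Ym))) rownames(Ym)
                   else sprintf("y%d", seq_len(nrow(Ym)))
    fit <- .nigFit(.clusterStats(Ym, basis), prior)
    .makePosterior(members, fit, basis@harmonics)
}

.makePosterior <- function(members, fit, harmonics) {
    H <- length(harmonics)
    hc <- cbind(a = fit$betaHat[2 * seq_len(H)],
                b = fit$betaHat[2 * seq_len(H) + 1])
    rownames(hc) <- as.character(harmonics)
    new("ClusterPosterior", members = as.character(members),
        betaHat = fit$betaHat, harmonics = as.integer(harmonics),
        harmonicCoeffs = hc,
        sigma2Post = c(shape = fit$an, scale = fit$bn),
        logEvidence = fit$logEvidence)
}

#' Fitted mean curve of a cluster posterior
#'
#' @param post a \linkS4class{ClusterPosterior}.
#' @param basis the \linkS4class{FourierBasis} the posterior was fitted on.
#' @return numeric vector, the posterior mean profile at the basis times.
#' @export
fittedProfile <- function(post, basis) {
    drop(basis@matrix %*% post@betaHat)
}
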