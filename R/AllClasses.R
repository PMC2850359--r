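#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#'   rowData<-
NULL

#' DielExperiment: a diel expression time course
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a genes x
#' samples matrix of normalized log2 expression values (assay \code{"exprs"},
#' missing values as \code{NA}) together with the per-sample design in
#' \code{colData}: \code{kinetic} (biological replicate series, 1..K),
#' \code{tod} (nominal time of day, hours in [0,24)), \code{t} (hours on the
#' concatenated multi-day axis, \code{t = 24*(kinetic-1) + tod}), \code{light}
#' (logical, light phase) and \code{background} (per-sample background signal
#' on the linear scale).
#'
#' @seealso [makeDielDesign()], [simulateDielData()], [readDielData()]
#' @exportClass DielExperiment
setClass("DielExperiment", contains = "SummarizedExperiment")

setValidity("DielExperiment", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- colData(object)
    need <- c("kinetic", "tod", "t", "light", "background")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(msg)) {
        if (any(cd$tod < 0 | cd$tod >= 24))
            msg <- c(msg, "tod must lie in [0, 24)")
        if (any(cd$background < 0))
            msg <- c(msg, "background must be nonnegative")
        if (!is.logical(cd$light))
            msg <- c(msg, "light must be logical")
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "gene ids (rownames) must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a DielExperiment
#'
#' @param exprs numeric matrix of log2 expression, genes x samples; \code{NA}
#'   marks missing values. Row names are gene ids, column names sample ids.
#' @param design a data.frame or DataFrame with one row per sample and columns
#'   \code{sample_id}, \code{kinetic}, \code{tod}, \code{t}, \code{light},
#'   \code{background} (see [makeDielDesign()]).
#' @param rowData optional per-gene annotation (e.g. truth labels).
#' @return a \linkS4class{DielExperiment}.
#' @examples
#' d <- makeDielDesign(nKinetics = 1, tods = c(0, 12))
#' m <- matrix(rnorm(4), 2, 2, dimnames = list(c("g1", "g2"), d$sample_id))
#' DielExperiment(m, d)
#' @export
DielExperiment <- function(exprs, design, rowData = NULL) {
    design <- as.data.frame(design)
    if (!is.null(design$sample_id)) {
        if (is.null(colnames(exprs)))
            colnames(exprs) <- design$sample_id
        if (!identical(colnames(exprs), as.character(design$sample_id)))
            stop("column names of 'exprs' do not match design$sample_id")
        rownames(design) <- design$sample_id
    }
    se <- SummarizedExperiment(
        assays = list(exprs = as.matrix(exprs)),
        colData = DataFrame(design))
    if (!is.null(rowData))
        rowData(se) <- DataFrame(rowData)
    new("DielExperiment", se)
}

#' FourierBasis: harmonic design matrix for curve fitting
#'
#' Columns are the constant term followed by (cos, sin) pairs for each
#' harmonic of the fundamental period, in ascending harmonic order, evaluated
#' at the concatenated sample times.
#'
#' @slot times numeric, sample times in hours (concatenated axis).
#' @slot harmonics integer, the included harmonics (default \code{c(1,3,6,9)}).
#' @slot period numeric, fundamental period in hours.
#' @slot matrix numeric matrix, \code{length(times)} x
#'   \code{2 * length(harmonics) + 1}.
#' @seealso [fourierBasis()]
#' @exportClass FourierBasis
setClass("FourierBasis",
    representation(times = "numeric", harmonics = "integer",
                   period = "numeric", matrix = "matrix"))

setValidity("FourierBasis", function(object) {
    msg <- character()
    if (anyDuplicated(object@harmonics))
        msg <- c(msg, "harmonics must be distinct")
    if (any(object@harmonics < 1))
        msg <- c(msg, "harmonics must be positive integers")
    if (length(object@period) != 1 || object@period <= 0)
        msg <- c(msg, "period must be a single positive number")
    if (nrow(object@matrix) != length(object@times))
        msg <- c(msg, "matrix rows must match times")
    if (ncol(object@matrix) != 2 * length(object@harmonics) + 1)
        msg <- c(msg, "matrix must have 2*|harmonics|+1 columns")
    if (length(msg)) msg else TRUE
})

#' NIGPrior: conjugate normal-inverse-gamma prior
#'
#' Prior for the Bayesian linear model \code{Y = B beta + eps}:
#' \code{beta | sigma2 ~ N(m0, sigma2 * v0 * I)} and
#' \code{sigma2 ~ InvGamma(a0, b0)}.
#'
#' @slot m0 numeric, prior mean of the coefficients (scalar recycled, or one
#'   value per basis column).
#' @slot v0 numeric, positive prior coefficient scale.
#' @slot a0,b0 numeric, positive inverse-gamma shape and scale for sigma2.
#' @seealso [nigPrior()]
#' @exportClass NIGPrior
setClass("NIGPrior",
    representation(m0 = "numeric", v0 = "numeric",
                   a0 = "numeric", b0 = "numeric"))

setValidity("NIGPrior", function(object) {
    if (object@v0 <= 0 || object@a0 <= 0 || object@b0 <= 0)
        "v0, a0 and b0 must all be positive" else TRUE
})

#' Construct an NIGPrior
#'
#' Defaults are weakly informative on log2-ratio expression data while keeping
#' the marginal likelihood proper.
#'
#' @param m0 prior coefficient mean (default 0).
#' @param v0 prior coefficient scale (default 100); the prior covariance of
#'   the coefficients is \code{sigma2 * v0 * I}.
#' @param a0,b0 inverse-gamma shape and scale for the noise variance
#'   (default 0.001 each).
#' @return an \linkS4class{NIGPrior}.
#' @examples nigPrior()
#' @export
nigPrior <- function(m0 = 0, v0 = 100, a0 = 0.001, b0 = 0.001) {
    new("NIGPrior", m0 = m0, v0 = v0, a0 = a0, b0 = b0)
}

#' ClusterPosterior: conjugate posterior for one cluster of curves
#'
#' @slot members character, gene ids in the cluster.
#' @slot betaHat numeric, posterior mean of the Fourier coefficients
#'   (constant, then cos/sin per harmonic).
#' @slot harmonics integer, harmonics of the basis used for the fit.
#' @slot harmonicCoeffs numeric matrix, one row per harmonic with columns
#'   \code{a} (cosine coefficient) and \code{b} (sine coefficient), read
#'   directly from \code{betaHat}.
#' @slot sigma2Post numeric length 2, posterior inverse-gamma (shape, scale)
#'   for the noise variance.
#' @slot logEvidence numeric, closed-form log marginal likelihood of the
#'   cluster's stacked observations.
#' @exportClass ClusterPosterior
setClass("ClusterPosterior",
    representation(members = "character", betaHat = "numeric",
                   harmonics = "integer", harmonicCoeffs = "matrix",
                   sigma2Post = "numeric", logEvidence = "numeric"))

setValidity("ClusterPosterior", function(object) {
    msg <- character()
    if (nrow(object@harmonicCoeffs) != length(object@harmonics))
        msg <- c(msg, "one harmonicCoeffs row per harmonic required")
    if (length(object@betaHat) != 2 * length(object@harmonics) + 1)
        msg <- c(msg, "betaHat length must be 2*|harmonics|+1")
    if (length(msg)) msg else TRUE
})

#' DielPartition: a clustering of expression curves
#'
#' The result of Bayesian Fourier Clustering: a set of disjoint clusters
#' covering the input genes, the partition score (sum of member-cluster log
#' evidences plus any log partition-prior term), and the greedy merge
#' trajectory.
#'
#' @slot clusters list of \linkS4class{ClusterPosterior}.
#' @slot score numeric, partition score.
#' @slot history data.frame with columns \code{step}, \code{cluster_i},
#'   \code{cluster_j}, \code{score}: the score after every merge (step 0 is
#'   the all-singletons state; \code{NA} merge indices).
#' @slot geneIds character, the full input gene set.
#' @slot basis the \linkS4class{FourierBasis} used.
#' @slot prior the \linkS4class{NIGPrior} used.
#' @slot partitionPrior character, \code{"uniform"} or \code{"cohesion"}.
#' @slot alpha numeric, cohesion concentration (ignored for uniform).
#' @slot geneStats list, per-gene sufficient statistics (internal; lets
#'   [bestMerge()] evaluate candidate merges without re-touching the data).
#' @exportClass DielPartition
setClass("DielPartition",
    representation(clusters = "list", score = "numeric",
                   history = "data.frame", geneIds = "character",
                   basis = "FourierBasis", prior = "NIGPrior",
                   partitionPrior = "character", alpha = "numeric",
                   geneStats = "list"))

setValidity("DielPartition", function(object) {
    members <- unlist(lapply(object@clusters, slot, "members"))
    if (anyDuplicated(members))
        return("clusters must be disjoint")
    if (!setequal(members, object@geneIds))
        return("clusters must cover the input gene set exactly")
    TRUE
})

setMethod("show", "DielExperiment", function(object) {
    callNextMethod()
    cd <- colData(object)
    cat(sprintf("diel design: %d kinetic(s), %d time points, L/D %s\n",
                length(unique(cd$kinetic)), length(unique(cd$tod)),
                if (any(cd$light) && any(!cd$light)) "cycling" else "constant"))
})

setMethod("show", "FourierBasis", function(object) {
    cat(sprintf(
        "FourierBasis: %d rows x %d columns (harmonics %s of %g h period)\n",
        nrow(object@matrix), ncol(object@matrix),
        paste(object@harmonics, collapse = ","), object@period))
})

setMethod("show", "NIGPrior", function(object) {
    cat(sprintf("NIGPrior: m0 = %s, v0 = %g, a0 = %g, b0 = %g\n",
                paste(format(object@m0), collapse = ","),
                object@v0, object@a0, object@b0))
})

setMethod("show", "ClusterPosterior", function(object) {
    cat(sprintf("ClusterPosterior: %d gene(s), log evidence %.4f\n",
                length(object@members), object@logEvidence))
})

setMethod("show", "DielPartition", function(object) {
    cat(sprintf(
        "DielPartition: %d genes in %d clusters, score %.4f (%s prior)\n",
        length(object@geneIds), length(object@clusters), object@score,
        object@partitionPrior))
})

#' Accessors for BFC objects
#'
#' \code{clusters()} returns the list of \linkS4class{ClusterPosterior}
#' objects of a partition; \code{partitionScore()} its score;
#' \code{clusterAssignments()} a named integer vector mapping each gene id to
#' its cluster index; \code{clusterSizes()} the member counts;
#' \code{logEvidenceOf()} the stored log evidence of a cluster;
#' \code{harmonicCoefficients()} the per-harmonic (a, b) coefficient matrix.
#'
#' @param x a \linkS4class{DielPartition} or \linkS4class{ClusterPosterior}.
#' @return see description.
#' @name partition-accessors
#' @examples
#' de <- simulateDielData(nClusters = 2, genesPerCluster = 3,
#'                        nArrhythmic = 0, nUnexpressed = 0, seed = 1)
#' p <- runBFC(de)
#' clusterSizes(p)
NULL

#' @rdname partition-accessors
#' @export
clusters <- function(x) x@clusters

#' @rdname partition-accessors
#' @export
partitionScore <- function(x) x@score

#' @rdname partition-accessors
#' @export
mergeHistory <- function(x) x@history

#' @rdname partition-accessors
#' @export
clusterAssignments <- function(x) {
    idx <- rep(seq_along(x@clusters),
               vapply(x@clusters, function(cl) length(cl@members), 1L))
    names(idx) <- unlist(lapply(x@clusters, slot, "members"))
    idx[x@geneIds]
}

#' @rdname partition-accessors
#' @export
clusterSizes <- function(x)
    vapply(x@clusters, function(cl) length(cl@members), 1L)

#' @rdname partition-accessors
#' @export
logEvidenceOf <- function(x) x@logEvidence

#' @rdname partition-accessors
#' @export
harmonicCoefficients <- function(x) x@harmonicCoeffs

#' @rdname partition-accessors
#' @export
posteriorMean <- function(x) x@betaHat

#' Sample design accessors
#'
#' Convenience accessors for the per-sample design of a
#' \linkS4class{DielExperiment}.
#'
#' @param x a \linkS4class{DielExperiment}.
#' @return \code{sampleDesign()} returns the design as a data.frame;
#'   the others return the corresponding per-sample vector.
#' @name design-accessors
#' @examples
#' de <- simulateDielData(nClusters = 1, genesPerCluster = 2, seed = 1)
#' head(sampleDesign(de))
NULL

#' @rdname design-accessors
#' @export
sampleDesign <- function(x) as.data.frame(colData(x))

#' @rdname design-accessors
#' @export
timeOfDay <- function(x) colData(x)$tod

#' @rdname design-accessors
#' @export
sampleTimes <- function(x) colData(x)$t

#' @rdname design-accessors
#' @export
lightPhase <- function(x) colData(x)$light

#' @rdname design-accessors
#' @export
backgroundLevel <- function(x) colData(x)$background

#' @rdname design-accessors
#' @export
kineticOf <- function(x) colData(x)$kinetic

#' @rdname design-accessors
#' @export
truthLabels <- function(x) as.data.frame(rowData(x))
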