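#' Third harmonic ratio: strength of the diurnal component
#'
#' The THR of a cluster is the fraction of its fitted harmonic power carried
#' by the diurnal harmonic (harmonic 3 of the 72-h fundamental, i.e. the 24-h
#' component):
#' \deqn{THR = (a_3^2 + b_3^2) / \sum_{i \in H} (a_i^2 + b_i^2)}
#' where \eqn{a_i}, \eqn{b_i} are the cosine and sine coefficients of harmonic
#' \eqn{i} and the sum runs over the included harmonics (the constant term
#' carries no rhythm information and is excluded). A flat cluster (all
#' harmonic power zero) gets THR 0 with attribute \code{flat = TRUE}.
#'
#' @param post a \linkS4class{ClusterPosterior}.
#' @param numeratorHarmonic harmonic of the diurnal component (default 3).
#' @param denominatorHarmonics harmonics to sum in the denominator; default
#'   all harmonics of the fit.
#' @return THR in [0, 1].
#' @examples
#' b <- fourierBasis(makeDielDesign())
#' thr(posteriorProfile(cos(2 * pi * b@times / 24), b))  # ~1
#' @export
thr <- function(post, numeratorHarmonic = 3L, denominatorHarmonics = NULL) {
    h <- post@harmonics
    if (!numeratorHarmonic %in% h)
        stop("configuration error: harmonic ", numeratorHarmonic,
             " is not in the fitted basis")
    if (is.null(denominatorHarmonics)) denominatorHarmonics <- h
    if (!all(denominatorHarmonics %in% h))
        stop("configuration error: denominator harmonics missing from basis")
    pw <- rowSums(post@harmonicCoeffs^2)
    den <- sum(pw[as.character(denominatorHarmonics)])
    if (den == 0) return(structure(0, flat = TRUE))
    unname(pw[as.character(numeratorHarmonic)] / den)
}

#' Classify cluster rhythmicity from THR
#'
#' Strict threshold rule: THR above \code{robustCut} is \code{"robust"},
#' above \code{rhythmicCut} is \code{"rhythmic"}, otherwise
#' \code{"arrhythmic"}. Defaults are the 0.4 / 0.6 cuts used to call clusters
#' rhythmic and robustly rhythmic.
#'
#' @param thrValue numeric THR value(s) in [0, 1].
#' @param rhythmicCut,robustCut thresholds with
#'   \code{0 <= rhythmicCut < robustCut <= 1}.
#' @return character vector of classes.
#' @examples
#' classifyRhythm(c(0.4, 0.41, 0.75))
#' @export
classifyRhythm <- function(thrValue, rhythmicCut = 0.4, robustCut = 0.6) {
    if (!(rhythmicCut >= 0 && rhythmicCut < robustCut && robustCut <= 1))
        stop("invalid argument: need 0 <= rhythmicCut < robustCut <= 1")
    ifelse(thrValue > robustCut, "robust",
           ifelse(thrValue > rhythmicCut, "rhythmic", "arrhythmic"))
}

#' Peak time of day of a cluster's diurnal component
#'
#' From the diurnal-harmonic coefficients (a, b), the fitted component is
#' \code{a cos(2 pi t / 24) + b sin(2 pi t / 24)}, which peaks at
#' \code{phase = (24 / 2 pi) * atan2(b, a) mod 24} hours on the design's
#' time-of-day convention.
#'
#' @param post a \linkS4class{ClusterPosterior}.
#' @param dielPeriod length of the diel cycle in hours (default 24).
#' @param harmonic the diurnal harmonic (default 3).
#' @return the phase in hours in [0, 24), or \code{NA} (with a warning) when
#'   the diurnal component is exactly zero.
#' @export
phaseEstimate <- function(post, dielPeriod = 24, harmonic = 3L) {
    if (!harmonic %in% post@harmonics)
        stop("configuration error: harmonic ", harmonic,
             " is not in the fitted basis")
    ab <- post@harmonicCoeffs[as.character(harmonic), ]
    if (ab[["a"]] == 0 && ab[["b"]] == 0) {
        warning("undefined phase: zero diurnal component")
        return(NA_real_)
    }
    (dielPeriod / (2 * pi) * atan2(ab[["b"]], ab[["a"]])) %% dielPeriod
}

#' Per-cluster rhythm summary
#'
#' Scores every cluster of a partition: size, THR, peak phase (hours),
#' and rhythmicity class under the strict 0.4 / 0.6 cuts.
#'
#' @param partition a \linkS4class{DielPartition}.
#' @param rhythmicCut,robustCut classification cuts (defaults 0.4 and 0.6).
#' @param dielPeriod diel cycle length in hours (default 24).
#' @param numeratorHarmonic diurnal harmonic for THR and phase (default 3).
#' @return a data.frame with columns \code{cluster_id}, \code{size},
#'   \code{thr}, \code{phase_h}, \code{rhythm_class}.
#' @examples
#' de <- simulateDielData(nClusters = 2, genesPerCluster = 5,
#'                        nArrhythmic = 0, nUnexpressed = 0, seed = 1)
#' rhythmSummary(runBFC(de))
#' @export
rhythmSummary <- function(partition, rhythmicCut = 0.4, robustCut = 0.6,
                          dielPeriod = 24, numeratorHarmonic = 3L) {
    cl <- clusters(partition)
    thrs <- vapply(cl, function(x)
        as.numeric(thr(x, numeratorHarmonic)), numeric(1))
    phases <- vapply(cl, function(x) {
        pw <- x@harmonicCoeffs[as.character(numeratorHarmonic), ]
        if (all(pw == 0)) NA_real_
        else phaseEstimate(x, dielPeriod, numeratorHarmonic)
    }, numeric(1))
    data.frame(cluster_id = sprintf("c%03d", seq_along(cl)),
               size = clusterSizes(partition),
               thr = thrs, phase_h = phases,
               rhythm_class = classifyRhythm(thrs, rhythmicCut, robustCut),
               stringsAsFactors = FALSE)
}

#' Polar-plot table of clusters around the diel clock
#'
#' Positions every cluster on the clock face: angle \code{2 pi phase / 24},
#' radius equal to the THR, and dot size proportional to the member count
#' (linear rule). Clusters with undefined phase are omitted and counted in the
#' \code{"n_omitted"} attribute.
#'
#' @param summary a rhythm summary as returned by [rhythmSummary()].
#' @param dielPeriod diel cycle length in hours (default 24).
#' @return a data.frame with columns \code{cluster_id}, \code{phase_h},
#'   \code{angle}, \code{radius}, \code{dot_size}, \code{rhythm_class};
#'   attribute \code{n_omitted} counts clusters without a phase.
#' @export
polarSummary <- function(summary, dielPeriod = 24) {
    keep <- !is.na(summary$phase_h)
    out <- data.frame(cluster_id = summary$cluster_id[keep],
                      phase_h = summary$phase_h[keep],
                      angle = 2 * pi * summary$phase_h[keep] / dielPeriod,
                      radius = summary$thr[keep],
                      dot_size = summary$size[keep],
                      rhythm_class = summary$rhythm_class[keep],
                      stringsAsFactors = FALSE)
    attr(out, "n_omitted") <- sum(!keep)
    out
}

#' Polar plot of clusters around the diel clock
#'
#' Reproduces the clock-face encoding: one square dot per cluster, positioned
#' by peak phase, at distance THR from the centre, sized by member count, with
#' the dark period shaded.
#'
#' @param polar a polar table from [polarSummary()].
#' @param lightOn,lightOff hours of the light schedule (defaults 9 and 21)
#'   used to shade the dark period.
#' @return a ggplot object.
#' @export
plotPolarClusters <- function(polar, lightOn = 9, lightOff = 21) {
    dark <- if (lightOn < lightOff)
        data.frame(xmin = c(0, lightOff), xmax = c(lightOn, 24))
    else data.frame(xmin = lightOff, xmax = lightOn)
    dark <- dark[dark$xmin < dark$xmax, , drop = FALSE]
    ggplot2::ggplot(polar) +
        ggplot2::geom_rect(data = dark,
            ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                         ymin = 0, ymax = 1),
            fill = "grey85") +
        ggplot2::geom_point(
            ggplot2::aes(x = .data$phase_h, y = .data$radius,
                         size = .data$dot_size,
                         colour = .data$rhythm_class),
            shape = 15) +
        ggplot2::coord_polar(start = 0) +
        ggplot2::scale_x_continuous(limits = c(0, 24),
                                    breaks = seq(0, 21, by = 3)) +
        ggplot2::scale_y_continuous(limits = c(0, 1)) +
        ggplot2::labs(x = "peak time of day (h)", y = "THR",
                      size = "cluster size", colour = "class") +
        ggplot2::theme_minimal()
}
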