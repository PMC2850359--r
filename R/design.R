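#' Build a diel sampling design
#'
#' Lays out \code{nKinetics} biological-replicate time courses (kinetics) on a
#' concatenated multi-day axis, \code{t = 24 * (kinetic - 1) + tod}, and sets
#' the light flag from a single light/dark schedule with the half-open
#' convention \code{[lightOn, lightOff)}. Duplicated times of day are allowed
#' (overlapping time points); the default grid samples every 3 h over one day
#' with the dawn point (Time 9) duplicated, giving 9 points per kinetic and 27
#' samples for three kinetics.
#'
#' @param nKinetics number of kinetics (default 3).
#' @param tods numeric, nominal times of day in hours, values in [0,24);
#'   duplicates permitted. Default \code{c(0,3,6,9,9,12,15,18,21)}.
#' @param lightOn,lightOff hours at which light switches on and off
#'   (default 9 and 21, a 12:12 schedule with dawn at Time 9).
#' @param backgrounds per-sample background signal on the linear scale;
#'   a scalar (recycled), one value per time of day, or one per sample.
#'   Default 100.
#' @return a data.frame with columns \code{sample_id}, \code{kinetic},
#'   \code{tod}, \code{t}, \code{light}, \code{background}, one row per
#'   sample, ordered by kinetic then time.
#' @examples
#' d <- makeDielDesign()
#' nrow(d)            # 27
#' d$light[d$tod == 9]  # light on at dawn
#' @export
makeDielDesign <- function(nKinetics = 3,
                           tods = c(0, 3, 6, 9, 9, 12, 15, 18, 21),
                           lightOn = 9, lightOff = 21,
                           backgrounds = 100) {
    if (length(tods) == 0)
        stop("invalid design: 'tods' must be nonempty")
    if (any(tods < 0 | tods >= 24))
        stop("invalid design: times of day must lie in [0, 24)")
    if (any(diff(tods) < 0))
        stop("invalid design: 'tods' must be nondecreasing")
    if (lightOn == lightOff)
        stop("invalid design: lightOn and lightOff must differ")
    stopIfNot(nKinetics >= 1, "nKinetics must be >= 1")

    nT <- length(tods)
    n <- nKinetics * nT
    if (length(backgrounds) == 1) backgrounds <- rep(backgrounds, n)
    else if (length(backgrounds) == nT) backgrounds <- rep(backgrounds, nKinetics)
    else if (length(backgrounds) != n)
        stop("invalid design: 'backgrounds' must have length 1, |tods| or ",
             "nKinetics * |tods|")
    if (any(backgrounds < 0))
        stop("invalid design: backgrounds must be nonnegative")

    kinetic <- rep(seq_len(nKinetics), each = nT)
    tod <- rep(tods, nKinetics)
    light <- if (lightOn < lightOff) tod >= lightOn & tod < lightOff
             else tod >= lightOn | tod < lightOff
    ids <- make.unique(sprintf("k%d_t%g", kinetic, tod), sep = "_")
    data.frame(sample_id = ids, kinetic = kinetic, tod = tod,
               t = 24 * (kinetic - 1) + tod, light = light,
               background = backgrounds, stringsAsFactors = FALSE)
}
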