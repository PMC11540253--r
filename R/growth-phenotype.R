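#' Maximum specific growth rate from an OD time series
#'
#' Slides a window of `windowH` hours along the series one sample at a time;
#' in each window the least-squares slope of `ln(OD)` vs. time is the growth
#' rate, and the maximum over all windows is returned.  Windows are defined
#' by time span, not point count, so irregular or missing samples are
#' tolerated.  On an exact exponential the estimate equals the true rate
#' regardless of the sampling interval.
#'
#' @param time Time points in hours, strictly increasing.
#' @param od Optical density readings, all > 0 (blank-corrected upstream).
#' @param windowH Window length in hours (default 5).
#' @return A list: `muMax` (1/h), `windowStart` (h), and `slopes`
#'   (`data.frame` of per-window start times and slopes).
#' @examples
#' t <- seq(0, 10, 0.25)
#' maxGrowthRate(t, 0.05 * exp(0.2 * t))$muMax
#' @export
maxGrowthRate <- function(time, od, windowH = 5) {
    if (windowH <= 0) stop("windowH must be > 0")
    if (length(time) != length(od)) stop("time and od lengths differ")
    if (any(diff(time) <= 0)) stop("time must be strictly increasing")
    if (any(od <= 0)) stop("non-positive OD: log undefined")
    span <- max(time) - min(time)
    if (span < windowH)
        stop("series spans ", span, " h < window of ", windowH, " h")
    y <- log(od)
    eps <- sqrt(.Machine$double.eps)
    startsIdx <- which(time + windowH <= max(time) + eps)
    slopes <- vapply(startsIdx, function(i) {
        sel <- time >= time[i] & time <= time[i] + windowH + eps
        tt <- time[sel]; yy <- y[sel]
        if (sum(sel) < 2L) return(NA_real_)
        stats::cov(tt, yy) / stats::var(tt)
    }, numeric(1))
    ok <- !is.na(slopes)
    best <- which.max(slopes[ok])
    list(muMax = slopes[ok][best],
         windowStart = time[startsIdx[ok][best]],
         slopes = data.frame(windowStart = time[startsIdx[ok]],
                             slope = slopes[ok]))
}

#' Biomass yield from dry cell weight
#'
#' `yield (gDCW / g substrate) = DCW (mg) / [substrate (g/L) x volume (L)
#' x 1000]`.
#'
#' @param dcwMg Dry cell weight of the harvested culture, in mg.
#' @param substrateGPerL Substrate concentration fed, in g/L.
#' @param volumeL Culture volume, in L.
#' @return Yield in g dry cell weight per g substrate.
#' @examples
#' biomassYield(100, 2, 0.05)  # 1.0
#' @export
biomassYield <- function(dcwMg, substrateGPerL, volumeL) {
    if (any(dcwMg <= 0) || any(substrateGPerL <= 0) || any(volumeL <= 0))
        stop("all inputs must be > 0")
    dcwMg / (substrateGPerL * volumeL * 1000)
}
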