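# Recovery estimators: read the architecture back out of metaprofiles.
# Both operate on base-resolution profiles and smooth with a centered
# 31-bp moving average (partial windows at the edges) before locating
# extrema.

.smoothMA <- function(v, k = 31L) {
    n <- length(v)
    h <- (k - 1L) %/% 2L
    cs <- c(0, cumsum(v))
    i <- seq_len(n)
    lo <- pmax(i - h, 1L)
    hi <- pmin(i + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Estimate the +1 nucleosome entry site from a mononucleosome profile
#'
#' Smooths the profile with a centered 31-bp moving average, locates the
#' NDR trough (the profile minimum nearest the TSS, searched within
#' `troughWindow`), takes the first local maximum downstream of the
#' trough as the +1 nucleosome peak, and -- assuming span-coverage
#' reduction, where the peak sits at the dyad -- reports
#' `peak - 73` bp as the entry site (the 5' edge of the 147 bp wrap).
#'
#' Because span coverage of ~130 bp fragments around a jittered dyad
#' yields a dome with a nearly flat top, the peak position is refined
#' to the centre of the contiguous region around the first local
#' maximum that stays within 10% of its height above the trough; this
#' is exact for noiseless symmetric peaks and averages out sampling
#' noise on flat-topped domes.
#'
#' @param monoProfile base-resolution (1 bp offset grid)
#'   [Profile-class] of mononucleosome span coverage around the TSS;
#'   must span the NDR and the +1 peak.
#' @param smoothBp smoothing window (bp, odd).
#' @param troughWindow offsets (bp) within which the NDR trough is
#'   searched.
#' @param minProminence a candidate local maximum must rise above the
#'   trough by at least this fraction of the post-trough dynamic range;
#'   guards against residual sampling wiggle on the flat NDR floor.
#' @return Entry-site offset in bp downstream of the TSS.
#' @examples
#' # a noiseless triangular +1 peak at +123 recovers entry = +50
#' offs <- -300:400
#' vals <- pmax(0, 70 - abs(offs - 123)) + pmax(0, 70 - abs(offs + 170))
#' estimatePlus1Entry(Profile(offs, vals))
#' @export
estimatePlus1Entry <- function(monoProfile, smoothBp = 31L,
                               troughWindow = c(-200L, 100L),
                               minProminence = 0.25) {
    offs <- offsets(monoProfile)
    if (!all(diff(offs) == 1L))
        stop("entry-site estimation requires a 1-bp offset grid")
    s <- .smoothMA(profileValues(monoProfile), smoothBp)
    inTrough <- which(offs >= troughWindow[1] & offs <= troughWindow[2])
    if (!length(inTrough))
        stop("profile does not cover the trough search window")
    ti <- inTrough[which.min(s[inTrough])]
    n <- length(s)
    if (ti >= n - 1L)
        stop("no profile downstream of the NDR trough")
    floorVal <- s[ti]
    rise <- max(s[(ti + 1L):n]) - floorVal
    if (rise <= 0)
        stop("no local maximum downstream of the NDR trough")
    thresh <- floorVal + minProminence * rise
    h <- (smoothBp - 1L) %/% 2L
    i <- ti + 1L
    while (i < n) {
        # a genuine peak dominates its whole smoothing neighbourhood;
        # noise wiggles on a rising flank do not
        if (s[i] >= thresh && s[i] > s[i - 1L] && s[i] >= s[i + 1L] &&
            s[i] >= max(s[max(1L, i - h):min(n, i + h)])) {
            # centre of the near-maximal region around the peak
            lev <- floorVal + 0.9 * (s[i] - floorVal)
            lo <- i; while (lo > 1L && s[lo - 1L] >= lev) lo <- lo - 1L
            hi2 <- i; while (hi2 < n && s[hi2 + 1L] >= lev)
                hi2 <- hi2 + 1L
            return(as.integer(round(mean(offs[lo:hi2]))) - 73L)
        }
        i <- i + 1L
    }
    stop("no local maximum downstream of the NDR trough")
}

#' Locate the peak of a footprint profile
#'
#' Position of the maximum of the 31-bp-smoothed profile within a
#' search window. When smoothing flattens a sharp peak into a plateau,
#' the plateau centre is reported; when several separate positions tie
#' at the maximum, the leftmost peak is reported. A flat profile within
#' the window is an error.
#'
#' @param profile base-resolution [Profile-class] (typically a
#'   short-fragment midpoint metaprofile).
#' @param searchWindow numeric `c(lo, hi)` offsets (bp) or a
#'   [windowSpec()] whose offsets bound the search.
#' @param smoothBp smoothing window (bp, odd).
#' @return Peak offset in bp from the profile anchor.
#' @export
estimatePeakOffset <- function(profile, searchWindow,
                               smoothBp = 31L) {
    if (inherits(searchWindow, "WindowSpec"))
        searchWindow <- c(searchWindow$startOffset,
                          searchWindow$endOffset)
    offs <- offsets(profile)
    if (!all(diff(offs) == 1L))
        stop("peak estimation requires a 1-bp offset grid")
    s <- .smoothMA(profileValues(profile), smoothBp)
    i <- which(offs >= searchWindow[1] & offs <= searchWindow[2])
    if (!length(i)) stop("profile does not cover the search window")
    if (max(s[i]) == min(s[i]))
        stop("flat profile within the search window")
    sw <- s[i]
    atMax <- which(sw == max(sw))
    # centre of the first contiguous run at the maximum
    runEnd <- if (length(atMax) > 1 && any(diff(atMax) > 1))
        atMax[min(which(diff(atMax) > 1))] else atMax[length(atMax)]
    first <- atMax[1]
    offs[i[(first + runEnd) %/% 2]]
}
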