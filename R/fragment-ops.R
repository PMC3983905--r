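# Size-class selection and reduction of fragments to per-base signal.
# Two reduction modes: fragment midpoints (sharpest localization, used
# for sub-nucleosomal footprint profiles) and full spans (occupancy: the
# number of fragments wrapping each base, used for nucleosome profiles).

#' Select fragments by size class
#'
#' Keeps exactly those fragments whose length satisfies
#' `minLen <= length <= maxLen` (both bounds inclusive, matching the
#' natural-language reading of ranges such as "35-75 bp"). The library
#' size is updated to the selected count, so downstream RPM
#' normalization is per selected library.
#'
#' @param frags a [FragmentSet-class].
#' @param sc a [SizeClass-class].
#' @return A [FragmentSet-class] restricted to the class.
#' @examples
#' fs <- FragmentSet(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 1), width = c(40, 130))))
#' librarySize(selectSizeClass(fs, sizeClass("short", 35, 75)))
#' @export
selectSizeClass <- function(frags, sc) {
    stopifnot(is(frags, "FragmentSet"), is(sc, "SizeClass"))
    w <- width(fragments(frags))
    keep <- w >= sc@minLen & w <= sc@maxLen
    FragmentSet(fragments(frags)[keep],
                c(frags@provenance, list(size_class = sc@name)))
}

.fragSeqlengths <- function(gr) {
    sl <- seqlengths(gr)
    if (any(is.na(sl))) {
        byc <- split(end(gr), as.character(seqnames(gr)))
        sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(cc)
            if (cc %in% names(byc)) max(byc[[cc]]) else 1L, numeric(1))
    }
    sl
}

#' Midpoint coverage of a fragment library
#'
#' The value at position `p` is the number of fragments whose midpoint
#' `floor((start + end - 1) / 2)` (0-based, even lengths rounded left)
#' equals `p`. Total signal equals the fragment count.
#'
#' @param frags a [FragmentSet-class].
#' @return A raw [SignalTrack-class].
#' @export
midpointCoverage <- function(frags) {
    gr <- fragments(frags)
    if (!length(gr))
        return(SignalTrack(as(list(), "SimpleRleList"), "raw",
                           c(frags@provenance, list(mode = "midpoint"))))
    # 0-based midpoint m0 = floor((s0 + e0ex - 1)/2); 1-based = m0 + 1
    m1 <- floor((start(gr) - 1 + end(gr) - 1) / 2) + 1L
    mids <- GRanges(seqnames(gr), IRanges(m1, width = 1L),
                    seqinfo = seqinfo(gr))
    sig <- coverage(mids, width = .fragSeqlengths(gr))
    SignalTrack(as(lapply(sig, function(r) Rle(as.numeric(runValue(r)),
                                               runLength(r))),
                   "SimpleRleList"), "raw",
                c(frags@provenance, list(mode = "midpoint")))
}

#' Span coverage of a fragment library
#'
#' The value at position `p` is the number of fragments with
#' `start <= p < end`; the total signal equals the summed fragment
#' lengths. This is the occupancy reduction: the number of fragments
#' wrapping each base.
#'
#' @param frags a [FragmentSet-class].
#' @return A raw [SignalTrack-class].
#' @export
spanCoverage <- function(frags) {
    gr <- fragments(frags)
    if (!length(gr))
        return(SignalTrack(as(list(), "SimpleRleList"), "raw",
                           c(frags@provenance, list(mode = "span"))))
    sig <- coverage(gr, width = .fragSeqlengths(gr))
    SignalTrack(as(lapply(sig, function(r) Rle(as.numeric(runValue(r)),
                                               runLength(r))),
                   "SimpleRleList"), "raw",
                c(frags@provenance, list(mode = "span")))
}

#' Normalize a track to fragments per million
#'
#' Multiplies every value by `1e6 / librarySize` and tags the track as
#' `rpm`. Normalization is per selected library (factor, condition, size
#' class), recorded in the provenance tag so comparisons are
#' like-for-like.
#'
#' @param track a [SignalTrack-class].
#' @param librarySize library size (fragment count) of the library the
#'   track was reduced from; must be >= 1.
#' @return The normalized [SignalTrack-class].
#' @export
normalizeRPM <- function(track, librarySize) {
    if (length(librarySize) != 1L || is.na(librarySize) ||
        librarySize < 1)
        stop("empty library: librarySize must be >= 1")
    f <- 1e6 / librarySize
    sig <- as(lapply(trackSignal(track), function(r) r * f),
              "SimpleRleList")
    SignalTrack(sig, "rpm",
                c(track@provenance, list(library_size = librarySize)))
}

#' Reduce a library to a normalized coverage track
#'
#' Convenience composition: size-class selection, midpoint or span
#' reduction, RPM normalization by the selected library size.
#'
#' @param frags a [FragmentSet-class].
#' @param sc a [SizeClass-class] (default: no restriction).
#' @param mode `"midpoint"` or `"span"`.
#' @return An rpm-normalized [SignalTrack-class].
#' @export
libraryTrack <- function(frags, sc = canonicalSizeClasses()$all,
                         mode = c("midpoint", "span")) {
    mode <- match.arg(mode)
    sel <- selectSizeClass(frags, sc)
    if (librarySize(sel) == 0) stop("no fragments in size class ",
                                    sc@name)
    red <- if (mode == "midpoint") midpointCoverage(sel)
           else spanCoverage(sel)
    normalizeRPM(red, librarySize(sel))
}
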