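# Core S4 containers. Interval coordinates follow Bioconductor convention
# in memory (1-based closed GRanges/IRanges); all file I/O and all gene
# anchor coordinates exposed to users are 0-based half-open (BED
# convention). Gene anchors are the 0-based position of the 5'-most
# transcribed base, so a minus-strand TSS is `end - 1` of its BED interval.

#' FragmentSet: paired-end fragment intervals
#'
#' Container for the genomic intervals of sequenced paired-end fragments,
#' the raw material of all footprinting analyses. Wraps a
#' [GenomicRanges::GRanges] and records the library size (number of
#' fragments) used for counts-per-million normalization, together with a
#' free-form provenance list (factor, condition, size class...).
#'
#' @slot granges GRanges of fragment intervals (1-based, closed).
#' @slot librarySize integer(1), number of fragments; always equals
#'   `length(granges)` after any selection.
#' @slot provenance named list describing how the library was obtained.
#'
#' @seealso [readFragments()], [selectSizeClass()], [spanCoverage()],
#'   [midpointCoverage()]
#' @exportClass FragmentSet
setClass("FragmentSet",
    slots = c(granges = "GRanges", librarySize = "integer",
              provenance = "list"))

setValidity("FragmentSet", function(object) {
    msg <- NULL
    if (length(object@granges) && any(width(object@granges) < 1L))
        msg <- c(msg, "all fragments must have length >= 1")
    if (object@librarySize != length(object@granges))
        msg <- c(msg, "librarySize must equal the number of records")
    if (is.null(msg)) TRUE else msg
})

#' Construct a FragmentSet
#'
#' @param granges GRanges of fragment intervals.
#' @param provenance optional named list of provenance tags.
#' @return A [FragmentSet-class] object.
#' @examples
#' fs <- FragmentSet(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(start = c(101, 121), end = c(160, 180))))
#' librarySize(fs)
#' @export
FragmentSet <- function(granges, provenance = list()) {
    new("FragmentSet", granges = granges,
        librarySize = length(granges), provenance = provenance)
}

#' SignalTrack: per-base signal over a reference
#'
#' Shared representation for fragment coverage and CATCH-IT turnover
#' signal: a run-length encoded per-base numeric value for each
#' chromosome. Coverage-derived tracks are non-negative; turnover tracks
#' may be negative (log-ratio-like signal). Positions not covered by any
#' run are treated as 0 throughout the package.
#'
#' @slot signal SimpleRleList, one numeric Rle per chromosome; the Rle
#'   length is the chromosome length.
#' @slot normalization `"raw"` or `"rpm"` (fragments-per-million).
#' @slot provenance named list (factor, condition, size class, reduction
#'   mode...).
#'
#' @seealso [spanCoverage()], [midpointCoverage()], [normalizeRPM()],
#'   [readBedGraph()], [writeBedGraph()]
#' @exportClass SignalTrack
setClass("SignalTrack",
    slots = c(signal = "SimpleRleList", normalization = "character",
              provenance = "list"))

setValidity("SignalTrack", function(object) {
    msg <- NULL
    if (!object@normalization %in% c("raw", "rpm"))
        msg <- c(msg, "normalization must be 'raw' or 'rpm'")
    vals <- unlist(lapply(object@signal, runValue), use.names = FALSE)
    if (length(vals) && !all(is.finite(vals)))
        msg <- c(msg, "all track values must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SignalTrack
#'
#' @param signal a named SimpleRleList (or list of numeric Rle /
#'   vectors), one element per chromosome.
#' @param normalization `"raw"` (default) or `"rpm"`.
#' @param provenance optional named list of provenance tags.
#' @return A [SignalTrack-class] object.
#' @export
SignalTrack <- function(signal, normalization = "raw",
                        provenance = list()) {
    if (!is(signal, "SimpleRleList"))
        signal <- as(lapply(signal, function(v)
            if (is(v, "Rle")) v else Rle(as.numeric(v))), "SimpleRleList")
    new("SignalTrack", signal = signal, normalization = normalization,
        provenance = provenance)
}

#' AnchoredMatrix: genes x offsets signal grid
#'
#' Gene-anchored matrix of signal around the TSS or TES, the basis of all
#' metaprofiles and heatmaps. Rows are genes (in the input gene order);
#' columns are transcription-oriented offset bins, so that increasing
#' offset always points in the direction of transcription, also for
#' minus-strand genes.
#'
#' @slot values numeric matrix, genes x offset bins; rownames are gene
#'   ids.
#' @slot anchor `"TSS"` or `"TES"`.
#' @slot offsets integer vector of bin start offsets (bp, transcription
#'   oriented).
#' @slot binSize integer(1), bin width in bp.
#'
#' @seealso [buildAnchoredMatrix()], [meanProfile()]
#' @exportClass AnchoredMatrix
setClass("AnchoredMatrix",
    slots = c(values = "matrix", anchor = "character",
              offsets = "integer", binSize = "integer"))

setValidity("AnchoredMatrix", function(object) {
    msg <- NULL
    if (!object@anchor %in% c("TSS", "TES"))
        msg <- c(msg, "anchor must be 'TSS' or 'TES'")
    if (ncol(object@values) != length(object@offsets))
        msg <- c(msg, "column count must match offset vector")
    if (is.unsorted(object@offsets, strictly = TRUE))
        msg <- c(msg, "offsets must be strictly increasing")
    if (is.null(msg)) TRUE else msg
})

#' Profile: averaged anchored signal
#'
#' A mean signal profile over a gene set: one value per transcription-
#' oriented offset, plus the number of genes that contributed.
#'
#' @slot offsets integer vector, strictly increasing offsets in bp.
#' @slot values numeric vector of mean signal, same length as offsets.
#' @slot nGenes integer(1), number of contributing genes.
#'
#' @seealso [meanProfile()], [percentDynamicRange()],
#'   [differenceProfile()]
#' @exportClass Profile
setClass("Profile",
    slots = c(offsets = "integer", values = "numeric",
              nGenes = "integer"))

setValidity("Profile", function(object) {
    msg <- NULL
    if (length(object@offsets) != length(object@values))
        msg <- c(msg, "offsets and values must have equal length")
    if (is.unsorted(object@offsets, strictly = TRUE))
        msg <- c(msg, "offsets must be strictly increasing")
    if (!all(is.finite(object@values)))
        msg <- c(msg, "profile values must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Construct a Profile
#'
#' @param offsets integer offsets (bp).
#' @param values numeric values, same length.
#' @param nGenes number of genes contributing.
#' @return A [Profile-class] object.
#' @export
Profile <- function(offsets, values, nGenes = 1L) {
    new("Profile", offsets = as.integer(offsets),
        values = as.numeric(values), nGenes = as.integer(nGenes))
}

#' SizeClass: a fragment-length interval
#'
#' Named fragment-length class with inclusive bounds. The two canonical
#' classes are the short factor-footprint class (35-75 bp) and the
#' mononucleosome class (111-140 bp).
#'
#' @slot name class label.
#' @slot minLen minimum fragment length (bp, inclusive).
#' @slot maxLen maximum fragment length (bp, inclusive; may be `Inf`).
#' @exportClass SizeClass
setClass("SizeClass",
    slots = c(name = "character", minLen = "numeric", maxLen = "numeric"))

setValidity("SizeClass", function(object) {
    if (object@minLen < 1 || object@minLen > object@maxLen)
        "require 1 <= minLen <= maxLen" else TRUE
})

#' Construct a SizeClass
#'
#' @param name class label.
#' @param minLen,maxLen inclusive length bounds in bp.
#' @return A [SizeClass-class] object.
#' @examples
#' sizeClass("short", 35, 75)
#' @export
sizeClass <- function(name, minLen, maxLen) {
    new("SizeClass", name = name, minLen = as.numeric(minLen),
        maxLen = as.numeric(maxLen))
}

#' Canonical fragment size classes
#'
#' The short factor-footprint class (35-75 bp), the mononucleosome class
#' (111-140 bp) and the unrestricted class.
#'
#' @return Named list of [SizeClass-class] objects `short`, `mono`,
#'   `all`.
#' @export
canonicalSizeClasses <- function() {
    list(short = sizeClass("short", 35, 75),
         mono = sizeClass("mono", 111, 140),
         all = sizeClass("all", 1, Inf))
}
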