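# Generics and accessor methods for the core classes.

#' @describeIn FragmentSet-class number of fragments in the library
#' @param x a FragmentSet
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname FragmentSet-class
#' @export
setMethod("librarySize", "FragmentSet", function(x) x@librarySize)

#' @describeIn FragmentSet-class the fragment intervals as a GRanges
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname FragmentSet-class
#' @export
setMethod("fragments", "FragmentSet", function(x) x@granges)

#' @describeIn FragmentSet-class fragment lengths in bp
#' @export
setGeneric("fragmentLengths",
    function(x) standardGeneric("fragmentLengths"))

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentLengths", "FragmentSet",
    function(x) width(x@granges))

#' @describeIn SignalTrack-class provenance tag list
#' @param x a SignalTrack / FragmentSet
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname SignalTrack-class
#' @export
setMethod("provenance", "SignalTrack", function(x) x@provenance)

#' @rdname FragmentSet-class
#' @export
setMethod("provenance", "FragmentSet", function(x) x@provenance)

#' @describeIn SignalTrack-class per-chromosome Rle signal
#' @export
setGeneric("trackSignal", function(x) standardGeneric("trackSignal"))

#' @rdname SignalTrack-class
#' @export
setMethod("trackSignal", "SignalTrack", function(x) x@signal)

#' @describeIn SignalTrack-class normalization tag ("raw" or "rpm")
#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))

#' @rdname SignalTrack-class
#' @export
setMethod("normalization", "SignalTrack", function(x) x@normalization)

#' @describeIn SignalTrack-class genome-wide sum of the signal
#' @export
setGeneric("trackSum", function(x) standardGeneric("trackSum"))

#' @rdname SignalTrack-class
#' @export
setMethod("trackSum", "SignalTrack",
    function(x) sum(vapply(x@signal, function(r) sum(as.numeric(r)),
                           numeric(1))))

#' @describeIn SignalTrack-class genome-wide per-base mean of the signal
#' @export
setGeneric("trackMean", function(x) standardGeneric("trackMean"))

#' @rdname SignalTrack-class
#' @export
setMethod("trackMean", "SignalTrack", function(x) {
    tot <- sum(vapply(x@signal, length, numeric(1)))
    if (tot == 0) return(0)
    trackSum(x) / tot
})

#' @describeIn AnchoredMatrix-class offset bin starts (bp)
#' @param x an AnchoredMatrix / Profile
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' @rdname AnchoredMatrix-class
#' @export
setMethod("offsets", "AnchoredMatrix", function(x) x@offsets)

#' @rdname Profile-class
#' @export
setMethod("offsets", "Profile", function(x) x@offsets)

#' @describeIn AnchoredMatrix-class anchor ("TSS" or "TES")
#' @export
setGeneric("anchor", function(x) standardGeneric("anchor"))

#' @rdname AnchoredMatrix-class
#' @export
setMethod("anchor", "AnchoredMatrix", function(x) x@anchor)

#' @describeIn Profile-class mean signal values
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname Profile-class
#' @export
setMethod("profileValues", "Profile", function(x) x@values)

#' @describeIn Profile-class number of genes contributing
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname Profile-class
#' @export
setMethod("nGenes", "Profile", function(x) x@nGenes)

#' @rdname AnchoredMatrix-class
#' @param ... unused
#' @export
setMethod("as.matrix", "AnchoredMatrix", function(x, ...) x@values)

#' @rdname Profile-class
#' @param row.names,optional,... passed through (unused)
#' @export
setMethod("as.data.frame", "Profile",
    function(x, row.names = NULL, optional = FALSE, ...)
        data.frame(offset = x@offsets, value = x@values))

setMethod("show", "FragmentSet", function(object) {
    cat("FragmentSet with", object@librarySize, "fragments\n")
    if (length(object@granges)) {
        w <- width(object@granges)
        cat("  length range:", min(w), "-", max(w), "bp;",
            "chromosomes:",
            paste(head(seqlevels(object@granges), 5), collapse = ", "),
            "\n")
    }
    if (length(object@provenance))
        cat("  provenance:",
            paste(names(object@provenance),
                  vapply(object@provenance, function(p)
                      paste(format(p), collapse = ","), character(1)),
                  sep = "=", collapse = "; "), "\n")
})

setMethod("show", "SignalTrack", function(object) {
    cat("SignalTrack (", object@normalization, ") over ",
        length(object@signal), " chromosome(s)\n", sep = "")
    cat("  total signal:", format(trackSum(object)), "\n")
})

setMethod("show", "AnchoredMatrix", function(object) {
    cat("AnchoredMatrix:", nrow(object@values), "genes x",
        ncol(object@values), "bins (", object@binSize, "bp ) around",
        object@anchor, "\n")
})

setMethod("show", "Profile", function(object) {
    cat("Profile over offsets [", min(object@offsets), ",",
        max(object@offsets), "] bp from", object@nGenes, "genes\n")
})

setMethod("show", "SizeClass", function(object) {
    cat("SizeClass '", object@name, "': [", object@minLen, ", ",
        object@maxLen, "] bp\n", sep = "")
})
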