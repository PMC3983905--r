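# Gene-anchored metaprofiles: anchored matrices, average profiles,
# rankings, quintiles and sliding-window trend curves. All offsets are
# transcription-oriented: increasing offset points downstream along the
# gene also for minus-strand genes. Positions absent from a track count
# as 0 (coverage tracks are dense by construction); only positions
# beyond the chromosome ends are truncated.

#' Analysis window specification
#'
#' A transcription-oriented window `[startOffset, endOffset)` in bp from
#' a gene anchor. The named windows used throughout the package (PolII
#' promoter -100..+300, traveling-ratio promoter -30..+300, Ser2 gene
#' body +1k..+5k, the CATCH-IT windows) are all WindowSpecs.
#'
#' @param anchor `"TSS"` or `"TES"`.
#' @param startOffset,endOffset window bounds in bp, `startOffset <
#'   endOffset`; negative = upstream of the anchor.
#' @return A list with class `WindowSpec`.
#' @examples
#' windowSpec("TSS", -100, 300)   # PolII promoter window
#' @export
windowSpec <- function(anchor = c("TSS", "TES"), startOffset,
                       endOffset) {
    anchor <- match.arg(anchor)
    if (startOffset >= endOffset)
        stop("window requires startOffset < endOffset")
    structure(list(anchor = anchor,
                   startOffset = as.integer(startOffset),
                   endOffset = as.integer(endOffset)),
              class = "WindowSpec")
}

.anchors0 <- function(genes, anchor) {
    if (anchor == "TSS") geneTSS(genes) else geneTES(genes)
}

# Genomic 0-based [lo, hi] bounds of an oriented offset window.
.windowBounds0 <- function(genes, anchor, so, eo) {
    a0 <- .anchors0(genes, anchor)
    plus <- as.character(strand(genes)) == "+"
    lo <- ifelse(plus, a0 + so, a0 - eo + 1)
    hi <- ifelse(plus, a0 + eo - 1, a0 - so)
    cbind(lo = lo, hi = hi)
}

#' Per-gene mean signal in an anchored window
#'
#' Mean normalized signal over the transcription-oriented offsets
#' `[startOffset, endOffset)` from each gene's anchor. Positions missing
#' from the track contribute 0; window parts beyond a chromosome end are
#' truncated (dropped from the denominator) with a single warning.
#'
#' @param track a [SignalTrack-class].
#' @param genes gene cohort GRanges.
#' @param window a [windowSpec()].
#' @return Named numeric vector of per-gene means (names = gene ids).
#' @export
windowMean <- function(track, genes, window) {
    stopifnot(inherits(window, "WindowSpec"))
    b <- .windowBounds0(genes, window$anchor, window$startOffset,
                        window$endOffset)
    sig <- trackSignal(track)
    chrom <- as.character(seqnames(genes))
    out <- numeric(length(genes))
    denom <- numeric(length(genes))
    truncated <- 0L
    for (cc in unique(chrom)) {
        i <- which(chrom == cc)
        if (!cc %in% names(sig)) {
            # chromosome absent from track: all-zero contribution
            denom[i] <- b[i, "hi"] - b[i, "lo"] + 1
            next
        }
        r <- sig[[cc]]
        lo1 <- b[i, "lo"] + 1
        hi1 <- b[i, "hi"] + 1
        clo <- pmax(lo1, 1)
        chi <- pmin(hi1, length(r))
        truncated <- truncated + sum(lo1 < 1 | hi1 > length(r))
        ok <- clo <= chi
        sums <- numeric(length(i))
        if (any(ok)) {
            v <- Views(r, start = clo[ok], end = chi[ok])
            sums[ok] <- viewSums(v)
        }
        out[i] <- sums
        denom[i] <- pmax(chi - clo + 1, 0)
    }
    if (truncated > 0)
        warning(truncated,
                " window(s) truncated at chromosome bounds")
    res <- ifelse(denom > 0, out / denom, 0)
    names(res) <- geneIds(genes)
    res
}

#' Build a gene-anchored signal matrix
#'
#' Row `g`, offset bin `o` holds the mean track value over the bin at
#' transcription-oriented offset `o` from gene `g`'s anchor;
#' minus-strand rows are coordinate-reversed so increasing offset always
#' points downstream. Positions absent from the track contribute 0; a
#' gene whose anchor lies on a chromosome absent from the track yields a
#' zero row with a warning.
#'
#' @param track a [SignalTrack-class].
#' @param genes gene cohort GRanges.
#' @param anchor `"TSS"` or `"TES"`.
#' @param flankUp,flankDown flank sizes in bp (positive multiples of
#'   `binSize`); the matrix covers offsets `[-flankUp, flankDown)`.
#' @param binSize bin width in bp (default 10 for heatmaps; use 1 for
#'   base-resolution average profiles).
#' @return An [AnchoredMatrix-class].
#' @export
buildAnchoredMatrix <- function(track, genes,
                                anchor = c("TSS", "TES"),
                                flankUp = 500L, flankDown = 2000L,
                                binSize = 10L) {
    anchor <- match.arg(anchor)
    flankUp <- as.integer(flankUp); flankDown <- as.integer(flankDown)
    binSize <- as.integer(binSize)
    if (flankUp <= 0L || flankDown <= 0L ||
        flankUp %% binSize != 0L || flankDown %% binSize != 0L)
        stop("flanks must be positive multiples of binSize")
    width <- flankUp + flankDown
    nbin <- width %/% binSize
    offs <- seq(-flankUp, flankDown - 1L, by = binSize)
    sig <- trackSignal(track)
    a0 <- .anchors0(genes, anchor)
    chrom <- as.character(seqnames(genes))
    plus <- as.character(strand(genes)) == "+"
    vals <- matrix(0, nrow = length(genes), ncol = nbin,
                   dimnames = list(geneIds(genes), offs))
    missing <- 0L
    for (g in seq_along(genes)) {
        cc <- chrom[g]
        if (!cc %in% names(sig)) { missing <- missing + 1L; next }
        r <- sig[[cc]]
        if (plus[g]) {
            lo1 <- a0[g] - flankUp + 1L
        } else {
            lo1 <- a0[g] - flankDown + 2L
        }
        hi1 <- lo1 + width - 1L
        v <- numeric(width)
        clo <- max(lo1, 1L); chi <- min(hi1, length(r))
        if (clo <= chi)
            v[(clo - lo1 + 1L):(chi - lo1 + 1L)] <-
                as.numeric(window(r, clo, chi))
        if (!plus[g]) v <- rev(v)
        vals[g, ] <- if (binSize == 1L) v
                     else colMeans(matrix(v, nrow = binSize))
    }
    if (missing > 0)
        warning(missing, " gene(s) on chromosomes absent from the ",
                "track: zero rows")
    new("AnchoredMatrix", values = vals, anchor = anchor,
        offsets = as.integer(offs), binSize = binSize)
}

#' Column-wise mean profile of an anchored matrix
#'
#' @param matrix an [AnchoredMatrix-class].
#' @param subset gene ids to average over (default: all rows).
#' @return A [Profile-class].
#' @export
meanProfile <- function(matrix, subset = NULL) {
    stopifnot(is(matrix, "AnchoredMatrix"))
    m <- matrix@values
    if (!is.null(subset)) {
        if (!all(subset %in% rownames(m)))
            stop("subset contains unknown gene ids")
        m <- m[subset, , drop = FALSE]
    }
    if (nrow(m) == 0) stop("empty gene subset")
    Profile(matrix@offsets, colMeans(m), nrow(m))
}

#' Rescale a profile to percent of its dynamic range
#'
#' Maps each value `v` to `100 * (v - min) / (max - min)`, so the
#' profile spans exactly `[0, 100]`. A constant profile maps to all
#' zeros with a warning.
#'
#' @param profile a [Profile-class].
#' @return The rescaled [Profile-class].
#' @export
percentDynamicRange <- function(profile) {
    v <- profileValues(profile)
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
        warning("constant profile: dynamic range is zero")
        return(Profile(offsets(profile), rep(0, length(v)),
                       nGenes(profile)))
    }
    Profile(offsets(profile), 100 * (v - lo) / (hi - lo),
            nGenes(profile))
}

#' Rank genes by a score
#'
#' Descending score order, ties broken lexicographically by gene id so
#' heatmap row order is deterministic.
#'
#' @param scores named numeric vector (names = gene ids); all finite.
#' @return data.frame with columns `gene_id`, `score`, ordered by
#'   descending score.
#' @export
rankGenes <- function(scores) {
    if (is.null(names(scores)) || any(!nzchar(names(scores))))
        stop("scores must be named by gene id")
    if (any(is.na(scores) | !is.finite(scores)))
        stop("non-finite score for gene(s): ",
             paste(head(names(scores)[!is.finite(scores)], 5),
                   collapse = ", "))
    o <- order(-scores, names(scores))
    data.frame(gene_id = names(scores)[o], score = unname(scores[o]))
}

#' Split a ranking into quintiles
#'
#' Contiguous blocks of the ranking; block sizes differ by at most one,
#' with the larger blocks first (the highest-score quintile absorbs the
#' remainder).
#'
#' @param ranking a ranking data.frame from [rankGenes()].
#' @return List of five character vectors of gene ids, highest-score
#'   quintile first.
#' @export
quintileSplit <- function(ranking) {
    n <- nrow(ranking)
    if (n < 5) stop("need at least 5 genes to form quintiles")
    base <- n %/% 5L
    sizes <- rep(base, 5L) + as.integer(seq_len(5L) <= n %% 5L)
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    lapply(seq_len(5L), function(i)
        ranking$gene_id[starts[i]:ends[i]])
}

#' Sliding-window trend of a score against a covariate
#'
#' Genes are taken in ranking order; a window of `window` genes slides
#' one gene per step, and each position yields the pair of arithmetic
#' means (mean score, mean covariate) over the window.
#'
#' @param ranking a ranking data.frame from [rankGenes()].
#' @param y named numeric vector, defined for every ranked gene.
#' @param window window size in genes (>= 1, <= number of genes);
#'   window 1 is the identity on the (score, y) pairs in rank order.
#' @return data.frame with columns `mean_score`, `mean_y`, one row per
#'   window position.
#' @export
slidingWindowXY <- function(ranking, y, window) {
    n <- nrow(ranking)
    window <- as.integer(window)
    if (window < 1) stop("window must hold at least 1 gene")
    if (window > n) stop("window larger than the number of genes")
    if (!all(ranking$gene_id %in% names(y)))
        stop("y is not defined for all ranked genes")
    yv <- as.numeric(y[ranking$gene_id])
    sv <- ranking$score
    cy <- c(0, cumsum(yv)); cs <- c(0, cumsum(sv))
    k <- seq_len(n - window + 1L)
    data.frame(mean_score = (cs[k + window] - cs[k]) / window,
               mean_y = (cy[k + window] - cy[k]) / window)
}

#' Write an AnchoredMatrix as heatmap-ready TSV
#'
#' Header row of offsets, one row per gene.
#'
#' @param matrix an [AnchoredMatrix-class].
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeAnchoredMatrix <- function(matrix, path, header = character(0)) {
    df <- data.frame(gene_id = rownames(matrix@values),
                     matrix@values, check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(header, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a Profile as two-column TSV
#'
#' @param profile a [Profile-class].
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path, header = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(header, con)
    write.table(as.data.frame(profile), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
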