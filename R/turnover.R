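# CATCH-IT turnover analysis: anchored region averages, condition
# difference curves, and turnover-versus-PolII trend curves. Turnover
# signal is a dense per-position SignalTrack (unitless relative
# incorporation); values may be negative. TES windows are
# transcription-oriented: -3000..-500 means upstream of the 3' end
# along the gene.

#' Named CATCH-IT analysis windows
#'
#' The fixed windows used for turnover region averages: the
#' promoter-proximal region (-350..+350 bp around the TSS, spanning the
#' -1 nucleosome through the +2 nucleosome), the promoter (-150..+150),
#' the +1 nucleosome (0..+150), the gene body anchored at the TSS
#' (+1k..+3k), and the gene body anchored at the TES (-3k..-0.5k).
#'
#' @return Named list of [windowSpec()] objects.
#' @export
catchitWindows <- function() {
    list(promoter_proximal = windowSpec("TSS", -350, 350),
         promoter = windowSpec("TSS", -150, 150),
         plus1 = windowSpec("TSS", 0, 150),
         body_tss = windowSpec("TSS", 1000, 3000),
         body_tes = windowSpec("TES", -3000, -500))
}

#' Per-gene turnover region averages
#'
#' Mean CATCH-IT signal in a transcription-oriented window per gene
#' (delegates to [windowMean()] semantics). Genes too short to contain a
#' gene-body window (window end beyond the TES for TSS-anchored body
#' windows, or start before the TSS for TES-anchored windows) are
#' excluded with a warning.
#'
#' @param track turnover [SignalTrack-class].
#' @param genes gene cohort GRanges.
#' @param window a [windowSpec()], e.g. one of [catchitWindows()].
#' @return data.frame with columns `gene_id`, `value`.
#' @export
catchitRegionMean <- function(track, genes, window) {
    len <- geneLengths(genes)
    short <- if (window$anchor == "TSS" && window$startOffset >= 0)
        len < window$endOffset
    else if (window$anchor == "TES" && window$endOffset <= 0)
        len < -window$startOffset
    else rep(FALSE, length(genes))
    if (any(short)) {
        warning(sum(short),
                " gene(s) too short for the requested window excluded")
        genes <- genes[!short]
    }
    v <- windowMean(track, genes, window)
    data.frame(gene_id = geneIds(genes), value = unname(v))
}

#' Pointwise difference of two profiles
#'
#' `a - b` on an identical offset grid; typically wild type minus
#' mutant CATCH-IT around the TSS.
#'
#' @param profileA,profileB [Profile-class] objects on the same offset
#'   grid.
#' @return A [Profile-class] of differences.
#' @export
differenceProfile <- function(profileA, profileB) {
    if (!identical(offsets(profileA), offsets(profileB)))
        stop("profiles are on different offset grids")
    Profile(offsets(profileA),
            profileValues(profileA) - profileValues(profileB),
            min(nGenes(profileA), nGenes(profileB)))
}

#' Turnover versus PolII density trend curve
#'
#' Sliding-window trend of per-gene turnover region averages against a
#' gene ranking (typically PolII promoter density): delegates to
#' [slidingWindowXY()] on (ranking score, turnover value).
#'
#' @param ranking ranking data.frame from [rankGenes()].
#' @param regionAverages data.frame from [catchitRegionMean()]; must
#'   cover all ranked genes.
#' @param window sliding-window size in genes.
#' @return data.frame with columns `mean_score`, `mean_y`.
#' @export
turnoverVsDensity <- function(ranking, regionAverages, window) {
    y <- regionAverages$value
    names(y) <- regionAverages$gene_id
    slidingWindowXY(ranking, y, window)
}

#' Gene-length-stratified turnover trend
#'
#' Genes are ranked by length and the per-gene turnover averages are
#' smoothed with a sliding window, yielding a (mean length, mean
#' turnover) trend curve.
#'
#' @param regionAverages data.frame from [catchitRegionMean()].
#' @param genes gene cohort GRanges supplying the lengths.
#' @param window sliding-window size in genes.
#' @return data.frame with columns `mean_length`, `mean_turnover`.
#' @export
geneLengthStratified <- function(regionAverages, genes, window) {
    len <- geneLengths(genes)
    names(len) <- geneIds(genes)
    len <- len[regionAverages$gene_id]
    rk <- rankGenes(len)
    tr <- turnoverVsDensity(rk, regionAverages, window)
    data.frame(mean_length = tr$mean_score,
               mean_turnover = tr$mean_y)
}

#' Write a trend curve as TSV
#'
#' @param trend data.frame of trend points.
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeTrend <- function(trend, path, header = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(header, con)
    write.table(trend, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
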