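# Per-gene transcription statistics: promoter and gene-body densities,
# stalling index, traveling ratio, elongation fold-enrichment, and the
# stalled/processive classification.
#
# Densities are per-bp window means (ratios of same-width windows are
# unchanged; across windows the per-bp convention is documented). Zero
# denominators are guarded by a pseudocount epsilon, by default 1% of
# the respective track's genome-wide mean, added to numerator and
# denominator; records whose body density falls below epsilon are
# flagged as denominator-limited.

.epsDefault <- function(track) 0.01 * trackMean(track)

#' Per-gene stalling index
#'
#' The stalling index of a gene is the ratio of total-PolII density at
#' the promoter (window -100..+300 bp around the TSS) to elongating
#' (Ser2-phosphorylated) PolII density in the gene body (+1 kb to +5 kb,
#' or the gene end for genes shorter than 5 kb). Genes of 1 kb or less
#' have an empty body window and are excluded with a warning.
#'
#' @param genes gene cohort GRanges.
#' @param totalTrack normalized total-PolII [SignalTrack-class].
#' @param ser2Track normalized Ser2phos-PolII [SignalTrack-class].
#' @param promWindow promoter [windowSpec()] (default TSS -100..+300).
#' @param bodyStart,bodyEnd gene-body window bounds in bp from the TSS;
#'   the end is capped at the gene length.
#' @param epsilon pseudocount; default 1% of each track's genome-wide
#'   mean (numerator uses the total track's, denominator the Ser2
#'   track's). Use 0 for raw ratios.
#' @return data.frame with columns `gene_id`, `d_prom`, `d_body`,
#'   `stalling_index`, `denominator_limited`.
#' @export
stallingIndex <- function(genes, totalTrack, ser2Track,
                          promWindow = windowSpec("TSS", -100, 300),
                          bodyStart = 1000L, bodyEnd = 5000L,
                          epsilon = NULL) {
    len <- geneLengths(genes)
    drop <- len <= bodyStart
    if (any(drop)) {
        warning(sum(drop), " gene(s) of <= ", bodyStart,
                " bp excluded from stalling analysis")
        genes <- genes[!drop]
        len <- len[!drop]
    }
    epsN <- if (is.null(epsilon)) .epsDefault(totalTrack) else epsilon
    epsD <- if (is.null(epsilon)) .epsDefault(ser2Track) else epsilon
    dProm <- windowMean(totalTrack, genes, promWindow)
    # per-gene body window end = min(bodyEnd, gene length)
    ends <- pmin(bodyEnd, len)
    dBody <- .perGeneBodyMean(ser2Track, genes, bodyStart, ends)
    data.frame(gene_id = geneIds(genes),
               d_prom = unname(dProm), d_body = unname(dBody),
               stalling_index = unname((dProm + epsN) /
                                       (dBody + epsD)),
               denominator_limited = unname(dBody < epsD))
}

# Mean over TSS-anchored window [bodyStart, ends_g) with per-gene end.
.perGeneBodyMean <- function(track, genes, bodyStart, ends) {
    out <- numeric(length(genes))
    for (g in seq_along(genes)) {
        w <- windowSpec("TSS", bodyStart, ends[g])
        out[g] <- windowMean(track, genes[g], w)
    }
    names(out) <- geneIds(genes)
    out
}

#' Per-gene traveling ratio
#'
#' Ratio of total-PolII density at the promoter (-30..+300 bp around the
#' TSS) to total-PolII density in the gene body, defined here as +300 bp
#' to the gene end. Genes of 300 bp or less are excluded with a warning.
#'
#' @param genes gene cohort GRanges.
#' @param totalTrack normalized total-PolII [SignalTrack-class].
#' @param promWindow promoter [windowSpec()] (default TSS -30..+300).
#' @param bodyStart start of the gene-body window (bp from TSS).
#' @param epsilon pseudocount, default 1% of the track's genome-wide
#'   mean.
#' @return Named numeric vector of traveling ratios.
#' @export
travelingRatio <- function(genes, totalTrack,
                           promWindow = windowSpec("TSS", -30, 300),
                           bodyStart = 300L, epsilon = NULL) {
    len <- geneLengths(genes)
    drop <- len <= bodyStart
    if (any(drop)) {
        warning(sum(drop), " gene(s) of <= ", bodyStart,
                " bp excluded from traveling-ratio analysis")
        genes <- genes[!drop]
        len <- len[!drop]
    }
    eps <- if (is.null(epsilon)) .epsDefault(totalTrack) else epsilon
    dProm <- windowMean(totalTrack, genes, promWindow)
    dBody <- .perGeneBodyMean(totalTrack, genes, bodyStart, len)
    (dProm + eps) / (dBody + eps)
}

#' Elongation fold-enrichment profile
#'
#' For each gene at least 5 kb long, elongating-PolII (Ser2phos) density
#' is averaged in consecutive 1 kb windows from the TSS and divided by
#' the gene's reference density, the mean over its first 5 kb. A uniform
#' track therefore gives fold enrichment 1 in every window. The cohort
#' mean and standard deviation are reported per window index.
#'
#' @param genes gene cohort GRanges; genes shorter than 5 kb are
#'   excluded.
#' @param ser2Track normalized Ser2phos [SignalTrack-class].
#' @param windowBp genic window width (default 1000 bp).
#' @param refWindows number of leading windows forming the reference
#'   (default 5, i.e. the first 5 kb).
#' @param maxWindows cap on the number of windows reported.
#' @param epsilon pseudocount on the reference density; default 1% of
#'   the track mean.
#' @return List with `perGene` (genes x windows matrix of fold
#'   enrichments, NA beyond a gene's end) and `summary` (data.frame
#'   `window`, `mean`, `sd`, `n`).
#' @export
elongationFoldEnrichment <- function(genes, ser2Track,
                                     windowBp = 1000L,
                                     refWindows = 5L,
                                     maxWindows = 10L,
                                     epsilon = NULL) {
    len <- geneLengths(genes)
    keep <- len >= windowBp * refWindows
    if (!any(keep))
        stop("no genes at least ", windowBp * refWindows, " bp long")
    genes <- genes[keep]; len <- len[keep]
    eps <- if (is.null(epsilon)) .epsDefault(ser2Track) else epsilon
    nw <- pmin(len %/% windowBp, maxWindows)
    fe <- matrix(NA_real_, nrow = length(genes), ncol = maxWindows,
                 dimnames = list(geneIds(genes),
                                 paste0("w", seq_len(maxWindows))))
    for (g in seq_along(genes)) {
        wm <- vapply(seq_len(nw[g]), function(w)
            windowMean(ser2Track, genes[g],
                       windowSpec("TSS", (w - 1L) * windowBp,
                                  w * windowBp)),
            numeric(1))
        ref <- mean(wm[seq_len(refWindows)])
        fe[g, seq_len(nw[g])] <- wm / (ref + eps)
    }
    summ <- data.frame(
        window = seq_len(maxWindows),
        mean = apply(fe, 2, function(v) mean(v, na.rm = TRUE)),
        sd = apply(fe, 2, function(v) sd(v, na.rm = TRUE)),
        n = apply(fe, 2, function(v) sum(!is.na(v))))
    list(perGene = fe, summary = summ)
}

#' Classify stalled and processive genes
#'
#' Restricted to the top PolII-promoter-occupancy quintile of the given
#' ranking, the `k` genes with the highest stalling index are classified
#' stalled and the `k` with the lowest processive. Ties are broken
#' lexicographically by gene id, so the two sets are always disjoint.
#'
#' @param records stalling record data.frame from [stallingIndex()].
#' @param polIIRanking ranking data.frame from [rankGenes()] on PolII
#'   promoter occupancy (all fragment sizes).
#' @param k set size; must satisfy `k <= floor(quintile size / 2)`.
#' @return List with character vectors `stalled` and `processive`.
#' @export
classifyStalledProcessive <- function(records, polIIRanking, k = 500L) {
    top <- quintileSplit(polIIRanking)[[1L]]
    top <- top[top %in% records$gene_id]
    if (k > length(top) %/% 2L)
        stop("k must be at most half the top-quintile size (",
             length(top) %/% 2L, ")")
    si <- records$stalling_index[match(top, records$gene_id)]
    o <- order(-si, top)   # descending index, id tie-break
    list(stalled = top[o][seq_len(k)],
         processive = rev(top[o])[seq_len(k)])
}

#' Median stalling-index ratio between two conditions
#'
#' Over the genes shared by two stalling tables, the median of the
#' per-gene ratio `stalling_index_b / stalling_index_a` (b = mutant,
#' a = reference), together with the ratio of the two medians.
#'
#' @param recordsA,recordsB stalling record data.frames from
#'   [stallingIndex()]; must share gene ids.
#' @return List with `median_ratio`, `ratio_of_medians`, `n`.
#' @export
medianStallingRatio <- function(recordsA, recordsB) {
    shared <- intersect(recordsA$gene_id, recordsB$gene_id)
    if (!length(shared)) stop("no shared genes between the records")
    a <- recordsA$stalling_index[match(shared, recordsA$gene_id)]
    b <- recordsB$stalling_index[match(shared, recordsB$gene_id)]
    list(median_ratio = median(b / a),
         ratio_of_medians = median(b) / median(a),
         n = length(shared))
}

#' Write a stalling record table as TSV
#'
#' @param records data.frame from [stallingIndex()], optionally with a
#'   `traveling_ratio` column merged in.
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeStallingTable <- function(records, path, header = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(header, con)
    write.table(records, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
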