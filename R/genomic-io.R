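# Readers and writers for the BED-family formats the pipeline touches.
# All files use 0-based half-open coordinates (BED convention); in memory
# intervals are held as 1-based closed GRanges. Gene cohorts are GRanges
# with a `gene_id` metadata column; TSS/TES anchors are derived, 0-based
# positions of the 5'-most / 3'-most transcribed base.

.splitFields <- function(lines) strsplit(trimws(lines), "[ \t]+")

.numOrStop <- function(x, what, lineno, path) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v)))
        stop("malformed ", what, " at line ",
             lineno[which(is.na(v))[1]], " of ", path)
    v
}

#' Read a gene model table (BED6 / BED12)
#'
#' Parses a BED6 or BED12 file into a gene cohort. Records whose strand
#' column is not `+` or `-` are rejected with a warning; malformed lines
#' (too few columns, non-numeric coordinates) raise an error naming the
#' line number.
#'
#' The returned GRanges carries a `gene_id` column; use [geneTSS()],
#' [geneTES()] and [geneLengths()] for the derived transcription anchors.
#' For a minus-strand gene the TSS is the right edge of the interval
#' (0-based `end - 1`).
#'
#' @param path path to the BED file.
#' @param format `"bed6"` or `"bed12"`; only the first six columns are
#'   used either way.
#' @return GRanges with metadata column `gene_id`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t1000\t5000\tgA\t0\t+",
#'              "chr1\t8000\t12000\tgB\t0\t-"), bed)
#' g <- readGenes(bed)
#' geneTSS(g)   # 1000 and 11999
#' @export
readGenes <- function(path, format = c("bed6", "bed12")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) &
                   !startsWith(trimws(lines), "#")]
    if (!length(lines))
        return(GRanges(gene_id = character(0)))
    fields <- .splitFields(lines)
    need <- if (format == "bed6") 6L else 12L
    nf <- lengths(fields)
    if (any(nf < need))
        stop("malformed line ", which(nf < need)[1], " in ", path,
             ": expected >= ", need, " columns")
    chrom <- vapply(fields, `[`, character(1), 1L)
    start0 <- .numOrStop(vapply(fields, `[`, character(1), 2L),
                         "start coordinate", seq_along(fields), path)
    end0 <- .numOrStop(vapply(fields, `[`, character(1), 3L),
                       "end coordinate", seq_along(fields), path)
    id <- vapply(fields, `[`, character(1), 4L)
    strand <- vapply(fields, `[`, character(1), 6L)
    bad <- !strand %in% c("+", "-")
    if (any(bad)) {
        warning(sum(bad), " record(s) with unknown strand rejected: ",
                paste(head(id[bad], 5), collapse = ", "))
        chrom <- chrom[!bad]; start0 <- start0[!bad]
        end0 <- end0[!bad]; id <- id[!bad]; strand <- strand[!bad]
    }
    if (any(start0 >= end0))
        stop("start >= end at line ", which(start0 >= end0)[1],
             " of ", path)
    if (anyDuplicated(id))
        stop("duplicate gene ids in ", path, ": ",
             paste(head(unique(id[duplicated(id)]), 5), collapse = ", "))
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                  gene_id = id)
    gr
}

#' TSS, TES and length accessors for a gene cohort
#'
#' `geneTSS`/`geneTES` return the 0-based genomic coordinate of the
#' 5'-most / 3'-most transcribed base; `geneLengths` the gene length in
#' bp (exclusive-end arithmetic); `geneIds` the id column.
#'
#' @param genes GRanges gene cohort as returned by [readGenes()] or
#'   [sampleGeneCohort()].
#' @return numeric (or character, for `geneIds`) vector, one entry per
#'   gene.
#' @export
geneTSS <- function(genes) {
    ifelse(as.character(strand(genes)) == "+",
           start(genes) - 1L, end(genes) - 1L)
}

#' @rdname geneTSS
#' @export
geneTES <- function(genes) {
    ifelse(as.character(strand(genes)) == "+",
           end(genes) - 1L, start(genes) - 1L)
}

#' @rdname geneTSS
#' @export
geneLengths <- function(genes) width(genes)

#' @rdname geneTSS
#' @export
geneIds <- function(genes) mcols(genes)$gene_id

#' Read paired-end fragments (BED3 / BEDPE)
#'
#' BED3 records are taken as-is; BEDPE mate pairs are collapsed to their
#' outer span (min start, max end). Inter-chromosomal BEDPE pairs are
#' skipped with a warning; a record with `start >= end` is a parse error.
#'
#' @param path path to the fragment file.
#' @param format `"bed3"` or `"bedpe"`.
#' @return A [FragmentSet-class]; `librarySize` equals the number of
#'   records kept.
#' @export
readFragments <- function(path, format = c("bed3", "bedpe")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) &
                   !startsWith(trimws(lines), "#")]
    if (!length(lines))
        return(FragmentSet(GRanges(), list(source = path)))
    fields <- .splitFields(lines)
    nf <- lengths(fields)
    need <- if (format == "bed3") 3L else 6L
    if (any(nf < need))
        stop("malformed line ", which(nf < need)[1], " in ", path,
             ": expected >= ", need, " columns")
    ln <- seq_along(fields)
    if (format == "bed3") {
        chrom <- vapply(fields, `[`, character(1), 1L)
        s <- .numOrStop(vapply(fields, `[`, character(1), 2L),
                        "start", ln, path)
        e <- .numOrStop(vapply(fields, `[`, character(1), 3L),
                        "end", ln, path)
    } else {
        c1 <- vapply(fields, `[`, character(1), 1L)
        c2 <- vapply(fields, `[`, character(1), 4L)
        inter <- c1 != c2
        if (any(inter))
            warning(sum(inter),
                    " inter-chromosomal BEDPE pair(s) skipped")
        s1 <- .numOrStop(vapply(fields, `[`, character(1), 2L),
                         "start", ln, path)
        e1 <- .numOrStop(vapply(fields, `[`, character(1), 3L),
                         "end", ln, path)
        s2 <- .numOrStop(vapply(fields, `[`, character(1), 5L),
                         "start", ln, path)
        e2 <- .numOrStop(vapply(fields, `[`, character(1), 6L),
                         "end", ln, path)
        keep <- !inter
        chrom <- c1[keep]
        s <- pmin(s1, s2)[keep]
        e <- pmax(e1, e2)[keep]
    }
    if (any(s >= e))
        stop("fragment with start >= end at line ", which(s >= e)[1],
             " of ", path)
    FragmentSet(GRanges(chrom, IRanges(s + 1L, e)),
                list(source = path, format = format))
}

#' Write fragments as BED3
#'
#' @param frags a [FragmentSet-class].
#' @param path output path.
#' @param header optional character vector of `#`-prefixed provenance
#'   lines to place at the top of the file.
#' @return `path`, invisibly.
#' @export
writeFragmentsBed <- function(frags, path, header = character(0)) {
    gr <- fragments(frags)
    lines <- sprintf("%s\t%d\t%d", as.character(seqnames(gr)),
                     start(gr) - 1L, end(gr))
    writeLines(c(header, lines), path)
    invisible(path)
}

#' Read a bedGraph file into a SignalTrack
#'
#' @param path bedGraph path (`chrom start end value`, 0-based
#'   half-open). Track definition lines and `#` comments are skipped.
#' @param seqlengths optional named vector of chromosome lengths; by
#'   default each chromosome extends to its last covered base.
#' @param normalization normalization tag to record.
#' @return A [SignalTrack-class]; positions absent from the file are 0.
#' @export
readBedGraph <- function(path, seqlengths = NULL,
                         normalization = "raw") {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!startsWith(trimws(lines), "#") &
                   !startsWith(trimws(lines), "track")]
    if (!length(lines))
        return(SignalTrack(as(list(), "SimpleRleList"), normalization))
    fields <- .splitFields(lines)
    if (any(lengths(fields) < 4L))
        stop("malformed bedGraph line ",
             which(lengths(fields) < 4L)[1], " in ", path)
    chrom <- vapply(fields, `[`, character(1), 1L)
    s <- .numOrStop(vapply(fields, `[`, character(1), 2L), "start",
                    seq_along(fields), path)
    e <- .numOrStop(vapply(fields, `[`, character(1), 3L), "end",
                    seq_along(fields), path)
    v <- .numOrStop(vapply(fields, `[`, character(1), 4L), "value",
                    seq_along(fields), path)
    chroms <- unique(chrom)
    if (is.null(seqlengths)) {
        seqlengths <- vapply(chroms,
            function(cc) max(e[chrom == cc]), numeric(1))
    }
    sig <- lapply(chroms, function(cc) {
        i <- chrom == cc
        len <- seqlengths[[cc]]
        r <- Rle(0, len)
        ir <- IRanges(s[i] + 1L, e[i])
        for (k in seq_along(ir))
            r[start(ir)[k]:end(ir)[k]] <- v[i][k]
        r
    })
    names(sig) <- chroms
    SignalTrack(as(sig, "SimpleRleList"), normalization,
                list(source = path))
}

#' Write a SignalTrack as bedGraph
#'
#' Runs of equal value are merged (run-length encoding); zero runs are
#' omitted, so reading the file back reproduces the track exactly on all
#' covered (non-zero) positions. Values are printed with full double
#' precision to make the round trip exact.
#'
#' @param track a [SignalTrack-class] with finite values.
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path, header = character(0)) {
    sig <- trackSignal(track)
    out <- c(header, unlist(lapply(names(sig), function(cc) {
        r <- sig[[cc]]
        ends <- cumsum(runLength(r))
        starts0 <- ends - runLength(r)   # 0-based starts
        keep <- runValue(r) != 0
        if (!any(keep)) return(character(0))
        sprintf("%s\t%d\t%d\t%s", cc, starts0[keep], ends[keep],
                sprintf("%.17g", runValue(r)[keep]))
    }), use.names = FALSE))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(out, con)
    invisible(path)
}

#' Write a gene cohort as a TSV table
#'
#' Emits `gene_id, chrom, strand, tss, tes, length` with 0-based anchor
#' coordinates, plus any extra metadata columns present on the cohort.
#'
#' @param genes gene cohort GRanges.
#' @param path output path.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path, header = character(0)) {
    df <- data.frame(gene_id = geneIds(genes),
                     chrom = as.character(seqnames(genes)),
                     strand = as.character(strand(genes)),
                     tss = geneTSS(genes), tes = geneTES(genes),
                     length = geneLengths(genes))
    extra <- setdiff(colnames(mcols(genes)), "gene_id")
    for (cc in extra) df[[cc]] <- mcols(genes)[[cc]]
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(header, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a gene cohort as BED6
#'
#' @inheritParams writeGeneTable
#' @return `path`, invisibly.
#' @export
writeGenesBed <- function(genes, path, header = character(0)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     as.character(seqnames(genes)), start(genes) - 1L,
                     end(genes), geneIds(genes),
                     as.character(strand(genes)))
    writeLines(c(header, lines), path)
    invisible(path)
}
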