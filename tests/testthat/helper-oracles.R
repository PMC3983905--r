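# Brute-force oracles and fixture builders, independent of the package
# implementation paths they check. All coordinates in the oracle layer
# are 0-based half-open, matching the package's I/O convention.

# data.frame (chrom, start0, end0) -> FragmentSet
makeFragments <- function(df) {
    FragmentSet(GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start0 + 1L, df$end0)))
}

randomFragmentDf <- function(n, seed, chroms = "chr1", span = 2000L,
                             minLen = 20L, maxLen = 200L) {
    set.seed(seed)
    len <- sample(minLen:maxLen, n, replace = TRUE)
    s0 <- sample(0:(span - maxLen - 1L), n, replace = TRUE)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start0 = s0, end0 = s0 + len)
}

# per-base span coverage by explicit looping
oracleSpanCoverage <- function(df, span) {
    out <- lapply(split(df, df$chrom), function(d) {
        v <- numeric(span)
        for (i in seq_len(nrow(d)))
            for (p in d$start0[i]:(d$end0[i] - 1L))
                v[p + 1L] <- v[p + 1L] + 1
        v
    })
    out
}

# per-base midpoint counts by explicit looping
oracleMidpointCoverage <- function(df, span) {
    out <- lapply(split(df, df$chrom), function(d) {
        v <- numeric(span)
        for (i in seq_len(nrow(d))) {
            m <- floor((d$start0[i] + d$end0[i] - 1) / 2)
            v[m + 1L] <- v[m + 1L] + 1
        }
        v
    })
    out
}

# track value at 0-based position (0 when absent)
trackValueAt <- function(track, chrom, pos0) {
    sig <- trackSignal(track)
    if (!chrom %in% names(sig)) return(0)
    r <- sig[[chrom]]
    i <- pos0 + 1L
    ifelse(i >= 1L & i <= length(r), as.numeric(r[i]), 0)
}

# transcription-oriented window mean by explicit looping
oracleWindowMean <- function(track, chrom, anchor0, strandChar, so,
                             eo) {
    tot <- 0
    for (o in so:(eo - 1L)) {
        g0 <- if (strandChar == "+") anchor0 + o else anchor0 - o
        tot <- tot + trackValueAt(track, chrom, g0)
    }
    tot / (eo - so)
}

# KS D by scanning the ECDF difference over all pooled points
oracleKsD <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(vapply(pts, function(x)
        abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# Pearson r by the long-hand sum formula
oraclePearson <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt(n * sum(x^2) - sum(x)^2) *
        sqrt(n * sum(y^2) - sum(y)^2)
    num / den
}

# Welch t statistic, degrees of freedom and two-sided p, textbook form
oracleWelch <- function(a, b) {
    na <- length(a); nb <- length(b)
    va <- sum((a - mean(a))^2) / (na - 1)
    vb <- sum((b - mean(b))^2) / (nb - 1)
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# a small deterministic gene cohort on both strands
makeGenes <- function(tbl) {
    GenomicRanges::GRanges(tbl$chrom,
        IRanges::IRanges(tbl$start0 + 1L, tbl$end0),
        strand = tbl$strand, gene_id = tbl$id)
}

# SignalTrack from plain numeric vectors (one per chromosome)
makeTrack <- function(..., normalization = "raw") {
    SignalTrack(list(...), normalization)
}

# small simulation setup shared by generator tests
smallSimConfig <- function(seed, nGenes = 400L, frags = 4e4, ...) {
    simConfig(seed = seed, nGenes = nGenes,
              fragmentsPerLibrary = frags, ...)
}
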