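# Stalling index, traveling ratio, elongation fold-enrichment and the
# stalled/processive classification.

# one plus-strand gene with uniform signal levels in chosen regions
.uniformGene <- function(promTotal, bodySer2, len = 8000L) {
    tss0 <- 2000L
    genes <- makeGenes(data.frame(chrom = "chr1", start0 = tss0,
                                  end0 = tss0 + len, strand = "+",
                                  id = "g1"))
    span <- tss0 + len + 2000L
    tot <- makeTrack(chr1 = rep(promTotal, span))
    ser <- makeTrack(chr1 = rep(bodySer2, span))
    list(genes = genes, tot = tot, ser = ser)
}

test_that("stalling index is the promoter/body density ratio", {
    u <- .uniformGene(4, 2)
    rec <- stallingIndex(u$genes, u$tot, u$ser, epsilon = 0)
    expect_equal(rec$d_prom, 4)
    expect_equal(rec$d_body, 2)
    expect_equal(rec$stalling_index, 2)

    same <- stallingIndex(u$genes, u$tot, u$tot, epsilon = 0)
    expect_equal(same$stalling_index, 1)
})

test_that("the pseudocount guards zero denominators and flags them", {
    u <- .uniformGene(5, 0)
    rec <- stallingIndex(u$genes, u$tot, u$ser, epsilon = 0.01)
    expect_equal(rec$stalling_index, 5.01 / 0.01)
    expect_true(rec$denominator_limited)

    # scale invariance at epsilon = 0: scaling both tracks cancels
    u2 <- .uniformGene(8, 4)
    r1 <- stallingIndex(u2$genes, u2$tot, u2$ser, epsilon = 0)
    sc <- SignalTrack(lapply(trackSignal(u2$tot), function(r) r * 7))
    ss <- SignalTrack(lapply(trackSignal(u2$ser), function(r) r * 7))
    r2 <- stallingIndex(u2$genes, sc, ss, epsilon = 0)
    expect_equal(r1$stalling_index, r2$stalling_index)
})

test_that("short genes are excluded from stalling analysis", {
    genes <- makeGenes(data.frame(
        chrom = "chr1", start0 = c(1000, 10000),
        end0 = c(1800, 18000), strand = "+", id = c("tiny", "ok")))
    tr <- makeTrack(chr1 = rep(1, 20000))
    expect_warning(rec <- stallingIndex(genes, tr, tr, epsilon = 0),
                   "excluded")
    expect_equal(rec$gene_id, "ok")
})

test_that("traveling ratio matches window-mean composition", {
    u <- .uniformGene(1, 1)
    expect_equal(unname(travelingRatio(u$genes, u$tot, epsilon = 0)),
                 1)

    # promoter mean 6, body mean 2
    tss0 <- 2000L
    v <- rep(2, 12000)
    v[(tss0 - 30):(tss0 + 299) + 1] <- 6
    genes <- u$genes
    tr6 <- makeTrack(chr1 = v)
    expect_equal(unname(travelingRatio(genes, tr6, epsilon = 0)), 3)

    set.seed(5)
    rnd <- makeTrack(chr1 = runif(12000))
    got <- travelingRatio(genes, rnd, epsilon = 0)
    num <- oracleWindowMean(rnd, "chr1", tss0, "+", -30, 300)
    den <- oracleWindowMean(rnd, "chr1", tss0, "+", 300, 8000)
    expect_equal(unname(got), num / den)
})

test_that("elongation fold-enrichment is 1 for uniform tracks", {
    genes <- makeGenes(data.frame(
        chrom = "chr1", start0 = c(1000, 20000),
        end0 = c(9000, 27000), strand = c("+", "-"),
        id = c("a", "b")))
    tr <- makeTrack(chr1 = rep(3, 40000))
    fe <- elongationFoldEnrichment(genes, tr, epsilon = 0)
    expect_true(all(abs(fe$summary$mean[fe$summary$n > 0] - 1) < 1e-12))
    expect_true(all(fe$summary$sd[fe$summary$n > 1] == 0))
    # first five windows of any gene average to 1 at epsilon = 0
    expect_equal(mean(fe$perGene["a", 1:5]), 1)
})

test_that("a doubled window shows fold-enrichment 2", {
    tss0 <- 1000L
    v <- rep(2, 20000)
    v[(tss0 + 1000):(tss0 + 1999) + 1] <- 2 * 6  # window 2 doubled
    # reference mean over first 5 kb = (4*2 + 12)/5 = 4; FE_2 = 12/4...
    # construct instead so the first-5kb mean equals the flat level:
    genes <- makeGenes(data.frame(chrom = "chr1", start0 = tss0,
                                  end0 = tss0 + 10000, strand = "+",
                                  id = "g"))
    fe <- elongationFoldEnrichment(genes, makeTrack(chr1 = v),
                                   epsilon = 0)
    ref <- (4 * 2 + 12) / 5
    expect_equal(fe$perGene["g", 2], 12 / ref)
    expect_equal(fe$perGene["g", 1], 2 / ref)
    expect_equal(mean(fe$perGene["g", 1:5]), 1)
})

test_that("per-window fold enrichments match a loop oracle on synthetic genes", {
    set.seed(4)
    n <- 10
    starts <- seq(2000, by = 15000, length.out = n)
    genes <- makeGenes(data.frame(
        chrom = "chr1", start0 = starts, end0 = starts + 9000,
        strand = rep(c("+", "-"), 5), id = sprintf("g%02d", 1:n)))
    tr <- makeTrack(chr1 = runif(max(starts) + 12000))
    fe <- elongationFoldEnrichment(genes, tr, epsilon = 0)
    a0 <- geneTSS(genes)
    st <- as.character(GenomicRanges::strand(genes))
    for (g in c(1, 4, 10)) {
        wm <- vapply(1:9, function(w)
            oracleWindowMean(tr, "chr1", a0[g], st[g],
                             (w - 1) * 1000, w * 1000), numeric(1))
        expect_equal(unname(fe$perGene[g, 1:9]),
                     wm / mean(wm[1:5]))
    }
    expect_equal(fe$summary$mean[3],
                 mean(fe$perGene[, 3], na.rm = TRUE))
})

test_that("stalled/processive classification splits the top quintile", {
    ids <- sprintf("g%02d", 1:50)
    rk <- rankGenes(stats::setNames(50:1, ids))   # top quintile g01..g10
    rec <- data.frame(gene_id = ids,
                      stalling_index = c(10:1, runif(40)))
    cls <- classifyStalledProcessive(rec, rk, k = 2)
    expect_equal(cls$stalled, c("g01", "g02"))
    expect_equal(cls$processive, c("g10", "g09"))
    expect_length(intersect(cls$stalled, cls$processive), 0)

    recTie <- data.frame(gene_id = ids, stalling_index = 1)
    clsT <- classifyStalledProcessive(recTie, rk, k = 2)
    expect_equal(clsT$stalled, c("g01", "g02"))      # id tie-break
    expect_equal(sort(clsT$processive), c("g09", "g10"))

    expect_error(classifyStalledProcessive(rec, rk, k = 6), "half")
})

test_that("classification matches a sort oracle on a large quintile", {
    set.seed(12)
    n <- 500
    ids <- sprintf("g%03d", 1:n)
    rk <- rankGenes(stats::setNames(runif(n), ids))
    rec <- data.frame(gene_id = ids, stalling_index = runif(n))
    k <- 50
    cls <- classifyStalledProcessive(rec, rk, k = k)
    top <- quintileSplit(rk)[[1]]
    si <- rec$stalling_index[match(top, rec$gene_id)]
    o <- order(-si, top)
    expect_equal(cls$stalled, top[o][1:k])
    expect_equal(cls$processive, top[o][n / 5 - (0:(k - 1))])
})

test_that("median stalling ratio reduces to simple cases", {
    ids <- sprintf("g%02d", 1:20)
    a <- data.frame(gene_id = ids, stalling_index = runif(20) + 0.5)
    b2 <- data.frame(gene_id = ids,
                     stalling_index = 2 * a$stalling_index)
    expect_equal(medianStallingRatio(a, b2)$median_ratio, 2)
    expect_equal(medianStallingRatio(a, a)$median_ratio, 1)

    set.seed(13)
    b <- data.frame(gene_id = sample(ids),
                    stalling_index = runif(20) + 0.2)
    got <- medianStallingRatio(a, b)
    ratios <- vapply(ids, function(id)
        b$stalling_index[b$gene_id == id] /
            a$stalling_index[a$gene_id == id], numeric(1))
    expect_equal(got$median_ratio, median(ratios))
    expect_equal(got$ratio_of_medians,
                 median(b$stalling_index) / median(a$stalling_index))
    dis <- data.frame(gene_id = "zz", stalling_index = 1)
    expect_error(medianStallingRatio(a, dis), "shared")
})
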