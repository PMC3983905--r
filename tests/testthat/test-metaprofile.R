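# Anchored matrices, profiles, rankings, quintiles, sliding windows.

test_that("anchored matrix is strand-corrected around the anchor", {
    genes <- makeGenes(data.frame(
        chrom = "chr1", start0 = c(500, 500), end0 = c(900, 900),
        strand = c("+", "-"), id = c("p", "m")))
    # plus TSS = 500, minus TSS = 899
    v <- numeric(1200)
    v[500 + 10 + 1] <- 5           # plus strand: genomic tss+10
    v[899 - 10 + 1] <- 7           # minus strand: genomic tss-10
    tr <- makeTrack(chr1 = v)
    am <- buildAnchoredMatrix(tr, genes, "TSS", 100L, 100L, 1L)
    m <- as.matrix(am)
    expect_equal(m["p", "10"], 5)
    expect_equal(m["m", "10"], 7)
    expect_equal(sum(m["p", ]), 5)
})

test_that("anchored matrix equals a per-gene loop oracle on random data", {
    set.seed(23)
    genes <- makeGenes(data.frame(
        chrom = "chr1", start0 = c(300, 900, 1500),
        end0 = c(700, 1300, 1900),
        strand = c("+", "-", "+"), id = c("a", "b", "c")))
    tr <- makeTrack(chr1 = runif(2500))
    am <- buildAnchoredMatrix(tr, genes, "TSS", 50L, 100L, 1L)
    m <- as.matrix(am)
    a0 <- geneTSS(genes)
    st <- as.character(GenomicRanges::strand(genes))
    for (g in 1:3) for (o in c(-50, -1, 0, 37, 99)) {
        g0 <- if (st[g] == "+") a0[g] + o else a0[g] - o
        expect_equal(m[g, as.character(o)],
                     trackValueAt(tr, "chr1", g0))
    }
    # binning averages within each bin
    am10 <- buildAnchoredMatrix(tr, genes, "TSS", 50L, 100L, 10L)
    expect_equal(as.matrix(am10)[2, "0"],
                 mean(m[2, as.character(0:9)]))
})

test_that("mirroring the genome and flipping strands leaves matrices identical", {
    L <- 3000L
    set.seed(99)
    v <- runif(L)
    genes <- makeGenes(data.frame(
        chrom = "chr1", start0 = c(400, 1800), end0 = c(1200, 2600),
        strand = c("+", "-"), id = c("a", "b")))
    tr <- makeTrack(chr1 = v)
    # mirrored genome: position p -> L-1-p
    genesM <- makeGenes(data.frame(
        chrom = "chr1", start0 = L - c(1200, 2600),
        end0 = L - c(400, 1800), strand = c("-", "+"),
        id = c("a", "b")))
    trM <- makeTrack(chr1 = rev(v))
    am <- buildAnchoredMatrix(tr, genes, "TSS", 100L, 200L, 1L)
    amM <- buildAnchoredMatrix(trM, genesM, "TSS", 100L, 200L, 1L)
    expect_identical(as.matrix(am), as.matrix(amM))
})

test_that("mean profiles average rows; quintile-weighted means recompose", {
    vals <- matrix(runif(20 * 6), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20), NULL))
    am <- new("AnchoredMatrix", values = vals, anchor = "TSS",
              offsets = 0:5, binSize = 1L)
    one <- meanProfile(am, "g03")
    expect_equal(profileValues(one), unname(vals["g03", ]))
    expect_equal(profileValues(meanProfile(am)),
                 unname(colMeans(vals)))
    expect_error(meanProfile(am, character(0)), "empty")
    expect_error(meanProfile(am, "nope"), "unknown")

    rk <- rankGenes(stats::setNames(runif(20), rownames(vals)))
    qs <- quintileSplit(rk)
    wavg <- Reduce(`+`, lapply(qs, function(ids)
        length(ids) * profileValues(meanProfile(am, ids)))) / 20
    expect_equal(wavg, profileValues(meanProfile(am)))
})

test_that("two shifted rows average to the midline", {
    a <- c(1, 4, 2, 8)
    vals <- rbind(a, a + 2)
    rownames(vals) <- c("x", "y")
    am <- new("AnchoredMatrix", values = vals, anchor = "TSS",
              offsets = 0:3, binSize = 1L)
    expect_equal(profileValues(meanProfile(am)), a + 1)
})

test_that("percent dynamic range maps [min,max] to [0,100]", {
    p <- Profile(1:3, c(2, 4, 6))
    expect_equal(profileValues(percentDynamicRange(p)),
                 c(0, 50, 100))
    expect_warning(z <- percentDynamicRange(Profile(1:3, c(5, 5, 5))),
                   "constant")
    expect_equal(profileValues(z), c(0, 0, 0))
    set.seed(2)
    pr <- percentDynamicRange(Profile(1:50, rnorm(50)))
    expect_equal(min(profileValues(pr)), 0)
    expect_equal(max(profileValues(pr)), 100)
})

test_that("window means are transcription-oriented with zero fill", {
    genes <- makeGenes(data.frame(
        chrom = "chr1", start0 = c(200, 600), end0 = c(500, 900),
        strand = c("+", "-"), id = c("p", "m")))
    tr <- makeTrack(chr1 = rep(4, 1000))
    w <- windowSpec("TSS", -50, 150)
    expect_equal(unname(windowMean(tr, genes, w)), c(4, 4))

    # value 10 on exactly half the window, 0 elsewhere
    v <- numeric(1000)
    v[(200 + 0):(200 + 99) + 1] <- 10
    expect_equal(unname(windowMean(makeTrack(chr1 = v), genes[1],
                                   windowSpec("TSS", 0, 200))), 5)

    set.seed(5)
    tr2 <- makeTrack(chr1 = runif(1000))
    for (g in 1:2) {
        got <- windowMean(tr2, genes[g], windowSpec("TSS", -30, 70))
        a0 <- geneTSS(genes)[g]
        st <- as.character(GenomicRanges::strand(genes))[g]
        expect_equal(unname(got),
                     oracleWindowMean(tr2, "chr1", a0, st, -30, 70))
    }
})

test_that("windows beyond chromosome bounds are truncated with a warning", {
    genes <- makeGenes(data.frame(chrom = "chr1", start0 = 10,
                                  end0 = 200, strand = "+",
                                  id = "edge"))
    tr <- makeTrack(chr1 = rep(2, 300))
    expect_warning(v <- windowMean(tr, genes,
                                   windowSpec("TSS", -50, 50)),
                   "truncated")
    expect_equal(unname(v), 2)  # truncated denominator, uniform value
})

test_that("gene ranking is descending with lexicographic tie-break", {
    rk <- rankGenes(c(a = 1, b = 3, c = 2))
    expect_equal(rk$gene_id, c("b", "c", "a"))
    expect_true(all(diff(rk$score) <= 0))
    tie <- rankGenes(c(z = 1, a = 1, m = 1))
    expect_equal(tie$gene_id, c("a", "m", "z"))
    expect_error(rankGenes(c(a = 1, b = NaN)), "b")
    set.seed(8)
    sc <- stats::setNames(runif(100), sprintf("g%03d", 1:100))
    rk2 <- rankGenes(sc)
    expect_equal(rk2$score, unname(sort(sc, decreasing = TRUE)))
    expect_setequal(rk2$gene_id, names(sc))
})

test_that("quintile split gives contiguous near-equal blocks, larger first", {
    rk10 <- rankGenes(stats::setNames(10:1, letters[1:10]))
    expect_equal(lengths(quintileSplit(rk10)), rep(2L, 5))
    rk12 <- rankGenes(stats::setNames(12:1, sprintf("g%02d", 1:12)))
    expect_equal(lengths(quintileSplit(rk12)), c(3L, 3L, 2L, 2L, 2L))
    expect_error(quintileSplit(rankGenes(c(a = 1, b = 2))), "5 genes")

    set.seed(31)
    big <- rankGenes(stats::setNames(runif(1000),
                                     sprintf("g%04d", 1:1000)))
    qs <- quintileSplit(big)
    expect_equal(sum(lengths(qs)), 1000L)
    expect_equal(anyDuplicated(unlist(qs)), 0L)
    expect_setequal(unlist(qs), big$gene_id)
})

test_that("sliding windows compute paired means, step one gene", {
    n <- 50
    set.seed(9)
    sc <- stats::setNames(runif(n), sprintf("g%02d", 1:n))
    y <- stats::setNames(runif(n), names(sc))
    rk <- rankGenes(sc)
    tr <- slidingWindowXY(rk, y, 10)
    expect_equal(nrow(tr), n - 10 + 1)
    for (k in c(1, 17, 41)) {
        ids <- rk$gene_id[k:(k + 9)]
        expect_equal(tr$mean_score[k], mean(sc[ids]))
        expect_equal(tr$mean_y[k], mean(y[ids]))
    }
    # window = n collapses to the overall means
    all1 <- slidingWindowXY(rk, y, n)
    expect_equal(nrow(all1), 1L)
    expect_equal(all1$mean_y, mean(y))
    # constant y stays constant
    cst <- slidingWindowXY(rk, stats::setNames(rep(3, n), names(y)), 7)
    expect_true(all(cst$mean_y == 3))
    # window 1 is the identity in rank order
    id1 <- slidingWindowXY(rk, y, 1)
    expect_equal(id1$mean_score, rk$score)
    expect_equal(id1$mean_y, unname(y[rk$gene_id]))
    expect_error(slidingWindowXY(rk, y, 0), "at least 1")
    expect_error(slidingWindowXY(rk, y, n + 1), "larger")
})
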