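# The synthetic cohort generator: determinism, architecture placement,
# library mixtures, turnover coupling, and the recovery estimators.

test_that("generator outputs are pure functions of config and seed", {
    cfg <- smallSimConfig(seed = 5, nGenes = 200L, frags = 1e4)
    g1 <- sampleGeneCohort(cfg)
    g2 <- sampleGeneCohort(smallSimConfig(seed = 5, nGenes = 200L,
                                          frags = 1e4))
    expect_identical(geneTSS(g1), geneTSS(g2))
    expect_identical(S4Vectors::mcols(g1)$activity,
                     S4Vectors::mcols(g2)$activity)

    l1 <- simulateLibrary("total_polII", "wt", g1, seed = 9)
    l2 <- simulateLibrary("total_polII", "wt", g2, seed = 9)
    expect_identical(GenomicRanges::start(fragments(l1)),
                     GenomicRanges::start(fragments(l2)))
    expect_identical(GenomicRanges::end(fragments(l1)),
                     GenomicRanges::end(fragments(l2)))

    c1 <- simulateCatchit(g1, "wt", seed = 11)
    c2 <- simulateCatchit(g2, "wt", seed = 11)
    expect_identical(trackSignal(c1), trackSignal(c2))
})

test_that("cohorts honour size, layout and activity structure", {
    expect_length(sampleGeneCohort(smallSimConfig(seed = 1,
                                                  nGenes = 0L)), 0L)
    cfg <- simConfig(seed = 2, nGenes = 2000L)
    g <- sampleGeneCohort(cfg)
    expect_length(g, 2000L)
    # non-overlapping with clear flanks by construction
    expect_length(filterGenes(g, minLength = 2000L), 2000L)
    act <- S4Vectors::mcols(g)$activity
    rk <- rankGenes(stats::setNames(act, geneIds(g)))
    expect_equal(lengths(quintileSplit(rk)), rep(400L, 5))
    expect_error(simConfig(nGenes = 10), "seed")
})

test_that("nucleosome placement realizes the architecture preset", {
    cfg <- smallSimConfig(seed = 3, nGenes = 300L)
    g <- sampleGeneCohort(cfg)
    exact <- architecturePreset(fuzzSd = 0)
    dy <- placeNucleosomes(g, exact, "wt")
    plus1 <- dy$offset[dy$nuc_index == 1L]
    expect_true(all(plus1 == 123L))   # entry +50 => dyad +123
    expect_true(all(dy$offset[dy$nuc_index == -1L] == -170L))
    expect_true(all(diff(dy$offset[dy$gene_idx == 1 &
                                   dy$nuc_index > 0]) == 190L))

    # same seed across conditions: identical dyads, scaled occupancy
    arch <- architecturePreset()
    dwt <- placeNucleosomes(g, arch, "wt")
    dkr <- placeNucleosomes(g, arch, "k510r")
    expect_identical(dwt$offset, dkr$offset)
    prox <- dwt$offset <= 600
    expect_equal(dkr$occupancy[prox] / dwt$occupancy[prox],
                 rep(0.6, sum(prox)))
    expect_equal(dkr$occupancy[!prox] / dwt$occupancy[!prox],
                 rep(0.75, sum(!prox)))
})

test_that("realized +1 dyads centre on the preset target", {
    cfg <- simConfig(seed = 8, nGenes = 2000L)
    g <- sampleGeneCohort(cfg)
    dy <- placeNucleosomes(g, architecturePreset(), "wt")
    expect_lt(abs(mean(dy$offset[dy$nuc_index == 1L]) - 123), 1)
})

test_that("crosslink probability controls the footprint/mono mixture", {
    base <- list(seed = 13, nGenes = 150L, frags = 2e4)
    noBg <- function(px) smallSimConfig(seed = base$seed,
        nGenes = base$nGenes, frags = base$frags,
        pCrosslink = px, bgFraction = 0, bgFractionMnase = 0)
    g0 <- sampleGeneCohort(noBg(0))
    lens0 <- fragmentLengths(simulateLibrary("chd1_wt", "wt", g0,
                                             seed = 21))
    expect_true(all(lens0 >= 20 & lens0 <= 45))

    g1 <- sampleGeneCohort(noBg(1))
    lens1 <- fragmentLengths(simulateLibrary("total_polII", "wt", g1,
                                             seed = 22))
    expect_true(all(lens1 >= 111 & lens1 <= 147))

    gp <- sampleGeneCohort(noBg(0.3))
    lensP <- fragmentLengths(simulateLibrary("total_polII", "wt", gp,
                                             seed = 23))
    nMono <- sum(lensP >= 111)
    n <- length(lensP)
    expect_lt(abs(nMono - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))

    expect_error(simulateLibrary("tfiib", "wt", gp), "unknown factor")
})

test_that("turnover signal follows the condition preset", {
    cfg <- smallSimConfig(seed = 17, nGenes = 250L)
    g <- sampleGeneCohort(cfg)
    act <- S4Vectors::mcols(g)$activity
    wins <- catchitWindows()

    flat <- conditionPreset("wt")
    flat$turnover$slope <- 0
    flat$turnover$noiseSd <- 0
    trF <- simulateCatchit(g, flat, seed = 31)
    pp <- catchitRegionMean(trF, g, wins$promoter)
    expect_equal(pp$value, rep(flat$turnover$basal, length(g)),
                 tolerance = 1e-12)

    # mutant promoter turnover is abrogated: no dependence on activity
    trK <- simulateCatchit(g, "k510r", seed = 32)
    ppK <- catchitRegionMean(trK, g, wins$promoter)
    slope <- unname(coef(lm(ppK$value ~ act))[2])
    expect_lt(abs(slope), 0.01)

    # constant gene-body increment delta at all elongation densities
    trW <- simulateCatchit(g, "wt", seed = 33)
    bW <- catchitRegionMean(trW, g, wins$body_tss)$value
    bK <- catchitRegionMean(simulateCatchit(g, "k510r", seed = 33),
                            g, wins$body_tss)$value
    dlt <- conditionPreset("k510r")$turnover$delta
    el <- act * S4Vectors::mcols(g)$escape
    bins <- cut(el, quantile(el, 0:4 / 4), include.lowest = TRUE,
                labels = FALSE)
    for (b in 1:4)
        expect_lt(abs(mean((bK - bW)[bins == b]) - dlt), 0.05)
})

test_that("wild-type promoter turnover rises with PolII and saturates; mutant is flat", {
    cfg <- smallSimConfig(seed = 19, nGenes = 600L)
    g <- sampleGeneCohort(cfg)
    act <- S4Vectors::mcols(g)$activity
    rk <- rankGenes(stats::setNames(act, geneIds(g)))
    wins <- catchitWindows()
    trW <- simulateCatchit(g, "wt", seed = 41)
    trK <- simulateCatchit(g, "k510r", seed = 42)
    raW <- catchitRegionMean(trW, g, wins$promoter_proximal)
    raK <- catchitRegionMean(trK, g, wins$promoter_proximal)
    tw <- turnoverVsDensity(rk, raW, 150)
    tk <- turnoverVsDensity(rk, raK, 150)
    # monotone rise below the ceiling
    below <- tw$mean_score < conditionPreset("wt")$turnover$ceiling
    expect_gt(cor(tw$mean_score[below], tw$mean_y[below]), 0.8)
    sW <- unname(coef(lm(mean_y ~ mean_score, tw))[2])
    sK <- unname(coef(lm(mean_y ~ mean_score, tk))[2])
    expect_lt(abs(sK), 0.05 * abs(sW))
})

test_that("condition contrasts show in the simulated libraries", {
    cfg <- smallSimConfig(seed = 23, nGenes = 400L, frags = 6e4)
    g <- sampleGeneCohort(cfg)
    sc <- canonicalSizeClasses()
    occ <- vapply(c("wt", "k510r"), function(cc) {
        tr <- libraryTrack(simulateLibrary("nucleosome", cc, g,
                                           seed = 51), sc$mono, "span")
        mean(windowMean(tr, g, windowSpec("TSS", -350, 350)))
    }, numeric(1))
    expect_lt(occ["k510r"], occ["wt"])

    # wild-type short-fragment PolII peaks over the TSS
    trP <- libraryTrack(simulateLibrary("total_polII", "wt", g,
                                        seed = 52), sc$short,
                        "midpoint")
    pP <- meanProfile(buildAnchoredMatrix(trP, g, "TSS", 1000L,
                                          2000L, 1L))
    expect_lt(abs(estimatePeakOffset(pP, c(-500, 1000))), 30)

    # wild-type remodeler signal declines beyond +500 bp
    trC <- libraryTrack(simulateLibrary("chd1_wt", "wt", g,
                                        seed = 53), sc$short,
                        "midpoint")
    pC <- meanProfile(buildAnchoredMatrix(trC, g, "TSS", 1000L,
                                          2000L, 1L))
    v <- profileValues(pC); o <- offsets(pC)
    m1 <- mean(v[o >= 300 & o < 500])
    m2 <- mean(v[o >= 700 & o < 900])
    m3 <- mean(v[o >= 1200 & o < 1400])
    expect_gt(m1, m2)
    expect_gt(m2, m3)
})

test_that("the entry-site estimator inverts the span-coverage geometry", {
    offs <- -300:400
    tri <- function(peak) pmax(0, 70 - abs(offs - peak)) +
        pmax(0, 70 - abs(offs + 170))
    expect_equal(estimatePlus1Entry(Profile(offs, tri(123))), 50)
    expect_equal(estimatePlus1Entry(Profile(offs, tri(140))), 67)
    expect_error(estimatePlus1Entry(Profile(offs, rep(1, length(offs)))),
                 "local maximum|downstream")
})

test_that("the peak estimator reports the smoothed maximum, leftmost on ties", {
    offs <- -200:500
    v <- numeric(length(offs))
    v[offs == 60] <- 10
    expect_equal(estimatePeakOffset(Profile(offs, v), c(-200, 500)),
                 60)
    v2 <- numeric(length(offs))
    v2[offs == 100] <- 10; v2[offs == 300] <- 10
    expect_equal(estimatePeakOffset(Profile(offs, v2), c(-200, 500)),
                 100)
    expect_error(estimatePeakOffset(Profile(offs, rep(2, length(offs))),
                                    c(-200, 500)), "flat")
})
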