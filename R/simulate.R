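# Synthetic cohort and library generator. The generator encodes the
# chromatin-architecture model: a phased nucleosome array with an NDR
# and a +1 nucleosome entering ~+50 bp; factor footprints (PolII ~35 bp,
# remodeler 20-45 bp) placed by per-factor rules; factor-nucleosome
# crosslinks recovered as mononucleosome-sized fragments at the nearest
# dyad; and CATCH-IT turnover coupled to PolII density with
# condition-specific perturbations. Everything is a pure function of
# (presets, config, seed).

.SIM_FACTORS <- c("total_polII", "ser2_polII", "chd1_wt",
                  "chd1_k510r", "nucleosome")

#' Sample a synthetic gene cohort
#'
#' Draws `nGenes` non-overlapping genes on both strands, laid out
#' sequentially over `nChrom` chromosomes with a fixed inter-gene gap.
#' Each gene carries a PolII `activity` (log-normal, long-tailed,
#' spanning the quintile range) and a promoter-escape efficiency
#' `escape` (log-normal) that scales its elongating-PolII rate. The
#' config (including the seed) is stored in `metadata()` of the result.
#'
#' @param config a [simConfig()].
#' @return GRanges cohort with metadata columns `gene_id`, `activity`,
#'   `escape`; deterministic for a fixed seed.
#' @export
sampleGeneCohort <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    n <- config$nGenes
    if (n == 0) {
        gr <- GRanges(gene_id = character(0))
        metadata(gr) <- list(config = config)
        return(gr)
    }
    len <- round(pmin(pmax(rlnorm(n, config$geneLengthMeanLog,
                                  config$geneLengthSdLog),
                           config$geneLengthMin),
                      config$geneLengthMax))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    act <- rlnorm(n, 0, config$activitySdLog)
    esc <- rlnorm(n, 0, config$escapeSdLog)
    chromOf <- rep(seq_len(config$nChrom), length.out = n)
    start0 <- integer(n)
    seqlen <- numeric(config$nChrom)
    for (cc in seq_len(config$nChrom)) {
        i <- which(chromOf == cc)
        # sequential layout: gap, gene, gap, gene, ...
        s <- config$spacing +
            c(0, cumsum(len[i][-length(i)] + config$spacing))
        start0[i] <- s
        seqlen[cc] <- s[length(s)] + len[i][length(i)] +
            config$spacing
    }
    chromNames <- paste0("chr", seq_len(config$nChrom))
    gr <- GRanges(chromNames[chromOf],
                  IRanges(start0 + 1L, width = len),
                  strand = strand,
                  seqinfo = Seqinfo(chromNames, seqlen),
                  gene_id = sprintf("g%04d", seq_len(n)),
                  activity = act, escape = esc)
    metadata(gr) <- list(config = config)
    gr
}

#' Place nucleosomes on a cohort
#'
#' Realizes the architecture preset per gene: a -1 dyad upstream of the
#' NDR and a downstream array starting at the +1 dyad
#' (`plus1Entry + 73`) with repeat-length spacing, each dyad jittered by
#' the preset fuzziness. Occupancies are 1, scaled by the condition's
#' promoter-proximal / gene-body multipliers. For a fixed seed the dyad
#' positions are identical across conditions; only occupancies differ.
#'
#' @param genes cohort GRanges from [sampleGeneCohort()].
#' @param arch an [architecturePreset()].
#' @param condition a [conditionPreset()] (or its name).
#' @param seed jitter seed; defaults to the cohort seed so every
#'   library simulated from the same cohort sees the same nucleosome
#'   positions.
#' @param promoterProximalMax dyads at offsets up to this (bp from the
#'   TSS) take the promoter-proximal occupancy multiplier (default 600,
#'   covering the -1 through +3 nucleosomes).
#' @return data.frame with columns `gene_id`, `gene_idx`, `nuc_index`
#'   (-1, 1, 2, ...), `offset` (realized transcription-oriented dyad
#'   offset from the TSS, bp), `occupancy`.
#' @export
placeNucleosomes <- function(genes, arch = architecturePreset(),
                             condition = conditionPreset("wt"),
                             seed = NULL,
                             promoterProximalMax = 600L) {
    if (is.character(condition)) condition <- conditionPreset(condition)
    if (is.null(seed)) {
        cfg <- metadata(genes)$config
        if (is.null(cfg)) stop("no cohort config; supply a seed")
        seed <- cfg$seed
    }
    len <- geneLengths(genes)
    if (any(len < arch$repeatLength))
        stop("all genes must be at least one repeat length long")
    set.seed(seed)
    nArr <- pmax(
        (len - 1L - arch$plus1Dyad) %/% arch$repeatLength + 1L, 1L)
    nTot <- nArr + 1L   # + the -1 nucleosome
    gidx <- rep(seq_along(genes), nTot)
    nucIdx <- unlist(lapply(nTot, function(k) c(-1L, seq_len(k - 1L))))
    meanOff <- ifelse(nucIdx == -1L, arch$minus1Dyad,
                      arch$plus1Dyad +
                          (nucIdx - 1L) * arch$repeatLength)
    off <- meanOff + round(rnorm(length(meanOff), 0, arch$fuzzSd))
    occ <- ifelse(off <= promoterProximalMax,
                  condition$occPromoter, condition$occBody)
    data.frame(gene_id = geneIds(genes)[gidx], gene_idx = gidx,
               nuc_index = nucIdx, offset = off, occupancy = occ)
}

# Per-gene stalling multipliers for the k510r condition: the effect
# e_g = a_g / b_g increases with the processivity (escape) rank
# (processive genes most affected), and the base strength is solved so
# that the analytically expected median of the per-gene stalling-index
# ratio equals the preset target. The analytics account for (i) the
# rpm library-size renormalization with its fixed-rate background
# anchor, (ii) the short-size-class retention of genic footprints vs
# uniform background fragments, and (iii) the promoter-window capture
# of each condition's placement rule.
.stallingEffects <- function(genes, condition,
                             arch = architecturePreset(),
                             config = metadata(genes)$config) {
    n <- length(genes)
    if (is.na(condition$stallingTarget))
        return(list(a = rep(1, n), b = rep(1, n)))
    act <- mcols(genes)$activity
    esc <- mcols(genes)$escape
    len <- geneLengths(genes)
    q <- (rank(esc, ties.method = "first") - 0.5) / n
    rawE <- exp(log(condition$stallingSpan) * (q - 0.5))
    wBody0 <- act * len * esc * config$polBodyPerBp
    captWt <- pnorm(300, 0, 20) - pnorm(-100, 0, 20)
    stallSd <- sqrt(12^2 + arch$fuzzSd^2)
    centers <- arch$plus1Entry +
        (seq_len(3L) - 1L) * arch$repeatLength + 20
    wMix <- c(0.55, 0.30, 0.15)
    captK <- sum(wMix * (pnorm(300, centers, stallSd) -
                         pnorm(-100, centers, stallSd)))
    # short-class (35-75 bp) retention: genic footprints ~N(35,5)
    # minus crosslinked events, vs uniform 30-200 bp background
    pKeepGen <- (1 - pnorm(34.5, 35, 5)) * (1 - config$pCrosslink)
    pKeepBg <- (75.5 - 34.5) / 170
    beta <- config$bgFraction
    G <- sum(seqlengths(genes))
    Wwt <- sum(act + wBody0)
    Vwt <- sum(act * len * esc)
    Bt <- beta / (1 - beta) * Wwt   # background rate, total library
    Bs <- beta / (1 - beta) * Vwt   # background rate, Ser2 library
    # expected per-bp short-class densities (up to a common constant):
    # genic signal plus the uniform background floor inside the
    # measured windows, over the selected-library size
    promDensity <- function(wPromG, W, B, capt) {
        ngen <- W / (B + W); nbg <- B / (B + W)
        L <- ngen * pKeepGen + nbg * pKeepBg
        (ngen * (wPromG / W) * pKeepGen * capt / 400 +
         nbg * pKeepBg / G) / L
    }
    bodyDensity <- function(vG, V, B) {
        ngen <- V / (B + V); nbg <- B / (B + V)
        L <- ngen * pKeepGen + nbg * pKeepBg
        (ngen * (vG / V) * pKeepGen / (len - 1000) +
         nbg * pKeepBg / G) / L
    }
    gam <- condition$stallingGamma
    multAt <- function(s)
        list(a = (s * rawE)^gam, b = (s * rawE)^(gam - 1))
    ratioAt <- function(s) {
        m <- multAt(s)
        dpWt <- promDensity(act, Wwt, Bt, captWt)
        dpK <- promDensity(act * m$a,
                           sum(act * m$a + wBody0 * m$b), Bt, captK)
        dbWt <- bodyDensity(act * len * esc, Vwt, Bs)
        dbK <- bodyDensity(act * len * esc * m$b,
                           sum(act * len * esc * m$b), Bs)
        (dpK / dpWt) / (dbK / dbWt)
    }
    # the cohort median of the measured per-gene ratio is lifted above
    # the designed per-gene contrast by heteroscedastic count noise
    # around the processivity-sloped effect; model the measured median
    # as the median of log-normal noise (variance ~ 1/expected window
    # count) around the analytic per-gene ratios
    N <- config$fragmentsPerLibrary
    win <- pmin(5000, len) - 1000
    lamProm <- function(wg, W, B, capt) {
        ng <- W / (B + W); nb <- B / (B + W)
        N * ng * (wg / W) * pKeepGen * capt + N * nb * pKeepBg * 400 / G
    }
    lamBody <- function(vg, V, B) {
        ng <- V / (B + V); nb <- B / (B + V)
        N * ng * (vg / V) * pKeepGen * (win / (len - 1000)) +
            N * nb * pKeepBg * win / G
    }
    measuredMedian <- function(s) {
        m <- multAt(s)
        pred <- ratioAt(s)
        Wk <- sum(act * m$a + wBody0 * m$b)
        Vk <- sum(act * len * esc * m$b)
        sig <- sqrt(1 / lamProm(act, Wwt, Bt, captWt) +
                    1 / lamProm(act * m$a, Wk, Bt, captK) +
                    1 / lamBody(act * len * esc, Vwt, Bs) +
                    1 / lamBody(act * len * esc * m$b, Vk, Bs))
        uniroot(function(r)
            mean(pnorm((log(r) - log(pred)) / sig)) - 0.5,
            c(1e-3, 1e3), tol = 1e-9)$root
    }
    f <- function(s) measuredMedian(s) - condition$stallingTarget
    hi <- 1000
    if (f(hi) < 0) {
        warning("designed stalling contrast not reachable at this ",
                "signal-to-noise; using the strongest feasible effect")
        s <- hi
    } else {
        s <- uniroot(f, c(0.01, hi), tol = 1e-8)$root
    }
    multAt(s)
}

.clipNorm <- function(n, mean, sd, lo, hi)
    pmin(pmax(rnorm(n, mean, sd), lo), hi)

#' Simulate a ChIP fragment library
#'
#' Draws a fragment library for one factor under one condition. Binding
#' events pick genes proportional to activity (promoter factors) or
#' activity x length x escape efficiency (elongating factors); each
#' event yields either a short factor-footprint fragment placed by the
#' factor's placement rule, or -- with probability `pCrosslink` -- a
#' mononucleosome-sized fragment centred on the nearest dyad
#' (factor-nucleosome crosslink). A uniform genomic background fraction
#' is added. The `nucleosome` factor samples dyads directly,
#' proportional to condition-scaled occupancy.
#'
#' Placement rules: wild-type total PolII centres on the TSS (N(0, 20));
#' under `k510r` total PolII stalls ~20 bp inside the entry sites of the
#' +1..+3 nucleosomes. Wild-type Chd1 spreads over 0..+500 bp with an
#' exponential tail beyond; K510R-Chd1 uses either the `genome_average`
#' placement (N(+60, 30) from the TSS) or the `processive` per-
#' nucleosome placement (~50 bp inside the +1..+3 entry sites). Ser2
#' PolII is uniform over +1 kb..TES; total PolII additionally carries an
#' elongating component uniform over +300..TES.
#'
#' @param factor one of `total_polII`, `ser2_polII`, `chd1_wt`,
#'   `chd1_k510r`, `nucleosome`.
#' @param condition a [conditionPreset()] or its name.
#' @param genes cohort GRanges from [sampleGeneCohort()].
#' @param arch an [architecturePreset()].
#' @param config a [simConfig()]; defaults to the cohort's.
#' @param seed library seed; defaults to the cohort seed.
#' @param placement for `chd1_k510r`: `"genome_average"` (default) or
#'   `"processive"`; ignored otherwise.
#' @return A [FragmentSet-class] with provenance (factor, condition,
#'   placement, seed); deterministic per seed.
#' @export
simulateLibrary <- function(factor, condition, genes,
                            arch = architecturePreset(),
                            config = NULL, seed = NULL,
                            placement = c("genome_average",
                                          "processive")) {
    if (!factor %in% .SIM_FACTORS)
        stop("unknown factor '", factor, "'; available: ",
             paste(.SIM_FACTORS, collapse = ", "))
    placement <- match.arg(placement)
    if (is.character(condition)) condition <- conditionPreset(condition)
    if (is.null(config)) config <- metadata(genes)$config
    if (is.null(config)) stop("no simulation config available")
    if (is.null(seed)) seed <- config$seed
    # nucleosome positions are a cohort property: jitter from the
    # cohort seed, identical for every library and condition
    dy <- placeNucleosomes(genes, arch, condition)
    set.seed(seed)

    n <- config$fragmentsPerLibrary
    act <- mcols(genes)$activity
    esc <- mcols(genes)$escape
    len <- geneLengths(genes)
    # stalling multipliers only shape the PolII libraries
    eff <- if (factor %in% c("total_polII", "ser2_polII"))
        .stallingEffects(genes, condition, arch, config)
    else list(a = rep(1, length(genes)), b = rep(1, length(genes)))

    # rate-based library composition: the background event rate is
    # pinned at the wild-type library's level, so condition effects on
    # genic rates shift the genic/background balance exactly as finite
    # ChIP signal-to-noise does
    beta <- if (factor == "nucleosome") config$bgFractionMnase
            else config$bgFraction
    if (factor == "nucleosome") {
        wSum <- sum(dy$occupancy); wSumWt <- nrow(dy)
    } else if (factor == "total_polII") {
        wProm <- act * eff$a
        wBody <- act * len * esc * eff$b * config$polBodyPerBp
        wSum <- sum(wProm + wBody)
        wSumWt <- sum(act + act * len * esc * config$polBodyPerBp)
    } else if (factor == "ser2_polII") {
        wSer <- act * len * esc * eff$b
        wSum <- sum(wSer); wSumWt <- sum(act * len * esc)
    } else {
        wSum <- wSumWt <- sum(act)
    }
    B <- beta / (1 - beta) * wSumWt
    nbg <- round(n * B / (B + wSum))
    ngen <- n - nbg

    # realized array-dyad offsets as a genes x K lookup matrix
    arr <- dy[dy$nuc_index > 0, ]
    kMax <- max(arr$nuc_index)
    dyOff <- matrix(NA_real_, nrow = length(genes), ncol = kMax)
    dyOff[cbind(arr$gene_idx, arr$nuc_index)] <- arr$offset
    nK <- tabulate(arr$gene_idx, nbins = length(genes))
    m1Off <- dy$offset[dy$nuc_index == -1L]

    fp <- footprintSpec(factor)
    sampleLen <- function(m, spec = fp) {
        if (spec$dist == "norm")
            round(.clipNorm(m, spec$mean, spec$sd, spec$min, spec$max))
        else round(runif(m, spec$min, spec$max))
    }
    stallMixture <- function(gi, inside) {
        j <- sample.int(3L, length(gi), replace = TRUE,
                        prob = c(0.55, 0.30, 0.15))
        j <- pmin(j, nK[gi])
        dyOff[cbind(gi, j)] - 73 + inside +
            rnorm(length(gi), 0, ifelse(inside == 20, 12, 15))
    }

    if (factor == "nucleosome") {
        idx <- sample.int(nrow(dy), ngen, replace = TRUE,
                          prob = dy$occupancy)
        gi <- dy$gene_idx[idx]
        centers <- dy$offset[idx]
        lens <- sampleLen(ngen)
        xl <- rep(FALSE, ngen)
    } else if (factor == "total_polII") {
        gi <- sample.int(length(genes), ngen, replace = TRUE,
                         prob = wProm + wBody)
        isProm <- runif(ngen) < (wProm / (wProm + wBody))[gi]
        centers <- numeric(ngen)
        if (condition$name == "wt") {
            centers[isProm] <- rnorm(sum(isProm), 0, 20)
        } else {
            centers[isProm] <- stallMixture(gi[isProm], 20)
        }
        centers[!isProm] <- runif(sum(!isProm), 300,
                                  len[gi[!isProm]])
        lens <- sampleLen(ngen)
        xl <- runif(ngen) < config$pCrosslink
    } else if (factor == "ser2_polII") {
        gi <- sample.int(length(genes), ngen, replace = TRUE,
                         prob = wSer)
        centers <- runif(ngen, 1000, len[gi])
        lens <- sampleLen(ngen)
        xl <- runif(ngen) < config$pCrosslink
    } else if (factor == "chd1_wt") {
        gi <- sample.int(length(genes), ngen, replace = TRUE,
                         prob = act)
        u <- runif(ngen)
        centers <- ifelse(u < 0.7, runif(ngen, 0, 500),
                          500 + rexp(ngen, rate = 1 / 400))
        lens <- sampleLen(ngen)
        xl <- runif(ngen) < config$pCrosslink
    } else {   # chd1_k510r
        gi <- sample.int(length(genes), ngen, replace = TRUE,
                         prob = act)
        centers <- if (placement == "genome_average")
            rnorm(ngen, 60, 30)
        else stallMixture(gi, 50)
        lens <- sampleLen(ngen)
        xl <- runif(ngen) < config$pCrosslink
    }

    if (any(xl)) {
        # crosslinked events: mononucleosome fragment at nearest dyad
        gx <- gi[xl]; cx <- centers[xl]
        k <- pmin(pmax(round((cx - arch$plus1Dyad) /
                             arch$repeatLength) + 1L, 1L), nK[gx])
        candA <- dyOff[cbind(gx, k)]
        candM <- m1Off[gx]
        nearest <- ifelse(abs(cx - candA) <= abs(cx - candM),
                          candA, candM)
        centers[xl] <- nearest
        lens[xl] <- round(.clipNorm(sum(xl), 130, 8, 111, 147))
    }

    # oriented offset -> genomic fragment (0-based half-open)
    tss0 <- geneTSS(genes)[gi]
    plus <- (as.character(strand(genes)) == "+")[gi]
    pos0 <- round(ifelse(plus, tss0 + centers, tss0 - centers))
    s0 <- pos0 - lens %/% 2L
    e0 <- s0 + lens
    chrom <- as.character(seqnames(genes))[gi]
    sl <- seqlengths(genes)
    s0 <- pmax(s0, 0)
    e0 <- pmin(e0, sl[chrom])
    keep <- e0 > s0
    genic <- GRanges(chrom[keep], IRanges(s0[keep] + 1L, e0[keep]),
                     seqinfo = seqinfo(genes))

    if (nbg > 0) {
        ci <- sample.int(length(sl), nbg, replace = TRUE, prob = sl)
        bl <- round(runif(nbg, 30, 200))
        bs0 <- floor(runif(nbg, 0, sl[ci] - bl))
        bg <- GRanges(names(sl)[ci], IRanges(bs0 + 1L, width = bl),
                      seqinfo = seqinfo(genes))
        genic <- c(genic, bg)
    }
    FragmentSet(genic,
                list(factor = factor, condition = condition$name,
                     placement = if (factor == "chd1_k510r" ||
                                     (factor == "total_polII" &&
                                      condition$name == "k510r"))
                         placement else "default",
                     seed = seed))
}

#' Simulate a CATCH-IT nucleosome-turnover track
#'
#' Builds a dense turnover signal over each gene and 1 kb flanks. The
#' promoter-proximal level is `basal + slope * min(activity, ceiling)`
#' in the wild type and `basal` (abrogated) under `k510r`; the gene-body
#' level is `bodyBasal + coupling * elongating density` (activity x
#' escape) plus the condition's constant increment `delta`. The signal
#' ramps smoothly between the promoter-proximal region and the gene
#' body, decays to basal beyond the flanks, and carries additive
#' Gaussian noise drawn per probe-sized block (25 bp), mirroring
#' array-probe resolution.
#'
#' @param genes cohort GRanges from [sampleGeneCohort()].
#' @param condition a [conditionPreset()] or its name.
#' @param config a [simConfig()]; defaults to the cohort's.
#' @param seed noise seed; defaults to the cohort seed.
#' @return A turnover [SignalTrack-class] (values may be negative);
#'   deterministic per seed.
#' @export
simulateCatchit <- function(genes, condition, config = NULL,
                            seed = NULL) {
    if (is.character(condition)) condition <- conditionPreset(condition)
    if (is.null(config)) config <- metadata(genes)$config
    if (is.null(config)) stop("no simulation config available")
    if (is.null(seed)) seed <- config$seed
    to <- condition$turnover
    set.seed(seed)
    P <- to$probeBp
    flank <- 1000L
    act <- mcols(genes)$activity
    esc <- mcols(genes)$escape
    len <- geneLengths(genes)
    Lp <- if (to$promoterCoupled)
        to$basal + to$slope * pmin(act, to$ceiling) else
        rep(to$basal, length(genes))
    Lb <- to$bodyBasal + to$coupling * act * esc + to$delta

    nb <- ((len + 2L * flank) + P - 1L) %/% P
    gidx <- rep(seq_along(genes), nb)
    j <- unlist(lapply(nb, seq_len)) - 1L
    offL <- -flank + j * P          # oriented block left edge
    mid <- offL + P / 2
    lenG <- len[gidx]; LpG <- Lp[gidx]; LbG <- Lb[gidx]
    base <- to$basal
    v <- ifelse(mid < -350,
                base + (LpG - base) * (mid + flank) / (flank - 350),
         ifelse(mid <= 350, LpG,
         ifelse(mid < 1000, LpG + (LbG - LpG) * (mid - 350) / 650,
         ifelse(mid <= lenG, LbG,
                LbG + (base - LbG) * (mid - lenG) / flank))))
    v <- v + rnorm(length(v), 0, to$noiseSd)

    tss0 <- geneTSS(genes)[gidx]
    plus <- (as.character(strand(genes)) == "+")[gidx]
    bs0 <- ifelse(plus, tss0 + offL, tss0 - offL - P + 1L)
    chrom <- as.character(seqnames(genes))[gidx]
    sl <- seqlengths(genes)
    s0 <- pmax(bs0, 0)
    e0 <- pmin(bs0 + P, sl[chrom])
    keep <- e0 > s0
    blocks <- GRanges(chrom[keep], IRanges(s0[keep] + 1L, e0[keep]),
                      seqinfo = seqinfo(genes))
    sig <- coverage(blocks, weight = v[keep], width = sl)
    SignalTrack(as(sig, "SimpleRleList"), "raw",
                list(kind = "catchit", condition = condition$name,
                     seed = seed))
}
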