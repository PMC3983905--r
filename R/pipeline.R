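# Orchestration layer: reproducible end-to-end runs over the synthetic
# cohort, driven by a plain list / YAML run configuration. Every output
# is a TSV/BED/bedGraph with a provenance header (preset names, seed,
# package version) and is byte-identical across re-runs with the same
# configuration.

#' Build / load a run configuration
#'
#' Accepts a YAML file path or a named list and fills defaults. Fields:
#' `seed` (mandatory), `outDir`, `nGenes`, `fragmentsPerLibrary`,
#' `pCrosslink`, `bgFraction`, `classifyK`, `windowStalling` (200),
#' `windowTurnover` (600), `windowCorrelation` (500), `minGeneLength`
#' and `clearance` for the gene filter.
#'
#' @param config path to a YAML file or a named list.
#' @return Normalized configuration list with class `RunConfig`.
#' @export
runConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("no such config file: ", config)
        config <- yaml::read_yaml(config)
    }
    if (is.null(config$seed)) stop("run config requires a seed")
    defaults <- list(outDir = ".", nGenes = 2000L,
                     fragmentsPerLibrary = 2e5, pCrosslink = 0.3,
                     bgFraction = 0.05, classifyK = 150L,
                     windowStalling = 200L, windowTurnover = 600L,
                     windowCorrelation = 500L,
                     minGeneLength = 2000L, clearance = 1000L)
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    structure(config, class = "RunConfig")
}

.provHeader <- function(config, what) {
    sprintf("# ChromEscape %s | %s | seed=%d | genes=%d | frags=%g",
            as.character(utils::packageVersion("ChromEscape")), what,
            as.integer(config$seed), as.integer(config$nGenes),
            config$fragmentsPerLibrary)
}

.simConfigOf <- function(config) {
    simConfig(seed = config$seed, nGenes = config$nGenes,
              fragmentsPerLibrary = config$fragmentsPerLibrary,
              pCrosslink = config$pCrosslink,
              bgFraction = config$bgFraction)
}

# Per-library seeds derived from the run seed so libraries are
# independent draws but each is reproducible in isolation.
.libSeed <- function(config, factor, condition) {
    as.integer(config$seed) + 1000L *
        match(factor, .SIM_FACTORS) +
        100L * match(condition, c("wt", "k510r"))
}

#' Filter a gene cohort for clean anchored windows
#'
#' Drops genes shorter than `minLength` and genes whose interval,
#' extended by `clearance` bp on both sides, overlaps another gene
#' (so TSS/TES windows never mix signal from neighbours).
#'
#' @param genes gene cohort GRanges.
#' @param minLength minimum gene length in bp.
#' @param clearance required clear flank in bp.
#' @return The filtered GRanges.
#' @export
filterGenes <- function(genes, minLength = 2000L, clearance = 1000L) {
    genes <- genes[geneLengths(genes) >= minLength]
    if (length(genes) > 1) {
        ext <- suppressWarnings(resize(genes,
            width(genes) + 2L * clearance, fix = "center"))
        hits <- findOverlaps(ext, genes, ignore.strand = TRUE)
        bad <- unique(queryHits(hits)[queryHits(hits) !=
                                      subjectHits(hits)])
        if (length(bad)) genes <- genes[-bad]
    }
    genes
}

# Simulate one normalized track (internal workhorse of the run_*
# commands).
.simTrack <- function(genes, config, factor, condition,
                      sc = canonicalSizeClasses()$short,
                      mode = "midpoint",
                      placement = "genome_average") {
    lib <- simulateLibrary(factor, condition, genes,
                           seed = .libSeed(config, factor, condition),
                           placement = placement)
    libraryTrack(lib, sc, mode)
}

#' Simulate the demo cohort and write all library files
#'
#' Generates the gene cohort, one fragment library per factor/condition
#' pair, and the CATCH-IT tracks for both conditions; writes BED6 genes,
#' a ground-truth TSV (activity, escape efficiency), BED3 fragment
#' libraries and bedGraph turnover tracks into `outDir`.
#'
#' @param config a [runConfig()] (or list/path accepted by it).
#' @return Invisibly, the list of files written.
#' @export
runSimulate <- function(config) {
    config <- runConfig(config)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    genes <- sampleGeneCohort(.simConfigOf(config))
    files <- c()
    f <- file.path(config$outDir, "genes.bed")
    writeGenesBed(genes, f, .provHeader(config, "gene cohort"))
    files <- c(files, f)
    f <- file.path(config$outDir, "truth.tsv")
    writeGeneTable(genes, f, .provHeader(config, "ground truth"))
    files <- c(files, f)
    pairs <- list(c("nucleosome", "wt"), c("nucleosome", "k510r"),
                  c("total_polII", "wt"), c("total_polII", "k510r"),
                  c("ser2_polII", "wt"), c("ser2_polII", "k510r"),
                  c("chd1_wt", "wt"), c("chd1_k510r", "k510r"))
    for (p in pairs) {
        lib <- simulateLibrary(p[1], p[2], genes,
                               seed = .libSeed(config, p[1], p[2]))
        f <- file.path(config$outDir,
                       paste0(p[1], "_", p[2], ".bed"))
        writeFragmentsBed(lib, f,
            .provHeader(config, paste0("library ", p[1], "/", p[2])))
        files <- c(files, f)
    }
    for (cond in c("wt", "k510r")) {
        tr <- simulateCatchit(genes, cond,
                              seed = .libSeed(config, "nucleosome",
                                              cond) + 7L)
        f <- file.path(config$outDir,
                       paste0("catchit_", cond, ".bedGraph"))
        writeBedGraph(tr, f,
                      .provHeader(config, paste0("catchit ", cond)))
        files <- c(files, f)
    }
    invisible(files)
}

#' Anchored profiles and heatmap matrices for the synthetic cohort
#'
#' Writes TSS-anchored mononucleosome occupancy profiles (both
#' conditions), the short-fragment factor profiles, and a 10-bp-binned
#' total-PolII heatmap matrix ranked by promoter occupancy.
#'
#' @param config a [runConfig()].
#' @return Invisibly, the list of files written.
#' @export
runProfiles <- function(config) {
    config <- runConfig(config)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    genes <- sampleGeneCohort(.simConfigOf(config))
    sc <- canonicalSizeClasses()
    files <- c()
    for (cond in c("wt", "k510r")) {
        tr <- .simTrack(genes, config, "nucleosome", cond,
                        sc$mono, "span")
        am <- buildAnchoredMatrix(tr, genes, "TSS", 500L, 1000L, 1L)
        f <- file.path(config$outDir,
                       paste0("mono_profile_", cond, ".tsv"))
        writeProfile(meanProfile(am), f,
                     .provHeader(config, paste0("mono TSS ", cond)))
        files <- c(files, f)
    }
    shorts <- list(c("total_polII", "wt"), c("chd1_wt", "wt"),
                   c("chd1_k510r", "k510r"))
    for (p in shorts) {
        tr <- .simTrack(genes, config, p[1], p[2], sc$short,
                        "midpoint")
        am <- buildAnchoredMatrix(tr, genes, "TSS", 1000L, 2000L, 1L)
        f <- file.path(config$outDir,
                       paste0("short_profile_", p[1], ".tsv"))
        writeProfile(meanProfile(am), f,
                     .provHeader(config,
                                 paste0("short ", p[1], "/", p[2])))
        files <- c(files, f)
    }
    # heatmap: total PolII (all fragments), rows ranked by promoter
    # occupancy
    tr <- .simTrack(genes, config, "total_polII", "wt", sc$all,
                    "midpoint")
    occ <- windowMean(tr, genes, windowSpec("TSS", -100, 300))
    rk <- rankGenes(occ)
    am <- buildAnchoredMatrix(tr, genes, "TSS", 500L, 2000L, 10L)
    m <- as.matrix(am)[rk$gene_id, ]
    f <- file.path(config$outDir, "polII_heatmap.tsv")
    writeAnchoredMatrix(new("AnchoredMatrix", values = m,
                            anchor = "TSS", offsets = offsets(am),
                            binSize = 10L),
                        f, .provHeader(config, "polII heatmap"))
    invisible(c(files, f))
}

#' Stalling analysis of the synthetic cohort
#'
#' Computes per-gene stalling records for both conditions, traveling
#' ratios, the stalled/processive classification within the top PolII
#' quintile, and the between-condition median stalling-index ratio;
#' writes the record tables, a classification table and a summary
#' report.
#'
#' @param config a [runConfig()].
#' @return Invisibly, a list with the stalling tables and the median
#'   ratio report (also written to `outDir`).
#' @export
runStalling <- function(config) {
    config <- runConfig(config)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    genes <- sampleGeneCohort(.simConfigOf(config))
    sc <- canonicalSizeClasses()
    recs <- list()
    for (cond in c("wt", "k510r")) {
        tot <- .simTrack(genes, config, "total_polII", cond,
                         sc$short, "midpoint")
        ser2 <- .simTrack(genes, config, "ser2_polII", cond,
                          sc$short, "midpoint")
        rec <- stallingIndex(genes, tot, ser2)
        tr <- travelingRatio(genes, tot)
        rec$traveling_ratio <- unname(tr[rec$gene_id])
        writeStallingTable(rec,
            file.path(config$outDir,
                      paste0("stalling_", cond, ".tsv")),
            .provHeader(config, paste0("stalling ", cond)))
        recs[[cond]] <- rec
    }
    totAll <- .simTrack(genes, config, "total_polII", "wt", sc$all,
                        "midpoint")
    occ <- windowMean(totAll, genes, windowSpec("TSS", -100, 300))
    rk <- rankGenes(occ)
    cls <- classifyStalledProcessive(recs$wt, rk,
                                     k = config$classifyK)
    clsDf <- data.frame(
        gene_id = c(cls$stalled, cls$processive),
        class = rep(c("stalled", "processive"),
                    times = c(length(cls$stalled),
                              length(cls$processive))))
    writeStallingTable(clsDf,
        file.path(config$outDir, "stalled_processive.tsv"),
        .provHeader(config, "classification"))
    rep_ <- medianStallingRatio(recs$wt, recs$k510r)
    repDf <- data.frame(metric = c("median_ratio",
                                   "ratio_of_medians", "n"),
                        value = c(rep_$median_ratio,
                                  rep_$ratio_of_medians, rep_$n))
    writeStallingTable(repDf,
        file.path(config$outDir, "stalling_ratio_report.tsv"),
        .provHeader(config, "median stalling ratio"))
    invisible(list(records = recs, classification = cls,
                   ratio = rep_))
}

#' CATCH-IT turnover analysis of the synthetic cohort
#'
#' Region averages for the named CATCH-IT windows, the wild-type minus
#' mutant difference profile around the TSS, and turnover-versus-PolII
#' trend curves for both conditions.
#'
#' @param config a [runConfig()].
#' @return Invisibly, the list of files written.
#' @export
runTurnover <- function(config) {
    config <- runConfig(config)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    genes <- sampleGeneCohort(.simConfigOf(config))
    sc <- canonicalSizeClasses()
    wins <- catchitWindows()
    tracks <- lapply(c(wt = "wt", k510r = "k510r"), function(cond)
        simulateCatchit(genes, cond,
                        seed = .libSeed(config, "nucleosome",
                                        cond) + 7L))
    files <- c()
    for (cond in names(tracks)) {
        ra <- catchitRegionMean(tracks[[cond]], genes,
                                wins$promoter_proximal)
        f <- file.path(config$outDir,
                       paste0("catchit_promprox_", cond, ".tsv"))
        writeTrend(ra, f,
                   .provHeader(config, paste0("catchit ", cond)))
        files <- c(files, f)
    }
    profs <- lapply(tracks, function(tr)
        meanProfile(buildAnchoredMatrix(tr, genes, "TSS", 500L,
                                        500L, 1L)))
    dif <- differenceProfile(profs$wt, profs$k510r)
    f <- file.path(config$outDir, "catchit_difference_tss.tsv")
    writeProfile(dif, f, .provHeader(config, "wt - k510r difference"))
    files <- c(files, f)
    totAll <- .simTrack(genes, config, "total_polII", "wt", sc$all,
                        "midpoint")
    occ <- windowMean(totAll, genes, windowSpec("TSS", -100, 300))
    rk <- rankGenes(occ)
    for (cond in names(tracks)) {
        ra <- catchitRegionMean(tracks[[cond]], genes,
                                wins$promoter_proximal)
        tr <- turnoverVsDensity(rk, ra, config$windowTurnover)
        f <- file.path(config$outDir,
                       paste0("turnover_trend_", cond, ".tsv"))
        writeTrend(tr, f,
                   .provHeader(config, paste0("trend ", cond)))
        files <- c(files, f)
    }
    invisible(files)
}

#' Statistical comparison report for the synthetic cohort
#'
#' KS tests on per-gene mononucleosome occupancy within 5 kb downstream
#' of the TSS (wild type vs mutant) and on stalling indices, plus a
#' Welch t test on gene-body turnover averages; writes a TestResult
#' report.
#'
#' @param config a [runConfig()].
#' @return Invisibly, the named list of test results (also written to
#'   `outDir`).
#' @export
runCompare <- function(config) {
    config <- runConfig(config)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    genes <- sampleGeneCohort(.simConfigOf(config))
    sc <- canonicalSizeClasses()
    w5k <- windowSpec("TSS", 0, 5000)
    occ <- lapply(c(wt = "wt", k510r = "k510r"), function(cond)
        windowMean(.simTrack(genes, config, "nucleosome", cond,
                             sc$mono, "span"), genes, w5k))
    res <- list(mono_tss_5kb = ksTwoSample(occ$wt, occ$k510r))
    tov <- lapply(c(wt = "wt", k510r = "k510r"), function(cond)
        catchitRegionMean(
            simulateCatchit(genes, cond,
                            seed = .libSeed(config, "nucleosome",
                                            cond) + 7L),
            genes, catchitWindows()$body_tes)$value)
    res$catchit_body_tes <- tTestWelch(tov$wt, tov$k510r)
    f <- file.path(config$outDir, "compare_report.tsv")
    writeTestReport(res, f, .provHeader(config, "comparisons"))
    invisible(res)
}
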