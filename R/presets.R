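# Generative presets: the chromatin architecture, factor footprints and
# condition parameters the synthetic cohort encodes. All ground-truth
# values live here (a versioned preset layer), not inside the sampling
# code.

#' Promoter chromatin architecture preset
#'
#' The phased nucleosome architecture the generator emulates: a 147 bp
#' nucleosome footprint, a nucleosome-depleted region (NDR) containing
#' the TSS, a +1 nucleosome whose entry site (5' DNA edge) sits ~50 bp
#' downstream of the TSS (dyad = entry + 73), an upstream -1 nucleosome,
#' and a downstream array with fixed repeat length. Dyad positions are
#' jittered per gene by a Gaussian fuzziness.
#'
#' @param nucLength nucleosome footprint, bp (147).
#' @param plus1Entry +1 nucleosome entry site, bp downstream of the TSS
#'   (50); the +1 dyad is `plus1Entry + 73`.
#' @param repeatLength nucleosome repeat length, bp (190).
#' @param fuzzSd per-gene dyad jitter standard deviation, bp (15).
#' @param minus1Dyad -1 nucleosome dyad offset, bp (-170).
#' @param ndr NDR interval in bp around the TSS (must contain offset 0).
#' @return List with class `ArchitecturePreset`.
#' @export
architecturePreset <- function(nucLength = 147L, plus1Entry = 50L,
                               repeatLength = 190L, fuzzSd = 15,
                               minus1Dyad = -170L,
                               ndr = c(-96L, 50L)) {
    if (ndr[1] > 0 || ndr[2] < 0)
        stop("the NDR must contain the TSS (offset 0)")
    structure(list(nucLength = as.integer(nucLength),
                   plus1Entry = as.integer(plus1Entry),
                   plus1Dyad = as.integer(plus1Entry + 73L),
                   repeatLength = as.integer(repeatLength),
                   fuzzSd = fuzzSd,
                   minus1Dyad = as.integer(minus1Dyad),
                   ndr = as.integer(ndr)),
              class = "ArchitecturePreset")
}

#' Factor footprint specifications
#'
#' Protected-fragment length distributions per factor: PolII protects
#' ~35 bp (Gaussian, clipped), the Chd1 remodeler 20-45 bp (uniform),
#' and a nucleosome yields mononucleosome-sized fragments (~130 bp,
#' MNase end-trimmed below the full 147 bp wrap).
#'
#' @param factor one of `total_polII`, `ser2_polII`, `chd1_wt`,
#'   `chd1_k510r`, `nucleosome`.
#' @return List `dist` (`"norm"` or `"unif"`), `mean`, `sd`, `min`,
#'   `max` (bp).
#' @export
footprintSpec <- function(factor = c("total_polII", "ser2_polII",
                                     "chd1_wt", "chd1_k510r",
                                     "nucleosome")) {
    factor <- match.arg(factor)
    switch(factor,
        total_polII = ,
        ser2_polII = list(dist = "norm", mean = 35, sd = 5,
                          min = 25, max = 50),
        chd1_wt = ,
        chd1_k510r = list(dist = "unif", mean = 32.5, sd = NA,
                          min = 20, max = 45),
        nucleosome = list(dist = "norm", mean = 130, sd = 8,
                          min = 111, max = 147))
}

#' Condition presets (wild type and K510R dominant negative)
#'
#' Encodes how the mutant condition perturbs the wild-type chromatin
#' model:
#' * nucleosome occupancy multipliers (reduced at promoter-proximal
#'   nucleosomes and in the gene body; positions unchanged);
#' * a stalling contrast (promoter total-PolII gain / gene-body Ser2
#'   loss) targeting a two-fold median stalling-index increase, applied
#'   per gene with strength increasing along the processivity
#'   (escape-efficiency) rank so processive genes are most affected;
#'   `stallingGamma` allocates the contrast between promoter gain
#'   (`gamma`) and body loss (`1 - gamma`) -- rpm-normalized densities
#'   register most of the effect on the promoter side, anchored by the
#'   libraries' finite signal-to-noise;
#' * turnover parameters: in the wild type, promoter-proximal turnover
#'   is basal + slope x activity up to a ceiling; in the mutant it is
#'   abrogated to the basal level. Gene-body turnover couples to
#'   elongating-PolII density; the mutant adds a constant increment
#'   delta at all densities.
#'
#' @param name `"wt"` or `"k510r"`.
#' @return List with class `ConditionPreset`: fields `name`,
#'   `occPromoter`, `occBody`, `stallingTarget`, `stallingSpan`,
#'   `turnover` (list `basal`, `slope`, `ceiling`, `bodyBasal`,
#'   `coupling`, `delta`, `noiseSd`, `probeBp`, `promoterCoupled`).
#' @export
conditionPreset <- function(name = c("wt", "k510r")) {
    name <- match.arg(name)
    base <- list(basal = 0.2, slope = 0.5, ceiling = 2,
                 bodyBasal = 0.12, coupling = 0.12, delta = 0,
                 noiseSd = 0.1, probeBp = 25L, promoterCoupled = TRUE)
    if (name == "wt") {
        structure(list(name = "wt", occPromoter = 1, occBody = 1,
                       stallingTarget = NA_real_, stallingSpan = 4,
                       stallingGamma = 0.85,
                       turnover = base),
                  class = "ConditionPreset")
    } else {
        to <- base
        to$promoterCoupled <- FALSE   # abrogation to basal
        to$delta <- 0.3               # constant gene-body increment
        structure(list(name = "k510r", occPromoter = 0.6,
                       occBody = 0.75,
                       stallingTarget = 2, stallingSpan = 4,
                       stallingGamma = 0.85,
                       turnover = to),
                  class = "ConditionPreset")
    }
}

#' Simulation configuration
#'
#' Cohort- and library-level parameters of the synthetic data: cohort
#' size, gene-length distribution, chromosome layout, fragments per
#' library, the probability that a factor-binding event is recovered as
#' a factor-nucleosome crosslink (yielding a mononucleosome-sized
#' fragment centred on the nearest dyad instead of the factor
#' footprint), and the uniform background fraction. A seed is mandatory;
#' every generator output is a pure function of (presets, config, seed).
#'
#' @param seed integer random seed (mandatory).
#' @param nGenes cohort size.
#' @param fragmentsPerLibrary fragments per simulated library.
#' @param pCrosslink crosslink probability `p_x`.
#' @param bgFraction background fraction of a wild-type ChIP library.
#'   The background is rate-based: its event rate is fixed at the
#'   wild-type level, so condition effects that change genic event
#'   rates shift the genic/background balance of the library exactly as
#'   finite ChIP signal-to-noise does in real data -- this is what lets
#'   rpm-normalized densities register absolute condition effects at
#'   all.
#' @param bgFractionMnase background fraction of the MNase
#'   (nucleosome) libraries, which are far cleaner than ChIP.
#' @param geneLengthMeanLog,geneLengthSdLog log-normal gene-length
#'   parameters (bp).
#' @param geneLengthMin,geneLengthMax clip bounds on gene length (bp).
#' @param activitySdLog log-sd of the long-tailed per-gene PolII
#'   activity distribution (log-normal, median 1).
#' @param escapeSdLog log-sd of the per-gene promoter-escape efficiency
#'   scaling elongating-PolII rates (log-normal, median 1); this is
#'   what spreads stalling indices over orders of magnitude.
#' @param spacing gap between consecutive genes on a chromosome (bp).
#' @param nChrom number of chromosomes in the layout.
#' @param polBodyPerBp per-bp weight of the elongating component of the
#'   total-PolII library relative to its promoter component; the
#'   default puts roughly 60% of total PolII at promoters.
#' @return List with class `SimConfig`.
#' @export
simConfig <- function(seed, nGenes = 2000L,
                      fragmentsPerLibrary = 2e5,
                      pCrosslink = 0.3, bgFraction = 0.55,
                      bgFractionMnase = 0.05,
                      geneLengthMeanLog = log(9000),
                      geneLengthSdLog = 0.5,
                      geneLengthMin = 4000L, geneLengthMax = 40000L,
                      activitySdLog = 1, escapeSdLog = 1.2,
                      spacing = 6000L, nChrom = 4L,
                      polBodyPerBp = 4e-5) {
    if (missing(seed) || is.null(seed) || is.na(seed))
        stop("a seed is mandatory")
    structure(list(seed = as.integer(seed),
                   nGenes = as.integer(nGenes),
                   fragmentsPerLibrary = as.integer(fragmentsPerLibrary),
                   pCrosslink = pCrosslink, bgFraction = bgFraction,
                   bgFractionMnase = bgFractionMnase,
                   geneLengthMeanLog = geneLengthMeanLog,
                   geneLengthSdLog = geneLengthSdLog,
                   geneLengthMin = as.integer(geneLengthMin),
                   geneLengthMax = as.integer(geneLengthMax),
                   activitySdLog = activitySdLog,
                   escapeSdLog = escapeSdLog,
                   spacing = as.integer(spacing),
                   nChrom = as.integer(nChrom),
                   polBodyPerBp = polBodyPerBp),
              class = "SimConfig")
}
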