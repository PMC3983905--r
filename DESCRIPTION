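Package: ChromEscape
Title: Fragment-Size-Class Footprinting, Nucleosome Turnover and PolII
    Promoter-Escape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for MNase-digested cross-linked ChIP-seq
    (MNase X-ChIP) and CATCH-IT nucleosome-turnover data. Partitions
    paired-end fragments into footprint (35-75 bp) and mononucleosome
    (111-140 bp) size classes, reduces them to normalized per-base signal
    tracks, builds strand-corrected TSS/TES-anchored metaprofiles,
    heatmaps, rankings and quintiles, and computes per-gene transcription
    statistics: promoter and gene-body PolII densities, stalling index,
    traveling ratio, elongation fold-enrichment and stalled/processive
    classification. Includes CATCH-IT turnover region averages, difference
    curves and turnover-versus-PolII trend analysis, a statistical
    comparison layer (Kolmogorov-Smirnov, Welch t, Pearson), and a
    synthetic-data generator encoding a phased promoter nucleosome
    architecture (NDR, +1 nucleosome entry ~+50 bp) with factor-nucleosome
    crosslinking, so every analysis stage can be exercised and validated
    at desk scale against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, Epigenetics, NucleosomePositioning, Transcription,
    Coverage, Software
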