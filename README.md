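# ChromEscape

Fragment-size-class footprinting and PolII promoter-escape analysis for
MNase-digested cross-linked ChIP-seq (MNase X-ChIP) and CATCH-IT
nucleosome-turnover data.

## The scientific problem

Sonication-based ChIP localizes a chromatin factor only to within
100–300 bp. Digesting formaldehyde-cross-linked chromatin with
micrococcal nuclease instead recovers the DNA actually protected by the
factor, so paired-end sequencing yields fragments whose *size*
separates two populations:

* **short footprints (35–75 bp)** — direct protections by factors such
  as RNA polymerase II (~35 bp) or a chromatin remodeler (20–45 bp);
* **mononucleosome-sized fragments (111–140 bp)** — nucleosomal
  protections, including factor–nucleosome crosslinks.

Analysing the two classes separately turns ordinary ChIP-seq into
base-pair-resolution footprinting of promoter chromatin: where PolII
sits relative to the +1 nucleosome, where a remodeler engages its
nucleosomal substrate, and how promoter-proximal nucleosomes gate the
transition from initiation to productive elongation (promoter escape).
The package implements this analysis end to end for anyone with
aligned paired-end fragments (BED3/BEDPE), gene models (BED6/BED12)
and, optionally, a per-base turnover track (bedGraph).

## What it computes

* **Size classes and signal tracks** — inclusive length classes,
  midpoint or full-span coverage, fragments-per-million normalization
  (`selectSizeClass`, `midpointCoverage`, `spanCoverage`,
  `normalizeRPM`, `libraryTrack`).
* **Metaprofiles** — strand-corrected TSS/TES-anchored matrices, mean
  profiles, percent-of-dynamic-range scaling, rankings, quintiles and
  sliding-window trend curves (`buildAnchoredMatrix`, `meanProfile`,
  `rankGenes`, `quintileSplit`, `slidingWindowXY`).
* **Transcription statistics** — per-gene promoter and gene-body
  densities and the derived stalling index

  `SI_g = mean(total PolII, TSS −100..+300) / mean(Ser2phos PolII, +1 kb..min(+5 kb, TES))`

  plus the traveling ratio (promoter −30..+300 over +300..TES, total
  PolII), elongation fold-enrichment in 1-kb genic windows relative to
  the first 5 kb, stalled/processive classification within the top
  PolII quintile, and between-condition median stalling ratios
  (`stallingIndex`, `travelingRatio`, `elongationFoldEnrichment`,
  `classifyStalledProcessive`, `medianStallingRatio`).
* **Turnover analysis** — CATCH-IT region averages in named windows,
  condition difference profiles, turnover-versus-PolII trends
  (`catchitRegionMean`, `differenceProfile`, `turnoverVsDensity`).
* **Statistics** — two-sample Kolmogorov–Smirnov, Welch t, Pearson r
  (`ksTwoSample`, `tTestWelch`, `pearsonR`).
* **A synthetic-data generator** encoding the promoter chromatin
  architecture (147-bp nucleosomes, NDR, +1 entry ~+50 bp, 190-bp
  repeat), factor footprints, factor–nucleosome crosslinking, a
  condition contrast (`wt` vs dominant-negative remodeler `k510r`) and
  PolII-coupled turnover — with recovery estimators
  (`estimatePlus1Entry`, `estimatePeakOffset`) so the whole pipeline
  is testable against known ground truth at desk scale.

## Worked example

Simulate a wild-type cohort, build the mononucleosome occupancy
metaprofile, and recover the +1 nucleosome entry site:

```r
library(ChromEscape)

genes <- sampleGeneCohort(simConfig(seed = 1))   # 2,000 genes
lib   <- simulateLibrary("nucleosome", "wt", genes, seed = 101)
lib
#> FragmentSet with 200000 fragments
#>   length range: 30 - 200 bp; chromosomes: chr1, chr2, chr3, chr4
#>   provenance: factor=nucleosome; condition=wt; placement=default; seed=101

track   <- libraryTrack(lib, canonicalSizeClasses()$mono, "span")
profile <- meanProfile(buildAnchoredMatrix(track, genes, "TSS",
                                           500, 1000, 1))
profile
#> Profile over offsets [ -500 , 999 ] bp from 2000 genes

estimatePlus1Entry(profile)
#> [1] 49
```

The estimate, 49 bp downstream of the TSS, recovers the generator's
architectural ground truth (entry site at +50 bp) to within 1 bp: the
mononucleosome span-coverage profile peaks at the +1 dyad (+123 bp) and
the entry site lies 73 bp upstream of the dyad.

The `runSimulate` / `runProfiles` / `runStalling` / `runTurnover` /
`runCompare` functions orchestrate complete, reproducible analyses from
a list or YAML configuration and write TSV/BED/bedGraph outputs with
provenance headers; see `vignettes/footprinting-methods.Rmd` for the
model, parameters and design choices.

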