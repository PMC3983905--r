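---
title: "Fragment-size-class footprinting: models, parameters and design choices"
author: "ChromEscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-size-class footprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model behind fragment-size-class footprinting, the per-gene
transcription statistics, the turnover analysis, and — in most detail —
the synthetic-data generator whose ground truths the test suite and the
acceptance script recover. It states no empirical result that the tests
and `scripts/acceptance.R` do not themselves compute.

## 1. The measurement model

MNase digestion of cross-linked chromatin protects two fragment
populations: short factor footprints and mononucleosomal DNA. The
package keeps both in one representation — a `FragmentSet` of genomic
intervals — and separates them by inclusive length classes, by default
**short = 35–75 bp** and **mono = 111–140 bp**. Bounds are inclusive on
both ends because natural-language ranges are.

Two reductions turn fragments into per-base `SignalTrack`s:

* **midpoint coverage** for short-fragment footprint profiles — the
  midpoint `floor((start + end − 1)/2)` is the sharpest available
  localization of a sub-nucleosomal protection;
* **span coverage** for nucleosome occupancy — occupancy is the
  probability that a base is wrapped, so every covered base counts.

Normalization is fragments-per-million **of the selected library**
(factor × condition × size class), recorded in the track's provenance
tag so that comparisons are like-for-like. Missing positions are
treated as zero, not missing data, because coverage tracks are dense by
construction; only window parts beyond a chromosome end are truncated
(with a warning).

Coordinates are 0-based half-open in every file read or written (BED
convention) and 1-based closed inside R (GRanges convention). A gene's
TSS is the 0-based position of its 5′-most transcribed base, so a
minus-strand TSS is `end − 1` of the BED interval; gene length uses
exclusive-end arithmetic. All anchored analyses are
transcription-oriented: increasing offset points downstream also for
minus-strand genes.

## 2. Per-gene transcription statistics

For gene $g$ with total-PolII track $T$ and elongating
(Ser2-phosphorylated) PolII track $S$:

$$\mathrm{SI}_g=\frac{\bar T_g(-100,+300)+\varepsilon_T}
{\bar S_g(+1000,\min(+5000,L_g))+\varepsilon_S},\qquad
\mathrm{TR}_g=\frac{\bar T_g(-30,+300)+\varepsilon_T}
{\bar T_g(+300,L_g)+\varepsilon_T}$$

where $\bar X_g(a,b)$ is the per-bp window mean at transcription-
oriented offsets $[a,b)$ from the TSS and $L_g$ the gene length.
Densities are per-bp means rather than window sums: ratios of
same-width windows are identical either way, and per-bp means stay
comparable across the unequal-width windows above. The pseudocount
$\varepsilon$ defaults to **1% of the respective track's genome-wide
mean**, applied to numerator and denominator; it guards zero
denominators while leaving typical densities (orders of magnitude above
the genome mean) essentially untouched, and records with body density
below $\varepsilon$ are flagged `denominator_limited`. The gene body
for the traveling ratio is +300 bp to the gene end — only the promoter
window is canonical, so the body window is exposed as an argument.
Genes of ≤1 kb (stalling) or ≤300 bp (traveling ratio) have empty body
windows and are excluded with a warning.

Elongation fold-enrichment divides each consecutive 1-kb genic window
mean by the gene's mean over its first five windows, so a uniform track
has fold enrichment exactly 1 everywhere and each gene's first five
fold enrichments average to 1 at $\varepsilon = 0$ (both are tested).

The stalled/processive classification restricts to the top quintile of
a PolII-promoter-occupancy ranking (ties broken lexicographically by
gene id everywhere, making heatmap row order and set membership
deterministic) and takes the `k` highest / lowest stalling indices. The
canonical `k` is 500; at the 2,000-gene synthetic scale the top
quintile holds 400 genes, so package runs use `k = 150`, satisfying
`k ≤ quintile/2`.

## 3. Turnover analysis

CATCH-IT turnover is carried as a dense per-position `SignalTrack`
(unitless relative incorporation, possibly negative). The named
windows — promoter-proximal (−350, +350), promoter (−150, +150), +1
nucleosome (0, +150), body from the TSS (+1k, +3k), body to the TES
(−3k, −0.5k) — are `windowSpec` objects; TES windows are
transcription-oriented (−3000..−500 means upstream of the 3′ end along
the gene). Trend analyses rank genes (by PolII density, or by length)
and slide a window of 200–600 genes one gene per step, reporting paired
means; the step size is fixed at one gene.

## 4. The synthetic-data generator

The generator encodes the chromatin-architecture model as three preset
layers; all ground-truth values live in the presets, not in the
sampling code.

**Architecture** (`architecturePreset`): 147-bp nucleosome footprint;
NDR (−96, +50) containing the TSS; **+1 entry site +50 bp** from the
TSS, hence +1 dyad +123; −1 dyad −170; repeat length 190 bp; per-gene
dyad jitter sd 15 bp. The entry and NDR are the modeled biology; repeat
length, jitter and the −1 position are filled in at values typical of
metazoan promoter arrays.

**Footprints** (`footprintSpec`): PolII N(35, 5) clipped to [25, 50]
bp; remodeler U(20, 45) bp; mononucleosomes N(130, 8) clipped to
[111, 147] bp (MNase end-trimming below the full 147-bp wrap, which
also populates the 111–140 class regardless of how one reads the
class's upper bound).

**Placement rules**: wild-type total PolII centres N(0, 20) on the TSS;
under the dominant-negative condition it stalls ~20 bp inside the entry
sites of the +1/+2/+3 nucleosomes (mixture weights 0.55/0.30/0.15, sd
12). Wild-type remodeler footprints spread uniformly over 0..+500 bp
(70%) with an exponential tail (mean 400 bp) beyond; the mutant
remodeler has two placements, kept side by side because they describe
different gene sets: a genome-average N(+60, 30) and a per-nucleosome
"processive" placement ~50 bp inside the +1/+2/+3 entries. Ser2 PolII
is uniform over +1 kb..TES; total PolII also carries an elongating
component (uniform +300..TES) weighted so that roughly 60% of the
wild-type library is promoter-proximal.

**Cohort**: 2,000 non-overlapping genes on 4 chromosomes with 6-kb
gaps; lengths log-normal (median 9 kb, log-sd 0.5, clipped to
4–40 kb) so every gene holds the +1..+3 array and the TES window clears
the promoter region; per-gene PolII **activity** log-normal (log-sd 1),
spanning the quintile range. A second log-normal variable, the
**promoter-escape efficiency** (log-sd 1.2), scales elongating-PolII
rates per gene; without it promoter and body densities would be
proportional and stalling indices could not spread over orders of
magnitude, as they must for the stalled/processive contrast to exist.

**Library composition** is rate-based: each factor's genic event rate
competes with a uniform background whose rate is pinned at the
wild-type level (ChIP background fraction 0.55; MNase libraries 0.05).
This matters: counts-per-million normalization cancels any purely
global change in genic rates, exactly as in real ChIP-seq, and it is
the finite signal-to-noise anchor that lets rpm-normalized densities
register absolute condition effects at all. Each binding event yields
the factor footprint, or with crosslink probability `pCrosslink = 0.3`
a mononucleosome-sized fragment centred on the nearest dyad.

**Condition contrast** (`conditionPreset("k510r")`): nucleosome
occupancy multipliers 0.6 (promoter-proximal dyads, offsets ≤ 600 bp)
and 0.75 (gene body) with positions unchanged; turnover abrogated to
basal at the promoter and incremented by a constant δ = 0.3 in the
body; and a stalling contrast targeting a **two-fold median
stalling-index increase**. The contrast is applied per gene with
strength increasing along the escape-efficiency rank (span 4 between
the most stalled and most processive genes), so processive genes are
most affected, and is allocated mostly to the promoter side
(`stallingGamma = 0.85`: promoter total-PolII gain
$(s\,e_g)^{0.85}$, body Ser2 loss $(s\,e_g)^{-0.15}$). The base
strength $s$ is solved (uniroot) so that the *expected measured* median
ratio equals the target: the solver uses the exact expected per-window
short-class densities — including the background floor inside the
measured windows, the size-class retention of genic footprints versus
uniform background fragments, the promoter-window capture of each
placement rule, and the library-size renormalization — and models the
per-gene measurement noise as log-normal with variance $\sum_i
1/\lambda_i$ over the four window counts, because the pooled median of
noisy per-gene ratios sits above the designed per-gene contrast when
the noise is heteroscedastic around a sloped effect. At very small
problem sizes the achievable contrast saturates below the target; the
generator then warns and applies the strongest feasible effect.

**Turnover model** (`simulateCatchit`): promoter-proximal level
`basal + slope · min(activity, ceiling)` (basal 0.2, slope 0.5,
ceiling 2) in the wild type, `basal` under the mutant; gene-body level
`bodyBasal + coupling · activity · escape` (0.12, 0.12) plus δ; linear
ramps join the promoter plateau (−350..+350) to the body by +1 kb and
decay to basal over 1-kb flanks. Gaussian noise (sd 0.1) is drawn per
25-bp block — array-probe-scale rather than per-base, which both
mirrors the resolution of promoter-array turnover readouts and keeps
the track run-length-compressible.

**Determinism**: every output is a pure function of (presets, config,
seed). Nucleosome positions are drawn from the cohort seed, so every
library and condition sees identical dyads (only occupancies differ);
library and noise seeds are explicit arguments.

## 5. Recovery estimators and their numerical choices

`estimatePlus1Entry` smooths a base-resolution mononucleosome
span-coverage profile with a centred 31-bp moving average (partial
windows at the edges), finds the NDR trough (minimum within
−200..+100), and walks downstream to the first local maximum that (i)
rises at least 25% of the post-trough dynamic range above the trough
and (ii) dominates its entire 31-bp neighbourhood — both guards exist
because the NDR floor and the rising flank carry sampling wiggle.
Because span coverage of ~130-bp fragments around a jittered dyad is a
dome with a nearly flat top, the peak position is refined to the centre
of the contiguous region within 10% of the peak height; this is exact
for noiseless symmetric peaks and averages noise out of flat tops. The
entry site is the peak (dyad) minus 73 bp, which presumes span-coverage
reduction — the estimator declares the reduction mode it assumes.
`estimatePeakOffset` reports the smoothed argmax within a search
window, taking the centre of a maximal plateau and the leftmost of
several separate tied peaks.

## 6. Problem sizes

The validation suite runs the full pipeline at 2,000 genes and 2×10⁵
fragments per library for the recovery checks (positional tolerances
±10 bp, ratio tolerance ±15%, trend correlation threshold 0.85), and
smaller cohorts (120–600 genes) for distributional and orchestration
tests; these sizes give stable recoveries while keeping a complete test
run in the low minutes on one CPU. `scripts/acceptance.R` re-runs the
recovery measurements from scratch at the 2,000-gene scale under a
user-supplied seed.

## 7. What the generator does and does not emulate

It emulates: the two protected-fragment populations and their length
distributions; factor–nucleosome crosslinking; a phased promoter
nucleosome architecture with NDR and jittered dyads; long-tailed
activity; finite ChIP signal-to-noise; turnover coupled to PolII with
saturation; and a mutant condition perturbing occupancy, escape and
turnover. It deliberately does not emulate: sequence (no FASTA, no
mappability or GC bias), MNase sequence preference, digestion-degree
variation, replicate/batch structure, inter-gene correlation,
alternative promoters, or probe-level array artefacts beyond
block-scale noise. Passing recovery tests therefore shows the analysis
stack is correct and well-calibrated on data with this statistical
structure — not that any biological conclusion about real chromatin
follows; on real data the unmodeled biases above can shift profiles
and densities.

## 8. Known limitations

* `stallingIndex` and `elongationFoldEnrichment` loop per gene over
  per-gene body windows; at cohorts far beyond 10⁴ genes a vectorized
  Views-based batch path would be preferable.
* The KS p-value is asymptotic (appropriate for hundreds–thousands of
  genes); exact small-sample p-values are out of scope, though the
  statistic itself is exact.
* The whole-genome background is uniform; structured background
  (accessibility-correlated) would lower the achievable stalling
  contrast further.
* BED parsing is line-oriented and strict by design (errors name line
  numbers); it is not tuned for multi-gigabyte files.
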