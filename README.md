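# tetramap

Nucleosome positioning and promoter architecture for archaeal
(histone-tetramer) chromatin.

## The problem

Archaea of the Halobacteria carry true histones that assemble as tetramers
and protect only ~60 bp of DNA — half a eukaryotic nucleosome. Micrococcal
nuclease (MNase) digestion of crosslinked chromatin leaves those protected
fragments behind, and their per-base pileup is a genome-wide occupancy map:
protected regions appear as peaks, linker DNA as troughs. `tetramap`
implements the computational side of such a study for small, GC-rich,
circular genomes:

1. **Smoothing.** The raw coverage `x[i]` is smoothed with a symmetric
   convolution sum `y[i] = Σⱼ G[j]·x[i−j]` using a discrete Gaussian kernel
   with `σ = M/6`; the bandwidth `M` spans `6σ`, which holds ≈99.73% of the
   Gaussian mass. The working bandwidth is `M = 27` bp; a two-pass simple
   moving average (40 bp, then 15 bp) is available as the classical
   alternative, and `select_window()` picks the strongest smoothing whose
   Pearson correlation with the raw track stays above a threshold.
2. **Nucleosome calling.** Extrema of the smoothed signal alternate
   maxima/minima around the circular replicon; maxima are nucleosome
   midpoints (dyads). The standard recipe (`call_dyads()`) smooths
   fragment-*midpoint* coverage, where each fragment's evidence sits on the
   dyad itself. Peak-to-peak distances, stratified into genic regions
   (transcript plus 40 bp upstream) versus non-genic regions, estimate the
   nucleosome repeat length; counts per kilobase give the density.
   Occupancy is also normalized into occupied / depleted / transition
   states by segment-wise min–max rescaling.
3. **Dyad sequence composition.** Nucleotide and dinucleotide counts in
   61-bp windows centered on called dyads, the GC gradient from fragment
   edge to midpoint, position probability / information-content matrices,
   and a permutation test for ~10-bp dinucleotide periodicity.
4. **Transcript refinement.** RNA-seq coverage classifies predicted genes
   as expressed, trims/extends their boundaries to the covered region,
   merges operon neighbors across covered gaps, and detects novel
   (unannotated) transcribed units.
5. **Promoter architecture.** Occupancy anchored at the TSS/TTS of each
   expressed unit (±200 bp, strand-oriented, row-mean normalized) gives
   aggregate profiles with a nucleosome-depleted region (NDR) flanked by
   the −1/+1 nucleosomes; the 5′ NDR is compared with the 3′ NDR, and
   per-transcript profiles are clustered hierarchically (average linkage,
   1 − Pearson r distance) into subclades.

Deposited sequencing data are not required: a seeded simulator
(`simulate_chromatin()`) generates genome, fragments, coverage, annotations
and a featureless naked-DNA control **with full ground truth**, so every
stage is validated by recovery of planted signal.

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
200 kb dataset (seed 7) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_nucleosomes.R
Rscript analysis/03_dyad_sequence.R
Rscript analysis/04_transcripts.R
Rscript analysis/05_promoter_architecture.R
```

Stage 2 prints:

```
called 2636 nucleosome midpoints (min prominence 0.276)
recovery vs planted dyads: recall 1.000, precision 0.991, MAE 0.59 bp
peak-to-peak spacing: genic 68.0 bp (n=1247), non-genic 76.5 bp (n=1201)
nucleosome density: 13.2 per kb (planted 13.1 per kb)
MNase vs naked-DNA control: r = -0.003
```

The planted genic/non-genic spacings are 68.5 and 76.1 bp, so the
estimator lands within half a base pair of truth on each class; the
near-zero correlation with the naked-DNA control shows the map is not a
sequence-bias artifact. Stage 3 reports the planted GC gradient
(`GC at dyad 71.9%, at fragment edge 60.4%`) and, as expected for this
organism, **no** ~10-bp AA periodicity around the dyad (p = 0.79). Stage 4
confirms 112/150 genes expressed (74.7%), all 9 expressed operons merged,
all 5 novel units found, and 100% of unit boundaries within 20 bp. Stage 5
locates the TSS NDR at −52 bp with depth 0.97 versus a TTS NDR of depth
0.65 — the 5′ NDR is deeper and wider (Δdepth 0.315, CI 0.288–0.341;
Δwidth 52 bp, CI 37–57).

In an R session the same pipeline is three calls:

```r
library(tetramap)
b  <- simulate_chromatin(sim_config(seed = 7))
cd <- call_dyads(b$fragments, b$replicon, M = 27)
truth_compare(cd$calls, b$truth$dyads$pos, tolerance = 5)$recall
#> [1] 1
```

## Layout

```
R/                  package code (io, smoothing, calling, composition,
                    transcripts, promoter architecture, simulator)
analysis/           numbered study drivers (see above)
scripts/acceptance.R  benchmark reproduction
tests/testthat/     unit, property and end-to-end recovery tests
vignettes/          methods vignette (model, parameters, design choices)
```
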