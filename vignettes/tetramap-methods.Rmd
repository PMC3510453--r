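---
title: "tetramap: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tetramap: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
```

`tetramap` maps nucleosome positions and promoter chromatin architecture in
archaeal genomes from MNase protection data. This vignette is the package's
account of its models and of the choices made where the procedure was
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The signal model

Archaeal histone tetramers protect ~60 bp of DNA from MNase digestion.
Sequencing size-selected 50–60 bp fragments and piling them up per base
gives an occupancy track `x[i]` whose peaks are protected (nucleosomal)
DNA and whose troughs are linker. Coverage noise is well described as
Gaussian, so the track is smoothed with a symmetric convolution sum

$$y[i] = \sum_{j=-\lfloor M/2\rfloor}^{\lfloor M/2\rfloor} G[j]\, x[i-j],
\qquad G[j] \propto e^{-j^2/2\sigma^2},\quad \sigma = M/6 .$$

The bandwidth `M` is tied to $6\sigma$ because that interval carries
$2\Phi(3)-1 \approx 99.73\%$ of the Gaussian mass — truncating the kernel
at the window edge discards essentially nothing. Numerical choices:

* the kernel is **sampled at integer offsets and renormalized to sum
  exactly 1**, so smoothing preserves the track mean and a constant track
  is a fixed point (the continuous density sampled discretely sums only
  approximately to 1);
* for any `M` the window uses $\lfloor M/2\rfloor$ offsets per side
  (symmetric, odd tap count);
* **edge handling**: circular replicons (the native state of haloarchaeal
  genetic elements) wrap indices modulo the length, which loses no mass;
  linear contigs truncate the kernel and divide by the in-bounds weight
  mass, so constants remain fixed points at the ends. Both modes are
  checked against a literal double-loop evaluation of the sum to 1e-9.

A two-pass simple moving average (defaults 40 bp then 15 bp) is provided
as the classical alternative; it equals a single convolution with the
composition of the two box kernels.

### Bandwidth selection

Correlation with the raw track is maximized by not smoothing at all, so
"the bandwidth best correlated with the raw data" cannot mean the maximum.
`select_window()` therefore returns the **largest** `M` whose Pearson
correlation with the raw track still reaches `r_min` (default 0.85) — the
strongest smoothing that still tracks the signal — together with the full
`(M, r)` table for inspection. This threshold rule is this package's
declared procedure; the headline analyses use `M = 27` bp, the bandwidth
established for this data type.

## Nucleosome calling

Extrema of the smoothed track are found run-wise: plateaus collapse to
their center (left-of-center for even runs — symmetric and deterministic),
and on circular replicons the scan wraps so maxima and minima alternate
strictly all the way around. Maxima are nucleosome midpoints (dyads);
each call carries its flanking minima and a prominence
(peak − the higher flanking trough). `call_nucleosomes()` keeps every
maximum by default — peak magnitude is deliberately not a filter — with
`min_prominence` available because counting noise at low depth can create
spurious alternations; merging removes the weakest peak together with its
shallower trough, preserving alternation.

**Which coverage to call on.** Full-fragment pileup of ~55 bp fragments at
~70 bp spacing produces nearly flat-topped peaks: the argmax of a flat top
is set by whatever mass its neighbors contribute, and beside a
nucleosome-depleted region that one-sided pull displaces calls by 10–15 bp.
Fragment-**midpoint** coverage concentrates each fragment's evidence at
its center and has no flat tops, so the standard recipe
(`call_dyads()`) smooths midpoint coverage and applies a depth-relative
prominence floor (default 0.5× the track mean) to suppress counting-noise
maxima. Pileup remains the signal for occupancy states, profiles and NDR
work, where the protection footprint — not the dyad — is the object of
interest.

Spacing statistics attribute a peak-to-peak distance to a region class
(genic = expressed transcript span plus 40 bp upstream, the average
promoter length in this organism; non-genic = the complement) only when
**both** flanking midpoints lie in that class; cross-class pairs are
excluded, and the wrap-around pair is included on circular replicons.
Density is calls per kilobase. Occupancy states rescale the signal to
[0, 1] within each segment between adjacent extrema and threshold at 2/3
(occupied) and 1/3 (depleted), with everything between in transition;
the thresholds are this package's choice (no canonical values exist) and
segment-wise min–max rescaling makes the states invariant to depth
differences along the genome. Flat segments have no dynamic range and are
assigned to transition with a warning.

## Dyad sequence composition

Windows of `2·30 + 1` bp (the tetramer footprint) centered on called
midpoints are taken on the forward genome strand; windows containing `N`
are dropped and counted, and a `symmetrize` option adds reverse
complements for palindromic statistics. From the per-position counts the
package derives the GC curve, grouped weak/strong dinucleotide series
(W = AA+AT+TA+TT, S = CC+CG+GC+GG), probability matrices and information
content (uniform background: $2 + \sum_b p\log_2 p$ bits; genome
background: relative entropy, zero exactly where the position matches the
genome composition). The edge value of the GC gradient is the mean of the
two outermost window positions — robust to single-position noise.

**Periodicity test.** The per-position frequency series of a dinucleotide
is linearly detrended, **prewhitened at lag one**, and its spectral power
summed over periods 9–11 bp is compared against position permutations
(exact-rank p-value, default 999 permutations, seeded). The prewhitening
step exists because overlapping dinucleotide indicators share a base and
are therefore positively autocorrelated at lag 1 even under a fully
i.i.d. sequence model; a plain permutation null ignores this and rejects
too often in exactly this frequency band. An AR(1) filter cannot itself
create or destroy an interior-frequency oscillation (its spectrum peaks
only at frequency 0 or 1/2), so power against a genuine ~10-bp signal is
preserved. Calibration (type-I error at the nominal 5% level) and power
against a planted 10-bp periodicity are both measured by the acceptance
script.

## Transcript refinement

Predicted annotations are refined against RNA-seq per-base coverage:

* **expressed** iff mean coverage ≥ `c_min` (default 5×);
* **boundary adjustment**: per annotation, a threshold
  `t = max(3, 0.1 × median within-annotation coverage)`; each end shrinks
  inward over bases below `t`, then extends outward over bases at or above
  `t`, capped at 250 bp and stopping before the nearest same-strand
  annotation. The shrink-then-extend rule with a relative threshold is this
  package's concrete definition of "adjusting boundaries to the covered
  region";
* **merging**: same-strand neighbors merge when every base of the
  intervening gap is covered at ≥ `t` (empty gaps merge trivially);
  merging is transitive, so operons collapse to single units;
* **novel units**: maximal covered runs ≥ 100 bp overlapping no refined
  unit, reported with strand "." and excluded from strand-dependent TSS
  analyses. Thresholds for "detectably expressed" and "high coverage" have
  no canonical values; the defaults above are declared and configurable.

Manual curation of the final unit set is out of scope; the pipeline is
fully automatic and reports counts.

## Promoter architecture

Occupancy rows are taken over `anchor ± 200` bp, strand-oriented so
positive offsets point downstream, and divided by their own mean — the
row-mean normalization embodies "degree of normalized occupancy" and makes
the aggregate invariant to per-region depth scaling (z-scoring is an
option). The profile signal is the smoothed pileup track, not the raw
counts and not the ternary states. NDR detection takes the aggregate
minimum inside a search window, finds the −1/+1 peaks as the highest local
maxima within 100 bp on each side (plateau runs count once, located at
the run point nearest the minimum), and summarizes depth
`(flank − min)/flank` and width (span below half-prominence). Because a
deep NDR has a nearly flat floor, the **span center** (`center_offset`) is
reported alongside the argmin as the location estimate; on flat-floored
basins the argmin wanders by tens of bp between random realizations while
the span center is stable to a few bp. The 5′/3′ comparison bootstraps
transcripts within each anchor's matrix (percentile intervals, seeded).

Per-transcript profiles are clustered with average linkage on
`1 − Pearson r` (centered by default; uncentered available for
compatibility with classic clustering tools). The tree is cut into `k`
groups (default 6) and the `k` largest subclades are labeled `1..k` in
decreasing size with row-order tie-breaking — the concrete version of
"taking the largest k subclades" — and exports are written in leaf order
for heatmap viewers.

## The simulator and what passing tests mean

`simulate_chromatin()` generates the study conditions the pipeline is
validated under, all from one seeded stream (re-running a config is
byte-identical):

| parameter | default | meaning |
|---|---|---|
| genome | 200 kb, circular, GC 0.65 | i.i.d. base composition |
| genes | 150 of 500–1100 bp | placed without overlap, ≥200 bp gaps |
| operons | 10 of 2–4 genes | 20–60 bp internal gaps, read-through coverage |
| expressed fraction | 0.75 | exact count, whole units at a time |
| dyad spacing | genic 68.5 ± 6, non-genic 76.1 ± 8 bp | sequential walk, class of the current position |
| fragments | 50–60 bp, 30× depth | Poisson count per dyad, centers jittered ± 3 bp |
| NDR zones | 5′: 120 bp at TSS−50, 5% background; 3′: 70 bp at TTS+20, 30% background | no dyads inside; low uniform fragment rate |
| dyad GC ramp | edge 0.61 → midpoint 0.75 (recentered) | resampled bases, linear in distance from dyad |
| RNA plateaus | lognormal level (median 50×), ends ragged ±20 bp | zero outside expressed/novel units |
| profile classes | off; e.g. {4, 5, 6} | exactly c evenly spaced dyads in the TSS ± 200 window |

Notes on deliberate choices:

* The expressed fraction is realized as an exact count rather than
  per-gene coin flips, so the planted fraction is a property of every
  bundle, not a sampling outcome.
* At ~70 bp spacing the 61-bp dyad windows tile most of the genome, so
  applying the raw 0.61→0.75 GC ramp would raise global GC to ~0.67. The
  ramp is therefore **recentered on the genome composition** (applied
  probabilities `gc + ramp − mean(ramp)`, edge ≈ 0.58, dyad ≈ 0.72): the
  gradient — the quantity the composition analysis measures — is preserved
  at 0.14 while global GC stays at 0.65.
* The 5′ NDR is planted wider and deeper than the 3′ (120 vs 70 bp, 5% vs
  30% residual fragment rate) to carry the qualitative promoter asymmetry.
* Planted periodicity, when enabled, forces an AA dinucleotide at offset
  `i` with probability `amp·(1 + cos(2πi/T))/2` — `amp` is the peak
  forcing rate.
* Polyploidy is not modeled: it rescales depth uniformly and adds nothing
  testable. No sequencer error model: the simulation starts at fragments.

The simulator emulates plateau-like expression, clean operon gaps, i.i.d.
genome background and stationary fragment sampling. Real data add MNase
sequence preference, copy-number and mappability variation, overlapping
antisense transcription and non-stationary digestion — so passing recovery
tests demonstrates the **estimators are correct on their stated signal
model**, not that real libraries are this clean. The naked-DNA control
(uniform fragments at matched count) is the in-model check that the
composition statistics do not hallucinate structure.

## Problem sizes

The standard benchmark runs on a 200 kb genome (≈2600 dyads, ≈110k
fragments); the shared test fixture uses 60 kb, calibration studies use
2000 windows × 200 replicates, and determinism is checked on 50 kb
bundles. These sizes give class-wise spacing standard errors well under
1 bp and binomial noise under a percentage point on recovery rates.

## Known limitations

* Boundary dyads beside depleted regions are the hardest calls; the
  midpoint-mode recipe handles the planted geometry, but heavily
  non-stationary digestion could still displace calls.
* `peak_spacing` reports classes with fewer than two usable calls as
  missing rather than guessing.
* Novel units carry no strand, so they never enter TSS/TTS profiles
  unless the user supplies strand from other evidence.
* The clustering cut rule (smallest height giving ≥ k groups, keep the k
  largest) is one of several defensible conventions; exports carry the
  full tree so other cuts can be applied downstream.
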