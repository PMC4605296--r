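---
title: "Mapping nucleosome positions, depleted regions, and sequence preference from MNase-Seq fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping nucleosome positions, depleted regions, and sequence preference from MNase-Seq fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmap)
```

## The problem

Micrococcal nuclease (MNase) preferentially digests linker DNA, leaving
~147 bp of nucleosome-wrapped DNA protected. Paired-end sequencing of the
protected fragments therefore reads out nucleosome positions: the fragment
midpoint estimates the dyad (the nucleosome's center of symmetry), and the
genome-wide pileup of fragments is the nucleosome occupancy landscape.
Regions between well-positioned nucleosomes with no nucleosome signal —
nucleosome-depleted regions (NDRs) — are where sequence-specific factors and
the replication machinery (notably the origin recognition complex, ORC) gain
access to DNA. nucmap implements the complete analysis path from fragment
intervals to called nucleosomes, NDRs, site-centered meta-profiles, and a
sequence-based occupancy prediction, together with a synthetic library
generator that plants a known architecture so every stage can be validated
against ground truth.

## Pipeline stages and their parameters

### Single-nucleosome size selection

`filter_by_length()` keeps fragments with length in the closed interval
[`lo`, `hi`], default **127–168 bp**. The bounds are inclusive on both ends:
the window is read as a closed range of single-nucleosome lengths. Fragments
below the window reflect sub-nucleosomal or non-histone protection; above
it, partial dinucleosomes. `length_histogram()` summarizes the library and
reports the modal length (~150 bp for a mononucleosomal library).

### Occupancy tracks

`coverage_track()` builds a per-base signal in one of two modes:

* `mode = "full"` (default) — each fragment contributes to every base it
  covers. This is the occupancy signal used for browser-style tracks and
  meta-profiles: its total equals the summed fragment length.
* `mode = "dyad"` — each fragment is trimmed to its midpoint ± `dyad_window`
  (default 20 bp) before counting. Because a mononucleosomal fragment's
  midpoint estimates the dyad, this is the sharper signal for *positioning*:
  the full-span pileup of ~150 bp fragments has a plateau roughly one
  fragment wide, so its argmax localizes dyads poorly, while the
  midpoint-window pileup concentrates the same information into a ~40 bp
  bump. All positioning analyses in this package (peak calling for dyad
  recovery) use dyad mode; occupancy figures use full mode.

Coordinates are 0-based half-open throughout; BED files on disk follow the
identical BED convention.

### Fourier smoothing

`fft_smooth()` keeps the lowest `ceiling(pc_keep * n)` frequency components
of the track's discrete Fourier transform and inverts it. The zero-frequency
component is always kept, so the mean is preserved exactly; `pc_keep = 1` is
the identity. The default `pc_keep = 0.02` is the customary
component-retention fraction for nucleosome coverage smoothing. Chromosomes
longer than `chunk` (default 2^20 bp) are filtered in overlapping chunks
(2,000 bp overlap) whose inner regions are stitched; the test suite verifies
that chunk seams neither add nor move called peaks. Smoothing can ring
slightly negative at sharp coverage edges (Gibbs phenomenon); values are
deliberately *not* clamped before peak calling — clamping would bias the
percentile threshold — and `clamp_track()` is applied only at export.

### Peak calling and scoring

`call_peaks()` takes candidate summits as strict local maxima of the
smoothed track lying strictly above a threshold: the `threshold_pct`-th
percentile (default 50) of smoothed values, computed over covered positions
only (raw coverage > 0), so unmappable or empty stretches do not deflate the
threshold (`threshold_over = "all"` is available). Summits closer than
`min_sep` (default 120 bp — below one footprint, so a single nucleosome is
never double-called, yet compatible with the short ~120 bp spacings seen in
vivo) are merged keeping the higher summit, ties resolved leftmost.

Each peak scores in [0, 1] as the mean of:

* a height score `score_h = pnorm((height - m) / s)`, with `m`, `s` the
  mean and SD of smoothed values over covered positions — the summit's
  standardized height mapped through the normal CDF; and
* a positioning score `score_w = max(0, 1 - MAD / (footprint / 4))`, where
  MAD is the raw median absolute deviation of fragment midpoints within the
  footprint. Midpoints spread uniformly across a 147 bp footprint give MAD
  ≈ footprint/4 and score ~0 (a "fuzzy" nucleosome); tightly phased
  midpoints score near 1.

Peaks with combined score ≤ `min_score` (default 0.25) are discarded. The
0.25 cutoff and the 50th-percentile threshold are the conventional defaults
for this style of non-parametric calling.

### NDRs and internucleosomal distances

The internucleosomal distance is the distance between adjacent called peaks,
**center-to-center** by default: this choice is parameter-free, whereas
edge-to-edge distances (available via `method = "edge"`) inherit the assumed
footprint width. An NDR is any internucleosomal region without a called
peak: exactly one per adjacent peak pair, so per chromosome
`#NDRs = max(0, #peaks - 1)`, and the NDR size multiset equals the distance
multiset — identities the tests assert. Chromosome ends are not NDRs (no
flanking pair). The genome-wide size distribution is summarized by a
Gaussian kernel density (Silverman bandwidth) evaluated on a log-spaced grid
so the heavy right tail (origin-scale NDRs of many hundreds of bp) is
resolved; `ndrs_at()` places the NDRs of a locus of interest on that
distribution as size quantiles. No lower floor is applied to distances.

### Meta-occupancy and site scores

`load_sites()` reads scored point features (e.g. ORC ChIP sites) and keeps
those with score ≥ 7.5 (inclusive), the customary significance cutoff for
such site lists; centers are floored midpoints. `meta_occupancy()` averages
a track in a ±`half_width` window (default 1,000 bp — the window is not
dictated by any convention and is exposed) around each site, dropping and
counting sites too close to a chromosome end. Sites are unstranded; no
profile flipping is performed. Both raw and genome-mean normalization are
provided because published meta-profiles vary in their y-axis convention;
under genome-mean a constant track profiles at exactly 1.
`score_vs_ndr()` pairs every site (typically unfiltered) with the size of
the NDR whose half-open interval contains it and reports the Spearman
correlation.

## The sequence-preference model

Nucleosome formation is favored by ~10 bp periodic occurrences of flexible
A/T-containing (WW) dinucleotides, which let the helix bend anisotropically
around the octamer, and disfavored by rigid poly(dA:dT) runs. The model
scores a footprint starting at position *i* as

E(i) = −α·s_per(i) + β·f_AT5(i)

where `s_per` is the dinucleotide periodicity score — the sliding dot
product of the dinucleotide class signal d (+1 for AA/AT/TA/TT, −1 for
CC/CG/GC/GG, 0 otherwise) with a cosine of period `p` (default 10.1 bp, the
nucleosomal helical repeat), divided by L — and `f_AT5` is the fraction of
the L−4 five-mers inside the footprint that are AAAAA or TTTTT. Defaults:
L = 147, α = 1, β = 4 (the poly(dA:dT) penalty dominates, as exclusion
dominates in vivo), μ = 0.

Two numerical conventions matter:

* **Kernel anchoring.** The cosine is centered on the dyad,
  `cos(2π(j − (L−2)/2)/p)`, not on the footprint start. A start-anchored
  cosine is not palindromic in j, which would make the energy depend on
  strand — physically wrong for a double helix. The centered kernel is
  palindromic, so reverse-complementing a sequence exactly reverses its
  energy profile (a property the tests assert).
* **Ambiguity codes.** Dinucleotides touching an N contribute 0; five-mers
  containing N never count as poly(dA:dT); footprints containing any N are
  flagged in the returned track.

### Equilibrium occupancy by hard-rod recursion

Given per-start weights `w(i) = exp(μ − E(i))`, nucleosomes are
non-overlapping rods of length L (a Tonks gas). The partition function
follows the exact forward recursion `F(b) = F(b−1) + w(b−L+1)·F(b−L)` with
its backward mirror R, giving
`start_prob(i) = F(i−1)·w(i)·R(i+L) / Z`; per-base occupancy is the sum of
start probabilities covering the base. All arithmetic is in log space
(log-sum-exp): Z grows exponentially and overflows linear doubles within a
few hundred bases. The tests verify the recursion against exhaustive
enumeration of all non-overlapping configurations for every lattice up to
N = 12.

One subtlety: per-base occupancy is **not** monotone in μ. Raising the
chemical potential increases the expected particle number
(dE\[N\]/dμ = Var(N) ≥ 0, so *mean* occupancy is monotone — asserted in the
tests), but higher density favors efficient tilings that can squeeze out a
locally favorable position and lower occupancy at the bases only it covers.
Enumeration produces explicit counterexamples; claims of per-base
monotonicity found in folklore are false for inhomogeneous rods.

### Composition and poly(dA:dT) tracts

`nucleotide_composition()` reports base fractions over centered sliding
windows (default 50 bp, step 1), with ambiguous bases excluded from the
denominator. `find_polyat_tracts()` finds either maximal pure A/T runs above
a length floor (default 20 bp) or, in windowed mode, maximal intervals in
which every 20 bp subwindow is ≥ 90% A/T — tolerant of isolated
interruptions, then trimmed to the outermost A/T bases, with overlapping
expansions merged.

## Track comparison

`compare_tracks()` mean-bins two tracks (default 50 bp) and reports Pearson
and Spearman correlations over shared bins; `bin = 1` reproduces the
unbinned correlation, and both statistics are invariant to positive affine
rescaling of either track. `occupancy_vs_binding()` summarizes each
naked-DNA fragment of an in-vitro binding table by its **mean** occupancy
(so long fragments are not overweighted) and reports the Spearman
correlation — the headline statistic, since the biological claim ("binding
is the inverse of occupancy") is ordinal — with a one-sided permutation
p-value for negativity.

## The synthetic library generator

`sim_genome()` builds a chromosome alternating **array blocks** (default 10
nucleosomes at a 197 bp repeat; GC-biased sequence, default 60% GC, with
AA/TT dinucleotides planted under each dyad at the 10.1 bp helical repeat so
successive sites stay rotationally coherent) and **depleted blocks**
(lengths drawn from {300, 700} bp — a promoter-like and an origin-like
size — built from 10–30 bp A/T homopolymer runs degraded to 95% purity with
scattered G/C, emulating the extended poly(dA:dT) tracts of real origin
NDRs). `sim_fragments()` draws the library: 90% of fragments center on a
uniformly chosen dyad with Normal(0, 20 bp) jitter, 10% are uniform
background; lengths are Normal(150, 8) rounded and clipped at 50 bp.
`sim_sites()` plants ORC-like scored sites at depleted-block centers (or
uniformly), and `sim_invitro_binding()` emits a binding table over the
planted blocks with binding a noisy decreasing function
(`10·(1−f) + Normal(0, 0.3)`, clipped at 0) of each block's planted
footprint coverage `f`. Everything is deterministic given (parameters,
seed).

What the generator does **not** emulate: mappability variation, sequencing
error, PCR duplicates, MNase sequence bias, partially unwrapped or
double-variant nucleosomes, and cell-population heterogeneity beyond
Gaussian dyad jitter. Passing the recovery tests therefore demonstrates the
pipeline's correctness on clean planted structure, not its robustness to
every artifact of real libraries.

### What the validation shows

On the default conditions (1 Mb chromosome, 200,000 fragments) the full
pipeline — size filter, dyad-mode coverage, Fourier smoothing, peak calling,
NDR detection, all at default parameters — recovers >99% of planted dyads
within ±20 bp at >99% precision; the internucleosomal-distance mode lands
within a basepair of the planted 197 bp repeat, with the origin-like 700 bp
blocks populating the distribution's right tail; meta-occupancy at planted
sites dips to <10% of the flanking level; and the synthetic in-vitro binding
table anticorrelates with observed occupancy at Spearman ρ ≈ −0.77
(permutation p ≈ 0.001). The test suite reproduces all of these on scaled
problem sizes (a 150 kb chromosome with 30,000 fragments for module tests;
the 1 Mb library for the end-to-end suite), chosen to exercise hundreds of
arrays and depleted blocks while keeping the default run fast.

One designed expectation deserves a caveat. Observed occupancy and
sequence-predicted occupancy agree strongly in *level structure* (depleted
blocks rank at the bottom of both tracks almost without exception), but the
overall binned Spearman correlation plateaus near 0.45. This is a rank
geometry ceiling, not a model failure: with ~20% of bins in depleted blocks,
perfect two-group separation with uncorrelated within-group ranks caps
Spearman at 1 − (0.2³ + 0.8³) ≈ 0.48. Within-array ranks cannot correlate,
because in the crowded hard-rod regime occupancy is nearly flat across an
array — the rotational phasing information lives in `start_prob`, not in
`occ` — while observed within-array variation is dominated by sampling
noise. The tests therefore assert the concordance against this derived
ceiling and a permutation null rather than against an arbitrary constant.

## Known limitations

* Sub-nucleosomal fragment classes (<127 bp) are filtered out, not modeled.
* The sequence model's parameters are generic class defaults, not values
  trained on a nucleosome collection; predictions are qualitative
  (favored/disfavored), not calibrated probabilities of in-vivo occupancy.
* Peak calling assumes mononucleosomal, strandless fragments; it does not
  deconvolve overlapping alternative positioning in heterogeneous cell
  populations.
* bedGraph is the only track export; BED/TSV writers cover the remaining
  outputs.

## A minimal session

```{r example, eval = FALSE}
library(nucmap)

truth <- sim_genome(sim_params(seed = 1))
frags <- sim_fragments(truth) |> filter_by_length()

pos <- coverage_track(frags, "chrS", mode = "dyad")
peaks <- call_peaks(fft_smooth(pos), pos, frags)
ndrs <- call_ndrs(peaks)

occ <- coverage_track(frags, "chrS")
profile <- meta_occupancy(occ, sim_sites(truth, 150))
autoplot(profile)
```
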