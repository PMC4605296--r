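# nucmap

Nucleosome positioning, depleted-region detection, and sequence-preference
analysis from paired-end MNase-Seq fragments.

## The problem

MNase digestion of chromatin leaves nucleosome-wrapped DNA (~147 bp)
protected; paired-end sequencing of the protected fragments reads out where
nucleosomes sit. From fragment intervals, an analyst wants: the
fragment-size distribution and its mononucleosomal mode; a smoothed
occupancy landscape; called nucleosome positions with confidence scores;
nucleosome-depleted regions (NDRs) — the internucleosomal gaps where
regulatory factors and the replication machinery (e.g. the origin
recognition complex, ORC) access DNA — and their genome-wide size
distribution; average occupancy around scored binding sites; and a
sequence-based prediction of occupancy to ask how much of the observed
landscape is encoded in DNA itself. nucmap implements this pipeline
end-to-end for R users working in regulatory genomics and chromatin
biology, with a deterministic synthetic-library generator so every stage is
testable against planted ground truth.

## Methods at the core

* **Size selection**: fragments with length in the closed window
  [127, 168] bp are kept as single-nucleosome protections.
* **Occupancy**: per-base fragment coverage, full-span for occupancy graphs
  or midpoint±20 bp ("dyad mode") for positioning; low-pass smoothed by
  retaining the lowest `⌈pc_keep·n⌉` Fourier components (default 2%).
* **Peak calling**: strict local maxima above the 50th percentile of the
  smoothed signal over covered positions, merged at 120 bp minimum
  separation; scored as the mean of a height score Φ((h−m)/s) and a
  positioning score 1 − MAD(midpoints)/(L/4), keeping score > 0.25.
* **NDRs**: center-to-center intervals between adjacent called peaks; per
  chromosome #NDRs = #peaks − 1, and the size multiset equals the
  internucleosomal-distance multiset.
* **Sequence preference**: per-start energy
  E(i) = −α·s_per(i) + β·f_AT5(i), combining a dyad-centered ~10.1 bp
  cosine-weighted WW/SS dinucleotide periodicity score with the fraction of
  AAAAA/TTTTT five-mers in the footprint; equilibrium occupancy from the
  exact hard-rod (Tonks gas) partition-function recursion
  F(b) = F(b−1) + w(b−L+1)·F(b−L), w(i) = exp(μ−E(i)), computed in log
  space and verified against exhaustive enumeration.
* **Integration**: binned Pearson/Spearman track comparison, and
  occupancy-vs-in-vitro-binding anticorrelation with a permutation test.

The methods vignette (`vignettes/nucleosome-positioning.Rmd`) documents
every parameter, numerical convention, and design decision.

## Worked example

Simulate the default study conditions (1 Mb chromosome of nucleosome arrays
at a 197 bp repeat interleaved with poly(dA:dT) depleted blocks; 200,000
fragments at 30× with 20 bp dyad jitter and 10% background), then run the
full pipeline:

```r
library(nucmap)

truth <- sim_genome(sim_params(seed = 1))
truth
#> <sim_truth> chrS: 999050 bp, 4050 planted dyads, 404 depleted blocks (seed 1)

frags <- filter_by_length(sim_fragments(truth))
hist <- length_histogram(frags)
attr(hist, "modal_length")
#> [1] 150

pos <- coverage_track(frags, "chrS", mode = "dyad")
peaks <- call_peaks(fft_smooth(pos), pos, frags)
peaks
#> # A tibble: 4,069 × 8
#>    chrom center start   end height score_h score_w score
#>    <chr>  <int> <int> <int>  <dbl>   <dbl>   <dbl> <dbl>
#>  1 chrS      95    22   169   39.0   0.996   0.673 0.835
#>  2 chrS     298   225   372   33.4   0.983   0.660 0.821
#>  3 chrS     490   417   564   41.2   0.998   0.673 0.836
#>  # ... 4,066 more rows

internucleosomal_distances(peaks)
#> <ndr_size_dist> n=4068  median=198 bp  mode~197 bp

occ <- coverage_track(frags, "chrS")
profile <- meta_occupancy(occ, sim_sites(truth, 150))
profile$mean_occ[profile$offset == 0]
#> [1] 0.104

glance(occupancy_vs_binding(occ, sim_invitro_binding(truth), seed = 2))
#> # A tibble: 1 × 6
#>   spearman_rho pearson_r p_perm n_fragments n_dropped reason
#>          <dbl>     <dbl>  <dbl>       <int>     <int> <chr>
#> 1       -0.768    -0.995  0.001          40         0 <NA>
```

Reading the output: the library's modal protected-fragment length is 150 bp
(mononucleosomal); 4,069 peaks are called against 4,050 planted dyads, and
the internucleosomal-distance mode sits at the planted 197 bp repeat.
Normalized occupancy directly over ORC-like sites planted in depleted
blocks is ~0.10 (a deep dip relative to the genome mean of 1), and in-vitro
binding of the planted blocks is strongly anticorrelated with observed
occupancy (Spearman ρ = −0.77, permutation p = 0.001) — binding tracks the
sequences nucleosomes avoid.

Plotting helpers (`autoplot()` on histograms, tracks, NDR size
distributions, meta-profiles, and composition tracks) and broom-style
`tidy()`/`glance()` methods accompany each result type.

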