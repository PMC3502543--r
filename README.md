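# chromdiver

Cross-species comparison of neuronal histone-methylation landscapes, and
the evolutionary footprints underneath them.

## What this is for

H3K4me3 marks active and poised transcription start sites. Comparing
peak-level H3K4me3 ChIP-seq signal in prefrontal-cortex neurons (NeuN+
sorted nuclei) across human, chimpanzee and macaque identifies loci where
the human lineage gained or lost the mark — candidate regulatory changes
behind human-specific brain biology. `chromdiver` implements that
comparative pipeline as reusable, tested R functions for anyone analysing
a cross-species peak atlas:

- **Quantification** — raw per-peak tag counts are normalized to
  densities `d(p,s) = count / (library_size/10^6) / (peak_length/10^3)`
  (ppm per kb), with optional input-library correction and
  sample-to-sample Pearson correlation summaries.
- **Species-specific calls** — a peak is a *gain* in the target species
  when it is at least `L` = 500 bp long, its target-group mean exceeds
  `F` = 2 times the comparison mean(s) (pseudo-density ε = 0.1 ppm/kb on
  both sides), and the two-sided exact Mann–Whitney rank-sum test of
  target vs pooled comparison samples survives Benjamini–Hochberg FDR at
  α = 0.05. *Loss* calls mirror this after a presence filter in the
  comparison species. Calls can be restricted to neuron-enriched
  chromatin (NeuN+ over NeuN−) and matched with least-divergent control
  peaks.
- **Resampling nulls for interval statistics** — the observed
  pairing-within-`d` count (peaks with a neighbour < 1 or 0.5 Mb on the
  same chromosome) or annotation-overlap category counts (e.g. sperm
  DNA-hypomethylated regions in one or both species) are compared with
  subsets drawn uniformly from the peak atlas; enrichment is reported as
  observed/expected with the add-one empirical p,
  `p = (1 + #{null ≥ obs}) / (1 + n_sims)`.
- **Evolutionary footprint** — in per-peak alignments of human against
  chimpanzee, gorilla, orangutan and macaque, a human-specific sequence
  alteration (HSA) is a column (or maximal indel run) where all
  comparison taxa unanimously carry a different state than human. HSA
  rates per kb of ungapped human sequence are compared between peak
  groups (Wilcoxon plus label permutation); archaic-hominin rows
  (Neanderthal/Denisova) partition each HSA into derived vs ancestral,
  giving the fraction of changes postdating each archaic split; IUPAC
  consensus motifs (e.g. GATA-1 `WGATTAG`) are scanned on both strands
  and scored as gained or lost through alignment-column orthology.
- **Synthetic cohorts with planted truth** — generators for peak pools
  (optionally with planted close pairs), overdispersed negative-binomial
  count matrices with planted species folds, annotation tracks with
  exact per-peak category truth, and alignment blocks with planted
  per-branch alteration rates and archaic states, so every stage can be
  scored (sensitivity, false-discovery proportion, enrichment power,
  rate recovery).

Everything is tibble-in/tibble-out and pipe-friendly; fitted result
objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

A self-contained synthetic run — simulate, quantify, call, test
enrichment, count HSAs — in one call:

```r
library(chromdiver)
run <- run_pipeline(seed = 1)
run
#> chromdiver synthetic run (seed 1 )
#>   n_gain_called                    73
#>   gain_sensitivity                 0.9125
#>   gain_fdp                         0
#>   n_loss_called                    0
#>   n_neuhp                          71
#>   n_controls                       32
#>   clustering_observed              72
#>   clustering_expected              27.36
#>   clustering_fold                  2.631
#>   clustering_p                     0.000999
#>   overlap_target_only_observed     20
#>   overlap_target_only_expected     4.378
#>   overlap_target_only_fold         4.568
#>   overlap_target_only_p            0.000999
#>   n_hsas_group                     618
#>   substitution_fraction            0.9628
#>   hsa_rate_group                   18.72
#>   hsa_rate_control                 8.024
#>   hsa_wilcox_p                     1.348e-11
#>   hsa_perm_p                       0.000999
#>   archaic_fraction_neanderthal     0.2816
#>   archaic_fraction_denisova        0.2864
#>   motifs_gained                    2
#>   motifs_lost                      0
```

Reading the report: of 80 planted fold-4 gain peaks, 73 were called
(sensitivity 0.91) with no false discoveries; the called set is 2.6-fold
enriched for close pairs (72 peaks with a neighbour < 1 Mb vs 27.4
expected from atlas resampling) and 4.6-fold enriched for target-only
annotation overlap; the enriched peak group carries 18.7 HSAs/kb vs 8.0
in controls (Wilcoxon p ≈ 1e-11), with ~28% of HSAs postdating each
archaic split (planted value 0.3). Permutation p-values of 0.000999 are
the add-one floor at 1,000 resamples.

Individual stages compose the same way:

```r
spec    <- generator_spec(n_peaks = 2000, n_gain = 100, gain_fold = 4)
pool    <- gen_peak_pool(spec)
samples <- gen_samples(spec)
counts  <- gen_counts(pool$peaks, spec, samples)
density <- normalize_density(counts$counts, samples, pool$peaks)
calls   <- call_gain(density, samples, pool$peaks,
                     "human", c("chimpanzee", "macaque"))
dplyr::count(calls, label)
```

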