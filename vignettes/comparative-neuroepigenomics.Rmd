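---
title: "Methods: cross-species peak classification, resampling nulls, and evolutionary footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species peak classification, resampling nulls, and evolutionary footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdiver)
```

`chromdiver` compares peak-level histone-methylation (H3K4me3) signal in
sorted neuronal nuclei across primate species, asks where the human
lineage gained or lost the mark, and characterises the DNA-sequence
changes underneath those loci. This vignette is the package's own account
of the statistical machinery: the models, their assumptions, the knobs
that matter, and the places where the design was genuinely open.

## 1. Densities and what they assume

All classification runs on **ppm-per-kb densities**:

$$d(p,s) = \frac{\mathrm{count}(p,s)}{\mathrm{library\_size}(s)/10^6
\cdot \mathrm{length}(p)/10^3}$$

Dividing by library size makes samples with different sequencing depth
comparable; dividing by peak length makes peaks of different widths
comparable (peaks here range from 500 bp to several kb, so raw ppm would
conflate width with intensity). Both units are available from
`normalize_density()`; classification always uses ppm/kb. The implicit
assumption is that tags accrue roughly proportionally to peak width —
adequate for broad promoter-proximal H3K4me3 domains, less so for very
sharp peaks embedded in wide intervals.

Input-library correction (`input_correct()`) rescales each peak by
`mean(input) / (input(p) + pseudo)`. It is **off by default**: a
mononucleosomal input library is only available in some designs (it is
most valuable when mapping all samples onto a non-reference genome, where
locus-specific background differs), and applying a noisy input track to
every analysis would add variance without removing bias.

Sample-to-sample structure is summarised with Pearson correlations over a
peak subset (`sample_correlations()`, typically conserved promoter peaks
supplied by the user as an id subset; conservation screening itself is
out of scope). Zero-variance samples produce `NA` correlations with a
warning rather than a silent zero. Whether such correlations should be
computed on raw counts or normalized densities is not uniquely
determined; both are supported and the default is **normalized**, since
library-size differences otherwise dominate the first principal
component of similarity.

## 2. Species-specific gain and loss calls

A peak is labeled `gain` for a target species when all three filters
pass:

1. **Length** ≥ `min_length` (default 500 bp) — short intervals carry too
   few tags for stable per-sample densities.
2. **Fold** — `(target mean + ε) / (comparison mean + ε) > F` with
   `F = 2` (primary screen; 1.5 for the secondary, age-matched screen)
   and pseudo-density `ε = 0.1` ppm/kb. ε bounds folds at zero-background
   peaks; at 0.1 ppm/kb it is an order of magnitude below typical peak
   densities (baseline strengths are log-normal around 4 ppm/kb), so it
   only bites where the comparison group is essentially empty. Two fold
   conventions exist because the screen can be read either way:
   `fold_mode = "each_species"` (default) demands the fold against *each*
   comparison species' mean — the stricter conjunction, matching the
   age-matched re-analysis — while `"pooled_average"` compares against
   the mean over all pooled comparison samples, matching the primary
   screen. The each-species mode provably never labels more peaks than
   the pooled mode on the same input; both are exposed, and the
   provable containment is property-tested.
3. **Significance** — a two-sided Mann–Whitney rank-sum test of the
   target samples against the pooled comparison samples, BH-adjusted
   over all tested peaks, `q ≤ α = 0.05`. The test engine is
   `stats::wilcox.test`: exact when the smaller group has ≤ 12 samples
   and there are no ties (the 11-vs-7 design sits squarely in the exact
   regime; the smallest attainable two-sided p is `2/C(18,7) ≈ 6.3e-5`,
   comfortably below any BH threshold in play), falling back to the
   normal approximation with continuity correction under ties. Ties have
   probability zero on continuous densities; they arise only in
   degenerate fixtures.

`call_depletion()` mirrors the definition with roles reversed, after a
**presence filter**: only peaks whose pooled comparison mean is at least
`presence_floor` (default 1 ppm/kb) are candidates, standing in for
"peaks detected in the comparison species". The mirror symmetry
(relabeling target and comparison swaps gain and loss sets on a common
candidate universe) is a tested invariant.

The neuronal restriction (`filter_celltype_enriched()`) keeps calls whose
NeuN+ mean exceeds `F` times each reference cell type's mean (NeuN−, and
optionally blood), with a BH-adjusted NeuN+ vs NeuN− rank-sum test over
the call list. The threshold against lymphocyte-type references is not
separately specified anywhere authoritative, so the same `F` is applied
to every reference — one knob, not two.

Control peaks (`select_control_peaks()`) are the `k` peaks minimising the
maximum absolute log2 fold over all species pairs of group means (ε
added), optionally restricted to peaks whose length falls within a window
of some target-set member — the natural notion of "least inter-species
difference", made reproducible by a stable score-then-id sort.

## 3. Resampling nulls for interval statistics

Two observed statistics are tested against the atlas:

- `pairing_count(peaks, d)` — the number of peaks with at least one other
  subset member within `d` bp on the same chromosome. Distance is
  **midpoint-to-midpoint** by default: the anchor is unstated in the
  source analyses, and midpoints are robust to unequal peak lengths
  (edge-to-edge is a config switch, as is counting pairs instead of
  peaks — the "245 of 410 within 1 Mb" phrasing reads most naturally as
  a peak count, which is the default).
- `overlap_categories()` — membership of each peak in two annotation
  tracks (≥ 1 bp intersection, no reciprocal-fraction requirement),
  cross-classified into both / target-only / other-only / neither.

The null (`resample_null()`) draws subsets **uniformly without
replacement from the peak atlas itself**, preserving the atlas's
chromosomal and positional structure exactly — it never re-places
intervals on the genome, so it answers "is this subset unusual among
peaks like these?" rather than "among random genomic positions?". The
empirical p is the add-one estimator
`p = (1 + #{null ≥ obs})/(1 + n_sims)` (direction `less` for depletion
tests); it can never be 0, and claims below `1/(1+n_sims)` simply require
more simulations — `n_sims` is a config value, 10,000 by default.
Identical seed and inputs give identical results, and under subset
exchangeability the rejection rate at 0.05 is calibrated (mildly
conservative, because count statistics are discrete); both are tested.

## 4. Evolutionary footprints

### HSA counting

In a per-peak alignment block (human plus chimpanzee, gorilla, orangutan,
macaque), a **substitution HSA** is a column where every comparison taxon
carries one identical non-gap, non-N base that differs from the human
base. Unanimity is the strictest parsimony rule: columns where the
comparison taxa disagree are phylogenetically uninformative for
"human-specific" and are skipped rather than guessed at (a
`min_agreeing_taxa` relaxation was considered and rejected — with only
four comparison taxa, 3-of-4 agreement already admits chimpanzee-lineage
changes). Maximal runs of human-gap columns (deletion) or
all-comparison-gap columns (insertion) form **one event each**, so a
120-bp insertion is one event, not 120; events of ≥ 100 bp are labeled
`long_indel` and not classified further (repeat/Alu annotation is out of
scope).

Archaic rows never create or destroy events (a tested invariant); they
only annotate each event as `derived` (archaic equals human),
`ancestral` (archaic equals the outgroup state) or `missing` (anything
else, including N and partial gap overlap). The **post-split fraction**
for an archaic taxon is `#ancestral / #non-missing`: an HSA where the
archaic still carries the outgroup allele must postdate the split from
that lineage.

Rates are **events per kb of ungapped human sequence** — not per peak
length (blocks need not tile the peak) and not per alignment column
(columns inflate with indels). `compare_groups()` tests rate differences
twice: the Wilcoxon rank-sum (same exact/approximate policy as above) and
a label-permutation test on the absolute difference of group means with
the add-one p. The permutation default of 10,000 draws gives a p floor of
1e-4.

### Motifs

`scan_motif()` matches IUPAC consensus patterns (e.g. GATA-1 `WGATTAG`)
on both strands, reporting 0-based forward-strand starts; an `N` in the
sequence never satisfies a non-N pattern letter, while pattern `N`
matches any base. Matching is delegated to `Biostrings::matchPattern`
with a fixed subject, which implements exactly this contract (verified
against a hand-rolled sliding-window oracle). Orthology for gain/loss
calls is resolved **through alignment columns**, not genome coordinates:
a human match whose column window contains no comparison-taxon match is
`gained`; a match shared by all comparison taxa with no human match in
the window is `lost`. For 2×2 tallies of event counts between groups,
`motif_tally_test()` reports Pearson, Yates-corrected and Fisher p-values
side by side — the variants can disagree near the significance boundary
and no single convention is canonical, so none is silently chosen.

## 5. The synthetic cohort: what it does and does not emulate

The generators plant every effect the pipeline is scored on, at the
magnitudes of the study conditions:

- **Peak pool** — 2,000–5,000 disjoint peaks of 500–5,000 bp placed on a
  10 × 30 Mb layout, chromosomes drawn proportionally to length; an
  optional subset is placed as pairs with midpoint distance below a
  threshold (0.4 Mb) for clustering power tests. Disjointness is a
  deliberate simplification: it makes annotation-category truth exact by
  construction.
- **Counts** — `NB(mean = strength × fold × lib/10^6 × len/10^3,
  dispersion 0.2)` with log-normal strengths (meanlog `log 4`, sdlog
  0.75, in ppm/kb): overdispersed like real peak counts, with planted
  fold-4 effects in 100 of 2,000 peaks for the 11-vs-7 recovery
  condition. An optional log-scale sample effect with species-level
  correlation (within 0.9, across 0.5) reproduces the observed
  correlation ordering (within-species R above cross-species R); it is
  off by default so the planted-truth scoring stays exact.
- **Annotations** — category probabilities both 0.73 / target-only
  0.057 / other-only 0.005 / neither 0.208, the enriched subset at
  target-only 0.22 (the 4-fold enrichment structure); intervals are
  carved inside their assigned peaks, so realized categories equal the
  truth table exactly.
- **Alignments** — star-with-outgroup history per peak: 1-kb ancestral
  sequence, independent substitutions on each comparison branch (5/kb;
  these break unanimity and therefore cannot masquerade as
  human-specific), human-branch substitutions at 20/kb (8.36/kb for
  control-group blocks) plus short (1–10 bp) and long (100–300 bp)
  indels, archaic rows ancestral at each planted event with probability
  0.3.

What the generator does **not** emulate: realistic sequence composition
(GC, repeats), mapping artefacts, correlated placement of annotations
with sequence features, overlapping peaks, phylogenetic tree structure
beyond a star (no shared chimp-gorilla branch), and back-mutation.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-calibrated under the stated generative model — not that
the biological effect sizes in any real data set will match.

## 6. Numerical and reproducibility choices

- Coordinates are 0-based half-open (BED) everywhere internally; peak ids
  are the authoritative join keys and mismatches are hard errors.
- `ε = 0.1` ppm/kb and `presence_floor = 1` ppm/kb are the only
  stabilizers; both are config values, and fold sensitivity to ε is
  visible directly in the call tables (folds are reported per comparison
  group).
- Ties in rank tests use mid-ranks via the normal approximation;
  degenerate inputs (all-identical groups) return p = 1.
- Control-peak and call orderings break ties by peak id, so outputs are
  stable across platforms.
- One run seed is expanded into fixed per-stage child seeds
  (`seed × 131 + stage offset, mod 2^31`), so any stage can be re-run in
  isolation and full reruns are byte-identical (the packaged reference
  config and its recorded report are shipped under `inst/extdata/` and
  checked in the test suite).
- Test-suite problem sizes are the package's own: oracle equivalence on
  100-instance batches of ≤ 300 peaks / ≤ 10 kb sequences, calibration
  on 200 × 1,000-draw replicates, recovery on 50 seeds of the
  2,000-peak / 100-gain condition, power on 20 seeds at 10,000 draws,
  footprint recovery on 500 one-kb blocks. These sizes keep the whole
  suite in a few minutes while leaving every binomial margin
  interpretable.

## 7. Known limitations

- The per-peak test treats samples as exchangeable within groups; batch
  or age structure must be handled by subsetting (the age-matched screen
  is exactly such a re-run), not by covariates — there is no
  mixed-model path.
- Depletion calls depend on the presence floor; peaks absent everywhere
  are unknowable, and the floor's value shifts the candidate universe,
  not just power.
- The atlas-resampling null conditions on the atlas; it cannot detect
  biases shared by the whole atlas (e.g. promoter enrichment of all
  peaks).
- HSA unanimity undercounts in regions where a comparison genome is
  poorly aligned (gaps/N reduce informative columns); rates are per
  ungapped human kb, which does not correct for that loss of
  informative sites.
- Motif gain/loss through column orthology assumes the alignment is
  locally correct; misalignment near indels can shift windows.
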