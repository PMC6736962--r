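# eeldelim

Integrative species delimitation for electric eels (*Electrophorus*) — and,
more generally, for any taxon where mitochondrial barcodes, gene trees,
communication-signal recordings and environmental occurrences must be
weighed together under the general lineage concept.

The package re-implements, as tested and reusable R functions, the
computational chain by which three electric eel species can be told apart:

* **Barcode distances** — Kimura two-parameter (K2P) pairwise distances
  with pairwise deletion, `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`, where
  `P` and `Q` are the transition and transversion proportions, plus
  within/between-lineage divergence summaries.
* **Barcode-gap partitioning** — an automatic barcode-gap discovery
  procedure: for each prior intraspecific limit on a log grid, the ranked
  pairwise distances are scanned for the first significant gap, individuals
  are split into connected components below the gap, and the scan recurses;
  the partition stable over the widest prior range is primary.
* **Single-threshold GMYC** — the general mixed Yule–coalescent model: a
  threshold time `T` on an ultrametric tree separates diversification
  (rate `λ_y n^{p_y}`) from within-species coalescence (total rate
  `λ_c Σ_k [n_k(n_k−1)]^{p_c}` over the clusters defined by branches
  crossing `T`), with both rates profiled out, `T` chosen by maximum
  likelihood, and a likelihood-ratio test against the single-process null
  (χ², 3 df).
* **Genealogical sorting index** — normalized exclusive ancestry of a
  labeled group (`gsi = 1` exactly at monophyly) with a label-permutation
  p-value.
* **Diagnostic nucleotides** — screening for states fixed in one lineage
  and absent from all other ingroup individuals, reported on fragment
  coordinates.
* **EOD waveform classification** — conditioning of electric organ
  discharge pulses (common rate, unit RMS, noise-robust peak centering),
  duration at a 1% amplitude threshold, a full-depth periodized Symmlet-4
  discrete wavelet transform (256 orthonormal coefficients), pairwise-ANOVA
  feature selection, nearest-neighbor (single-linkage) clustering, and
  Mahalanobis `D²` between species centroids with a pooled within-species
  covariance.
* **Niche MANOVA** — Pillai's trace `V = tr(H (H + E)^{-1})` with its F
  approximation, testing multivariate environmental separation of lineages.
* **Synthetic data** — seeded generators for COI-like alignments (with
  planted diagnostic sites and calibrated K2P divergences), ultrametric
  Yule-between/coalescent-within trees, head-positive monophasic EOD
  pulses, and grouped environmental tables, so the entire pipeline runs
  without any download.

## Worked example

```r
library(eeldelim)

# a 107-individual, 569-bp COI-like alignment at the published divergences
aln  <- simulate_alignment(preset_electrophorus(), seed = 1)
keep <- !alignment_tags(aln)$is_outgroup
dm   <- distance_matrix(unclass(aln)[keep, , drop = FALSE])
dm$lineage <- attr(aln, "lineage")[keep]
group_divergences(dm)
#>   type    lineage_a  lineage_b  mean_dist percent n_pairs n_saturated
#> 1 within  electricus electricus   0         0         171           0
#> 2 within  voltai     voltai       0.00294   0.294     903           0
#> 3 within  varii      varii        0.00345   0.345     990           0
#> 4 between electricus voltai       0.0698    6.98      817           0
#> 5 between electricus varii        0.0857    8.57      855           0
#> 6 between voltai     varii        0.0751    7.51     1935           0

barcode_gap_partition(dm)
#> <eel_partition> 107 individuals in 3 clusters (threshold 0.01246, prior 0.04833)

tr  <- simulate_tree(3, c(19, 43, 45), speciation_depth = 5,
                     coalescent_depth = 0.1, seed = 1,
                     species_names = c("electricus", "voltai", "varii"))
gmyc_fit(tr)
#> <gmyc_fit> 107 tips; threshold 2.133 (root 5)
#>   logL = 770.1823, null logL = 757.8259, LRT = 24.713 (df 3), p = 1.77e-05
#>   clusters: 3

smap <- attr(tr, "species_map")
gsi_pvalue(tr, smap$tip[smap$species == "voltai"], n_perm = 10000, seed = 1)
#> <gsi_result> gsi = 1.0000, p = 0.0001 (10000 permutations)
```

The three delimitation methods agree: the within-lineage divergences
(≤ 0.35%) sit far below the between-lineage ones (7–9%), the gap
partitioner finds exactly three clusters congruent with the simulated
lineages, the GMYC threshold model beats the single-population null
decisively, and every species group is perfectly sorted (gsi = 1) with the
smallest p-value 10000 permutations can resolve.

`run_pipeline(list(seed = 1))` chains every stage (distances, gap
partition, diagnostics, GMYC, gsi, the EOD chain and the niche MANOVA) and
writes all artifacts plus a concordance report stating the consensus
lineage count — 3, with an adjusted Rand index of 1 between the
sequence-based partitions.

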