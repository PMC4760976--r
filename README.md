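# arcticpico

Community analysis of Arctic marine pico-eukaryotes (0.4–3 µm) in
relation to water masses, sea ice and photosynthetic biomass — a
reusable, fully tested R implementation of the workflow used to map
pico-eukaryote biogeography across Fram Strait, the Nansen Basin and
the Amundsen Basin during the record sea-ice-minimum summer of 2012
(RV Polarstern cruise PS80 / ARK-XXVII).

## What the package does

**ARISA fingerprinting.** Automated Ribosomal Intergenic Spacer
Analysis reads a community as a set of fluorescent fragment-length
peaks (the ITS region's length is taxon-specific). The package performs
peak QC (fragments < 50 bp are primer artifacts and are dropped),
consolidates triplicate runs (a peak must appear in ≥ 2 of 3
replicates within 1 bp), and bins fragment sizes into presence/absence
community profiles. Because the bin grid's origin is arbitrary,
candidate binning frames are generated by shifting the origin over
[0, *w*) and the frame maximizing the mean pairwise Jaccard similarity
among samples is selected.

**Community statistics, from first principles.** For profiles
*a*, *b* the Jaccard distance is *d* = 1 − |a ∩ b| / |a ∪ b|.
On the distance matrix the package provides:

- non-metric multidimensional scaling minimizing Kruskal's stress-1,
  √(Σ(d − d̂)² / Σd²), with pool-adjacent-violators monotone
  regression, Guttman updates, and best-of-restarts;
- Ward clustering via the Lance–Williams recurrence (classic
  `ward.D`, with `ward.D2` as an option);
- ANOSIM: R = (r̄_between − r̄_within)/(M/2) over averaged ranks, with
  one-sided permutation p-values using the +1 convention (minimum
  attainable p at 999 permutations is 0.001), plus exhaustive
  enumeration for small n;
- the Mantel test (lower-triangle Pearson r, joint row/column
  permutations) and plain Pearson correlation.

**454-style amplicon pipeline.** Reads are kept iff their length lies
in [300, 670] bp, they carry at most one N, and they start with the
forward primer 528F (`GCGGTAATTCCAGCTCCAA`). A two-parent (bimera)
split model screens dereplicated reads for chimeras. OTUs are built by
farthest-neighbour (complete-linkage) clustering at 97% global
alignment identity, so *every* pair of reads inside an OTU is ≥ 97%
identical; majority-rule consensus sequences are called by center-star
alignment, singleton OTUs are removed, and a per-sample OTU table is
emitted. Taxonomy is assigned by a bootstrapped k-mer nearest-reference
classifier with an 85% confidence threshold; fungal and metazoan OTUs
are excluded; OTUs above 1% of a sample's reads (strictly) form that
sample's abundant biosphere, the rest its rare biosphere.

**Oceanography and chlorophyll.** The EOS-80 surface freezing line
T_f(S) = −0.0575·S + 1.710523×10⁻³·S^1.5 − 2.154996×10⁻⁴·S² and
one-atmosphere density anomaly classify stations into Atlantic inflow
(S ≥ 34.5, T ≥ 2 °C) vs Arctic halocline (within 0.7 °C of the
freezing line); the nitrate:phosphate relationship yields
Pacific-water fractions; Welch t-tests compare regional nutrient and
chlorophyll levels; size-fractionated chlorophyll a (> 10, 3–10,
0.4–3 µm) is summed into totals and pico shares.

**Synthetic data.** Every input the pipeline consumes can be generated
with known truth: four water-mass-structured community clusters,
triplicate ARISA tables with size jitter, dropout and noise peaks,
reads with substitutions, Ns, length artifacts, chimeras and singleton
variants, and chlorophyll coupled to a Phaeocystaceae-like bloom
taxon. The package ships the PS80 station environment table
(`ps80_stations()`), which both anchors the statistics and calibrates
the generator.

## Worked example

```r
library(arcticpico)

## published environment table: regional means and nutrient inference
group_summary(ps80_stations())
#>      group  n  ice  temp  sal  no3   si   po4
#> 1 amundsen 16 57.6 -1.50 32.0 1.35 3.02 0.272
#> 2   fram_E 13 13.7  4.78 34.9 4.92 3.66 0.460
#> 3   fram_W  6 88.0 -1.56 32.1 3.53 4.08 0.590
#> 4   nansen 11 71.8 -1.43 34.0 4.38 1.83 0.391

st <- ps80_stations()
welch_t_test(st$po4[st$region == "nansen"], st$po4[st$region == "amundsen"])
#> Welch t-test: t = 2.9346, df = 10.43, p = 0.0143 (n = 10, 16)

## synthetic ARISA study with known 4-cluster truth
pool  <- make_taxon_pool(seed = 1)
stx   <- make_stations(n_per_group = 4, seed = 1)
truth <- simulate_community(stx$truth, pool, seed = 1)
peaks <- simulate_arisa(truth, pool, seed = 1)
res   <- run_arisa_pipeline(peaks, pipeline_config(seed = 1))
res$anosim
#> ANOSIM: R = 0.9501, p = 0.001 (999 permutations; groups: 4/4/4/4)
res$nmds
#> NMDS: 16 points in 2 dims, stress-1 = 0.04455 (converged, 20 restarts)
adjusted_rand_index(res$clusters, truth$cluster[names(res$clusters)])
#> [1] 1
```

The regional means reproduce the published per-region averages (ice
72% in the Nansen Basin, 14% in the Atlantic-inflow side of Fram
Strait, and so on), the Welch p-values match the published nutrient
contrasts (PO4 0.015, NO3 0.002, Si 0.007 at the printed precision),
and the synthetic four-cluster community is recovered with a strongly
significant ANOSIM and a perfect adjusted Rand index — mirroring the
water-mass-structured clustering seen in the field data.

A command-line interface (`exec/arcticpico`) wraps the same functions
as composable subcommands: `simulate`, `arisa`, `amplicon`,
`oceanenv`, `stats`, `report`.

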