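---
title: "Methods: pico-eukaryote community analysis across Arctic water masses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pico-eukaryote community analysis across Arctic water masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcticpico)
```

# The scientific problem

Pico-eukaryotes dominate Arctic phytoplankton biomass for much of the
year, and their biogeography tracks the physical structure of the upper
ocean: warm, saline Atlantic inflow water in eastern Fram Strait versus
the cold, salinity-stratified Arctic halocline whose temperatures hug
the seawater freezing line. This package implements the complete
analysis chain used to test that association: ARISA community
fingerprints compared by Jaccard distances, ordination and clustering
with permutation inference, a 454-style amplicon pipeline for
taxonomic composition, chlorophyll *a* size-fraction bookkeeping, and
the water-mass physics needed to classify stations.

Because the original cruise's raw fingerprints and reads are not
bundled, a synthetic-data generator produces all pipeline inputs with
the statistical structure the analysis assumes — and with known truth,
so every stage's correctness is decidable.

# ARISA processing

An ARISA profile is a set of fragment lengths. Three deliberate
processing steps precede any statistics:

* **QC** (`qc_peaks`): fragments shorter than `min_fragment_bp`
  (default 50 bp) are discarded as primer/primer-dimer artifacts. The
  boundary value is kept; the threshold is a minimum fragment size.
* **Triplicate consolidation** (`consolidate_replicates`): peaks are
  pooled across a sample's three replicate runs, sorted by size, and
  grouped greedily — a peak joins the current group while it is within
  `tol_bp` (default 1 bp) of the group's smallest member. Groups
  spanning fewer than `min_count` (default 2) distinct replicates are
  dropped. The replicate rule and tolerance are not dictated by the
  ARISA protocol itself; both are configurable, and the defaults are
  the package's own choice: requiring 2-of-3 suppresses the
  irreproducible noise peaks the generator injects at Poisson rate 1
  per replicate while retaining genuine peaks even under 10% dropout.
* **Binning** (`bin_fragments`): sizes map into half-open bins of
  `bin_width_bp` (default 2 bp). The bin grid's origin is arbitrary,
  so origins over [0, width) are scanned in `shift_step` (0.1 bp)
  increments and the frame maximizing the mean pairwise Jaccard
  similarity among samples is selected, ties going to the smallest
  origin. This objective is this package's formulation of
  interactive-binner-style frame selection: the frame that best aligns
  jittered estimates of the same true fragment across samples is the
  frame under which profiles are most mutually consistent. Output is
  presence/absence only; peak heights are carried but never used for
  presence calls.

# Community statistics

All of these are implemented from first principles in this package
(vegan and `hclust` serve as independent cross-checks in the test
suite, never as the implementation):

* **Jaccard distance** between presence sets,
  $d = 1 - |A \cap B|/|A \cup B|$. Samples with empty profiles are an
  error rather than a convention.
* **NMDS** minimizes Kruskal's stress-1
  $\sqrt{\sum (d_{ij}-\hat d_{ij})^2 / \sum d_{ij}^2}$, alternating a
  pool-adjacent-violators monotone regression of configuration
  distances on dissimilarity ranks (primary tie treatment: tied
  dissimilarities are pre-ordered by current configuration distance)
  with a Guttman update. An update is accepted only if stress
  decreases, so the per-run stress trace is monotone; each fit takes
  the best of 20 random starts plus one classical-scaling start.
  A simplex of $k+1$ equidistant points embeds exactly in $k$
  dimensions, so the implementation requires only $n \ge k+1$.
* **Ward clustering** by the Lance–Williams recurrence applied to the
  dissimilarities as given (the classic pre-3.1 `ward.D` behaviour;
  `ward.D2` squares within the update). Merge ties break on the
  smallest pair of original sample indices. The cluster count is a
  parameter with default 4, matching the four water-mass groups the
  study design assumes; nothing in the method selects it
  automatically.
* **ANOSIM** uses averaged ranks of all off-diagonal distances,
  $R = (\bar r_B - \bar r_W)/(M/2)$, and a one-sided (greater)
  permutation p with the observed labeling included:
  $p = (1 + \#\{R^* \ge R\})/(n_{perm}+1)$, so 0.001 is the smallest
  attainable p at 999 permutations. `exact = TRUE` enumerates all
  distinct label arrangements instead.
* **Mantel** correlates lower triangles and permutes rows and columns
  of the second matrix jointly, with the same one-sided +1 convention
  and an exact mode for $n \le 7$.

# The amplicon pipeline

* **Filters** (`filter_reads`): length in [300, 670] bp, at most one
  N, exact forward-primer prefix (528F; an N in the primer region is a
  mismatch). Rules are evaluated cheap-first (length-low, length-high,
  N-count, primer) and the rejection log attributes each read to the
  first rule that fired; the kept set is order-independent.
* **Identity** (`pairwise_identity`): Needleman–Wunsch global
  alignment with match +1, mismatch 0, linear gap −1 (configurable);
  identity is matches divided by alignment length, so gaps penalize
  identity, and N matches nothing. Among co-optimal alignments the
  score is disambiguated by maximizing matches, then minimizing
  alignment length, which makes the value deterministic and lets an
  independent dynamic program reproduce it exactly.
* **Chimera screen** (`detect_bimeras`/`flag_chimeras`): an explicitly
  simplified two-parent split model, not a reimplementation of any
  published chimera detector, and pluggable so a real one can
  substitute. For each ordered parent pair and each breakpoint (10 bp
  stride) the length-weighted identity of query-left vs parent-A-left
  and query-right vs parent-B-right is computed; a query is flagged
  iff the best split beats the best single parent by
  `min_split_gain` (0.02) and reaches 0.99. Candidate parents must be
  at least twice the query's abundance and are ranked by shared k-mer
  fraction with the query (a true bimera shares about half its k-mers
  with each parent). Two shortcuts change no decisions: a query whose
  best single parent already exceeds $1 -$ `min_split_gain` can never
  be flagged, and a query sharing under 20% of its k-mers with every
  parent cannot reach the 0.99 floor.
* **OTUs** (`cluster_otus_farthest_neighbor`): complete-linkage
  agglomeration on $1 - $ identity that merges only while the maximum
  intra-cluster distance stays within $1 - 0.97$; every emitted OTU
  therefore satisfies the farthest-neighbour guarantee, which the
  tests assert exhaustively. Identical reads are collapsed first
  (provably partition-preserving), and an optional k-mer prescreen
  scores far pairs as identity 0 without alignment — a pair at 97%
  identity shares well over half of its 8-mers, so the prescreen
  cannot affect the partition at the defaults.
* **Consensus** (`consensus_sequence`): center-star alignment to the
  longest member, symbols projected onto star columns, majority vote
  per column over non-N bases with alphabetical tie-breaks; columns
  gapped in a majority of members are dropped.
* **Taxonomy** (`assign_taxonomy`): a bootstrapped k-mer
  nearest-reference classifier stands in for phylogenetic placement
  while keeping the same thresholding semantics: the confidence at
  each rank is the fraction of 100 bootstrap rounds (each resampling
  1/8 of the query's 8-mers) agreeing with the point estimate's
  lineage at that rank, and the deepest rank at or above 85% is
  reported. Two guards make the null behave: bootstrap rounds with no
  shared k-mer abstain, and a query whose nearest reference shares
  under 10% of its k-mers is unassigned outright — without the latter,
  any random sequence would be "assigned" at the domain rank simply
  because all references agree there. The interface is pluggable, so a
  true placement tool can substitute.
* **Abundant biosphere** (`abundant_biosphere`): an OTU is abundant in
  a sample iff it exceeds 1% of that sample's reads *strictly*;
  exactly 1% is rare. The boundary is undefined in common usage
  (">1%" vs "<1%"); strict-greater is this package's documented
  choice. Classification is per sample.

# Water-mass physics

Freezing point and density use the closed-form EOS-80 formulas at
surface pressure (the density implementation reproduces the published
one-atmosphere check values to 5 decimals). Classification applies the
Atlantic rule first (S ≥ 34.5 and T ≥ 2 °C), then assigns Arctic
halocline to water within `freezing_band_degC` of the freezing line.
"Within a few tenths of a degree" is inherently vague; the default
band of 0.7 °C is configurable. Pacific-water fractions interpolate an
observation's NO3 linearly between configurable Atlantic and Pacific
NO3-vs-PO4 endmember lines at its PO4; the defaults are classic
literature-style lines (17.499·PO4 − 3.072 and 12.368·PO4 − 10.549)
supplied as representative values, not constants of the method.
The regional t-tests are Welch's (unequal variances, two-sided,
Welch–Satterthwaite df): applied to the shipped PS80 table they
reproduce the published nutrient p-values at printed precision,
whereas the pooled-variance variant does not, which settles the
"t-test" ambiguity.

A labelling caveat on the shipped table: the published table names its
warm, ice-free Fram Strait block "W of 0°" and the icy shelf block
"E of 0°", opposite to the accompanying text. The package labels the
regions physically (`fram_E` = Atlantic inflow side, `fram_W` = Polar
Water side); no numeric result depends on the naming.

# The synthetic study conditions

The generator's defaults define the study the tests and the acceptance
script analyse; they were chosen once, as follows, and are not tuned
per run:

* **Stations** (`make_stations`, default 8 per group): the
  Atlantic group draws S ~ N(34.95, 0.1), T ~ N(5, 1); the three
  halocline groups draw S ~ U(30, 34.3) with T on the freezing line
  plus |N(0, 0.15)| — so halocline stations sit within a few tenths of
  a degree of freezing by construction. Ice and nutrients are drawn
  from each region's observed mean and SD in the shipped PS80 table
  (ice: mean ± U(−15, 15) clipped to [0, 100]; nutrients truncated at
  zero). The recorded "true" Pacific fraction is derived from the
  drawn nutrients under the generating endmember lines, since
  nutrients themselves are pinned to the observed regional statistics.
* **Taxon pool** (`make_taxon_pool`, 40 taxa): taxa derive from four
  fixed seed sequences mutated at ~12% of positions, verified pairwise
  below 90% identity so the 97% OTU radius separates taxa by
  construction. ARISA fragment lengths sit on a 5 bp grid (≥ 2× the
  2 bp bin width). Four cluster pools overlap by index range, with the
  Nansen and western-Fram pools overlapping strongly (mirroring the
  observed mixing of those communities); a dominant
  Phaeocystaceae-like taxon carries most Atlantic-water mass, a
  Micromonas-like taxon peaks in the Nansen cluster, and one fungal
  plus one metazoan taxon exercise lineage exclusion.
* **Communities** (`simulate_community`): cluster dominants
  (weight ≥ 2) are always present; other pool members appear with
  probability 0.75; proportions are affinity weights × lognormal(0,
  0.5) noise, renormalized.
* **ARISA noise** (`simulate_arisa`): size jitter N(0, 0.3 bp), peak
  dropout probability 0.1·(1 − q), Poisson(1) spurious peaks per
  replicate at U(40, 1200) bp — some below 50 bp, exercising the QC
  filter. Jitter and Poisson noise are the package's own noise models;
  the fingerprinting protocol prescribes none.
* **Reads** (`simulate_reads`, 150 per sample): per-base substitution
  2×10⁻³ and N conversion 5×10⁻⁴ (typical pyrosequencing-era
  magnitudes), 4% of reads truncated below 300 bp or padded above
  670 bp, 5% chimeras, 2 singleton variants per sample ~8% diverged
  from every pool sequence. Chimeras splice two closely related
  (same seed family) co-amplified templates at a homologous
  coordinate, with the pair sampled proportionally to the product of
  the two template abundances above a floor — reflecting PCR
  re-priming kinetics, under which splices of unrelated templates at
  arbitrary coordinates are vanishingly rare. This matters for
  interpretation: the split-model screen is *designed* for
  related-parent bimeras (its 0.99 split-identity floor is
  unreachable when the parents are ~75% diverged and spliced
  non-homologously), so the generator models the phenomenon the
  screen targets.
* **Chlorophyll** (`simulate_chl`): total Chl *a* is lognormal
  (σ_log = 0.25) with the Atlantic group's median five-fold the
  halocline groups'; within each group the log-residual is coupled at
  r = 0.8 to the bloom taxon's standardized proportion. The pico share
  is U(0.60, 0.90) except at designated runoff stations
  (U(0.10, 0.35)), where larger cells dominate. The coupling is
  defined within groups; the marginal correlation across all stations
  additionally reflects the group contrast, which is why the
  sampling-distribution check evaluates the correlation within the
  Atlantic group.

## What the synthetic data does and does not show

The generator reproduces the *structure* the methods assume —
water-mass-partitioned communities with overlapping pools, noisy
triplicate fingerprints, realistic read artifacts with known truth —
so passing tests demonstrate that each algorithm does what it claims
on data of that structure (cluster recovery with adjusted Rand
≥ 0.9, ANOSIM R ≥ 0.7 at p = 0.001, chimera sensitivity ≥ 0.8 at
false-positive rate ≤ 0.05, exact farthest-neighbour partitions).
They do not certify performance on real electropherograms or real 454
data: homopolymer-specific errors, flowgram noise, fluorescence
saturation, chimera diversity beyond the two-parent model, and real
phylogenetic sequence evolution are all outside the generator's scope.
The published community statistics that depend on the undeposited raw
matrices (ANOSIM R = 0.72, Mantel r = 0.49 / R = 0.7179, the
chlorophyll p-values) are therefore targets of *qualitative*
reproduction on synthetic data, while everything computable from the
printed station table (regional means, nutrient Welch tests,
freezing-line values) is reproduced exactly at printed precision.

# Numerical choices and degenerate inputs

* Permutation p-values include the observed statistic (+1 convention);
  identical profiles across all samples give similarity 1 in every
  binning frame and the smallest origin wins ties.
* Zero-variance inputs error rather than return NaN: Pearson and
  Mantel on constant triangles, Welch on two constant groups,
  pico share of a zero total, Jaccard of an empty profile.
* Alignment tie-breaks (diagonal > up > left; maximize matches, then
  diagonal steps) are part of the identity definition, making results
  independent of implementation details.
* OTU ids are assigned by decreasing abundance with lexicographic
  read-id tie-breaks, so shuffling input reads cannot change output.
* The test problem sizes (8 stations per group for the ARISA study,
  8 sequenced samples × 150 reads for the amplicon study, 20-read
  instances for the clustering oracle, 1000 null simulations for
  type-I calibration) are the package's chosen desk-scale study
  conditions; they keep every property decidable while the full suite
  runs in about a minute.

# Known limitations

* The binner's frame-selection objective is a documented stand-in for
  interactive binning; other objectives (total peak mass in bins,
  within-sample consistency) are plausible and would select slightly
  different frames.
* The chimera screen is a two-parent split model with fixed stride; it
  does not score three-parent chimeras and is conservative near read
  ends.
* The k-mer classifier's confidence is not a phylogenetic likelihood;
  it shares only the thresholding semantics (85%, deepest confident
  rank) with placement-based annotation.
* EOS-80 (not TEOS-10) is used throughout, at surface pressure only.
* Pacific-fraction endmember lines are configuration, and the derived
  fractions are only as good as the lines supplied.
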