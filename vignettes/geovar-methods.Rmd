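---
title: "Methods: matrix correlation biogeography and threshold species delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matrix correlation biogeography and threshold species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geovar)
```

## The question and the data

Thermoacidophilic methanotrophic Verrucomicrobia live in acidic
geothermal springs — effectively isolated "islands" separated by
tens to thousands of kilometres of uninhabitable terrain. If dispersal
between springs is rare, genetic divergence between isolates should
increase with the geographic separation of their home springs
(isolation by distance), and isolates from the same tectonic region
should resemble each other more than isolates from different regions.

`geovar` implements that comparative analysis as a reusable pipeline.
Its inputs are deliberately modest, matching what such studies publish:

* a **site table** (strain label, sampling coordinates in
  degree/decimal-minute notation, tectonic-plate label, optional
  temperature and pH),
* **pairwise genomic similarity matrices** (in silico DNA–DNA
  hybridization (DDH) %, 16S rRNA identity %, ANI %), printed
  lower-triangular, and/or **marker sequences** in FASTA from which the
  package computes identity matrices itself.

The package ships the published six-site sampling table and the
nine-strain DDH/16S matrices as machine-readable fixtures
(`packaged_fixtures()`); three reference strains (SolV, V4, Kam1)
appear in the matrices but have no published coordinates, which the
pipeline treats as an explicit, warned-about restriction rather than a
silent drop.

## Geographic distances

Coordinates are parsed from `<N|S>deg°min′<E|W>deg°min′` strings
(decimal degrees = degrees + minutes/60, negated for S/W) and distances
computed as haversine great circles on a sphere of radius
R = 6371.0088 km (the IUGG mean radius). The original analysis measured
distances with an online map tool; a closed-form sphere is used here
because it is reproducible, and it differs from ellipsoidal geodesics
by under 0.5% — immaterial for matrices whose entries span two orders
of magnitude. The haversine argument is clamped into [0, 1] so
antipodal and coincident points are exact. The unit tests verify the
implementation against an independent spherical-law-of-cosines oracle
to below 0.1 km over random point pairs.

## The Mantel statistic

Genetic similarity S (%) is first converted to distance D = 100 − S, so
one sign convention holds end to end. For two distance matrices with a
common label set the test statistic is

$$ r_M = \frac{1}{d-1} \sum_{i<j} \mathrm{stand}(D^{gen})_{ij}\,
   \mathrm{stand}(D^{geo})_{ij}, \qquad d = \frac{n(n-1)}{2}, $$

where `stand()` z-scores the d upper-triangle entries with their sample
(d − 1) standard deviation. With that normalization $r_M$ is exactly
the Pearson correlation of the two vectorized upper triangles, which is
what the unit tests assert against a textbook oracle (and against
`vegan::mantel`'s statistic).

Significance comes from the permutation null: rows and columns of one
matrix are relabeled jointly, and

$$ p = \frac{\#\{r^{perm} \ge r^{obs}\} + 1}{B + 1} $$

for the one-sided "greater" alternative (isolation by distance predicts
positive correlation; "less" and a doubled-tail "two-sided" option are
available). The add-one convention counts the observed labeling as one
permutation, so p is never 0. For n ≤ 7 and a requested B ≥ n! the
package enumerates all n! relabelings instead and reports an exact p
(flagged `exhaustive`). Matrices with zero upper-triangle variance
(e.g. a simulated dataset with rate 0) make the statistic undefined;
the package raises a `degenerate` error and the pipeline records it
instead of silently producing a number.

## Sympatry and the Spearman rank test

Tectonic-plate sympatry is a binary matrix: 1 when two isolates were
sampled on the same plate, 0 otherwise. Plate labels are always
user-supplied — two of the nine published sites sit on plate
boundaries, and the package refuses to guess; the shipped fixture
assigns Ice to the Eurasian plate and Phi to a Philippine-boundary
label, following the study's own discussion.

The statistic is the Spearman rank correlation between the d
upper-triangle genetic similarities and the d sympatry indicators:
both vectors are ranked (average ranks on ties — the sympatry vector is
almost all ties) and $r_s$ is the Pearson correlation of the rank
vectors, i.e. the covariance of the rank variables over the product of
their standard deviations. Positive $r_s$ means same-plate pairs are
genetically more similar. The permutation p-value relabels the sympatry
matrix exactly as in the Mantel test.

## Species and geovar delimitation

Delimitation follows the field's threshold conventions, all inclusive
(≥):

| threshold | default | meaning |
|---|---|---|
| `ddh_species` | 70% | DDH at or above → same species |
| `s16_species` | 98.7% | modern 16S identity species cutoff |
| `s16_classic` | 97% | classic 16S species threshold |

`cluster_at_threshold()` partitions isolates at a similarity cutoff.
The default single linkage takes connected components of the graph with
an edge wherever similarity ≥ threshold — the conventional reading of
"these strains share ≥ 70%". Complete linkage (merges allowed only when
*every* cross pair passes, best-supported merge first, lexicographic
tie-break) is available for sensitivity analysis; on the shipped DDH
matrix both give the same five groups at 70%, and the six newly
described isolates split into three species-level groups. Partitions
are deterministic: members sorted within groups, groups sorted by first
member, invariant to input label order.

`classify_relationship()` encodes the pairwise decision table. DDH is
authoritative when present: ≥ 70% is `same_species` (or
`same_geovar_candidate` when the caller marks the pair as originating
from separated sites), below 70% is `distinct_species`, with an
`ambiguous_16s` flag when the 16S identity nevertheless meets the
98.7% cutoff — the situation of the Yellowstone isolate, whose 16S
identity to the European clade is 99.5% while its DDH values sit at
55–61%. When DDH is unavailable the 16S value decides alone, with an
`ambiguous` label between the 97% and 98.7% thresholds. One documented
quirk of the published tables: the text states the Philippine and New
Zealand strains share "less than 21.6%" homology with the others,
while the printed matrix contains cells exactly equal to 21.6; the
package reports the table value.

## The synthetic generator

The simulator exists so that every stage — parsing, distances,
identity, Mantel, delimitation — can be exercised on data with known
ground truth, including parameter recovery.

* **Sites.** `uniform_sphere` draws area-uniform points
  (lon ~ U(−180, 180], lat = asin U(−1, 1)); each site then counts as
  its own "plate", the fully allopatric regime. `clustered` draws k
  centers and scatters sites around them with Gaussian spread (default
  1°), mimicking regional groups of springs; plates follow cluster
  membership. Default 9 sites, matching the scale of the motivating
  study.
* **Colonization.** A random root site; remaining sites join in random
  order, each attaching to the nearest already-colonized site
  (stepping-stone colonization). Ties attach to the lexicographically
  smaller name. A spanning tree guarantees the pairwise identities are
  realizable by an actual sequence history, which pairwise-independent
  noise would not.
* **Sequences.** The root gets a uniform ACGT sequence of `seq_length`
  bases (default 10 kb). Along an edge of length g km every position
  substitutes independently with the Jukes–Cantor probability
  p(g) = (3/4)(1 − exp(−(4/3)·μ·g/1000)); μ is expressed per 1000 km
  because site separations are of order 10³–10⁴ km. The default
  μ = 0.005 substitutions/site/1000 km puts typical pairs in the
  informative 1–30% divergence range without saturating
  transcontinental pairs.
* **Reproducibility.** One root seed; each stage derives its own child
  seed deterministically, so outputs are bit-identical across runs.

`recover_mu()` inverts the generator: per-pair JC69-corrected
divergence (−(3/4)ln(1 − 4p/3)) is regressed through the origin on
tree-path distance, and the slope (rescaled to per-1000-km) estimates
μ. Saturated pairs (p ≥ 0.75) are excluded with a warning. At the
reference design used in the validation suite (10 sites, 20 kb, fixed
seed) the estimate lands within a few percent of truth; the acceptance
harness allows 20%, the replicate spread observed across seeds. A
companion power check (12 sites, 10 kb, 100 seeded replicates, 199
permutations each) requires the Mantel test to reject at p ≤ 0.05 in at
least 90% of replicates.

**What the simulator does not model:** coalescent population structure,
migration after colonization, recombination, selection, rate variation
among sites or lineages, and indels (sequences stay positionally
homologous, which is why `p_distance_matrix()` may compare positions
directly). Passing tests on synthetic data therefore demonstrate the
statistical machinery, not the realism of any biological inference on
real data.

## Alignment-based identity

When genetic input arrives as FASTA, identity matrices come from global
(Needleman–Wunsch/Gotoh) alignment with affine gaps, implemented in
C++. Defaults: match +1, mismatch −1, gap open −2, gap extend −0.5
(a run of L gap columns costs open + (L − 1)·extend), free end gaps.
The original study does not state how its identities were computed, so
these conventional rRNA-scale defaults are explicit and configurable.
Identity is 100 · matches / aligned columns, where terminal overhang
columns are excluded under free end gaps ("identity over the aligned
region", as in the 16S threshold literature) and `N` never counts as a
match. Co-optimal alignments are resolved deterministically (diagonal
over up over left at every tie), and the pair is always aligned in a
canonical orientation so identity is exactly symmetric in its
arguments. The dynamic program is validated against an exhaustive
enumeration of all alignments on short sequences (1000 seeded pairs up
to length 8 in the validation suite). Memory is quadratic in sequence
length, which is fine for markers up to a few kb; genome-scale
similarity should enter as precomputed matrices instead.

## Numerical and interface choices

* Symmetry/diagonal tolerance for matrices read from files: 1e-9
  absolute — inputs are hand-entered percentages, so anything larger is
  a real inconsistency, not noise.
* `write_matrix()` emits the short decimal form of each cell whenever
  that form re-parses to the identical double, otherwise 17 significant
  digits; read–write round-trips are lossless for any valid matrix.
* Label sets must match exactly between correlated matrices; the
  mismatch error names the offending labels, and subsetting is an
  explicit caller action (`subset_matrix()`). This keeps the
  coordinate-less reference strains visible in every report.
* Permutation p-values use the add-one (B + 1) convention; seeds are
  mandatory whenever Monte-Carlo permutations run, and the pipeline
  refuses to start without one.
* Thresholds compare inclusively (≥), matching the usual statement of
  the 70% DDH rule.

## Validation problem sizes

The test suite validates against: the full published tables (9 strains,
6 coordinate-bearing sites); exhaustive permutation enumeration up to
n = 6 (720 relabelings); 500 seeded null replicates for p-value
calibration at n = 6, B = 99; 1000 random point pairs for the geodesic
oracle; 1000 short sequence pairs for the alignment oracle; and the
simulator designs quoted above. These sizes were chosen so the whole
suite exercises every guarantee in well under half an hour on a single
CPU while keeping Monte-Carlo margins (3 binomial standard errors)
meaningful.

## Known limitations

* The published correlation values for this system (r_M = 0.885,
  r_s = 0.532) were computed on a marker identity matrix shown only as
  a heat-map figure, with three of the nine sampling coordinates
  unpublished; they cannot be recomputed from the printed tables. The
  package therefore validates the statistics property-wise (oracle
  equality, exact enumeration, null calibration) and directionally on
  the printed data: genetic distance vs geographic distance over the
  six coordinate-bearing isolates gives a positive r_M with exact
  p ≤ 0.05.
* Distances are spherical, not ellipsoidal; plate labels are taken on
  faith; the aligner is for markers, not genomes; the simulator is a
  test harness, not a biogeography model of record.
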