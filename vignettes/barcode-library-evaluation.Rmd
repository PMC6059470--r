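---
title: "Evaluating DNA barcode reference libraries with barcodeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode reference libraries with barcodeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

# Scope and model

A DNA barcode reference library is a curated set of short, standardized
marker sequences (here the nuclear ribosomal ITS2, the spacer between the
5.8S and 28S rRNA genes, a standard marker for plants and medicinal herbs)
with expert-verified species labels. Before such a library can be trusted
for identification, three questions must be answered:

1. **Divergence structure.** Are conspecific sequences much closer to each
   other than to other species? This is quantified by Kimura 2-parameter
   (K2P) distances summarized within species, within genera and within
   families, and per species by the *barcoding gap*: the maximum
   intraspecific distance against the minimum distance to the nearest
   neighboring species. A species whose intraspecific variation exceeds
   its distance to the nearest neighbor cannot be identified reliably by
   that marker.
2. **Tree-based discrimination.** Do the specimens of each species form an
   exclusive cluster (monophyly) on a neighbor-joining tree built from the
   K2P matrix?
3. **Similarity-based identification.** When each sequence is queried
   against the library with itself removed, do its best matches come from
   the right species?

`barcodeval` implements this full evaluation workflow together with a
sequence simulator that produces libraries with known taxonomy and
controlled divergence, so every downstream stage can be validated against
ground truth. The `analysis/` scripts in the source repository run the
stages in order on the simulated study library.

# The simulator

## Taxonomy and tree shape

`library_config()` fixes a hierarchy of families ⊃ genera ⊃ species ⊃
specimens. Counts may be ranges (`specimens_per_species = c(1, 3)` creates
singleton species, which all downstream denominators must handle). The
generating tree is star-like within each rank: every child diverges
independently from its rank ancestor. This is the simplest shape that
gives exact control over expected pairwise distances; it deliberately
ignores coalescent substructure within species and unbalanced radiation
within genera.

## Branch lengths

Divergence scales are *pairwise* expectations: `d_intra` is the expected
K2P distance between two conspecific specimens, `d_species` between
congeneric species, `d_genus` between confamilial genera, and `d_family`
across families. Because two lineages each contribute half of a pairwise
path, the branch from a rank ancestor to its child is the *increment*
`(d_rank − d_subrank) / 2`; the factor 2 converts per-lineage branch
length into pairwise expectation. With the defaults
(0.006 / 0.12 / 0.37 / 0.50 substitutions per site) the realized rank
means mirror the scales typically reported for plant ITS2 libraries
(about 0.6%, 12% and 37% within species, genus and family).

One deviation from a pure "independent root per family" design is worth
stating: all family roots descend from a single library root. Fully
independent family roots would make cross-family sequence pairs random
with respect to each other (expected mismatch fraction 0.75), which puts
the K2P logarithm outside its domain and leaves most cross-family
distances undefined — and an NJ tree over the library impossible. Evolving
family roots from one ancestor at the `d_family` scale keeps cross-family
divergence controlled and the distance matrix defined, at no cost to the
rank structure.

## Substitution process, composition, lengths, indels

Sites evolve independently under the Kimura two-parameter model: with
transition/transversion rate ratio κ (default 2, a typical value for
plant nuclear spacers), the exact K80 transition probabilities for a
branch of length *d* are used to sample each child site, so compounding
over ranks is exact and the K2P estimator recovers branch lengths without
simulation bias. The root sequence is drawn i.i.d. at `gc_target`
(default 0.63, matching observed ITS2 composition). Because K80's
stationary composition is uniform, tip GC drifts a few percentage points
below the root target over the deepest branches; this is a property of
the model, not a bug, and the reported GC statistics are computed from
the sequences as they are.

Per-family ITS2 lengths are truncations of a common 348 bp root, drawn
from a Beta(2, 3.67) stretched over 158–348 bp so that the mean sits near
225 bp. Indels (default rate 0.002 per site, length 1–3) are applied to
terminal sequences after substitution and never touch the flank motifs,
which keeps the annotation ground truth exact. Generation is restricted
to A/C/G/T; `corrupt_records()` optionally introduces `N`s to exercise
pairwise deletion.

All randomness flows from a single seed set once per run
(`simulate_library()`), so identical configurations give byte-identical
FASTA output.

## Flank motifs

`add_flanks()` prepends a 5.8S-tail motif and appends a 28S-head motif to
each ITS2, producing full amplicons with recorded true spans. The default
motifs are built around the universal ITS2 primer sites (the forward
primer sequence inside the 5.8S and the reverse complement of the reverse
primer in the 28S), giving realistic conserved context for the annotation
stage.

# Annotation

The conserved flanks are located by position-weight-matrix log-odds
scanning (`build_profile()`, `scan_profile()`): each offset is scored by
the summed `log(freq/0.25)` over profile columns, ties resolve to the
smallest offset, and non-ACGT symbols contribute the background score 0.
A PWM replaces the profile HMMs often used for rRNA spacer annotation
deliberately: the 5.8S/28S flanks are short, highly conserved and nearly
gap-free, so insert/delete states add nothing here, and a PWM is
deterministic and dependency-free. A pseudocount of 0.5 per cell keeps
log-odds finite for single-sequence profiles; the acceptance threshold
defaults to 60% of the profile's maximum attainable score, which accepts
moderately mutated motifs while rejecting random sequence. Both choices
are configurable, and profiles round-trip through a plain column-frequency
text format.

`trim_its2()` takes the subsequence strictly between the end of the 5'
hit and the start of the 3' hit; coordinates are 0-based half-open
everywhere, which makes `trim_its2(add_flanks(x)) == x` an exact identity
on unmutated flanks. Failures carry reason codes (`flank_not_found`,
`out_of_order`, `empty_its2`) rather than silently returning partial
sequence.

Length is counted over non-gap characters; GC is (G+C)/(A+C+G+T) with
ambiguity codes excluded from the denominator. Group summaries use
R's default type-7 quantiles (linear interpolation).

# Alignment and K2P distances

The built-in progressive aligner builds a guide tree by average-linkage
clustering of fractional-common-6-mer distances and merges profiles by
affine-gap Needleman–Wunsch (match +1, mismatch −1, gap open −2, extend
−0.5; column scores are expected pairwise scores between column base
frequencies). Tie preference in the dynamic program is fixed, so
alignments are deterministic. This is a convenience for desk-scale
libraries — distance results always depend on the alignment, so
`as_alignment()` accepts an externally computed MSA and bypasses the
aligner entirely.

`k2p()` implements
*d* = −½·ln[(1−2P−Q)·√(1−2Q)], with P and Q the transition and
transversion proportions over compared sites. Sites with a gap or
ambiguity code in either row are excluded per pair (pairwise deletion),
matching the convention of the standard barcode distance-summary tools.
When no sites remain or a logarithm argument is non-positive the distance
is **masked, not clamped**: clamping to an arbitrary ceiling would bias
rank summaries silently, whereas masked entries are excluded and counted.
`nj_tree()` refuses matrices with undefined entries and names the pairs;
`prune_undefined()` greedily drops the sequences responsible.

Rank summaries follow the nested convention implied by barcode
distance-summary tables: the species level pools conspecific pairs, the
genus level pools congeneric pairs *of different species*, and the family
level confamilial pairs *of different genera*, so the three levels are
disjoint. Distances are reported in percent; internally everything is a
fraction.

# Barcoding gap

`gap_table()` uses sequence-level extrema (the maximum intraspecific
pairwise distance, and the minimum over all pairs to any other species),
not species means — the convention of the standard barcoding-gap tools.
Violations use the strict inequality max_intra > min_inter; exact ties
are reported separately as non-violations. Singletons are excluded, as is
any species whose entire intraspecific distance set is masked (with a
reason attribute). The nearest-neighbor species is the arg-min, with
lexicographic tie-breaking so output is reproducible.

# NJ tree and discrimination

`nj_tree()` is the standard Saitou–Nei agglomeration with the Q-criterion
and two-point branch lengths, ending in a three-point trifurcation.
Ties in the Q-criterion break to the lowest (row, column) pair and
negative branch lengths are clamped to zero, so the output is fully
deterministic; on additive matrices the tree reproduces input path
lengths to machine precision (a property the test suite checks against
independently generated random trees).

A species is *identified* when some edge of the unrooted tree separates
exactly its specimens from everything else — exclusivity/monophyly judged
on topology alone. Bootstrap support (`bootstrap_support()`: column
resampling, per-replicate K2P + NJ, bipartition matching) is reported but
never gates discrimination, because cluster counts in the field are
typically reported without a support threshold. The discrimination rate
excludes singleton species from its denominator. Mixed clusters (maximal
clades consisting entirely of unidentified species' leaves) are counted
for completeness, but cluster-count conventions differ between tools; only
the identified count and rate are meant to be compared across
implementations. Within bootstrap replicates only, resampling can
occasionally saturate a pair; such entries are imputed with the
replicate's maximum defined distance rather than dropping the replicate.
The full-data tree never imputes.

# Identification

`best_match()` aligns the query globally against every library sequence
with the aligner's scoring, then measures identity as matches over
aligned columns *excluding end gaps* — the semi-global convention that
mimics local-alignment identity on full-length barcodes — and coverage as
the fraction of the query inside the aligned span. Hits must clear
identity ≥ 0.97 and coverage ≥ 0.95 by default, the cutoffs observed for
correctly identified ITS2 barcodes. The best-hit set is all hits within
1e-9 of the top identity, i.e. exact ties; a wider top-N window is
deliberately not the default because it changes the meaning of
"ambiguous".

`classify()` applies the three-way rule: *correct* when every top hit is
conspecific, *ambiguous* when top hits mix conspecific and heterospecific
labels, *incorrect* when none is conspecific; the same rule applies to
genus labels for the genus-level call. In leave-one-out evaluation
(`identify_library()`) queries whose species has no other representative
mirror novel barcodes: excluded at species level, kept at genus level
when the top identity exceeds 0.95. `conspecific_consistency()` flags
species whose conspecific queries return disjoint best-match sets
(cryptic candidates) and distinguishes them from overlapping-but-unequal
sets (inconsistent-ambiguous).

# Validation, problem sizes, limitations

The test suite validates each stage against independent oracles:
brute-force K2P recomputation and an independent K80 implementation for
distances, exhaustive alignment enumeration at tiny sizes, random
additive matrices for NJ exactness, a rooted monophyly oracle for
exclusivity, and a direct truth table for the three-way classification.
End-to-end checks run on a simulated study library of 50 species × 5
specimens at ~300 bp — large enough for stable rank summaries, small
enough that the whole suite runs in minutes — and on batteries of smaller
libraries across seeds for the degradation properties (violations rise
and discrimination falls as `d_intra` approaches `d_species`).

What passing these tests shows: the distance, gap, tree and
identification machinery is numerically correct and behaves monotonically
under controlled degradation. What it does not show: performance on real
libraries, where alignment uncertainty, rate heterogeneity across sites
and lineages, intragenomic ITS2 polymorphism, misidentified vouchers and
database gaps all degrade identification in ways a star-shaped,
homogeneous-rate simulator cannot emulate. The simulator also draws
singletons and sample sizes symmetrically, unlike the strongly skewed
specimen counts of real collections. Results on simulated libraries are
therefore a correctness floor, not a forecast.
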