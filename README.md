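# barcodeval

Evaluation of DNA barcode reference libraries, built around the plant
ITS2 marker (the nuclear ribosomal spacer between the 5.8S and 28S rRNA
genes).

A barcode reference library — specimen sequences with expert-verified
species labels — is only useful for identification if its divergence
structure supports it. `barcodeval` answers that question three ways, the
standard battery for library papers:

- **Distance summaries and the barcoding gap.** Pairwise Kimura
  2-parameter distances, d = −½·ln[(1−2P−Q)·√(1−2Q)] with transition
  proportion P and transversion proportion Q, computed with pairwise
  deletion of gaps/ambiguities; pooled means per rank (within species /
  genus / family); and per species the maximum intraspecific distance
  against the minimum distance to the nearest neighbor, with a violation
  flag when the former strictly exceeds the latter.
- **Tree-based discrimination.** A deterministic Saitou–Nei
  neighbor-joining tree (optionally with column-bootstrap support); a
  species counts as identified when its specimens form an exclusive
  cluster (some edge of the unrooted tree isolates exactly them).
  Singleton species are excluded from the rate's denominator.
- **Best-match identification.** Each query is aligned against the whole
  library (leave-one-out), hits are filtered at identity ≥ 0.97 and
  coverage ≥ 0.95, and the tied best-hit set is classified *correct*
  (all conspecific), *ambiguous* (mixed) or *incorrect* (none), at
  species and genus level, plus conspecific-consistency flags for
  cryptic-diversity candidates.

Because real libraries have no ground truth, the package ships a
simulator (`simulate_library()`) that generates ITS2-like libraries over
a known taxonomic hierarchy with controlled divergence at every rank,
conserved 5.8S/28S flanking motifs for testing the annotation stage, and
the generating tree as ground truth. The `analysis/` directory runs the
whole workflow as numbered scripts (`01_simulate.R` … `06_identify.R`)
writing tables under `results/`.

## Worked example

Simulate a small library (2 families × 2 genera × 3 species × 3
specimens), trim the amplicons to the ITS2, and run the three
evaluations:

```r
library(barcodeval)

cfg <- library_config(n_families = 2, genera_per_family = 2,
                      species_per_genus = 3, specimens_per_species = 3,
                      seed = 1)
sim <- simulate_library(cfg)
ann <- annotate_library(sim$amplicons, config = cfg)
aln <- progressive_align(ann$records)
dmat <- distance_matrix(aln)

do.call(rbind, lapply(c("species", "genus", "family"),
                      function(r) summarize_rank(dmat, sim$taxonomy, r)))
#>     rank n_taxa n_comparisons min_pct max_pct mean_pct n_undefined
#>  species     12            36    0.00    2.29    0.675           0
#>    genus      4           108    5.96   17.17   11.056           0
#>   family      2           162   28.34   44.68   34.289           0

sum(gap_table(dmat, sim$taxonomy)$violation)
#> [1] 0

species_clusters(nj_tree(dmat), sim$taxonomy)$report
#> clusters: 12 (12 single-species)
#> species identified: 12 / 12 (100.00%); 0 singletons excluded

success_rates(identify_library(ann$records, sim$taxonomy), "species")
#>    level n_evaluated n_no_hit correct_pct ambiguous_pct incorrect_pct
#>  species          35        1         100             0             0
```

Reading the output: conspecific sequences sit at ~0.7% mean divergence
against ~11% between congeneric species, so every species keeps a clean
barcoding gap (0 violations), forms its own cluster on the NJ tree
(discrimination 12/12), and every classifiable leave-one-out query finds
only conspecific best matches (one query fell below the identity/coverage
thresholds and is reported as a no-hit, not a misidentification).

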