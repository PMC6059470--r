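#!/usr/bin/env Rscript

# Stage 4: barcoding-gap analysis. For every non-singleton species,
# maximum intraspecific K2P distance vs minimum distance to the nearest
# neighbor; a species violates the gap when the former strictly exceeds
# the latter.

library(barcodeval)

out_dir <- "results/gap"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

aln <- as_alignment(read_fasta("results/distance/alignment.fasta"))
taxonomy <- read_taxonomy("results/library/taxonomy.tsv")
dmat <- distance_matrix(aln)

gap <- gap_table(dmat, taxonomy)
write.table(gap, file.path(out_dir, "gap_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(x_max_intra_pct = gap$max_intra_pct,
                       y_min_inter_pct = gap$min_inter_pct,
                       species = gap$species),
            file.path(out_dir, "gap_scatter.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

excl <- attr(gap, "excluded")
cat(sprintf("%d species evaluated (%d excluded: %s)\n", nrow(gap),
            nrow(excl),
            if (nrow(excl)) paste(excl$reason, collapse = ", ") else "-"))
cat(sprintf("barcoding-gap violations: %d; ties: %d\n",
            sum(gap$violation), sum(gap$tie)))
if (any(gap$violation))
  print(gap[gap$violation, c("species", "max_intra_pct", "nn_species",
                             "min_inter_pct")], row.names = FALSE)
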