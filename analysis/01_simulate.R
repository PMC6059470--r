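#!/usr/bin/env Rscript

# Stage 1: simulate the reference library used by the whole analysis.
#
# The default configuration encodes the study conditions: 5 families x 2
# genera x 5 species x 5 specimens (50 species, 250 specimens),
# ITS2-like sequences of 158-348 bp at GC ~0.63, divergence scales
# d_intra = 0.006, d_species = 0.12, d_genus = 0.37, d_family = 0.50,
# and conserved 5.8S/28S flanking motifs for the annotation stage.

library(barcodeval)

out_dir <- "results/library"
cfg <- library_config(seed = 42)
print(cfg)

sim <- simulate_library(cfg)
paths <- write_library(sim$amplicons, sim$taxonomy, out_dir)
write_fasta(sim$its2, file.path(out_dir, "its2_truth.fasta"))
ape::write.tree(sim$ground_truth$tree,
                file.path(out_dir, "generating_tree.nwk"))
write_tsv <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE)
write_tsv(data.frame(specimen_id = sim$amplicons$specimen_id,
                     its2_start = sim$amplicons$its2_start,
                     its2_end = sim$amplicons$its2_end),
          file.path(out_dir, "its2_spans_truth.tsv"))

cat(sprintf("\nwrote %d amplicons from %d species (%d genera, %d families)\n",
            nrow(sim$amplicons), length(unique(sim$taxonomy$species)),
            length(unique(sim$taxonomy$genus)),
            length(unique(sim$taxonomy$family))))
cat("outputs under", out_dir, "\n")
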