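#!/usr/bin/env Rscript

# Stage 6: similarity-based identification. Every sequence is queried
# against the library with itself removed (leave-one-out) and classified
# correct / ambiguous / incorrect from its tied best-hit set, at species
# and genus level, plus conspecific-consistency (cryptic) flags.

library(barcodeval)

out_dir <- "results/identification"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

its2 <- read_fasta("results/annotation/its2.fasta")
taxonomy <- read_taxonomy("results/library/taxonomy.tsv")

res <- identify_library(its2, taxonomy)
write.table(res, file.path(out_dir, "identification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rates <- rbind(success_rates(res, "species"), success_rates(res, "genus"))
write.table(rates, file.path(out_dir, "success_rates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("identification success rates (%):\n")
print(rates, row.names = FALSE, digits = 4)

cons <- conspecific_consistency(res)
write.table(cons, file.path(out_dir, "consistency.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
n_cryptic <- sum(cons$status == "cryptic_candidate")
cat(sprintf("\nconspecific consistency: %d/%d species consistent; %d cryptic candidates\n",
            sum(cons$status == "consistent"), nrow(cons), n_cryptic))
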