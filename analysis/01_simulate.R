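#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-tissue study with planted truth.
#
# Emits the complete input bundle (genome, annotations, FPKM table,
# conservation track, gene sets, external score tables, liftover chains)
# plus the truth table under results/data/. Everything downstream reads
# only these files.

suppressMessages(library(linckit))

seed <- 7L
out <- "results/data"
ds <- generate_dataset(default_generator_config(), seed = seed,
                       out_dir = out)

cat("Synthetic study written to", out, "\n")
cat("Transcripts by planted class:\n")
print(table(ds$truth$true_class))
cat("\nlincRNA tissue patterns:\n")
linc <- ds$truth$true_class %in% c("lincRNA_known", "lincRNA_novel")
print(table(ds$truth$pattern[linc]))
cat(sprintf("\nfetal: %d  bidirectional: %d  with planted ortholog: %d\n",
            sum(ds$truth$fetal[linc]), sum(ds$truth$bidirectional[linc]),
            sum(!is.na(ds$truth$ortholog_chrom[linc]))))
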