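#!/usr/bin/env Rscript
# Stage 6: project the lincRNA catalog onto the second toy genome through
# the chain alignments and compare against the planted orthologs.

suppressMessages(library(linckit))

assembly <- read_gtf("results/data/assembly.gtf")
chains <- read_chain("results/data/chains.chain")
entries <- read.delim("results/entries.tsv")
truth <- read.delim("results/data/truth.tsv")

by_id <- setNames(assembly, vapply(assembly, `[[`, "", "transcript_id"))
hits <- list()
for (tid in entries$transcript_id)
  hits <- c(hits, map_transcript(by_id[[tid]], chains,
                                 min_mapped_fraction = 0.5))

orthologs <- do.call(rbind, lapply(hits, function(h)
  data.frame(transcript_id = h$transcript_id, chain_id = h$chain_id,
             target_chrom = h$target_chrom,
             target_start = h$intervals$start[1],
             target_end = h$intervals$end[nrow(h$intervals)],
             mapped_fraction = h$mapped_fraction,
             chain_score = h$chain_score)))

planted <- truth$transcript_id[!is.na(truth$ortholog_chrom) &
                                 truth$true_class %in%
                                 c("lincRNA_known", "lincRNA_novel")]
cat(sprintf("Ortholog regions: %d for %d lincRNAs (planted: %d)\n",
            nrow(orthologs), length(unique(orthologs$transcript_id)),
            length(planted)))
cat(sprintf("Planted orthologs recovered: %d / %d\n",
            length(intersect(orthologs$transcript_id, planted)),
            length(planted)))

write.table(orthologs, "results/orthologs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
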