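#!/usr/bin/env Rscript
# Stage 5: differential expression between heart stages and clustering.
#
# Welch t on log2 FPKM with BH FDR (fold > 2, FDR < 0.05), hierarchical
# clustering (Pearson distance, complete linkage) of the DE transcripts,
# and K-means with silhouette-selected k.

suppressMessages(library(linckit))

expr <- read_expression_table("results/data/fpkm.tsv")
de <- differential_expression(expr, "AH", "EH")
cat(sprintf("Differentially expressed (EH vs AH): %d of %d\n",
            sum(de$significant), nrow(de)))

de_ids <- de$transcript_id[de$significant]
mat <- log2(expr$fpkm[de_ids, , drop = FALSE] + 0.01)

hc <- hierarchical_cluster(mat)
cl <- kmeans_silhouette(mat, k_range = 2:6, n_init = 10L, seed = 9L)
cat("Average silhouette width per k:\n")
print(round(cl$silhouette, 3))
cat(sprintf("Chosen k = %d\n", cl$k))

truth <- read.delim("results/data/truth.tsv")
fetal <- truth$transcript_id[truth$fetal]
in_de <- intersect(fetal, de_ids)
tab <- table(cl$labels[in_de],
              truth$fetal_direction[match(in_de, truth$transcript_id)])
cat("\nFetal lincRNAs by cluster and planted direction:\n")
print(tab)

write.table(de, "results/differential_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(transcript_id = names(cl$labels),
                       cluster = unname(cl$labels)),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
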