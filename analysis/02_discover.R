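#!/usr/bin/env Rscript
# Stage 2: the six-filter lincRNA identification cascade.
#
# Reads the stage-1 bundle from disk (exercising every format reader),
# trains the CPAT-style coding model on the reference annotation, applies
# the cascade, and writes the catalog and its audit trail.

suppressMessages({
  library(linckit)
  library(Biostrings)
})

data_dir <- "results/data"
genome <- readDNAStringSet(file.path(data_dir, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))
reference <- read_gtf(file.path(data_dir, "reference.gtf"))
assembly <- read_gtf(file.path(data_dir, "assembly.gtf"))
expr <- read_expression_table(file.path(data_dir, "fpkm.tsv"))
scores <- list(pfam = read_score_table(file.path(data_dir, "pfam.tsv")),
               cpc = read_score_table(file.path(data_dir, "cpc.tsv")),
               phylocsf = read_score_table(file.path(data_dir,
                                                     "phylocsf.tsv")))

ref_coding <- Filter(function(m) m$biotype == "protein_coding", reference)
ref_linc <- Filter(function(m) m$biotype == "lincRNA", reference)

# train the coding/noncoding combiner on the reference annotation
coding_seqs <- vapply(ref_coding, extract_spliced_sequence, "", genome = genome)
linc_seqs <- vapply(ref_linc, extract_spliced_sequence, "", genome = genome)
hex_table <- train_hexamer_table(coding_seqs, linc_seqs)
train <- rbind(
  do.call(rbind, lapply(seq_along(ref_coding), function(i)
    coding_features(ref_coding[[i]]$transcript_id, coding_seqs[i],
                    hex_table))),
  do.call(rbind, lapply(seq_along(ref_linc), function(i)
    coding_features(ref_linc[[i]]$transcript_id, linc_seqs[i], hex_table))))
model <- fit_coding_model(train, c(rep(TRUE, length(ref_coding)),
                                   rep(FALSE, length(ref_linc))))
cat(sprintf("CPAT-style cutoff (sensitivity = specificity): %.3f\n",
            model$threshold))

reports <- do.call(rbind, lapply(assembly, function(m) {
  f <- coding_features(m$transcript_id,
                       extract_spliced_sequence(m, genome), hex_table)
  f$coding_probability <- coding_probability(f, model)
  f$pfam_p <- unname(scores$pfam[m$transcript_id])
  f$cpc_score <- unname(scores$cpc[m$transcript_id])
  f$phylocsf_score <- unname(scores$phylocsf[m$transcript_id])
  f
}))

th <- default_thresholds()
th$cpat_cutoff <- model$threshold
linc_refs <- list(
  ensembl = Filter(function(m) m$source == "ensembl_ref", ref_linc),
  zflncrnapedia = Filter(function(m) m$source == "zflncrnapedia_ref",
                         ref_linc))
out <- run_cascade(assembly, ref_coding, linc_refs, expr, reports, th)

cat("\nCascade audit:\n")
print(out$audit[, c("step", "n_in", "n_removed", "n_out")])
cat(sprintf("\nCatalog: %d lincRNAs (%d known, %d novel)\n",
            nrow(out$catalog),
            sum(startsWith(out$catalog$status, "known")),
            sum(out$catalog$status == "novel")))

truth <- read.delim(file.path(data_dir, "truth.tsv"))
planted <- truth$transcript_id[truth$true_class %in%
                                 c("lincRNA_known", "lincRNA_novel")]
tp <- length(intersect(out$catalog$transcript_id, planted))
cat(sprintf("Planted-truth recovery: sensitivity %.3f, precision %.3f\n",
            tp / length(planted), tp / nrow(out$catalog)))

write.table(out$catalog, "results/catalog.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(out$audit, "results/audit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(reports, "results/coding_reports.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
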