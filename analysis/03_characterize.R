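#!/usr/bin/env Rscript
# Stage 3: characterize the lincRNA catalog.
#
# Tissue-enrichment patterns, the fetal program, conservation scores,
# nearest coding neighbors and bidirectional flags; plus the per-class
# molecular profile (exon counts, lengths, expression, conservation).

suppressMessages(library(linckit))

data_dir <- "results/data"
assembly <- read_gtf(file.path(data_dir, "assembly.gtf"))
reference <- read_gtf(file.path(data_dir, "reference.gtf"))
expr <- read_expression_table(file.path(data_dir, "fpkm.tsv"))
track <- read_conservation_track(file.path(data_dir,
                                           "conservation.bedgraph"))
catalog <- read.delim("results/catalog.tsv")

ref_coding <- Filter(function(m) m$biotype == "protein_coding", reference)
by_id <- setNames(assembly, vapply(assembly, `[[`, "", "transcript_id"))
flags <- expressed_flags(expr)
gm <- group_means(expr)

entries <- cbind(catalog, do.call(rbind, lapply(
  catalog$transcript_id, function(tid) {
    m <- by_id[[tid]]
    f <- flags[tid, ]
    fp <- fetal_program(gm[tid, "EH"], gm[tid, "AH"])
    nb <- nearest_coding_neighbor(m, ref_coding)
    partner <- Filter(function(r)
      identical(r$transcript_id, nb$neighbor_transcript_id), ref_coding)
    data.frame(
      expressed_EH = f[["EH"]], expressed_AH = f[["AH"]],
      expressed_AM = f[["AM"]],
      pattern = classify_tissue_pattern(f[["EH"]], f[["AH"]], f[["AM"]]),
      fetal = fp$fetal, fetal_direction = fp$direction,
      bidirectional = length(partner) > 0 &&
        is_bidirectional(m, partner[[1]]),
      neighbor_gene_id = nb$neighbor_gene_id,
      neighbor_distance = nb$distance,
      conservation = transcript_conservation(m, track))
  })))
entries$cardiac <- entries$expressed_EH | entries$expressed_AH

cat(sprintf("Cardiac catalog: %d of %d lincRNAs (EH %d, AH %d)\n",
            sum(entries$cardiac), nrow(entries),
            sum(entries$expressed_EH), sum(entries$expressed_AH)))
cat("Tissue patterns:\n"); print(table(entries$pattern))
cat(sprintf("Fetal program: %d lincRNAs (%d embryonic-high)\n",
            sum(entries$fetal),
            sum(entries$fetal_direction == "embryonic_high")))
cat(sprintf("Bidirectional: %d lincRNAs\n", sum(entries$bidirectional)))

# molecular profile: expressed coding transcriptome vs known/novel lincRNAs
audit <- read.delim("results/audit.tsv")
coding_ids <- strsplit(audit$removed_ids[audit$step == "overlap_coding"],
                       ",")[[1]]
class_map <- c(setNames(rep("coding", length(coding_ids)), coding_ids),
               setNames(ifelse(startsWith(entries$status, "known"),
                               "known_lincRNA", "novel_lincRNA"),
                        entries$transcript_id))
profile <- suppressWarnings(molecular_profile(class_map, assembly, expr,
                                              track))
agg <- aggregate(cbind(n_exons, length, conservation) ~ class, profile,
                 mean, na.action = na.omit)
cat("\nClass means (exons, length, conservation):\n"); print(agg)

write.table(entries, "results/entries.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(profile, "results/profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
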