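#' Default end-to-end pipeline configuration
#'
#' Bundles the generator parameters, the filtering thresholds, and the
#' analysis parameters (association permutations, clustering k range,
#' bidirectional window, fetal fold, liftover fraction) with a master seed.
#'
#' @return named list.
#' @export
default_pipeline_config <- function() {
  list(seed = 7L,
       generator = default_generator_config(),
       thresholds = default_thresholds(),
       n_perm = 500L,
       k_range = 2:6, n_init = 10L,
       bidirectional_window = 1000L,
       fetal_fold = 4, de_fold = 2, de_fdr = 0.05,
       min_mapped_fraction = 0.5,
       conservation_method = "exon_mean")
}

#' Run the full discovery and characterization pipeline
#'
#' Executes, in order: synthetic dataset generation; CPAT-style
#' coding-model training on the reference annotation (coding transcripts
#' vs known lincRNAs); the six-filter identification cascade;
#' characterization of the catalog (tissue patterns, fetal program,
#' conservation, nearest neighbors, bidirectional flags); the molecular
#' profile; the gene-set association matrix; differential expression
#' between embryonic and adult heart plus K-means/silhouette clustering;
#' and ortholog projection through the chains. Deterministic given the
#' config seed; when `out_dir` is given every table is also written as TSV.
#'
#' @param config list from [default_pipeline_config] (entries may be
#'   overridden).
#' @param out_dir optional output directory for the report bundle.
#' @return list with `dataset`, `coding_model`, `reports`, `catalog`,
#'   `audit`, `entries` (characterized catalog), `profile`, `association`,
#'   `de`, `clustering`, `orthologs`, `summary`.
#' @export
run_all <- function(config = default_pipeline_config(), out_dir = NULL) {
  config <- utils::modifyList(default_pipeline_config(), config)
  for (field in c("seed", "generator", "thresholds"))
    if (is.null(config[[field]]))
      stop(sprintf("config error: missing '%s'", field))

  ds <- generate_dataset(config$generator, seed = config$seed)

  # --- train the coding/noncoding combiner on the reference annotation ----
  ref_coding <- Filter(function(m) m$biotype == "protein_coding",
                       ds$reference)
  ref_linc <- Filter(function(m) m$biotype == "lincRNA", ds$reference)
  coding_seqs <- vapply(ref_coding, extract_spliced_sequence,
                        character(1L), genome = ds$genome)
  linc_seqs <- vapply(ref_linc, extract_spliced_sequence,
                      character(1L), genome = ds$genome)
  hex_table <- train_hexamer_table(coding_seqs, linc_seqs)
  train_feats <- rbind(
    do.call(rbind, lapply(seq_along(coding_seqs), function(i)
      coding_features(ref_coding[[i]]$transcript_id, coding_seqs[i],
                      hex_table))),
    do.call(rbind, lapply(seq_along(linc_seqs), function(i)
      coding_features(ref_linc[[i]]$transcript_id, linc_seqs[i],
                      hex_table))))
  labels <- c(rep(TRUE, length(coding_seqs)), rep(FALSE, length(linc_seqs)))
  model <- suppressMessages(fit_coding_model(train_feats, labels))

  # --- per-transcript coding-potential reports ----------------------------
  asm_seqs <- vapply(ds$assembly, extract_spliced_sequence,
                     character(1L), genome = ds$genome)
  reports <- do.call(rbind, lapply(seq_along(ds$assembly), function(i)
    coding_features(ds$assembly[[i]]$transcript_id, asm_seqs[i], hex_table)))
  reports$coding_probability <- coding_probability(reports, model)
  reports$pfam_p <- unname(ds$scores$pfam[reports$transcript_id])
  reports$cpc_score <- unname(ds$scores$cpc[reports$transcript_id])
  reports$phylocsf_score <- unname(ds$scores$phylocsf[reports$transcript_id])

  # --- cascade -------------------------------------------------------------
  th <- config$thresholds
  if (is.null(th$cpat_cutoff)) th$cpat_cutoff <- model$threshold
  linc_refs <- list(
    ensembl = Filter(function(m) m$source == "ensembl_ref", ref_linc),
    zflncrnapedia = Filter(function(m) m$source == "zflncrnapedia_ref",
                           ref_linc))
  casc <- run_cascade(ds$assembly, ref_coding, linc_refs, ds$expr,
                      reports, th)

  # --- characterization ----------------------------------------------------
  asm_by_id <- stats::setNames(ds$assembly,
                               vapply(ds$assembly, `[[`, "",
                                      "transcript_id"))
  flags <- expressed_flags(ds$expr, threshold = th$fpkm)
  gm <- group_means(ds$expr)
  entries <- casc$catalog
  chr_rows <- lapply(entries$transcript_id, function(tid) {
    m <- asm_by_id[[tid]]
    f <- flags[tid, ]
    fp <- fetal_program(gm[tid, "EH"], gm[tid, "AH"],
                        fold = config$fetal_fold)
    nb <- nearest_coding_neighbor(m, ref_coding)
    bid <- if (!is.na(nb$neighbor_transcript_id)) {
      partner <- Filter(function(r)
        r$transcript_id == nb$neighbor_transcript_id, ref_coding)[[1L]]
      is_bidirectional(m, partner, window = config$bidirectional_window)
    } else FALSE
    data.frame(
      expressed_EH = f[["EH"]], expressed_AH = f[["AH"]],
      expressed_AM = f[["AM"]],
      pattern = classify_tissue_pattern(f[["EH"]], f[["AH"]], f[["AM"]]),
      fetal = fp$fetal, fetal_direction = fp$direction,
      bidirectional = bid,
      neighbor_gene_id = nb$neighbor_gene_id,
      neighbor_distance = nb$distance,
      conservation = transcript_conservation(
        m, ds$track, method = config$conservation_method))
  })
  entries <- cbind(entries, do.call(rbind, chr_rows))
  entries$cardiac <- entries$expressed_EH | entries$expressed_AH

  # --- molecular profile ---------------------------------------------------
  coding_ids <- names(asm_by_id)[vapply(asm_by_id, function(m)
    m$biotype == "protein_coding", TRUE)]
  # the coding class for the profile: assembly transcripts removed at
  # filter 1 (expressed protein-coding transcriptome)
  removed1 <- strsplit(casc$audit$removed_ids[
    casc$audit$step == "overlap_coding"], ",")[[1L]]
  class_map <- c(
    stats::setNames(rep("coding", length(removed1)), removed1),
    stats::setNames(
      ifelse(startsWith(entries$status, "known"), "known_lincRNA",
             "novel_lincRNA"), entries$transcript_id))
  profile <- suppressWarnings(
    molecular_profile(class_map, ds$assembly, ds$expr, ds$track))

  # --- gene-set association -------------------------------------------------
  cardiac_ids <- entries$transcript_id[entries$cardiac]
  linc_mat <- ds$expr$fpkm[cardiac_ids, , drop = FALSE]
  linc_mat <- linc_mat[apply(linc_mat, 1L, stats::var) > 0, , drop = FALSE]
  gene_rows <- ds$expr$fpkm[removed1, , drop = FALSE]
  rownames(gene_rows) <- vapply(asm_by_id[removed1], `[[`, "", "gene_id")
  assoc <- association_matrix(log2(linc_mat + 0.01),
                              log2(gene_rows + 0.01), ds$sets,
                              n_perm = config$n_perm,
                              seed = config$seed + 1L)

  # --- differential expression and clustering ------------------------------
  de <- differential_expression(ds$expr, "AH", "EH",
                                fold_cutoff = config$de_fold,
                                fdr_cutoff = config$de_fdr)
  de_ids <- de$transcript_id[de$significant]
  clustering <- NULL
  if (length(de_ids) >= 4L) {
    de_mat <- log2(ds$expr$fpkm[de_ids, , drop = FALSE] + 0.01)
    clustering <- kmeans_silhouette(de_mat, k_range = config$k_range,
                                    n_init = config$n_init,
                                    seed = config$seed + 2L)
  }

  # --- ortholog projection -------------------------------------------------
  ortho_hits <- list()
  for (tid in entries$transcript_id) {
    hits <- map_transcript(asm_by_id[[tid]], ds$chains,
                           min_mapped_fraction = config$min_mapped_fraction)
    ortho_hits <- c(ortho_hits, hits)
  }
  orthologs <- if (length(ortho_hits))
    do.call(rbind, lapply(ortho_hits, function(h)
      data.frame(transcript_id = h$transcript_id, chain_id = h$chain_id,
                 target_chrom = h$target_chrom,
                 target_start = h$intervals$start[1L],
                 target_end = h$intervals$end[nrow(h$intervals)],
                 mapped_fraction = h$mapped_fraction,
                 chain_score = h$chain_score)))
  else data.frame()

  summary <- list(
    n_assembled = length(ds$assembly),
    n_catalog = nrow(entries),
    n_known = sum(startsWith(entries$status, "known")),
    n_novel = sum(entries$status == "novel"),
    n_cardiac = sum(entries$cardiac),
    n_embryonic_expressed = sum(entries$expressed_EH),
    n_adult_expressed = sum(entries$expressed_AH),
    n_cardiac_specific = sum(entries$pattern %in%
                               c("heart_specific_adult",
                                 "heart_specific_embryonic", "heart_both")),
    n_fetal = sum(entries$fetal & entries$cardiac),
    n_bidirectional = sum(entries$bidirectional),
    n_ortholog_lincs = length(unique(orthologs$transcript_id)),
    n_ortholog_regions = nrow(orthologs),
    chosen_k = if (is.null(clustering)) NA_integer_ else clustering$k)

  result <- list(dataset = ds, coding_model = model, reports = reports,
                 catalog = casc$catalog, audit = casc$audit,
                 entries = entries, profile = profile, association = assoc,
                 de = de, clustering = clustering, orthologs = orthologs,
                 summary = summary)
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) utils::write.table(
    df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$catalog, "catalog.tsv")
  wt(result$audit, "audit.tsv")
  wt(result$entries, "entries.tsv")
  wt(result$profile, "profile.tsv")
  a <- result$association
  tidy <- data.frame(
    linc = rep(rownames(a$score), ncol(a$score)),
    set = rep(colnames(a$score), each = nrow(a$score)),
    score = as.vector(a$score), fdr = as.vector(a$fdr),
    ternary = as.vector(a$ternary))
  wt(tidy, "association.tsv")
  wt(result$de, "differential_expression.tsv")
  if (!is.null(result$clustering))
    wt(data.frame(transcript_id = names(result$clustering$labels),
                  cluster = unname(result$clustering$labels)),
       "clusters.tsv")
  if (nrow(result$orthologs)) wt(result$orthologs, "orthologs.tsv")
  yaml::write_yaml(result$summary, p("summary.yaml"))
  invisible(out_dir)
}
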