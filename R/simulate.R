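#' Default generator configuration
#'
#' Parameters of the synthetic study. The defaults emulate the three-tissue
#' design (embryonic heart EH, adult heart AH, adult muscle AM; three
#' replicates each) with planted transcript classes, expression patterns,
#' a fetal subprogram, a correlated gene set, conservation contrast and
#' orthologous loci. All counts, means and distribution parameters are
#' overridable; see the methods vignette for the rationale behind each
#' default.
#'
#' @return named list of generator parameters.
#' @export
default_generator_config <- function() {
  list(
    n_coding = 60L, n_known_linc = 30L, n_novel_linc = 40L,
    n_artifact_single_exon = 10L, n_artifact_short = 10L,
    n_zflnc_known = 10L,              # of the known lincs, how many are
                                      # annotated only in the zflncRNApedia-
                                      # style reference
    n_chrom = 4L, chrom_length = 300000L,
    target_n_chrom = 2L, target_chrom_length = 400000L,
    groups = c("EH", "AH", "AM"), n_replicates = 3L,
    # planted FPKM means: "on" per pattern, "off" well below the 0.1 cutoff
    coding_mean = 30, linc_on_mean = 15, off_mean = 0.02,
    fetal_high_mean = 40, fetal_low_mean = 5,
    sdlog = 0.3,                      # log-normal replicate noise (natural log)
    # lincRNA tissue-pattern mixture
    pattern_probs = c(heart_specific_adult = 0.20,
                      heart_specific_embryonic = 0.15,
                      heart_both = 0.25,
                      muscle_enriched = 0.15,
                      shared = 0.25),
    frac_fetal = 0.2,                 # of heart_both lincs, made >= 4-fold
    frac_bidirectional = 0.15, bidirectional_gap = 400L,
    frac_ortholog = 0.5,
    codon_concentration = 0.5,        # Dirichlet concentration of the
                                      # biased codon table (smaller = more
                                      # skew, more hexamer signal)
    noncoding_base_probs = c(A = 0.32, C = 0.17, G = 0.17, T = 0.34),
    cons_beta_coding = c(8, 2), cons_beta_noncoding = c(2, 8),
    n_gene_sets = 8L, genes_per_set = 12L,
    n_assoc_linc = 10L, latent_sd = 0.6, latent_noise_sd = 0.15,
    label_noise = 0                   # per-table flip rate of external scores
  )
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE)[, 3:1], 1L,
               paste, collapse = "")
  setdiff(all, STOP_CODONS)
}

random_seq <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

sample_exon_structure <- function(n_exons, exon_len_range, intron_len_range) {
  lens <- sample(exon_len_range[1L]:exon_len_range[2L], n_exons,
                 replace = TRUE)
  introns <- if (n_exons > 1L)
    sample(intron_len_range[1L]:intron_len_range[2L], n_exons - 1L,
           replace = TRUE) else integer(0)
  starts <- cumsum(c(0L, lens[-n_exons] + introns))
  data.frame(start = starts, end = starts + lens)
}

#' Place a lincRNA head-to-head with a coding gene
#'
#' Translates the lincRNA so that the two transcription start sites lie on
#' opposite strands, pointing away from each other, with exactly `gap`
#' nucleotides strictly between the two TSS bases (so the TSS-to-TSS
#' position difference is `gap + 1`; a planted gap of 999 sits exactly at
#' the closed 1000-nt bidirectional boundary). The coding model is
#' unchanged.
#'
#' @param linc,coding [transcript_model]s on the same chromosome with
#'   opposite strands.
#' @param gap number of intervening bases (>= 0).
#' @return list with adjusted `linc` and unchanged `coding`.
#' @export
plant_bidirectional_pair <- function(linc, coding, gap) {
  if (gap < 0L) stop("gap must be non-negative")
  if (linc$strand == coding$strand)
    stop("bidirectional pair needs opposite strands")
  target_tss <- if (coding$strand == "+")
    transcript_tss(coding) - (gap + 1L) else transcript_tss(coding) + gap + 1L
  shift <- target_tss - transcript_tss(linc)
  exons <- linc$exons
  exons$start <- exons$start + shift
  exons$end <- exons$end + shift
  if (any(exons$start < 0L)) stop("shift would place lincRNA before origin")
  moved <- transcript_model(linc$transcript_id, linc$gene_id, coding$chrom,
                            linc$strand, exons, linc$biotype, linc$source)
  if (spans_overlap(transcript_span(moved), transcript_span(coding)))
    stop("bidirectional placement would overlap the coding gene")
  list(linc = moved, coding = coding)
}

spans_overlap <- function(a, b) a[1L] < b[2L] && b[1L] < a[2L]

#' Generate a complete synthetic dataset with planted truth
#'
#' Emits a toy genome, reference and assembled annotations, a replicate
#' FPKM table, a conservation track, gene sets, external coding-evidence
#' score tables, liftover chains to a second toy genome, and a truth table
#' recording every planted property. Deterministic given `(config, seed)`.
#'
#' @param config list from [default_generator_config] (entries may be
#'   overridden).
#' @param seed integer seed.
#' @param out_dir directory to write the file bundle into, or `NULL` for an
#'   in-memory bundle only.
#' @return list with `genome`, `reference`, `assembly` (model lists),
#'   `expr` ([expression_table]), `track`, `sets`, `scores`
#'   (list pfam/cpc/phylocsf), `chains`, `truth` (data.frame), `config`,
#'   and `paths` (when `out_dir` is given).
#' @export
generate_dataset <- function(config = default_generator_config(), seed = 1L,
                             out_dir = NULL) {
  cfg <- utils::modifyList(default_generator_config(), config)
  set.seed(seed)

  n_linc <- cfg$n_known_linc + cfg$n_novel_linc
  classes <- c(rep("coding", cfg$n_coding),
               rep("lincRNA_known", cfg$n_known_linc),
               rep("lincRNA_novel", cfg$n_novel_linc),
               rep("artifact_single_exon", cfg$n_artifact_single_exon),
               rep("artifact_short", cfg$n_artifact_short))
  n_total <- length(classes)

  # --- transcript structures (locus-relative) -------------------------------
  structures <- vector("list", n_total)
  strands <- sample(c("+", "-"), n_total, replace = TRUE)
  for (i in seq_len(n_total)) {
    structures[[i]] <- switch(
      classes[i],
      coding = sample_exon_structure(sample(4:7, 1L), c(150L, 350L),
                                     c(200L, 800L)),
      lincRNA_known = ,
      lincRNA_novel = sample_exon_structure(sample(2:4, 1L), c(150L, 450L),
                                            c(200L, 800L)),
      artifact_single_exon = sample_exon_structure(1L, c(600L, 1200L),
                                                   c(0L, 0L)),
      artifact_short = sample_exon_structure(2L, c(70L, 95L), c(200L, 400L)))
  }

  # --- lincRNA truth attributes ---------------------------------------------
  linc_idx <- which(classes %in% c("lincRNA_known", "lincRNA_novel"))
  patterns <- rep("shared", n_total)
  patterns[classes == "coding"] <- "shared"
  patterns[classes %in% c("artifact_single_exon", "artifact_short")] <-
    "shared"
  patterns[linc_idx] <- sample(names(cfg$pattern_probs), length(linc_idx),
                               replace = TRUE, prob = cfg$pattern_probs)
  fetal_dir <- rep("none", n_total)
  hb <- linc_idx[patterns[linc_idx] == "heart_both"]
  n_fet <- round(cfg$frac_fetal * length(linc_idx))
  fet <- hb[seq_len(min(n_fet, length(hb)))]
  fetal_dir[fet] <- sample(c("embryonic_high", "adult_high"), length(fet),
                           replace = TRUE)

  bidir <- rep(FALSE, n_total)
  n_bid <- round(cfg$frac_bidirectional * length(linc_idx))
  bidir[sample(linc_idx, n_bid)] <- TRUE

  ortho <- rep(FALSE, n_total)
  n_ort <- round(cfg$frac_ortholog * length(linc_idx))
  ortho[sample(linc_idx, n_ort)] <- TRUE

  # planted-association lincs: shared-pattern, non-fetal lincs
  assoc_pool <- linc_idx[patterns[linc_idx] == "shared"]
  assoc_linc <- assoc_pool[seq_len(min(cfg$n_assoc_linc, length(assoc_pool)))]

  # --- genomic layout -------------------------------------------------------
  # each transcript is a locus; bidirectional lincs are paired with a fresh
  # coding partner chosen round-robin
  ids <- character(n_total)
  gene_ids <- character(n_total)
  k_coding <- 0L; k_known <- 0L; k_other <- 0L
  for (i in seq_len(n_total)) {
    if (classes[i] == "coding") {
      k_coding <- k_coding + 1L
      ids[i] <- sprintf("TCONS_C%04d", k_coding)
      gene_ids[i] <- sprintf("gene_pc%03d", k_coding)
    } else if (classes[i] == "lincRNA_known") {
      k_known <- k_known + 1L
      ids[i] <- sprintf("TCONS_K%04d", k_known)
      gene_ids[i] <- sprintf("gene_lk%03d", k_known)
    } else {
      k_other <- k_other + 1L
      ids[i] <- sprintf("TCONS_N%04d", k_other)
      gene_ids[i] <- sprintf("gene_nl%03d", k_other)
    }
  }

  coding_order <- which(classes == "coding")
  pair_of <- rep(NA_integer_, n_total)
  free_coding <- coding_order
  for (i in which(bidir)) {
    if (length(free_coding) == 0L)
      stop("config error: not enough coding genes for bidirectional pairs")
    pair_of[i] <- free_coding[1L]
    free_coding <- free_coding[-1L]
  }

  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chrom))
  cursor <- stats::setNames(rep(1000L, cfg$n_chrom), chrom_names)
  placement <- vector("list", n_total)  # chrom + offset per transcript
  order_idx <- sample(setdiff(seq_len(n_total), stats::na.omit(pair_of)))
  ci <- 0L
  place <- function(i, chrom, offset) {
    ex <- structures[[i]]
    placement[[i]] <<- list(chrom = chrom,
                            exons = data.frame(start = ex$start + offset,
                                               end = ex$end + offset))
  }
  for (i in order_idx) {
    ci <- ci + 1L
    chrom <- chrom_names[(ci - 1L) %% cfg$n_chrom + 1L]
    gap <- sample(2000:4000, 1L)
    offset <- cursor[[chrom]] + gap
    width_i <- max(structures[[i]]$end)
    if (!is.na(pair_of[i])) {
      # head-to-head unit: lincRNA (-) then its coding partner (+)
      j <- pair_of[i]
      strands[i] <- "-"; strands[j] <- "+"
      place(i, chrom, offset)
      linc_tss <- placement[[i]]$exons$end[nrow(structures[[i]])] - 1L
      place(j, chrom, linc_tss + cfg$bidirectional_gap + 1L)
      width_i <- max(placement[[j]]$exons$end) - offset
      cursor[[chrom]] <- offset + width_i
    } else {
      place(i, chrom, offset)
      cursor[[chrom]] <- offset + width_i
    }
    if (cursor[[chrom]] > cfg$chrom_length - 2000L)
      stop("config error: transcripts exceed chromosome capacity")
  }

  models <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    biotype <- if (classes[i] == "coding") "protein_coding"
    else if (classes[i] %in% c("lincRNA_known", "lincRNA_novel")) "lincRNA"
    else "unknown"
    models[[i]] <- transcript_model(ids[i], gene_ids[i],
                                    placement[[i]]$chrom, strands[i],
                                    placement[[i]]$exons, biotype, "assembly")
  }

  # --- genome sequence with planted coding/noncoding composition -----------
  codons <- sense_codons()
  codon_probs <- stats::rgamma(length(codons), shape = cfg$codon_concentration)
  codon_probs <- codon_probs / sum(codon_probs)
  chrom_seqs <- lapply(chrom_names, function(ch)
    sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE,
           prob = cfg$noncoding_base_probs))
  names(chrom_seqs) <- chrom_names

  make_mrna <- function(len, coding) {
    if (!coding) {
      return(random_seq(len, cfg$noncoding_base_probs))
    }
    orf_nt <- min(900L, 3L * ((len - 80L) %/% 3L))
    orf_nt <- max(306L, orf_nt)
    n_codon <- orf_nt %/% 3L - 2L
    body <- paste(sample(codons, n_codon, replace = TRUE, prob = codon_probs),
                  collapse = "")
    orf <- paste0("ATG", body, sample(STOP_CODONS, 1L))
    utr_total <- len - nchar(orf)
    utr5 <- utr_total %/% 2L
    paste0(random_seq(utr5, cfg$noncoding_base_probs), orf,
           random_seq(utr_total - utr5, cfg$noncoding_base_probs))
  }

  for (i in seq_len(n_total)) {
    m <- models[[i]]
    len <- transcript_length(m)
    mrna <- make_mrna(len, classes[i] == "coding")
    genomic <- if (m$strand == "+") mrna else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(mrna)))
    chars <- strsplit(genomic, "", fixed = TRUE)[[1L]]
    pos <- unlist(lapply(seq_len(nrow(m$exons)), function(e)
      seq.int(m$exons$start[e] + 1L, m$exons$end[e])))
    chrom_seqs[[m$chrom]][pos] <- chars
  }
  genome <- Biostrings::DNAStringSet(vapply(chrom_seqs, paste,
                                            character(1L), collapse = ""))
  names(genome) <- chrom_names

  # --- reference annotation -------------------------------------------------
  reference <- list()
  for (i in seq_len(n_total)) {
    if (classes[i] == "coding") {
      r <- models[[i]]
      r$transcript_id <- sub("TCONS_C", "ENSDART_C", r$transcript_id)
      r$source <- "ensembl_ref"
      reference[[length(reference) + 1L]] <- r
    } else if (classes[i] == "lincRNA_known") {
      r <- models[[i]]
      zf <- k_index(ids[i]) <= cfg$n_zflnc_known
      r$transcript_id <- if (zf) sub("TCONS_K", "ZFLNC_", r$transcript_id)
      else sub("TCONS_K", "ENSDART_L", r$transcript_id)
      r$source <- if (zf) "zflncrnapedia_ref" else "ensembl_ref"
      reference[[length(reference) + 1L]] <- r
    }
  }

  # --- expression ------------------------------------------------------------
  samples <- as.vector(t(outer(cfg$groups, seq_len(cfg$n_replicates),
                               function(g, r) paste0(g, "_", r))))
  design <- data.frame(sample = samples,
                       group = rep(cfg$groups, each = cfg$n_replicates),
                       replicate = rep(seq_len(cfg$n_replicates),
                                       times = length(cfg$groups)))
  pattern_means <- function(i) {
    on <- if (classes[i] == "coding") cfg$coding_mean else cfg$linc_on_mean
    p <- patterns[i]
    m <- c(EH = cfg$off_mean, AH = cfg$off_mean, AM = cfg$off_mean)
    if (p == "heart_specific_adult") m["AH"] <- on
    else if (p == "heart_specific_embryonic") m["EH"] <- on
    else if (p == "heart_both") m[c("EH", "AH")] <- on
    else if (p == "muscle_enriched") m["AM"] <- on
    else m[] <- on
    if (fetal_dir[i] == "embryonic_high")
      m[c("EH", "AH")] <- c(cfg$fetal_high_mean, cfg$fetal_low_mean)
    if (fetal_dir[i] == "adult_high")
      m[c("EH", "AH")] <- c(cfg$fetal_low_mean, cfg$fetal_high_mean)
    m
  }
  mean_mat <- t(vapply(seq_len(n_total), pattern_means, numeric(3L)))
  latent <- stats::rnorm(length(samples), sd = cfg$latent_sd)
  planted_set_id <- "set_planted_cardiac"
  # planted-association members: first `genes_per_set` coding genes
  assoc_gene <- seq_len(n_total) %in%
    coding_order[seq_len(min(cfg$genes_per_set, length(coding_order)))]
  fpkm <- matrix(0, n_total, length(samples),
                 dimnames = list(ids, samples))
  for (i in seq_len(n_total)) {
    mu <- mean_mat[i, design$group]
    noise_sd <- if (i %in% assoc_linc || assoc_gene[i])
      cfg$latent_noise_sd else cfg$sdlog
    lat <- if (i %in% assoc_linc || assoc_gene[i]) latent else 0
    fpkm[i, ] <- exp(log(mu) + lat + stats::rnorm(length(samples),
                                                  sd = noise_sd))
  }
  expr <- expression_table(fpkm, design)

  # --- conservation track ----------------------------------------------------
  pos_by <- stats::setNames(vector("list", cfg$n_chrom), chrom_names)
  score_by <- pos_by
  for (i in seq_len(n_total)) {
    m <- models[[i]]
    ab <- if (classes[i] == "coding") cfg$cons_beta_coding
    else cfg$cons_beta_noncoding
    pos <- unlist(lapply(seq_len(nrow(m$exons)), function(e)
      seq.int(m$exons$start[e], m$exons$end[e] - 1L)))
    pos_by[[m$chrom]] <- c(pos_by[[m$chrom]], pos)
    score_by[[m$chrom]] <- c(score_by[[m$chrom]],
                             round(stats::rbeta(length(pos), ab[1L], ab[2L]),
                                   4L))
  }
  track <- conservation_track(lapply(stats::setNames(nm = chrom_names),
                                     function(ch) list(
                                       pos = pos_by[[ch]] %||% integer(0),
                                       score = score_by[[ch]] %||% numeric(0))))

  # --- gene sets --------------------------------------------------------------
  coding_genes <- gene_ids[coding_order]
  sets <- list(gene_set(planted_set_id,
                        "planted latent-factor cardiac process",
                        gene_ids[assoc_gene]))
  remaining <- setdiff(coding_genes, gene_ids[assoc_gene])
  for (s in seq_len(cfg$n_gene_sets - 1L)) {
    members <- sample(remaining, min(cfg$genes_per_set, length(remaining)))
    sets[[length(sets) + 1L]] <-
      gene_set(sprintf("set_%02d", s), sprintf("random process %d", s),
               members)
  }

  # --- external scores ---------------------------------------------------------
  is_coding <- classes == "coding"
  flip <- function() stats::runif(n_total) < cfg$label_noise
  side <- function(truth_coding, coding_draw, noncoding_draw) {
    eff <- xor(truth_coding, flip())
    ifelse(eff, coding_draw, noncoding_draw)
  }
  scores <- list(
    pfam = stats::setNames(side(is_coding,
                                10^-stats::runif(n_total, 6, 12),
                                stats::runif(n_total, 0.01, 1)), ids),
    cpc = stats::setNames(side(is_coding,
                               stats::runif(n_total, 1, 5),
                               stats::runif(n_total, -5, -0.5)), ids),
    phylocsf = stats::setNames(side(is_coding,
                                    stats::runif(n_total, 50, 500),
                                    stats::runif(n_total, -200, 10)), ids))

  # --- liftover chains ----------------------------------------------------------
  tgt_names <- sprintf("tchr%d", seq_len(cfg$target_n_chrom))
  tgt_cursor <- stats::setNames(rep(1000L, cfg$target_n_chrom), tgt_names)
  chains <- list()
  truth_ortho <- data.frame(transcript_id = ids,
                            ortholog_chrom = NA_character_,
                            ortholog_start = NA_integer_,
                            ortholog_end = NA_integer_)
  for (i in which(ortho)) {
    m <- models[[i]]
    sp <- transcript_span(m)
    src_start <- max(0L, sp[1L] - 200L)
    src_end <- sp[2L] + 200L
    span <- src_end - src_start
    tc <- tgt_names[(i %% cfg$target_n_chrom) + 1L]
    t0 <- tgt_cursor[[tc]]
    tstrand <- sample(c("+", "-"), 1L)
    # half the chains carry one interior deletion (dt gap) in the source
    if (stats::runif(1L) < 0.5 && span > 400L) {
      g <- sample(30:80, 1L)
      s1 <- sample(150:(span - g - 150L), 1L)
      blocks <- data.frame(size = c(s1, span - s1 - g),
                           dt = c(g, 0L), dq = c(0L, 0L))
      tgt_span <- span - g
    } else {
      blocks <- data.frame(size = span, dt = 0L, dq = 0L)
      tgt_span <- span
    }
    tstart_fwd <- t0; tend_fwd <- t0 + tgt_span
    tsize <- cfg$target_chrom_length
    if (tstrand == "-") {
      qstart <- tsize - tend_fwd; qend <- tsize - tstart_fwd
    } else {
      qstart <- tstart_fwd; qend <- tend_fwd
    }
    chains[[length(chains) + 1L]] <- chain_alignment(
      id = sprintf("chain_%s", ids[i]),
      score = as.numeric(sample(1000:100000, 1L)),
      source = list(chrom = m$chrom, size = cfg$chrom_length, strand = "+",
                    start = src_start, end = src_end),
      target = list(chrom = tc, size = tsize, strand = tstrand,
                    start = qstart, end = qend),
      blocks = blocks)
    truth_ortho$ortholog_chrom[i] <- tc
    truth_ortho$ortholog_start[i] <- tstart_fwd
    truth_ortho$ortholog_end[i] <- tend_fwd
    tgt_cursor[[tc]] <- tend_fwd + sample(500:1500, 1L)
    if (tgt_cursor[[tc]] > cfg$target_chrom_length - 2000L)
      stop("config error: orthologs exceed target chromosome capacity")
  }

  # --- truth table ---------------------------------------------------------------
  # the fetal truth flag follows from the planted means, so strongly
  # heart-stage-specific lincs (on in one heart stage, off in the other)
  # are fetal too, exactly as the >= 4-fold definition implies
  truth_fetal <- vapply(seq_len(n_total), function(i) {
    if (mean_mat[i, "EH"] <= 0.1 && mean_mat[i, "AH"] <= 0.1) return("none")
    fp <- fetal_program(mean_mat[i, "EH"], mean_mat[i, "AH"])
    fp$direction
  }, character(1L))
  truth <- data.frame(
    transcript_id = ids,
    gene_id = gene_ids,
    true_class = classes,
    pattern = patterns,
    fetal = truth_fetal != "none",
    fetal_direction = truth_fetal,
    bidirectional = bidir,
    bidirectional_partner = ifelse(is.na(pair_of), NA_character_,
                                   ids[ifelse(is.na(pair_of), 1L, pair_of)]),
    planted_assoc = seq_len(n_total) %in% assoc_linc,
    planted_assoc_set = ifelse(seq_len(n_total) %in% assoc_linc,
                               planted_set_id, NA_character_),
    mean_EH = mean_mat[, "EH"], mean_AH = mean_mat[, "AH"],
    mean_AM = mean_mat[, "AM"],
    stringsAsFactors = FALSE)
  truth <- merge(truth, truth_ortho, by = "transcript_id", sort = FALSE)

  bundle <- list(genome = genome, reference = reference, assembly = models,
                 expr = expr, track = track, sets = sets, scores = scores,
                 chains = chains, truth = truth, config = cfg)
  if (!is.null(out_dir)) bundle$paths <- write_bundle(bundle, out_dir)
  bundle
}

k_index <- function(id) as.integer(sub("TCONS_K", "", id))

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  write_gtf(bundle$reference, p("reference.gtf"))
  write_gtf(bundle$assembly, p("assembly.gtf"))
  write_expression_table(bundle$expr, p("fpkm.tsv"))
  write_conservation_track(bundle$track, p("conservation.bedgraph"))
  write_gmt(bundle$sets, p("gene_sets.gmt"))
  write_score_table(bundle$scores$pfam, p("pfam.tsv"))
  write_score_table(bundle$scores$cpc, p("cpc.tsv"))
  write_score_table(bundle$scores$phylocsf, p("phylocsf.tsv"))
  write_chain(bundle$chains, p("chains.chain"))
  utils::write.table(bundle$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(genome = p("genome.fa"), reference = p("reference.gtf"),
       assembly = p("assembly.gtf"), fpkm = p("fpkm.tsv"),
       conservation = p("conservation.bedgraph"), gmt = p("gene_sets.gmt"),
       pfam = p("pfam.tsv"), cpc = p("cpc.tsv"),
       phylocsf = p("phylocsf.tsv"), chains = p("chains.chain"),
       truth = p("truth.tsv"))
}
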