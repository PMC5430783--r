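# Shared fixtures and independent oracle implementations. Oracles are
# deliberately naive (per-base loops, exhaustive scans, textbook formulas)
# and share no code with the package internals they check.

small_config <- function(...) {
  utils::modifyList(
    list(n_coding = 25L, n_known_linc = 20L, n_novel_linc = 15L,
         n_artifact_single_exon = 4L, n_artifact_short = 4L,
         n_zflnc_known = 6L, n_chrom = 2L, chrom_length = 250000L,
         n_gene_sets = 4L, genes_per_set = 8L, n_assoc_linc = 6L),
    list(...))
}

# a cached default-config dataset at the canonical study seed
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(seed = 7L)
    cache
  }
})

make_model <- function(id, chrom, strand, starts, ends, gene = paste0("g_", id),
                       biotype = "unknown", source = "assembly") {
  transcript_model(id, gene, chrom, strand,
                   data.frame(start = starts, end = ends), biotype, source)
}

random_model <- function(id, chrom = "chr1", max_pos = 10000L) {
  n_ex <- sample(1:5, 1L)
  lens <- sample(20:120, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1L) sample(30:200, n_ex - 1L, replace = TRUE) else integer(0)
  origin <- sample(0:max_pos, 1L)
  starts <- origin + cumsum(c(0L, lens[-n_ex] + gaps))
  make_model(id, chrom, sample(c("+", "-"), 1L), starts, starts + lens)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# --- class-code oracle: per-base overlap + intron-chain equality -----------
oracle_class_code <- function(query, reference) {
  q_bases <- function(m) {
    pos <- unlist(lapply(seq_len(nrow(m$exons)), function(i)
      seq.int(m$exons$start[i], m$exons$end[i] - 1L)))
    paste0(m$chrom, ":", pos)
  }
  introns_of <- function(m) {
    n <- nrow(m$exons)
    if (n < 2L) return("none")
    paste(m$exons$end[-n], m$exons$start[-1L], sep = "-", collapse = ";")
  }
  qb <- q_bases(query)
  if (nrow(query$exons) > 1L) {
    for (ref in reference) {
      if (ref$chrom == query$chrom && ref$strand == query$strand &&
          nrow(ref$exons) > 1L &&
          identical(introns_of(ref), introns_of(query)))
        return("=")
    }
  }
  for (ref in reference)
    if (length(intersect(qb, q_bases(ref))) > 0L) return("o")
  "u"
}

# --- longest ORF oracle: exhaustive start-codon scan ------------------------
oracle_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- NULL
  for (s in seq_len(max(0L, n - 2L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    j <- s
    while (j + 2L <= n) {
      codon <- substr(seq, j, j + 2L)
      if (grepl("N", codon)) break
      if (codon %in% c("TAA", "TAG", "TGA")) {
        size <- j + 2L - s + 1L
        if (is.null(best) || size > best$size) best <- list(start = s - 1L,
                                                            size = size)
        break
      }
      j <- j + 3L
    }
  }
  best
}

# --- Fickett oracle: direct table walk, written against the published
# constants independently of the package internals ---------------------------
oracle_fickett <- function(seq) {
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  pos_cut <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  con_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  con_cut <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
  chars <- strsplit(toupper(seq), "")[[1]]
  frame <- (seq_along(chars) - 1L) %% 3L
  keep <- chars %in% c("A", "C", "G", "T")
  chars <- chars[keep]; frame <- frame[keep]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- sapply(0:2, function(f) sum(chars == b & frame == f))
    pp <- max(counts) / (min(counts) + 1)
    cp <- sum(counts) / length(chars)
    total <- total + pos_prob[[b]][which(pp >= pos_cut)[1]] * pos_w[[b]] +
      con_prob[[b]][which(cp >= con_cut)[1]] * con_w[[b]]
  }
  total
}

# --- BH step-up definition oracle ------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in seq(n, 1L)) {
    val <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# --- textbook silhouette oracle --------------------------------------------
oracle_silhouette <- function(labels, dmat) {
  n <- length(labels)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0L) { widths[i] <- 0; next }
    a <- mean(dmat[i, own])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(k)
      mean(dmat[i, labels == k])))
    widths[i] <- (b - a) / max(a, b)
  }
  mean(widths)
}

# --- per-base chain projection oracle --------------------------------------
oracle_project <- function(chrom, start, end, chain) {
  if (chrom != chain$source$chrom) return(integer(0))
  s <- chain$source$start; t <- chain$target$start
  mapped <- integer(0)
  for (i in seq_len(nrow(chain$blocks))) {
    sz <- chain$blocks$size[i]
    for (b in seq_len(sz) - 1L) {
      src <- s + b
      if (src >= start && src < end) mapped <- c(mapped, t + b)
    }
    s <- s + sz + chain$blocks$dt[i]
    t <- t + sz + chain$blocks$dq[i]
  }
  if (chain$target$strand == "-")
    mapped <- chain$target$size - 1L - mapped
  sort(mapped)
}

intervals_to_bases <- function(df) {
  if (nrow(df) == 0L) return(integer(0))
  sort(unlist(lapply(seq_len(nrow(df)), function(i)
    seq.int(df$start[i], df$end[i] - 1L))))
}

# random single-chromosome chain for projection tests
random_chain <- function(id = "c1", src_chrom = "chr1") {
  n_blocks <- sample(1:4, 1L)
  sizes <- sample(5:40, n_blocks, replace = TRUE)
  dt <- c(sample(0:15, n_blocks - 1L, replace = TRUE), 0L)
  dq <- c(sample(0:15, n_blocks - 1L, replace = TRUE), 0L)
  s0 <- sample(0:50, 1L)
  t0 <- sample(0:50, 1L)
  span_s <- sum(sizes + dt); span_q <- sum(sizes + dq)
  chain_alignment(id, 1000,
    source = list(chrom = src_chrom, size = 1000L, strand = "+",
                  start = s0, end = s0 + span_s),
    target = list(chrom = "tchr", size = 1000L,
                  strand = sample(c("+", "-"), 1L),
                  start = t0, end = t0 + span_q),
    blocks = data.frame(size = sizes, dt = dt, dq = dq))
}
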