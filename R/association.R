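#' Gene-set association score for one lincRNA
#'
#' The raw association score between a lincRNA and a functional gene set is
#' the mean, over set members present in the expression data, of the Pearson
#' correlation between the lincRNA's and the member's expression profiles
#' across samples. Members with zero variance are skipped; if no member is
#' scorable the score is `NA` (downstream: FDR 1, ternary 0).
#'
#' @param linc_expr numeric vector of the lincRNA's expression across
#'   samples (length >= 3, variance > 0).
#' @param member_expr numeric matrix, one row per set member, columns =
#'   the same samples.
#' @return mean Pearson correlation, or `NA_real_`.
#' @export
linc_geneset_score <- function(linc_expr, member_expr) {
  stopifnot(length(linc_expr) >= 3L)
  if (stats::var(linc_expr) == 0) stop("lincRNA profile has zero variance")
  rs <- apply(member_expr, 1L, function(g) {
    if (stats::var(g) == 0) return(NA_real_)
    stats::cor(linc_expr, g)
  })
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0L) return(NA_real_)
  mean(rs)
}

#' Build the lincRNA x gene-set association matrix
#'
#' Computes the raw score for every (lincRNA, set) pair, a two-sided
#' permutation p-value per cell (gene labels permuted: each null draw
#' replaces the set's members with a random same-size draw from all scorable
#' genes), Benjamini-Hochberg FDR across all cells, and the ternary value:
#' 0 when FDR is 0.5 or above (or the score is 0/NA), else the sign of the
#' score.
#'
#' @param linc_mat numeric matrix lincRNAs x samples.
#' @param gene_mat numeric matrix genes x samples (same sample order).
#' @param sets list of `gene_set`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; the null is deterministic given it.
#' @return list with matrices `score`, `p`, `fdr`, `ternary`
#'   (lincRNAs x sets).
#' @export
association_matrix <- function(linc_mat, gene_mat, sets, n_perm = 500L,
                               seed = 1L) {
  stopifnot(n_perm >= 100L)
  ok_gene <- apply(gene_mat, 1L, stats::var) > 0
  gene_ok <- gene_mat[ok_gene, , drop = FALSE]
  # lincRNA x gene correlation matrix, computed once; permuting gene labels
  # only changes which columns a set owns
  C <- stats::cor(t(linc_mat), t(gene_ok))
  set_ids <- vapply(sets, `[[`, "", "set_id")
  obs <- sapply(sets, function(s) {
    members <- intersect(s$gene_ids, rownames(gene_ok))
    if (length(members) == 0L) return(rep(NA_real_, nrow(C)))
    rowMeans(C[, members, drop = FALSE])
  })
  if (is.null(dim(obs))) obs <- matrix(obs, nrow = nrow(C))
  dimnames(obs) <- list(rownames(linc_mat), set_ids)
  sizes <- vapply(sets, function(s)
    length(intersect(s$gene_ids, rownames(gene_ok))), 0L)
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    for (j in seq_along(sets)) {
      if (sizes[j] == 0L) next
      null_members <- sample(ncol(C), sizes[j])
      null_score <- rowMeans(C[, null_members, drop = FALSE])
      exceed[, j] <- exceed[, j] + (abs(null_score) >= abs(obs[, j]))
    }
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[is.na(obs)] <- 1
  fdr <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                dimnames = dimnames(obs))
  ternary <- matrix(mapply(ternarize, obs, fdr), nrow(obs), ncol(obs),
                    dimnames = dimnames(obs))
  dimnames(p) <- dimnames(obs)
  list(score = obs, p = p, fdr = fdr, ternary = ternary)
}

#' Ternarize an association score
#'
#' The study rule: FDR above 0.5 (or exactly 0.5, the open boundary) gives
#' 0; FDR below 0.5 gives +1 for a positive score and -1 for a negative
#' score; a zero or missing score gives 0.
#'
#' @param score raw association score (may be `NA`).
#' @param fdr FDR in [0,1].
#' @return integer in {-1, 0, 1}.
#' @export
ternarize <- function(score, fdr) {
  if (is.na(score) || fdr >= 0.5 || score == 0) return(0L)
  if (score > 0) 1L else -1L
}

#' Hypergeometric gene-set enrichment of a neighbor gene list
#'
#' One-sided hypergeometric tail probability of observing at least the seen
#' overlap between the neighbor list and each set, within the given
#' universe; BH-adjusted across sets.
#'
#' @param neighbors character vector of gene ids (subset of `universe`).
#' @param sets list of `gene_set`.
#' @param universe character vector of all candidate gene ids.
#' @return data.frame: `set_id`, `overlap`, `set_size`, `p`, `fdr`.
#' @export
neighbor_enrichment <- function(neighbors, sets, universe) {
  neighbors <- unique(neighbors)
  if (!all(neighbors %in% universe))
    stop("neighbors must be contained in the universe")
  n_u <- length(universe); n_n <- length(neighbors)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$gene_ids, universe)
    k <- length(intersect(neighbors, members))
    p <- if (n_n == 0L) 1 else
      stats::phyper(k - 1L, length(members), n_u - length(members), n_n,
                    lower.tail = FALSE)
    data.frame(set_id = s$set_id, overlap = k, set_size = length(members),
               p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
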