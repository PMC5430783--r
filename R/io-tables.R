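#' Expression tables
#'
#' An `expression_table` pairs a transcript x sample FPKM matrix with a
#' design mapping each sample to a (group, replicate). Groups follow the
#' three-tissue study design: EH (embryonic heart), AH (adult heart),
#' AM (adult muscle); any group labels are accepted as long as each has at
#' least two replicates.
#'
#' @param fpkm numeric matrix, rownames = transcript ids, colnames = samples.
#' @param design data.frame with columns `sample`, `group`, `replicate`.
#' @return an `expression_table`.
#' @export
expression_table <- function(fpkm, design) {
  stopifnot(is.matrix(fpkm), !is.null(rownames(fpkm)), !is.null(colnames(fpkm)))
  if (anyDuplicated(rownames(fpkm)))
    stop("duplicated transcript_id in expression matrix")
  if (any(!is.finite(fpkm)) || any(fpkm < 0))
    stop("FPKM values must be non-negative and finite")
  stopifnot(all(c("sample", "group", "replicate") %in% names(design)))
  if (!setequal(design$sample, colnames(fpkm)))
    stop("design samples do not match matrix columns")
  design <- design[match(colnames(fpkm), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  reps <- table(design$group)
  if (any(reps < 2L))
    stop(sprintf("group(s) with fewer than 2 replicates: %s",
                 paste(names(reps)[reps < 2L], collapse = ", ")))
  structure(list(fpkm = fpkm, design = design), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table %d transcripts x %d samples; groups: %s>\n",
              nrow(x$fpkm), ncol(x$fpkm),
              paste(unique(x$design$group), collapse = ", ")))
  invisible(x)
}

#' Samples belonging to one group
#' @param expr an `expression_table`.
#' @param group group label.
#' @return character vector of sample names.
#' @export
group_samples <- function(expr, group)
  expr$design$sample[expr$design$group == group]

#' Per-group mean FPKM
#' @param expr an `expression_table`.
#' @return matrix transcripts x groups of replicate means.
#' @export
group_means <- function(expr) {
  groups <- unique(expr$design$group)
  out <- sapply(groups, function(g)
    rowMeans(expr$fpkm[, group_samples(expr, g), drop = FALSE]))
  rownames(out) <- rownames(expr$fpkm)
  out
}

#' Read an FPKM table plus its design sidecar
#'
#' The main file is a TSV with a `transcript_id` column followed by one
#' column per sample; the design sidecar (`<path>.design.tsv` by default) is
#' a TSV with columns `sample`, `group`, `replicate`.
#'
#' @param path FPKM TSV path.
#' @param design_path design sidecar path.
#' @return an [expression_table].
#' @export
read_expression_table <- function(path,
                                  design_path = paste0(path, ".design.tsv")) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "transcript_id")
    stop("first column must be transcript_id")
  if (anyDuplicated(tab$transcript_id))
    stop("duplicated transcript_id in expression table")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric FPKM value")
  rownames(mat) <- tab$transcript_id
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  expression_table(mat, design)
}

#' Write an FPKM table plus its design sidecar
#' @param expr an [expression_table].
#' @param path output TSV path; design goes to `<path>.design.tsv`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  tab <- data.frame(transcript_id = rownames(expr$fpkm),
                    expr$fpkm, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$design, paste0(path, ".design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column external score table
#'
#' TSV with header `transcript_id <TAB> score`, used for precomputed
#' Pfam P-values, CPC scores and PhyloCSF scores.
#'
#' @param path TSV path.
#' @return named numeric vector keyed by transcript id.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "score") %in% names(tab)))
    stop("score table needs transcript_id and score columns")
  stats::setNames(as.numeric(tab$score), tab$transcript_id)
}

#' Write a two-column external score table
#' @param scores named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(
    data.frame(transcript_id = names(scores), score = scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path GMT path.
#' @return list of `gene_set` objects (set_id, description, gene_ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) stop("GMT line with fewer than 3 fields")
    gene_set(fields[1L], fields[2L], fields[-(1:2)])
  })
}

#' Construct a gene set
#' @param set_id,description identifiers.
#' @param gene_ids character vector; must be non-empty and unique.
#' @return a `gene_set`.
#' @export
gene_set <- function(set_id, description, gene_ids) {
  if (length(gene_ids) < 1L) stop("gene set must contain at least one gene")
  if (anyDuplicated(gene_ids))
    stop(sprintf("duplicate gene ids in set %s", set_id))
  structure(list(set_id = set_id, description = description,
                 gene_ids = gene_ids), class = "gene_set")
}

#' Write gene sets in GMT format
#' @param sets list of `gene_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$set_id, s$description, s$gene_ids), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
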