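#' Read transcript models from a GTF file
#'
#' Parses GTF 2.2 (1-based, inclusive coordinates) and groups `exon` records
#' into [transcript_model] objects. Coordinates are converted to the
#' package-internal 0-based half-open convention at this boundary. The
#' biotype is taken from a `transcript_biotype` or `gene_biotype` attribute
#' when present, else `"unknown"`; provenance from a `source_tag` attribute
#' when present, else `"assembly"`.
#'
#' @param path GTF file path.
#' @return list of [transcript_model], in order of first appearance.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  recs <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L)
      stop(sprintf("%s line %d: expected 9 tab-separated fields, got %d",
                   path, i, length(fields)))
    if (fields[3L] != "exon") next
    start1 <- suppressWarnings(as.integer(fields[4L]))
    end1 <- suppressWarnings(as.integer(fields[5L]))
    if (is.na(start1) || is.na(end1))
      stop(sprintf("%s line %d: non-numeric coordinates", path, i))
    if (end1 < start1)
      stop(sprintf("%s line %d: end < start", path, i))
    attrs <- parse_gtf_attributes(fields[9L], path, i)
    if (is.null(attrs$transcript_id) || is.null(attrs$gene_id))
      stop(sprintf("%s line %d: missing transcript_id/gene_id", path, i))
    recs[[length(recs) + 1L]] <- list(
      tid = attrs$transcript_id, gid = attrs$gene_id,
      chrom = fields[1L], strand = fields[7L],
      start = start1 - 1L, end = end1,   # 1-based inclusive -> 0-based half-open
      biotype = attrs$transcript_biotype %||% attrs$gene_biotype %||% "unknown",
      source = attrs$source_tag %||% "assembly")
  }
  if (length(recs) == 0L) return(list())
  tids <- vapply(recs, `[[`, "", "tid")
  models <- list()
  for (tid in unique(tids)) {
    grp <- recs[tids == tid]
    chroms <- unique(vapply(grp, `[[`, "", "chrom"))
    strands <- unique(vapply(grp, `[[`, "", "strand"))
    if (length(chroms) != 1L)
      stop(sprintf("transcript %s: exons on multiple chromosomes", tid))
    if (length(strands) != 1L)
      stop(sprintf("transcript %s: mixed strands", tid))
    exons <- data.frame(start = vapply(grp, `[[`, 0L, "start"),
                        end = vapply(grp, `[[`, 0L, "end"))
    models[[length(models) + 1L]] <- transcript_model(
      transcript_id = tid, gene_id = grp[[1L]]$gid, chrom = chroms,
      strand = strands, exons = exons, biotype = grp[[1L]]$biotype,
      source = grp[[1L]]$source)
  }
  models
}

parse_gtf_attributes <- function(text, path, lineno) {
  out <- list()
  parts <- strsplit(text, ";", fixed = TRUE)[[1L]]
  for (p in parts) {
    p <- trimws(p)
    if (!nzchar(p)) next
    m <- regmatches(p, regexec('^(\\S+)\\s+"([^"]*)"$', p))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("%s line %d: malformed attribute '%s'", path, lineno, p))
    out[[m[2L]]] <- m[3L]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write transcript models to a GTF file
#'
#' Emits GTF 2.2 with 1-based inclusive coordinates: one `transcript`
#' feature per model and one `exon` feature per exon, carrying
#' `gene_id`, `transcript_id`, `transcript_biotype` and `source_tag`
#' attributes so that [read_gtf] round-trips losslessly.
#'
#' @param models list of [transcript_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- c("##format: gtf")
  for (m in models) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s"; source_tag "%s";',
      m$gene_id, m$transcript_id, m$biotype, m$source)
    sp <- transcript_span(m)
    lines <- c(lines,
               paste(m$chrom, "linckit", "transcript", sp[1L] + 1L, sp[2L],
                     ".", m$strand, ".", attrs, sep = "\t"),
               paste(m$chrom, "linckit", "exon", m$exons$start + 1L,
                     m$exons$end, ".", m$strand, ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
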