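#' Chain alignments
#'
#' UCSC chain format describes a pairwise genome alignment as a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id` followed by gapless block lines `size dt dq` (the last line is a
#' bare `size`). Following liftover-chain conventions the `t` side is the
#' source genome (the one intervals are projected from) and the `q` side the
#' target. Coordinates on a `-` strand side are given on the reversed
#' sequence, as in the UCSC format.
#'
#' @param id chain id.
#' @param score alignment score.
#' @param source,target lists with `chrom`, `size`, `strand`, `start`, `end`.
#' @param blocks data.frame with columns `size`, `dt`, `dq` (last row's
#'   `dt`/`dq` are 0).
#' @return a `chain_alignment`.
#' @export
chain_alignment <- function(id, score, source, target, blocks) {
  blocks <- data.frame(size = as.integer(blocks$size),
                       dt = as.integer(blocks$dt),
                       dq = as.integer(blocks$dq))
  if (any(blocks$size <= 0L)) stop("chain block with non-positive size")
  if (any(blocks$dt < 0L) || any(blocks$dq < 0L))
    stop("negative chain gap")
  span_t <- sum(blocks$size + blocks$dt)
  span_q <- sum(blocks$size + blocks$dq)
  if (span_t != source$end - source$start)
    stop(sprintf("chain %s: blocks span %d on source but header says %d",
                 id, span_t, source$end - source$start))
  if (span_q != target$end - target$start)
    stop(sprintf("chain %s: blocks span %d on target but header says %d",
                 id, span_q, target$end - target$start))
  structure(list(id = id, score = score, source = source, target = target,
                 blocks = blocks), class = "chain_alignment")
}

#' Read a UCSC chain file
#' @param path chain file path.
#' @return list of [chain_alignment].
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!startsWith(line, "chain"))
      stop(sprintf("%s line %d: expected chain header", path, i))
    h <- strsplit(line, "[ \t]+")[[1L]]
    if (length(h) != 13L)
      stop(sprintf("%s line %d: chain header needs 13 fields", path, i))
    src <- list(chrom = h[3L], size = as.integer(h[4L]), strand = h[5L],
                start = as.integer(h[6L]), end = as.integer(h[7L]))
    tgt <- list(chrom = h[8L], size = as.integer(h[9L]), strand = h[10L],
                start = as.integer(h[11L]), end = as.integer(h[12L]))
    blocks <- list()
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop("chain truncated: missing final block line")
      bl <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1L]]
      i <- i + 1L
      if (length(bl) == 1L) {
        blocks[[length(blocks) + 1L]] <- c(as.integer(bl), 0L, 0L)
        break
      } else if (length(bl) == 3L) {
        blocks[[length(blocks) + 1L]] <- as.integer(bl)
      } else stop("malformed chain block line")
    }
    bdf <- as.data.frame(do.call(rbind, blocks))
    names(bdf) <- c("size", "dt", "dq")
    chains[[length(chains) + 1L]] <-
      chain_alignment(id = h[13L], score = as.numeric(h[2L]),
                      source = src, target = tgt, blocks = bdf)
  }
  chains
}

#' Write chains in UCSC chain format
#' @param chains list of [chain_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(paste("chain", format_score(ch$score),
                     ch$source$chrom, ch$source$size, ch$source$strand,
                     ch$source$start, ch$source$end,
                     ch$target$chrom, ch$target$size, ch$target$strand,
                     ch$target$start, ch$target$end, ch$id), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1L)
      writeLines(paste(b$size[-n], b$dt[-n], b$dq[-n]), con)
    writeLines(c(as.character(b$size[n]), ""), con)
  }
  invisible(path)
}
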