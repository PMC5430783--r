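#' Project a genomic interval through a chain alignment
#'
#' Maps each base of the interval through the chain's gapless blocks; bases
#' falling into source (`dt`) or target (`dq`) gaps are unmapped. Contiguous
#' mapped runs are merged. When the chain's target strand is `-`, target
#' block coordinates (given on the reversed sequence, per the UCSC format)
#' are reflected back to forward-strand coordinates.
#'
#' @param chrom,start,end the source interval (0-based half-open).
#' @param chain a [chain_alignment] (source strand must be `+`).
#' @return data.frame of target intervals (`chrom`, `start`, `end`), sorted
#'   and non-overlapping; zero rows when nothing maps.
#' @export
project_interval <- function(chrom, start, end, chain) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  if (chain$source$strand != "+")
    stop("chains with '-' source strand are not supported")
  if (chrom != chain$source$chrom) return(empty)
  s_cur <- chain$source$start
  t_cur <- chain$target$start
  out_start <- integer(0); out_end <- integer(0)
  for (i in seq_len(nrow(chain$blocks))) {
    size <- chain$blocks$size[i]
    ov_lo <- max(start, s_cur)
    ov_hi <- min(end, s_cur + size)
    if (ov_lo < ov_hi) {
      off <- t_cur - s_cur
      out_start <- c(out_start, ov_lo + off)
      out_end <- c(out_end, ov_hi + off)
    }
    s_cur <- s_cur + size + chain$blocks$dt[i]
    t_cur <- t_cur + size + chain$blocks$dq[i]
  }
  if (length(out_start) == 0L) return(empty)
  if (chain$target$strand == "-") {
    sz <- chain$target$size
    new_start <- sz - out_end
    out_end <- sz - out_start
    out_start <- new_start
  }
  ord <- order(out_start)
  out_start <- out_start[ord]; out_end <- out_end[ord]
  # merge abutting/contiguous runs
  ms <- out_start[1L]; me <- out_end[1L]
  res_s <- integer(0); res_e <- integer(0)
  for (i in seq_along(out_start)[-1L]) {
    if (out_start[i] <= me) me <- max(me, out_end[i])
    else { res_s <- c(res_s, ms); res_e <- c(res_e, me)
           ms <- out_start[i]; me <- out_end[i] }
  }
  res_s <- c(res_s, ms); res_e <- c(res_e, me)
  data.frame(chrom = rep(chain$target$chrom, length(res_s)),
             start = res_s, end = res_e)
}

#' Map a transcript onto a second genome through chains
#'
#' Projects each exon through every chain overlapping the transcript span on
#' its chromosome and reports hits whose mapped fraction (mapped source
#' exonic bases over total exonic length) reaches `min_mapped_fraction`.
#' Hits are ranked by chain score; one transcript may map through several
#' chains.
#'
#' @param model a [transcript_model].
#' @param chains list of [chain_alignment].
#' @param min_mapped_fraction minimum mapped fraction (default 0.5).
#' @return list of hits, each with `transcript_id`, `chain_id`,
#'   `target_chrom`, `intervals` (data.frame), `mapped_fraction`,
#'   `chain_score`; empty list when nothing qualifies.
#' @export
map_transcript <- function(model, chains, min_mapped_fraction = 0.5) {
  sp <- transcript_span(model)
  cand <- Filter(function(ch)
    ch$source$chrom == model$chrom &&
      ch$source$start < sp[2L] && ch$source$end > sp[1L], chains)
  if (length(cand) == 0L) return(list())
  cand <- cand[order(vapply(cand, `[[`, 0, "score"), decreasing = TRUE)]
  total <- transcript_length(model)
  hits <- list()
  for (ch in cand) {
    projs <- lapply(seq_len(nrow(model$exons)), function(i)
      project_interval(model$chrom, model$exons$start[i],
                       model$exons$end[i], ch))
    proj <- do.call(rbind, projs)
    mapped <- if (nrow(proj) == 0L) 0L else sum(proj$end - proj$start)
    frac <- mapped / total
    if (frac >= min_mapped_fraction) {
      proj <- proj[order(proj$start), , drop = FALSE]
      rownames(proj) <- NULL
      hits[[length(hits) + 1L]] <- list(
        transcript_id = model$transcript_id, chain_id = ch$id,
        target_chrom = ch$target$chrom, intervals = proj,
        mapped_fraction = frac, chain_score = ch$score)
    }
  }
  hits
}
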