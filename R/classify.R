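#' Intron chain of a transcript
#'
#' The ordered gaps between consecutive exons in ascending genomic order.
#' A single-exon transcript has an empty chain.
#'
#' @param model a [transcript_model].
#' @return data.frame with `start`, `end` columns (0-based half-open),
#'   possibly zero rows.
#' @export
intron_chain <- function(model) {
  n <- nrow(model$exons)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = model$exons$end[-n], end = model$exons$start[-1L])
}

#' Classify an assembled transcript against a reference annotation
#'
#' Assigns a Cuffcompare-style class code relating the query to a reference
#' transcript set, using the minimal subset the lincRNA workflow needs:
#' \describe{
#'   \item{`=`}{some same-strand, same-chromosome multi-exon reference
#'     transcript has an identical intron chain (terminal exon ends may
#'     differ);}
#'   \item{`o`}{any query exon base overlaps any reference exon, on either
#'     strand;}
#'   \item{`u`}{intergenic: no exonic overlap with the reference.}
#' }
#' Precedence is `=` > `o` > `u`. Single-exon queries have no intron chain
#' and can never be `=`.
#'
#' @param query a [transcript_model].
#' @param reference list of [transcript_model].
#' @return list with `code` (`"="`, `"o"` or `"u"`) and
#'   `matched_reference_id` (id for `=`/`o`, `NA` for `u`).
#' @export
classify_against_reference <- function(query, reference) {
  q_chain <- intron_chain(query)
  overlap_id <- NA_character_
  for (ref in reference) {
    if (ref$chrom != query$chrom) next
    if (nrow(q_chain) > 0L && ref$strand == query$strand) {
      r_chain <- intron_chain(ref)
      if (nrow(r_chain) == nrow(q_chain) &&
          all(r_chain$start == q_chain$start) &&
          all(r_chain$end == q_chain$end))
        return(list(code = "=", matched_reference_id = ref$transcript_id))
    }
    if (is.na(overlap_id) && exons_overlap(query$exons, ref$exons))
      overlap_id <- ref$transcript_id
  }
  if (!is.na(overlap_id))
    return(list(code = "o", matched_reference_id = overlap_id))
  list(code = "u", matched_reference_id = NA_character_)
}

exons_overlap <- function(a, b) {
  for (i in seq_len(nrow(a)))
    if (any(b$start < a$end[i] & b$end > a$start[i])) return(TRUE)
  FALSE
}

#' Nearest protein-coding neighbor of a lincRNA
#'
#' Finds the coding transcript on the same chromosome minimizing the gap
#' between genomic spans (0 if the spans abut or overlap). Ties are broken
#' toward the 5' side of the lincRNA, then by lexicographic gene id. The
#' signed distance is negative when the neighbor lies upstream of the
#' lincRNA TSS (in lincRNA orientation).
#'
#' @param linc a [transcript_model] (already classified intergenic).
#' @param coding list of coding [transcript_model].
#' @return list with `linc_id`, `neighbor_gene_id`, `neighbor_transcript_id`,
#'   `distance` (gap, nt), `signed_distance`, `orientation`
#'   (`same_strand`/`opposite_strand`); all-`NA` result if no neighbor exists.
#' @export
nearest_coding_neighbor <- function(linc, coding) {
  cands <- Filter(function(m) m$chrom == linc$chrom, coding)
  if (length(cands) == 0L)
    return(list(linc_id = linc$transcript_id,
                neighbor_gene_id = NA_character_,
                neighbor_transcript_id = NA_character_,
                distance = NA_integer_, signed_distance = NA_integer_,
                orientation = NA_character_))
  lsp <- transcript_span(linc)
  best <- NULL
  for (m in cands) {
    msp <- transcript_span(m)
    gap <- max(0L, msp[1L] - lsp[2L], lsp[1L] - msp[2L])
    # neighbor center relative to linc 5' end, for the tie rule
    five_prime <- if (linc$strand == "+") msp[2L] <= lsp[1L] else msp[1L] >= lsp[2L]
    key <- list(gap = gap, five_prime = five_prime, gene_id = m$gene_id)
    if (is.null(best) || neighbor_key_less(key, best$key))
      best <- list(model = m, key = key)
  }
  m <- best$model
  msp <- transcript_span(m)
  gap <- best$key$gap
  # sign: negative when the neighbor is upstream of the lincRNA TSS
  upstream <- if (linc$strand == "+") msp[1L] < lsp[1L] else msp[2L] > lsp[2L]
  list(linc_id = linc$transcript_id,
       neighbor_gene_id = m$gene_id,
       neighbor_transcript_id = m$transcript_id,
       distance = gap,
       signed_distance = if (upstream) -gap else gap,
       orientation = if (m$strand == linc$strand) "same_strand"
                     else "opposite_strand")
}

# order: smaller gap first; 5' side (of the lincRNA) first; then gene id
neighbor_key_less <- function(a, b) {
  if (a$gap != b$gap) return(a$gap < b$gap)
  if (a$five_prime != b$five_prime) return(a$five_prime)
  a$gene_id < b$gene_id
}

#' Bidirectional (divergent) lincRNA test
#'
#' A lincRNA is bidirectional when its transcription start site lies
#' head-to-head with a neighboring gene's TSS on the opposite strand within
#' `window` bases: the two transcripts point away from each other and the
#' TSS-to-TSS separation is at most `window` (closed threshold).
#'
#' @param linc,neighbor [transcript_model]s.
#' @param window maximum TSS separation in nt (default 1000).
#' @return logical flag. Symmetric in its first two arguments.
#' @export
is_bidirectional <- function(linc, neighbor, window = 1000L) {
  if (linc$chrom != neighbor$chrom) return(FALSE)
  if (linc$strand == neighbor$strand) return(FALSE)
  plus <- if (linc$strand == "+") linc else neighbor
  minus <- if (linc$strand == "-") linc else neighbor
  tss_plus <- transcript_tss(plus)
  tss_minus <- transcript_tss(minus)
  # divergent: the - transcript runs leftward from a TSS left of the + TSS
  if (tss_minus > tss_plus) return(FALSE)
  (tss_plus - tss_minus) <= window
}
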