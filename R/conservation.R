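#' Mean conservation score of one exon
#'
#' The exon score is the arithmetic mean of the per-nucleotide scores over
#' the exon's covered bases; bases absent from the track contribute to
#' neither numerator nor denominator. An exon with no covered base has no
#' score (`NA`).
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open exon interval.
#' @param track a [conservation_track].
#' @return numeric score in [0,1], or `NA_real_` when uncovered.
#' @export
exon_conservation <- function(chrom, start, end, track) {
  scores <- track_scores(track, chrom, start, end)
  if (length(scores) == 0L) return(NA_real_)
  mean(scores)
}

#' Transcript-level conservation score
#'
#' Aggregates exon scores over the transcript. The default (`"exon_mean"`)
#' is the unweighted mean over exons that have a score; exons with no
#' covered base are ignored. `"base_mean"` instead averages over all covered
#' bases of the transcript, weighting exons by their covered length.
#'
#' @param model a [transcript_model].
#' @param track a [conservation_track].
#' @param method `"exon_mean"` (default) or `"base_mean"`.
#' @return numeric score in [0,1], or `NA_real_` when no exon is covered.
#' @export
transcript_conservation <- function(model, track,
                                    method = c("exon_mean", "base_mean")) {
  method <- match.arg(method)
  if (method == "base_mean") {
    scores <- unlist(lapply(seq_len(nrow(model$exons)), function(i)
      track_scores(track, model$chrom,
                   model$exons$start[i], model$exons$end[i])))
    if (length(scores) == 0L) return(NA_real_)
    return(mean(scores))
  }
  per_exon <- vapply(seq_len(nrow(model$exons)), function(i)
    exon_conservation(model$chrom, model$exons$start[i],
                      model$exons$end[i], track), 0)
  per_exon <- per_exon[!is.na(per_exon)]
  if (length(per_exon) == 0L) return(NA_real_)
  mean(per_exon)
}
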