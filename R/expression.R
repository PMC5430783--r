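#' Expressed call for one group of replicates
#'
#' A transcript is called expressed in a group when its FPKM exceeds
#' `threshold` (strictly) in at least 2 of 3 replicates; for other replicate
#' counts n the generalized rule requires at least `ceiling(2n/3)` values
#' above threshold.
#'
#' @param values numeric replicate FPKMs for one group (length >= 2).
#' @param threshold FPKM cutoff (default 0.1).
#' @return logical flag.
#' @export
expressed_call <- function(values, threshold = 0.1) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 replicates")
  sum(values > threshold) >= ceiling(2 * n / 3)
}

#' Group-wise expressed flags for every transcript
#' @param expr an [expression_table].
#' @param threshold FPKM cutoff.
#' @return logical matrix transcripts x groups.
#' @export
expressed_flags <- function(expr, threshold = 0.1) {
  groups <- unique(expr$design$group)
  out <- sapply(groups, function(g) {
    sub <- expr$fpkm[, group_samples(expr, g), drop = FALSE]
    apply(sub, 1L, expressed_call, threshold = threshold)
  })
  rownames(out) <- rownames(expr$fpkm)
  out
}

#' Differential expression between two groups
#'
#' Per transcript: fold change `(mean_B + eps) / (mean_A + eps)`, a Welch t
#' test on `log2(FPKM + eps)`, Benjamini-Hochberg FDR across all tested
#' transcripts, and a significance flag per the study rule: more than
#' 2-fold change and FDR below 0.05. When both groups are constant with
#' equal means the p-value is 1.
#'
#' @param expr an [expression_table].
#' @param group_a,group_b group labels (fold is B over A).
#' @param eps FPKM offset guarding against zeros (default 0.01).
#' @param fold_cutoff,fdr_cutoff significance rule (defaults 2 and 0.05).
#' @return data.frame: `transcript_id`, `log2_fold_change`, `p_value`,
#'   `fdr`, `significant`.
#' @export
differential_expression <- function(expr, group_a, group_b, eps = 0.01,
                                    fold_cutoff = 2, fdr_cutoff = 0.05) {
  a <- expr$fpkm[, group_samples(expr, group_a), drop = FALSE]
  b <- expr$fpkm[, group_samples(expr, group_b), drop = FALSE]
  la <- log2(a + eps); lb <- log2(b + eps)
  fold <- (rowMeans(b) + eps) / (rowMeans(a) + eps)
  p <- vapply(seq_len(nrow(expr$fpkm)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      if (mean(xa) == mean(xb)) return(1)
      return(0)
    }
    stats::t.test(xb, xa, var.equal = FALSE)$p.value
  }, 0)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(transcript_id = rownames(expr$fpkm),
             log2_fold_change = log2(fold),
             p_value = p, fdr = fdr,
             significant = (fold > fold_cutoff | fold < 1 / fold_cutoff) &
               fdr < fdr_cutoff)
}

#' Tissue-enrichment pattern from group expressed flags
#'
#' Presence/absence taxonomy over the three groups (EH embryonic heart,
#' AH adult heart, AM adult muscle):
#' heart-expressed = EH or AH; cardiac-specific = heart-expressed and not AM,
#' subdivided into adult-only, embryonic-only and heart-both;
#' muscle-enriched = AM only; everything else expressed somewhere is shared;
#' transcripts expressed nowhere are `not_expressed`.
#'
#' @param eh,ah,am logical expressed flags.
#' @return character pattern: one of `heart_specific_adult`,
#'   `heart_specific_embryonic`, `heart_both`, `muscle_enriched`, `shared`,
#'   `not_expressed`.
#' @export
classify_tissue_pattern <- function(eh, ah, am) {
  if (!eh && !ah && !am) return("not_expressed")
  if (ah && !eh && !am) return("heart_specific_adult")
  if (eh && !ah && !am) return("heart_specific_embryonic")
  if (eh && ah && !am) return("heart_both")
  if (am && !eh && !ah) return("muscle_enriched")
  "shared"
}

#' Fetal gene-program call
#'
#' A transcript belongs to the fetal program when its expression differs at
#' least `fold`-fold (closed threshold) between embryonic and adult heart:
#' `(EH + eps) / (AH + eps) >= fold` (embryonic-high) or `<= 1/fold`
#' (adult-high).
#'
#' @param eh_mean,ah_mean group mean FPKMs.
#' @param fold fold threshold (default 4).
#' @param eps FPKM offset (default 0.01).
#' @return list with `fetal` flag and `direction`
#'   (`embryonic_high`/`adult_high`/`none`).
#' @export
fetal_program <- function(eh_mean, ah_mean, fold = 4, eps = 0.01) {
  ratio <- (eh_mean + eps) / (ah_mean + eps)
  if (ratio >= fold) list(fetal = TRUE, direction = "embryonic_high")
  else if (ratio <= 1 / fold) list(fetal = TRUE, direction = "adult_high")
  else list(fetal = FALSE, direction = "none")
}

#' Molecular-property profile per transcript class
#'
#' For each class (protein-coding, known lincRNA, novel lincRNA) tabulates
#' exon count, spliced length, mean FPKM (reported only for transcripts with
#' a group mean above `fpkm_min` in at least one group) and transcript
#' conservation score, one row per transcript.
#'
#' @param class_map named character vector transcript_id -> class label.
#' @param models list of [transcript_model] (superset of `class_map` ids).
#' @param expr an [expression_table].
#' @param track a [conservation_track], or `NULL` to skip conservation.
#' @param fpkm_min inclusion cutoff for the FPKM column (default 0.1).
#' @return data.frame: `transcript_id`, `class`, `n_exons`, `length`,
#'   `mean_fpkm` (NA when below cutoff everywhere), `conservation`.
#' @export
molecular_profile <- function(class_map, models, expr, track = NULL,
                              fpkm_min = 0.1) {
  idx <- stats::setNames(seq_along(models),
                         vapply(models, `[[`, "", "transcript_id"))
  gm <- group_means(expr)
  rows <- lapply(names(class_map), function(tid) {
    m <- models[[idx[[tid]]]]
    mf <- if (tid %in% rownames(gm) && max(gm[tid, ]) > fpkm_min)
      mean(expr$fpkm[tid, ]) else NA_real_
    cons <- if (is.null(track)) NA_real_
    else transcript_conservation(m, track)
    data.frame(transcript_id = tid, class = class_map[[tid]],
               n_exons = nrow(m$exons), length = transcript_length(m),
               mean_fpkm = mf,
               conservation = if (is.na(cons)) NA_real_ else cons)
  })
  out <- do.call(rbind, rows)
  empty <- setdiff(unique(class_map), out$class)
  if (length(empty)) warning(sprintf("empty class(es): %s",
                                     paste(empty, collapse = ", ")))
  rownames(out) <- NULL
  out
}

#' Relative quantification by the -ddCt method
#'
#' Fold change `2^(-ddCt)` with
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#'         (Ct_target,control - Ct_ref,control)`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (finite).
#' @return fold change.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated,
           ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
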