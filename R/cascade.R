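#' Default filtering thresholds
#'
#' Every numeric threshold of the identification cascade, explicit and
#' overridable: minimum length 200 nt, minimum 2 exons, FPKM 0.1 with the
#' "2 of 3 replicates" rule by default (the max-group-mean rule is
#' selectable), Pfam P 1e-5, CPC 0, PhyloCSF 20; the CPAT-style cutoff
#' defaults to the fitted model's sensitivity = specificity point
#' (`cpat_cutoff = NULL`).
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_length = 200L, min_exons = 2L, fpkm = 0.1,
       expr_rule = "2of3",        # or "mean": max group mean > fpkm
       cpat_cutoff = NULL, pfam_p = 1e-5, cpc = 0, phylocsf = 20)
}

#' Run the six-filter lincRNA identification cascade
#'
#' Filters an assembled transcriptome down to a lincRNA catalog with a
#' complete audit trail:
#' \enumerate{
#'   \item remove transcripts overlapping known protein-coding genes
#'     (class `=` or `o` against the coding reference);
#'   \item remove transcripts with a single exon, length under 200 nt, or
#'     no expression (per `expr_rule`);
#'   \item set aside transcripts matching a reference lincRNA annotation as
#'     known lincRNAs (first reference set takes precedence); known
#'     lincRNAs bypass the coding-potential gates;
#'   \item CPAT-style gate: remove candidates with coding probability at or
#'     above the cutoff;
#'   \item Pfam gate: remove candidates with a significant protein-domain
#'     hit (P below `pfam_p`);
#'   \item CPC gate: remove candidates with CPC score at or above `cpc`;
#'   \item PhyloCSF gate: remove candidates scoring at or above `phylocsf`.
#' }
#' Survivors are novel lincRNAs; the catalog is the union of known and
#' novel. Missing external scores pass their gate.
#'
#' @param assembly list of [transcript_model].
#' @param reference_coding list of coding reference [transcript_model].
#' @param reference_linc_sets named list of reference lincRNA model lists,
#'   in precedence order (e.g. `list(ensembl = ..., zflncrnapedia = ...)`).
#' @param expr an [expression_table] covering the assembly ids.
#' @param reports data.frame with `transcript_id`, `coding_probability`,
#'   `pfam_p`, `cpc_score`, `phylocsf_score` (NA = missing score).
#' @param thresholds list from [default_thresholds].
#' @return list with `catalog` (data.frame: `transcript_id`, `status`,
#'   `class_code`, `matched_reference_id`) and `audit` (data.frame: `step`,
#'   `n_in`, `n_removed`, `n_out`, `removed_ids`).
#' @export
run_cascade <- function(assembly, reference_coding, reference_linc_sets,
                        expr, reports, thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  if (is.null(th$cpat_cutoff))
    stop("config error: cpat_cutoff must be set (fit_coding_model provides one)")
  ids <- vapply(assembly, `[[`, "", "transcript_id")
  names(assembly) <- ids
  rep_idx <- match(ids, reports$transcript_id)

  audit <- data.frame(step = character(0), n_in = integer(0),
                      n_removed = integer(0), n_out = integer(0),
                      removed_ids = character(0))
  log_step <- function(step, pool, removed) {
    audit <<- rbind(audit, data.frame(
      step = step, n_in = length(pool), n_removed = length(removed),
      n_out = length(pool) - length(removed),
      removed_ids = paste(removed, collapse = ",")))
    setdiff(pool, removed)
  }

  # filter 1: overlap with protein-coding reference
  codes <- lapply(assembly, classify_against_reference, reference_coding)
  code_chr <- vapply(codes, `[[`, "", "code")
  pool <- ids
  pool <- log_step("overlap_coding", pool, ids[code_chr != "u"])

  # filter 2: structure and expression
  flags <- expressed_flags(expr, threshold = th$fpkm)
  gm <- group_means(expr)
  expressed_ok <- if (th$expr_rule == "mean") {
    apply(gm > th$fpkm, 1L, any)
  } else {
    apply(flags, 1L, any)
  }
  bad_structure <- vapply(pool, function(tid) {
    m <- assembly[[tid]]
    nrow(m$exons) < th$min_exons ||
      transcript_length(m) < th$min_length ||
      !expressed_ok[[tid]]
  }, TRUE)
  pool <- log_step("structure_expression", pool, pool[bad_structure])

  # set aside known lincRNAs (reference sets in precedence order)
  known_status <- character(0); known_match <- character(0)
  known_ids <- character(0)
  remaining <- pool
  for (ref_name in names(reference_linc_sets)) {
    hits <- vapply(remaining, function(tid) {
      cc <- classify_against_reference(assembly[[tid]],
                                       reference_linc_sets[[ref_name]])
      if (cc$code == "u") NA_character_ else cc$matched_reference_id
    }, NA_character_)
    found <- remaining[!is.na(hits)]
    known_ids <- c(known_ids, found)
    known_status <- c(known_status, rep(paste0("known_", ref_name),
                                        length(found)))
    known_match <- c(known_match, hits[!is.na(hits)])
    remaining <- setdiff(remaining, found)
  }
  pool <- log_step("known_setaside", pool, known_ids)

  # filters 3-6: coding-potential gates on the novel candidates
  rp <- reports[rep_idx, ]
  rownames(rp) <- ids
  gate <- function(pool, step, removed_if) {
    vals <- rp[pool, ]
    rm_ids <- pool[removed_if(vals)]
    log_step(step, pool, rm_ids)
  }
  pool <- gate(pool, "cpat", function(v)
    !is.na(v$coding_probability) & v$coding_probability >= th$cpat_cutoff)
  pool <- gate(pool, "pfam", function(v)
    !is.na(v$pfam_p) & v$pfam_p < th$pfam_p)
  pool <- gate(pool, "cpc", function(v)
    !is.na(v$cpc_score) & v$cpc_score >= th$cpc)
  pool <- gate(pool, "phylocsf", function(v)
    !is.na(v$phylocsf_score) & v$phylocsf_score >= th$phylocsf)

  catalog <- rbind(
    if (length(known_ids))
      data.frame(transcript_id = known_ids, status = known_status,
                 class_code = code_chr[known_ids],
                 matched_reference_id = known_match),
    if (length(pool))
      data.frame(transcript_id = pool, status = "novel",
                 class_code = code_chr[pool],
                 matched_reference_id = NA_character_))
  rownames(catalog) <- NULL
  list(catalog = catalog, audit = audit)
}
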