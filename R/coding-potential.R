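#' Longest open reading frame
#'
#' Scans the three forward frames of the given (sense) sequence for the
#' longest span `ATG ... in-frame stop` (TAA/TAG/TGA). The reported length
#' includes the stop codon. When several ATGs open onto the same stop the
#' earliest is used; ties across frames go to the smallest start. Codons
#' containing `N` are skipped: they neither start, extend nor close an ORF,
#' and any ORF would have to restart after them.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @return list with `start` (0-based), `end` (exclusive), `frame` (0..2),
#'   `size` (nt), or `NULL` when no complete ORF exists.
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN symbols")
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    open_start <- NA_integer_
    i <- frame
    while (i + 3L <= n) {
      codon <- substr(seq, i + 1L, i + 3L)
      if (grepl("N", codon, fixed = TRUE)) {
        open_start <- NA_integer_
      } else if (codon %in% c("TAA", "TAG", "TGA")) {
        if (!is.na(open_start)) {
          size <- i + 3L - open_start
          if (is.null(best) || size > best$size ||
              (size == best$size && open_start < best$start))
            best <- list(start = open_start, end = i + 3L,
                         frame = frame, size = size)
          open_start <- NA_integer_
        }
      } else if (codon == "ATG" && is.na(open_start)) {
        open_start <- i
      }
      i <- i + 3L
    }
  }
  best
}

# Fickett (1982) TESTCODE lookup tables, as distributed with CPAT.
# Rows are the 10 parameter intervals; the *_para vectors give the interval
# lower bounds checked in order (first threshold <= value wins).
fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
fickett_position_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
fickett_content_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21,
                          0.19, 0.17, 0.0)

fickett_lookup <- function(value, para, prob, weight) {
  idx <- which(value >= para)[1L]
  prob[idx] * weight
}

#' Fickett TESTCODE statistic
#'
#' The classic TESTCODE score: for each base the position parameter
#' (max over the three codon-frame counts divided by min + 1) and the
#' content parameter (base frequency) are converted to probability-of-coding
#' weights through the published lookup tables and summed. Values above
#' ~0.74 indicate coding in the original calibration. `N` bases are excluded
#' from both counts.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @return numeric score.
#' @export
fickett_testcode <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN symbols")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  keep <- chars != "N"
  phase <- (seq_along(chars) - 1L) %% 3L
  chars <- chars[keep]; phase <- phase[keep]
  total <- length(chars)
  if (total == 0L) return(0)
  score <- 0
  for (base in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(chars == base & phase == p), 0L)
    position_par <- max(cnt) / (min(cnt) + 1)
    content_par <- sum(cnt) / total
    score <- score +
      fickett_lookup(position_par, fickett_position_para,
                     fickett_position_prob[[base]],
                     fickett_position_weight[[base]]) +
      fickett_lookup(content_par, fickett_content_para,
                     fickett_content_prob[[base]],
                     fickett_content_weight[[base]])
  }
  score
}

#' Train a hexamer usage table
#'
#' Counts sliding (step 1) hexamers over each training set, adds a
#' pseudocount to every one of the 4^6 hexamers, and normalizes to
#' frequencies. Hexamers containing `N` are skipped.
#'
#' @param coding_seqs,noncoding_seqs character vectors of training sequences.
#' @param pseudocount added to every hexamer count (default 1).
#' @return a `hexamer_table`: list with `coding` and `noncoding` named
#'   frequency vectors over all 4096 hexamers, each summing to 1.
#' @export
train_hexamer_table <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (length(coding_seqs) == 0L || length(noncoding_seqs) == 0L)
    stop("both training sets must be non-empty")
  all_hex <- all_hexamers()
  count_set <- function(seqs) {
    counts <- stats::setNames(rep(pseudocount, length(all_hex)), all_hex)
    for (s in seqs) {
      h <- sliding_hexamers(toupper(s), step = 1L)
      if (length(h) == 0L) next
      t <- table(h)
      counts[names(t)] <- counts[names(t)] + as.vector(t)
    }
    counts / sum(counts)
  }
  structure(list(coding = count_set(coding_seqs),
                 noncoding = count_set(noncoding_seqs)),
            class = "hexamer_table")
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  # fastest-varying first so order is deterministic but arbitrary
  apply(g[, 6:1], 1L, paste, collapse = "")
}

sliding_hexamers <- function(seq, step = 1L) {
  n <- nchar(seq)
  if (n < 6L) return(character(0))
  starts <- seq.int(1L, n - 5L, by = step)
  h <- substring(seq, starts, starts + 5L)
  h[!grepl("N", h, fixed = TRUE)]
}

#' Hexamer usage bias score
#'
#' Average log-likelihood ratio (base e) of hexamer frequencies under the
#' coding versus noncoding background models. When the sequence contains a
#' complete ORF the in-frame (step 3) hexamers of the longest ORF are
#' scored; otherwise all sliding hexamers of the transcript are used.
#'
#' @param seq nucleotide string.
#' @param table a `hexamer_table` from [train_hexamer_table].
#' @param orf optional precomputed [longest_orf] result (`NULL` to compute).
#' @return mean log(f_coding/f_noncoding) over scored hexamers; 0 with a
#'   warning when nothing is scorable.
#' @export
hexamer_score <- function(seq, table, orf = longest_orf(seq)) {
  seq <- toupper(seq)
  if (!is.null(orf)) {
    region <- substr(seq, orf$start + 1L, orf$end)
    hex <- sliding_hexamers(region, step = 3L)
  } else {
    hex <- sliding_hexamers(seq, step = 1L)
  }
  if (length(hex) == 0L) {
    warning("no scorable hexamers; returning 0")
    return(0)
  }
  mean(log(table$coding[hex] / table$noncoding[hex]))
}

#' Compute coding-potential features for one transcript
#'
#' @param transcript_id id to report.
#' @param seq spliced transcript sequence.
#' @param hex_table a `hexamer_table`.
#' @return one-row data.frame: `transcript_id`, `orf_size`, `orf_coverage`,
#'   `fickett_score`, `hexamer_score`.
#' @export
coding_features <- function(transcript_id, seq, hex_table) {
  orf <- longest_orf(seq)
  orf_size <- if (is.null(orf)) 0L else orf$size
  data.frame(transcript_id = transcript_id,
             orf_size = orf_size,
             orf_coverage = orf_size / nchar(seq),
             fickett_score = fickett_testcode(seq),
             hexamer_score = suppressWarnings(
               hexamer_score(seq, hex_table, orf = orf)))
}

#' Fit the logistic coding/noncoding combiner
#'
#' Standard logistic regression of the coding label on the four features
#' (`orf_size`, `orf_coverage`, `fickett_score`, `hexamer_score`). On
#' perfect separation (or non-convergence) the fit falls back to a small
#' L2-regularized (ridge) fit, with a message. The default classification
#' threshold is placed where training sensitivity equals specificity.
#'
#' @param features data.frame from [coding_features] rows.
#' @param labels logical vector, `TRUE` = coding.
#' @return a `coding_model`: list with `coefficients` (named, incl.
#'   `(Intercept)`), `threshold`, and `regularized` flag.
#' @export
fit_coding_model <- function(features, labels) {
  stopifnot(nrow(features) == length(labels))
  if (sum(labels) < 20L || sum(!labels) < 20L)
    stop("need at least 20 labeled examples per class")
  feats <- c("orf_size", "orf_coverage", "fickett_score", "hexamer_score")
  df <- features[, feats]
  df$y <- as.integer(labels)
  regularized <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        regularized <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (regularized) {
    message("perfect separation detected; refitting with ridge penalty")
    x <- as.matrix(features[, feats])
    gfit <- glmnet::glmnet(x, df$y, family = "binomial", alpha = 0,
                           lambda = 1e-3, standardize = TRUE)
    coefs <- as.numeric(stats::coef(gfit))
    names(coefs) <- rownames(stats::coef(gfit))
  } else {
    coefs <- stats::coef(fit)
  }
  model <- structure(list(coefficients = coefs, threshold = 0.5,
                          regularized = regularized),
                     class = "coding_model")
  probs <- coding_probability(features, model)
  model$threshold <- sens_eq_spec_threshold(probs, labels)
  model
}

# threshold where sensitivity equals specificity on the training data
sens_eq_spec_threshold <- function(probs, labels) {
  cand <- sort(unique(c(0, probs, 1)))
  gaps <- vapply(cand, function(th) {
    sens <- mean(probs[labels] >= th)
    spec <- mean(probs[!labels] < th)
    abs(sens - spec)
  }, 0)
  cand[which.min(gaps)]
}

#' Coding probability under a fitted combiner
#' @param features data.frame with the four feature columns (one or more rows).
#' @param model a `coding_model` from [fit_coding_model].
#' @return numeric vector of probabilities in [0,1].
#' @export
coding_probability <- function(features, model) {
  feats <- c("orf_size", "orf_coverage", "fickett_score", "hexamer_score")
  x <- cbind(1, as.matrix(features[, feats, drop = FALSE]))
  eta <- as.vector(x %*% model$coefficients[c("(Intercept)", feats)])
  stats::plogis(eta)
}

#' Apply the external coding-evidence gates
#'
#' Decides removal under the three external filters: a transcript is removed
#' when its Pfam P-value is below `pfam_p` (significant protein-domain hit),
#' when its CPC score is at or above `cpc` (CPC calls scores >= 0 coding),
#' or when its PhyloCSF score is at or above `phylocsf`. Missing scores pass
#' the corresponding gate: the filters act only on positive evidence of
#' coding.
#'
#' @param transcript_ids character vector.
#' @param pfam_p,cpc_score,phylocsf_score named numeric vectors (may lack
#'   some ids).
#' @param thresholds list with `pfam_p` (default 1e-5), `cpc` (0),
#'   `phylocsf` (20).
#' @return data.frame with logical columns `pfam_removed`, `cpc_removed`,
#'   `phylocsf_removed`.
#' @export
apply_external_gates <- function(transcript_ids, pfam_p, cpc_score,
                                 phylocsf_score,
                                 thresholds = list(pfam_p = 1e-5, cpc = 0,
                                                   phylocsf = 20)) {
  gate <- function(scores, fun) {
    vals <- scores[transcript_ids]
    out <- !is.na(vals) & fun(vals)
    unname(out)
  }
  data.frame(
    transcript_id = transcript_ids,
    pfam_removed = gate(pfam_p, function(v) v < thresholds$pfam_p),
    cpc_removed = gate(cpc_score, function(v) v >= thresholds$cpc),
    phylocsf_removed = gate(phylocsf_score,
                            function(v) v >= thresholds$phylocsf))
}
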