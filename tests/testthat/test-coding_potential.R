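test_that("longest ORF scanning handles simple and degenerate cases", {
  orf <- longest_orf("ATGAAATAA")
  expect_equal(orf$start, 0L)
  expect_equal(orf$end, 9L)
  expect_equal(orf$frame, 0L)
  expect_equal(orf$size, 9L)
  expect_null(longest_orf("CCCCCC"))
  # N inside the span invalidates the ORF
  expect_null(longest_orf("ATGANATAA"))
  expect_error(longest_orf("ATGXXX"), "non-ACGTN")
})

test_that("longest ORF equals the exhaustive start-codon scan", {
  set.seed(51)
  for (i in 1:200) {
    seq <- random_dna(sample(30:300, 1),
                      alphabet = c("A", "C", "G", "T",
                                   if (i %% 5 == 0) "N"))
    got <- longest_orf(seq)
    want <- oracle_longest_orf(seq)
    if (is.null(want)) expect_null(got)
    else {
      expect_equal(got$size, want$size)
      expect_equal(got$start, want$start)
    }
  }
})

test_that("Fickett TESTCODE matches the published-table oracle", {
  # period-4 sequence balances codon-frame usage: noncoding regime
  per4 <- strrep("ACGT", 75)
  expect_lt(fickett_testcode(per4), 0.74)
  expect_equal(fickett_testcode(per4), oracle_fickett(per4),
               tolerance = 1e-12)
  # duplication leaves composition and periodicity unchanged (frame-biased
  # sequence keeps every lookup parameter in the same table bin)
  seq <- strrep("ACG", 80)
  expect_equal(fickett_testcode(seq), fickett_testcode(strrep(seq, 2)),
               tolerance = 1e-12)
  set.seed(61)
  for (i in 1:200) {
    s <- random_dna(sample(200:400, 1))
    expect_equal(fickett_testcode(s), oracle_fickett(s), tolerance = 1e-12)
  }
  expect_error(fickett_testcode("ACGU"), "non-ACGTN")
})

test_that("hexamer score is the mean log ratio and is antisymmetric", {
  set.seed(71)
  coding <- replicate(5, random_dna(300))
  noncoding <- replicate(5, random_dna(300))
  # identical training sets: every score 0
  same <- train_hexamer_table(coding, coding)
  expect_equal(hexamer_score(random_dna(100), same), 0, tolerance = 1e-12)
  # synthetic table with f_c = 2 f_nc everywhere: score log 2
  tab <- train_hexamer_table(coding, noncoding)
  tab$coding <- rep(1 / 4096, 4096); names(tab$coding) <- names(tab$noncoding)
  tab$noncoding <- tab$coding / 2
  expect_equal(hexamer_score("ACGTACGTACGT", tab, orf = NULL), log(2),
               tolerance = 1e-12)
  # antisymmetry under swapping training sets
  fwd <- train_hexamer_table(coding, noncoding)
  rev <- train_hexamer_table(noncoding, coding)
  for (i in 1:20) {
    s <- random_dna(150)
    expect_equal(hexamer_score(s, fwd), -hexamer_score(s, rev),
                 tolerance = 1e-12)
  }
  # direct-formula oracle on in-frame ORF hexamers
  s <- "ATGAAACCCGGGTTTTAA"
  orf <- longest_orf(s)
  hexes <- substring(s, seq(1, nchar(s) - 5, by = 3),
                     seq(6, nchar(s), by = 3))
  want <- mean(log(fwd$coding[hexes] / fwd$noncoding[hexes]))
  expect_equal(hexamer_score(s, fwd), unname(want), tolerance = 1e-12)
})

test_that("planted coding and noncoding transcripts separate on hexamer score", {
  ds <- default_dataset()
  seqs <- vapply(ds$assembly, extract_spliced_sequence, "",
                 genome = ds$genome)
  cls <- ds$truth$true_class
  tab <- train_hexamer_table(seqs[cls == "coding"],
                             seqs[cls == "lincRNA_known"])
  score <- vapply(seqs, function(s)
    suppressWarnings(hexamer_score(s, tab)), 0)
  cod <- score[cls == "coding"]
  non <- score[cls == "lincRNA_novel"]
  pooled_sd <- sqrt((stats::var(cod) + stats::var(non)) / 2)
  expect_gt((mean(cod) - mean(non)) / pooled_sd, 2)
})

test_that("logistic combiner behaves sanely and classifies held-out truth", {
  zero <- structure(list(coefficients = c(`(Intercept)` = 0, orf_size = 0,
                                          orf_coverage = 0,
                                          fickett_score = 0,
                                          hexamer_score = 0),
                         threshold = 0.5, regularized = FALSE),
                    class = "coding_model")
  f <- data.frame(orf_size = 500, orf_coverage = 0.5, fickett_score = 1,
                  hexamer_score = 2)
  expect_equal(coding_probability(f, zero), 0.5)

  ds <- default_dataset()
  seqs <- vapply(ds$assembly, extract_spliced_sequence, "",
                 genome = ds$genome)
  names(seqs) <- ds$truth$transcript_id
  cls <- ds$truth$true_class
  train_idx <- which(cls %in% c("coding", "lincRNA_known"))
  tab <- train_hexamer_table(seqs[cls == "coding"],
                             seqs[cls == "lincRNA_known"])
  feats <- do.call(rbind, lapply(seq_along(seqs), function(i)
    coding_features(names(seqs)[i], seqs[i], tab)))
  model <- suppressMessages(
    fit_coding_model(feats[train_idx, ], cls[train_idx] == "coding"))
  # held out: novel lincs (noncoding) and artifacts were never trained on
  held <- which(cls == "lincRNA_novel")
  p_held <- coding_probability(feats[held, ], model)
  expect_gte(mean(p_held < model$threshold), 0.9)
  # monotonicity in orf_size given a positive fitted weight
  w <- model$coefficients[["orf_size"]]
  base <- feats[held[1], ]
  bigger <- base; bigger$orf_size <- bigger$orf_size + 300
  if (w > 0) expect_gte(coding_probability(bigger, model),
                        coding_probability(base, model))
  else expect_lte(coding_probability(bigger, model),
                  coding_probability(base, model))
})

test_that("external gates remove only on positive evidence of coding", {
  ids <- c("a", "b", "c", "d")
  g <- apply_external_gates(
    ids,
    pfam_p = c(a = 1e-6, b = 1e-5, c = 0.5),
    cpc_score = c(a = 1, b = -2, c = 0),
    phylocsf_score = c(a = 100, b = 19.9, c = 20))
  expect_true(g$pfam_removed[g$transcript_id == "a"])    # P < 1e-5
  expect_false(g$pfam_removed[g$transcript_id == "b"])   # boundary open
  expect_false(g$phylocsf_removed[g$transcript_id == "b"])  # 19.9 retained
  expect_true(g$phylocsf_removed[g$transcript_id == "c"])   # threshold closed
  expect_true(g$cpc_removed[g$transcript_id == "c"])        # CPC >= 0 coding
  # all scores missing: retained everywhere
  expect_false(any(unlist(g[g$transcript_id == "d",
                            c("pfam_removed", "cpc_removed",
                              "phylocsf_removed")])))
})
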