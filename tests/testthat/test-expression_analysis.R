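test_that("expressed call implements the 2-of-3 replicate rule", {
  expect_true(expressed_call(c(0.05, 0.2, 0.3)))
  expect_false(expressed_call(c(0.05, 0.05, 5.0)))
  expect_true(expressed_call(c(127, 120, 130)))     # housekeeping-level FPKM
  expect_false(expressed_call(c(0.1, 0.1, 0.1)))    # strictly greater than
  expect_true(expressed_call(c(0.2, 0.2, 0.05, 0.05, 0.2, 0.2)))  # 4 of 6
  expect_error(expressed_call(0.5), "2 replicates")
})

test_that("differential expression flags planted fold changes", {
  set.seed(7)
  n_null <- 60; n_de <- 40
  base <- 10
  fpkm <- rbind(
    matrix(2^(log2(base) + rnorm(n_null * 6, sd = 0.25)), n_null, 6),
    cbind(matrix(2^(log2(base) + rnorm(n_de * 3, sd = 0.25)), n_de, 3),
          matrix(2^(log2(base * 8) + rnorm(n_de * 3, sd = 0.25)), n_de, 3)))
  rownames(fpkm) <- sprintf("t%03d", seq_len(n_null + n_de))
  colnames(fpkm) <- paste0(rep(c("A", "B"), each = 3), "_", 1:3)
  design <- data.frame(sample = colnames(fpkm),
                       group = rep(c("A", "B"), each = 3),
                       replicate = rep(1:3, 2))
  expr <- expression_table(fpkm, design)
  de <- differential_expression(expr, "A", "B")
  planted <- seq_len(n_de) + n_null
  expect_gte(mean(de$significant[planted]), 0.9)
  expect_lte(mean(de$significant[seq_len(n_null)]), 0.1)
  # identical groups: fold 1, not significant
  same <- expression_table(matrix(5, 2, 6, dimnames = list(c("x", "y"),
                                                           colnames(fpkm))),
                           design)
  de0 <- differential_expression(same, "A", "B")
  expect_equal(de0$log2_fold_change, c(0, 0))
  expect_false(any(de0$significant))
})

test_that("BH adjustment equals the step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(stats::p.adjust(p, method = "BH"), oracle_bh(p))
  expect_equal(stats::p.adjust(p, method = "BH")[1:3],
               c(0.04, 0.04, 0.04))
  set.seed(81)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))
    adj <- stats::p.adjust(p, method = "BH")
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("tissue patterns follow the presence/absence taxonomy", {
  expect_equal(classify_tissue_pattern(FALSE, TRUE, FALSE),
               "heart_specific_adult")
  expect_equal(classify_tissue_pattern(TRUE, FALSE, FALSE),
               "heart_specific_embryonic")
  expect_equal(classify_tissue_pattern(TRUE, TRUE, FALSE), "heart_both")
  expect_equal(classify_tissue_pattern(FALSE, FALSE, TRUE),
               "muscle_enriched")
  expect_equal(classify_tissue_pattern(TRUE, TRUE, TRUE), "shared")
  expect_equal(classify_tissue_pattern(TRUE, FALSE, TRUE), "shared")
  expect_equal(classify_tissue_pattern(FALSE, FALSE, FALSE),
               "not_expressed")
})

test_that("fetal program uses a closed 4-fold threshold and is symmetric", {
  expect_true(fetal_program(8, 1)$fetal)
  expect_equal(fetal_program(8, 1)$direction, "embryonic_high")
  expect_false(fetal_program(3, 1)$fetal)
  # boundary: exactly 4-fold is fetal ("at least 4-fold")
  edge <- fetal_program(4 * (1 + 0.01) - 0.01, 1)
  expect_true(edge$fetal)
  set.seed(91)
  for (i in 1:30) {
    a <- runif(1, 0, 50); b <- runif(1, 0, 50)
    fwd <- fetal_program(a, b); rev <- fetal_program(b, a)
    expect_equal(fwd$fetal, rev$fetal)
    if (fwd$fetal)
      expect_true(setequal(c(fwd$direction, rev$direction),
                           c("embryonic_high", "adult_high")) ||
                    fwd$direction == rev$direction)
  }
})

test_that("molecular profile summarizes classes and applies the FPKM rule", {
  ds <- default_dataset()
  truth <- ds$truth
  class_map <- stats::setNames(truth$true_class, truth$transcript_id)
  class_map <- class_map[class_map %in% c("coding", "lincRNA_known",
                                          "lincRNA_novel")]
  prof <- molecular_profile(class_map, ds$assembly, ds$expr, ds$track)
  one <- prof[prof$transcript_id == prof$transcript_id[1], ]
  m <- Filter(function(x) x$transcript_id == one$transcript_id,
              ds$assembly)[[1]]
  expect_equal(one$n_exons, nrow(m$exons))
  expect_equal(one$length, transcript_length(m))
  # directional structure checks mirror the study's profiles
  by_class <- split(prof, prof$class)
  expect_gt(mean(by_class$coding$length),
            mean(by_class$lincRNA_novel$length))
  expect_gt(mean(by_class$coding$n_exons),
            mean(by_class$lincRNA_known$n_exons))
  # low-expression transcripts get NA in the FPKM column
  gm <- group_means(ds$expr)
  low <- rownames(gm)[apply(gm, 1, max) <= 0.1]
  low <- intersect(low, prof$transcript_id)
  if (length(low))
    expect_true(all(is.na(prof$mean_fpkm[prof$transcript_id %in% low])))
})

test_that("tissue and fetal calls recover the planted truth", {
  ds <- default_dataset()
  truth <- ds$truth
  lincs <- truth[truth$true_class %in% c("lincRNA_known", "lincRNA_novel"), ]
  flags <- expressed_flags(ds$expr)
  gm <- group_means(ds$expr)
  pat <- vapply(lincs$transcript_id, function(tid)
    classify_tissue_pattern(flags[tid, "EH"], flags[tid, "AH"],
                            flags[tid, "AM"]), "")
  expect_gte(mean(pat == lincs$pattern), 0.95)
  fet <- vapply(lincs$transcript_id, function(tid)
    fetal_program(gm[tid, "EH"], gm[tid, "AH"])$fetal, TRUE)
  expect_gte(mean(fet == lincs$fetal), 0.95)
})

test_that("-ddCt fold changes follow 2^(-ddCt)", {
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1)
  expect_equal(ddct_fold_change(19, 20, 20, 20), 2)   # ddCt = -1
  expect_equal(ddct_fold_change(22, 20, 20, 20), 0.25) # ddCt = 2
  expect_error(ddct_fold_change(Inf, 20, 20, 20), "finite")
})
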