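# a tiny hand-built cascade scenario: one coding overlap, one single-exon
# artifact, one short artifact, one unexpressed, one known linc, one novel
# candidate per gate
tiny_cascade_inputs <- function() {
  ref_coding <- list(make_model("refC", "chr1", "+", c(1000L, 2000L),
                                c(1500L, 2600L), gene = "gc",
                                biotype = "protein_coding",
                                source = "ensembl_ref"))
  ref_linc <- list(make_model("refL", "chr1", "+", c(50000L, 51000L),
                              c(50400L, 51500L), gene = "gl",
                              biotype = "lincRNA", source = "ensembl_ref"))
  assembly <- list(
    make_model("t_overlap", "chr1", "+", c(1000L, 2000L), c(1500L, 2600L)),
    make_model("t_single", "chr1", "+", 10000L, 15000L),
    make_model("t_short", "chr1", "+", c(20000L, 20300L),
               c(20090L, 20380L)),
    make_model("t_silent", "chr1", "+", c(30000L, 31000L),
               c(30400L, 31500L)),
    make_model("t_known", "chr1", "+", c(50000L, 51000L),
               c(50400L, 51500L)),
    make_model("t_cpat", "chr1", "+", c(60000L, 61000L),
               c(60400L, 61500L)),
    make_model("t_pfam", "chr1", "+", c(70000L, 71000L),
               c(70400L, 71500L)),
    make_model("t_ok", "chr1", "+", c(80000L, 81000L),
               c(80400L, 81500L)))
  ids <- vapply(assembly, `[[`, "", "transcript_id")
  fpkm <- matrix(10, length(ids), 9,
                 dimnames = list(ids, paste0(rep(c("EH", "AH", "AM"),
                                                 each = 3), "_", 1:3)))
  fpkm["t_silent", ] <- 0.01
  design <- data.frame(sample = colnames(fpkm),
                       group = rep(c("EH", "AH", "AM"), each = 3),
                       replicate = rep(1:3, 3))
  reports <- data.frame(
    transcript_id = ids, coding_probability = 0.01,
    pfam_p = NA_real_, cpc_score = NA_real_, phylocsf_score = NA_real_)
  reports$coding_probability[ids == "t_cpat"] <- 0.99
  reports$pfam_p[ids == "t_pfam"] <- 1e-9
  reports$pfam_p[ids == "t_known"] <- 1e-9   # knowns bypass the gates
  list(assembly = assembly, ref_coding = ref_coding,
       ref_linc = list(ensembl = ref_linc),
       expr = expression_table(fpkm, design), reports = reports)
}

test_that("each filter removes exactly its planted offender", {
  x <- tiny_cascade_inputs()
  out <- run_cascade(x$assembly, x$ref_coding, x$ref_linc, x$expr,
                     x$reports, list(cpat_cutoff = 0.5))
  audit <- out$audit
  removed <- function(step)
    strsplit(audit$removed_ids[audit$step == step], ",")[[1]]
  expect_equal(removed("overlap_coding"), "t_overlap")
  expect_setequal(removed("structure_expression"),
                  c("t_single", "t_short", "t_silent"))
  expect_equal(removed("known_setaside"), "t_known")
  expect_equal(removed("cpat"), "t_cpat")
  expect_equal(removed("pfam"), "t_pfam")
  # the known lincRNA keeps its catalog slot despite its Pfam score
  expect_equal(out$catalog$status[out$catalog$transcript_id == "t_known"],
               "known_ensembl")
  expect_setequal(out$catalog$transcript_id, c("t_known", "t_ok"))
  expect_equal(out$catalog$status[out$catalog$transcript_id == "t_ok"],
               "novel")
})

test_that("a long, expressed single-exon transcript still fails filter 2", {
  x <- tiny_cascade_inputs()
  out <- run_cascade(x$assembly, x$ref_coding, x$ref_linc, x$expr,
                     x$reports, list(cpat_cutoff = 0.5))
  audit <- out$audit
  rm2 <- strsplit(audit$removed_ids[audit$step == "structure_expression"],
                  ",")[[1]]
  expect_true("t_single" %in% rm2)   # 5 kb, FPKM 10, but one exon
})

test_that("audit counts chain and the catalog partitions known/novel", {
  for (seed in c(4L, 12L, 23L)) {
    res <- run_all(list(seed = seed, generator = small_config(),
                        n_perm = 100L))
    a <- res$audit
    expect_equal(a$n_out, a$n_in - a$n_removed)
    expect_equal(a$n_in[-1], a$n_out[-nrow(a)])
    expect_true(all(diff(a$n_in) <= 0))
    known <- res$catalog$transcript_id[
      startsWith(res$catalog$status, "known")]
    novel <- res$catalog$transcript_id[res$catalog$status == "novel"]
    expect_length(intersect(known, novel), 0L)
    expect_equal(length(known) + length(novel), nrow(res$catalog))
  }
})

test_that("the cascade is idempotent on its own output", {
  x <- tiny_cascade_inputs()
  th <- list(cpat_cutoff = 0.5)
  out1 <- run_cascade(x$assembly, x$ref_coding, x$ref_linc, x$expr,
                      x$reports, th)
  keep <- out1$catalog$transcript_id
  sub_assembly <- Filter(function(m) m$transcript_id %in% keep, x$assembly)
  out2 <- run_cascade(sub_assembly, x$ref_coding, x$ref_linc, x$expr,
                      x$reports, th)
  expect_setequal(out2$catalog$transcript_id, keep)
  expect_equal(out2$catalog[order(out2$catalog$transcript_id), ],
               out1$catalog[order(out1$catalog$transcript_id), ],
               ignore_attr = TRUE)
})

test_that("missing CPAT cutoff is a config error", {
  x <- tiny_cascade_inputs()
  expect_error(run_cascade(x$assembly, x$ref_coding, x$ref_linc, x$expr,
                           x$reports, list()), "config error")
})
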