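identity_chain <- function(len = 1000L, chrom = "chr1", tchrom = "tchr") {
  chain_alignment("id", 1000,
    source = list(chrom = chrom, size = len, strand = "+", start = 0L,
                  end = len),
    target = list(chrom = tchrom, size = len, strand = "+", start = 0L,
                  end = len),
    blocks = data.frame(size = len, dt = 0L, dq = 0L))
}

test_that("identity chains project intervals unchanged", {
  ch <- identity_chain()
  out <- project_interval("chr1", 100L, 200L, ch)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 200L)
  expect_equal(out$chrom, "tchr")
})

test_that("intervals inside source gaps vanish", {
  ch <- chain_alignment("g", 1,
    source = list(chrom = "chr1", size = 1000L, strand = "+", start = 0L,
                  end = 300L),
    target = list(chrom = "t", size = 1000L, strand = "+", start = 0L,
                  end = 200L),
    blocks = data.frame(size = c(100L, 100L), dt = c(100L, 0L),
                        dq = c(0L, 0L)))
  expect_equal(nrow(project_interval("chr1", 120L, 180L, ch)), 0L)
  # straddling the gap yields two merged-from-runs pieces? no: target is
  # contiguous across this gap (dq = 0), so the runs merge into one
  out <- project_interval("chr1", 50L, 250L, ch)
  expect_equal(sum(out$end - out$start), 100L)
})

test_that("projection equals the per-base oracle, including - strand targets", {
  set.seed(171)
  for (i in 1:300) {
    ch <- random_chain()
    lo <- sample(0:250, 1)
    hi <- lo + sample(1:100, 1)
    got <- intervals_to_bases(project_interval("chr1", lo, hi, ch))
    want <- oracle_project("chr1", lo, hi, ch)
    expect_equal(got, want)
  }
})

test_that("round trip through the inverse chain restores mapped bases", {
  set.seed(181)
  for (i in 1:50) {
    ch <- random_chain()
    if (ch$target$strand == "-") next   # inverse defined for + targets here
    inv <- chain_alignment("inv", ch$score,
                           source = ch$target, target = ch$source,
                           blocks = data.frame(size = ch$blocks$size,
                                               dt = ch$blocks$dq,
                                               dq = ch$blocks$dt))
    inv$source$chrom <- ch$target$chrom
    lo <- sample(0:250, 1); hi <- lo + sample(1:100, 1)
    fwd <- project_interval("chr1", lo, hi, ch)
    back <- c(integer(0), unlist(lapply(seq_len(nrow(fwd)), function(j)
      intervals_to_bases(project_interval(fwd$chrom[j], fwd$start[j],
                                          fwd$end[j], inv)))))
    mapped_src <- intersect(lo:(hi - 1),
                            unlist(lapply(seq_len(nrow(ch$blocks)), function(b) {
                              s <- ch$source$start +
                                cumsum(c(0L, (ch$blocks$size +
                                                ch$blocks$dt)))[b]
                              seq.int(s, s + ch$blocks$size[b] - 1L)
                            })))
    expect_equal(sort(unique(back)), sort(unique(as.integer(mapped_src))))
  }
})

test_that("mapped fraction gates transcript hits", {
  m <- make_model("t", "chr1", "+", c(100L, 400L), c(200L, 500L))
  full <- identity_chain()
  hits <- map_transcript(m, list(full))
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$mapped_fraction, 1)
  # chain covering only 80 of 200 exonic bases: below the 0.5 default
  part <- chain_alignment("p", 10,
    source = list(chrom = "chr1", size = 1000L, strand = "+", start = 120L,
                  end = 200L),
    target = list(chrom = "t", size = 1000L, strand = "+", start = 0L,
                  end = 80L),
    blocks = data.frame(size = 80L, dt = 0L, dq = 0L))
  expect_length(map_transcript(m, list(part)), 0L)
  expect_length(map_transcript(m, list(part), min_mapped_fraction = 0.3), 1L)
  # fraction monotone non-increasing as source gaps are added
  gap <- chain_alignment("g", 10,
    source = list(chrom = "chr1", size = 1000L, strand = "+", start = 0L,
                  end = 1000L),
    target = list(chrom = "t", size = 1000L, strand = "+", start = 0L,
                  end = 960L),
    blocks = data.frame(size = c(150L, 810L), dt = c(40L, 0L),
                        dq = c(0L, 0L)))
  h_gap <- map_transcript(m, list(gap), min_mapped_fraction = 0)
  expect_lt(h_gap[[1]]$mapped_fraction, 1)
})

test_that("planted orthologs are recovered exactly", {
  ds <- default_dataset()
  truth <- ds$truth
  lincs <- truth[truth$true_class %in% c("lincRNA_known", "lincRNA_novel"), ]
  by_id <- stats::setNames(ds$assembly,
                           vapply(ds$assembly, `[[`, "", "transcript_id"))
  hit_ids <- character(0)
  for (tid in lincs$transcript_id) {
    hits <- map_transcript(by_id[[tid]], ds$chains)
    if (length(hits)) {
      hit_ids <- c(hit_ids, tid)
      expect_equal(hits[[1]]$target_chrom,
                   truth$ortholog_chrom[truth$transcript_id == tid])
    }
  }
  expect_setequal(hit_ids,
                  lincs$transcript_id[!is.na(lincs$ortholog_chrom)])
})
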