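test_that("intron chain is the ordered gap list between exons", {
  m <- make_model("t", "chr1", "+", c(0L, 200L), c(100L, 300L))
  expect_equal(intron_chain(m), data.frame(start = 100L, end = 200L))
  single <- make_model("s", "chr1", "+", 0L, 100L)
  expect_equal(nrow(intron_chain(single)), 0L)

  set.seed(21)
  for (i in 1:20) {
    m <- random_model("r")
    ch <- intron_chain(m)
    n <- nrow(m$exons)
    if (n < 2) { expect_equal(nrow(ch), 0L); next }
    expect_equal(ch$start, m$exons$end[-n])
    expect_equal(ch$end, m$exons$start[-1])
  }
})

test_that("class codes follow intron-chain match then exonic overlap", {
  ref <- make_model("ref1", "chr1", "+", c(100L, 500L, 900L),
                    c(300L, 700L, 1100L))
  # identical structure
  q1 <- make_model("q1", "chr1", "+", c(100L, 500L, 900L),
                   c(300L, 700L, 1100L))
  expect_equal(classify_against_reference(q1, list(ref))$code, "=")
  # same intron chain, 50-nt-longer terminal exons: still a complete match
  q2 <- make_model("q2", "chr1", "+", c(50L, 500L, 900L),
                   c(300L, 700L, 1150L))
  cc2 <- classify_against_reference(q2, list(ref))
  expect_equal(cc2$code, "=")
  expect_equal(cc2$matched_reference_id, "ref1")
  # exonic overlap on the other strand
  q3 <- make_model("q3", "chr1", "-", c(250L, 600L), c(350L, 650L))
  expect_equal(classify_against_reference(q3, list(ref))$code, "o")
  # intronic placement does not overlap exons
  q4 <- make_model("q4", "chr1", "+", c(320L, 400L), c(360L, 450L))
  expect_equal(classify_against_reference(q4, list(ref))$code, "u")
  # single-exon query can never be '='
  q5 <- make_model("q5", "chr1", "+", 100L, 300L)
  expect_equal(classify_against_reference(q5, list(ref))$code, "o")
})

test_that("class codes agree with the brute-force oracle on random pairs", {
  set.seed(31)
  for (i in 1:250) {
    ref <- lapply(1:3, function(j)
      random_model(paste0("ref", j), max_pos = 800L))
    q <- random_model("q", max_pos = 800L)
    expect_equal(classify_against_reference(q, ref)$code,
                 oracle_class_code(q, ref))
  }
})

test_that("nearest coding neighbor minimizes gap with 5'-side tie rule", {
  linc <- make_model("L", "chr1", "+", 10000L, 11000L)
  up <- make_model("up", "chr1", "+", 7000L, 8000L, gene = "geneU")
  expect_equal(nearest_coding_neighbor(linc, list(up))$distance, 2000L)
  expect_equal(nearest_coding_neighbor(linc, list(up))$signed_distance,
               -2000L)
  # equidistant up/downstream: the 5' side wins
  down <- make_model("down", "chr1", "+", 13000L, 14000L, gene = "geneD")
  nb <- nearest_coding_neighbor(linc, list(down, up))
  expect_equal(nb$neighbor_gene_id, "geneU")
  # abutting spans have distance 0
  abut <- make_model("ab", "chr1", "-", 11000L, 12000L, gene = "geneA")
  expect_equal(nearest_coding_neighbor(linc, list(abut))$distance, 0L)
  # empty coding list
  expect_true(is.na(nearest_coding_neighbor(linc, list())$distance))
})

test_that("nearest neighbor matches an exhaustive scan on random layouts", {
  set.seed(41)
  for (i in 1:100) {
    linc <- random_model("L", max_pos = 5000L)
    coding <- lapply(1:5, function(j)
      random_model(paste0("c", j), max_pos = 5000L))
    got <- nearest_coding_neighbor(linc, coding)
    lsp <- transcript_span(linc)
    gaps <- vapply(coding, function(m) {
      msp <- transcript_span(m)
      max(0L, msp[1] - lsp[2], lsp[1] - msp[2])
    }, 0L)
    expect_equal(got$distance, min(gaps))
  }
})

test_that("bidirectional rule needs opposite strands, divergence, and the window", {
  plus <- make_model("P", "chr1", "+", 5000L, 6000L)
  minus_near <- make_model("M", "chr1", "-", 3500L, 4201L)   # TSS 4200
  expect_true(is_bidirectional(plus, minus_near))            # sep 800
  expect_true(is_bidirectional(minus_near, plus))            # symmetric
  same <- make_model("S", "chr1", "+", 3500L, 4201L)
  expect_false(is_bidirectional(plus, same))
  # separation exactly 1000: closed threshold
  minus_edge <- make_model("E", "chr1", "-", 3000L, 4001L)   # TSS 4000
  expect_true(is_bidirectional(plus, minus_edge))
  minus_far <- make_model("F", "chr1", "-", 3000L, 4000L)    # TSS 3999, sep 1001
  expect_false(is_bidirectional(plus, minus_far))
  # convergent orientation is not bidirectional
  minus_conv <- make_model("C", "chr1", "-", 5200L, 5900L)
  expect_false(is_bidirectional(plus, minus_conv))
})
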