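make_hits <- function(...) {
  hit_table(tibble::tribble(...))
}

test_that("best-hit reduction keeps max identity, ties by position then contig", {
  raw <- make_hits(
    ~query_id, ~reference_id, ~contig, ~position, ~pct_identity,
    "q1", "r1", "c1", 100L, 90,
    "q1", "r1", "c1", 200L, 95)
  expect_equal(best_hits(raw)$pct_identity, 95)

  single <- make_hits(~query_id, ~reference_id, ~contig, ~position,
                      ~pct_identity, "q1", "r1", "c1", 5L, 80)
  expect_equal(as_tibble(best_hits(single)), as_tibble(single))

  tie <- make_hits(
    ~query_id, ~reference_id, ~contig, ~position, ~pct_identity,
    "q1", "r1", "c1", 10L, 95,
    "q1", "r1", "c1", 5L, 95)
  expect_equal(best_hits(tie)$position, 5L)

  tie2 <- make_hits(
    ~query_id, ~reference_id, ~contig, ~position, ~pct_identity,
    "q1", "r1", "cB", 5L, 95,
    "q1", "r1", "cA", 5L, 95)
  expect_equal(best_hits(tie2)$contig, "cA")
})

test_that("windowed depth probabilities follow the stated closed forms", {
  # 4 queries all within one window: p = 1, h = 0
  h4 <- make_hits(
    ~query_id, ~reference_id, ~contig, ~position, ~pct_identity,
    "q1", "r", "c", 0L, 90, "q2", "r", "c", 10L, 90,
    "q3", "r", "c", 20L, 90, "q4", "r", "c", 30L, 90)
  m <- windowed_depth_model(h4, "r", window = 2000)
  expect_equal(unname(m$probs), rep(1, 4))
  expect_equal(as.numeric(self_information(m, c("q1", "q4"))), c(0, 0))

  # 1 isolated query among 100 aligned: p = 0.01
  pos <- c(seq(0, 99) * 10L)  # 99 clustered + 1 isolated
  h100 <- hit_table(tibble::tibble(
    query_id = sprintf("q%03d", 1:100), reference_id = "r", contig = "c",
    position = c(pos[1:99], 900000L), pct_identity = 90))
  m <- windowed_depth_model(h100, "r", window = 1000)
  expect_equal(unname(m$probs[m$bins == "q100"]), 0.01)
  expect_equal(as.numeric(self_information(m, "q100")), -log(0.01))

  # 3 queries at 0, 10, 10000 with window 1000: depths 2, 2, 1
  h3 <- make_hits(
    ~query_id, ~reference_id, ~contig, ~position, ~pct_identity,
    "a", "r", "c", 0L, 90, "b", "r", "c", 10L, 90,
    "d", "r", "c", 10000L, 90)
  m <- windowed_depth_model(h3, "r", window = 1000)
  expect_equal(unname(m$depths[c("a", "b", "d")]), c(2L, 2L, 1L))
  expect_equal(unname(m$probs[match(c("a", "b", "d"), m$bins)]),
               c(2, 2, 1) / 3)

  expect_error(windowed_depth_model(h3, "nope"), class = "unknown-reference")
})

test_that("windowed depths equal the O(n^2) brute-force oracle", {
  set.seed(13)
  n <- 400
  hits <- hit_table(tibble::tibble(
    query_id = sprintf("q%04d", 1:n), reference_id = "r",
    contig = sample(c("c1", "c2"), n, replace = TRUE),
    position = as.integer(sample(0:50000, n, replace = TRUE)),
    pct_identity = runif(n, 70, 100)))
  for (w in c(500, 2000)) {
    m <- windowed_depth_model(hits, "r", window = w)
    expected <- oracle_depths(hits$position, hits$contig, w)
    expect_equal(unname(m$depths[hits$query_id]), expected)
  }
  # depth >= 1 (each query sees itself) and p <= 1
  m <- windowed_depth_model(hits, "r", window = 500)
  expect_true(all(m$depths >= 1))
  expect_true(all(m$probs <= 1))
  # doubling the window never decreases any depth
  m2 <- windowed_depth_model(hits, "r", window = 1000)
  expect_true(all(m2$depths[hits$query_id] >= m$depths[hits$query_id]))
})

test_that("panel tensors flag unaligned cells and respect symmetry", {
  hits <- make_hits(
    ~query_id, ~reference_id, ~contig, ~position, ~pct_identity,
    "q1", "A", "c", 0L, 95, "q2", "A", "c", 100L, 95,
    "q1", "B", "c", 0L, 95, "q2", "B", "c", 100L, 95)
  tens <- panel_information_tensor(hits, window = 1000)
  # identical references: every spectrum has equal coordinates
  expect_equal(tens$values[, "A", 1], tens$values[, "B", 1])

  hits2 <- make_hits(
    ~query_id, ~reference_id, ~contig, ~position, ~pct_identity,
    "q1", "A", "c", 0L, 95, "q2", "A", "c", 10L, 95,
    "q1", "B", "c", 0L, 95)
  tens2 <- panel_information_tensor(hits2, window = 1000)
  expect_true(tens2$flags["q2", "B"])
  expect_false(tens2$flags["q2", "A"])
  # flagged cell carries the pseudo-count self-information of model B
  expect_equal(tens2$values["q2", "B", 1], -log(0.5 / 1.5))
})

test_that("percent-identity co-spectra pass best identities through", {
  hits <- make_hits(
    ~query_id, ~reference_id, ~contig, ~position, ~pct_identity,
    "p1", "A", "c", 0L, 100,
    "p2", "A", "c", 0L, 97, "p2", "B", "c", 0L, 97)
  tens <- pctid_cospectra(hits)
  expect_equal(tens$values["p1", "A", 1], 100)
  expect_equal(tens$values["p2", "A", 1], 97)
  expect_equal(tens$values["p2", "B", 1], 97)
  # no hit: 0 + flag
  expect_equal(tens$values["p1", "B", 1], 0)
  expect_true(tens$flags["p1", "B"])
})

test_that("BLAST outfmt 6, internal TSV and SAM readers agree on positions", {
  dir <- withr::local_tempdir()
  blast <- file.path(dir, "hits.blast")
  writeLines(c(
    "q1\tctg1\t98.5\t100\t1\t0\t1\t100\t501\t600\t1e-50\t180",
    "q2\tctg2\t90.0\t80\t8\t0\t1\t80\t900\t821\t1e-20\t90"),
    blast)
  hb <- read_blast_hits(blast, "refX")
  expect_equal(hb$position, c(500L, 820L))  # 0-based, strand absorbed
  expect_equal(hb$pct_identity, c(98.5, 90))

  tsv <- file.path(dir, "hits.tsv")
  readr::write_tsv(tibble::tibble(query = "q1", ref = "refX", contig = "ctg1",
                                  pos = 500L, pctid = 98.5), tsv)
  ht <- read_hits_tsv(tsv)
  expect_equal(ht$position, 500L)

  sam <- file.path(dir, "hits.sam")
  writeLines(c(
    "@SQ\tSN:ctg1\tLN:10000",
    "q1\t0\tctg1\t501\t60\t100M\t*\t0\t0\tACGT\tIIII\tNM:i:2",
    "q2\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII",          # unmapped: dropped
    "q3\t256\tctg1\t700\t0\t50M\t*\t0\t0\tACGT\tIIII\tNM:i:0"),  # secondary
    sam)
  hs <- read_sam_hits(sam, "refX")
  expect_equal(nrow(hs), 1)
  expect_equal(hs$position, 500L)
  expect_equal(hs$pct_identity, 98)
})
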