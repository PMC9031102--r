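test_that("match classification applies the identity and gap rules", {
  # full identity, no gaps, full subject coverage
  expect_identical(classify_match(100, 0, 500, 500), "complete")
  # high identity, no gaps
  expect_identical(classify_match(96, 0, 480, 500), "partial")
  # a gap opening disqualifies
  expect_identical(classify_match(96, 1, 480, 500), "unmatched")
  # identity below 95
  expect_identical(classify_match(94.9, 0, 500, 500), "unmatched")
  # full identity but partial subject coverage: partial under the coverage
  # rule, complete under the literal rule
  expect_identical(classify_match(100, 0, 300, 500), "partial")
  expect_identical(classify_match(100, 0, 300, 500, coverage_check = FALSE),
                   "complete")
  expect_error(classify_match(101, 0, 10, 10), "percent_identity")
})

test_that("detection summary counts best class per sample and group", {
  d <- default_design(5)
  # one gene complete in every sample
  m_all <- data.frame(query_id = paste0("q", 1:20), subject_id = "ref_A",
                      gene_id = "A", percent_identity = 100,
                      gap_openings = 0, alignment_length = 400,
                      subject_length = 400, sample_id = d$sample_id,
                      stringsAsFactors = FALSE)
  s <- summarize_detection(m_all, d)
  expect_true(all(s$percent_detected == 100))
  expect_true(all(s$n_complete == 5))
  # a gene matched in 11 of 20 samples: 55% overall detection
  m_11 <- m_all[1:11, ]
  s11 <- summarize_detection(m_11, d)
  expect_equal(sum(s11$n_complete + s11$n_partial) / sum(s11$n_samples), 0.55)
  # empty match table: all-none rows over the stated gene universe
  s0 <- summarize_detection(m_all[0, ], d, genes = c("A", "B"))
  expect_equal(nrow(s0), 8L)
  expect_true(all(s0$n_none == 5) && all(s0$percent_detected == 0))
  expect_equal(nrow(summarize_detection(m_all[0, ], d)), 0L)
  # unknown sample id
  m_bad <- m_all
  m_bad$sample_id[1] <- "nope"
  expect_error(summarize_detection(m_bad, d), "nope")
})

test_that("best-class reduction is order-independent and idempotent", {
  d <- default_design(5)
  set.seed(40)
  m <- random_match_table(d, n_genes = 4, n_matches = 50)
  a <- summarize_detection(m, d)
  b <- summarize_detection(m[sample(nrow(m)), ], d)
  expect_equal(a, b)
})

test_that("detection summary equals the brute-force oracle on random tables", {
  d <- default_design(5)
  set.seed(41)
  for (k in 1:20) {
    m <- random_match_table(d, n_genes = sample(2:6, 1),
                            n_matches = sample(20:80, 1))
    mine <- summarize_detection(m, d)
    ref <- oracle_detection(m, d, classify_match)
    ord <- function(x) x[order(x$gene_id, x$treatment, x$region), ]
    expect_equal(ord(mine), ord(ref), ignore_attr = TRUE)
  }
})

test_that("BLAST tabular matches are read and joined with subject lengths", {
  path <- tempfile(fileext = ".tsv")
  lines <- c("q1\tref_A\t100.000\t400\t0\t0\t1\t400\t1\t400\t1e-180\t700",
             "q2\tref_A\t96.500\t380\t10\t0\t5\t384\t10\t389\t1e-150\t600",
             "q3\tref_B\t88.000\t200\t20\t2\t1\t200\t1\t200\t1e-50\t200")
  writeLines(lines, path)
  slen <- data.frame(subject_id = c("ref_A", "ref_B"),
                     subject_length = c(400, 250),
                     gene_id = c("A", "B"), stringsAsFactors = FALSE)
  m <- read_blast_matches(path, slen,
                          sample_of_query = c(q1 = "s1", q2 = "s1", q3 = "s2"))
  expect_equal(nrow(m), 3L)
  expect_equal(m$subject_length, c(400, 400, 250))
  expect_identical(
    vapply(seq_len(3), function(i)
      classify_match(m$percent_identity[i], m$gap_openings[i],
                     m$alignment_length[i], m$subject_length[i]),
      character(1)),
    c("complete", "partial", "unmatched"))
  # unknown subject id
  slen_bad <- slen[1, ]
  expect_error(read_blast_matches(path, slen_bad, c(q1 = "s1", q2 = "s1",
                                                    q3 = "s2")), "ref_B")
})
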