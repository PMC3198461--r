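test_that("pair keys depend only on uppercased mate prefixes", {
  expect_identical(pair_key("ACGTA", "TTTTT", k = 3), "ACG|TTT")
  expect_identical(pair_key("acgta", "ttttt", k = 3), "ACG|TTT")
  a <- strrep("A", 60)
  b51 <- paste0(strrep("A", 50), "C", strrep("A", 9))
  # difference beyond the 50-base prefix is invisible to the key
  expect_identical(pair_key(a, a), pair_key(b51, a))
  # difference at base 1 of either mate changes the key
  expect_false(pair_key(a, a) == pair_key(a, paste0("C", strrep("A", 59))))
  # short reads contribute their full sequence
  expect_identical(pair_key("AC", "G", k = 50), "AC|G")
})

test_that("dedup keeps the first pair per key, preserving order", {
  q <- function(n) rep(30L, n)
  m1 <- fastq_reads(c("a/1", "b/1", "c/1"),
                    c("ACGT", "GGGG", "ACGT"),
                    list(q(4), q(4), q(4)))
  m2 <- fastq_reads(c("a/2", "b/2", "c/2"),
                    c("TTTT", "CCCC", "TTTT"),
                    list(q(4), q(4), q(4)))
  res <- dedup_pairs(m1, m2, k = 4)
  expect_equal(res$removed, 1L)
  expect_identical(res$mate1$id, c("a/1", "b/1"))
  expect_identical(res$mate2$id, c("a/2", "b/2"))

  distinct <- dedup_pairs(m1[1:2], m2[1:2], k = 4)
  expect_equal(distinct$removed, 0L)
  expect_reads_equal(distinct$mate1, m1[1:2])
})

test_that("dedup output is a subsequence with pairwise-distinct keys, and is idempotent", {
  set.seed(31)
  n <- 200
  base1 <- reads_from_scores(random_score_list(n, len_range = c(55L, 70L)))
  base2 <- reads_from_scores(random_score_list(n, len_range = c(55L, 70L)))
  # force some duplicates by copying sequences around
  dup_from <- sample(n, 40)
  dup_to <- sample(setdiff(seq_len(n), dup_from), 40)
  base1$sequence[dup_to] <- base1$sequence[dup_from]
  base1$quality[dup_to] <- base1$quality[dup_from]
  base2$sequence[dup_to] <- base2$sequence[dup_from]
  base2$quality[dup_to] <- base2$quality[dup_from]
  res <- dedup_pairs(base1, base2)
  keys <- pair_key(res$mate1$sequence, res$mate2$sequence)
  expect_false(any(duplicated(keys)))
  expect_true(all(res$mate1$id %in% base1$id))
  expect_identical(res$mate1$id,
                   base1$id[base1$id %in% res$mate1$id])  # order preserved
  res2 <- dedup_pairs(res$mate1, res$mate2)
  expect_equal(res2$removed, 0L)
  expect_reads_equal(res2$mate1, res$mate1)
  expect_reads_equal(res2$mate2, res$mate2)
})

test_that("dedup removes exactly the generator's injected duplicates", {
  sim <- generate_pairs(100, quality_profile(read_length = 60),
                        dup_rate = 0.2, seed = 77)
  expect_equal(sim$truth$duplicates_injected, 20L)
  res <- dedup_pairs(sim$mate1, sim$mate2)
  expect_equal(res$removed, 20L)
  expect_equal(n_reads(res$mate1), 80L)
})

test_that("file-based dedup streams to uniq outputs with a removed count", {
  sim <- generate_pairs(60, quality_profile(read_length = 55),
                        dup_rate = 0.25, seed = 78)
  p1 <- write_temp_fastq(sim$mate1)
  p2 <- write_temp_fastq(sim$mate2)
  prefix <- tempfile()
  res <- dedup_pairs(p1, p2, prefix = prefix, chunk_size = 13L)
  expect_equal(res$removed, sim$truth$duplicates_injected)
  u1 <- read_fastq(paste0(prefix, "_uniq1.fastq"), "sanger")
  u2 <- read_fastq(paste0(prefix, "_uniq2.fastq"), "sanger")
  expect_equal(n_reads(u1), 60L - res$removed)
  expect_equal(n_reads(u1), n_reads(u2))
  mem <- dedup_pairs(sim$mate1, sim$mate2)
  expect_reads_equal(u1, mem$mate1)
})

test_that("duplicate filtering runs before trimming in the paired pipeline", {
  sim <- generate_pairs(80, quality_profile(read_length = 70, q_start = 40,
                                            q_end = 35, noise_sd = 0),
                        dup_rate = 0.25, seed = 79)
  p1 <- write_temp_fastq(sim$mate1)
  p2 <- write_temp_fastq(sim$mate2)
  prefix <- tempfile()
  stats <- process_pairs(p1, p2, prefix, trim_config(), dedup = TRUE,
                         chunk_size = 11L, quiet = TRUE)
  expect_equal(stats$duplicates_removed, sim$truth$duplicates_injected)
  # high, flat profile: every surviving pair passes untouched
  expect_equal(stats$pairs_scanned, 80L - stats$duplicates_removed)
  expect_equal(stats$pairs_kept, stats$pairs_scanned)
})
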