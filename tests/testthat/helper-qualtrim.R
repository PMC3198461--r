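# Declarative characterization of the 3'-end trim point, written directly
# from the rule it must satisfy and independent of the package's scanning
# automaton: the kept end is the 3'-most position e with score[e] >= qh
# such that, scanning from e toward the 5' end, a run of nh consecutive
# high-quality bases is completed before any run of nl + 1 consecutive
# low-quality bases; 0 if no position qualifies. Positions below minlen
# never qualify.
oracle_end_index <- function(scores, qh, nh, nl, minlen = 1L) {
  hq <- scores >= qh
  valid_end <- function(e) {
    if (!hq[e]) return(FALSE)
    hq_run <- 0L
    lq_run <- 0L
    for (p in e:1) {
      if (hq[p]) {
        hq_run <- hq_run + 1L
        lq_run <- 0L
        if (hq_run >= nh) return(TRUE)
      } else {
        lq_run <- lq_run + 1L
        hq_run <- 0L
        if (lq_run > nl) return(FALSE)
      }
    }
    FALSE
  }
  for (e in rev(seq_along(scores))) {
    if (e < minlen) break
    if (valid_end(e)) return(e)
  }
  0L
}

# Build a fastq_reads object carrying the given score vectors over random
# (but seed-reproducible within the calling test) base sequences.
reads_from_scores <- function(score_list, ids = NULL) {
  score_list <- lapply(score_list, as.integer)
  n <- length(score_list)
  if (is.null(ids)) ids <- sprintf("read_%04d", seq_len(n))
  seqs <- vapply(lengths(score_list), function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
  fastq_reads(ids, seqs, score_list)
}

# Random score vectors spanning kept and rejected regimes.
random_score_list <- function(n, len_range = c(30L, 90L),
                              score_range = c(2L, 40L)) {
  lapply(seq_len(n), function(i) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    sample(score_range[1L]:score_range[2L], len, replace = TRUE)
  })
}

# Score vectors that mostly survive the default filter: high-quality
# baseline with sparse mid-quality dips (kept above the default floor).
random_keepable_scores <- function(n, len_range = c(55L, 90L)) {
  lapply(seq_len(n), function(i) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    q <- sample(25:40, len, replace = TRUE)
    dips <- which(runif(len) < 0.06)
    q[dips] <- sample(10:24, length(dips), replace = TRUE)
    as.integer(q)
  })
}

# A mixture of regimes so every trim verdict occurs: clean reads,
# survivable reads with dips, decayed tails, and hopeless reads.
random_mixed_scores <- function(n, len_range = c(45L, 90L)) {
  lapply(seq_len(n), function(i) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    regime <- sample(4L, 1L)
    hi <- max(1L, len - 20L)
    q <- switch(regime,
      rep(40L, len),
      random_keepable_scores(1L, c(len, len))[[1L]],
      c(sample(28:40, hi, replace = TRUE),
        sample(2:15, len - hi, replace = TRUE)),
      sample(2:40, len, replace = TRUE))
    as.integer(q)
  })
}

# Write a fastq_reads object to a temp file and return the path.
write_temp_fastq <- function(reads, encoding = "sanger", gzip = FALSE) {
  path <- tempfile(fileext = if (gzip) ".fastq.gz" else ".fastq")
  write_fastq(reads, path, encoding, gzip = gzip)
  path
}

expect_reads_equal <- function(a, b) {
  expect_identical(a$id, b$id)
  expect_identical(a$sequence, b$sequence)
  expect_identical(lapply(a$quality, as.integer),
                   lapply(b$quality, as.integer))
}
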