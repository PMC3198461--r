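cfg_default <- trim_config()

test_that("the 3' automaton reproduces hand-simulated trim points", {
  # untouched read: no base below the threshold
  expect_equal(trim_3prime(rep(40L, 50), cfg_default)$end_index, 50L)
  # low-quality 3' tail dropped, then a clean high-quality run terminates
  expect_equal(trim_3prime(c(rep(30L, 55), rep(10L, 5)), cfg_default)$end_index,
               55L)
  # candidate restart: first candidate dies on two consecutive low-quality
  # bases, second candidate tolerates one and completes the run
  cfg5 <- trim_config(min_length = 5L)
  expect_equal(
    trim_3prime(c(rep(30L, 10), 10L, 30L, 10L, 10L, 30L), cfg5)$end_index,
    12L)
  # hopeless read: no base ever reaches the threshold
  res <- trim_3prime(rep(2L, 60), cfg_default)
  expect_equal(res$end_index, 0L)
  expect_false(res$terminated_by_run)
})

test_that("approval applies the low-quality floor then the strict fraction rule", {
  cfg <- trim_config(min_length = 5L)
  expect_identical(approve_scores(c(rep(30L, 9), 20L), cfg), "kept")
  expect_identical(approve_scores(c(rep(30L, 9), 5L), cfg),
                   "rejected_lq_floor")
  # exactly the threshold fraction is not enough ("more than" is strict)
  expect_identical(approve_scores(c(rep(30L, 8), 20L, 20L), cfg),
                   "rejected_fraction")
  # a base at exactly the floor survives; exactly hq_threshold counts as HQ
  expect_identical(approve_scores(c(rep(25L, 9), 10L), cfg), "kept")
})

test_that("trim_reads composes trimming, length check and approval", {
  reads <- reads_from_scores(list(
    rep(40L, 50),                       # kept untouched
    rep(40L, 49),                       # below min_length from the start
    c(rep(30L, 55), rep(10L, 5)),       # trimmed to 55 then approved
    rep(2L, 60),                        # never reaches a candidate
    c(rep(30L, 30), rep(5L, 20), rep(30L, 10))  # interior 5s: floor kill
  ))
  res <- trim_reads(reads, cfg_default)
  expect_identical(res$status,
                   c("kept", "rejected_short", "kept", "rejected_short",
                     "rejected_lq_floor"))
  expect_identical(res$kept_length, c(50L, 0L, 55L, 0L, 0L))
  expect_equal(n_reads(res$kept), 2L)
  expect_identical(res$kept$sequence[1], reads$sequence[1])
  expect_identical(res$kept$sequence[2], substr(reads$sequence[3], 1, 55))
})

test_that("kept reads are prefixes ending in a high-quality base of legal length", {
  set.seed(101)
  reads <- reads_from_scores(random_mixed_scores(300))
  res <- trim_reads(reads, cfg_default)
  keep <- which(res$status == "kept")
  expect_gt(length(keep), 20)
  for (j in seq_along(keep)) {
    i <- keep[j]
    k <- res$kept$quality[[j]]
    expect_gte(length(k), cfg_default$min_length)
    expect_gte(k[length(k)], cfg_default$hq_threshold)
    expect_identical(k, reads$quality[[i]][seq_along(k)])
    expect_identical(res$kept$sequence[j],
                     substr(reads$sequence[i], 1, length(k)))
  }
})

test_that("trimming an already-kept read changes nothing (idempotence)", {
  set.seed(202)
  reads <- reads_from_scores(random_mixed_scores(300))
  res <- trim_reads(reads, cfg_default)
  expect_gt(n_reads(res$kept), 20)
  res2 <- trim_reads(res$kept, cfg_default)
  expect_true(all(res2$status == "kept"))
  expect_reads_equal(res$kept, res2$kept)
})

test_that("with no low-quality tolerance the trim point is the last clean run end", {
  set.seed(303)
  cfg0 <- trim_config(lq_tolerance = 0L, min_length = 1L)
  for (i in 1:200) {
    q <- sample(c(5L, 20L, 30L), sample(1:40, 1L), replace = TRUE)
    hq <- q >= cfg0$hq_threshold
    # closed form: 3'-most position ending an uninterrupted run of hq_run
    runs <- integer(length(q))
    r <- 0L
    for (p in seq_along(q)) {
      r <- if (hq[p]) r + 1L else 0L
      runs[p] <- r
    }
    valid <- which(runs >= cfg0$hq_run)
    expected <- if (length(valid)) max(valid) else 0L
    expect_equal(trim_3prime(q, cfg0)$end_index, expected)
  }
})

test_that("raising the low-quality tolerance never shortens the kept read", {
  set.seed(404)
  for (i in 1:150) {
    q <- sample(c(5L, 20L, 30L), sample(5:40, 1L), replace = TRUE)
    ends <- vapply(0:3, function(nl) {
      cfg <- trim_config(lq_tolerance = nl, min_length = 1L)
      trim_3prime(q, cfg)$end_index
    }, 0L)
    expect_true(all(diff(ends) >= 0L))
  }
})

test_that("automaton agrees with the declarative oracle on random strings", {
  set.seed(505)
  for (i in 1:300) {
    q <- sample(c(5L, 20L, 30L), sample(1:30, 1L), replace = TRUE)
    nh <- sample(1:5, 1L)
    nl <- sample(0:3, 1L)
    minlen <- sample(1:10, 1L)
    cfg <- trim_config(hq_run = nh, lq_tolerance = nl, min_length = minlen,
                       lq_floor = 1L)
    expect_equal(trim_3prime(q, cfg)$end_index,
                 oracle_end_index(q, 25L, nh, nl, minlen))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(trim_config(lq_floor = 30), "lq_floor")
  expect_error(trim_config(hq_run = 0), "hq_run")
  expect_error(trim_config(lq_tolerance = -1), "lq_tolerance")
  expect_error(trim_config(min_length = 0), "min_length")
  expect_error(trim_config(hq_fraction = 0), "hq_fraction")
  expect_error(trim_config(hq_fraction = 1.2), "hq_fraction")
})
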