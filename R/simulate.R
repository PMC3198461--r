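#' Positional quality profile for synthetic Illumina-like reads
#'
#' Describes how expected base quality changes along a read. Illumina
#' base-call error probability grows roughly exponentially from the 5' to
#' the 3' end of a read; the default `"exponential_error"` decay
#' interpolates the error probability geometrically from `p(q_start)` to
#' `p(q_end)` (on the encoding's scale) and converts back to scores.
#' On the Phred scale this is equivalent to a linear decline in score;
#' on the Solexa log-odds scale the two modes differ slightly at low
#' quality. Per-base jitter is additive Gaussian noise on the score,
#' rounded to integers and clipped to the encodable range.
#'
#' The defaults (100 bp reads falling from Q38 to Q10 with jitter SD 3)
#' emulate a late-cycle-degraded Illumina GAII run.
#'
#' @param read_length Read length in bases.
#' @param q_start Expected score at the 5' end (must be >= `q_end`).
#' @param q_end Expected score at the 3' end.
#' @param decay `"exponential_error"` or `"linear"` (linear in score).
#' @param noise_sd Standard deviation of the per-base score jitter.
#' @param encoding A [quality_encoding()] or dialect name.
#' @return An object of class `quality_profile`.
#' @examples
#' profile_scores(quality_profile(read_length = 10))
#' @export
quality_profile <- function(read_length = 100L, q_start = 38, q_end = 10,
                            decay = c("exponential_error", "linear"),
                            noise_sd = 3,
                            encoding = quality_encoding("sanger")) {
  decay <- match.arg(decay)
  encoding <- as_quality_encoding(encoding)
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be >= 1", call. = FALSE)
  if (q_start < q_end) stop("q_start must be >= q_end", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (q_end < encoding$min_score || q_start > encoding$max_score)
    stop("q_start/q_end outside the encodable score range", call. = FALSE)
  structure(
    list(read_length = read_length, q_start = q_start, q_end = q_end,
         decay = decay, noise_sd = noise_sd, encoding = encoding),
    class = "quality_profile"
  )
}

#' @rdname quality_profile
#' @param profile A `quality_profile`.
#' @return `profile_scores()`: numeric vector of expected (pre-jitter)
#'   scores per position, 5' to 3'.
#' @export
profile_scores <- function(profile) {
  stopifnot(inherits(profile, "quality_profile"))
  len <- profile$read_length
  if (len == 1L) return(profile$q_start)
  if (profile$decay == "linear") {
    seq(profile$q_start, profile$q_end, length.out = len)
  } else {
    scale <- profile$encoding$scale
    p <- exp(seq(log(error_probability(profile$q_start, scale)),
                 log(error_probability(profile$q_end, scale)),
                 length.out = len))
    score_from_error_probability(p, scale)
  }
}

random_sequences <- function(n, len) {
  if (n == 0L) return(character())
  bases <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  apply(matrix(bases, nrow = len), 2L, paste, collapse = "")
}

sample_qualities <- function(n, profile) {
  mu <- profile_scores(profile)
  len <- profile$read_length
  enc <- profile$encoding
  lapply(seq_len(n), function(i) {
    q <- as.integer(round(mu + rnorm(len, sd = profile$noise_sd)))
    pmin(pmax(q, enc$min_score), enc$max_score)
  })
}

#' Generate synthetic paired-end reads with injected duplicates
#'
#' Emulates a paired-end Illumina library at the level the trimmer sees:
#' uniform-random base sequences (no reference genome, adapters or
#' indels) carrying qualities drawn from a positional [quality_profile()],
#' with `floor(n * dup_rate)` pairs injected as exact copies (sequence and
#' qualities) of earlier pairs. Fully deterministic for a fixed `seed`.
#'
#' @param n Number of pairs to generate.
#' @param profile A [quality_profile()].
#' @param dup_rate Fraction of pairs that are duplicates, in `[0, 1)`.
#' @param seed Integer seed; set for reproducibility.
#' @param prefix If non-`NULL`, write `<prefix>_1.fastq[.gz]`,
#'   `<prefix>_2.fastq[.gz]` and a `<prefix>_truth.txt` sidecar
#'   (`key<TAB>value`) instead of only returning the reads.
#' @param gzip Compress the written files.
#' @return A list: `mate1`, `mate2` ([fastq_reads()]), and `truth`, a list
#'   with `n_pairs`, `duplicates_injected`, and `profile_mean` (the
#'   expected score per position).
#' @examples
#' sim <- generate_pairs(10, quality_profile(read_length = 20), seed = 1)
#' sim$truth$duplicates_injected
#' @export
generate_pairs <- function(n, profile = quality_profile(), dup_rate = 0,
                           seed = NULL, prefix = NULL, gzip = FALSE) {
  stopifnot(inherits(profile, "quality_profile"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (dup_rate < 0 || dup_rate >= 1)
    stop("dup_rate must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_dup <- as.integer(floor(n * dup_rate))
  if (n_dup > 0L && n < 2L)
    stop("cannot inject duplicates into a single pair", call. = FALSE)
  dup_pos <- if (n_dup > 0L) sort(sample(2:n, n_dup)) else integer()
  is_dup <- logical(n)
  is_dup[dup_pos] <- TRUE

  n_orig <- n - n_dup
  seq1 <- character(n); seq2 <- character(n)
  seq1[!is_dup] <- random_sequences(n_orig, profile$read_length)
  seq2[!is_dup] <- random_sequences(n_orig, profile$read_length)
  qual1 <- vector("list", n); qual2 <- vector("list", n)
  qual1[!is_dup] <- sample_qualities(n_orig, profile)
  qual2[!is_dup] <- sample_qualities(n_orig, profile)
  for (i in dup_pos) {
    src <- sample.int(i - 1L, 1L)   # copy any earlier pair, dup or not
    seq1[i] <- seq1[src]; seq2[i] <- seq2[src]
    qual1[[i]] <- qual1[[src]]; qual2[[i]] <- qual2[[src]]
  }

  ids <- sprintf("sim_%06d", seq_len(n))
  mate1 <- fastq_reads(paste0(ids, "/1"), seq1, qual1)
  mate2 <- fastq_reads(paste0(ids, "/2"), seq2, qual2)
  truth <- list(n_pairs = n, duplicates_injected = n_dup,
                profile_mean = profile_scores(profile))

  if (!is.null(prefix)) {
    enc <- profile$encoding
    write_fastq(mate1, out_name(prefix, "_1", gzip), enc, gzip)
    write_fastq(mate2, out_name(prefix, "_2", gzip), enc, gzip)
    writeLines(c(
      paste0("n_pairs\t", n),
      paste0("duplicates_injected\t", n_dup),
      paste0("read_length\t", profile$read_length),
      paste0("profile_mean\t",
             paste(signif(truth$profile_mean, 6), collapse = ","))
    ), paste0(prefix, "_truth.txt"))
  }
  list(mate1 = mate1, mate2 = mate2, truth = truth)
}

#' Per-position quality summary
#'
#' Mean quality score and read coverage at each position along the reads,
#' the standard per-cycle diagnostic for spotting 3' quality decay.
#'
#' @param reads A [fastq_reads()] object.
#' @return A data frame with columns `position`, `mean_q`, `n_reads`
#'   (number of reads covering the position); zero rows for empty input.
#' @export
quality_by_position <- function(reads) {
  stopifnot(inherits(reads, "fastq_reads"))
  lens <- lengths(reads$quality)
  if (!length(lens) || max(lens) == 0L) {
    return(data.frame(position = integer(), mean_q = numeric(),
                      n_reads = integer()))
  }
  maxlen <- max(lens)
  sums <- numeric(maxlen)
  counts <- integer(maxlen)
  for (q in reads$quality) {
    idx <- seq_along(q)
    sums[idx] <- sums[idx] + q
    counts[idx] <- counts[idx] + 1L
  }
  keep <- counts > 0L
  data.frame(position = which(keep), mean_q = sums[keep] / counts[keep],
             n_reads = counts[keep])
}
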