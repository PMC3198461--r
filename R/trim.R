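#' Trimming and approval parameters
#'
#' Bundles every tunable of the two-stage read filter together with the
#' quality-score dialect of the input.
#'
#' The defaults (`hq_threshold` 25, `lq_floor` 10, `hq_run` 5,
#' `lq_tolerance` 1, `min_length` 50, `hq_fraction` 0.8) target de novo
#' assembly of Illumina reads: score 25 corresponds to an error
#' probability of roughly 0.003, score 10 to roughly 0.09 on the log-odds
#' scale, and 50 bp is a practical floor for reads feeding a de Bruijn
#' graph assembler. They are starting points, not universal constants;
#' inspect per-cycle quality distributions of your own data before
#' changing them, and keep `hq_run`/`lq_tolerance` consistent with
#' `hq_fraction` (tolerating 1 low-quality base per 5 high-quality bases
#' implies at least ~83% high-quality content, slightly above the default
#' fraction of 80%).
#'
#' @param hq_threshold High-quality threshold: a base is high-quality when
#'   its score is >= this value; 3' bases below it are trim candidates.
#' @param lq_floor Low-quality floor: an approved read may contain no base
#'   scoring below this value.
#' @param hq_run Number of consecutive high-quality bases that terminates
#'   3' trimming.
#' @param lq_tolerance Maximum run of consecutive low-quality bases
#'   tolerated in the interior of the scan (0 = none).
#' @param min_length Minimum retained read length after trimming.
#' @param hq_fraction An approved read must contain more than this
#'   fraction of high-quality bases (strict inequality), computed over the
#'   trimmed length.
#' @param encoding A [quality_encoding()] object or dialect name.
#' @return An object of class `trim_config`.
#' @examples
#' trim_config()
#' trim_config(hq_threshold = 30, min_length = 75, encoding = "illumina")
#' @export
trim_config <- function(hq_threshold = 25L, lq_floor = 10L, hq_run = 5L,
                        lq_tolerance = 1L, min_length = 50L,
                        hq_fraction = 0.8,
                        encoding = quality_encoding("sanger")) {
  encoding <- as_quality_encoding(encoding)
  hq_threshold <- as.integer(hq_threshold)
  lq_floor <- as.integer(lq_floor)
  hq_run <- as.integer(hq_run)
  lq_tolerance <- as.integer(lq_tolerance)
  min_length <- as.integer(min_length)
  if (lq_floor > hq_threshold)
    stop("lq_floor must be <= hq_threshold", call. = FALSE)
  if (hq_run < 1L) stop("hq_run must be >= 1", call. = FALSE)
  if (lq_tolerance < 0L) stop("lq_tolerance must be >= 0", call. = FALSE)
  if (min_length < 1L) stop("min_length must be >= 1", call. = FALSE)
  if (!is.numeric(hq_fraction) || hq_fraction <= 0 || hq_fraction > 1)
    stop("hq_fraction must be in (0, 1]", call. = FALSE)
  structure(
    list(hq_threshold = hq_threshold, lq_floor = lq_floor, hq_run = hq_run,
         lq_tolerance = lq_tolerance, min_length = min_length,
         hq_fraction = hq_fraction, encoding = encoding),
    class = "trim_config"
  )
}

#' @export
print.trim_config <- function(x, ...) {
  cat(sprintf(
    "<trim_config> hq_threshold=%d lq_floor=%d hq_run=%d lq_tolerance=%d min_length=%d hq_fraction=%g format=%s\n",
    x$hq_threshold, x$lq_floor, x$hq_run, x$lq_tolerance, x$min_length,
    x$hq_fraction, x$encoding$dialect))
  invisible(x)
}

#' 3'-end trimming automaton
#'
#' Determines how much of a read's 3' end to remove, scanning from the 3'
#' end toward the 5' end:
#'
#' 1. Bases scoring below `hq_threshold` are discarded until a
#'    high-quality base is found; it becomes the candidate 3' end and is
#'    kept tentatively.
#' 2. The scan continues inward. High-quality bases increment a
#'    consecutive-run counter; up to `lq_tolerance` consecutive
#'    low-quality bases are tolerated (kept tentatively, resetting the
#'    counter).
#' 3. When `hq_run` consecutive high-quality bases have been seen, the
#'    read is cut at the candidate end and all tentatively kept bases --
#'    including tolerated interior low-quality ones -- are retained.
#' 4. If `lq_tolerance + 1` consecutive low-quality bases occur, all
#'    tentatively kept bases are dropped and the scan restarts inward of
#'    the offending run.
#'
#' A candidate end that would leave fewer than `min_length` bases, or a
#' scan reaching the 5' end without completing the run, keeps nothing
#' (`end_index` 0). Only 3' bases are ever removed: the kept read is a
#' prefix of the input.
#'
#' @param quality Integer vector of per-base quality scores, 5' to 3'.
#' @param config A [trim_config()].
#' @return A list: `end_index` (1-based inclusive end of the kept prefix,
#'   0 if nothing is kept) and `terminated_by_run` (`TRUE` when trimming
#'   terminated on a completed high-quality run, in which case the base at
#'   `end_index` scores >= `hq_threshold`).
#' @examples
#' cfg <- trim_config(min_length = 5)
#' trim_3prime(c(rep(30L, 10), rep(10L, 5)), cfg)  # end_index 10
#' @export
trim_3prime <- function(quality, config) {
  stopifnot(inherits(config, "trim_config"))
  quality <- as.integer(quality)
  end <- .trim_ends_cpp(quality, length(quality), config$hq_threshold,
                        config$hq_run, config$lq_tolerance,
                        config$min_length)
  list(end_index = end, terminated_by_run = end > 0L)
}

# Batched automaton over a list of integer score vectors.
trim_ends <- function(quality_list, config) {
  lens <- lengths(quality_list)
  scores <- unlist(quality_list, use.names = FALSE)
  if (is.null(scores)) scores <- integer()
  .trim_ends_cpp(as.integer(scores), as.integer(lens), config$hq_threshold,
                 config$hq_run, config$lq_tolerance, config$min_length)
}

#' Approval filter for an already-trimmed read
#'
#' Second filtering stage. A trimmed read is approved only if it contains
#' no base scoring below `lq_floor`, and strictly more than `hq_fraction`
#' of its bases (over the trimmed length) score at or above
#' `hq_threshold`.
#'
#' @param quality Integer scores of the trimmed read.
#' @param config A [trim_config()].
#' @return One of `"kept"`, `"rejected_lq_floor"`, `"rejected_fraction"`.
#' @examples
#' cfg <- trim_config(min_length = 5)
#' approve_scores(c(rep(30L, 9), 20L), cfg)   # "kept" (fraction 0.9)
#' approve_scores(c(rep(30L, 9), 5L), cfg)    # "rejected_lq_floor"
#' @export
approve_scores <- function(quality, config) {
  stopifnot(inherits(config, "trim_config"))
  if (any(quality < config$lq_floor)) return("rejected_lq_floor")
  if (!(sum(quality >= config$hq_threshold) / length(quality) >
        config$hq_fraction)) return("rejected_fraction")
  "kept"
}

#' Trim and approve reads
#'
#' Applies the two filtering stages to each read: the 3' trimming
#' automaton ([trim_3prime()]), a minimum-length check, then the approval
#' filter ([approve_scores()]). Works on one read or many.
#'
#' @param reads A [fastq_reads()] object.
#' @param config A [trim_config()].
#' @return A list with:
#'   * `status`: per input read, one of `"kept"`, `"rejected_short"`,
#'     `"rejected_lq_floor"`, `"rejected_fraction"`;
#'   * `kept`: a [fastq_reads()] of the kept reads, trimmed, in input
#'     order;
#'   * `kept_length`: per input read, the trimmed length (0 when not
#'     kept).
#' @examples
#' cfg <- trim_config(min_length = 5)
#' r <- fastq_reads("r1", strrep("A", 10),
#'                  list(c(rep(30L, 8), 10L, 10L)))
#' trim_reads(r, cfg)$status
#' @export
trim_reads <- function(reads, config) {
  stopifnot(inherits(reads, "fastq_reads"), inherits(config, "trim_config"))
  n <- n_reads(reads)
  ends <- trim_ends(reads$quality, config)
  status <- character(n)
  status[ends == 0L] <- "rejected_short"
  keep_idx <- which(ends > 0L)
  trimmed_qual <- vector("list", n)
  for (i in keep_idx) {
    q <- reads$quality[[i]][seq_len(ends[i])]
    trimmed_qual[[i]] <- q
    status[i] <- approve_scores(q, config)
  }
  kept_i <- which(status == "kept")
  kept <- fastq_reads(
    reads$id[kept_i],
    substring(reads$sequence[kept_i], 1L, ends[kept_i]),
    trimmed_qual[kept_i]
  )
  kept_length <- integer(n)
  kept_length[kept_i] <- ends[kept_i]
  list(status = status, kept = kept, kept_length = kept_length)
}
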