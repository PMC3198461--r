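#' Run statistics
#'
#' Counters accumulated by [process_single()] and [process_pairs()].
#' Invariants: `reads_scanned = reads_removed + reads_kept_paired +
#' reads_kept_unpaired`, and `reads_kept_paired = 2 * pairs_kept`.
#' `duplicates_removed` counts read pairs dropped by the duplicate filter
#' before trimming; those pairs are not counted as scanned.
#'
#' @param reads_scanned,reads_removed,reads_kept_paired,reads_kept_unpaired
#'   Read-level counters.
#' @param pairs_scanned,pairs_kept Pair-level counters (zero in single-end
#'   runs).
#' @param duplicates_removed Pairs removed by the duplicate filter.
#' @return An object of class `run_stats`.
#' @export
run_stats <- function(reads_scanned = 0L, reads_removed = 0L,
                      reads_kept_paired = 0L, reads_kept_unpaired = 0L,
                      pairs_scanned = 0L, pairs_kept = 0L,
                      duplicates_removed = 0L) {
  structure(
    list(reads_scanned = as.integer(reads_scanned),
         reads_removed = as.integer(reads_removed),
         reads_kept_paired = as.integer(reads_kept_paired),
         reads_kept_unpaired = as.integer(reads_kept_unpaired),
         pairs_scanned = as.integer(pairs_scanned),
         pairs_kept = as.integer(pairs_kept),
         duplicates_removed = as.integer(duplicates_removed)),
    class = "run_stats"
  )
}

stats_fields <- c("reads_scanned", "reads_removed", "reads_kept_paired",
                  "reads_kept_unpaired", "pairs_scanned", "pairs_kept",
                  "duplicates_removed")

add_stats <- function(a, b) {
  do.call(run_stats, setNames(
    lapply(stats_fields, function(f) a[[f]] + b[[f]]), stats_fields))
}

#' @export
print.run_stats <- function(x, ...) {
  cat("<run_stats>\n")
  cat(paste0("  ", report_stats(x)), sep = "\n")
  invisible(x)
}

#' Format run statistics as a key/value table
#'
#' One `key<TAB>value` line per counter; both human-readable and
#' machine-parsable (see [parse_stats()]).
#'
#' @param stats A [run_stats()] object.
#' @return Character vector of lines.
#' @export
report_stats <- function(stats) {
  stopifnot(inherits(stats, "run_stats"))
  vapply(stats_fields, function(f) paste0(f, "\t", stats[[f]]), "")
}

#' Parse a run-statistics table
#'
#' Inverse of [report_stats()].
#'
#' @param lines Character vector of `key<TAB>value` lines (or a file path
#'   when `is_path = TRUE`).
#' @param is_path Treat `lines` as a file path.
#' @return A [run_stats()] object.
#' @export
parse_stats <- function(lines, is_path = FALSE) {
  if (is_path) lines <- readLines(lines)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  kv <- setNames(
    as.integer(vapply(parts, `[`, "", 2L)),
    vapply(parts, `[`, "", 1L))
  missing <- setdiff(stats_fields, names(kv))
  if (length(missing))
    stop("stats table missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(run_stats, as.list(kv[stats_fields]))
}

# Trim both mates of a chunk of pairs and route the survivors.
# Returns trimmed paired/unpaired fastq_reads plus chunk-level run_stats.
route_pairs <- function(mate1, mate2, config) {
  stopifnot(n_reads(mate1) == n_reads(mate2))
  t1 <- trim_reads(mate1, config)
  t2 <- trim_reads(mate2, config)
  ok1 <- t1$status == "kept"
  ok2 <- t2$status == "kept"
  both <- which(ok1 & ok2)
  only1 <- ok1 & !ok2
  only2 <- !ok1 & ok2

  # t*$kept holds survivors in input order; map pair index -> kept index
  kidx1 <- match(both, which(ok1))
  kidx2 <- match(both, which(ok2))
  paired1 <- t1$kept[kidx1]
  paired2 <- t2$kept[kidx2]

  # unpaired survivors in input-pair order, taking whichever mate survived
  single_pairs <- which(only1 | only2)
  un_id <- character(length(single_pairs))
  un_seq <- character(length(single_pairs))
  un_qual <- vector("list", length(single_pairs))
  for (j in seq_along(single_pairs)) {
    i <- single_pairs[j]
    src <- if (only1[i]) t1 else t2
    k <- match(i, which(src$status == "kept"))
    un_id[j] <- src$kept$id[k]
    un_seq[j] <- src$kept$sequence[k]
    un_qual[[j]] <- src$kept$quality[[k]]
  }
  unpaired <- fastq_reads(un_id, un_seq, un_qual)

  n <- n_reads(mate1)
  kept_paired <- 2L * length(both)
  kept_unpaired <- n_reads(unpaired)
  stats <- run_stats(
    reads_scanned = 2L * n,
    reads_removed = 2L * n - kept_paired - kept_unpaired,
    reads_kept_paired = kept_paired,
    reads_kept_unpaired = kept_unpaired,
    pairs_scanned = n,
    pairs_kept = length(both)
  )
  list(paired1 = paired1, paired2 = paired2, unpaired = unpaired,
       stats = stats)
}

resolve_gzip <- function(gzip, input) {
  if (is.na(gzip)) is_gzipped(input) else isTRUE(gzip)
}

out_name <- function(prefix, suffix, gzip) {
  paste0(prefix, suffix, ".fastq", if (gzip) ".gz" else "")
}

log_stats <- function(stats, quiet) {
  if (!quiet) for (line in report_stats(stats)) message(line)
}

#' Trim a single-end FASTQ file
#'
#' Streams `input`, applies [trim_reads()] to every record, and writes the
#' kept reads (trimmed, in input order) to `<prefix>_trim.fastq[.gz]`
#' together with a `<prefix>.stats` counter table. Counters are also
#' logged to standard error.
#'
#' @param input Path to a FASTQ file (plain or gzip).
#' @param prefix Output path prefix.
#' @param config A [trim_config()].
#' @param gzip Compress outputs? `NA` mirrors the input's compression.
#' @param chunk_size Records per streaming chunk.
#' @param quiet Suppress the standard-error log.
#' @return Invisibly, the [run_stats()] of the run.
#' @export
process_single <- function(input, prefix, config = trim_config(),
                           gzip = NA, chunk_size = 5000L, quiet = FALSE) {
  stopifnot(inherits(config, "trim_config"))
  gz <- resolve_gzip(gzip, input)
  reader <- fastq_chunk_reader(input, config$encoding, chunk_size)
  writer <- fastq_writer(out_name(prefix, "_trim", gz), config$encoding, gz)
  on.exit(writer$close(), add = TRUE)
  total <- run_stats()
  repeat {
    chunk <- reader()
    if (is.null(chunk)) break
    res <- trim_reads(chunk, config)
    writer$write(res$kept)
    nk <- n_reads(res$kept)
    total <- add_stats(total, run_stats(
      reads_scanned = n_reads(chunk),
      reads_removed = n_reads(chunk) - nk,
      reads_kept_unpaired = nk))
  }
  writeLines(report_stats(total), paste0(prefix, ".stats"))
  log_stats(total, quiet)
  invisible(total)
}

#' Trim paired-end FASTQ files
#'
#' Streams the two mate files in lockstep, optionally removes duplicate
#' pairs first (see [dedup_pairs()]), trims both mates of every pair, and
#' routes the output:
#'
#' * both mates approved: written to `<prefix>_trim1.fastq[.gz]` and
#'   `<prefix>_trim2.fastq[.gz]` at matching ordinal positions;
#' * exactly one mate approved: written to
#'   `<prefix>_trim_unpaired.fastq[.gz]` (usable as single-end reads);
#' * neither approved: both reads counted as removed.
#'
#' A `<prefix>.stats` counter table is written and the counters are
#' logged to standard error. Every scanned read ends up in exactly one of
#' paired output, unpaired output, or the removed count.
#'
#' @param input1,input2 The two mate FASTQ files (records in matching
#'   order).
#' @param prefix Output path prefix.
#' @param config A [trim_config()].
#' @param gzip Compress outputs? `NA` mirrors `input1`'s compression.
#' @param dedup Remove duplicate pairs (keyed on the first `dedup_k` bases
#'   of each mate) before trimming.
#' @param dedup_k Prefix length for the duplicate key.
#' @param chunk_size Pairs per streaming chunk.
#' @param quiet Suppress the standard-error log.
#' @return Invisibly, the [run_stats()] of the run.
#' @export
process_pairs <- function(input1, input2, prefix, config = trim_config(),
                          gzip = NA, dedup = FALSE, dedup_k = 50L,
                          chunk_size = 5000L, quiet = FALSE) {
  stopifnot(inherits(config, "trim_config"))
  gz <- resolve_gzip(gzip, input1)
  reader <- pair_chunk_reader(input1, input2, config$encoding, chunk_size)
  w1 <- fastq_writer(out_name(prefix, "_trim1", gz), config$encoding, gz)
  w2 <- fastq_writer(out_name(prefix, "_trim2", gz), config$encoding, gz)
  wu <- fastq_writer(out_name(prefix, "_trim_unpaired", gz),
                     config$encoding, gz)
  on.exit({ w1$close(); w2$close(); wu$close() }, add = TRUE)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  total <- run_stats()
  repeat {
    chunk <- reader()
    if (is.null(chunk)) break
    m1 <- chunk$mate1; m2 <- chunk$mate2
    if (dedup) {
      keep <- dedup_mark(m1$sequence, m2$sequence, dedup_k, seen)
      total <- add_stats(total, run_stats(
        duplicates_removed = sum(!keep)))
      m1 <- m1[keep]; m2 <- m2[keep]
    }
    routed <- route_pairs(m1, m2, config)
    w1$write(routed$paired1)
    w2$write(routed$paired2)
    wu$write(routed$unpaired)
    total <- add_stats(total, routed$stats)
  }
  writeLines(report_stats(total), paste0(prefix, ".stats"))
  log_stats(total, quiet)
  invisible(total)
}
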