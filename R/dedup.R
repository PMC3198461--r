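#' Duplicate key for a read pair
#'
#' PCR and optical duplicates are read pairs copied from the same original
#' fragment; they are identified by sequence alone. The key is the
#' uppercased concatenation of the first `k` bases of each mate (the full
#' sequence when a mate is shorter than `k`), separated by `"|"`.
#' Qualities and read names play no part, and no strand or mate-swap
#' canonicalization is applied: a pair and its mate-swapped twin get
#' different keys.
#'
#' @param seq1,seq2 Character vectors of mate-1 and mate-2 sequences
#'   (recycled to equal length is not supported; supply equal lengths).
#' @param k Prefix length (default 50).
#' @return Character vector of keys.
#' @examples
#' pair_key("ACGTA", "TTTTT", k = 3)  # "ACG|TTT"
#' @export
pair_key <- function(seq1, seq2, k = 50L) {
  stopifnot(length(seq1) == length(seq2), k >= 1L)
  paste0(toupper(substr(seq1, 1L, k)), "|", toupper(substr(seq2, 1L, k)))
}

# Streaming first-occurrence marker: returns a logical keep-vector for the
# chunk and records new keys in the environment `seen`.
dedup_mark <- function(seq1, seq2, k, seen) {
  keys <- pair_key(seq1, seq2, k)
  keep <- logical(length(keys))
  for (i in seq_along(keys)) {
    if (!exists(keys[i], envir = seen, inherits = FALSE)) {
      assign(keys[i], TRUE, envir = seen)
      keep[i] <- TRUE
    }
  }
  keep
}

#' Remove duplicate read pairs
#'
#' Keeps the first pair seen for each duplicate key ([pair_key()]), in
#' input order; later pairs with the same key are dropped. One key is held
#' in memory per unique pair, which is the scaling limit of this filter.
#'
#' When both `mate1`/`mate2` are [fastq_reads()] the filter runs in
#' memory; when they are file paths, `prefix` is required and the unique
#' pairs are streamed to `<prefix>_uniq1.fastq[.gz]` and
#' `<prefix>_uniq2.fastq[.gz]`.
#'
#' @param mate1,mate2 [fastq_reads()] objects, or paths to the two mate
#'   FASTQ files.
#' @param k Prefix length for the key (default 50).
#' @param prefix Output path prefix (file input only).
#' @param encoding A [quality_encoding()] or dialect name (file input
#'   only).
#' @param gzip Compress outputs? `NA` mirrors the input (file input only).
#' @param chunk_size Pairs per streaming chunk (file input only).
#' @param quiet Suppress the standard-error log.
#' @return A list: `mate1`, `mate2` (the unique pairs, in-memory mode
#'   only), `pairs_in`, `pairs_out`, and `removed` (the number of
#'   duplicate pairs dropped).
#' @examples
#' m1 <- fastq_reads(c("a", "b"), c("ACGT", "ACGT"),
#'                   list(rep(30L, 4), rep(30L, 4)))
#' dedup_pairs(m1, m1, k = 4)$removed  # 1
#' @export
dedup_pairs <- function(mate1, mate2, k = 50L, prefix = NULL,
                        encoding = quality_encoding("sanger"), gzip = NA,
                        chunk_size = 5000L, quiet = TRUE) {
  if (inherits(mate1, "fastq_reads")) {
    stopifnot(inherits(mate2, "fastq_reads"),
              n_reads(mate1) == n_reads(mate2))
    keys <- pair_key(mate1$sequence, mate2$sequence, k)
    keep <- !duplicated(keys)
    res <- list(mate1 = mate1[keep], mate2 = mate2[keep],
                pairs_in = n_reads(mate1), pairs_out = sum(keep),
                removed = sum(!keep))
    if (!quiet) message("duplicate pairs removed\t", res$removed)
    return(res)
  }
  if (is.null(prefix))
    stop("`prefix` is required when deduplicating files", call. = FALSE)
  gz <- resolve_gzip(gzip, mate1)
  reader <- pair_chunk_reader(mate1, mate2, encoding, chunk_size)
  w1 <- fastq_writer(out_name(prefix, "_uniq1", gz), encoding, gz)
  w2 <- fastq_writer(out_name(prefix, "_uniq2", gz), encoding, gz)
  on.exit({ w1$close(); w2$close() }, add = TRUE)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  pairs_in <- 0L; pairs_out <- 0L
  repeat {
    chunk <- reader()
    if (is.null(chunk)) break
    keep <- dedup_mark(chunk$mate1$sequence, chunk$mate2$sequence, k, seen)
    pairs_in <- pairs_in + length(keep)
    pairs_out <- pairs_out + sum(keep)
    w1$write(chunk$mate1[keep])
    w2$write(chunk$mate2[keep])
  }
  res <- list(mate1 = NULL, mate2 = NULL, pairs_in = pairs_in,
              pairs_out = pairs_out, removed = pairs_in - pairs_out)
  if (!quiet) message("duplicate pairs removed\t", res$removed)
  res
}
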