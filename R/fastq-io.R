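#' In-memory set of FASTQ records
#'
#' A light column-oriented container for sequencing reads: parallel vectors
#' of identifiers, base sequences, and decoded integer quality scores.
#'
#' @param id Character vector of read identifiers (header line without the
#'   leading `@`); must be non-empty strings.
#' @param sequence Character vector of base sequences over
#'   `A/C/G/T/N` (lowercase accepted; bases are passed through unmodified).
#' @param quality List of integer vectors, one score per base.
#' @return An object of class `fastq_reads`.
#' @examples
#' r <- fastq_reads("read1", "ACGT", list(c(30L, 30L, 30L, 30L)))
#' n_reads(r)
#' @export
fastq_reads <- function(id = character(), sequence = character(),
                        quality = list()) {
  id <- as.character(id)
  sequence <- as.character(sequence)
  if (length(id) != length(sequence) || length(id) != length(quality))
    stop("id, sequence and quality must have equal lengths", call. = FALSE)
  if (any(!nzchar(id)))
    stop("read identifiers must be non-empty", call. = FALSE)
  qlen <- lengths(quality)
  bad <- which(nchar(sequence) != qlen)
  if (length(bad)) {
    stop(sprintf("read '%s': sequence length %d != quality length %d",
                 id[bad[1L]], nchar(sequence[bad[1L]]), qlen[bad[1L]]),
         call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, quality = quality),
            class = "fastq_reads")
}

#' @rdname fastq_reads
#' @param x A `fastq_reads` object.
#' @export
n_reads <- function(x) {
  stopifnot(inherits(x, "fastq_reads"))
  length(x$id)
}

#' @export
length.fastq_reads <- function(x) length(x$id)

#' @export
`[.fastq_reads` <- function(x, i) {
  fastq_reads(x$id[i], x$sequence[i], x$quality[i])
}

#' @export
print.fastq_reads <- function(x, ...) {
  n <- n_reads(x)
  cat(sprintf("<fastq_reads> %d record%s\n", n, if (n == 1L) "" else "s"))
  for (i in seq_len(min(n, 6L))) {
    cat(sprintf("  @%s  %s%s  (len %d)\n", x$id[i],
                substr(x$sequence[i], 1L, 40L),
                if (nchar(x$sequence[i]) > 40L) "..." else "",
                nchar(x$sequence[i])))
  }
  if (n > 6L) cat(sprintf("  ... and %d more\n", n - 6L))
  invisible(x)
}

# Concatenate fastq_reads objects.
concat_reads <- function(...) {
  parts <- list(...)
  fastq_reads(
    unlist(lapply(parts, `[[`, "id")),
    unlist(lapply(parts, `[[`, "sequence")),
    do.call(c, lapply(parts, `[[`, "quality"))
  )
}

#' Is a file gzip-compressed?
#'
#' Sniffs the two gzip magic bytes.
#'
#' @param path Path to an existing file.
#' @return `TRUE` if the file starts with the gzip magic bytes.
#' @export
is_gzipped <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

# Convert a block of raw FASTQ lines (length divisible by 4) into
# fastq_reads. `first_record` is the 1-based index of the first record in
# the file, for error messages.
parse_fastq_lines <- function(lines, encoding, first_record = 1L) {
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop(sprintf("record %d: header line does not start with '@'",
                 first_record + bad[1L] - 1L), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("record %d: '+' separator line missing",
                 first_record + bad[1L] - 1L), call. = FALSE)
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf(
      "record %d ('%s'): sequence length %d != quality length %d",
      first_record + bad[1L] - 1L, sub("^@", "", hdr[bad[1L]]),
      nchar(seq[bad[1L]]), nchar(qual[bad[1L]])), call. = FALSE)
  }
  ids <- sub("^@", "", hdr)
  if (any(!nzchar(ids))) {
    bad <- which(!nzchar(ids))[1L]
    stop(sprintf("record %d: empty read identifier",
                 first_record + bad - 1L), call. = FALSE)
  }
  fastq_reads(ids, seq, decode_quality_all(qual, encoding, ids))
}

#' Open a streaming FASTQ reader
#'
#' Returns a closure that yields successive chunks of records, so files of
#' any size can be processed in bounded memory. Plain and gzip-compressed
#' files are both handled (gzip is detected transparently).
#'
#' @param path Path to a FASTQ file (4 lines per record; multi-line
#'   sequences are not supported).
#' @param encoding A [quality_encoding()] object or dialect name.
#' @param chunk_size Number of records per chunk.
#' @return A function that returns a [fastq_reads()] chunk, or `NULL` at
#'   end of file (the connection is closed automatically).
#' @seealso [read_fastq()] for small files.
#' @export
fastq_chunk_reader <- function(path, encoding, chunk_size = 5000L) {
  encoding <- as_quality_encoding(encoding)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  done <- FALSE
  record_no <- 1L
  reader <- function() {
    if (done) return(NULL)
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) {
      close(con); done <<- TRUE
      return(NULL)
    }
    if (length(lines) %% 4L != 0L) {
      close(con); done <<- TRUE
      stop(sprintf("truncated FASTQ record at record %d in '%s'",
                   record_no + length(lines) %/% 4L, path), call. = FALSE)
    }
    chunk <- tryCatch(
      parse_fastq_lines(lines, encoding, first_record = record_no),
      error = function(e) { close(con); done <<- TRUE; stop(e) })
    record_no <<- record_no + n_reads(chunk)
    if (n_reads(chunk) < chunk_size) { close(con); done <<- TRUE }
    chunk
  }
  attr(reader, "close") <- function() {
    if (!done) { close(con); done <<- TRUE }
  }
  reader
}

#' Read a whole FASTQ file into memory
#'
#' Convenience wrapper over [fastq_chunk_reader()] for files of modest
#' size; pipelines stream instead.
#'
#' @inheritParams fastq_chunk_reader
#' @return A [fastq_reads()] object (possibly empty).
#' @export
read_fastq <- function(path, encoding) {
  reader <- fastq_chunk_reader(path, encoding, chunk_size = 100000L)
  out <- fastq_reads()
  repeat {
    chunk <- reader()
    if (is.null(chunk)) break
    out <- concat_reads(out, chunk)
  }
  out
}

#' Open a streaming paired-end FASTQ reader
#'
#' Reads two mate files in lockstep; mates are paired by ordinal position
#' (record i of file 1 with record i of file 2), the convention for
#' Illumina paired-end file pairs.
#'
#' @param path1,path2 The two mate FASTQ files.
#' @inheritParams fastq_chunk_reader
#' @return A function yielding `list(mate1 =, mate2 =)` chunks of equal
#'   record count, or `NULL` at end of input. If one file runs out before
#'   the other, an error names the longer file.
#' @export
pair_chunk_reader <- function(path1, path2, encoding, chunk_size = 5000L) {
  r1 <- fastq_chunk_reader(path1, encoding, chunk_size)
  r2 <- fastq_chunk_reader(path2, encoding, chunk_size)
  function() {
    c1 <- r1()
    c2 <- r2()
    n1 <- if (is.null(c1)) 0L else n_reads(c1)
    n2 <- if (is.null(c2)) 0L else n_reads(c2)
    if (n1 != n2) {
      longer <- if (n1 > n2) path1 else path2
      attr(r1, "close")(); attr(r2, "close")()
      stop(sprintf("mate files are out of step: '%s' has more records",
                   longer), call. = FALSE)
    }
    if (n1 == 0L) return(NULL)
    list(mate1 = c1, mate2 = c2)
  }
}

#' Read two mate FASTQ files into memory
#'
#' @inheritParams pair_chunk_reader
#' @return `list(mate1 =, mate2 =)` of [fastq_reads()] with equal counts.
#' @export
read_pairs <- function(path1, path2, encoding) {
  reader <- pair_chunk_reader(path1, path2, encoding, chunk_size = 100000L)
  m1 <- fastq_reads(); m2 <- fastq_reads()
  repeat {
    chunk <- reader()
    if (is.null(chunk)) break
    m1 <- concat_reads(m1, chunk$mate1)
    m2 <- concat_reads(m2, chunk$mate2)
  }
  list(mate1 = m1, mate2 = m2)
}

# Format fastq_reads as FASTQ lines ('+' separator written bare).
format_fastq_lines <- function(reads, encoding) {
  encoding <- as_quality_encoding(encoding)
  n <- n_reads(reads)
  if (n == 0L) return(character())
  qual <- vapply(reads$quality, encode_quality, "", encoding = encoding)
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$id)
  lines[seq(2L, by = 4L, length.out = n)] <- reads$sequence
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- qual
  lines
}

#' Open a streaming FASTQ writer
#'
#' @param path Output path.
#' @param encoding A [quality_encoding()] object or dialect name.
#' @param gzip Write gzip-compressed output? `NA` infers from a `.gz`
#'   suffix on `path`.
#' @return A list with functions `write(reads)` (appends a chunk, returns
#'   the record count so far) and `close()` (closes the file and returns
#'   the total record count).
#' @export
fastq_writer <- function(path, encoding, gzip = NA) {
  encoding <- as_quality_encoding(encoding)
  if (is.na(gzip)) gzip <- endsWith(path, ".gz")
  con <- if (gzip) gzfile(path, open = "wt") else file(path, open = "wt")
  count <- 0L
  open_flag <- TRUE
  list(
    write = function(reads) {
      writeLines(format_fastq_lines(reads, encoding), con)
      count <<- count + n_reads(reads)
      invisible(count)
    },
    close = function() {
      if (open_flag) { close(con); open_flag <<- FALSE }
      count
    }
  )
}

#' Write FASTQ records to a file
#'
#' Output is re-readable by [read_fastq()] into identical records; the
#' `+` separator line is written bare.
#'
#' @param reads A [fastq_reads()] object.
#' @inheritParams fastq_writer
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(reads, path, encoding, gzip = NA) {
  w <- fastq_writer(path, encoding, gzip)
  w$write(reads)
  invisible(w$close())
}
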