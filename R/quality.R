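#' Quality-score encodings
#'
#' Describes how per-base quality scores are stored in a FASTQ file. Three
#' dialects are supported:
#'
#' * `"sanger"`: ASCII offset 33, Phred scale (`p = 10^(-Q/10)`). The
#'   modern standard (Illumina 1.8+, CASAVA >= 1.8).
#' * `"illumina"`: ASCII offset 64, Phred scale (Illumina 1.3--1.7).
#' * `"solexa"`: ASCII offset 64, log-odds scale
#'   (`p = 1 / (1 + 10^(Q/10))`), as produced by the original Solexa
#'   pipeline; scores may be as low as -5.
#'
#' Dialects are never auto-detected from data: offsets 64 and 33 overlap
#' over a wide score range, so silent mis-scoring would be easy. State the
#' dialect explicitly.
#'
#' @param dialect One of `"sanger"`, `"illumina"`, `"solexa"`.
#' @return An object of class `quality_encoding`: a list with elements
#'   `dialect`, `ascii_offset` (33 or 64), `scale` (`"phred"` or
#'   `"solexa_odds"`), `min_score` and `max_score` (the encodable range).
#' @examples
#' quality_encoding("sanger")
#' quality_encoding("solexa")$min_score  # -5
#' @export
quality_encoding <- function(dialect = c("sanger", "illumina", "solexa")) {
  dialect <- match.arg(dialect)
  offset <- if (dialect == "sanger") 33L else 64L
  scale <- if (dialect == "solexa") "solexa_odds" else "phred"
  structure(
    list(
      dialect = dialect,
      ascii_offset = offset,
      scale = scale,
      min_score = if (scale == "solexa_odds") -5L else 0L,
      max_score = 126L - offset
    ),
    class = "quality_encoding"
  )
}

#' @export
print.quality_encoding <- function(x, ...) {
  cat(sprintf("<quality_encoding> %s: ASCII offset %d, %s scale, scores %d..%d\n",
              x$dialect, x$ascii_offset,
              if (x$scale == "phred") "Phred" else "Solexa log-odds",
              x$min_score, x$max_score))
  invisible(x)
}

as_quality_encoding <- function(encoding) {
  if (inherits(encoding, "quality_encoding")) return(encoding)
  if (is.character(encoding) && length(encoding) == 1L)
    return(quality_encoding(encoding))
  stop("`encoding` must be a quality_encoding object or a dialect name",
       call. = FALSE)
}

#' Decode a FASTQ quality string into integer scores
#'
#' @param qual A single quality string (one character per base).
#' @param encoding A [quality_encoding()] object or dialect name.
#' @param id Optional read identifier used in error messages.
#' @return Integer vector of quality scores, one per base.
#' @examples
#' decode_quality("II5", "sanger")          # 40 40 20
#' decode_quality("hh", "illumina")         # 40 40
#' @export
decode_quality <- function(qual, encoding, id = NULL) {
  encoding <- as_quality_encoding(encoding)
  stopifnot(is.character(qual), length(qual) == 1L)
  scores <- utf8ToInt(qual) - encoding$ascii_offset
  bad <- which(scores < encoding$min_score)
  if (length(bad)) {
    stop(sprintf(
      "malformed quality string%s: character '%s' at position %d is below the %s range (score %d < %d)",
      if (is.null(id)) "" else paste0(" in read '", id, "'"),
      substr(qual, bad[1L], bad[1L]), bad[1L], encoding$dialect,
      scores[bad[1L]], encoding$min_score), call. = FALSE)
  }
  scores
}

# Vectorized decoding for a character vector of quality strings; returns a
# list of integer score vectors. Range violations are reported with the
# offending read's id.
decode_quality_all <- function(quals, encoding, ids = NULL) {
  encoding <- as_quality_encoding(encoding)
  offset <- encoding$ascii_offset
  scores <- lapply(quals, function(q) utf8ToInt(q) - offset)
  mins <- vapply(scores, function(s) if (length(s)) min(s) else encoding$min_score, 0L)
  bad <- which(mins < encoding$min_score)
  if (length(bad)) {
    i <- bad[1L]
    decode_quality(quals[i], encoding,
                   id = if (is.null(ids)) paste0("record ", i) else ids[i])
  }
  scores
}

#' Encode integer quality scores as a FASTQ quality string
#'
#' Inverse of [decode_quality()].
#'
#' @param scores Integer vector of quality scores.
#' @param encoding A [quality_encoding()] object or dialect name.
#' @return A single quality string.
#' @examples
#' encode_quality(c(40, 40), "sanger")  # "II"
#' encode_quality(0, "illumina")        # "@"
#' @export
encode_quality <- function(scores, encoding) {
  encoding <- as_quality_encoding(encoding)
  scores <- as.integer(scores)
  bad <- which(scores < encoding$min_score | scores > encoding$max_score)
  if (length(bad)) {
    stop(sprintf(
      "score %d at position %d is outside the encodable %s range [%d, %d]",
      scores[bad[1L]], bad[1L], encoding$dialect,
      encoding$min_score, encoding$max_score), call. = FALSE)
  }
  if (!length(scores)) return("")
  intToUtf8(scores + encoding$ascii_offset)
}

#' Convert a quality score to a sequencing-error probability
#'
#' On the Phred scale `p = 10^(-Q/10)`; on the Solexa log-odds scale
#' `p = 1 / (1 + 10^(Q/10))`. The two agree closely for Q >= 30 but
#' diverge at low quality (Q = 10 gives 0.1 on the Phred scale but 0.0909
#' on the odds scale). Error probabilities are informational (reporting,
#' simulation); all trimming decisions compare integer scores against
#' integer thresholds.
#'
#' @param score Numeric vector of quality scores.
#' @param scale `"phred"`, `"solexa_odds"`, or a [quality_encoding()]
#'   whose scale is used.
#' @return Numeric vector of error probabilities in (0, 1].
#' @examples
#' error_probability(25, "solexa_odds")  # ~0.0032
#' error_probability(10, "solexa_odds")  # ~0.0909
#' error_probability(0, "phred")         # 1
#' @export
error_probability <- function(score, scale = "phred") {
  if (inherits(scale, "quality_encoding")) scale <- scale$scale
  if (!is.character(scale) || length(scale) != 1L ||
      !scale %in% c("phred", "solexa_odds")) {
    stop("`scale` must be \"phred\" or \"solexa_odds\"", call. = FALSE)
  }
  if (scale == "phred") {
    if (any(score < 0)) stop("Phred scores must be >= 0", call. = FALSE)
    10^(-score / 10)
  } else {
    if (any(score < -5)) stop("Solexa scores must be >= -5", call. = FALSE)
    1 / (1 + 10^(score / 10))
  }
}

# Inverse of error_probability on either scale; returns a real-valued
# score (not rounded to integer).
score_from_error_probability <- function(p, scale = "phred") {
  if (inherits(scale, "quality_encoding")) scale <- scale$scale
  stopifnot(all(p > 0), all(p <= 1))
  if (scale == "phred") -10 * log10(p) else 10 * log10((1 - p) / p)
}
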