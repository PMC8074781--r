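#' Circular DNA sequence
#'
#' A light container for a (usually circular) DNA sequence. All coordinates
#' in the package are 0-based, half-open, and interpreted modulo the length
#' when the sequence is circular; intervals may have `end > length` to
#' denote wraparound across the origin.
#'
#' @param seq single DNA string over A/C/G/T/N.
#' @param id sequence identifier.
#' @param circular logical; is the molecule circular?
#' @return an object of class `circ_seq` with fields `id`, `seq`, `length`,
#'   `circular`.
#' @export
circ_seq <- function(seq, id = "seq", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  structure(
    list(id = as.character(id), seq = seq, length = nchar(seq),
         circular = isTRUE(circular)),
    class = "circ_seq"
  )
}

#' @export
print.circ_seq <- function(x, ...) {
  cat(sprintf("<circ_seq> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.circ_seq <- function(x) x$length

#' Reverse complement of a DNA string
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) cpp_revcomp(seq)

#' Extract a subsequence with modulo-length coordinates
#'
#' On a circular sequence `end` may exceed the length (wraparound); the
#' start is reduced modulo the length first.
#'
#' @param x a [circ_seq()].
#' @param start,end 0-based half-open interval; `end - start` must not
#'   exceed twice the length.
#' @return DNA string.
#' @export
subseq_circular <- function(x, start, end) {
  stopifnot(inherits(x, "circ_seq"), end > start, end - start <= 2 * x$length)
  span <- end - start
  start <- start %% x$length
  s2 <- if (x$circular) strrep(x$seq, ceiling((start + span) / x$length)) else x$seq
  if (start + span > nchar(s2)) {
    stop("interval extends past the end of a linear sequence", call. = FALSE)
  }
  substr(s2, start + 1L, start + span)
}

#' Canonical rotation of a circular sequence
#'
#' Returns the lexicographically minimal rotation over both strands, the
#' normal form used when comparing independently assembled circles.
#'
#' @param x a [circ_seq()] or DNA string.
#' @return a `circ_seq` in normal form (same id).
#' @export
normalize_rotation <- function(x) {
  s <- if (inherits(x, "circ_seq")) x$seq else x
  id <- if (inherits(x, "circ_seq")) x$id else "seq"
  rot <- function(z) {
    i <- cpp_min_rotation(z)
    paste0(substr(z, i + 1L, nchar(z)), substr(z, 1L, i))
  }
  fwd <- rot(s)
  rev <- rot(revcomp(s))
  circ_seq(if (fwd <= rev) fwd else rev, id = id, circular = TRUE)
}

#' Doubled form of a circular sequence
#'
#' Concatenates the sequence with itself so that any window of up to one
#' full length can be read without modular arithmetic.
#'
#' @param x a [circ_seq()].
#' @return DNA string of length `2 * length(x)`.
#' @export
doubled <- function(x) {
  stopifnot(inherits(x, "circ_seq"))
  strrep(x$seq, 2L)
}

#' Feature annotation table
#'
#' Validates and normalizes a feature table (tibble with columns `name`,
#' `kind`, `start`, `end`, `strand`). `end` may exceed the sequence length
#' to denote a feature wrapping the origin.
#'
#' @param name,kind,start,end,strand vectors of equal length; `kind` one of
#'   PCG, tRNA, rRNA, CR, TR, ssA, other.
#' @param length sequence length the features live on (for validation).
#' @return a tibble of class `feature_table`.
#' @export
feature_table <- function(name, kind, start, end, strand = "+", length = NULL) {
  kinds <- c("PCG", "tRNA", "rRNA", "CR", "TR", "ssA", "other")
  stopifnot(all(kind %in% kinds), all(start < end))
  ft <- tibble(name = as.character(name), kind = as.character(kind),
               start = as.integer(start), end = as.integer(end),
               strand = rep_len(as.character(strand), base::length(name)))
  if (!is.null(length)) {
    stopifnot(all(ft$start >= 0), all(ft$start < length),
              all(ft$end - ft$start <= 2L * length))
  }
  class(ft) <- c("feature_table", class(ft))
  ft
}
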