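#' Count canonical k-mers
#'
#' Canonical counting (a k-mer and its reverse complement are the same key,
#' keyed by the lexicographically smaller of the two); k-mers containing N
#' are skipped entirely. The default k = 23 matches the word size used to
#' profile the raw short reads.
#'
#' @param x a `read_set` (paired reads are counted; long reads are not), a
#'   character vector of sequences, or a [circ_seq()] (counted around the
#'   circle, including origin-spanning windows).
#' @param k odd word size, 11–31.
#' @param solid_min minimum count for a k-mer to be considered solid
#'   (genuine rather than a sequencing error).
#' @return object of class `kmer_table`: fields `k`, `kmer`, `count`,
#'   `solid_min`.
#' @export
count_kmers <- function(x, k = 23L, solid_min = 3L) {
  stopifnot(k %% 2 == 1, k >= 11, k <= 31)
  seqs <- kmer_input_seqs(x, k)
  res <- cpp_count_kmers(seqs, as.integer(k))
  structure(list(k = as.integer(k), kmer = as.character(res$kmer),
                 count = as.integer(res$count), solid_min = as.integer(solid_min)),
            class = "kmer_table")
}

kmer_input_seqs <- function(x, k) {
  if (inherits(x, "read_set")) c(x$paired$read1, x$paired$read2)
  else if (inherits(x, "circ_seq")) {
    if (x$circular) paste0(x$seq, substr(x$seq, 1L, k - 1L)) else x$seq
  } else if (is.character(x)) x
  else stop("unsupported input for k-mer counting", call. = FALSE)
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d, %s distinct canonical k-mers, solid_min=%d\n",
              x$k, format(length(x$kmer), big.mark = ","), x$solid_min))
  invisible(x)
}

# lookup environment: every table k-mer and its reverse complement map to
# the canonical count, so walk steps need no canonicalization
kmer_lookup_env <- function(table) {
  counts <- c(setNames(table$count, table$kmer),
              setNames(table$count, cpp_revcomp(table$kmer)))
  list2env(as.list(counts), hash = TRUE, size = length(counts) * 2L)
}

kmer_count_of <- function(env, kmers) {
  vapply(kmers, function(w) {
    if (is.na(w)) 0L else get0(w, envir = env, ifnotfound = 0L)
  }, 0L, USE.NAMES = FALSE)
}

#' Map k-mer counts onto a reference
#'
#' Per-start coverage profile: the canonical count of the k-mer starting at
#' each reference position (0 where absent). Circular references wrap, so
#' the profile has one entry per position; linear references have
#' `length - k + 1` entries.
#'
#' @param table a [count_kmers()] table.
#' @param reference a [circ_seq()].
#' @return object of class `coverage_profile`: `reference_id`, `k`,
#'   `coverage` (integer vector).
#' @export
map_kmer_coverage <- function(table, reference) {
  stopifnot(inherits(table, "kmer_table"), inherits(reference, "circ_seq"),
            table$k <= reference$length)
  s <- if (reference$circular)
    paste0(reference$seq, substr(reference$seq, 1L, table$k - 1L))
  else reference$seq
  wins <- cpp_window_kmers(s, table$k, TRUE)
  env <- kmer_lookup_env(table)
  structure(list(reference_id = reference$id, k = table$k,
                 coverage = kmer_count_of(env, wins)),
            class = "coverage_profile")
}

#' Recruit reads sharing k-mers with a bait set
#'
#' Retains a read (or read pair) when it shares at least `min_shared`
#' distinct canonical k-mers with the bait table — the same logic used to
#' fish mitochondrial reads out of whole-genome data with k-mers from a
#' draft mitogenome.
#'
#' @param reads a `read_set` (pairs retained jointly) or character vector.
#' @param bait a [count_kmers()] table built from the draft/bait sequence.
#' @param min_shared minimum number of shared distinct canonical k-mers.
#' @return same type as `reads`, subset to the recruited reads.
#' @export
recruit_reads <- function(reads, bait, min_shared = 1L) {
  stopifnot(inherits(bait, "kmer_table"), length(bait$kmer) > 0)
  if (inherits(reads, "read_set")) {
    n1 <- cpp_shared_kmer_counts(reads$paired$read1, bait$kmer, bait$k)
    n2 <- cpp_shared_kmer_counts(reads$paired$read2, bait$kmer, bait$k)
    keep_p <- (n1 + n2) >= min_shared
    out <- reads
    out$paired <- reads$paired[keep_p, , drop = FALSE]
    if (nrow(reads$long) > 0) {
      nl <- cpp_shared_kmer_counts(reads$long$seq, bait$kmer, bait$k)
      out$long <- reads$long[nl >= min_shared, , drop = FALSE]
    }
    out
  } else {
    n <- cpp_shared_kmer_counts(reads, bait$kmer, bait$k)
    reads[n >= min_shared]
  }
}

#' Classify solid and weak regions of a long read and trim
#'
#' A base is solid when it is covered by at least one k-mer whose canonical
#' count reaches `table$solid_min`; the retained interval is the longest
#' run of solid bases (leftmost on ties). This is the simplified
#' solid/weak-region classification used to trim error-prone long reads
#' against a short-read k-mer spectrum.
#'
#' @param long_read a DNA string.
#' @param table a [count_kmers()] table with `solid_min` set.
#' @param read_id identifier carried into the result.
#' @return object of class `solidity_mask`: `read_id`, `mask` (logical,
#'   TRUE = solid), `trimmed` (0-based half-open retained interval),
#'   `trimmed_seq`.
#' @export
trim_weak_regions <- function(long_read, table, read_id = "read") {
  stopifnot(inherits(table, "kmer_table"))
  n <- nchar(long_read)
  mask <- rep(FALSE, n)
  if (n >= table$k) {
    wins <- cpp_window_kmers(long_read, table$k, TRUE)
    env <- kmer_lookup_env(table)
    solid_start <- kmer_count_of(env, wins) >= table$solid_min
    idx <- which(solid_start)
    for (p in idx) mask[p:(p + table$k - 1L)] <- TRUE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  solid_runs <- which(r$values)
  if (length(solid_runs) == 0) {
    trimmed <- c(0L, 0L)
  } else {
    best <- solid_runs[which.max(r$lengths[solid_runs])]
    trimmed <- c(starts[best], ends[best])
  }
  structure(list(read_id = read_id, mask = mask,
                 trimmed = as.integer(trimmed),
                 trimmed_seq = substr(long_read, trimmed[1] + 1L, trimmed[2])),
            class = "solidity_mask")
}
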