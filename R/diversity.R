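#' Build an alignment matrix from aligned sequences
#'
#' @param x named character vector of equal-length aligned sequences
#'   (characters A, C, G, T, N, `-`), a `DNAStringSet`, or a path to an
#'   aligned FASTA file.
#' @return object of class `alignment_matrix`: `taxa`, `mat` (character
#'   matrix, taxa x columns), `length`.
#' @export
alignment_matrix <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- read_fasta(x)
  }
  if (inherits(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  stopifnot(is.character(x), length(x) >= 2)
  if (is.null(names(x))) names(x) <- paste0("taxon", seq_along(x))
  lens <- nchar(x)
  if (length(unique(lens)) != 1) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  rownames(mat) <- names(x)
  bad <- !(mat %in% c("A", "C", "G", "T", "N", "-"))
  mat[bad] <- "N"
  structure(list(taxa = names(x), mat = mat, length = ncol(mat)),
            class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("<alignment_matrix> %d taxa x %s columns\n", length(x$taxa),
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Columns at which two aligned taxa disagree
#'
#' Columns where either taxon has N are skipped; a gap against a base
#' counts as a difference only when `count_gaps` is TRUE; gap-vs-gap never
#' counts.
#'
#' @param aln an [alignment_matrix()].
#' @param ref_taxon,other taxon ids.
#' @param count_gaps logical (default FALSE).
#' @return tibble of class `difference_list` with sorted 0-based column
#'   `position`s, plus attributes `ref_taxon`, `other_taxon`, `length`.
#' @export
pairwise_differences <- function(aln, ref_taxon, other, count_gaps = FALSE) {
  stopifnot(inherits(aln, "alignment_matrix"))
  for (t in c(ref_taxon, other)) {
    if (!t %in% aln$taxa) stop(sprintf("unknown taxon '%s'", t), call. = FALSE)
  }
  a <- aln$mat[ref_taxon, ]
  b <- aln$mat[other, ]
  usable <- a != "N" & b != "N"
  if (!count_gaps) usable <- usable & a != "-" & b != "-"
  diff <- usable & a != b & !(a == "-" & b == "-")
  out <- tibble(position = which(diff) - 1L)
  attr(out, "ref_taxon") <- ref_taxon
  attr(out, "other_taxon") <- other
  attr(out, "length") <- aln$length
  class(out) <- c("difference_list", class(out))
  out
}

#' Variant counts per window block
#'
#' Counts difference positions in consecutive `window`-bp blocks from
#' column 0; the final partial block keeps its raw count (no per-bp
#' normalization). This is the per-100-bp disagreement track drawn around
#' the mitogenome circle.
#'
#' @param diffs a [pairwise_differences()] list, or an integer vector of
#'   0-based positions.
#' @param length total alignment length in columns (taken from `diffs`
#'   when available).
#' @param window block width in bp (default 100).
#' @return tibble of class `density_track`: `block` (0-based), `start`,
#'   `end`, `count`; attribute `total`.
#' @export
block_density <- function(diffs, length = NULL, window = 100L) {
  stopifnot(window >= 1)
  pos <- if (is.data.frame(diffs)) diffs$position else as.integer(diffs)
  length <- length %||% attr(diffs, "length")
  stopifnot(!is.null(length), all(pos >= 0), all(pos < length))
  n_blocks <- ceiling(length / window)
  block <- pos %/% window
  counts <- tabulate(block + 1L, nbins = n_blocks)
  out <- tibble(
    block = seq_len(n_blocks) - 1L,
    start = (seq_len(n_blocks) - 1L) * as.integer(window),
    end = pmin(seq_len(n_blocks) * as.integer(window), as.integer(length)),
    count = as.integer(counts)
  )
  attr(out, "total") <- base::length(pos)
  attr(out, "window") <- as.integer(window)
  class(out) <- c("density_track", class(out))
  out
}

#' Nucleotide diversity (pi)
#'
#' Mean over all unordered sequence pairs of the proportion of differing
#' sites among comparable sites, where a site is comparable for a pair
#' when both sequences carry an unambiguous base (pairwise deletion of
#' gaps and N). Pairs with no comparable columns are excluded with a
#' warning.
#'
#' @param aln an [alignment_matrix()].
#' @return nucleotide diversity as a fraction.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "alignment_matrix"))
  n <- length(aln$taxa)
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- aln$mat[i, ]
      b <- aln$mat[j, ]
      comp <- a %in% DNA_BASES & b %in% DNA_BASES
      if (!any(comp)) {
        warning(sprintf("no comparable columns for pair (%s, %s); excluded",
                        aln$taxa[i], aln$taxa[j]), call. = FALSE)
        next
      }
      vals <- c(vals, sum(a[comp] != b[comp]) / sum(comp))
    }
  }
  mean(vals)
}

#' Pairwise identity matrix
#'
#' identity(i, j) = 100 x matches / columns where both taxa carry a base
#' (A, C, G, or T). The diagonal is 100 and the matrix is symmetric.
#'
#' @param aln an [alignment_matrix()].
#' @return symmetric numeric matrix of percent identities.
#' @export
identity_matrix <- function(aln) {
  stopifnot(inherits(aln, "alignment_matrix"))
  n <- length(aln$taxa)
  m <- matrix(100, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- aln$mat[i, ]
      b <- aln$mat[j, ]
      comp <- a %in% DNA_BASES & b %in% DNA_BASES
      id <- if (any(comp)) 100 * sum(a[comp] == b[comp]) / sum(comp) else NA_real_
      m[i, j] <- m[j, i] <- id
    }
  }
  m
}
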