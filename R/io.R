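#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, a [circ_seq()], or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "circ_seq")) seqs <- setNames(seqs$seq, seqs$id)
  if (is.list(seqs)) {
    seqs <- setNames(vapply(seqs, function(x) x$seq, ""),
                     vapply(seqs, function(x) x$id, ""))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Paired reads go to `<stem>_1.fastq` and `<stem>_2.fastq`, long reads to
#' `<stem>_long.fastq`; qualities are uniform placeholders (the simulator
#' has no quality model).
#'
#' @param reads a `read_set`.
#' @param stem output path stem.
#' @return character vector of files written, invisibly.
#' @export
write_fastq <- function(reads, stem) {
  stopifnot(inherits(reads, "read_set"))
  write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
      strrep("I", n), ""))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
    path
  }
  files <- c()
  if (nrow(reads$paired) > 0) {
    ids <- sprintf("pair%06d", seq_len(nrow(reads$paired)))
    files <- c(files,
               write_one(reads$paired$read1, ids, paste0(stem, "_1.fastq")),
               write_one(reads$paired$read2, ids, paste0(stem, "_2.fastq")))
  }
  if (nrow(reads$long) > 0) {
    files <- c(files,
               write_one(reads$long$seq,
                         sprintf("long%04d", seq_len(nrow(reads$long))),
                         paste0(stem, "_long.fastq")))
  }
  invisible(files)
}

#' Read paired FASTQ files into a read set
#'
#' @param fastq1,fastq2 mate FASTQ files.
#' @param long optional long-read FASTQ.
#' @return a `read_set` (origin fields are NA; files carry no truth).
#' @export
read_fastq <- function(fastq1, fastq2, long = NULL) {
  r1 <- as.character(Biostrings::readDNAStringSet(fastq1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fastq2, format = "fastq"))
  stopifnot(length(r1) == length(r2))
  lr <- if (!is.null(long))
    as.character(Biostrings::readDNAStringSet(long, format = "fastq"))
  else character(0)
  structure(list(
    paired = tibble(read1 = unname(r1), read2 = unname(r2),
                    origin = NA_character_, frag_start = NA_integer_,
                    insert = NA_integer_, strand = NA_character_),
    long = tibble(seq = unname(lr), origin = NA_character_,
                  start = NA_integer_, length = nchar(lr),
                  error_rate = NA_real_, strand = NA_character_),
    profile = NULL
  ), class = "read_set")
}

# tab-separated writer with a commented header naming the conventions
write_track_tsv <- function(df, path, comment_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a feature table
#'
#' Tab-separated: name, kind, start, end, strand; 0-based half-open
#' coordinates, stated in a commented header.
#'
#' @param features a [feature_table()].
#' @param path output file.
#' @export
write_features <- function(features, path) {
  write_track_tsv(features[, c("name", "kind", "start", "end", "strand")],
                  path, "feature table; coordinates 0-based half-open, bp")
}

#' Read a feature table written by [write_features()]
#'
#' @param path file path.
#' @param length optional sequence length for validation.
#' @return a [feature_table()].
#' @export
read_features <- function(path, length = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  feature_table(df$name, df$kind, df$start, df$end, df$strand, length = length)
}

#' Write a variant-density track
#'
#' BED-like tab-separated block track consumable by circular plotters.
#'
#' @param track a [block_density()] track.
#' @param path output file.
#' @param id sequence name for the first column.
#' @export
write_density_track <- function(track, path, id = "mitogenome") {
  df <- tibble(seq = id, start = track$start, end = track$end,
               count = track$count)
  write_track_tsv(df, path,
                  sprintf("variant density per %d bp block; 0-based half-open",
                          attr(track, "window")))
}

#' Write a NUMT hit table
#'
#' BED-compatible first three columns (nuclear id, start, end) followed by
#' mito coordinates, strand, identity, e-value, score.
#'
#' @param hits a [numt_search()] table.
#' @param path output file.
#' @export
write_numt_hits <- function(hits, path) {
  cfg <- attr(hits, "config")
  hdr <- "NUMT hits; coordinates 0-based half-open; identity in percent"
  if (!is.null(cfg)) {
    hdr <- c(hdr, sprintf(
      "scoring: match %+d mismatch %+d gap %d/%d; lambda %.3f K %.2f; E <= %g; word %d",
      cfg$match, cfg$mismatch, cfg$gap_open, cfg$gap_extend,
      cfg$lambda, cfg$karlin_k, cfg$evalue_max, cfg$word))
  }
  write_track_tsv(as.data.frame(hits), path, hdr)
}

#' Write a k-mer table
#'
#' @param table a [count_kmers()] table.
#' @param path output file.
#' @export
write_kmer_table <- function(table, path) {
  write_track_tsv(tibble(kmer = table$kmer, count = table$count), path,
                  sprintf("canonical %d-mer counts; solid_min=%d",
                          table$k, table$solid_min))
}

#' Read / write newick trees
#'
#' Thin wrappers over `ape` so the package round-trips its own files.
#'
#' @param tree an `ape::phylo` object.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` its path,
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
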