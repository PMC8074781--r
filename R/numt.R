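#' Configuration for the NUMT search
#'
#' Scoring follows blastn-style conventions (positive reward, negative
#' penalty, positive gap costs) with the corresponding Karlin-Altschul
#' parameters; e-values come from `E = K * m * n * exp(-lambda * S)`. The
#' scoring scheme and statistical parameters are recorded in every report
#' so hit lists are auditable.
#'
#' @param evalue_max e-value cutoff (hits above it are dropped).
#' @param word exact seed word size.
#' @param match,mismatch,gap_open,gap_extend alignment scores/penalties.
#' @param lambda,karlin_k Karlin-Altschul parameters for the scheme.
#' @return list of class `numt_config`.
#' @export
numt_config <- function(evalue_max = 1e-4, word = 11L,
                        match = 2L, mismatch = -3L,
                        gap_open = 5L, gap_extend = 2L,
                        lambda = 0.625, karlin_k = 0.41) {
  stopifnot(evalue_max > 0, match > 0, mismatch < 0,
            gap_open >= 0, gap_extend > 0, lambda > 0, karlin_k > 0)
  structure(list(evalue_max = evalue_max, word = as.integer(word),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, karlin_k = karlin_k),
            class = "numt_config")
}

empty_numt_hits <- function() {
  tibble(nuclear_id = character(), nuclear_start = integer(),
         nuclear_end = integer(), mito_start = integer(), mito_end = integer(),
         strand = character(), aligned_length = integer(),
         identity = double(), evalue = double(), score = integer())
}

#' Search a nuclear assembly for copies of the mitogenome
#'
#' Seeded, gapped local alignment of the mitogenome (doubled, so hits may
#' cross the origin) against each nuclear sequence, both strands. Exact
#' word seeds are clustered by diagonal and extended by banded
#' Smith-Waterman with affine gaps; hits are kept when their e-value is at
#' or below `config$evalue_max`. Identity is the percentage of matching
#' columns among columns where both sequences carry a base.
#'
#' @param mito a [circ_seq()] mitogenome (the query).
#' @param nuclear named character vector of nuclear sequences, or a
#'   `nuclear_background` from [plant_numts()].
#' @param config a [numt_config()].
#' @return tibble of hits (class `numt_hits`): nuclear_id, nuclear_start,
#'   nuclear_end, mito_start, mito_end (0-based half-open, mito coordinates
#'   modulo the circle), strand, aligned_length, identity (percent),
#'   evalue, score; sorted by nuclear coordinate.
#' @export
numt_search <- function(mito, nuclear, config = numt_config()) {
  stopifnot(inherits(mito, "circ_seq"), inherits(config, "numt_config"))
  if (inherits(nuclear, "nuclear_background")) {
    nuclear <- c(nuclear_genome = nuclear$seq)
  }
  if (is.null(names(nuclear))) {
    names(nuclear) <- paste0("nuclear", seq_along(nuclear))
  }
  L <- mito$length
  q2 <- if (mito$circular) doubled(mito) else mito$seq
  total_n <- sum(nchar(nuclear))
  # min raw score that can reach the cutoff: E = K m n exp(-lambda S)
  min_score <- ceiling(log(config$karlin_k * L * total_n / config$evalue_max) /
                         config$lambda)
  out <- list()
  for (sid in names(nuclear)) {
    subj <- nuclear[[sid]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") q2 else revcomp(q2)
      h <- cpp_seed_extend(q, subj, config$word, config$match, config$mismatch,
                           config$gap_open, config$gap_extend,
                           as.integer(min_score), 24L)
      if (nrow(h) == 0) next
      h <- as_tibble(h)
      # map query coords back to forward mito circle
      if (strand == "-") {
        qs <- nchar(q) - h$q_end
        qe <- nchar(q) - h$q_start
      } else {
        qs <- h$q_start
        qe <- h$q_end
      }
      out[[length(out) + 1L]] <- tibble(
        nuclear_id = sid,
        nuclear_start = h$s_start, nuclear_end = h$s_end,
        mito_start = qs %% L, mito_end = qs %% L + (qe - qs),
        strand = strand,
        aligned_length = (h$q_end - h$q_start) + h$q_gaps,
        identity = 100 * h$matches / (h$matches + h$mismatches),
        evalue = config$karlin_k * L * total_n *
          exp(-config$lambda * h$score),
        score = h$score)
    }
  }
  hits <- if (length(out)) dplyr::bind_rows(out) else empty_numt_hits()
  hits <- hits[hits$evalue <= config$evalue_max, , drop = FALSE]
  # the doubled query reports origin-crossing hits twice: collapse
  hits <- dedupe_identical_hits(hits)
  hits <- hits[order(hits$nuclear_id, hits$nuclear_start), , drop = FALSE]
  attr(hits, "config") <- config   # scoring scheme is part of the result
  class(hits) <- c("numt_hits", class(hits))
  hits
}

# identical matches (same nuclear interval, mito interval, strand) count once;
# hits wholly contained in a higher-scoring hit on the same interval pair are
# collapsed as well (seed clusters can rediscover fragments of one alignment)
dedupe_identical_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  key <- paste(hits$nuclear_id, hits$nuclear_start, hits$nuclear_end,
               hits$mito_start %% 1e9, hits$mito_end, hits$strand)
  hits <- hits[!duplicated(key), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  ord <- order(hits$score, decreasing = TRUE)
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    for (j in seq_along(ord)) {
      b <- ord[j]
      if (a == b || !keep[b]) next
      if (hits$nuclear_id[a] == hits$nuclear_id[b] &&
          hits$strand[a] == hits$strand[b] &&
          hits$nuclear_start[b] >= hits$nuclear_start[a] &&
          hits$nuclear_end[b] <= hits$nuclear_end[a] &&
          hits$score[b] <= hits$score[a]) {
        keep[b] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Calibrate the NUMT identity threshold from a mitogenome panel
#'
#' Returns the largest pairwise global-alignment identity (percent) among
#' the supplied mitogenomes. Candidate NUMT hits more similar to the
#' mitogenome than any two species' mitogenomes are to each other are taken
#' to be genuine mtDNA misassembled into the nuclear sequence, not nuclear
#' copies; this value is the filtering threshold.
#'
#' @param panel character vector (>= 2) of mitogenome sequences, or a list
#'   of [circ_seq()] objects.
#' @return largest pairwise identity, in percent.
#' @export
calibrate_identity_threshold <- function(panel) {
  if (is.list(panel)) {
    panel <- vapply(panel, function(x)
      if (inherits(x, "circ_seq")) x$seq else as.character(x), "")
  }
  if (length(panel) < 2) {
    stop("at least two mitogenomes are needed for calibration", call. = FALSE)
  }
  best <- 0
  for (i in seq_len(length(panel) - 1L)) {
    for (j in seq(i + 1L, length(panel))) {
      best <- max(best, 100 * identity_global(panel[i], panel[j]))
    }
  }
  best
}

#' Filter NUMT candidates by identity and collapse identical matches
#'
#' Hits with identity above the calibrated threshold are discarded as
#' genuine mitochondrial sequence misidentified as nuclear; identical
#' matches (same nuclear interval, mito interval, and strand) are counted
#' once.
#'
#' @param hits a [numt_search()] hit table.
#' @param threshold identity threshold in percent (e.g. from
#'   [calibrate_identity_threshold()]).
#' @return filtered hit tibble, sorted by nuclear coordinate.
#' @export
filter_and_dedupe <- function(hits, threshold) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 100)
  out <- hits[hits$identity <= threshold, , drop = FALSE]
  out <- dedupe_identical_hits(out)
  out[order(out$nuclear_id, out$nuclear_start), , drop = FALSE]
}

#' Summarize a deduplicated NUMT hit list
#'
#' Produces the summary the study reports for the nuclear genome: hit
#' count, length range, number of segments over 1000 bp, mean +/- sample
#' standard deviation, total bp, percentage of the nuclear genome, and the
#' identity range.
#'
#' @param hits filtered, deduplicated hit tibble.
#' @param genome_bp nuclear genome size in bp.
#' @return one-row tibble of class `numt_report`.
#' @export
summarize_numts <- function(hits, genome_bp) {
  stopifnot(genome_bp > 0)
  len <- hits$nuclear_end - hits$nuclear_start
  n <- length(len)
  total <- sum(len)
  out <- tibble(
    n_hits = n,
    min_length = if (n) min(len) else NA_integer_,
    max_length = if (n) max(len) else NA_integer_,
    mean_length = if (n) mean(len) else NA_real_,
    sd_length = if (n > 1) sd(len) else NA_real_,
    n_over_1000 = sum(len > 1000),
    total_bp = total,
    genome_bp = genome_bp,
    percent_of_genome = 100 * total / genome_bp,
    identity_min = if (n) min(hits$identity) else NA_real_,
    identity_max = if (n) max(hits$identity) else NA_real_
  )
  class(out) <- c("numt_report", class(out))
  out
}

#' @export
print.numt_report <- function(x, ...) {
  if (x$n_hits == 0) {
    cat("<numt_report> no NUMT segments\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<numt_report> %d NUMT segments, %d-%d bp ",
                     "(mean %.1f bp +/- %.1f), %d longer than 1000 bp\n"),
              x$n_hits, x$min_length, x$max_length, x$mean_length,
              if (is.na(x$sd_length)) 0 else x$sd_length, x$n_over_1000))
  cat(sprintf("  total %s bp in %s bp (%.5f%% of the nuclear genome)\n",
              format(x$total_bp, big.mark = ","),
              format(x$genome_bp, big.mark = ","), x$percent_of_genome))
  cat(sprintf("  identity %.1f-%.1f%%\n", x$identity_min, x$identity_max))
  invisible(x)
}
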