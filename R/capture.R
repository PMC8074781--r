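#' Design a tiled hybridization-capture bait set
#'
#' Baits of `bait_length` bp start every `bait_length / tiling` bp around
#' the circular reference, so every position is covered exactly `tiling`
#' times — the 80 bp / 4x design used for the mitogenome capture panel.
#'
#' @param reference a [circ_seq()].
#' @param bait_length bait length in bp (default 80).
#' @param tiling tiling factor (default 4); must divide `bait_length`.
#' @return list of class `bait_set`: `reference_id`, `bait_length`,
#'   `tiling`, `step`, and `baits` (tibble: start, seq).
#' @export
design_baits <- function(reference, bait_length = 80L, tiling = 4L) {
  stopifnot(inherits(reference, "circ_seq"),
            bait_length %% tiling == 0)
  if (bait_length > reference$length) {
    stop("bait length exceeds the reference length", call. = FALSE)
  }
  step <- bait_length %/% tiling
  starts <- seq(0L, reference$length - 1L, by = step)
  baits <- tibble(
    start = as.integer(starts),
    seq = vapply(starts, function(s)
      subseq_circular(reference, s, s + bait_length), "")
  )
  structure(list(reference_id = reference$id,
                 bait_length = as.integer(bait_length),
                 tiling = as.integer(tiling), step = as.integer(step),
                 baits = baits),
            class = "bait_set")
}

#' Per-position bait coverage on the circular reference
#'
#' @param baits a [design_baits()] set.
#' @param reference_length circle length in bp.
#' @return integer vector of coverage, one entry per position.
#' @export
bait_coverage <- function(baits, reference_length) {
  cov <- integer(reference_length)
  for (s in baits$baits$start) {
    idx <- (seq.int(s, s + baits$bait_length - 1L) %% reference_length) + 1L
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

#' Place reads on a reference by exact seed and Hamming extension
#'
#' Gapless placement: candidate positions come from an exact k-mer lookup
#' of the read's first word, the full read is then compared by Hamming
#' distance (both strands), and the read is placed at the position with the
#' fewest mismatches if the fraction is at most `max_mismatch_frac`. A tie
#' between equally good positions (reads from an exact repeat) leaves the
#' read unplaced.
#'
#' @param reads character vector of reads, or a `read_set` (paired mates
#'   are placed independently).
#' @param reference a [circ_seq()].
#' @param max_mismatch_frac maximum mismatch fraction (default 0.05).
#' @param seed_k exact seed length.
#' @return tibble: read (index), pos (0-based, modulo the circle), strand,
#'   mismatches; unplaced reads are absent.
#' @export
place_reads <- function(reads, reference, max_mismatch_frac = 0.05,
                        seed_k = 23L) {
  stopifnot(inherits(reference, "circ_seq"))
  if (inherits(reads, "read_set")) {
    reads <- c(reads$paired$read1, reads$paired$read2)
  }
  L <- reference$length
  g2 <- if (reference$circular) doubled(reference) else reference$seq
  # seed index: k-mer -> 0-based positions (first copy only)
  wins <- cpp_window_kmers(substr(g2, 1L, min(nchar(g2), L + seed_k - 1L)),
                           seed_k, FALSE)
  env <- new.env(parent = emptyenv(), size = length(wins) * 2L)
  for (i in seq_along(wins)) {
    if (is.na(wins[i])) next
    assign(wins[i], c(get0(wins[i], envir = env), i - 1L), envir = env)
  }
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    r <- reads[i]
    if (nchar(r) < seed_k) next
    best <- NULL
    # seed at the read start, middle, and end, so a sequencing error in any
    # one seed window cannot orphan the read
    offs <- unique(c(0L, (nchar(r) - seed_k) %/% 2L, nchar(r) - seed_k))
    for (strand in c("+", "-")) {
      rs <- if (strand == "+") r else revcomp(r)
      cand <- unique(unlist(lapply(offs, function(o) {
        hit <- get0(substr(rs, o + 1L, o + seed_k), envir = env)
        if (is.null(hit)) NULL else (hit - o) %% L
      })))
      for (p in cand) {
        mm <- cpp_mismatch_at(g2, rs, p)
        if (mm < 0) next
        if (is.null(best) || mm < best$mm) {
          best <- list(pos = p %% L, strand = strand, mm = mm, tie = FALSE)
        } else if (mm == best$mm && (p %% L) != best$pos) {
          best$tie <- TRUE
        }
      }
    }
    if (!is.null(best) && !best$tie &&
        best$mm / nchar(r) <= max_mismatch_frac) {
      out[[i]] <- tibble(read = i, pos = best$pos, strand = best$strand,
                         mismatches = best$mm, length = nchar(r))
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(tibble(read = integer(), pos = integer(), strand = character(),
                  mismatches = integer(), length = integer()))
  }
  dplyr::bind_rows(out)
}

#' Call a per-individual consensus from placed reads
#'
#' Majority base per reference position among covering reads; positions
#' with depth below `min_depth`, or with an exact tie, are called N so
#' that downstream difference counting stays binary.
#'
#' @param placements a [place_reads()] table.
#' @param reads the read vector the placements refer to (same order/indices).
#' @param reference a [circ_seq()].
#' @param min_depth minimum depth to call a base (default 3).
#' @param individual_id identifier carried into the result.
#' @return list of class `consensus_sequence`: `individual_id`, `seq`
#'   (string with N at uncalled sites), `depth` (integer vector).
#' @export
call_consensus <- function(placements, reads, reference, min_depth = 3L,
                           individual_id = "individual") {
  stopifnot(inherits(reference, "circ_seq"))
  if (inherits(reads, "read_set")) {
    reads <- c(reads$paired$read1, reads$paired$read2)
  }
  L <- reference$length
  counts <- matrix(0L, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(nrow(placements))) {
    p <- placements$pos[i]
    rs <- reads[placements$read[i]]
    if (placements$strand[i] == "-") rs <- revcomp(rs)
    ch <- strsplit(rs, "", fixed = TRUE)[[1]]
    idx <- (seq.int(p, p + length(ch) - 1L) %% L) + 1L
    ok <- ch %in% DNA_BASES
    for (b in DNA_BASES) {
      sel <- idx[ok & ch == b]
      if (length(sel)) counts[b, sel] <- counts[b, sel] + 1L
    }
  }
  depth <- colSums(counts)
  top <- apply(counts, 2, max)
  called <- depth >= min_depth & top > 0 &
    colSums(counts == rep(top, each = 4)) == 1  # unique majority
  base <- rep("N", L)
  base[called] <- DNA_BASES[apply(counts[, called, drop = FALSE], 2, which.max)]
  structure(list(individual_id = individual_id,
                 seq = paste0(base, collapse = ""),
                 depth = as.integer(depth), min_depth = as.integer(min_depth)),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  n_n <- sum(strsplit(x$seq, "", fixed = TRUE)[[1]] == "N")
  cat(sprintf("<consensus_sequence> %s: %d bp, %d uncalled (N)\n",
              x$individual_id, nchar(x$seq), n_n))
  invisible(x)
}
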