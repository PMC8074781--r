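VERT_MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Find open reading frames under the vertebrate mitochondrial code
#'
#' Maximal ORFs on both strands; on circular input frames wrap the origin
#' and an origin-spanning ORF is reported once with `end > length`. Stop
#' codons are TAA/TAG/AGA/AGG (vertebrate mitochondrial code); the start
#' codon is ATG, with GTG admitted when `allow_gtg_start` is TRUE.
#'
#' @param genome a [circ_seq()].
#' @param min_aa minimum peptide length (codons before the stop).
#' @param allow_gtg_start admit GTG as a start codon.
#' @return tibble: start, end (0-based half-open, may exceed length),
#'   strand, frame, length_aa, truncated (no in-frame stop before the
#'   sequence end; linear input only).
#' @export
find_orfs <- function(genome, min_aa = 30L, allow_gtg_start = FALSE) {
  stopifnot(inherits(genome, "circ_seq"))
  starts_ok <- c("ATG", if (allow_gtg_start) "GTG")
  L <- genome$length
  scan_strand <- function(seq, strand) {
    s <- if (genome$circular) strrep(seq, 2L) else seq
    rows <- list()
    for (frame in 0:2) {
      n_codon <- (nchar(s) - frame) %/% 3L
      if (n_codon < 1) next
      cpos <- frame + 3L * (seq_len(n_codon) - 1L)      # 0-based codon starts
      codons <- substring(s, cpos + 1L, cpos + 3L)
      is_stop <- codons %in% VERT_MITO_STOPS
      is_start <- codons %in% starts_ok
      open_from <- NA_integer_                           # codon index of ORF start
      for (ci in seq_len(n_codon)) {
        if (is_stop[ci]) {
          if (!is.na(open_from)) {
            aa <- ci - open_from
            st <- cpos[open_from]
            en <- cpos[ci] + 3L
            if (aa >= min_aa && st < L) {
              rows[[length(rows) + 1L]] <-
                list(start = st, end = en, frame = frame,
                     length_aa = aa, truncated = FALSE)
            }
            open_from <- NA_integer_
          }
        } else if (is.na(open_from) && is_start[ci]) {
          open_from <- ci
        }
      }
      if (!genome$circular && !is.na(open_from)) {
        aa <- n_codon - open_from + 1L
        if (aa >= min_aa) {
          rows[[length(rows) + 1L]] <-
            list(start = cpos[open_from], end = cpos[n_codon] + 3L,
                 frame = frame, length_aa = aa, truncated = TRUE)
        }
      }
    }
    if (length(rows) == 0) return(NULL)
    df <- dplyr::bind_rows(rows)
    df$strand <- strand
    # circular scan reports each ORF once per doubled copy and can run
    # ORFs longer than the circle; keep starts on the first copy, cap span
    df <- df[df$end - df$start <= L, , drop = FALSE]
    df[!duplicated(paste(df$start %% L, (df$end - df$start), df$strand)), ,
       drop = FALSE]
  }
  plus <- scan_strand(genome$seq, "+")
  minus <- scan_strand(revcomp(genome$seq), "-")
  if (!is.null(minus) && nrow(minus)) {
    # map minus-strand coordinates back to the plus strand
    st <- minus$start; en <- minus$end
    minus$start <- (L - en %% L) %% L
    minus$end <- minus$start + (en - st)
  }
  out <- dplyr::bind_rows(plus, minus)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  frame = integer(), length_aa = integer(),
                  truncated = logical()))
  }
  tibble(start = as.integer(out$start), end = as.integer(out$end),
         strand = out$strand, frame = as.integer(out$frame),
         length_aa = as.integer(out$length_aa), truncated = out$truncated)
}

#' Transfer a reference annotation onto a new assembly
#'
#' Locates each reference feature on the target by seeded local alignment
#' of the feature sequence (both strands, across the target origin).
#' Features whose best alignment identity falls below `min_identity`, or
#' that find no alignment at all, are reported unplaced.
#'
#' @param reference a [circ_seq()] with known annotation.
#' @param ref_features its [feature_table()].
#' @param target the new assembly (a [circ_seq()], rotation-normalized).
#' @param min_identity percent identity floor (default 70).
#' @return tibble: name, kind, start, end, strand (target coordinates,
#'   0-based half-open, wrapping via `end > length`), identity, placed.
#' @export
transfer_annotation <- function(reference, ref_features, target,
                                min_identity = 70) {
  stopifnot(inherits(reference, "circ_seq"), inherits(target, "circ_seq"))
  t2 <- if (target$circular) doubled(target) else target$seq
  L <- target$length
  rows <- lapply(seq_len(nrow(ref_features)), function(i) {
    f <- ref_features[i, ]
    fs <- subseq_circular(reference, f$start, f$end)
    best <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") fs else revcomp(fs)
      h <- cpp_seed_extend(q, t2, 11L, 2L, -3L, 5L, 2L, 20L, 24L)
      if (nrow(h) == 0) next
      h <- h[which.max(h$score), ]
      id <- 100 * h$matches / (h$matches + h$mismatches)
      # a placement must cover at least half the feature: short spurious
      # local matches elsewhere should not "place" a deleted feature
      if ((h$q_end - h$q_start) < 0.5 * nchar(fs)) next
      if (is.null(best) || h$score > best$score) {
        # project the full feature interval from the alignment anchor, so
        # mismatches at the feature edges do not erode the coordinates
        proj <- h$s_start - h$q_start
        best <- list(score = h$score, id = id,
                     start = proj, end = proj + nchar(fs), strand = strand)
      }
    }
    if (is.null(best) || best$id < min_identity) {
      return(tibble(name = f$name, kind = f$kind, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    identity = if (is.null(best)) NA_real_ else best$id,
                    placed = FALSE))
    }
    tibble(name = f$name, kind = f$kind,
           start = as.integer(best$start %% L),
           end = as.integer(best$start %% L + (best$end - best$start)),
           strand = best$strand, identity = best$id, placed = TRUE)
  })
  dplyr::bind_rows(rows)
}
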