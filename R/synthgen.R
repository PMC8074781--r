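#' Specification of a synthetic parrot-style mitogenome
#'
#' Describes the circular mitogenome the generator emulates: an avian
#' mitochondrial gene complement (13 protein-coding genes plus one
#' pseudogene, 22 tRNAs plus one pseudogene, 2 rRNAs) and the duplicated
#' control region characteristic of Amazona parrots — two nearly identical
#' copies (CR1, CR2), each carrying a tandem-repeat tract, separated by a
#' short spacer. The duplication is the assembly obstacle every downstream
#' module is exercised against.
#'
#' @param total_length total circle length in bp.
#' @param cr_length length of each control-region copy in bp.
#' @param cr_copy_identity target pairwise identity of CR1 vs CR2 in `[0,1]`;
#'   divergence is introduced by per-base substitution outside the
#'   tandem-repeat tract.
#' @param tr_unit tandem-repeat unit length in bp.
#' @param tr_copies_cr1,tr_copies_cr2 number of exact repeat units in each
#'   copy's tract.
#' @param gc_target background GC fraction.
#' @param feature_template optional tibble (`name`, `kind`, `length`)
#'   overriding the built-in gene complement (control regions excluded; they
#'   are governed by `cr_length`).
#' @param rng_seed integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return a list of class `mitogenome_spec`.
#' @export
mitogenome_spec <- function(total_length = 18600,
                            cr_length = 1100,
                            cr_copy_identity = 0.98,
                            tr_unit = 12,
                            tr_copies_cr1 = 14,
                            tr_copies_cr2 = 14,
                            gc_target = 0.46,
                            feature_template = NULL,
                            rng_seed = 1L) {
  stopifnot(cr_copy_identity >= 0, cr_copy_identity <= 1,
            tr_unit * max(tr_copies_cr1, tr_copies_cr2) < cr_length,
            gc_target > 0, gc_target < 1)
  spec <- list(
    total_length = as.integer(total_length),
    cr_length = as.integer(cr_length),
    cr_copy_identity = cr_copy_identity,
    tr_unit = as.integer(tr_unit),
    tr_copies_cr1 = as.integer(tr_copies_cr1),
    tr_copies_cr2 = as.integer(tr_copies_cr2),
    gc_target = gc_target,
    feature_template = feature_template %||% default_feature_template(),
    rng_seed = as.integer(rng_seed)
  )
  if (sum(spec$feature_template$length) + 2L * spec$cr_length > spec$total_length) {
    stop("infeasible mitogenome spec: features exceed total_length", call. = FALSE)
  }
  class(spec) <- "mitogenome_spec"
  spec
}

# 13 PCGs + 1 pseudogene, 22 tRNAs + 1 pseudogene, 2 rRNAs, one ssA element;
# lengths follow typical avian mitogenomes. Order interleaves tRNAs between
# the larger genes, with 12S rRNA early (it carries the assembly seed).
default_feature_template <- function() {
  pcg <- c(ND1 = 957, ND2 = 1038, COX1 = 1551, COX2 = 684, ATP8 = 168,
           ATP6 = 684, COX3 = 784, ND3 = 351, ND4L = 297, ND4 = 1378,
           ND5 = 1812, CYTB = 1143, ND6 = 522, `ND6-psi` = 240)
  trna <- setNames(rep(70L, 23L),
                   c(paste0("tRNA-", c("Phe", "Val", "Leu", "Ile", "Gln", "Met",
                                       "Trp", "Ala", "Asn", "Cys", "Tyr", "Ser",
                                       "Asp", "Lys", "Gly", "Arg", "His", "Ser2",
                                       "Leu2", "Glu", "Thr", "Pro")), "tRNA-psi"))
  rrna <- c(`12S rRNA` = 975, `16S rRNA` = 1590)
  tt <- tibble(
    name = c("tRNA-Phe", "12S rRNA", "tRNA-Val", "16S rRNA", "tRNA-Leu",
             names(pcg)[1:13],
             names(trna)[4:23],
             "ND6-psi", "ssA"),
    kind = c("tRNA", "rRNA", "tRNA", "rRNA", "tRNA",
             rep("PCG", 13), rep("tRNA", 20), "PCG", "ssA")
  )
  lens <- c(trna, rrna, pcg, ssA = 210L)
  tt$length <- as.integer(lens[tt$name])
  tt
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# substitute n random positions of a DNA string, never to the same base;
# positions restricted to `allowed` (1-based) when given
substitute_bases <- function(seq, n, allowed = NULL) {
  if (n <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(allowed %||% seq_along(ch), n)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  paste0(ch, collapse = "")
}

#' Generate a synthetic mitogenome with a duplicated control region
#'
#' Lays out the gene complement of `spec` around a circle, builds CR1 as
#' unique flanking sequence around an exact tandem-repeat tract, and derives
#' CR2 from CR1 by substituting bases outside the tract at rate
#' `1 - cr_copy_identity`. Remaining length is distributed over short
#' intergenic spacers.
#'
#' @param spec a [mitogenome_spec()].
#' @return list with elements `genome` (a [circ_seq()]), `features` (a
#'   [feature_table()], including CR and TR tracks), and `truth` (generator
#'   internals: CR intervals, tract intervals, substituted positions).
#' @export
generate_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "mitogenome_spec"))
  withr::with_seed(spec$rng_seed, {
    tt <- spec$feature_template
    # CR1 parts: pre-tract, tract, post-tract
    tract1_len <- spec$tr_unit * spec$tr_copies_cr1
    tract2_len <- spec$tr_unit * spec$tr_copies_cr2
    pre_len <- as.integer(floor((spec$cr_length - tract1_len) * 0.45))
    post_len <- spec$cr_length - tract1_len - pre_len
    unit <- random_dna(spec$tr_unit, spec$gc_target)
    pre <- random_dna(pre_len, spec$gc_target)
    post <- random_dna(post_len, spec$gc_target)
    cr1 <- paste0(pre, strrep(unit, spec$tr_copies_cr1), post)
    # CR2: substitute flanks at the divergence rate, swap tract copy number
    n_sub <- round((1 - spec$cr_copy_identity) * spec$cr_length)
    flank2 <- substitute_bases(paste0(pre, post), n_sub)
    pre2 <- substr(flank2, 1L, pre_len)
    post2 <- substr(flank2, pre_len + 1L, pre_len + post_len)
    cr2 <- paste0(pre2, strrep(unit, spec$tr_copies_cr2), post2)

    # order: genes ... CR1, ssA spacer, CR2, final spacer back to origin
    ssa_i <- which(tt$name == "ssA")
    genes <- tt[-ssa_i, ]
    ssa <- tt[ssa_i, ]
    blocks <- tibble(
      name = c(genes$name, "CR1", ssa$name, "CR2"),
      kind = c(genes$kind, "CR", ssa$kind, "CR"),
      length = c(genes$length, nchar(cr1), ssa$length, nchar(cr2)),
      seq = c(vapply(genes$length, random_dna, "", gc = spec$gc_target),
              cr1, random_dna(ssa$length, spec$gc_target), cr2)
    )
    spare <- spec$total_length - sum(blocks$length)
    if (spare < 0) stop("infeasible mitogenome spec: features exceed total_length",
                        call. = FALSE)
    # distribute spare bp over intergenic spacers (one after each block)
    gaps <- rep(spare %/% nrow(blocks), nrow(blocks))
    extra <- spare %% nrow(blocks)
    if (extra > 0) gaps[seq_len(extra)] <- gaps[seq_len(extra)] + 1L
    gap_seq <- vapply(gaps, random_dna, "", gc = spec$gc_target)

    seqs <- as.vector(rbind(blocks$seq, gap_seq))
    genome_seq <- paste0(seqs, collapse = "")
    starts <- cumsum(c(0L, head(nchar(blocks$seq) + gaps, -1L)))
    feats <- feature_table(blocks$name, blocks$kind, starts,
                           starts + blocks$length,
                           length = spec$total_length)
    # TR tracks inside each CR
    cr_rows <- which(feats$kind == "CR")
    tr1_start <- feats$start[cr_rows[1]] + pre_len
    tr2_start <- feats$start[cr_rows[2]] + pre_len
    tr <- feature_table(c("TR1", "TR2"), c("TR", "TR"),
                        c(tr1_start, tr2_start),
                        c(tr1_start + tract1_len, tr2_start + tract2_len),
                        length = spec$total_length)
    features <- rbind(feats, tr)
    genome <- circ_seq(genome_seq, id = "synthetic_mitogenome", circular = TRUE)
    stopifnot(genome$length == spec$total_length)
    list(genome = genome, features = features,
         truth = list(
           cr1 = c(feats$start[cr_rows[1]], feats$end[cr_rows[1]]),
           cr2 = c(feats$start[cr_rows[2]], feats$end[cr_rows[2]]),
           tr_unit = unit,
           spec = spec))
  })
}

#' Plant nuclear copies of mitochondrial DNA into a random background
#'
#' Samples `n` intervals of the mitogenome, degrades each to a target
#' identity drawn uniformly from `identity_range` (substitutions and indels
#' at a 10:1 ratio), and inserts the degraded copies at non-overlapping
#' random positions of a random nuclear background. The default length and
#' identity bounds reproduce the NUMT landscape reported for the Puerto
#' Rican parrot nuclear assembly: segment lengths 54–5499 bp and identities
#' 64.8–95.2%.
#'
#' @param background_length nuclear background length in bp.
#' @param mito a [circ_seq()] mitogenome.
#' @param n number of copies to plant.
#' @param length_range,identity_range sampling bounds (bp; fraction).
#' @param gc background GC fraction.
#' @param seed integer seed.
#' @param measure_identity compute realized identity of each planted copy by
#'   global alignment (slower; default TRUE).
#' @return list of class `nuclear_background`: `seq` (DNA string) and
#'   `planted` (tibble: mito_start, mito_end, insertion_pos, length,
#'   target_identity, realized_identity, strand).
#' @export
plant_numts <- function(background_length, mito, n,
                        length_range = c(54, 5499),
                        identity_range = c(0.648, 0.952),
                        gc = 0.42, seed = 1L,
                        measure_identity = TRUE) {
  stopifnot(inherits(mito, "circ_seq"),
            length_range[1] > 0, length_range[2] <= mito$length,
            identity_range[1] > 0, identity_range[2] < 1)
  withr::with_seed(seed, {
    bg <- random_dna(background_length, gc)
    if (n == 0) {
      return(structure(list(seq = bg, planted = empty_planted()),
                       class = "nuclear_background"))
    }
    lens <- round(runif(n, length_range[1], length_range[2]))
    ids <- runif(n, identity_range[1], identity_range[2])
    starts <- sample.int(mito$length, n) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    copies <- character(n)
    for (i in seq_len(n)) {
      src <- subseq_circular(mito, starts[i], starts[i] + lens[i])
      if (strands[i] == "-") src <- revcomp(src)
      copies[i] <- degrade_to_identity(src, ids[i])
    }
    # non-overlapping insertion points, left to right
    total_insert <- sum(nchar(copies))
    if (total_insert + n >= background_length) {
      stop("cannot place NUMT copies without overlap", call. = FALSE)
    }
    gaps_at <- sort(sample.int(background_length - 1L, n))
    pieces <- character(0)
    prev <- 0L
    ins_pos <- integer(n)
    offset <- 0L
    for (i in seq_len(n)) {
      pieces <- c(pieces, substr(bg, prev + 1L, gaps_at[i]), copies[i])
      ins_pos[i] <- gaps_at[i] + offset
      offset <- offset + nchar(copies[i])
      prev <- gaps_at[i]
    }
    pieces <- c(pieces, substr(bg, prev + 1L, background_length))
    out_seq <- paste0(pieces, collapse = "")
    realized <- rep(NA_real_, n)
    if (measure_identity) {
      for (i in seq_len(n)) {
        src <- subseq_circular(mito, starts[i], starts[i] + lens[i])
        if (strands[i] == "-") src <- revcomp(src)
        realized[i] <- identity_global(src, copies[i])
      }
    }
    planted <- tibble(
      mito_start = starts, mito_end = starts + lens,
      insertion_pos = ins_pos, length = nchar(copies),
      target_identity = ids, realized_identity = realized, strand = strands
    )
    structure(list(seq = out_seq, planted = planted),
              class = "nuclear_background")
  })
}

empty_planted <- function() {
  tibble(mito_start = integer(), mito_end = integer(),
         insertion_pos = integer(), length = integer(),
         target_identity = double(), realized_identity = double(),
         strand = character())
}

# degrade a sequence to a target identity using substitutions and indels at
# a 10:1 ratio (indels split evenly between 1-bp insertions and deletions);
# identity is measured over aligned columns where both sequences carry a
# base, so substitutions set the identity and indels ride along at 1/10
degrade_to_identity <- function(seq, identity) {
  len <- nchar(seq)
  n_sub <- round((1 - identity) * len)
  if (n_sub == 0) return(seq)
  n_indel <- round(n_sub / 10)
  out <- substitute_bases(seq, n_sub)
  ch <- strsplit(out, "", fixed = TRUE)[[1]]
  if (n_indel > 0) {
    n_del <- n_indel %/% 2
    n_ins <- n_indel - n_del
    if (n_del > 0) ch <- ch[-sample(length(ch), n_del)]
    for (j in seq_len(n_ins)) {
      at <- sample(length(ch), 1L)
      ch <- append(ch, sample(DNA_BASES, 1L), after = at)
    }
  }
  paste0(ch, collapse = "")
}

# global-alignment identity: matches / columns where both carry a base
identity_global <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  m <- Biostrings::nmatch(pa)
  mm <- Biostrings::nmismatch(pa)
  m / (m + mm)
}

#' Read-simulation profile
#'
#' @param coverage paired-end coverage of each genome.
#' @param read_len paired-end read length in bp.
#' @param insert_mean,insert_sd fragment-length model in bp.
#' @param paired_error per-base substitution rate on paired-end reads.
#' @param long_n number of long reads.
#' @param long_mean,long_sd long-read length model in bp (the study's
#'   spanning reads averaged 3–4 kb).
#' @param long_error per-base substitution rate on long reads.
#' @param long_span optional `c(start, end)` interval (0-based half-open,
#'   may exceed the genome length) that every long read must cover — used to
#'   emulate reads spanning the duplicated control region.
#' @return list of class `read_profile`.
#' @export
read_profile <- function(coverage = 100, read_len = 150,
                         insert_mean = 350, insert_sd = 40,
                         paired_error = 0,
                         long_n = 6, long_mean = 3500, long_sd = 300,
                         long_error = 0.10, long_span = NULL) {
  stopifnot(paired_error >= 0, paired_error <= 0.3,
            long_error >= 0, long_error <= 0.3)
  structure(list(coverage = coverage, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 paired_error = paired_error,
                 long_n = as.integer(long_n), long_mean = long_mean,
                 long_sd = long_sd, long_error = long_error,
                 long_span = long_span),
            class = "read_profile")
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- rbinom(1L, nchar(seq), rate)
  substitute_bases(seq, n)
}

#' Simulate paired-end and long reads from circular genomes
#'
#' Paired-end reads are FR-oriented with Gaussian fragment lengths; long
#' reads follow a Gaussian length model with per-base substitution errors.
#' Reads wrap the origin on circular genomes; every read records its true
#' origin, so downstream recall/precision can be scored against truth.
#'
#' @param genomes a [circ_seq()] or list of them.
#' @param profile a [read_profile()].
#' @param seed integer seed.
#' @return list of class `read_set` with tibbles `paired` (read1, read2,
#'   origin, frag_start, insert, strand) and `long` (seq, origin, start,
#'   length, error_rate, strand).
#' @export
simulate_reads <- function(genomes, profile = read_profile(), seed = 1L) {
  if (inherits(genomes, "circ_seq")) genomes <- list(genomes)
  stopifnot(all(vapply(genomes, inherits, TRUE, "circ_seq")))
  withr::with_seed(seed, {
    paired <- list()
    long <- list()
    for (g in genomes) {
      L <- g$length
      if (profile$read_len >= L) {
        stop("read length must be smaller than the genome", call. = FALSE)
      }
      g2 <- if (g$circular) doubled(g) else g$seq
      n_pairs <- ceiling(profile$coverage * L / (2 * profile$read_len))
      ins <- pmax(profile$read_len,
                  round(rnorm(n_pairs, profile$insert_mean, profile$insert_sd)))
      ins <- pmin(ins, L)
      fs <- sample.int(L, n_pairs, replace = TRUE) - 1L
      strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
      frag <- substr(rep(g2, n_pairs), fs + 1L, fs + ins)
      frag <- ifelse(strand == "-", revcomp(frag), frag)
      r1 <- substr(frag, 1L, profile$read_len)
      r2 <- revcomp(substr(frag, ins - profile$read_len + 1L, ins))
      if (profile$paired_error > 0) {
        r1 <- vapply(r1, apply_substitutions, "", rate = profile$paired_error,
                     USE.NAMES = FALSE)
        r2 <- vapply(r2, apply_substitutions, "", rate = profile$paired_error,
                     USE.NAMES = FALSE)
      }
      paired[[length(paired) + 1L]] <- tibble(
        read1 = r1, read2 = r2, origin = g$id, frag_start = fs,
        insert = as.integer(ins), strand = strand)
      if (profile$long_n > 0) {
        ll <- pmax(profile$read_len,
                   round(rnorm(profile$long_n, profile$long_mean, profile$long_sd)))
        ll <- pmin(ll, L)
        if (!is.null(profile$long_span)) {
          s0 <- profile$long_span[1]; e0 <- profile$long_span[2]
          if (e0 - s0 > L) {
            stop("span region exceeds the genome length", call. = FALSE)
          }
          ll <- pmin(pmax(ll, e0 - s0), L)  # spanning reads must cover the region
          ls <- vapply(ll, function(l) {
            lo <- e0 - l
            round(runif(1, lo, s0)) %% L
          }, 0)
        } else {
          ls <- sample.int(L, profile$long_n, replace = TRUE) - 1L
        }
        lseq <- substr(rep(g2, profile$long_n), ls + 1L, ls + ll)
        lstrand <- sample(c("+", "-"), profile$long_n, replace = TRUE)
        lseq <- ifelse(lstrand == "-", revcomp(lseq), lseq)
        if (profile$long_error > 0) {
          lseq <- vapply(lseq, apply_substitutions, "",
                         rate = profile$long_error, USE.NAMES = FALSE)
        }
        long[[length(long) + 1L]] <- tibble(
          seq = lseq, origin = g$id, start = as.integer(ls),
          length = as.integer(ll), error_rate = profile$long_error,
          strand = lstrand)
      }
    }
    structure(list(
      paired = do.call(rbind, paired),
      long = if (length(long)) do.call(rbind, long) else
        tibble(seq = character(), origin = character(), start = integer(),
               length = integer(), error_rate = double(), strand = character()),
      profile = profile
    ), class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d read pairs, %d long reads\n",
              nrow(x$paired), nrow(x$long)))
  invisible(x)
}

#' Compute PCR amplicon evidence from primer positions
#'
#' Expected product length is the half-open span `rev - fwd`, wrapping the
#' origin when `rev < fwd` on a circular genome. Default primer pairs tile
#' the circle with overlapping ~2 kb products, inside the 500–3100 bp range
#' the original Sanger walk used. Primer site sequences are recorded so
#' product lengths can be re-implied on a candidate assembly.
#'
#' @param genome a [circ_seq()].
#' @param primer_pairs optional tibble with 0-based columns `fwd` (product
#'   start) and `rev` (product end, half-open).
#' @param primer_len primer site length recorded for re-anchoring (bp).
#' @param target_len,step product length and tiling step of the default
#'   design (bp).
#' @return tibble: amplicon_id, fwd, rev, expected_length, fwd_site,
#'   rev_site.
#' @export
simulate_pcr_evidence <- function(genome, primer_pairs = NULL,
                                  primer_len = 24, target_len = 2000,
                                  step = 1500) {
  stopifnot(inherits(genome, "circ_seq"))
  L <- genome$length
  if (is.null(primer_pairs)) {
    fwd <- seq(0L, L - 1L, by = step)
    primer_pairs <- tibble(fwd = fwd, rev = (fwd + target_len) %% L)
  }
  stopifnot(all(primer_pairs$fwd >= 0), all(primer_pairs$fwd < L),
            all(primer_pairs$rev >= 0), all(primer_pairs$rev <= L))
  elen <- (primer_pairs$rev - primer_pairs$fwd) %% L
  if (any(elen == 0)) stop("zero-length amplicon", call. = FALSE)
  tibble(
    amplicon_id = sprintf("amp%02d", seq_len(nrow(primer_pairs))),
    fwd = as.integer(primer_pairs$fwd),
    rev = as.integer(primer_pairs$rev),
    expected_length = as.integer(elen),
    fwd_site = vapply(primer_pairs$fwd, function(p)
      subseq_circular(genome, p, p + primer_len), ""),
    rev_site = vapply(seq_len(nrow(primer_pairs)), function(i) {
      e <- primer_pairs$rev[i]
      s <- (e - primer_len) %% L
      subseq_circular(genome, s, s + primer_len)
    }, "")
  )
}

#' Bundle the evidence classes used to arbitrate assembly forks
#'
#' @param amplicons amplicon table from [simulate_pcr_evidence()].
#' @param reads a [read_set()][simulate_reads]; supplies both the paired-end
#'   insert evidence and the long reads.
#' @param insert_mean,insert_sd paired-end insert model (defaults taken from
#'   the read profile when `reads` carries one).
#' @param length_tolerance relative tolerance on amplicon lengths
#'   (gel-estimate precision).
#' @param use_long_reads logical; set `FALSE` to withhold long-read evidence.
#' @return list of class `evidence_set`.
#' @export
evidence_set <- function(amplicons = NULL, reads = NULL,
                         insert_mean = NULL, insert_sd = NULL,
                         length_tolerance = 0.10, use_long_reads = TRUE) {
  stopifnot(length_tolerance > 0, length_tolerance < 0.5)
  prof <- if (!is.null(reads)) reads$profile else NULL
  structure(list(
    amplicons = amplicons,
    paired = if (!is.null(reads)) reads$paired else NULL,
    long = if (!is.null(reads) && use_long_reads) reads$long else NULL,
    insert_mean = insert_mean %||% (if (!is.null(prof)) prof$insert_mean else 350),
    insert_sd = insert_sd %||% (if (!is.null(prof)) prof$insert_sd else 40),
    length_tolerance = length_tolerance
  ), class = "evidence_set")
}

#' Simulate the full study scenario for one seeded replicate
#'
#' Bundles the default conditions the assembler is benchmarked under: a
#' mitogenome with a 0.98-identity duplicated control region, 100x
#' error-free paired-end reads, three 10%-error long reads spanning the
#' duplication, a tiling amplicon design, and a reference relative derived
#' from the truth by 1% substitution.
#'
#' @param seed integer seed driving every stochastic component.
#' @param with_long_reads withhold the spanning long reads when FALSE.
#' @param coverage paired-end coverage.
#' @return list: `genome`, `features`, `truth`, `reads`, `evidence`,
#'   `reference`, `ref_features`.
#' @export
study_scenario <- function(seed, with_long_reads = TRUE, coverage = 100) {
  gm <- generate_mitogenome(mitogenome_spec(rng_seed = seed))
  cr_region <- c(gm$truth$cr1[1] - 300, gm$truth$cr2[2] + 300)
  prof <- read_profile(coverage = coverage, long_n = if (with_long_reads) 3L else 0L,
                       long_error = 0.10, long_span = cr_region)
  reads <- simulate_reads(gm$genome, prof, seed = seed + 1000L)
  amp <- simulate_pcr_evidence(gm$genome)
  ev <- evidence_set(amplicons = amp, reads = reads,
                     use_long_reads = with_long_reads)
  ref <- withr::with_seed(seed + 2000L, circ_seq(
    substitute_bases(gm$genome$seq, round(0.01 * gm$genome$length)),
    id = "reference"))
  list(genome = gm$genome, features = gm$features, truth = gm$truth,
       reads = reads, evidence = ev, reference = ref,
       ref_features = gm$features)
}

#' Simulate a panel of related mitogenome sequences
#'
#' Derives `n` sequences from a common ancestor by independent per-base
#' substitution (no indels), emulating consensus mitogenomes of related
#' individuals or species. Because divergence is substitution-only, the
#' panel is intrinsically aligned and can be fed straight to
#' [alignment_matrix()].
#'
#' @param genome ancestral [circ_seq()].
#' @param n panel size.
#' @param divergence per-sequence substitution fraction (scalar or vector
#'   of length `n`).
#' @param seed integer seed.
#' @param ids sequence names.
#' @return named character vector of sequences, all the ancestor's length.
#' @export
simulate_panel <- function(genome, n, divergence = 0.01, seed = 1L,
                           ids = NULL) {
  stopifnot(inherits(genome, "circ_seq"), n >= 1)
  divergence <- rep_len(divergence, n)
  ids <- ids %||% sprintf("taxon%02d", seq_len(n))
  withr::with_seed(seed, {
    setNames(vapply(seq_len(n), function(i) {
      substitute_bases(genome$seq, round(divergence[i] * genome$length))
    }, ""), ids)
  })
}
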