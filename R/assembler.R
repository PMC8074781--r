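#' Classify k-mers as mitochondrial by coverage
#'
#' Whole-genome short-read data cover the mitogenome far deeper than the
#' nuclear background, so the k-mer count spectrum is bimodal. A k-mer is
#' mito-class when its count reaches the geometric mean of the two coverage
#' modes — supplied directly, or inferred from the count histogram.
#'
#' @param table a [count_kmers()] table.
#' @param mito_cov,autosomal_cov coverage estimates; both or neither.
#' @return object of class `kmer_classifier`: `table`, `threshold`, `env`
#'   (lookup environment), `k`.
#' @export
classify_mito_kmers <- function(table, mito_cov = NULL, autosomal_cov = NULL) {
  stopifnot(inherits(table, "kmer_table"))
  if (is.null(mito_cov) != is.null(autosomal_cov)) {
    stop("supply both coverage estimates or neither", call. = FALSE)
  }
  if (is.null(mito_cov)) {
    modes <- histogram_modes(table$count)
    if (length(modes) < 2) {
      stop(paste("k-mer count histogram is unimodal; supply explicit",
                 "mito_cov and autosomal_cov estimates"), call. = FALSE)
    }
    autosomal_cov <- min(modes)
    mito_cov <- max(modes)
  }
  stopifnot(mito_cov > autosomal_cov, autosomal_cov > 0)
  structure(list(table = table, k = table$k,
                 mito_cov = mito_cov, autosomal_cov = autosomal_cov,
                 threshold = sqrt(mito_cov * autosomal_cov),
                 env = kmer_lookup_env(table)),
            class = "kmer_classifier")
}

# two most prominent local maxima of the count histogram, if separated by
# at least a factor of two in coverage
histogram_modes <- function(counts) {
  tab <- table(counts)
  v <- as.integer(names(tab))
  f <- as.integer(tab)
  if (length(v) < 3) return(v[which.max(f)])
  is_max <- vapply(seq_along(v), function(i) {
    left <- if (i > 1) f[i - 1] else -Inf
    right <- if (i < length(v)) f[i + 1] else -Inf
    f[i] >= left && f[i] >= right
  }, TRUE)
  cand <- v[is_max][order(f[is_max], decreasing = TRUE)]
  if (length(cand) < 2) return(cand[1])
  top <- cand[1]
  second <- cand[cand / top >= 2 | cand / top <= 0.5][1]
  if (is.na(second)) top else c(top, second)
}

#' Is a k-mer mito-class?
#'
#' @param classifier a [classify_mito_kmers()] object.
#' @param kmers character vector of k-mers (either strand).
#' @return logical vector.
#' @export
is_mito_kmer <- function(classifier, kmers) {
  kmer_count_of(classifier$env, kmers) >= classifier$threshold
}

#' Select the assembly seed k-mer from a reference feature
#'
#' Scans the named feature of the reference left to right and returns the
#' first k-mer that is present mito-class in the read table — the automated
#' analogue of seeding the walkthrough at the first exact 12S rRNA match.
#'
#' @param reference a [circ_seq()] reference genome.
#' @param features its [feature_table()].
#' @param feature_name feature to scan (default `"12S rRNA"`).
#' @param classifier a [classify_mito_kmers()] object.
#' @return seed k-mer (character scalar), oriented as in the reference.
#' @export
select_seed <- function(reference, features, feature_name = "12S rRNA",
                        classifier) {
  stopifnot(inherits(reference, "circ_seq"), inherits(classifier, "kmer_classifier"))
  row <- which(features$name == feature_name)
  if (length(row) == 0) {
    stop(sprintf("feature '%s' absent from the reference annotation", feature_name),
         call. = FALSE)
  }
  fs <- subseq_circular(reference, features$start[row[1]], features$end[row[1]])
  wins <- cpp_window_kmers(fs, classifier$k, FALSE)
  hit <- which(is_mito_kmer(classifier, wins))
  if (length(hit) == 0) {
    stop("no mito-class seed k-mer found in the named feature", call. = FALSE)
  }
  wins[hit[1]]
}

# mito-class successor bases of a frontier k-mer (rightward)
succ_bases <- function(classifier, frontier) {
  suffix <- substr(frontier, 2L, classifier$k)
  cand <- paste0(suffix, DNA_BASES)
  DNA_BASES[kmer_count_of(classifier$env, cand) >= classifier$threshold]
}

#' Walk state for the k-mer walkthrough
#'
#' @param contig current contig string (starts as the seed k-mer).
#' @param direction `"right"` or `"left"`.
#' @return object of class `walk_state`.
#' @export
walk_state <- function(contig, direction = "right") {
  structure(list(contig = contig, direction = direction,
                 steps = 0L), class = "walk_state")
}

#' Extend a walk until a bifurcation, dead end, or circularization
#'
#' Appends bases while exactly one of the four successor k-mers is
#' mito-class. Stops at a fork (two or more mito-class successors), a dead
#' end (none), circularization (the frontier k-mer returns to `seed`), or
#' after `max_steps`.
#'
#' @param state a [walk_state()].
#' @param classifier a [classify_mito_kmers()] object.
#' @param seed seed k-mer for circularization detection (optional).
#' @param max_steps cap on appended bases.
#' @return list: `state` (updated), `event` one of `"fork"`, `"dead_end"`,
#'   `"circular"`, `"max_steps"`, and for forks `successors` (candidate
#'   bases).
#' @export
extend_path <- function(state, classifier, seed = NULL, max_steps = Inf) {
  stopifnot(inherits(state, "walk_state"))
  left <- identical(state$direction, "left")
  contig <- if (left) revcomp(state$contig) else state$contig
  seed_use <- if (left && !is.null(seed)) revcomp(seed) else seed
  w <- walk_right(classifier, contig, seed_use, max_steps)
  out_contig <- if (left) revcomp(w$contig) else w$contig
  state$contig <- out_contig
  state$steps <- state$steps + w$new
  res <- list(state = state, event = w$event)
  if (w$event == "fork") {
    res$successors <- if (left) revcomp(w$successors) else w$successors
  }
  res
}

# rightward unique-extension walk on a plain string
walk_right <- function(classifier, contig, seed = NULL, max_steps = Inf) {
  k <- classifier$k
  frontier <- substr(contig, nchar(contig) - k + 1L, nchar(contig))
  buf <- character(256L)
  nb <- 0L
  flush <- function() {
    if (nb > 0) contig <<- paste0(contig, paste0(buf[seq_len(nb)], collapse = ""))
    nb <<- 0L
  }
  repeat {
    if (!is.null(seed) && frontier == seed && (nb > 0 || nchar(contig) > k)) {
      flush()
      return(list(contig = contig, event = "circular", new = nb, frontier = frontier))
    }
    if (nb >= max_steps) {
      flush()
      return(list(contig = contig, event = "max_steps", frontier = frontier))
    }
    sb <- succ_bases(classifier, frontier)
    if (length(sb) == 1L) {
      nb <- nb + 1L
      if (nb > length(buf)) buf <- c(buf, character(length(buf)))
      buf[nb] <- sb
      frontier <- paste0(substr(frontier, 2L, k), sb)
      if (nb %% 256L == 0L) { flush(); }
    } else {
      flush()
      ev <- if (length(sb) == 0L) "dead_end" else "fork"
      return(list(contig = contig, event = ev, successors = sb, frontier = frontier))
    }
  }
}

#' Assemble a circular mitogenome by supervised k-mer walkthrough
#'
#' The core algorithm: count k-mers in the short reads, classify them as
#' mitochondrial by coverage, seed the walk at the reference's 12S rRNA,
#' and extend base by base. At every bifurcation of the de Bruijn graph
#' (duplicated control region, tandem-repeat tracts) candidate extensions
#' are enumerated and arbitrated against the independent evidence classes —
#' PCR product lengths, paired-end inserts, and spanning long reads — and
#' only a uniquely consistent continuation is committed. A fork no evidence
#' can settle is reported as AMBIGUOUS, the automated analogue of "manual
#' intervention required".
#'
#' @param reads a `read_set` with paired-end reads.
#' @param reference a [circ_seq()] related reference genome.
#' @param ref_features [feature_table()] of the reference (must contain the
#'   seed feature).
#' @param evidence an [evidence_set()]; defaults to the paired-end evidence
#'   of `reads` alone.
#' @param seed_feature feature whose first table-present k-mer seeds the
#'   walk.
#' @param k word size.
#' @param mito_cov,autosomal_cov coverage estimates for
#'   [classify_mito_kmers()]; inferred from the histogram when omitted.
#' @param force_first on an AMBIGUOUS fork, commit the first branch instead
#'   of aborting (off by default; the refusal to guess silently is the
#'   point).
#' @param max_branch_depth bp to which fork branches are enumerated.
#' @param expected_length used for the runaway guard (2x) and reporting;
#'   defaults to the reference length.
#' @return object of class `assembly_report`: `assembled` (rotation- and
#'   strand-normalized [circ_seq()] when circularized), `circularized`,
#'   `status` (`"circular"`, `"ambiguous"`, `"dead_end"`), `forks` (list of
#'   fork events), `validation` (three named checks), `seed`, `threshold`.
#' @export
assemble_mitogenome <- function(reads, reference, ref_features,
                                evidence = NULL,
                                seed_feature = "12S rRNA", k = 23L,
                                mito_cov = NULL, autosomal_cov = NULL,
                                force_first = FALSE,
                                max_branch_depth = 5000L,
                                expected_length = NULL) {
  stopifnot(inherits(reads, "read_set"))
  table <- count_kmers(reads, k)
  cls <- classify_mito_kmers(table, mito_cov, autosomal_cov)
  seed <- select_seed(reference, ref_features, seed_feature, cls)
  if (is.null(evidence)) evidence <- evidence_set(reads = reads)
  expected <- expected_length %||% reference$length
  opts <- fork_opts(evidence, max_branch_depth)
  ectx <- evidence_context(evidence, cls, opts)

  contig <- seed
  forks <- list()
  status <- "walking"
  limit <- 2L * expected + k
  repeat {
    frontier <- substr(contig, nchar(contig) - k + 1L, nchar(contig))
    w <- walk_right(cls, contig, seed, max_steps = limit - nchar(contig))
    contig <- w$contig
    if (w$event == "circular") { status <- "circular"; break }
    if (w$event == "dead_end") { status <- "dead_end"; break }
    if (w$event == "max_steps") {
      stop("failed to circularize within twice the expected length", call. = FALSE)
    }
    fe <- arbitrate_fork(contig, w$frontier, w$successors, cls, ectx, opts, seed)
    forks[[length(forks) + 1L]] <- fe
    if (identical(fe$resolution, "AMBIGUOUS")) {
      if (force_first) {
        contig <- paste0(contig, w$successors[1])
        next
      }
      status <- "ambiguous"
      break
    }
    contig <- paste0(contig, fe$commit)
    # circularization may occur inside a committed extension
    tail_from <- max(1L, nchar(contig) - nchar(fe$commit) - k + 1L)
    hit <- cpp_exact_find(substr(contig, tail_from, nchar(contig)), seed)
    if (length(hit) > 0) {
      pos <- tail_from + hit[1]  # 1-based start of the seed recurrence
      if (pos > 1L) {
        contig <- substr(contig, 1L, pos - 1L + k)
        status <- "circular"
        break
      }
    }
    if (nchar(contig) > limit) {
      stop("failed to circularize within twice the expected length", call. = FALSE)
    }
  }

  circularized <- identical(status, "circular")
  assembled <- NULL
  validation <- NULL
  if (circularized) {
    circle <- substr(contig, 1L, nchar(contig) - k)  # drop repeated seed
    assembled <- normalize_rotation(circ_seq(circle, id = "assembly"))
    validation <- validate_assembly_internal(assembled, evidence, table, ectx)
  }
  structure(list(assembled = assembled, contig = contig,
                 circularized = circularized, status = status,
                 forks = forks, validation = validation,
                 seed = seed, k = k, threshold = cls$threshold,
                 n_forks = length(forks)),
            class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("<assembly_report> status=%s, %d fork(s)%s\n", x$status, x$n_forks,
              if (x$circularized)
                sprintf(", %s bp circular", format(x$assembled$length, big.mark = ","))
              else ""))
  invisible(x)
}

# ---- fork arbitration ------------------------------------------------------

fork_opts <- function(evidence, max_branch_depth) {
  rl <- if (!is.null(evidence$paired) && nrow(evidence$paired) > 0)
    nchar(evidence$paired$read1[1]) else 150L
  imin <- max(rl, floor(evidence$insert_mean - 4 * evidence$insert_sd))
  imax <- ceiling(evidence$insert_mean + 4 * evidence$insert_sd)
  list(max_branch_depth = as.integer(max_branch_depth),
       depth_target = min(as.integer(max_branch_depth),
                          as.integer(imax + 2L * rl + 128L)),
       beam_cap = 256L, prune_every = 64L,
       # bases within one read length of the candidate frontier cannot be
       # phase-adjudicated yet: linking fragments' rightmost mates must fit
       # inside the candidate, so adjudication trails by read_len + 16
       slack = as.integer(rl + 16L),
       long_floor = 0.8, min_long_cmp = 48L, vote_window = 256L,
       tail_window = 128L,
       read_len = rl, imin = as.integer(imin), imax = as.integer(imax),
       reach = as.integer(max(rl, floor(evidence$insert_mean -
                                          2 * evidence$insert_sd))),
       ctx_len = as.integer(imax + 2L * rl + 200L))
}

# precomputed evidence machinery: pair index (C++), long-read registry
evidence_context <- function(evidence, cls, opts) {
  ctx <- list(evidence = evidence, pairs = NULL, lr = NULL)
  if (!is.null(evidence$paired) && nrow(evidence$paired) > 0) {
    ctx$pairs <- cpp_make_pair_index(evidence$paired$read1, evidence$paired$read2)
  }
  if (!is.null(evidence$long) && nrow(evidence$long) > 0) {
    ctx$lr <- new.env(parent = emptyenv())
    ctx$lr$reads <- lapply(seq_len(nrow(evidence$long)), function(i) {
      s <- evidence$long$seq[i]
      mask <- trim_weak_regions(s, cls$table, read_id = paste0("long", i))$mask
      list(fwd = s, rev = revcomp(s),
           mask_fwd = mask, mask_rev = rev(mask),
           env_fwd = read_kmer_env(s, cls$k),
           env_rev = read_kmer_env(revcomp(s), cls$k),
           orient = NA_character_, diag = NA_integer_)
    })
  }
  ctx
}

read_kmer_env <- function(seq, k) {
  wins <- cpp_window_kmers(seq, k, FALSE)
  e <- new.env(parent = emptyenv(), size = length(wins) * 2L)
  for (i in seq_along(wins)) {
    if (is.na(wins[i])) next
    prev <- get0(wins[i], envir = e)
    assign(wins[i], c(prev, i - 1L), envir = e)
  }
  e
}

# anchor any still-unanchored long reads to the contig; the simulator's
# substitution-only error process keeps the contig-to-read offset constant,
# so one confident diagonal fixes the read for the rest of the walk
anchor_long_reads <- function(ectx, contig, k) {
  if (is.null(ectx$lr)) return(invisible())
  win <- 1200L
  from <- max(0L, nchar(contig) - win)
  anchor <- substr(contig, from + 1L, nchar(contig))
  wins <- cpp_window_kmers(anchor, k, FALSE)
  for (i in seq_along(ectx$lr$reads)) {
    r <- ectx$lr$reads[[i]]
    if (!is.na(r$diag)) next
    best <- list(votes = 0L, second = 0L, orient = NA, diag = NA)
    for (orient in c("fwd", "rev")) {
      env <- r[[paste0("env_", orient)]]
      diags <- integer(0)
      for (j in seq_along(wins)) {
        if (is.na(wins[j])) next
        pos <- get0(wins[j], envir = env)
        if (!is.null(pos)) diags <- c(diags, pos - (from + j - 1L))
      }
      if (length(diags) == 0) next
      tb <- sort(table(diags), decreasing = TRUE)
      v1 <- as.integer(tb[1])
      v2 <- if (length(tb) > 1) as.integer(tb[2]) else 0L
      if (v1 > best$votes) {
        best <- list(votes = v1, second = max(v2, best$votes),
                     orient = orient, diag = as.integer(names(tb)[1]))
      } else if (v1 > best$second) best$second <- v1
    }
    # the homologous control-region copy always draws a competing diagonal
    # from shared k-mers; the true diagonal adds unique-flank and allele
    # k-mers on top, so a 1.5x margin over a long anchor window separates them
    if (best$votes >= 10L && best$votes >= 1.5 * best$second) {
      # verify the winning diagonal by masked positional identity of the
      # anchor window: a diagonal captured by the homologous CR copy
      # mismatches across the window's unique flank and is rejected here
      seqr <- r[[best$orient]]
      mask <- r[[paste0("mask_", best$orient)]]
      skip <- max(0L, -(best$diag + from))  # window part before the read starts
      chk <- cpp_positional_identity(anchor, skip, seqr,
                                     best$diag + from + skip,
                                     nchar(anchor) - skip, mask)
      if (chk$compared >= 30L && chk$matches / chk$compared >= 0.85) {
        r$orient <- best$orient
        r$diag <- best$diag
        ectx$lr$reads[[i]] <- r
      }
    }
  }
  invisible()
}

# positional identity of a candidate continuation against each long read,
# compared over the read's solid positions only; one entry per read, NA for
# unanchored reads or windows with too few comparable positions
long_read_identities <- function(ectx, contig_len, cand, min_cmp) {
  if (is.null(ectx$lr)) return(numeric(0))
  vapply(ectx$lr$reads, function(r) {
    if (is.na(r$diag)) return(NA_real_)
    rp <- r$diag + contig_len           # 0-based position of cand[0] in read
    seq <- r[[r$orient]]
    mask <- r[[paste0("mask_", r$orient)]]
    res <- cpp_positional_identity(cand, 0L, seq, rp, nchar(cand), mask)
    if (res$compared < min_cmp) return(NA_real_)
    res$matches / res$compared
  }, 0)
}

# implied amplicon product lengths on an assembly string; on a partial
# (linear) assembly only uniquely occurring primer sites are informative;
# on a completed circle (`circular_len` set, `x` its doubled form) each
# product takes the occurrence pairing closest to its expected size, since
# the near-identical control-region copies can host exact twins of a
# primer site
implied_amplicon_lengths <- function(x, amplicons, circular_len = NULL) {
  if (is.null(amplicons) || nrow(amplicons) == 0) {
    return(tibble(amplicon_id = character(), implied = integer(),
                  expected = integer()))
  }
  rows <- lapply(seq_len(nrow(amplicons)), function(i) {
    a <- amplicons[i, ]
    for (orient in c("+", "-")) {
      fs <- if (orient == "+") a$fwd_site else revcomp(a$rev_site)
      rs <- if (orient == "+") a$rev_site else revcomp(a$fwd_site)
      pf <- cpp_exact_find(x, fs)
      pr <- cpp_exact_find(x, rs)
      if (!is.null(circular_len)) {
        pf <- pf[pf < circular_len]
        if (length(pf) == 0 || length(pr) == 0) next
        cand <- unlist(lapply(pf, function(f) {
          d <- pr + nchar(rs) - f
          d[d > 0 & d <= circular_len + nchar(rs)]
        }))
        if (length(cand) == 0) next
        return(tibble(amplicon_id = a$amplicon_id,
                      implied = as.integer(cand[which.min(abs(cand - a$expected_length))]),
                      expected = a$expected_length))
      }
      if (length(pf) == 1L && length(pr) == 1L && pr >= pf) {
        return(tibble(amplicon_id = a$amplicon_id,
                      implied = as.integer(pr + nchar(rs) - pf),
                      expected = a$expected_length))
      }
    }
    NULL
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) tibble(amplicon_id = character(), implied = integer(),
                                expected = integer())
  else do.call(rbind, rows)
}

# partial = TRUE is used mid-assembly: an implied product can come out too
# short when a primer site has an exact twin in the not-yet-assembled
# homologous control-region copy, so only over-length products disqualify a
# branch; the completed circle is checked in both directions.
amplicon_consistent <- function(x, amplicons, tol, partial = FALSE) {
  imp <- implied_amplicon_lengths(x, amplicons)
  if (nrow(imp) == 0) return(list(informative = FALSE, ok = TRUE, table = imp))
  ok <- if (partial) all(imp$implied <= (1 + tol) * imp$expected)
  else all(abs(imp$implied - imp$expected) <= tol * imp$expected)
  list(informative = TRUE, ok = ok, table = imp)
}

# enumerate candidate extensions through sub-forks (beam search with
# evidence pruning) and arbitrate: see the methods vignette for why pair
# confirmation and positional long-read identity are the discriminating
# checks
arbitrate_fork <- function(contig, frontier, successors, cls, ectx, opts, seed) {
  k <- cls$k
  clen <- nchar(contig)
  anchor_long_reads(ectx, contig, k)
  ctx <- substr(contig, max(1L, clen - opts$ctx_len + 1L), clen)
  ctx_n <- nchar(ctx)
  have_pairs <- !is.null(ectx$pairs)
  have_long <- !is.null(ectx$lr) &&
    any(vapply(ectx$lr$reads, function(r) !is.na(r$diag), TRUE))

  new_path <- function(base) {
    list(seq = base, frontier = paste0(substr(frontier, 2L, k), base),
         alive = TRUE, terminal = NULL, adj_done = 0L, first = base,
         killed_by = NA_character_, long_informative = FALSE)
  }
  paths <- lapply(successors, new_path)
  overflow <- FALSE

  adjudicate <- function(p, final = FALSE) {
    len <- nchar(p$seq)
    if (have_pairs) {
      new_to <- len - opts$slack
      if (new_to > p$adj_done) {
        x <- paste0(ctx, p$seq)
        bad <- cpp_phase_check(x, ctx_n + p$adj_done, ctx_n + new_to,
                               ectx$pairs, opts$imin, opts$imax, opts$reach)
        if (bad >= 0) {
          p$alive <- FALSE
          p$killed_by <- "paired"
          return(p)
        }
        p$adj_done <- new_to
      }
    }
    if (have_long && len >= opts$min_long_cmp) {
      ids <- long_read_identities(ectx, clen, p$seq, opts$min_long_cmp)
      informative <- !is.na(ids)
      if (any(informative)) {
        p$long_informative <- TRUE
        if (max(ids[informative]) < opts$long_floor) {
          p$alive <- FALSE
          p$killed_by <- "long_read"
          return(p)
        }
        # the identity floor alone lets a structural error near the path
        # end hide behind a long matching prefix (a wrong tandem-repeat
        # exit at depth 800 of 940 still averages above 0.8), so the
        # trailing window is held to the floor on its own — judged only by
        # reads whose full-window identity passes, so a read whose anchor
        # drifted cannot veto a branch it does not even match overall
        if (len >= 2L * opts$tail_window) {
          sane <- informative & ids >= opts$long_floor
          if (any(sane)) {
            tail_cand <- substr(p$seq, len - opts$tail_window + 1L, len)
            tid <- long_read_identities(ectx, clen + len - opts$tail_window,
                                        tail_cand, opts$min_long_cmp)
            tid <- tid[sane]
            if (any(!is.na(tid)) && max(tid, na.rm = TRUE) < opts$long_floor) {
              p$alive <- FALSE
              p$killed_by <- "long_read"
              return(p)
            }
          }
        }
      }
    }
    if (final) {
      amp <- amplicon_consistent(paste0(contig, p$seq),
                                 ectx$evidence$amplicons,
                                 ectx$evidence$length_tolerance,
                                 partial = TRUE)
      if (amp$informative && !amp$ok) {
        p$alive <- FALSE
        p$killed_by <- "amplicon"
      }
    }
    p
  }

  repeat {
    idx <- which(vapply(paths, function(p) p$alive && is.null(p$terminal), TRUE))
    if (length(idx) == 0 || overflow) break
    next_paths <- list()
    for (p in paths) {
      if (!(p$alive && is.null(p$terminal))) {
        next_paths[[length(next_paths) + 1L]] <- p
        next
      }
      len <- nchar(p$seq)
      step_cap <- min(opts$prune_every - (len %% opts$prune_every),
                      opts$depth_target - len)
      w <- walk_right(cls, paste0(substr(frontier, 2L, k), p$seq),
                      seed = seed, max_steps = step_cap)
      grown <- substr(w$contig, k + len, nchar(w$contig))  # bases beyond p$seq
      p$seq <- paste0(p$seq, grown)
      if (w$event == "circular") {
        p$terminal <- "circular"
        next_paths[[length(next_paths) + 1L]] <- p
      } else if (w$event == "dead_end") {
        p$alive <- FALSE
        p$killed_by <- "dead_end"
        next_paths[[length(next_paths) + 1L]] <- p
      } else if (w$event == "max_steps") {
        if (nchar(p$seq) >= opts$depth_target) p$terminal <- "depth"
        next_paths[[length(next_paths) + 1L]] <- adjudicate(p)
      } else { # fork: spawn children
        p <- adjudicate(p)
        if (!p$alive) {
          next_paths[[length(next_paths) + 1L]] <- p
        } else {
          for (b in w$successors) {
            child <- p
            child$seq <- paste0(p$seq, b)
            next_paths[[length(next_paths) + 1L]] <- child
          }
        }
      }
    }
    paths <- next_paths
    n_active <- sum(vapply(paths, function(p) p$alive, TRUE))
    if (n_active > opts$beam_cap) overflow <- TRUE
  }

  if (!overflow) {
    paths <- lapply(paths, function(p) {
      if (p$alive && !is.null(p$terminal)) adjudicate(p, final = TRUE) else p
    })
  }
  surv <- Filter(function(p) p$alive && !is.null(p$terminal), paths)
  # When otherwise-consistent branches differ only near the fork (a
  # substitution site of the duplicated control region beyond read-pair
  # phasing reach), let the spanning long reads vote: each anchored read
  # backs the branch its own bases match best over the first window, and a
  # strict majority eliminates the others. Without long reads such forks
  # stay AMBIGUOUS.
  if (length(surv) > 1 && have_long) {
    firsts <- vapply(surv, function(p) p$first, "")
    if (length(unique(firsts)) > 1) {
      groups <- unique(firsts)
      reps <- vapply(groups, function(g) {
        cand <- surv[firsts == g]
        cand[[which.max(vapply(cand, function(p) nchar(p$seq), 0L))]]$seq
      }, "")
      votes <- setNames(integer(length(groups)), groups)
      nread <- 0L
      for (r in ectx$lr$reads) {
        if (is.na(r$diag)) next
        rp <- r$diag + clen
        seqr <- r[[r$orient]]
        # the vote is a relative comparison over identical read positions,
        # so sequencing errors cancel between candidates and no solidity
        # mask is needed; the long window lets structural divergence
        # between candidates dominate single-base read errors
        sc <- vapply(reps, function(s) {
          w <- min(opts$vote_window, nchar(s))
          res <- cpp_positional_identity(s, 0L, seqr, rp, w, logical(0))
          if (res$compared < 32L) return(NA_real_)
          res$matches / res$compared
        }, 0)
        if (anyNA(sc)) next
        best <- which(sc == max(sc))
        if (length(best) == 1L) {
          votes[best] <- votes[best] + 1L
          nread <- nread + 1L
        }
      }
      if (nread > 0L) {
        top <- which(votes == max(votes))
        if (length(top) == 1L && votes[top] > nread / 2) {
          surv <- Filter(function(p) p$first == groups[top], surv)
        }
      }
    }
  }
  branches <- tibble(
    base = successors,
    n_candidates = vapply(successors, function(b)
      sum(vapply(paths, function(p) p$first == b, TRUE)), 0L),
    n_surviving = vapply(successors, function(b)
      sum(vapply(surv, function(p) p$first == b, TRUE)), 0L)
  )
  branches$verdict <- ifelse(branches$n_surviving > 0, "consistent",
                             if (have_pairs || have_long) "inconsistent"
                             else "uninformative")
  resolution <- "AMBIGUOUS"
  commit <- NULL
  reason <- if (overflow) "beam_overflow" else
    if (length(surv) == 0) "no_consistent_branch" else
      if (length(unique(vapply(surv, function(p) p$first, ""))) > 1)
        "multiple_consistent_branches" else NA_character_
  if (!overflow && length(surv) > 0 &&
      length(unique(vapply(surv, function(p) p$first, ""))) == 1) {
    resolution <- surv[[1]]$first
    commit <- longest_common_prefix(vapply(surv, function(p) p$seq, ""))
    reason <- NA_character_
  }
  structure(list(position = clen, frontier = frontier, successors = successors,
                 branches = branches, resolution = resolution, commit = commit,
                 reason = reason,
                 candidates = tibble(
                   first = vapply(paths, function(p) p$first, ""),
                   length = vapply(paths, function(p) nchar(p$seq), 0L),
                   alive = vapply(paths, function(p) p$alive, TRUE),
                   terminal = vapply(paths, function(p)
                     p$terminal %||% NA_character_, ""),
                   killed_by = vapply(paths, function(p) p$killed_by, ""),
                   seq = vapply(paths, function(p) p$seq, "")),
                 evidence_informative = c(paired = have_pairs, long = have_long,
                                          amplicon = !is.null(ectx$evidence$amplicons))),
            class = "fork_event")
}

longest_common_prefix <- function(strings) {
  if (length(strings) == 1) return(strings)
  n <- min(nchar(strings))
  ref <- strings[1]
  for (i in seq_len(n)) {
    ch <- substr(ref, i, i)
    if (!all(substr(strings, i, i) == ch)) return(substr(ref, 1L, i - 1L))
  }
  substr(ref, 1L, n)
}

#' @export
print.fork_event <- function(x, ...) {
  cat(sprintf("<fork_event> at %d bp: %d branches -> %s%s\n", x$position,
              length(x$successors),
              if (identical(x$resolution, "AMBIGUOUS")) "AMBIGUOUS"
              else sprintf("branch '%s' (+%d bp committed)", x$resolution,
                           nchar(x$commit)),
              if (!is.na(x$reason)) paste0(" [", x$reason, "]") else ""))
  invisible(x)
}

#' Resolve a single fork event against the evidence
#'
#' Standalone entry point to the arbitration used inside
#' [assemble_mitogenome()]: enumerates candidate continuations from the
#' fork's successors and tests each against amplicon lengths, paired-end
#' insert consistency, and spanning long reads.
#'
#' @param contig contig assembled so far (string ending at the fork).
#' @param successors candidate successor bases at the fork.
#' @param classifier a [classify_mito_kmers()] object.
#' @param evidence an [evidence_set()].
#' @param max_branch_depth enumeration depth in bp.
#' @param seed optional seed k-mer (lets branches terminate by
#'   circularization).
#' @return a `fork_event` with per-branch verdicts and either a committed
#'   extension or an AMBIGUOUS resolution.
#' @export
resolve_fork <- function(contig, successors, classifier, evidence,
                         max_branch_depth = 5000L, seed = NULL) {
  opts <- fork_opts(evidence, max_branch_depth)
  ectx <- evidence_context(evidence, classifier, opts)
  frontier <- substr(contig, nchar(contig) - classifier$k + 1L, nchar(contig))
  arbitrate_fork(contig, frontier, successors, classifier, ectx, opts,
                 seed %||% "")
}

# ---- validation ------------------------------------------------------------

validate_assembly_internal <- function(assembled, evidence, table, ectx) {
  x2 <- doubled(assembled)
  # (1) long-read consistency
  if (!is.null(evidence$long) && nrow(evidence$long) > 0) {
    ids <- vapply(seq_len(nrow(evidence$long)), function(i) {
      long_read_identity_vs(assembled, evidence$long$seq[i], table)
    }, 0)
    lr_pass <- length(ids) > 0 && median(ids, na.rm = TRUE) >= 0.8
    lr_metric <- median(ids, na.rm = TRUE)
  } else {
    lr_pass <- NA
    lr_metric <- NA_real_
  }
  # (2) amplicon length consistency
  imp <- implied_amplicon_lengths(x2, evidence$amplicons,
                                  circular_len = assembled$length)
  amp <- list(informative = nrow(imp) > 0,
              ok = nrow(imp) > 0 &&
                all(abs(imp$implied - imp$expected) <=
                      evidence$length_tolerance * imp$expected),
              table = imp)
  amp_pass <- if (amp$informative) amp$ok else NA
  amp_metric <- if (nrow(amp$table) > 0)
    max(abs(amp$table$implied - amp$table$expected) / amp$table$expected) else NA_real_
  # (3) short-read coverage continuity
  prof <- map_kmer_coverage(table, assembled)
  cov_pass <- all(prof$coverage >= 1L)
  cov_metric <- mean(prof$coverage == 0L)
  tibble(check = c("long_read_consistency", "amplicon_length_consistency",
                   "coverage_continuity"),
         pass = c(lr_pass, amp_pass, cov_pass),
         metric = c(lr_metric, amp_metric, cov_metric))
}

# anchored positional identity of one long read against the assembly,
# compared over the read's solid positions
long_read_identity_vs <- function(assembled, read_seq, table) {
  k <- table$k
  x2 <- doubled(assembled)
  mask <- trim_weak_regions(read_seq, table)$mask
  best <- NA_real_
  for (orient in c("+", "-")) {
    rs <- if (orient == "+") read_seq else revcomp(read_seq)
    msk <- if (orient == "+") mask else rev(mask)
    wins <- cpp_window_kmers(rs, k, FALSE)
    diags <- integer(0)
    step <- max(1L, length(wins) %/% 400L)
    for (j in seq(1L, length(wins), by = step)) {
      if (is.na(wins[j])) next
      pos <- cpp_exact_find(x2, wins[j])
      if (length(pos) > 0) diags <- c(diags, pos - (j - 1L))
    }
    if (length(diags) == 0) next
    d <- as.integer(names(sort(table(diags), decreasing = TRUE))[1])
    res <- cpp_positional_identity(x2, d, rs, 0L, nchar(rs), msk)
    if (res$compared >= 100) {
      id <- res$matches / res$compared
      if (is.na(best) || id > best) best <- id
    }
  }
  best
}

#' Validate an assembly against the three independent evidence classes
#'
#' Recomputes the three checks the original assembly was verified with:
#' long-read consistency (median anchored identity of each long read
#' against the assembly, solid regions only, pass at >= 0.8), amplicon
#' length consistency (every implied product within tolerance of its
#' expected size), and short-read coverage continuity (no k-mer start on
#' the circle absent from the read table).
#'
#' @param report an [assemble_mitogenome()] report (must be circularized).
#' @param evidence an [evidence_set()].
#' @param reads the `read_set` the assembly was built from (for the k-mer
#'   table).
#' @return tibble with columns `check`, `pass`, `metric`.
#' @export
validate_assembly <- function(report, evidence, reads) {
  stopifnot(inherits(report, "assembly_report"))
  if (!report$circularized) stop("assembly is not circularized", call. = FALSE)
  table <- count_kmers(reads, report$k)
  validate_assembly_internal(report$assembled, evidence, table, NULL)
}
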