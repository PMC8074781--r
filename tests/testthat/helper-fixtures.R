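# Shared fixtures, generated once per test run. Everything is seeded so the
# suite is deterministic.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# default synthetic mitogenome (18.6 kb, duplicated CR)
fx_mitogenome <- function() {
  fixture("mitogenome", function() generate_mitogenome(mitogenome_spec(rng_seed = 101)))
}

# small repeat-free circular genome for fast assembly / k-mer tests
fx_small_genome <- function() {
  fixture("small_genome", function() {
    withr::with_seed(7, {
      circ_seq(paste0(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                      collapse = ""), id = "small")
    })
  })
}

# brute-force canonical k-mer counter (oracle)
oracle_count_kmers <- function(seqs, k) {
  canon <- function(w) {
    r <- as.character(revcomp(w))
    ifelse(w <= r, w, r)
  }
  all <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  all <- all[!grepl("[^ACGT]", all)]
  table(canon(all))
}

# brute-force Fitch via exhaustive internal-state enumeration (oracle);
# assumes a rooted binary ape tree
oracle_fitch <- function(tree, aln) {
  masks <- mitoforge:::state_masks(aln)[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  states <- c(1L, 2L, 4L, 8L)
  combos <- as.matrix(expand.grid(rep(list(states), n_int)))
  total <- 0L
  for (site in seq_len(ncol(masks))) {
    leaf <- masks[, site]
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      assign_int <- combos[r, ]
      cost <- 0L
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; c2 <- tree$edge[e, 2]
        ps <- assign_int[p - n_tip]
        cs <- if (c2 <= n_tip) leaf[c2] else assign_int[c2 - n_tip]
        # leaf with missing data is compatible with any parent state
        if (c2 <= n_tip) {
          if (bitwAnd(ps, cs) == 0L) cost <- cost + 1L
        } else if (ps != cs) cost <- cost + 1L
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

random_alignment <- function(n_taxa, n_col, seed, p_missing = 0) {
  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), n_taxa * n_col, replace = TRUE)
    if (p_missing > 0) {
      miss <- runif(n_taxa * n_col) < p_missing
      chars[miss] <- "N"
    }
    seqs <- apply(matrix(chars, nrow = n_taxa), 1, paste0, collapse = "")
    alignment_matrix(setNames(seqs, paste0("t", seq_len(n_taxa))))
  })
}

random_binary_tree <- function(taxa, seed) {
  withr::with_seed(seed, ape::rtree(length(taxa), tip.label = sample(taxa)))
}
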