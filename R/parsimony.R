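#' Parsimony-informative site count
#'
#' A column is parsimony-informative when at least two distinct states
#' each occur in at least two taxa; characters other than A/C/G/T are
#' ignored.
#'
#' @param aln an [alignment_matrix()].
#' @return integer count.
#' @export
count_informative_sites <- function(aln) {
  stopifnot(inherits(aln, "alignment_matrix"))
  sum(apply(aln$mat, 2, function(col) {
    tab <- table(col[col %in% DNA_BASES])
    sum(tab >= 2) >= 2
  }))
}

# per-taxon bitmask matrix: A=1, C=2, G=4, T=8, anything else = 15 (missing)
state_masks <- function(aln) {
  lut <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, `-` = 15L)
  m <- matrix(lut[aln$mat], nrow = nrow(aln$mat),
              dimnames = dimnames(aln$mat))
  m[is.na(m)] <- 15L
  m
}

normalize_tree <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
    else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree
}

# per-site Fitch step counts on a (bifurcating) tree
fitch_site_steps <- function(tree, aln) {
  tree <- normalize_tree(tree)
  if (!all(tree$tip.label %in% aln$taxa)) {
    stop("tree tips not all present in the alignment", call. = FALSE)
  }
  masks <- state_masks(aln)[tree$tip.label, , drop = FALSE]
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  L <- ncol(masks)
  state <- matrix(0L, n_tip + tree$Nnode, L)
  state[seq_len(n_tip), ] <- masks
  filled <- logical(n_tip + tree$Nnode)
  filled[seq_len(n_tip)] <- TRUE
  steps <- integer(L)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    if (!filled[parent]) {
      state[parent, ] <- state[child, ]
      filled[parent] <- TRUE
    } else {
      inter <- bitwAnd(state[parent, ], state[child, ])
      miss <- inter == 0L
      steps <- steps + miss
      state[parent, ] <- ifelse(miss,
                                bitwOr(state[parent, ], state[child, ]),
                                inter)
    }
  }
  steps
}

#' Fitch small-parsimony tree length
#'
#' Sum over alignment columns of the minimum number of state changes on
#' the fixed topology (Fitch's algorithm). Non-ACGT characters are treated
#' as missing (compatible with every state); polytomies are resolved
#' arbitrarily but deterministically before scoring, and the result is
#' invariant to the rooting of the tree.
#'
#' @param tree an `ape::phylo` tree, a newick string, or a newick file
#'   path; tip labels must appear in the alignment.
#' @param aln an [alignment_matrix()].
#' @return tree length in steps.
#' @export
fitch_length <- function(tree, aln) {
  sum(fitch_site_steps(tree, aln))
}

#' Homoplasy indices of a tree on an alignment
#'
#' From the Fitch tree length S, the minimum conceivable steps
#' M = sum per site of (observed states - 1) and the maximum
#' G = sum per site of (occurrences - modal state count), computes the
#' consistency index CI = M/S, the retention index RI = (G-S)/(G-M), and
#' their product, the rescaled (composite) consistency index RC = CI x RI.
#' Both the all-sites and the informative-sites-only versions are
#' reported, as the two are commonly printed side by side.
#'
#' @param tree tree as in [fitch_length()].
#' @param aln an [alignment_matrix()].
#' @return tibble of class `parsimony_stats`, one row per site set
#'   (`all`, `informative`): `site_set`, `n_sites`, `n_informative`,
#'   `tree_length`, `min_steps`, `max_steps`, `ci`, `ri`, `rc`. Indices
#'   are NA when the site set shows no variation (S = 0).
#' @export
homoplasy_indices <- function(tree, aln) {
  stopifnot(inherits(aln, "alignment_matrix"))
  steps <- fitch_site_steps(tree, aln)
  per_site <- apply(aln$mat, 2, function(col) {
    tab <- table(col[col %in% DNA_BASES])
    c(m = if (length(tab)) length(tab) - 1L else 0L,
      g = if (length(tab)) sum(tab) - max(tab) else 0L,
      informative = sum(tab >= 2) >= 2)
  })
  m_site <- per_site["m", ]
  g_site <- per_site["g", ]
  inf_site <- as.logical(per_site["informative", ])
  one <- function(idx, label) {
    S <- sum(steps[idx])
    M <- sum(m_site[idx])
    G <- sum(g_site[idx])
    ci <- if (S > 0) M / S else NA_real_
    ri <- if (S > 0 && G > M) (G - S) / (G - M) else NA_real_
    tibble(site_set = label, n_sites = sum(idx),
           n_informative = sum(inf_site & idx),
           tree_length = S, min_steps = M, max_steps = G,
           ci = ci, ri = ri, rc = ci * ri)
  }
  out <- dplyr::bind_rows(
    one(rep(TRUE, length(steps)), "all"),
    one(inf_site, "informative")
  )
  class(out) <- c("parsimony_stats", class(out))
  out
}

#' @export
print.parsimony_stats <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-12s sites: length %d steps, CI %.3f, RI %.3f, RC %.3f (n = %d)\n",
                x$site_set[i], x$tree_length[i], x$ci[i], x$ri[i], x$rc[i],
                x$n_sites[i]))
  }
  invisible(x)
}
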