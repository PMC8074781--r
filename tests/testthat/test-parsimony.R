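test_that("parsimony-informative sites follow the two-by-two definition", {
  aln <- alignment_matrix(c(a = "AAAA", b = "AAAA", c = "CACA", d = "CAAC"))
  # col1 {A,A,C,C} informative; col2 constant; col3 {A,A,C,A} not;
  # col4 {A,A,A,C} not
  expect_equal(count_informative_sites(aln), 1L)
  const <- alignment_matrix(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  expect_equal(count_informative_sites(const), 0L)
  # random alignment vs brute-force per-column check
  aln2 <- random_alignment(6, 200, seed = 42, p_missing = 0.05)
  oracle <- sum(apply(aln2$mat, 2, function(col) {
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    sum(tab >= 2) >= 2
  }))
  expect_equal(count_informative_sites(aln2), oracle)
})

test_that("Fitch length matches exhaustive small-parsimony enumeration", {
  # identical sequences: zero steps
  same <- alignment_matrix(setNames(rep(strrep("ACGT", 10), 4), paste0("t", 1:4)))
  tree4 <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_equal(fitch_length(tree4, same), 0L)
  # 4-taxon random alignments vs brute force
  for (s in 1:5) {
    aln <- random_alignment(4, 30, seed = 100 + s)
    tree <- random_binary_tree(aln$taxa, seed = 200 + s)
    expect_equal(fitch_length(tree, aln), oracle_fitch(tree, aln))
  }
  # missing data (treated as the full state set) against the oracle
  alnm <- random_alignment(4, 25, seed = 300, p_missing = 0.15)
  treem <- random_binary_tree(alnm$taxa, seed = 301)
  expect_equal(fitch_length(treem, alnm), oracle_fitch(treem, alnm))
})

test_that("Fitch length is invariant to rooting and matches phangorn", {
  aln <- random_alignment(6, 120, seed = 17)
  tree <- random_binary_tree(aln$taxa, seed = 18)
  len <- fitch_length(tree, aln)
  for (og in c(2, 4)) {
    rooted <- ape::root(tree, outgroup = tree$tip.label[og], resolve.root = TRUE)
    expect_equal(fitch_length(rooted, aln), len)
  }
  skip_if_not_installed("phangorn")
  dat <- phangorn::phyDat(aln$mat, type = "DNA")
  expect_equal(len, phangorn::parsimony(tree, dat, method = "fitch"))
  expect_error(fitch_length(ape::read.tree(text = "(x,(y,z));"), aln),
               "tips")
})

test_that("homoplasy-free data score CI = RI = RC = 1", {
  # mutations on distinct sites along the generating tree: no homoplasy
  anc <- strrep("A", 60)
  mut <- function(s, pos, base) { substr(s, pos, pos) <- base; s }
  left <- mut(anc, 5, "C")              # shared by t1, t2
  right <- mut(anc, 20, "G")            # shared by t3, t4
  seqs <- c(t1 = mut(left, 30, "T"), t2 = mut(left, 40, "T"),
            t3 = mut(right, 50, "C"), t4 = mut(right, 55, "G"))
  aln <- alignment_matrix(seqs)
  tree <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  st <- homoplasy_indices(tree, aln)
  all_row <- st[st$site_set == "all", ]
  expect_equal(all_row$ci, 1)
  expect_equal(all_row$ri, 1)
  expect_equal(all_row$rc, 1)
  expect_equal(all_row$tree_length, all_row$min_steps)
})

test_that("indices satisfy their identities on random fixtures", {
  for (s in 1:5) {
    aln <- random_alignment(6, 150, seed = 500 + s)
    tree <- random_binary_tree(aln$taxa, seed = 600 + s)
    st <- homoplasy_indices(tree, aln)
    for (r in seq_len(nrow(st))) {
      expect_equal(st$rc[r], st$ci[r] * st$ri[r], tolerance = 1e-12)
      expect_lte(st$min_steps[r], st$tree_length[r])
      expect_lte(st$tree_length[r], st$max_steps[r])
    }
  }
})

test_that("constant columns leave S, M, G unchanged and S = 0 gives NA indices", {
  aln <- random_alignment(5, 80, seed = 7)
  tree <- random_binary_tree(aln$taxa, seed = 8)
  st1 <- homoplasy_indices(tree, aln)
  plus <- alignment_matrix(setNames(
    paste0(apply(aln$mat, 1, paste0, collapse = ""), strrep("A", 5)), aln$taxa))
  st2 <- homoplasy_indices(tree, plus)
  a1 <- st1[st1$site_set == "all", ]
  a2 <- st2[st2$site_set == "all", ]
  expect_equal(a2$tree_length, a1$tree_length)
  expect_equal(a2$min_steps, a1$min_steps)
  expect_equal(a2$max_steps, a1$max_steps)
  const <- alignment_matrix(setNames(rep(strrep("ACG", 10), 5), aln$taxa))
  stc <- homoplasy_indices(tree, const)
  expect_true(all(is.na(stc$ci)))
})
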