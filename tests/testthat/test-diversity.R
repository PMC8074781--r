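test_that("pairwise differences find exactly the disagreeing columns", {
  base <- strrep("ACGT", 100)                      # 400 columns
  other <- base
  for (p in c(10L, 250L, 251L)) {                  # 0-based targets
    cur <- substr(other, p + 1, p + 1)
    substr(other, p + 1, p + 1) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  aln <- alignment_matrix(c(ref = base, alt = other))
  d <- pairwise_differences(aln, "ref", "alt")
  expect_equal(d$position, c(10L, 250L, 251L))
  # identical rows give an empty list
  aln2 <- alignment_matrix(c(a = base, b = base))
  expect_equal(nrow(pairwise_differences(aln2, "a", "b")), 0L)
  # N at a mismatching column is excluded
  masked <- other
  substr(masked, 11, 11) <- "N"
  aln3 <- alignment_matrix(c(ref = base, alt = masked))
  expect_equal(pairwise_differences(aln3, "ref", "alt")$position, c(250L, 251L))
  expect_error(pairwise_differences(aln, "ref", "nope"), "unknown taxon")
})

test_that("gaps count as differences only when requested", {
  aln <- alignment_matrix(c(a = "ACGTAC", b = "AC-TAC"))
  expect_equal(nrow(pairwise_differences(aln, "a", "b")), 0L)
  expect_equal(pairwise_differences(aln, "a", "b", count_gaps = TRUE)$position, 2L)
})

test_that("block densities conserve the total difference count", {
  expect_equal(formals(block_density)$window, 100L)
  # no differences: all-zero track
  tr0 <- block_density(integer(0), length = 950)
  expect_equal(nrow(tr0), 10L)
  expect_true(all(tr0$count == 0L))
  # conservation over random difference sets, partial final block kept raw
  withr::with_seed(77, {
    for (i in 1:50) {
      L <- sample(300:2000, 1)
      pos <- sort(sample(0:(L - 1), sample(0:100, 1)))
      tr <- block_density(pos, length = L)
      expect_equal(sum(tr$count), length(pos))
      expect_equal(nrow(tr), ceiling(L / 100))
      # oracle: direct per-block recount
      oracle <- tabulate(pos %/% 100 + 1L, nbins = ceiling(L / 100))
      expect_equal(tr$count, as.integer(oracle))
    }
  })
})

test_that("nucleotide diversity equals the brute-force all-pairs average", {
  # forced arithmetic: 2 sequences, 100 comparable columns, 1 difference
  a <- strrep("A", 100)
  b <- paste0("C", strrep("A", 99))
  expect_equal(nucleotide_diversity(alignment_matrix(c(a = a, b = b))), 0.01)
  expect_equal(nucleotide_diversity(alignment_matrix(c(a = a, b = a))), 0)
  # 10 seeded sequences vs brute force to 1e-12
  aln <- random_alignment(10, 400, seed = 91, p_missing = 0.05)
  pi_pkg <- nucleotide_diversity(aln)
  vals <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    x <- aln$mat[i, ]; y <- aln$mat[j, ]
    comp <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    vals <- c(vals, sum(x[comp] != y[comp]) / sum(comp))
  }
  expect_equal(pi_pkg, mean(vals), tolerance = 1e-12)
})

test_that("pi is invariant to taxon order and all-N columns", {
  aln <- random_alignment(6, 200, seed = 13)
  pi1 <- nucleotide_diversity(aln)
  perm <- alignment_matrix(setNames(
    apply(aln$mat[c(3, 1, 6, 2, 5, 4), ], 1, paste0, collapse = ""),
    paste0("p", 1:6)))
  expect_equal(nucleotide_diversity(perm), pi1, tolerance = 1e-15)
  withN <- alignment_matrix(setNames(
    paste0(apply(aln$mat, 1, paste0, collapse = ""), "N"), aln$taxa))
  expect_equal(nucleotide_diversity(withN), pi1, tolerance = 1e-15)
})

test_that("identity matrices agree with hand-computed values", {
  aln <- alignment_matrix(c(
    a = "ACGTACGTACGTACGTACGT",
    b = "ACGTACGTAC-TACGTACGA",   # 1 gap col, 1 mismatch -> 18/18... and vs a
    c = "TCGTACGTACGTACGTACGT"))
  m <- identity_matrix(aln)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_equal(m["a", "b"], 100 * 18 / 19)  # 19 both-base cols, 1 mismatch
  expect_equal(m["a", "c"], 100 * 19 / 20)
  expect_equal(m["b", "c"], 100 * 17 / 19)
  # identical pair: 100
  aln2 <- alignment_matrix(c(x = "ACGT", y = "ACGT"))
  expect_equal(identity_matrix(aln2)["x", "y"], 100)
})

test_that("identity and difference fraction are complementary on gap-free data", {
  aln <- random_alignment(4, 300, seed = 5)
  m <- identity_matrix(aln)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- pairwise_differences(aln, aln$taxa[i], aln$taxa[j])
    expect_equal(m[i, j] + 100 * nrow(d) / aln$length, 100, tolerance = 1e-9)
  }
})
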