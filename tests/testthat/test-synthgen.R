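test_that("the default mitogenome carries the full gene complement", {
  gm <- fx_mitogenome()
  kinds <- table(gm$features$kind)
  expect_equal(unname(kinds["tRNA"]), 23L)
  expect_equal(unname(kinds["PCG"]), 14L)
  expect_equal(unname(kinds["rRNA"]), 2L)
  expect_equal(unname(kinds["CR"]), 2L)
  expect_equal(unname(kinds["TR"]), 2L)
  expect_equal(gm$genome$length, mitogenome_spec()$total_length)
  # annotation covers every generated feature within bounds
  expect_true(all(gm$features$start >= 0 & gm$features$end <= gm$genome$length))
})

test_that("generation is byte-identical for a fixed seed", {
  a <- generate_mitogenome(mitogenome_spec(rng_seed = 55))
  b <- generate_mitogenome(mitogenome_spec(rng_seed = 55))
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$features, b$features)
  c <- generate_mitogenome(mitogenome_spec(rng_seed = 56))
  expect_false(identical(a$genome$seq, c$genome$seq))
})

test_that("control-region copies hit their target identity", {
  # identity 1 with equal tract copies: exact duplication
  gm1 <- generate_mitogenome(mitogenome_spec(cr_copy_identity = 1, rng_seed = 3))
  cr1 <- subseq_circular(gm1$genome, gm1$truth$cr1[1], gm1$truth$cr1[2])
  cr2 <- subseq_circular(gm1$genome, gm1$truth$cr2[1], gm1$truth$cr2[2])
  expect_identical(cr1, cr2)
  # identity 0.98: independent global-alignment identity in [0.97, 0.99]
  gm <- fx_mitogenome()
  cr1 <- subseq_circular(gm$genome, gm$truth$cr1[1], gm$truth$cr1[2])
  cr2 <- subseq_circular(gm$genome, gm$truth$cr2[1], gm$truth$cr2[2])
  id <- mitoforge:::identity_global(cr1, cr2)
  expect_gte(id, 0.97)
  expect_lte(id, 0.99)
})

test_that("infeasible specs are rejected", {
  expect_error(mitogenome_spec(total_length = 10000), "infeasible")
})

test_that("planted NUMTs match their sampled identities", {
  gm <- fx_mitogenome()
  # defaults mirror the reported NUMT landscape
  expect_equal(formals(plant_numts)$length_range, quote(c(54, 5499)))
  expect_equal(formals(plant_numts)$identity_range, quote(c(0.648, 0.952)))
  bg <- plant_numts(50000, gm$genome, n = 5, length_range = c(100, 800),
                    identity_range = c(0.75, 0.95), seed = 12)
  expect_equal(nrow(bg$planted), 5L)
  # realized identity (independent global aligner) within 0.02 of target
  expect_true(all(abs(bg$planted$realized_identity -
                        bg$planted$target_identity) <= 0.02))
  # n = 0 leaves the background untouched
  bg0a <- plant_numts(20000, gm$genome, n = 0, seed = 5)
  bg0b <- plant_numts(20000, gm$genome, n = 0, seed = 5)
  expect_identical(bg0a$seq, bg0b$seq)
  expect_equal(nrow(bg0a$planted), 0L)
})

test_that("error-free paired reads are exact substrings of the doubled genome", {
  g <- fx_small_genome()
  rs <- simulate_reads(g, read_profile(coverage = 10, long_n = 0), seed = 2)
  g2 <- doubled(g)
  g2rc <- as.character(revcomp(g2))
  ok <- vapply(seq_len(nrow(rs$paired)), function(i) {
    r1 <- rs$paired$read1[i]
    r2 <- as.character(revcomp(rs$paired$read2[i]))
    (grepl(r1, g2, fixed = TRUE) || grepl(r1, g2rc, fixed = TRUE)) &&
      (grepl(r2, g2, fixed = TRUE) || grepl(r2, g2rc, fixed = TRUE))
  }, TRUE)
  expect_true(all(ok))
  # reads trace back to their true origins
  ok2 <- vapply(seq_len(min(50, nrow(rs$paired))), function(i) {
    fs <- rs$paired$frag_start[i]
    ins <- rs$paired$insert[i]
    frag <- subseq_circular(g, fs, fs + ins)
    if (rs$paired$strand[i] == "-") frag <- as.character(revcomp(frag))
    substr(frag, 1, 150) == rs$paired$read1[i]
  }, TRUE)
  expect_true(all(ok2))
})

test_that("long reads follow the 3-4 kb length model and error rate", {
  gm <- fx_mitogenome()
  prof <- read_profile(coverage = 1, long_n = 300, long_error = 0.10)
  rs <- simulate_reads(gm$genome, prof, seed = 9)
  expect_gte(mean(rs$long$length), 3000)
  expect_lte(mean(rs$long$length), 4000)
  # empirical substitution rate over >= 1e6 bases within 3 SE of 0.10
  g2 <- doubled(gm$genome)
  n_err <- 0L; n_tot <- 0L
  for (i in seq_len(nrow(rs$long))) {
    truth <- substr(g2, rs$long$start[i] + 1, rs$long$start[i] + rs$long$length[i])
    if (rs$long$strand[i] == "-") truth <- as.character(revcomp(truth))
    cmp <- mitoforge:::cpp_positional_identity(truth, 0L, rs$long$seq[i], 0L,
                                               nchar(truth), logical(0))
    n_err <- n_err + (cmp$compared - cmp$matches)
    n_tot <- n_tot + cmp$compared
  }
  expect_gte(n_tot, 1e6)
  se <- sqrt(0.1 * 0.9 / n_tot)
  expect_lt(abs(n_err / n_tot - 0.10), 3 * se)
})

test_that("reads longer than the genome are rejected", {
  g <- circ_seq(strrep("ACGT", 30))
  expect_error(simulate_reads(g, read_profile(coverage = 2, read_len = 150)),
               "read length")
})

test_that("amplicon arithmetic is half-open and wraps the origin", {
  g <- fx_small_genome()
  L <- g$length
  ev <- simulate_pcr_evidence(g, primer_pairs = tibble::tibble(
    fwd = c(0L, L - 200L), rev = c(500L, 300L)))
  expect_equal(ev$expected_length, c(500L, 500L))
  expect_error(simulate_pcr_evidence(g, primer_pairs = tibble::tibble(fwd = 5L, rev = 5L)),
               "zero-length")
  # default tiling design stays inside the Sanger-walk product range
  gm <- fx_mitogenome()
  amp <- simulate_pcr_evidence(gm$genome)
  expect_true(all(amp$expected_length >= 500 & amp$expected_length <= 3100))
})

test_that("panels are substitution-only and aligned to the ancestor", {
  gm <- fx_mitogenome()
  p <- simulate_panel(gm$genome, 3, divergence = 0.01, seed = 4)
  expect_true(all(nchar(p) == gm$genome$length))
  d <- mapply(function(s) sum(strsplit(s, "")[[1]] !=
                                strsplit(gm$genome$seq, "")[[1]]), p)
  expect_equal(unname(d), rep(round(0.01 * gm$genome$length), 3))
})
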