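test_that("mito k-mer classification thresholds at the geometric mean", {
  # counts drawn as nuclear ~5x (many k-mers), mito ~100x (fewer)
  withr::with_seed(31, {
    km <- unique(vapply(1:6000, function(i)
      paste0(sample(c("A", "C", "G", "T"), 23, replace = TRUE), collapse = ""), ""))
    n_nuc <- 5000L
    counts <- c(pmax(1L, stats::rpois(n_nuc, 5)),
                pmax(1L, stats::rpois(length(km) - n_nuc, 100)))
  })
  tab <- structure(list(k = 23L, kmer = km, count = as.integer(counts),
                        solid_min = 3L), class = "kmer_table")
  cls <- classify_mito_kmers(tab, mito_cov = 100, autosomal_cov = 5)
  expect_equal(cls$threshold, sqrt(500), tolerance = 1e-12)
  truth_mito <- seq_along(km) > n_nuc
  pass <- is_mito_kmer(cls, km)
  expect_gt(mean(pass[truth_mito]), 0.99)
  # histogram inference finds the same two modes
  cls2 <- classify_mito_kmers(tab)
  expect_lt(abs(cls2$threshold - sqrt(500)) / sqrt(500), 0.25)
  # monotone: any k-mer counted at least as often as a passing one passes
  thr_counts <- counts[pass]
  expect_true(all(counts >= min(thr_counts) | !pass))
})

test_that("a degenerate (unimodal) histogram demands explicit estimates", {
  tab <- structure(list(k = 23L, kmer = c("ACGTACGTACGTACGTACGTACG"),
                        count = 7L, solid_min = 3L), class = "kmer_table")
  tab$kmer <- rep(tab$kmer, 10)
  tab$count <- rep(7L, 10)
  expect_error(classify_mito_kmers(tab), "unimodal|estimates")
  expect_error(classify_mito_kmers(tab, mito_cov = 100), "both")
})

test_that("the seed k-mer comes from the named reference feature", {
  gm <- fx_mitogenome()
  rs <- simulate_reads(gm$genome, read_profile(coverage = 40, long_n = 0), seed = 6)
  tab <- count_kmers(rs)
  cls <- classify_mito_kmers(tab, 100, 5)
  expect_equal(formals(select_seed)$feature_name, "12S rRNA")
  seed <- select_seed(gm$genome, gm$features, "12S rRNA", cls)
  expect_equal(nchar(seed), 23L)
  # provenance: the seed lies inside the 12S rRNA feature
  row <- gm$features[gm$features$name == "12S rRNA", ]
  feat_seq <- subseq_circular(gm$genome, row$start, row$end)
  expect_true(grepl(seed, feat_seq, fixed = TRUE))
  expect_error(select_seed(gm$genome, gm$features, "no such gene", cls),
               "absent")
})

test_that("unique extension reproduces a repeat-free genome with zero forks", {
  g <- fx_small_genome()
  rs <- simulate_reads(g, read_profile(coverage = 40, long_n = 0), seed = 8)
  tab <- count_kmers(rs)
  cls <- classify_mito_kmers(tab, 40, 2)
  seed <- substr(g$seq, 1, 23)
  st <- walk_state(seed)
  res <- extend_path(st, cls, seed = seed)
  expect_equal(res$event, "circular")
  expect_identical(normalize_rotation(circ_seq(substr(res$state$contig, 1,
                                                      nchar(res$state$contig) - 23)))$seq,
                   normalize_rotation(g)$seq)
})

test_that("an exact internal repeat >= k halts the walk at a fork", {
  withr::with_seed(13, {
    u <- paste0(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    a <- paste0(sample(c("A", "C", "G", "T"), 700, replace = TRUE), collapse = "")
    b <- paste0(sample(c("A", "C", "G", "T"), 700, replace = TRUE), collapse = "")
  })
  g <- circ_seq(paste0(a, u, b, u))  # two exact copies of u (40 bp > k)
  tab <- count_kmers(g)
  cls <- classify_mito_kmers(tab, mito_cov = 2, autosomal_cov = 0.5)
  seed <- substr(g$seq, 1, 23)
  res <- extend_path(walk_state(seed), cls, seed = seed)
  expect_equal(res$event, "fork")
  expect_gte(length(res$successors), 2)
  # the fork sits where the walk leaves the first repeat copy: the frontier
  # k-mer occurs more than once in the genome
  frontier <- substr(res$state$contig, nchar(res$state$contig) - 22,
                     nchar(res$state$contig))
  expect_gte(length(mitoforge:::cpp_exact_find(doubled(g), frontier)), 2)
})

test_that("a linear fragment walks into a dead end", {
  withr::with_seed(14, {
    s <- paste0(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  })
  tab <- count_kmers(s)
  cls <- classify_mito_kmers(tab, mito_cov = 2, autosomal_cov = 0.5)
  res <- extend_path(walk_state(substr(s, 1, 23)), cls)
  expect_equal(res$event, "dead_end")
  expect_identical(res$state$contig, s)
  # leftward extension reaches the other end
  resl <- extend_path(walk_state(substr(s, 478, 500), direction = "left"), cls)
  expect_equal(resl$event, "dead_end")
  expect_identical(resl$state$contig, s)
})

test_that("fork arbitration picks the evidence-consistent branch", {
  sc <- study_scenario(3)
  tab <- count_kmers(sc$reads)
  cls <- classify_mito_kmers(tab, 100, 5)
  seed <- select_seed(sc$reference, sc$ref_features, "12S rRNA", cls)
  w <- mitoforge:::walk_right(cls, seed, seed)
  expect_equal(w$event, "fork")
  fe <- resolve_fork(w$contig, w$successors, cls, sc$evidence, seed = seed)
  expect_false(identical(fe$resolution, "AMBIGUOUS"))
  # the committed continuation matches the true genome
  g2 <- doubled(sc$genome)
  pos <- mitoforge:::cpp_exact_find(g2, substr(w$contig, nchar(w$contig) - 22,
                                               nchar(w$contig)))
  truth_next <- vapply(pos, function(p)
    substr(g2, p + 24, p + 23 + nchar(fe$commit)), "")
  expect_true(fe$commit %in% truth_next)
  # with no informative evidence at all the same fork is AMBIGUOUS
  ev0 <- evidence_set(length_tolerance = 0.1)
  fe0 <- resolve_fork(w$contig, w$successors, cls, ev0, seed = seed)
  expect_identical(fe0$resolution, "AMBIGUOUS")
})

test_that("over-length amplicon products disqualify a branch", {
  g <- fx_small_genome()
  amp <- simulate_pcr_evidence(g, primer_pairs = tibble::tibble(fwd = 100L, rev = 1100L))
  # candidate x with 300 bp inserted inside the product: implied 1300 vs 1000
  x_bad <- paste0(subseq_circular(g, 0, 600),
                  strrep("ACGT", 75),
                  subseq_circular(g, 600, 1400))
  chk <- mitoforge:::amplicon_consistent(x_bad, amp, tol = 0.10, partial = TRUE)
  expect_true(chk$informative)
  expect_false(chk$ok)
  # the true sequence is consistent
  chk2 <- mitoforge:::amplicon_consistent(subseq_circular(g, 0, 1400), amp,
                                          tol = 0.10, partial = TRUE)
  expect_true(chk2$ok)
})

test_that("validation flags constructed assembly defects", {
  sc <- study_scenario(4)
  rep1 <- assemble_mitogenome(sc$reads, sc$reference, sc$ref_features,
                              sc$evidence, mito_cov = 100, autosomal_cov = 5)
  expect_true(rep1$circularized)
  expect_true(all(rep1$validation$pass, na.rm = TRUE))
  # a 500 bp deletion breaks spanning amplicon lengths
  s <- rep1$assembled$seq
  broken <- circ_seq(paste0(substr(s, 1, 4000), substr(s, 4501, nchar(s))))
  tab <- count_kmers(sc$reads)
  val <- mitoforge:::validate_assembly_internal(broken, sc$evidence, tab, NULL)
  expect_false(val$pass[val$check == "amplicon_length_consistency"])
  # a 50 bp novel insertion absent from the reads breaks coverage continuity
  ins <- circ_seq(paste0(substr(s, 1, 4000), strrep("ACGTG", 10),
                         substr(s, 4001, nchar(s))))
  val2 <- mitoforge:::validate_assembly_internal(ins, sc$evidence, tab, NULL)
  expect_false(val2$pass[val2$check == "coverage_continuity"])
})

test_that("assembly is invariant to the strand of the input genome", {
  sc <- study_scenario(5)
  rep1 <- assemble_mitogenome(sc$reads, sc$reference, sc$ref_features,
                              sc$evidence, mito_cov = 100, autosomal_cov = 5)
  expect_true(rep1$circularized)
  norm_truth <- normalize_rotation(sc$genome)$seq
  expect_identical(rep1$assembled$seq, norm_truth)
  # the normal form of the reverse-complemented truth is the same sequence
  expect_identical(normalize_rotation(circ_seq(as.character(revcomp(sc$genome$seq))))$seq,
                   norm_truth)
  # report tidiers
  td <- tidy(rep1)
  expect_true(all(c("position", "resolution", "committed") %in% names(td)))
  gl <- glance(rep1)
  expect_equal(gl$status, "circular")
  expect_equal(gl$n_ambiguous, 0L)
})
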