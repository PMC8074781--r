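test_that("canonical counting matches a brute-force window oracle", {
  withr::with_seed(11, {
    seqs <- vapply(1:20, function(i)
      paste0(sample(c("A", "C", "G", "T"), sample(20:80, 1), replace = TRUE),
             collapse = ""), "")
  })
  k <- 23L
  tab <- count_kmers(seqs, k)
  oracle <- oracle_count_kmers(seqs, k)
  expect_equal(sort(tab$kmer), sort(names(oracle)))
  expect_equal(tab$count[match(names(oracle), tab$kmer)],
               unname(as.integer(oracle)))
  # total count mass equals sum over reads of max(0, len - k + 1)
  expect_equal(sum(tab$count), sum(pmax(0L, nchar(seqs) - k + 1L)))
})

test_that("counting is canonical and defaults to k = 23", {
  expect_equal(formals(count_kmers)$k, 23L)
  r <- "ACGTACGTACGTACGTACGTACG"  # length 23
  tab <- count_kmers(r)
  expect_equal(length(tab$kmer), 1L)
  expect_equal(tab$count, 1L)
  # a read and its reverse complement give identical tables
  withr::with_seed(3, {
    s <- paste0(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  })
  t1 <- count_kmers(s)
  t2 <- count_kmers(as.character(revcomp(s)))
  expect_equal(t1$kmer[order(t1$kmer)], t2$kmer[order(t2$kmer)])
  expect_equal(t1$count[order(t1$kmer)], t2$count[order(t2$kmer)])
  # reads shorter than k contribute nothing
  expect_equal(length(count_kmers("ACGT")$kmer), 0L)
  # k-mers containing N are skipped
  expect_equal(length(count_kmers(paste0(strrep("A", 11), "N", strrep("A", 11)))$kmer), 0L)
})

test_that("coverage profiles agree with exhaustive lookup", {
  g <- fx_small_genome()
  tab <- count_kmers(g)            # one copy of the genome, circular
  prof <- map_kmer_coverage(tab, g)
  expect_length(prof$coverage, g$length)
  expect_true(all(prof$coverage >= 1L))
  # brute-force oracle at every start position
  g2 <- paste0(g$seq, substr(g$seq, 1, 22))
  wins <- substring(g2, 1:g$length, 23:(g$length + 22))
  canon <- ifelse(wins <= as.character(revcomp(wins)), wins,
                  as.character(revcomp(wins)))
  counts <- setNames(tab$count, tab$kmer)
  oracle <- unname(counts[canon])
  oracle[is.na(oracle)] <- 0L
  expect_equal(prof$coverage, as.integer(oracle))
})

test_that("disjoint sequences produce an all-zero profile", {
  # AT-only vs GC-only genomes share no canonical 23-mers
  withr::with_seed(8, {
    at <- circ_seq(paste0(sample(c("A", "T"), 400, replace = TRUE), collapse = ""))
    gc <- circ_seq(paste0(sample(c("G", "C"), 400, replace = TRUE), collapse = ""))
  })
  tab <- count_kmers(at)
  prof <- map_kmer_coverage(tab, gc)
  expect_true(all(prof$coverage == 0L))
})

test_that("read recruitment separates mito from nuclear perfectly on disjoint genomes", {
  withr::with_seed(21, {
    mito <- circ_seq(paste0(sample(c("A", "T"), 2000, replace = TRUE), collapse = ""),
                     id = "mito")
    nuc <- circ_seq(paste0(sample(c("G", "C"), 2000, replace = TRUE), collapse = ""),
                    id = "nuclear")
  })
  rs_m <- simulate_reads(mito, read_profile(coverage = 15, long_n = 0), seed = 1)
  rs_n <- simulate_reads(nuc, read_profile(coverage = 135, long_n = 0), seed = 2)
  mixed <- rs_m
  mixed$paired <- rbind(rs_m$paired, rs_n$paired)
  bait <- count_kmers(mito)
  rec <- recruit_reads(mixed, bait)
  expect_true(all(rec$paired$origin == "mito"))        # precision 1
  expect_equal(nrow(rec$paired), nrow(rs_m$paired))    # recall 1
  # recruited set is a subset and recruitment is idempotent
  rec2 <- recruit_reads(rec, bait)
  expect_identical(rec2$paired, rec$paired)
  # monotone in the threshold
  for (m in c(2L, 5L, 20L)) {
    r_m <- recruit_reads(mixed, bait, min_shared = m)
    expect_true(all(r_m$paired$read1 %in% rec$paired$read1))
  }
  # a read sharing no k-mers is excluded
  expect_length(recruit_reads(paste0(strrep("G", 30)), bait), 0L)
})

test_that("solidity masks match the brute-force footprint oracle", {
  g <- fx_small_genome()
  rs <- simulate_reads(g, read_profile(coverage = 30, long_n = 0), seed = 3)
  tab <- count_kmers(rs)
  # a long read with a corrupted middle: weak region appears there
  read <- subseq_circular(g, 100, 700)
  read <- paste0(substr(read, 1, 280), strrep("A", 30), substr(read, 311, 600))
  mask <- trim_weak_regions(read, tab)
  # oracle: union of footprints of solid k-mers
  wins <- substring(read, 1:(nchar(read) - 22), 23:nchar(read))
  canon <- ifelse(wins <= as.character(revcomp(wins)), wins,
                  as.character(revcomp(wins)))
  counts <- setNames(tab$count, tab$kmer)
  solid <- !is.na(counts[canon]) & counts[canon] >= tab$solid_min
  oracle <- rep(FALSE, nchar(read))
  for (p in which(solid)) oracle[p:(p + 22)] <- TRUE
  expect_equal(mask$mask, oracle)
  # trimmed interval is the longest solid run, and only solid bases
  expect_true(all(mask$mask[(mask$trimmed[1] + 1):mask$trimmed[2]]))
})

test_that("trimming edge cases: fully solid, fully weak, short reads", {
  g <- fx_small_genome()
  tab <- count_kmers(g, solid_min = 1L)
  clean <- subseq_circular(g, 0, 300)
  m1 <- trim_weak_regions(clean, tab)
  expect_true(all(m1$mask))
  expect_equal(m1$trimmed, c(0L, 300L))
  m2 <- trim_weak_regions(strrep("A", 100), tab)
  expect_false(any(m2$mask))
  expect_equal(m2$trimmed, c(0L, 0L))
  m3 <- trim_weak_regions("ACGT", tab)   # shorter than k: fully weak
  expect_false(any(m3$mask))
})
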