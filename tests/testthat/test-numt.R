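test_that("a planted NUMT is recovered with reciprocal overlap >= 0.9", {
  gm <- fx_mitogenome()
  expect_equal(numt_config()$evalue_max, 1e-4)
  bg <- plant_numts(200000, gm$genome, n = 1, length_range = c(300, 300),
                    identity_range = c(0.85, 0.85), seed = 7,
                    measure_identity = FALSE)
  hits <- numt_search(gm$genome, bg)
  expect_gte(nrow(hits), 1)
  ps <- bg$planted$insertion_pos[1]
  pe <- ps + bg$planted$length[1]
  ov <- min(pe, hits$nuclear_end[1]) - max(ps, hits$nuclear_start[1])
  expect_gte(ov / (pe - ps), 0.9)
  expect_gte(ov / (hits$nuclear_end[1] - hits$nuclear_start[1]), 0.9)
  expect_equal(hits$strand[1], bg$planted$strand[1])
  # mito interval agrees with the planted source
  expect_lt(abs(hits$mito_start[1] - bg$planted$mito_start[1]), 40)
})

test_that("a clean random background yields no hits at the cutoff", {
  gm <- fx_mitogenome()
  bg <- plant_numts(200000, gm$genome, n = 0, seed = 42)
  hits <- numt_search(gm$genome, bg)
  expect_equal(nrow(hits), 0L)
})

test_that("lowering the e-value cutoff never increases the hit count", {
  gm <- fx_mitogenome()
  bg <- plant_numts(100000, gm$genome, n = 4, length_range = c(150, 600),
                    identity_range = c(0.7, 0.95), seed = 3,
                    measure_identity = FALSE)
  n_prev <- Inf
  for (e in c(1e-2, 1e-4, 1e-20, 1e-60)) {
    n <- nrow(numt_search(gm$genome, bg, numt_config(evalue_max = e)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("identity threshold calibration matches planted divergence", {
  gm <- fx_mitogenome()
  part <- subseq_circular(gm$genome, 0, 4000)
  # identical sequences: 100%
  expect_equal(calibrate_identity_threshold(c(part, part)), 100)
  # two sequences at planted 95% identity: within 1 point
  withr::with_seed(19, {
    mut <- mitoforge:::substitute_bases(part, round(0.05 * nchar(part)))
  })
  thr <- calibrate_identity_threshold(c(part, mut))
  expect_lt(abs(thr - 95), 1)
  expect_error(calibrate_identity_threshold(part), "two")
})

test_that("filtering discards over-threshold hits and collapses duplicates", {
  h <- tibble::tibble(
    nuclear_id = "n", nuclear_start = c(10L, 10L, 500L, 900L),
    nuclear_end = c(200L, 200L, 700L, 1200L),
    mito_start = c(0L, 0L, 3000L, 5000L), mito_end = c(190L, 190L, 3200L, 5300L),
    strand = c("+", "+", "-", "+"), aligned_length = c(190L, 190L, 200L, 300L),
    identity = c(90, 90, 98, 85), evalue = rep(1e-10, 4), score = c(100L, 100L, 300L, 200L))
  out <- filter_and_dedupe(h, 96.8)
  # the 98% hit is discarded (above the calibrated ceiling); the duplicate collapses
  expect_equal(nrow(out), 2L)
  expect_true(all(out$identity <= 96.8))
  # brute-force oracle: set comprehension over the hit list
  oracle <- unique(h[h$identity <= 96.8, ])
  expect_equal(nrow(out), nrow(oracle))
  # output is a subset of input and filtering is idempotent
  expect_identical(filter_and_dedupe(out, 96.8), out)
})

test_that("NUMT summaries reproduce hand-computed statistics", {
  mk <- function(lens) tibble::tibble(
    nuclear_id = "n", nuclear_start = cumsum(c(0L, utils::head(lens, -1) + 50L)),
    nuclear_end = cumsum(c(0L, utils::head(lens, -1) + 50L)) + lens,
    mito_start = 0L, mito_end = lens, strand = "+", aligned_length = lens,
    identity = 80, evalue = 1e-10, score = lens)
  rep1 <- summarize_numts(mk(c(100L, 200L, 300L)), 1e6)
  expect_equal(rep1$total_bp, 600L)
  expect_equal(rep1$percent_of_genome, 0.06)
  expect_equal(rep1$mean_length, 200)
  expect_equal(rep1$sd_length, 100)
  expect_equal(rep1$n_over_1000, 0L)
  # empty input: zero counts, not an error
  rep0 <- summarize_numts(mk(integer(0)), 1e6)
  expect_equal(rep0$n_hits, 0L)
  expect_equal(rep0$percent_of_genome, 0)
  # percent is exact to 1e-9 relative error
  rep2 <- summarize_numts(mk(c(123L, 456L, 789L)), 987654321)
  expect_equal(rep2$percent_of_genome, 100 * 1368 / 987654321,
               tolerance = 1e-9)
})
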