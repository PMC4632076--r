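test_that("overlap windows are half-sums of adjacent bins and respect gaps", {
  # 10 contiguous bins with known values -> 9 windows, hand-computed
  df <- tibble::tibble(chrom = "chrT", bin = 1:10,
                       start = (0:9) * 1e5, end = (1:10) * 1e5,
                       z = c(4, 8, 2, 6, 10, 0, 4, 2, 8, 6))
  w <- overlap_bins(df, "z")
  expect_equal(nrow(w), 9)
  expect_equal(w$value, c(6, 5, 4, 8, 5, 2, 3, 5, 7))
  expect_equal(w$start[1], 0.5e5)
  expect_equal(w$end[1], 1.5e5)

  # constant input -> constant windows
  dfc <- dplyr::mutate(df, z = 3)
  expect_true(all(overlap_bins(dfc, "z")$value == 3))

  # a single spiked bin elevates exactly two windows
  dfs <- dplyr::mutate(df, z = ifelse(bin == 5, 12, 0))
  ws <- overlap_bins(dfs, "z")
  expect_equal(sum(ws$value > 0), 2)
  expect_equal(ws$bin_left[ws$value > 0], c(4L, 5L))

  # windows never bridge a gap in the bin grid
  dfg <- df[df$bin != 5, ]
  wg <- overlap_bins(dfg, "z")
  expect_equal(nrow(wg), 7)
  expect_false(any(wg$bin_left == 4 | wg$bin_left == 5))
})

test_that("null signals stay a single segment, steps are recovered near-exactly", {
  # i.i.d. standard normal, 500 windows: one segment in >= 95% of runs
  n_single <- vapply(1:40, function(i) {
    set.seed(400 + i)
    nrow(segment_signal(rnorm(500)))
  }, 0L)
  expect_gte(mean(n_single == 1), 0.95)

  # one step 0 -> +2, noise SD 0.3: breakpoint within +/- 2 windows
  set.seed(41)
  x <- c(rnorm(50, 0, 0.3), rnorm(50, 2, 0.3))
  segs <- segment_signal(x, seed = 1)
  expect_equal(nrow(segs), 2)
  expect_lte(abs(segs$end_idx[1] - 50), 2)

  # two steps (0, +2, 0): both breakpoints recovered
  set.seed(42)
  x2 <- c(rnorm(50, 0, 0.3), rnorm(50, 2, 0.3), rnorm(50, 0, 0.3))
  segs2 <- segment_signal(x2, seed = 1)
  expect_equal(nrow(segs2), 3)
  expect_lte(abs(segs2$end_idx[1] - 50), 2)
  expect_lte(abs(segs2$end_idx[2] - 100), 2)

  # all-equal input: a single segment, no spurious split
  expect_equal(nrow(segment_signal(rep(1.3, 100), seed = 1)), 1)
})

test_that("recovered breakpoints agree with the exhaustive least-squares oracle", {
  # random short signals with 0-2 strong changepoints
  set.seed(43)
  for (case in 1:20) {
    n <- sample(30:60, 1)
    k <- sample(0:2, 1)
    bps <- sort(sample(seq(5, n - 5), k))
    while (k == 2 && diff(bps) < 8) bps <- sort(sample(seq(5, n - 5), 2))
    means <- cumsum(c(0, sample(c(-2, 2), k, replace = TRUE)))
    lv <- rep(means, diff(c(0, bps, n)))
    x <- rnorm(n, lv, 0.3)
    segs <- segment_signal(x, seed = case)
    found <- utils::head(segs$end_idx, -1)
    expect_equal(length(found), k,
                 info = sprintf("case %d: expected %d changepoints", case, k))
    if (k > 0 && length(found) == k) {
      oracle <- oracle_breakpoints(x, k)
      expect_true(all(abs(found - oracle) <= 1),
                  info = sprintf("case %d: oracle mismatch", case))
    }
  }
})

test_that("the undo step merges adjacent segments closer than the threshold", {
  # a weak step well below 4 standard errors must be undone
  set.seed(44)
  x <- c(rnorm(200, 0, 1), rnorm(200, 0.25, 1))
  segs4 <- segment_signal(x, sd_coefficient = 4, seed = 1)
  expect_equal(nrow(segs4), 1)
  # with a tiny coefficient the same split survives (if detected at all)
  segs0 <- segment_signal(x, sd_coefficient = 0.5, seed = 1)
  expect_gte(nrow(segs0), nrow(segs4))
})

test_that("non-finite windows are excluded before segmentation", {
  set.seed(45)
  x <- rnorm(100)
  x[c(10, 20)] <- NaN
  expect_warning(segs <- segment_signal(x), "non-finite")
  expect_equal(sum(segs$n), 98)
})

test_that("maternal CNVs are called with accurate size and copy number", {
  g <- test_genome()
  panel <- test_panel()

  run_sample <- function(params, chroms) {
    s <- prepare_sample(simulate_sample(g, params), g)
    windows <- overlap_bins(bin_zscores(s, panel), "z")
    segment_windows(windows, chroms = chroms, seed = 7)
  }

  # 2 Mb dup cn=3 at f=0.10: one call, size within 0.2 Mb, cn 3
  cnv <- place_cnv(g, "chr21", size_mb = 2, cn = 3)
  segs <- run_sample(sim_params(fetal_fraction = 0.10, maternal_cnvs = cnv,
                                total_reads = test_reads, seed = 46),
                     "chr21")
  calls <- call_maternal_cnvs(segs, panel)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$size_mb, 2, tolerance = 0.11)
  expect_equal(calls$cn, 3L)
  expect_equal(calls$direction, "dup")
  expect_lte(abs(calls$start - cnv$start_mb * 1e6), 1.5e5)

  # deletion: 1.5 Mb cn=1
  del <- place_cnv(g, "chr18", size_mb = 1.5, cn = 1)
  segs <- run_sample(sim_params(fetal_fraction = 0.10, maternal_cnvs = del,
                                total_reads = test_reads, seed = 47),
                     "chr18")
  calls <- call_maternal_cnvs(segs, panel)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$cn, 1L)
  expect_equal(calls$direction, "del")

  # 0.2 Mb dup: below the 300 kb rule, no call
  tiny <- place_cnv(g, "chr21", size_mb = 0.2, cn = 3)
  segs <- run_sample(sim_params(fetal_fraction = 0.10, maternal_cnvs = tiny,
                                total_reads = test_reads, seed = 48),
                     "chr21")
  expect_equal(nrow(call_maternal_cnvs(segs, panel)), 0)
})

test_that("euploid CNV-free samples rarely produce calls", {
  g <- test_genome()
  panel <- test_panel()
  n_calls <- vapply(1:20, function(i) {
    s <- prepare_sample(simulate_sample(
      g, sim_params(fetal_fraction = 0.1, total_reads = test_reads,
                    seed = 500 + i)), g)
    windows <- overlap_bins(bin_zscores(s, panel), "z")
    segs <- segment_windows(windows,
                            chroms = c("chr13", "chr18", "chr21"), seed = i)
    nrow(call_maternal_cnvs(segs, panel))
  }, 0L)
  expect_gte(mean(n_calls == 0), 0.95)
})

test_that("a whole-chromosome trisomy shift is not mistaken for a maternal CNV", {
  g <- test_genome()
  panel <- test_panel()
  s <- prepare_sample(simulate_sample(
    g, sim_params(fetal_fraction = 0.15, trisomy_chrom = "chr21",
                  fetus_sex = "male", total_reads = test_reads, seed = 49)), g)
  windows <- overlap_bins(bin_zscores(s, panel), "z")
  segs <- segment_windows(windows, chroms = "chr21", seed = 7)
  calls <- call_maternal_cnvs(segs, panel)
  # the uniform f/2 shift rounds back to cn = 2 and is dropped
  expect_equal(nrow(calls), 0)
})
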