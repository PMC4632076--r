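# A 2 Mb single-chromosome genome (20 bins, central 20% gap -> bins 9-12
# invalid) and a hand-constructed SAM file exercising the retention policy.
sam_genome <- function() {
  make_genome_fixture(c(chrT = 2, chrX = 1), gap_fraction = c(chrT = 0.2, chrX = 0),
                      seed = 21)
}

write_sam_fixture <- function(path) {
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:2000000",
    "@SQ\tSN:chrX\tLN:1000000",
    # three reads in chrT bin 1 ([0, 100000))
    "r01\t0\tchrT\t1\t60\t35M\t*\t0\t0\t*\t*",
    "r02\t0\tchrT\t500\t60\t35M\t*\t0\t0\t*\t*",
    "r03\t16\tchrT\t99966\t60\t35M\t*\t0\t0\t*\t*",
    # boundary: 1-based pos 100001 = 0-based 100000 -> bin 2, half-open
    "r04\t0\tchrT\t100001\t60\t35M\t*\t0\t0\t*\t*",
    # two more in bin 2
    "r05\t0\tchrT\t150000\t60\t35M\t*\t0\t0\t*\t*",
    "r06\t16\tchrT\t199000\t60\t35M\t*\t0\t0\t*\t*",
    # bin 20
    "r07\t0\tchrT\t1950001\t60\t35M\t*\t0\t0\t*\t*",
    # chrX bin 1
    "r08\t0\tchrX\t5000\t60\t35M\t*\t0\t0\t*\t*",
    # read in the central gap (bin 9 of chrT, invalid) -> discarded
    "r09\t0\tchrT\t850001\t60\t35M\t*\t0\t0\t*\t*",
    # low mapping quality -> not counted
    "r10\t0\tchrT\t600001\t10\t35M\t*\t0\t0\t*\t*",
    # secondary alignment flag (256) -> not counted
    "r11\t256\tchrT\t600001\t60\t35M\t*\t0\t0\t*\t*",
    # duplicate flag (1024) -> not counted
    "r12\t1024\tchrT\t600001\t60\t35M\t*\t0\t0\t*\t*"
  )
  writeLines(sam, path)
  path
}

test_that("read counting honours the unique-read policy and bin conventions", {
  skip_if_not_installed("Rsamtools")
  g <- sam_genome()
  sam <- write_sam_fixture(withr::local_tempfile(fileext = ".sam"))
  counts <- count_reads_in_bins(sam, g)

  expect_equal(counts$raw_count[counts$chrom == "chrT" & counts$bin == 1], 3)
  expect_equal(counts$raw_count[counts$chrom == "chrT" & counts$bin == 2], 3)
  expect_equal(counts$raw_count[counts$chrom == "chrT" & counts$bin == 20], 1)
  expect_equal(counts$raw_count[counts$chrom == "chrX" & counts$bin == 1], 1)
  # low-mapq, secondary and duplicate reads all fell in chrT bin 7
  expect_equal(counts$raw_count[counts$chrom == "chrT" & counts$bin == 7], 0)
  # gap bins are absent from the result and their reads discarded
  expect_false(any(counts$bin %in% 9:12 & counts$chrom == "chrT"))
  expect_equal(sum(counts$raw_count), 8)
})

test_that("reads on unknown contigs are skipped with a warning", {
  skip_if_not_installed("Rsamtools")
  g <- sam_genome()
  path <- withr::local_tempfile(fileext = ".sam")
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chrT\tLN:2000000",
    "@SQ\tSN:chrX\tLN:1000000",
    "@SQ\tSN:chrUn\tLN:1000000",
    "r1\t0\tchrT\t1\t60\t35M\t*\t0\t0\t*\t*",
    "r2\t0\tchrUn\t5\t60\t35M\t*\t0\t0\t*\t*"
  )
  writeLines(sam, path)
  expect_warning(counts <- count_reads_in_bins(path, g), "chrUn")
  expect_equal(sum(counts$raw_count), 1)
})

test_that("GC correction is the identity on unbiased counts and flattens injected bias", {
  g <- test_genome()
  # no GC dependence: corrected approximately equals raw, bin by bin
  flat <- simulate_sample(
    g, sim_params(fetal_fraction = 0, total_reads = test_reads,
                  gc_bias_amplitude = 0, seed = 22))
  cg <- correct_gc(flat, g)
  ratio <- cg$corrected_count[flat$raw_count > 0] /
    cg$raw_count[flat$raw_count > 0]
  expect_lt(max(abs(ratio - 1)), 0.01 + 3 / sqrt(min(flat$raw_count[flat$raw_count > 0])))
  expect_lt(abs(sum(cg$corrected_count) / sum(cg$raw_count) - 1), 0.1)

  # injected quadratic bias: the count-GC dependence (regression on the
  # bias curve, which carries the signal; the purely linear gc term is
  # weak because the curve is nearly symmetric about the GC mean)
  # shrinks by >= 90% after correction
  biased <- simulate_sample(
    g, sim_params(fetal_fraction = 0, total_reads = test_reads, seed = 23))
  cb <- correct_gc(biased, g)
  gc <- g$gc[g$valid]
  bias <- gc_bias_multiplier(gc)
  slope_before <- stats::coef(stats::lm(biased$raw_count ~ bias))[2]
  slope_after <- stats::coef(stats::lm(cb$corrected_count ~ bias))[2]
  expect_lt(abs(slope_after), 0.1 * abs(slope_before))

  # re-applying the fit changes corrected counts by < 1%
  cb2 <- correct_gc(cb, g, recorrect = TRUE)
  expect_lt(max(abs(cb2$corrected_count / cb$corrected_count - 1)), 0.01)
})

test_that("mappability correction divides counts and is a no-op at mappability 1", {
  g <- test_genome()
  s <- simulate_sample(g, sim_params(fetal_fraction = 0,
                                     total_reads = test_reads, seed = 24))
  s$corrected_count <- as.numeric(s$raw_count)

  g1 <- g
  g1$mappability[g1$valid] <- 1
  expect_equal(correct_mappability(s, g1)$corrected_count,
               as.numeric(s$raw_count))

  g2 <- g
  g2$mappability[g2$valid] <- 0.5
  expect_equal(correct_mappability(s, g2)$corrected_count,
               2 * as.numeric(s$raw_count))
})

test_that("mappability correction removes coverage dips", {
  # same Poisson draws with and without a mappability dip on one chromosome:
  # corrected chromosome coverage must agree within 0.5%
  g <- make_genome_fixture(c(chrA = 60, chrB = 60, chrX = 20),
                           gap_fraction = 0, seed = 25)
  g_dip <- g
  dip_bins <- g_dip$valid & g_dip$chrom == "chrA" & g_dip$bin <= 200
  g_dip$mappability[dip_bins] <- g_dip$mappability[dip_bins] * 0.6

  p <- sim_params(fetal_fraction = 0, total_reads = test_reads, seed = 26)
  cov <- chromosome_coverage(prepare_sample(simulate_sample(g, p), g), g)
  cov_dip <- chromosome_coverage(prepare_sample(simulate_sample(g_dip, p), g_dip),
                                 g_dip)
  expect_lt(abs(cov_dip$proportion[cov_dip$chrom == "chrA"] /
                  cov$proportion[cov$chrom == "chrA"] - 1), 0.005)
})

test_that("bin Z-scores are calibrated against the panel", {
  g <- test_genome()
  panel <- test_panel()

  # held-out euploid sample: approximately standard normal, light tails
  s <- prepare_sample(simulate_sample(
    g, sim_params(fetal_fraction = 0, total_reads = test_reads, seed = 27)), g)
  z <- bin_zscores(s, panel)
  expect_lt(abs(mean(z$z)), 0.1)
  expect_gt(stats::sd(z$z), 0.8)
  expect_lt(stats::sd(z$z), 1.2)
  expect_lt(mean(abs(z$z) > 4), 0.01)

  # a maternal dup cn=3 region shifts bin Z by ~0.5 / (per-bin CV)
  cnv <- place_cnv(g, "chr13", size_mb = 5, cn = 3)
  sd_ <- prepare_sample(simulate_sample(
    g, sim_params(fetal_fraction = 0, maternal_cnvs = cnv,
                  total_reads = test_reads, seed = 28)), g)
  zd <- bin_zscores(sd_, panel)
  in_cnv <- zd$chrom == "chr13" & zd$start >= cnv$start_mb * 1e6 &
    zd$end <= (cnv$start_mb + 5) * 1e6
  cv <- with(panel$bins[in_cnv, ], mean(sd / mean))
  expect_gt(mean(zd$z[in_cnv]), 0)
  expect_equal(mean(zd$z[in_cnv]), 0.5 / cv, tolerance = 0.25)
})

test_that("bin value equal to the panel mean gives Z = 0", {
  panel <- test_panel()
  s <- test_panel()$bins
  fake <- tibble::tibble(chrom = s$chrom, bin = s$bin, start = s$start,
                         end = s$end, corrected_count = s$mean)
  z <- bin_zscores(fake, panel)
  expect_equal(max(abs(z$z)), 0, tolerance = 1e-9)
})

test_that("chromosome coverage proportions sum to one and follow dosage", {
  g <- test_genome()
  # equal counts -> proportions proportional to valid bin counts
  gv <- g[g$valid, ]
  eq <- tibble::tibble(chrom = gv$chrom, bin = gv$bin, start = gv$start,
                       end = gv$end, raw_count = 7L)
  cov <- chromosome_coverage(eq, g)
  expect_equal(sum(cov$proportion), 1, tolerance = 1e-9)
  nb <- table(gv$chrom)
  expect_equal(cov$proportion,
               as.numeric(nb[cov$chrom]) / sum(nb), tolerance = 1e-12)

  # counts on one chromosome only -> proportion 1
  one <- eq
  one$raw_count <- ifelse(one$chrom == "chr21", 5L, 0L)
  cov1 <- chromosome_coverage(one, g)
  expect_equal(cov1$proportion[cov1$chrom == "chr21"], 1)

  # simulated trisomy at f = 0.10: proportion inflated ~1.05x over panel
  panel <- test_panel()
  reps <- vapply(1:30, function(i) {
    s <- prepare_sample(simulate_sample(
      g, sim_params(fetal_fraction = 0.10, trisomy_chrom = "chr21",
                    total_reads = test_reads, seed = 3000 + i)), g)
    cc <- chromosome_coverage(s, g)
    auto <- cc[cc$chrom %in% autosomes(g), ]
    auto$coverage[auto$chrom == "chr21"] / sum(auto$coverage)
  }, 0)
  pm <- panel$chromosomes$mean[panel$chromosomes$chrom == "chr21"]
  w <- pm  # trisomy also inflates the autosomal total by w * f/2
  expected_ratio <- 1.05 / (1 + w * 0.05)
  expect_equal(mean(reps) / pm, expected_ratio, tolerance = 0.003)
})
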