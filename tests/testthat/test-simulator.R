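fixture_genome <- function() {
  make_genome_fixture(c(chrA = 40, chrB = 75, chrC = 100, chrX = 155),
                      gap_fraction = 0.05, seed = 11)
}

test_that("expected dosage reflects fetal sex, trisomy and maternal CNVs", {
  g <- fixture_genome()

  # male fetus: chrX carries (1 - f) + f/2 of the autosomal dosage
  er <- expected_bin_rates(g, sim_params(fetal_fraction = 0.10,
                                         fetus_sex = "male"))
  expect_equal(unique(er$dosage[er$chrom == "chrX"]), 0.95)
  expect_equal(unique(er$dosage[er$chrom == "chrA"]), 1)

  # fetal trisomy: 1 + f/2 on the trisomic chromosome
  er <- expected_bin_rates(g, sim_params(fetal_fraction = 0.10,
                                         trisomy_chrom = "chrB"))
  expect_equal(unique(er$dosage[er$chrom == "chrB"]), 1.05)

  # non-inherited maternal dup cn=3: (1 - f) * 3/2 + f inside the CNV
  cnv <- place_cnv(g, "chrA", size_mb = 2, cn = 3)
  er <- expected_bin_rates(g, sim_params(fetal_fraction = 0.10,
                                         maternal_cnvs = cnv))
  in_cnv <- er$chrom == "chrA" &
    er$start >= cnv$start_mb * 1e6 & er$end <= (cnv$start_mb + 2) * 1e6
  expect_equal(unique(er$dosage[in_cnv]), 0.9 * 1.5 + 0.1)
  expect_equal(unique(er$dosage[er$chrom == "chrA" & !in_cnv]), 1)

  # inherited CNV: both compartments carry cn, dosage is cn/2
  cnv_inh <- place_cnv(g, "chrA", size_mb = 2, cn = 3, inherited = TRUE)
  er <- expected_bin_rates(g, sim_params(fetal_fraction = 0.10,
                                         maternal_cnvs = cnv_inh))
  in_cnv <- er$chrom == "chrA" &
    er$start >= cnv$start_mb * 1e6 & er$end <= (cnv$start_mb + 2) * 1e6
  expect_equal(unique(er$dosage[in_cnv]), 1.5)
})

test_that("expected rates conserve total reads and are dosage-linear", {
  g <- fixture_genome()
  # euploid female, f = 0: baseline sums exactly to total_reads
  er <- expected_bin_rates(g, sim_params(fetal_fraction = 0,
                                         total_reads = 1e6))
  expect_equal(sum(er$lambda), 1e6)

  # doubling (cn - 2) doubles the expected excess of the CNV region
  excess_for <- function(cn) {
    cnv <- place_cnv(g, "chrA", size_mb = 3, cn = cn)
    er <- expected_bin_rates(g, sim_params(fetal_fraction = 0.10,
                                           maternal_cnvs = cnv,
                                           total_reads = 1e6))
    er0 <- expected_bin_rates(g, sim_params(fetal_fraction = 0.10,
                                            total_reads = 1e6))
    sum(er$lambda[er$chrom == "chrA"]) - sum(er0$lambda[er0$chrom == "chrA"])
  }
  expect_equal(excess_for(4), 2 * excess_for(3), tolerance = 1e-12)

  # inherited CNVs shift coverage strictly more than non-inherited at f > 0
  shift_for <- function(inherited) {
    cnv <- place_cnv(g, "chrA", size_mb = 3, cn = 3, inherited = inherited)
    er <- expected_bin_rates(g, sim_params(fetal_fraction = 0.15,
                                           maternal_cnvs = cnv,
                                           total_reads = 1e6))
    sum(er$lambda[er$chrom == "chrA"])
  }
  expect_gt(shift_for(TRUE), shift_for(FALSE))
})

test_that("simulation is deterministic under a fixed seed", {
  g <- fixture_genome()
  p <- sim_params(fetal_fraction = 0.1, total_reads = 1e5, seed = 42)
  expect_identical(simulate_sample(g, p), simulate_sample(g, p))

  pan1 <- simulate_reference_panel(g, 3, total_reads = 1e5, seed = 7)
  pan2 <- simulate_reference_panel(g, 3, total_reads = 1e5, seed = 7)
  expect_identical(pan1, pan2)
  expect_length(pan1, 3)
  # each panel sample lands near its expected depth
  expect_true(all(abs(vapply(pan1, function(s) sum(s$raw_count), 0) - 1e5) <
                    5 * sqrt(1e5)))
})

test_that("empirical total counts match the configured depth", {
  g <- make_genome_fixture(c(chrA = 40, chrX = 20), gap_fraction = 0,
                           seed = 12)
  sums <- vapply(1:50, function(i) {
    p <- sim_params(fetal_fraction = 0, total_reads = 1e6, seed = 1000 + i)
    sum(simulate_sample(g, p)$raw_count)
  }, 0)
  expect_lt(abs(mean(sums) - 1e6), 5 * sqrt(1e6 / 50))
})

test_that("a 2 Mb non-inherited dup shifts chromosome coverage by the analytic ratio", {
  g <- fixture_genome()  # chrA valid length 38 Mb
  reps <- alpha_effect_sizes(g, chrom = "chrA", sizes_mb = 2, f = 0.10,
                             cn = 3, replicates = 200, total_reads = 1e6,
                             seed = 13)
  expect_equal(nrow(reps), 200)
  # alpha = 1 + 0.9 * 2 / (2 * 38)
  expect_equal(unique(reps$alpha), 1 + 0.9 * 2 / 76, tolerance = 1e-12)
  expect_equal(mean(reps$ratio), 1 + 0.9 * 2 / 76, tolerance = 2e-3)
})

test_that("panel per-bin means converge to the Poisson rates", {
  g <- make_genome_fixture(c(chrA = 40, chrX = 20), gap_fraction = 0.05,
                           seed = 14)
  n <- 500
  lam <- expected_bin_rates(
    g, sim_params(fetal_fraction = 0, total_reads = 2e5)
  )$lambda
  panel <- simulate_reference_panel(g, n, total_reads = 2e5, seed = 15)
  mat <- vapply(panel, function(s) as.numeric(s$raw_count),
                numeric(length(lam)))
  dev <- abs(rowMeans(mat) - lam)
  expect_gte(mean(dev <= 3 * sqrt(lam / n)), 0.99)
})

test_that("simulation parameters are validated", {
  g <- fixture_genome()
  expect_error(sim_params(fetal_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(maternal_cnvs = maternal_cnv("chrA", 5, 2, cn = 2)),
               "cn")
  expect_error(
    sim_params(trisomy_chrom = "chrA",
               maternal_cnvs = maternal_cnv("chrA", 5, 2, cn = 3)),
    "allow_cnv_on_trisomy"
  )
  expect_no_error(
    sim_params(trisomy_chrom = "chrA",
               maternal_cnvs = maternal_cnv("chrA", 5, 2, cn = 3),
               allow_cnv_on_trisomy = TRUE)
  )
  expect_error(simulate_reference_panel(g, 1), "at least 2")
  # CNV spanning the central gap is rejected
  p_gap <- sim_params(maternal_cnvs = maternal_cnv("chrA", 18, 6, cn = 3))
  expect_error(expected_bin_rates(g, p_gap), "valid bins")
})

test_that("the study grid enumerates the full simulation design", {
  grid <- simulation_grid()
  expect_equal(nrow(grid), 3 * 2 * 19 * 3)
  expect_setequal(unique(grid$cn), c(3L, 1L))
  expect_equal(range(grid$size_mb), c(0.5, 5))
  expect_equal(sort(unique(grid$f)), c(0.05, 0.10, 0.15))
  expect_equal(nrow(dplyr::distinct(grid)), nrow(grid))
})
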