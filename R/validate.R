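#' Paired-simulation check of the coverage coefficient
#'
#' For each CNV size, simulates pairs of plasma samples that differ only in
#' the presence of the maternal CNV and compares the empirical
#' chromosome-coverage ratio (with-CNV over without-CNV) against the
#' analytic coefficient computed from the truth parameters. Only the
#' affected chromosome's bins are drawn (other chromosomes cancel from the
#' ratio), from the same per-bin Poisson rates [simulate_sample()] uses.
#' Coverage is computed on bias-corrected counts, dividing each bin by
#' the simulator's known relative efficiency (the product of mappability
#' and GC bias) in place of re-estimating it with LOWESS: the experiment
#' probes the dosage model, and the coefficient relates *length* shares,
#' which raw efficiency-weighted sums would distort by each chromosome's
#' realised efficiency profile.
#'
#' The two arms of a pair share their baseline draws (common random
#' numbers): the with-CNV arm adds an independent Poisson increment on the
#' duplicated bins, or binomially thins the deleted ones, so each arm is
#' still exactly Poisson with its own rates while the pair difference
#' carries only the CNV signal.
#'
#' @param genome A `nipt_genome` tibble.
#' @param chrom Chromosome carrying the CNV.
#' @param sizes_mb CNV sizes in Mb.
#' @param f Fetal fraction.
#' @param cn CNV copy number.
#' @param inherited Is the CNV inherited by the fetus?
#' @param replicates Paired replicates per size. The CNV position is drawn
#'   uniformly over the chromosome's contiguous valid runs for every
#'   replicate, so local GC/mappability structure averages out instead of
#'   biasing one placement.
#' @param total_reads Expected reads per sample.
#' @param seed Master seed.
#' @return Replicate-level tibble with `chrom`, `size_mb`, `f`, `cn`,
#'   `replicate`, `alpha` (truth), `ratio` (empirical), `deviation`.
#' @seealso [summarize_alpha_effect()]
#' @export
alpha_effect_sizes <- function(genome, chrom = "chr21",
                               sizes_mb = seq(0.5, 5, by = 0.25),
                               f = 0.10, cn = 3, inherited = FALSE,
                               replicates = 50, total_reads = 7.5e6,
                               seed = 1L) {
  m <- valid_length_mb(genome)
  m <- m$m_mb[m$chrom == chrom]
  bs <- attr(genome, "bin_size")

  p0 <- sim_params(fetal_fraction = f, fetus_sex = "male",
                   total_reads = total_reads)
  er <- expected_bin_rates(genome, p0)
  er <- er[er$chrom == chrom, ]
  lam0 <- er$lambda
  runs <- split(seq_along(er$bin), cumsum(c(1, diff(er$bin) != 1L)))

  # CNV dosage multiplier relative to the euploid baseline (dosage 1)
  d_cnv <- if (inherited) cn / 2 else f + (1 - f) * cn / 2

  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(sizes_mb) * replicates),
                  nrow = length(sizes_mb))

  purrr::imap_dfr(sizes_mb, function(n, i) {
    nb <- as.integer(round(n * 1e6 / bs))
    feasible <- purrr::keep(runs, ~ length(.x) >= nb)
    if (length(feasible) == 0) {
      rlang::abort(sprintf("no valid run on %s can hold a %.2f Mb CNV",
                           chrom, n))
    }
    n_starts <- vapply(feasible, function(r) length(r) - nb + 1L, 0L)
    a <- if (inherited) alpha_inherited(m, n, cn) else alpha_not_inherited(m, n, cn, f)
    purrr::map_dfr(seq_len(replicates), function(r) {
      set.seed(seeds[i, r])
      # uniform start over all feasible positions
      pick <- sample.int(sum(n_starts), 1)
      run_id <- findInterval(pick - 1L, cumsum(c(0L, n_starts))[-1]) + 1L
      offset <- pick - c(0L, cumsum(n_starts))[run_id]
      sel <- feasible[[run_id]][offset:(offset + nb - 1L)]

      cnt0 <- stats::rpois(length(lam0), lam0)
      cnt1 <- cnt0
      if (d_cnv > 1) {
        cnt1[sel] <- cnt0[sel] + stats::rpois(nb, lam0[sel] * (d_cnv - 1))
      } else if (d_cnv < 1) {
        cnt1[sel] <- stats::rbinom(nb, cnt0[sel], d_cnv)
      }
      # bias-corrected coverage: divide by the known per-bin efficiency
      ratio <- sum(cnt1 / er$base) / sum(cnt0 / er$base)
      tibble::tibble(chrom = chrom, size_mb = n, f = f, cn = cn,
                     replicate = r, alpha = a, ratio = ratio,
                     deviation = ratio - a)
    })
  })
}

#' Summarise an alpha-effect experiment per grid cell
#'
#' Collapses the replicate-level output of [alpha_effect_sizes()] to one
#' row per cell with the empirical mean ratio and the Shapiro-Wilk
#' P-value of the deviations (testing that the coefficient differs from
#' the real effect only by symmetric sampling noise).
#'
#' @param reps Output of [alpha_effect_sizes()] (possibly row-bound over
#'   several fractions/chromosomes).
#' @return Tibble with one row per `(chrom, size_mb, f, cn)` cell:
#'   `alpha`, `mean_ratio`, `shapiro_p`, `n`.
#' @export
summarize_alpha_effect <- function(reps) {
  reps |>
    dplyr::group_by(.data$chrom, .data$size_mb, .data$f, .data$cn) |>
    dplyr::summarise(
      alpha = .data$alpha[1],
      mean_ratio = mean(.data$ratio),
      shapiro_p = stats::shapiro.test(.data$deviation)$p.value,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Z-scores of simulated euploid samples across a maternal-CNV grid
#'
#' Runs the screening pipeline on simulated male-fetus euploid samples
#' carrying the maternal CNV of each grid cell and records the raw and
#' adjusted Z-score of the affected chromosome. In `"general"` mode the
#' maternal-CNV adjustment is skipped (adjusted equals raw), which is
#' cheap and sufficient when only raw Z-scores are wanted.
#'
#' @param genome A `nipt_genome` tibble.
#' @param panel A `nipt_panel`.
#' @param grid Tibble from [simulation_grid()] (columns `chrom`, `cn`,
#'   `size_mb`, `f`).
#' @param replicates Replicates per cell.
#' @param total_reads Expected reads per sample.
#' @param mode `"full"` (detected-CNV adjustment) or `"general"`.
#' @param seed Master seed.
#' @param offset_mb CNV placement offset.
#' @return Tibble with one row per cell and replicate: grid columns plus
#'   `replicate`, `alpha`, `raw_z`, `adjusted_z`, `call`.
#' @export
grid_zscores <- function(genome, panel, grid, replicates = 3,
                         total_reads = 7.5e6, mode = c("full", "general"),
                         seed = 1L, offset_mb = 5) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             nrow(grid) * replicates), nrow = nrow(grid))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    cnv <- place_cnv(genome, row$chrom, size_mb = row$size_mb, cn = row$cn,
                     offset_mb = offset_mb)
    purrr::map_dfr(seq_len(replicates), function(r) {
      p <- sim_params(fetal_fraction = row$f, fetus_sex = "male",
                      maternal_cnvs = cnv, total_reads = total_reads,
                      seed = seeds[i, r])
      s <- simulate_sample(genome, p)
      rep <- run_pipeline(s, panel, genome, target_chroms = row$chrom,
                          general_mode = (mode == "general"),
                          seed = seeds[i, r])
      zz <- rep$chromosomes[rep$chromosomes$chrom == row$chrom, ]
      dplyr::bind_cols(
        row,
        tibble::tibble(replicate = r, alpha = zz$alpha, raw_z = zz$raw_z,
                       adjusted_z = zz$adjusted_z, call = zz$call)
      )
    })
  })
}
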