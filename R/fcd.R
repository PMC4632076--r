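#' Fetal fraction from chromosome X under-representation
#'
#' For a male fetus the single fetal X depresses chromosome X coverage by
#' half the fetal fraction, so `f = 2 * (1 - xbar)` where `xbar` is the
#' average reads-per-bin on chromosome X normalised to the autosomal
#' average. The estimate is clipped to `[0, 1]`.
#'
#' @param xbar Normalised chromosome X reads-per-bin ratio (must be
#'   positive; values above 1.02 indicate a female fetus or an
#'   uninformative sample and raise an error).
#' @return Fetal fraction estimate.
#' @examples
#' fetal_fraction_from_x(0.95)
#' @export
fetal_fraction_from_x <- function(xbar) {
  if (any(xbar <= 0)) rlang::abort("`xbar` must be positive.")
  if (any(xbar > 1.02)) {
    rlang::abort("chrX not under-represented (xbar > 1.02): female fetus or uninformative sample.")
  }
  pmin(pmax(2 * (1 - xbar), 0), 1)
}

#' Fetal fraction from the aneuploid chromosome's over-representation
#'
#' A fetal trisomy adds half a fetal-fraction's worth of coverage to the
#' affected chromosome, so `f = 2 * (rbar - 1)` where `rbar` is the
#' normalised reads-per-bin ratio of the aneuploid chromosome. Clipped to
#' `[0, 1]`; a ratio below 0.98 for a sample called positive is
#' inconsistent and warns.
#'
#' @param rbar Normalised aneuploid-chromosome reads-per-bin ratio.
#' @return Fetal fraction estimate.
#' @examples
#' fetal_fraction_from_trisomy(1.05)
#' @export
fetal_fraction_from_trisomy <- function(rbar) {
  if (any(rbar < 0.98)) {
    rlang::warn("aneuploid-chromosome ratio below 0.98: inconsistent with a positive call.")
  }
  pmin(pmax(2 * (rbar - 1), 0), 1)
}

#' Normalised reads-per-bin ratio of one chromosome
#'
#' Computes the per-bin coverage ratio of a sample against the panel's
#' per-bin means (cancelling residual GC/mappability structure) and
#' references the target chromosome's average ratio to the average over
#' autosomes, excluding both chromosome X and the target chromosome
#' itself from the reference so the target's own dosage cannot dilute the
#' denominator.
#'
#' @param counts Corrected `nipt_counts` tibble.
#' @param panel A `nipt_panel`.
#' @param genome A `nipt_genome` tibble.
#' @param chrom Chromosome whose ratio is wanted (e.g. `"chrX"` or an
#'   aneuploid autosome).
#' @param exclude Further chromosomes left out of the reference average
#'   (e.g. a possibly trisomic chromosome when normalising chromosome X).
#' @return The normalised reads-per-bin ratio (1 = autosomal average).
#' @export
chromosome_ratio <- function(counts, panel, genome, chrom,
                             exclude = character()) {
  norm <- counts$corrected_count / sum(counts$corrected_count)
  df <- tibble::tibble(chrom = counts$chrom, bin = counts$bin, norm = norm) |>
    dplyr::inner_join(panel$bins[, c("chrom", "bin", "mean")],
                      by = c("chrom", "bin")) |>
    dplyr::mutate(ratio = .data$norm / .data$mean)
  ref_chroms <- setdiff(autosomes(genome), c(chrom, exclude))
  if (length(ref_chroms) == 0) {
    rlang::abort("no reference chromosomes left after exclusions.")
  }
  tgt <- mean(df$ratio[df$chrom == chrom])
  ref <- mean(df$ratio[df$chrom %in% ref_chroms])
  tgt / ref
}

#' Fetal fraction estimates for one sample
#'
#' Convenience wrapper producing both estimates: from chromosome X
#' (male fetus) and, when an aneuploid chromosome is given, from its
#' over-representation.
#'
#' @inheritParams chromosome_ratio
#' @param aneuploid_chrom Aneuploid chromosome name or `NULL`. It is
#'   excluded from the reference average of the chromosome X ratio so that
#'   its own over-representation cannot bias the X estimate.
#' @return Tibble with `f_x` (NA for a female/uninformative sample) and
#'   `f_aneu` (NA when no aneuploid chromosome given).
#' @export
fetal_fractions <- function(counts, panel, genome, aneuploid_chrom = NULL) {
  xc <- x_chromosome(genome)
  f_x <- NA_real_
  if (!is.na(xc)) {
    xbar <- chromosome_ratio(counts, panel, genome, xc,
                             exclude = aneuploid_chrom %||% character())
    f_x <- tryCatch(fetal_fraction_from_x(xbar), error = function(e) NA_real_)
  }
  f_aneu <- NA_real_
  if (!is.null(aneuploid_chrom)) {
    rbar <- chromosome_ratio(counts, panel, genome, aneuploid_chrom)
    f_aneu <- suppressWarnings(fetal_fraction_from_trisomy(rbar))
  }
  tibble::tibble(f_x = f_x, f_aneu = f_aneu)
}

#' Cohort SD of the fetal-fraction difference
#'
#' Among concordant positive samples (male fetus, true trisomy) the two
#' fetal-fraction estimates agree up to sampling noise; the SD of their
#' differences calibrates the discrepancy statistic for new samples.
#'
#' @param positive_cohort Tibble with columns `f_x`, `f_aneu` from
#'   concordant positive samples.
#' @param configured_sd Fallback SD used (with a warning) when fewer than
#'   5 cohort samples are available.
#' @return The SD of `f_x - f_aneu`.
#' @export
estimate_fcd_sd <- function(positive_cohort, configured_sd = NULL) {
  n <- nrow(positive_cohort)
  if (n < 5) {
    if (is.null(configured_sd)) {
      rlang::abort("need at least 5 positive samples, or a configured SD.")
    }
    rlang::warn("fewer than 5 cohort samples; using the configured SD.")
    return(configured_sd)
  }
  s <- stats::sd(positive_cohort$f_x - positive_cohort$f_aneu)
  if (s == 0) {
    rlang::abort("fetal-fraction differences have zero SD; discrepancy scoring disabled.")
  }
  s
}

#' Fetal-concentration discrepancy statistic
#'
#' `z_fetal = (f_x - f_aneu) / sd_fcd`: the standardised disagreement
#' between the two fetal-fraction estimates of a positive male-fetus
#' sample. A concordant trisomy gives values near 0; a positive call
#' driven by something other than a fetal trisomy (e.g. a maternal
#' duplication) inflates `f_x` relative to `f_aneu`. Samples with
#' `|z_fetal| >= threshold` (default 3) are flagged as potential false
#' positives and recommended for karyotyping; the positive call itself is
#' never removed.
#'
#' @param f_x Fetal fraction from chromosome X.
#' @param f_aneu Fetal fraction from the aneuploid chromosome.
#' @param sd_fcd Cohort SD from [estimate_fcd_sd()] (must be positive).
#' @param threshold Flag threshold, default 3.
#' @return Tibble with `z_fetal` and `flagged`.
#' @examples
#' z_fetal(0.122, 0.035, 0.018)
#' @export
z_fetal <- function(f_x, f_aneu, sd_fcd, threshold = 3) {
  if (any(sd_fcd <= 0)) rlang::abort("`sd_fcd` must be positive.")
  z <- (f_x - f_aneu) / sd_fcd
  tibble::tibble(z_fetal = z, flagged = abs(z) >= threshold)
}

#' Mosaicism ratio implied by discordant fetal fractions
#'
#' Under a mosaic-trisomy model the fraction of trisomic fetal cells is
#' the aneuploid-chromosome fetal fraction over the chromosome X (or Y)
#' fetal fraction. Reported as a percentage rounded half-up to one
#' decimal; the euploid complement is `100 - mosaic`.
#'
#' @param f_aneu Fetal fraction from the aneuploid chromosome.
#' @param f_x Fetal fraction from chromosome X (must be positive).
#' @return Mosaic percentage, one decimal.
#' @examples
#' mosaic_ratio(0.035, 0.122)  # 28.7
#' @export
mosaic_ratio <- function(f_aneu, f_x) {
  if (any(f_x <= 0)) rlang::abort("`f_x` must be positive.")
  floor(1000 * f_aneu / f_x + 0.5) / 10
}
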