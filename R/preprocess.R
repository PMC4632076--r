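#' Count uniquely mapped reads into genome bins
#'
#' Reads a SAM/BAM file and counts retained alignments into the genome
#' model's bins, keyed by the leftmost aligned base (0-based half-open
#' convention: a read starting exactly at a bin boundary belongs to the bin
#' that starts there). "Uniquely mapped" is operationalised as primary,
#' non-duplicate, non-secondary alignments with mapping quality at least
#' `min_mapq`. Reads falling in gap (invalid) bins are discarded; reads on
#' contigs absent from the genome model are skipped and counted in a
#' warning.
#'
#' @param path Path to a SAM or BAM file (SAM is converted on the fly;
#'   requires the Rsamtools package).
#' @param genome A `nipt_genome` tibble.
#' @param min_mapq Minimum mapping quality (default 30).
#' @return A `nipt_counts` tibble over valid bins with `raw_count`.
#' @export
count_reads_in_bins <- function(path, genome, min_mapq = 30) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    rlang::abort("count_reads_in_bins() requires the Rsamtools package.")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos", "mapq"))
  aln <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(aln$pos) & !is.na(aln$mapq) & aln$mapq >= min_mapq
  rname <- as.character(aln$rname)[keep]
  pos0 <- aln$pos[keep] - 1L  # SAM is 1-based; bins are 0-based half-open

  known <- rname %in% unique(genome$chrom)
  if (any(!known)) {
    rlang::warn(sprintf("%d read(s) on unknown contig(s) skipped: %s",
                        sum(!known),
                        paste(unique(rname[!known]), collapse = ", ")))
  }
  rname <- rname[known]
  pos0 <- pos0[known]
  if (length(pos0) == 0) {
    rlang::warn("no reads retained; returning all-zero counts.")
  }

  bs <- attr(genome, "bin_size")
  key <- paste(rname, floor(pos0 / bs) + 1L)
  tab <- table(key)

  g <- genome[genome$valid, ]
  counts <- tibble::tibble(
    chrom = g$chrom, bin = g$bin, start = g$start, end = g$end,
    raw_count = as.integer(tab[paste(g$chrom, g$bin)])
  )
  counts$raw_count[is.na(counts$raw_count)] <- 0L
  new_nipt_counts(counts, sample_id = basename(path),
                  total_reads = length(pos0))
}

#' GC-bias correction of bin counts by LOWESS
#'
#' Fits a LOWESS curve of raw count on GC fraction over valid bins and
#' rescales each bin by `median(raw) / fit(gc)`, flattening the
#' count-versus-GC relationship while preserving overall scale. The curve
#' is built in two backfitting passes (the second smooths the residual
#' ratio, removing the curvature a single locally-linear pass leaves where
#' the bias is steep) and is evaluated on the central 98% of the GC
#' distribution, held constant beyond it, where data are too sparse for a
#' stable local fit. If the fitted curve is non-positive anywhere it is
#' replaced there by the nearest positive fitted value, with a warning.
#'
#' @param counts A `nipt_counts` tibble (needs `raw_count`; re-corrects
#'   `corrected_count` instead when `recorrect = TRUE`).
#' @param genome A `nipt_genome` tibble supplying per-bin GC.
#' @param span LOWESS smoother span (default 0.3).
#' @param iterations Robustness iterations (default 1).
#' @param recorrect Apply the fit to an existing `corrected_count` column
#'   (used to check idempotence). Default `FALSE`.
#' @return The counts tibble with a `corrected_count` column.
#' @export
correct_gc <- function(counts, genome, span = 0.3, iterations = 1,
                       recorrect = FALSE) {
  if (nrow(counts) < 100) rlang::abort("need at least 100 bins for a GC fit.")
  g <- genome[genome$valid, c("chrom", "bin", "gc")]
  df <- dplyr::inner_join(counts, g, by = c("chrom", "bin"))
  if (nrow(df) != nrow(counts)) {
    rlang::abort("counts and genome bin grids do not match.")
  }
  y <- if (recorrect) df$corrected_count else df$raw_count
  # evaluate on the central 98% of the GC distribution and hold the curve
  # constant beyond it: the local fit is unstable where GC data are sparse
  qr <- stats::quantile(df$gc, c(0.01, 0.99))
  xout <- pmin(pmax(df$gc, qr[1]), qr[2])
  # two backfitting passes: the second smooth of the residual ratio mops up
  # the curvature a single locally-linear pass leaves in steep GC tails
  yhat <- rep(1, nrow(df))
  for (pass in 1:2) {
    fit <- stats::lowess(df$gc, y / yhat, f = span, iter = iterations)
    step <- stats::approx(fit$x, fit$y, xout = xout, rule = 2,
                          ties = "ordered")$y
    if (any(step <= 0)) {
      if (!any(step > 0)) rlang::abort("GC fit is non-positive everywhere.")
      rlang::warn("non-positive GC fit at some bins; substituting nearest positive fitted value.")
      step <- nearest_positive(step, df$gc)
    }
    yhat <- yhat * step
  }
  out <- counts
  out$corrected_count <- y * stats::median(y) / yhat
  out
}

# replace non-positive fitted values by the nearest (in x) positive one
nearest_positive <- function(vals, x) {
  ord <- order(x)
  vo <- vals[ord]
  good <- which(vo > 0)
  prev <- findInterval(seq_along(vo), good)
  prev[prev == 0] <- 1L
  vo[vo <= 0] <- vo[good[prev]][vo <= 0]
  vals[ord] <- vo
  vals
}

#' Mappability correction of bin counts
#'
#' Divides each bin's corrected count by its mappability, restoring the
#' reads lost to non-unique alignment. Bins with non-positive mappability
#' are dropped (marked invalid downstream).
#'
#' @param counts A `nipt_counts` tibble with `corrected_count` (falls back
#'   to `raw_count` when absent).
#' @param genome A `nipt_genome` tibble supplying per-bin mappability.
#' @return The counts tibble with `corrected_count` divided by mappability.
#' @export
correct_mappability <- function(counts, genome) {
  g <- genome[genome$valid, c("chrom", "bin", "mappability")]
  df <- dplyr::inner_join(counts, g, by = c("chrom", "bin"))
  if (nrow(df) != nrow(counts)) {
    rlang::abort("counts and genome bin grids do not match.")
  }
  base <- df[["corrected_count"]] %||% df$raw_count
  bad <- !(df$mappability > 0)
  if (any(bad)) {
    rlang::warn(sprintf("%d bin(s) with non-positive mappability dropped.", sum(bad)))
  }
  out <- counts[!bad, ]
  out$corrected_count <- base[!bad] / df$mappability[!bad]
  out
}

#' Standard preprocessing: GC then mappability correction
#'
#' @inheritParams correct_gc
#' @return Counts tibble with `corrected_count`.
#' @export
prepare_sample <- function(counts, genome, span = 0.3) {
  counts |>
    correct_gc(genome, span = span) |>
    correct_mappability(genome)
}

#' Per-bin Z-scores against a reference panel
#'
#' Normalises corrected counts by the sample's total corrected count and
#' standardises each bin with the panel's per-bin mean and SD. Bins whose
#' panel SD is not positive are excluded with a warning.
#'
#' @param counts Corrected `nipt_counts` tibble.
#' @param panel A `nipt_panel` object (see [build_reference_panel()]).
#' @return Tibble with `chrom`, `bin`, `start`, `end`, `z`.
#' @export
bin_zscores <- function(counts, panel) {
  if (!"corrected_count" %in% names(counts)) {
    rlang::abort("run correct_gc()/correct_mappability() first.")
  }
  norm <- counts$corrected_count / sum(counts$corrected_count)
  df <- tibble::tibble(chrom = counts$chrom, bin = counts$bin,
                       start = counts$start, end = counts$end, norm = norm)
  df <- dplyr::inner_join(df, panel$bins[, c("chrom", "bin", "mean", "sd")],
                          by = c("chrom", "bin"))
  if (nrow(df) != nrow(counts)) {
    rlang::abort("sample and panel bin grids do not match.")
  }
  bad <- !(df$sd > 0)
  if (any(bad)) {
    rlang::warn(sprintf("%d bin(s) with zero panel SD excluded.", sum(bad)))
    df <- df[!bad, ]
  }
  df |>
    dplyr::mutate(z = (.data$norm - .data$mean) / .data$sd) |>
    dplyr::select("chrom", "bin", "start", "end", "z")
}

#' Chromosome coverage from corrected bin counts
#'
#' Sums corrected counts per chromosome and reports each chromosome's
#' coverage proportion (summing to 1 over all chromosomes present) together
#' with its valid length `m` in Mb.
#'
#' @param counts Corrected `nipt_counts` tibble (uses `raw_count` when no
#'   corrected column exists).
#' @param genome A `nipt_genome` tibble.
#' @return Tibble with `chrom`, `n_bins`, `m_mb`, `coverage`, `proportion`.
#' @export
chromosome_coverage <- function(counts, genome) {
  val <- counts[["corrected_count"]] %||% counts$raw_count
  cov <- tibble::tibble(chrom = counts$chrom, value = val) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n_bins = dplyr::n(), coverage = sum(.data$value),
                     .groups = "drop")
  cov <- dplyr::inner_join(cov, valid_length_mb(genome), by = "chrom")
  cov <- cov[cov$n_bins > 0, ]
  cov$proportion <- cov$coverage / sum(cov$coverage)
  cov[, c("chrom", "n_bins", "m_mb", "coverage", "proportion")]
}

# Coverage proportions over valid autosomes only (the Z-score denominator;
# chrX excluded so male-fetus samples are comparable to a female panel).
autosomal_proportions <- function(coverage, genome) {
  auto <- coverage[coverage$chrom %in% autosomes(genome), ]
  auto$proportion_auto <- auto$coverage / sum(auto$coverage)
  auto
}
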