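#' Build a euploid reference panel
#'
#' Computes the standardisation statistics used throughout the workflow
#' from a collection of euploid samples: per-bin mean and SD of
#' totals-normalised corrected counts, and per-chromosome mean and SD of
#' the autosomal coverage proportion. SDs are floored at `sd_floor` with a
#' warning, so degenerate panels never produce infinite Z-scores.
#'
#' @param samples List of `nipt_counts` tibbles (raw counts are corrected
#'   internally with [prepare_sample()] unless a `corrected_count` column
#'   is already present).
#' @param genome A `nipt_genome` tibble.
#' @param sd_floor Lower bound for panel SDs (default 1e-6 on the
#'   normalised-count scale, i.e. one part per million of total coverage).
#' @return A list of class `nipt_panel` with elements `bins` (tibble:
#'   `chrom`, `bin`, `start`, `end`, `mean`, `sd`), `chromosomes` (tibble:
#'   `chrom`, `mean`, `sd`, `m_mb`, over valid autosomes), and `n_samples`.
#' @examples
#' g <- make_genome_fixture(c(chrA = 40, chrX = 30), seed = 1)
#' panel <- simulate_reference_panel(g, 12, total_reads = 2e5, seed = 3) |>
#'   build_reference_panel(g)
#' panel$n_samples
#' @export
build_reference_panel <- function(samples, genome, sd_floor = 1e-6) {
  if (!is.list(samples) || length(samples) < 2) {
    rlang::abort("need at least 2 panel samples.")
  }
  if (length(samples) < 10) {
    rlang::warn("fewer than 10 panel samples; SD estimates will be noisy.")
  }
  samples <- purrr::map(samples, function(s) {
    if (!"corrected_count" %in% names(s)) prepare_sample(s, genome) else s
  })

  grid <- samples[[1]][, c("chrom", "bin", "start", "end")]
  norm_mat <- vapply(samples, function(s) {
    if (!identical(s$bin, grid$bin) || !identical(s$chrom, grid$chrom)) {
      rlang::abort("panel samples are not on a common bin grid.")
    }
    s$corrected_count / sum(s$corrected_count)
  }, numeric(nrow(grid)))

  bin_mean <- rowMeans(norm_mat)
  bin_sd <- apply(norm_mat, 1, stats::sd)
  floored <- bin_sd < sd_floor
  if (any(floored)) {
    rlang::warn(sprintf("%d bin SD(s) at floor %g.", sum(floored), sd_floor))
    bin_sd[floored] <- sd_floor
  }

  covs <- purrr::map(samples, function(s) {
    chromosome_coverage(s, genome) |> autosomal_proportions(genome)
  })
  prop_mat <- matrix(vapply(covs, `[[`, numeric(nrow(covs[[1]])),
                            "proportion_auto"),
                     nrow = nrow(covs[[1]]))
  chrom_stats <- tibble::tibble(
    chrom = covs[[1]]$chrom,
    mean = rowMeans(prop_mat),
    sd = apply(prop_mat, 1, stats::sd),
    m_mb = covs[[1]]$m_mb
  )
  ch_floored <- chrom_stats$sd < sd_floor
  if (any(ch_floored)) {
    rlang::warn(sprintf("%d chromosome SD(s) at floor %g.", sum(ch_floored), sd_floor))
    chrom_stats$sd[ch_floored] <- sd_floor
  }

  structure(
    list(
      bins = dplyr::bind_cols(grid, tibble::tibble(mean = bin_mean, sd = bin_sd)),
      chromosomes = chrom_stats,
      n_samples = length(samples)
    ),
    class = "nipt_panel"
  )
}

#' Write or read a reference panel
#'
#' Per-bin statistics go to `bins.tsv`, per-chromosome statistics and
#' metadata to `chromosomes.json` under `dir`.
#'
#' @param panel A `nipt_panel` object.
#' @param dir Directory (created if missing).
#' @return `read_panel()` returns a `nipt_panel`; `write_panel()` the
#'   directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(panel$bins, file.path(dir, "bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(chromosomes = panel$chromosomes, n_samples = panel$n_samples),
    file.path(dir, "chromosomes.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  bins <- tibble::as_tibble(
    utils::read.table(file.path(dir, "bins.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  )
  meta <- jsonlite::read_json(file.path(dir, "chromosomes.json"),
                              simplifyVector = TRUE)
  structure(
    list(bins = bins, chromosomes = tibble::as_tibble(meta$chromosomes),
         n_samples = meta$n_samples),
    class = "nipt_panel"
  )
}
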