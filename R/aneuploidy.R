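#' Chromosome Z-scores against a reference panel
#'
#' Standardises a sample's autosomal coverage proportions with the panel's
#' per-chromosome mean and SD, both raw and after dividing the proportion
#' by the maternal-CNV coefficient `alpha`.
#'
#' @param coverage Output of [chromosome_coverage()].
#' @param panel A `nipt_panel`.
#' @param alphas Optional tibble with columns `chrom`, `alpha` (chromosomes
#'   not listed use `alpha = 1`).
#' @param chroms Chromosomes to score (default: all autosomes in the
#'   panel).
#' @return Tibble with `chrom`, `proportion`, `alpha`, `raw_z`,
#'   `adjusted_z`.
#' @export
zscore_chromosome <- function(coverage, panel, alphas = NULL,
                              chroms = panel$chromosomes$chrom) {
  auto <- coverage[coverage$chrom %in% panel$chromosomes$chrom, ]
  auto$prop_auto <- auto$coverage / sum(auto$coverage)
  df <- dplyr::inner_join(auto, panel$chromosomes, by = "chrom",
                          suffix = c("", ".panel"))
  if (any(df$sd <= 0)) rlang::abort("panel chromosome SD must be positive.")
  if (!is.null(alphas)) {
    df <- dplyr::left_join(df, alphas[, c("chrom", "alpha")], by = "chrom")
    df$alpha[is.na(df$alpha)] <- 1
  } else {
    df$alpha <- 1
  }
  df |>
    dplyr::filter(.data$chrom %in% chroms) |>
    dplyr::mutate(
      raw_z = (.data$prop_auto - .data$mean) / .data$sd,
      adjusted_z = (adjust_coverage(.data$prop_auto, .data$alpha) - .data$mean) / .data$sd
    ) |>
    dplyr::select("chrom", proportion = "prop_auto", "alpha", "raw_z",
                  "adjusted_z")
}

#' Call fetal aneuploidy from adjusted Z-scores
#'
#' A chromosome is called trisomic when its adjusted Z-score exceeds
#' `threshold` (default 3). Z-scores below `-threshold` are flagged as
#' possible monosomy but not auto-called, since the clinical scope is
#' trisomy 13/18/21; non-finite Z-scores produce a no-call.
#'
#' @param zscores Output of [zscore_chromosome()] (needs `chrom`,
#'   `adjusted_z`).
#' @param threshold Z-score threshold, default 3.
#' @return Input tibble with columns `call` (one of `"euploid"`,
#'   `"trisomy"`, `"monosomy-flag"`, `"no-call"`) and `threshold`.
#' @examples
#' call_aneuploidy(tibble::tibble(chrom = "chr21", adjusted_z = 3.01))
#' @export
call_aneuploidy <- function(zscores, threshold = 3) {
  zscores |>
    dplyr::mutate(
      call = dplyr::case_when(
        !is.finite(.data$adjusted_z) ~ "no-call",
        .data$adjusted_z > threshold ~ "trisomy",
        .data$adjusted_z < -threshold ~ "monosomy-flag",
        TRUE ~ "euploid"
      ),
      threshold = threshold
    )
}
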