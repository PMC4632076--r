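#' Run the full aneuploidy-screening pipeline on one sample
#'
#' Stage order: GC correction, mappability correction, chromosome
#' coverage, fetal-fraction estimate from chromosome X, then (unless
#' `general_mode`) per-bin Z-scores on the half-shifted overlap windows,
#' segmentation, maternal CNV calling and the per-chromosome coverage
#' coefficient, and finally chromosome Z-scores, the trisomy call, and for
#' positive male-fetus samples the fetal-concentration-discrepancy
#' statistic. `general_mode = TRUE` disables the maternal-CNV adjustment
#' and the discrepancy filter, reproducing a plain read-count NIPT for
#' comparison. Deterministic given the inputs and `seed`.
#'
#' @param counts Raw `nipt_counts` tibble (e.g. from [simulate_sample()],
#'   [read_bin_counts()] or [count_reads_in_bins()]).
#' @param panel A `nipt_panel`.
#' @param genome A `nipt_genome` tibble.
#' @param target_chroms Chromosomes screened for trisomy (default: those
#'   of `chr13`, `chr18`, `chr21` present in the panel; otherwise all
#'   panel autosomes).
#' @param z_threshold Aneuploidy Z-score threshold (default 3).
#' @param z_fetal_threshold Discrepancy flag threshold (default 3).
#' @param min_cnv_size_mb Minimum maternal CNV size adjusted for
#'   (default 0.3 Mb).
#' @param sd_coefficient Segmentation/undo coefficient (default 4).
#' @param general_mode Disable maternal-CNV adjustment and the
#'   discrepancy filter (default `FALSE`).
#' @param fcd_sd Cohort SD for the discrepancy statistic, or `NULL` (the
#'   statistic is then reported as unavailable).
#' @param span LOWESS span for GC correction.
#' @param nperm Segmentation permutations.
#' @param seed Seed for the segmentation permutations (default 1).
#' @param verbose Emit per-stage messages.
#' @return A `nipt_report`: list with `sample_id`, `general_mode`,
#'   `fetus_sex`, `f_x`, `chromosomes` (per-chromosome tibble with
#'   `proportion`, `alpha`, `raw_z`, `adjusted_z`, `call`), `cnv_calls`,
#'   `fcd`, and `provenance`.
#' @examples
#' \donttest{
#' g <- make_genome_fixture(c(chrA = 60, chr21 = 40, chrX = 50), seed = 1)
#' panel <- simulate_reference_panel(g, 20, total_reads = 5e5, seed = 2) |>
#'   build_reference_panel(g)
#' s <- simulate_sample(g, sim_params(fetal_fraction = 0.1, fetus_sex = "male",
#'                                    trisomy_chrom = "chr21",
#'                                    total_reads = 5e5, seed = 3))
#' rep <- run_pipeline(s, panel, g)
#' tidy(rep)
#' }
#' @export
run_pipeline <- function(counts, panel, genome,
                         target_chroms = NULL,
                         z_threshold = 3,
                         z_fetal_threshold = 3,
                         min_cnv_size_mb = 0.3,
                         sd_coefficient = 4,
                         general_mode = FALSE,
                         fcd_sd = NULL,
                         span = 0.3,
                         nperm = 500,
                         seed = 1L,
                         verbose = FALSE) {
  stopifnot(z_threshold > 0, z_fetal_threshold > 0, min_cnv_size_mb > 0)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(target_chroms)) {
    target_chroms <- intersect(c("chr13", "chr18", "chr21"),
                               panel$chromosomes$chrom)
    if (length(target_chroms) == 0) target_chroms <- panel$chromosomes$chrom
  }
  set.seed(as.integer(seed))

  say("correcting GC and mappability bias (%d bins)", nrow(counts))
  corrected <- prepare_sample(counts, genome, span = span)

  cov <- chromosome_coverage(corrected, genome)
  say("chromosome coverage computed for %d chromosomes", nrow(cov))

  xc <- x_chromosome(genome)
  f_x <- NA_real_
  fetus_sex <- "unknown"
  if (!is.na(xc)) {
    # screened chromosomes are excluded from the X reference so that a
    # trisomy (or a large maternal CNV) on them cannot bias f_x; fall back
    # to all autosomes if nothing else is left
    excl <- target_chroms
    if (length(setdiff(autosomes(genome), excl)) == 0) excl <- character()
    xbar <- chromosome_ratio(corrected, panel, genome, xc, exclude = excl)
    if (xbar < 0.99) {
      fetus_sex <- "male"
      f_x <- fetal_fraction_from_x(xbar)
    } else {
      # includes xbar > 1.02: no informative chrX under-representation
      fetus_sex <- "female-or-uninformative"
    }
    say("chrX ratio %.4f -> fetus %s, f_x = %s", xbar, fetus_sex,
        format(f_x, digits = 3))
  }

  mlen <- valid_length_mb(genome)
  cnv_calls <- tibble::tibble(chrom = character(), start = numeric(),
                              end = numeric(), size_mb = numeric(),
                              mean_z = numeric(), cn = integer(),
                              direction = character())
  alphas <- tibble::tibble(chrom = target_chroms, alpha = 1,
                           n_cnvs = 0L, functions = "")
  if (!general_mode) {
    bz <- bin_zscores(corrected, panel)
    windows <- overlap_bins(bz, "z")
    segs <- segment_windows(windows, chroms = target_chroms,
                            sd_coefficient = sd_coefficient, nperm = nperm)
    cnv_calls <- call_maternal_cnvs(segs, panel,
                                    min_size_mb = min_cnv_size_mb,
                                    sd_coefficient = sd_coefficient)
    say("%d maternal CNV call(s)", nrow(cnv_calls))
    alphas <- purrr::map_dfr(target_chroms, function(ch) {
      m <- mlen$m_mb[mlen$chrom == ch]
      a <- select_alpha(cnv_calls[cnv_calls$chrom == ch, ], m = m, f = f_x,
                        min_size_mb = min_cnv_size_mb)
      dplyr::bind_cols(tibble::tibble(chrom = ch), a)
    })
  }

  zs <- zscore_chromosome(cov, panel, alphas = alphas, chroms = target_chroms)
  chrom_calls <- call_aneuploidy(zs, threshold = z_threshold)
  say("calls: %s", paste(chrom_calls$chrom, chrom_calls$call,
                         sep = "=", collapse = ", "))

  fcd <- tibble::tibble(chrom = character(), f_x = numeric(),
                        f_aneu = numeric(), sd_used = numeric(),
                        z_fetal = numeric(), flagged = logical(),
                        mosaic_ratio_pct = numeric(), note = character())
  positives <- chrom_calls$chrom[chrom_calls$call == "trisomy"]
  if (!general_mode && length(positives) > 0) {
    fcd <- purrr::map_dfr(positives, function(ch) {
      rbar <- chromosome_ratio(corrected, panel, genome, ch)
      f_aneu <- suppressWarnings(fetal_fraction_from_trisomy(rbar))
      if (fetus_sex != "male" || is.na(f_x)) {
        return(tibble::tibble(chrom = ch, f_x = NA_real_, f_aneu = f_aneu,
                              sd_used = NA_real_, z_fetal = NA_real_,
                              flagged = NA, mosaic_ratio_pct = NA_real_,
                              note = "not applicable: no male-fetus chrX estimate"))
      }
      if (is.null(fcd_sd)) {
        return(tibble::tibble(chrom = ch, f_x = f_x, f_aneu = f_aneu,
                              sd_used = NA_real_, z_fetal = NA_real_,
                              flagged = NA, mosaic_ratio_pct = NA_real_,
                              note = "no cohort SD configured"))
      }
      zf <- z_fetal(f_x, f_aneu, fcd_sd, threshold = z_fetal_threshold)
      tibble::tibble(
        chrom = ch, f_x = round(f_x, 3), f_aneu = round(f_aneu, 3),
        sd_used = fcd_sd, z_fetal = zf$z_fetal, flagged = zf$flagged,
        mosaic_ratio_pct = if (f_x > 0) mosaic_ratio(f_aneu, f_x) else NA_real_,
        note = ifelse(zf$flagged,
                      "potential false positive - recommend karyotyping", "")
      )
    })
  } else if (length(positives) > 0) {
    fcd <- tibble::tibble(chrom = positives, f_x = NA_real_,
                          f_aneu = NA_real_, sd_used = NA_real_,
                          z_fetal = NA_real_, flagged = NA,
                          mosaic_ratio_pct = NA_real_,
                          note = "discrepancy filter disabled in general mode")
  }

  structure(
    list(
      sample_id = attr(counts, "sample_id") %||% "sample",
      general_mode = general_mode,
      fetus_sex = fetus_sex,
      f_x = f_x,
      chromosomes = chrom_calls,
      cnv_calls = cnv_calls,
      fcd = fcd,
      provenance = list(
        package = "niptcnv",
        version = as.character(utils::packageVersion("niptcnv")),
        seed = as.integer(seed),
        z_threshold = z_threshold,
        z_fetal_threshold = z_fetal_threshold,
        min_cnv_size_mb = min_cnv_size_mb,
        sd_coefficient = sd_coefficient,
        span = span,
        nperm = nperm
      )
    ),
    class = "nipt_report"
  )
}

#' @export
print.nipt_report <- function(x, ...) {
  cat(sprintf("<nipt_report> sample %s (%s mode)\n", x$sample_id,
              if (x$general_mode) "general" else "full"))
  cat(sprintf("fetus: %s; f_x = %s\n", x$fetus_sex,
              format(x$f_x, digits = 3)))
  print(x$chromosomes)
  if (nrow(x$cnv_calls) > 0) {
    cat("maternal CNV calls:\n")
    print(x$cnv_calls)
  }
  if (nrow(x$fcd) > 0) {
    cat("fetal-concentration discrepancy:\n")
    print(x$fcd)
  }
  invisible(x)
}

#' Tidy a pipeline report
#'
#' `tidy()` returns the per-chromosome call table; `glance()` a one-row
#' summary.
#'
#' @param x A `nipt_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nipt_report <- function(x, ...) {
  dplyr::mutate(x$chromosomes, sample_id = x$sample_id, .before = 1)
}

#' @rdname tidy.nipt_report
#' @export
glance.nipt_report <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    general_mode = x$general_mode,
    fetus_sex = x$fetus_sex,
    f_x = x$f_x,
    n_cnv_calls = nrow(x$cnv_calls),
    n_trisomy = sum(x$chromosomes$call == "trisomy"),
    any_fcd_flag = isTRUE(any(x$fcd$flagged)),
    max_adjusted_z = max(x$chromosomes$adjusted_z)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
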