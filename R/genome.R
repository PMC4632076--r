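#' Build a synthetic genome model for plasma read-depth simulation
#'
#' Constructs a bin-level genome model: fixed-width bins tiling a set of
#' chromosomes, a contiguous central gap per chromosome standing in for the
#' centromere/assembly-gap regions that unique reads cannot cover, and a GC
#' fraction and mappability value for every valid bin. The model is the
#' coordinate system for all downstream counting, correction and
#' segmentation; it is entirely synthetic, so nothing needs to be downloaded.
#'
#' Valid chromosome length `m` (in Mb), used by the coverage coefficient, is
#' the number of valid bins times the bin size.
#'
#' @param chrom_lengths_mb Named numeric vector of chromosome lengths in Mb.
#'   Names become chromosome names. Each chromosome must span at least 10
#'   bins.
#' @param gap_fraction Fraction of each chromosome masked as invalid
#'   (a single central block, a centromere proxy). Either a scalar or a
#'   vector named by chromosome. Default 0.05.
#' @param bin_size Bin width in bp (default 100000).
#' @param x_chrom Name of the chromosome treated as X-like for fetal-sex
#'   dosage and fetal-fraction estimation. Use `NA` for none. Default
#'   `"chrX"` when present among `chrom_lengths_mb` names.
#' @param gc_shape1,gc_shape2 Beta parameters for per-bin GC fractions
#'   (defaults give mean ~0.41, sd ~0.05, the mammalian bulk).
#' @param mappability_range Range of per-bin mappability for ordinary bins;
#'   a random 5% of bins get a lower dip in `c(0.5, 0.85)`.
#' @param seed Integer seed; the model is deterministic given the seed.
#'
#' @return A tibble of class `nipt_genome` with columns `chrom`, `start`,
#'   `end` (0-based half-open bp), `bin` (index within chromosome), `valid`,
#'   `gc`, `mappability`, and attributes `bin_size` and `x_chrom`.
#' @examples
#' g <- make_genome_fixture(c(chrA = 40, chrB = 75, chrC = 100, chrX = 155),
#'                          gap_fraction = 0.05, seed = 1)
#' valid_length_mb(g)
#' @export
make_genome_fixture <- function(chrom_lengths_mb,
                                gap_fraction = 0.05,
                                bin_size = 1e5,
                                x_chrom = if ("chrX" %in% names(chrom_lengths_mb)) "chrX" else NA_character_,
                                gc_shape1 = 39,
                                gc_shape2 = 56,
                                mappability_range = c(0.9, 1),
                                seed = 1L) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    rlang::abort("`bin_size` must be a single positive number.")
  }
  if (is.null(names(chrom_lengths_mb)) || any(!nzchar(names(chrom_lengths_mb)))) {
    rlang::abort("`chrom_lengths_mb` must be a named vector.")
  }
  n_bins <- floor(chrom_lengths_mb * 1e6 / bin_size)
  if (any(n_bins < 10)) {
    rlang::abort("every chromosome must span at least 10 bins.")
  }
  gap <- if (length(gap_fraction) == 1L) {
    stats::setNames(rep(gap_fraction, length(chrom_lengths_mb)), names(chrom_lengths_mb))
  } else {
    gap_fraction[names(chrom_lengths_mb)]
  }
  if (anyNA(gap) || any(gap < 0) || any(gap >= 1)) {
    rlang::abort("`gap_fraction` must cover every chromosome and lie in [0, 1).")
  }

  set.seed(as.integer(seed))
  rows <- purrr::imap(as.list(n_bins), function(nb, chrom) {
    # central contiguous gap block (centromere proxy)
    n_gap <- round(gap[[chrom]] * nb)
    gap_lo <- floor((nb - n_gap) / 2) + 1L
    valid <- rep(TRUE, nb)
    if (n_gap > 0) valid[seq(gap_lo, gap_lo + n_gap - 1L)] <- FALSE
    tibble::tibble(
      chrom = chrom,
      bin = seq_len(nb),
      start = (seq_len(nb) - 1) * bin_size,
      end = seq_len(nb) * bin_size,
      valid = valid
    )
  })
  g <- dplyr::bind_rows(rows)
  nv <- sum(g$valid)
  if (nv == 0) rlang::abort("genome model has zero valid bins.")

  gc <- pmin(pmax(stats::rbeta(nv, gc_shape1, gc_shape2), 0.2), 0.75)
  mapp <- stats::runif(nv, mappability_range[1], mappability_range[2])
  dip <- stats::runif(nv) < 0.05
  mapp[dip] <- stats::runif(sum(dip), 0.5, 0.85)

  g$gc <- NA_real_
  g$mappability <- NA_real_
  g$gc[g$valid] <- gc
  g$mappability[g$valid] <- mapp

  new_nipt_genome(g, bin_size = bin_size, x_chrom = x_chrom)
}

new_nipt_genome <- function(df, bin_size, x_chrom) {
  df <- tibble::as_tibble(df)
  attr(df, "bin_size") <- as.numeric(bin_size)
  attr(df, "x_chrom") <- x_chrom
  class(df) <- unique(c("nipt_genome", class(df)))
  df
}

#' Default study genome for simulation experiments
#'
#' An hg19-scale synthetic genome: chr13/18/21-like chromosomes whose valid
#' (non-gap) lengths approximate the build-37 uniquely mappable lengths
#' (~95.5, ~74.1 and ~35.0 Mb respectively), an X chromosome, and five
#' background autosomes totalling 2.5 Gb so that chromosome coverage
#' proportions, and hence their Poisson sampling variances, are
#' genome-realistic.
#'
#' @param seed Integer seed passed to [make_genome_fixture()].
#' @param bin_size Bin width in bp.
#' @return A `nipt_genome` tibble.
#' @export
default_genome <- function(seed = 1L, bin_size = 1e5) {
  make_genome_fixture(
    chrom_lengths_mb = c(
      chrO1 = 500, chrO2 = 500, chrO3 = 500, chrO4 = 500, chrO5 = 500,
      chr13 = 115, chr18 = 78, chr21 = 48, chrX = 155
    ),
    gap_fraction = c(
      chrO1 = 0.05, chrO2 = 0.05, chrO3 = 0.05, chrO4 = 0.05, chrO5 = 0.05,
      chr13 = 0.17, chr18 = 0.05, chr21 = 0.27, chrX = 0.05
    ),
    bin_size = bin_size,
    x_chrom = "chrX",
    seed = seed
  )
}

#' Valid chromosome length in Mb
#'
#' The length `m` entering the maternal-CNV coverage coefficient: number of
#' valid bins times bin size, per chromosome.
#'
#' @param genome A `nipt_genome` tibble.
#' @return A tibble with columns `chrom` and `m_mb`.
#' @export
valid_length_mb <- function(genome) {
  bs <- attr(genome, "bin_size")
  genome |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(m_mb = sum(.data$valid) * bs / 1e6, .groups = "drop")
}

#' @rdname valid_length_mb
#' @export
x_chromosome <- function(genome) attr(genome, "x_chrom")

#' Chromosomes of a genome model excluding the X-like chromosome
#' @param genome A `nipt_genome` tibble.
#' @return Character vector of autosome names.
#' @export
autosomes <- function(genome) {
  setdiff(unique(genome$chrom), x_chromosome(genome))
}

#' Read or write a genome model as a BED-like TSV
#'
#' Columns `chrom`, `start`, `end`, `gc`, `mappability`, `valid`
#' (0-based half-open coordinates). Bin size and the X-like chromosome name
#' are stored in `#key value` header lines.
#'
#' @param genome A `nipt_genome` tibble.
#' @param path File path.
#' @return `read_genome()` returns a `nipt_genome` tibble;
#'   `write_genome()` returns `path` invisibly.
#' @export
write_genome <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bin_size %s", format(attr(genome, "bin_size"), scientific = FALSE)), con)
  writeLines(sprintf("#x_chrom %s", attr(genome, "x_chrom") %||% "NA"), con)
  df <- genome[, c("chrom", "start", "end", "gc", "mappability", "valid")]
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- strsplit(sub("^#", "", hdr), " ")
  meta <- stats::setNames(
    vapply(meta, `[`, "", 2L),
    vapply(meta, `[`, "", 1L)
  )
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  bs <- as.numeric(meta[["bin_size"]])
  df <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(bin = as.integer(.data$start / bs) + 1L) |>
    dplyr::ungroup()
  xc <- meta[["x_chrom"]]
  if (identical(xc, "NA")) xc <- NA_character_
  new_nipt_genome(df, bin_size = bs, x_chrom = xc)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
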