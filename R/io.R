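#' Read and write per-bin counts as TSV
#'
#' The on-disk format is a tab-separated table with header columns
#' `chrom`, `start`, `end`, `raw_count` (and optionally
#' `corrected_count`), 0-based half-open coordinates. Reading validates
#' every row (malformed or negative entries are reported with their line
#' number) and, when a genome model is supplied, checks the intervals
#' against its bin grid and returns bins in genome order regardless of the
#' input row order.
#'
#' @param counts A `nipt_counts` tibble.
#' @param path File path.
#' @param genome Optional `nipt_genome` for grid validation.
#' @param sample_id Sample identifier for the returned object (default:
#'   file name).
#' @return `read_bin_counts()` returns a `nipt_counts` tibble;
#'   `write_bin_counts()` returns `path` invisibly.
#' @export
write_bin_counts <- function(counts, path) {
  keep <- intersect(c("chrom", "start", "end", "raw_count", "corrected_count"),
                    names(counts))
  utils::write.table(counts[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path, genome = NULL, sample_id = basename(path)) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = NA)
  need <- c("chrom", "start", "end", "raw_count")
  if (!all(need %in% names(raw))) {
    rlang::abort(paste0("counts TSV must have columns: ",
                        paste(need, collapse = ", ")))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # account for header line
  bad <- !is.finite(raw$start) | !is.finite(raw$end) |
    !is.finite(raw$raw_count) | raw$end <= raw$start
  if (any(bad)) {
    rlang::abort(sprintf("malformed row(s) at line(s): %s",
                         paste(line_no[bad], collapse = ", ")))
  }
  neg <- raw$raw_count < 0
  if (any(neg)) {
    rlang::abort(sprintf("negative count(s) at line(s): %s",
                         paste(line_no[neg], collapse = ", ")))
  }
  df <- tibble::as_tibble(raw)
  if (!is.null(genome)) {
    g <- genome[genome$valid, c("chrom", "bin", "start", "end")]
    merged <- dplyr::inner_join(g, df, by = c("chrom", "start", "end"))
    if (nrow(merged) != nrow(g) || nrow(df) != nrow(g)) {
      rlang::abort("counts do not match the genome model's valid bin grid.")
    }
    df <- merged
  } else {
    bs <- df$end[1] - df$start[1]
    df$bin <- as.integer(df$start / bs) + 1L
    df <- df[, c("chrom", "bin", "start", "end",
                 intersect("raw_count", names(df)),
                 intersect("corrected_count", names(df)))]
  }
  new_nipt_counts(df, sample_id = sample_id,
                  total_reads = sum(df$raw_count))
}

#' Write or read a call report as JSON
#'
#' The report serialises losslessly: writing, reading and re-writing
#' yields identical JSON.
#'
#' @param report A `nipt_report` (see [run_pipeline()]).
#' @param path File path.
#' @return `read_report()` returns a `nipt_report`; `write_report()` the
#'   path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("chromosomes", "cnv_calls", "fcd")) {
    if (!is.null(x[[nm]])) x[[nm]] <- tibble::as_tibble(x[[nm]])
  }
  structure(x, class = "nipt_report")
}
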