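#' Maternal CNV coverage coefficient
#'
#' The coefficient `alpha` measures the multiplicative effect of a maternal
#' CNV on chromosome coverage: the ratio of coverage with the CNV to
#' coverage without it. Dividing the observed coverage by `alpha` restores
#' the CNV-free value before Z-scoring.
#'
#' For a CNV of size `n` Mb and copy number `cn` on a chromosome of valid
#' length `m` Mb:
#' * inherited by the fetus (both compartments carry `cn`):
#'   `alpha = 1 + n * (cn - 2) / (2 * m)`
#' * not inherited (only the maternal fraction `1 - f` carries it):
#'   `alpha = 1 + (1 - f) * n * (cn - 2) / (2 * m)`
#'
#' Both reduce to 1 when `cn = 2` or `n = 0` (no CNV), exceed 1 for a
#' duplication and fall below 1 for a deletion; the not-inherited form
#' equals the inherited one at `f = 0` and is attenuated toward 1 as the
#' fetal fraction grows.
#'
#' @param m Valid chromosome length in Mb (> 0).
#' @param n CNV size in Mb (`0 <= n <= m`).
#' @param cn Non-negative integer copy number.
#' @param f Fetal fraction in `[0, 1]`.
#' @return The coefficient `alpha` (dimensionless).
#' @examples
#' alpha_inherited(m = 35.417, n = 0.85, cn = 3)
#' alpha_not_inherited(m = 38, n = 2, cn = 3, f = 0.1)
#' @export
alpha_inherited <- function(m, n, cn) {
  check_alpha_args(m, n, cn)
  1 + n * (cn - 2) / (2 * m)
}

#' @rdname alpha_inherited
#' @export
alpha_not_inherited <- function(m, n, cn, f) {
  check_alpha_args(m, n, cn)
  if (any(f < 0 | f > 1)) rlang::abort("`f` must lie in [0, 1].")
  1 + (1 - f) * n * (cn - 2) / (2 * m)
}

check_alpha_args <- function(m, n, cn) {
  if (any(m <= 0)) rlang::abort("`m` must be positive.")
  if (any(n < 0)) rlang::abort("`n` must be non-negative.")
  if (any(n > m)) rlang::abort("CNV size `n` cannot exceed valid length `m`.")
  if (any(cn < 0)) rlang::abort("`cn` must be non-negative.")
  invisible(TRUE)
}

#' Combine maternal CNV calls into one per-chromosome coefficient
#'
#' Applies the selection rule for which coefficient form to use:
#' duplications take the not-inherited form (attenuated by `1 - f`),
#' deletions the inherited form. The rule errs on the side of
#' over-correcting duplications and under-correcting deletions, so a wrong
#' inheritance guess can only push the adjusted Z-score away from a
#' false-negative call. Multiple CNVs on one chromosome combine additively
#' in the excess term:
#' `alpha = 1 + sum_i k_i * n_i * (cn_i - 2) / (2 * m)`,
#' with `k_i = 1 - f` for duplications and `k_i = 1` for deletions.
#' An explicit `inherited` column set to `TRUE` overrides the rule and
#' forces the inherited form for that CNV.
#'
#' @param cnv_calls Tibble of CNV calls for one chromosome (columns
#'   `size_mb`, `cn`; optional `inherited`), e.g. from
#'   [call_maternal_cnvs()]. May have zero rows.
#' @param m Valid chromosome length in Mb.
#' @param f Fetal fraction; if `NA` while a duplication is present, the
#'   inherited form is used for it with a warning.
#' @param min_size_mb Calls at or below this size are ignored (default
#'   0.3).
#' @return One-row tibble with `alpha`, `n_cnvs`, `functions` (comma-joined
#'   "1"/"2" per CNV used).
#' @export
select_alpha <- function(cnv_calls, m, f = NA_real_, min_size_mb = 0.3) {
  if (is.null(cnv_calls) || nrow(cnv_calls) == 0) {
    return(tibble::tibble(alpha = 1, n_cnvs = 0L, functions = ""))
  }
  calls <- cnv_calls[cnv_calls$size_mb > min_size_mb, ]
  if (nrow(calls) == 0) {
    return(tibble::tibble(alpha = 1, n_cnvs = 0L, functions = ""))
  }
  inherited <- if ("inherited" %in% names(calls)) calls$inherited else rep(FALSE, nrow(calls))
  is_dup <- calls$cn > 2
  use_f2 <- is_dup & !inherited
  if (any(use_f2) && is.na(f)) {
    rlang::warn("fetal fraction unavailable; using the inherited form for duplication(s).")
    use_f2[] <- FALSE
  }
  k <- ifelse(use_f2, 1 - f, 1)
  excess <- sum(k * calls$size_mb * (calls$cn - 2) / (2 * m))
  tibble::tibble(
    alpha = 1 + excess,
    n_cnvs = nrow(calls),
    functions = paste(ifelse(use_f2, "2", "1"), collapse = ",")
  )
}

#' Remove the maternal CNV effect from chromosome coverage
#'
#' Since `alpha` is defined as coverage-with-CNV over coverage-without,
#' division restores the CNV-free coverage.
#'
#' @param coverage Numeric coverage (or coverage proportion) values.
#' @param alpha Coefficient(s), must be positive.
#' @return `coverage / alpha`.
#' @examples
#' adjust_coverage(0.0150, 1.012)
#' @export
adjust_coverage <- function(coverage, alpha) {
  if (any(alpha <= 0)) rlang::abort("`alpha` must be positive.")
  coverage / alpha
}
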