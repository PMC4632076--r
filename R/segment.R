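#' Half-shifted overlapping windows from bin values
#'
#' Builds the 100-kb windows, offset by half a bin, used for maternal CNV
#' detection: each window is the sum of the two 50-kb halves contributed by
#' a pair of adjacent valid bins, i.e. `(v[j] + v[j+1]) / 2` on the
#' per-100-kb scale. Every base bin contributes to exactly two windows, so
#' a CNV breakpoint falling mid-bin still produces a clean step. Windows
#' are only formed between genomically adjacent valid bins: they never
#' bridge a gap, and chromosome arms shorter than one window are skipped.
#'
#' @param df Tibble with columns `chrom`, `bin`, `start`, `end` and the
#'   value column (valid bins only, as produced by [simulate_sample()] or
#'   [bin_zscores()]).
#' @param value Name of the value column to window (default `"z"`).
#' @return Tibble with `chrom`, `window`, `start`, `end`, `bin_left`,
#'   `bin_right`, `value`.
#' @export
overlap_bins <- function(df, value = "z") {
  v <- df[[value]]
  if (is.null(v)) rlang::abort(sprintf("no column `%s` in input.", value))
  df |>
    dplyr::mutate(.val = v) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$bin, .by_group = TRUE) |>
    dplyr::reframe({
      d <- dplyr::pick(dplyr::everything())
      if (nrow(d) < 2) {
        tibble::tibble(window = integer(), start = numeric(),
                       end = numeric(), bin_left = integer(),
                       bin_right = integer(), value = numeric())
      } else {
        adj <- which(diff(d$bin) == 1L)
        bs <- d$end[1] - d$start[1]
        tibble::tibble(
          window = seq_along(adj),
          start = d$start[adj] + bs / 2,
          end = d$start[adj] + 3 * bs / 2,
          bin_left = d$bin[adj],
          bin_right = d$bin[adj + 1L],
          value = (d$.val[adj] + d$.val[adj + 1L]) / 2,
          value_left = d$.val[adj],
          value_right = d$.val[adj + 1L]
        )
      }
    })
}

#' Segment a numeric signal by recursive maximal-t splitting
#'
#' Changepoint detection in the style of circular binary segmentation,
#' re-implemented natively: the best split of each segment is the position
#' maximising the two-sample t-statistic between left and right means, the
#' split is accepted when its permutation p-value falls below `alpha`, and
#' the two halves are segmented recursively. Segments where no single
#' split is significant are
#' additionally probed with the best *pair* of splits (permutation-tested
#' on an F-type statistic), because an inserted arc that returns to
#' baseline — a CNV in the middle of a flat chromosome — can be invisible
#' to any single split when its flanks share a mean. Accepted breakpoints
#' are then refined: each one is re-located at the best split within its
#' two flanking segments, since the first greedy split of a
#' multi-changepoint segment can land a couple of points off the
#' least-squares optimum. Finally, adjacent segments are re-merged (the
#' "undo" step) whenever their means differ by less than
#' `sd_coefficient` noise standard deviations (the flat `undo.SD`
#' convention of segmentation practice), with the per-point noise SD
#' estimated robustly as `mad(diff(x)) / sqrt(2)`. `sd_coefficient`
#' defaults to 4: a deliberately conservative setting, since a wrongly
#' called maternal CNV harms the downstream aneuploidy call more than a
#' missed small one.
#'
#' @param x Numeric vector (NaN/NA entries are dropped with a warning).
#' @param bins Optional numeric vector of length `length(x) + 1` when `x`
#'   consists of half-shifted overlap windows `x[j] = (bins[j] +
#'   bins[j+1]) / 2`. Adjacent windows then share a bin and are not
#'   exchangeable, so permutations shuffle the bins and rebuild windows —
#'   without this the test is anticonservative on window input.
#' @param sd_coefficient Merge ("undo") coefficient, default 4.
#' @param alpha Permutation p-value threshold for accepting a split
#'   (default 0.01).
#' @param nperm Number of permutations (default 500).
#' @param min_width Minimum segment width in points (default 2).
#' @param seed Optional seed for the permutation draws.
#' @return Tibble with `start_idx`, `end_idx` (indices into `x` after NA
#'   removal), `n`, `mean`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(50), rnorm(50, 2))
#' segment_signal(x, seed = 1)
#' @export
segment_signal <- function(x, bins = NULL, sd_coefficient = 4, alpha = 0.01,
                           nperm = 500, min_width = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  keep <- is.finite(x)
  if (!all(keep)) {
    rlang::warn(sprintf("%d non-finite value(s) dropped before segmentation.",
                        sum(!keep)))
    x <- x[keep]
    bins <- NULL  # bin alignment is lost once windows are dropped
  }
  n <- length(x)
  if (n == 0) return(tibble::tibble(start_idx = integer(), end_idx = integer(),
                                    n = integer(), mean = numeric()))
  if (!is.null(bins) && length(bins) != n + 1L) {
    rlang::abort("`bins` must have length(x) + 1 elements.")
  }

  breaks <- recurse_split(x, 1L, n, alpha, nperm, min_width, bins = bins)
  bounds <- sort(unique(c(0L, breaks, n)))
  bounds <- refine_breakpoints(x, bounds, min_width)
  segs <- tibble::tibble(
    start_idx = utils::head(bounds, -1) + 1L,
    end_idx = utils::tail(bounds, -1)
  )
  segs$n <- segs$end_idx - segs$start_idx + 1L
  segs$mean <- purrr::map2_dbl(segs$start_idx, segs$end_idx,
                               ~ mean(x[.x:.y]))

  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma == 0) sigma <- 1e-12

  undo_merge(segs, sd_coefficient, sigma)
}

# re-locate each interior breakpoint at the least-squares split within its
# two flanking segments, iterating to stability
refine_breakpoints <- function(x, bounds, min_width, max_iter = 5L) {
  if (length(bounds) < 3) return(bounds)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (j in 2:(length(bounds) - 1L)) {
      lo <- bounds[j - 1] + 1L
      hi <- bounds[j + 1]
      bs <- best_split(x[lo:hi], min_width)
      if (is.null(bs)) next
      newb <- lo + bs$k - 1L
      if (newb != bounds[j] && newb > bounds[j - 1] && newb < bounds[j + 1]) {
        bounds[j] <- newb
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(unique(bounds))
}

# best pair of splits (b1, b2) minimising the 3-segment RSS, with an
# F-like statistic against the 1-segment fit; catches the symmetric
# return-to-baseline pattern (an inserted arc) that a single maximal-t
# split cannot see because both flanks share the same mean
best_pair <- function(x, min_width, max_arc = 100L) {
  n <- length(x)
  if (n < 3 * min_width) return(NULL)
  S <- cumsum(x)
  S2 <- cumsum(x^2)
  rss <- function(i, j) {
    s <- S[j] - ifelse(i > 1, S[i - 1], 0)
    s2 <- S2[j] - ifelse(i > 1, S2[i - 1], 0)
    s2 - s^2 / (j - i + 1)
  }
  rss0 <- rss(1, n)
  best <- NULL
  best_rss <- Inf
  # scan by arc length (middle-segment width d), vectorised over positions;
  # d is capped at max_arc: the pair stage only needs to see CNV-scale
  # arcs, larger structure falls to single splits
  for (d in min_width:min(max_arc, n - 2 * min_width)) {
    b1 <- min_width:(n - min_width - d)
    s_l <- S[b1]
    rss_l <- S2[b1] - s_l^2 / b1
    s_m <- S[b1 + d] - s_l
    rss_m <- (S2[b1 + d] - S2[b1]) - s_m^2 / d
    s_r <- S[n] - S[b1 + d]
    rss_r <- (S2[n] - S2[b1 + d]) - s_r^2 / (n - b1 - d)
    total <- rss_l + rss_m + rss_r
    i <- which.min(total)
    if (total[i] < best_rss) {
      best_rss <- total[i]
      best <- c(b1[i], b1[i] + d)
    }
  }
  fstat <- ((rss0 - best_rss) / 2) / max(best_rss / max(n - 3, 1), 1e-300)
  list(b = best, fstat = fstat)
}

# best split of x: position k maximising |t|; returns list(k, tmax)
best_split <- function(x, min_width) {
  n <- length(x)
  if (n < 2 * min_width) return(NULL)
  S <- cumsum(x)
  k <- min_width:(n - min_width)
  mL <- S[k] / k
  mR <- (S[n] - S[k]) / (n - k)
  d <- mL - mR
  inv <- 1 / k + 1 / (n - k)
  TSS <- sum(x^2) - S[n]^2 / n
  W <- pmax(TSS - d^2 / inv, 0)
  tt <- abs(d) / sqrt(pmax(W / max(n - 2, 1), 1e-300) * inv)
  i <- which.max(tt)
  list(k = k[i], tmax = tt[i])
}

# permutation p-value with early exit once it can no longer fall below
# alpha; `stat_fun` maps a segment to its scan statistic. When `seg_bins`
# is given, exchangeability holds at the bin level: each permutation
# shuffles the bins and rebuilds the half-shifted windows.
perm_significant <- function(seg, observed, stat_fun, alpha, nperm,
                             seg_bins = NULL) {
  draw <- if (is.null(seg_bins)) {
    function() sample(seg)
  } else {
    function() {
      b <- sample(seg_bins)
      (b[-length(b)] + b[-1]) / 2
    }
  }
  exceed <- 0L
  for (b in seq_len(nperm)) {
    ps <- stat_fun(draw())
    if (!is.null(ps) && ps >= observed) exceed <- exceed + 1L
    if ((exceed + 1) / (nperm + 1) >= alpha) return(FALSE)
  }
  (exceed + 1) / (nperm + 1) < alpha
}

recurse_split <- function(x, lo, hi, alpha, nperm, min_width, bins = NULL) {
  seg <- x[lo:hi]
  if (length(seg) < 2 * min_width || stats::var(seg) == 0) return(integer())
  seg_bins <- if (!is.null(bins)) bins[lo:(hi + 1L)]

  bs <- best_split(seg, min_width)
  if (!is.null(bs) && is.finite(bs$tmax) &&
      perm_significant(seg, bs$tmax,
                       function(s) best_split(s, min_width)$tmax,
                       alpha, nperm, seg_bins)) {
    k <- lo + bs$k - 1L
    return(c(recurse_split(x, lo, k, alpha, nperm, min_width, bins), k,
             recurse_split(x, k + 1L, hi, alpha, nperm, min_width, bins)))
  }

  # second stage: a symmetric inserted arc leaves the single-split scan
  # blind; test the best split pair against its own permutation null
  bp <- best_pair(seg, min_width)
  if (!is.null(bp) && is.finite(bp$fstat) &&
      perm_significant(seg, bp$fstat,
                       function(s) {
                         p <- best_pair(s, min_width)
                         if (is.null(p)) NULL else p$fstat
                       },
                       alpha, nperm, seg_bins)) {
    k1 <- lo + bp$b[1] - 1L
    k2 <- lo + bp$b[2] - 1L
    return(c(recurse_split(x, lo, k1, alpha, nperm, min_width, bins), k1,
             recurse_split(x, k1 + 1L, k2, alpha, nperm, min_width, bins), k2,
             recurse_split(x, k2 + 1L, hi, alpha, nperm, min_width, bins)))
  }
  integer()
}

undo_merge <- function(segs, sd_coefficient, sigma) {
  repeat {
    if (nrow(segs) < 2) break
    d <- abs(diff(segs$mean))
    # flat threshold in per-point noise SD units (undo.SD convention)
    thr <- sd_coefficient * sigma
    weak <- which(d < thr)
    if (length(weak) == 0) break
    i <- weak[which.min((d - thr)[weak])]
    ntot <- segs$n[i] + segs$n[i + 1]
    segs$mean[i] <- (segs$mean[i] * segs$n[i] + segs$mean[i + 1] * segs$n[i + 1]) / ntot
    segs$n[i] <- ntot
    segs$end_idx[i] <- segs$end_idx[i + 1]
    segs <- segs[-(i + 1), ]
  }
  segs
}

#' Segment overlap-window Z-scores per chromosome
#'
#' Applies [segment_signal()] independently to each contiguous run of
#' windows (runs never span assembly gaps, so no segment can either) and
#' maps segments back to genomic coordinates.
#'
#' @param windows Output of [overlap_bins()] on window Z-scores.
#' @param chroms Chromosomes to segment (default: all present).
#' @inheritParams segment_signal
#' @return Tibble with `chrom`, `start`, `end` (bp), `n_windows`,
#'   `mean_z`, `sigma` (per-chromosome noise SD estimate).
#' @export
segment_windows <- function(windows, chroms = unique(windows$chrom),
                            sd_coefficient = 4, alpha = 0.01, nperm = 500,
                            min_width = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  windows |>
    dplyr::filter(.data$chrom %in% chroms) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$window, .by_group = TRUE) |>
    dplyr::reframe({
      d <- dplyr::pick(dplyr::everything())
      run <- cumsum(c(1, diff(d$bin_left) != 1L))
      purrr::map_dfr(split(seq_along(run), run), function(idx) {
        v <- d$value[idx]
        vb <- c(d$value_left[idx[1]], d$value_right[idx])
        sigma <- stats::mad(diff(v)) / sqrt(2)
        if (!is.finite(sigma) || sigma == 0) sigma <- max(stats::sd(v), 1e-12)
        segs <- segment_signal(v, bins = vb,
                               sd_coefficient = sd_coefficient,
                               alpha = alpha, nperm = nperm,
                               min_width = min_width)
        tibble::tibble(
          start = d$start[idx][segs$start_idx],
          end = d$end[idx][segs$end_idx],
          n_windows = segs$n,
          mean_z = segs$mean,
          sigma = sigma
        )
      })
    })
}

#' Call maternal CNVs from Z-score segments
#'
#' A segment becomes a maternal CNV call when its mean Z-score is
#' detectably non-zero (`|mean_z| >= sd_coefficient * sigma /
#' sqrt(n_windows)`), its genomic footprint exceeds `min_size_mb`, and its
#' estimated integer copy number differs from 2. The copy number is
#' bridged from the Z scale through the panel's per-bin coefficient of
#' variation: the relative coverage excess is `mean_z * cv`, and
#' `cn = 2 * (1 + excess)` rounded half away from 2 (conservative toward
#' calling a CNV). Note the excess observed in plasma for a non-inherited
#' CNV is attenuated by `(1 - f)`; rounding absorbs that attenuation for
#' typical fetal fractions.
#'
#' @param segments Output of [segment_windows()].
#' @param panel A `nipt_panel` (for the per-bin CV bridge).
#' @param min_size_mb Minimum CNV footprint in Mb (default 0.3; calls must
#'   exceed it strictly).
#' @param sd_coefficient Detection coefficient, default 4 (the
#'   conservative setting; 3 restores the usual sensitivity).
#' @return Tibble with `chrom`, `start`, `end`, `size_mb`, `mean_z`, `cn`,
#'   `direction`.
#' @export
call_maternal_cnvs <- function(segments, panel, min_size_mb = 0.3,
                               sd_coefficient = 4) {
  cv_by_chrom <- panel$bins |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(cv = mean(.data$sd / .data$mean), .groups = "drop")

  candidates <- segments |>
    dplyr::inner_join(cv_by_chrom, by = "chrom") |>
    dplyr::filter(
      abs(.data$mean_z) >=
        sd_coefficient * .data$sigma / sqrt(.data$n_windows),
      # individually CNV-like: excess far enough from 0 to round off cn = 2
      abs(.data$mean_z * .data$cv) >= 0.25
    ) |>
    dplyr::select(-"cv")
  if (nrow(candidates) == 0) return(empty_cnv_calls())

  # collapse genomically contiguous same-sign segments before sizing, so a
  # CNV split by level heterogeneity is still measured on its full footprint
  merged <- candidates |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(grp = cumsum(c(1, diff_break(.data$start, .data$end,
                                               .data$mean_z)))) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      mean_z = stats::weighted.mean(.data$mean_z, .data$n_windows),
      n_windows = sum(.data$n_windows), .groups = "drop"
    )

  merged |>
    dplyr::inner_join(cv_by_chrom, by = "chrom") |>
    dplyr::mutate(
      size_mb = (.data$end - .data$start) / 1e6,
      excess = .data$mean_z * .data$cv,
      cn = round_away_from_2(2 * (1 + .data$excess))
    ) |>
    dplyr::filter(.data$size_mb > min_size_mb, .data$cn != 2L,
                  .data$cn >= 0L) |>
    dplyr::mutate(direction = ifelse(.data$cn > 2, "dup", "del")) |>
    dplyr::select("chrom", "start", "end", "size_mb", "mean_z", "cn",
                  "direction")
}

# TRUE where a new merge group must start: non-adjacent or opposite sign
diff_break <- function(start, end, mean_z) {
  if (length(start) < 2) return(logical(0))
  non_adjacent <- start[-1] > end[-length(end)]
  sign_flip <- sign(mean_z[-1]) != sign(mean_z[-length(mean_z)])
  non_adjacent | sign_flip
}

empty_cnv_calls <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 size_mb = numeric(), mean_z = numeric(), cn = integer(),
                 direction = character())
}

# round to integer, with exact .5 ties resolved away from 2
round_away_from_2 <- function(x) {
  up <- x >= 2
  as.integer(ifelse(up, floor(x + 0.5), ceiling(x - 0.5)))
}
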