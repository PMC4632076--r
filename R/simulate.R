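#' Simulation parameters for a maternal plasma sample
#'
#' Bundles everything that defines one synthetic plasma sample: fetal
#' fraction, fetal sex, an optional fetal trisomy, maternal constitutional
#' CNVs, sequencing depth and seed. Plasma cell-free DNA is modelled as a
#' two-compartment mixture: a fraction `fetal_fraction` of reads from the
#' feto-placental genome and the remainder from the maternal genome.
#'
#' @param fetal_fraction Fetal (placental) DNA fraction `f` in `[0, 1]`.
#' @param fetus_sex `"female"` or `"male"`; a male fetus carries one X, so
#'   X-like coverage is depressed by `f/2`.
#' @param trisomy_chrom Chromosome name carrying a fetal trisomy, or `NULL`.
#' @param maternal_cnvs Tibble with columns `chrom`, `start_mb`, `size_mb`,
#'   `cn`, `inherited`, one row per maternal CNV (see [maternal_cnv()]), or
#'   `NULL`. `cn` must be a non-negative integer other than 2. When
#'   `inherited` is `TRUE`, the fetus carries the same copy number.
#' @param total_reads Expected total unique read count (default 7.5e6,
#'   the midpoint of the 5-10 million reads typical of shallow plasma
#'   sequencing).
#' @param gc_bias_amplitude Amplitude of the unimodal GC bias injected into
#'   expected bin rates (default 0.2, i.e. up to +/-20%); see
#'   [gc_bias_multiplier()].
#' @param allow_cnv_on_trisomy Permit a maternal CNV on the trisomic
#'   chromosome (default `FALSE`; rejected otherwise so that accidental
#'   confounding is explicit).
#' @param seed Integer seed for the Poisson draws, or `NULL`.
#'
#' @return A list of class `sim_params`.
#' @examples
#' p <- sim_params(fetal_fraction = 0.1, fetus_sex = "male",
#'                 trisomy_chrom = "chr21", total_reads = 1e6, seed = 1)
#' @export
sim_params <- function(fetal_fraction = 0.1,
                       fetus_sex = c("female", "male"),
                       trisomy_chrom = NULL,
                       maternal_cnvs = NULL,
                       total_reads = 7.5e6,
                       gc_bias_amplitude = 0.2,
                       allow_cnv_on_trisomy = FALSE,
                       seed = NULL) {
  fetus_sex <- match.arg(fetus_sex)
  if (!is.numeric(fetal_fraction) || length(fetal_fraction) != 1L ||
      is.na(fetal_fraction) || fetal_fraction < 0 || fetal_fraction > 1) {
    rlang::abort("`fetal_fraction` must be a single number in [0, 1].")
  }
  if (!is.null(maternal_cnvs)) {
    maternal_cnvs <- tibble::as_tibble(maternal_cnvs)
    need <- c("chrom", "start_mb", "size_mb", "cn", "inherited")
    if (!all(need %in% names(maternal_cnvs))) {
      rlang::abort(paste0("`maternal_cnvs` needs columns: ",
                          paste(need, collapse = ", ")))
    }
    bad_cn <- maternal_cnvs$cn %% 1 != 0 | maternal_cnvs$cn < 0 |
      maternal_cnvs$cn == 2
    if (any(bad_cn)) {
      rlang::abort("maternal CNV `cn` must be a non-negative integer != 2.")
    }
    if (any(maternal_cnvs$size_mb <= 0)) {
      rlang::abort("maternal CNV `size_mb` must be > 0.")
    }
    if (!is.null(trisomy_chrom) && !allow_cnv_on_trisomy &&
        any(maternal_cnvs$chrom == trisomy_chrom)) {
      rlang::abort(paste0(
        "maternal CNV on the trisomic chromosome; ",
        "set `allow_cnv_on_trisomy = TRUE` to opt in."))
    }
  }
  if (total_reads <= 0) rlang::abort("`total_reads` must be positive.")
  structure(
    list(
      fetal_fraction = fetal_fraction,
      fetus_sex = fetus_sex,
      trisomy_chrom = trisomy_chrom,
      maternal_cnvs = maternal_cnvs,
      total_reads = total_reads,
      gc_bias_amplitude = gc_bias_amplitude,
      allow_cnv_on_trisomy = allow_cnv_on_trisomy,
      seed = seed
    ),
    class = "sim_params"
  )
}

#' Describe one maternal CNV
#'
#' @param chrom Chromosome name.
#' @param start_mb CNV start in Mb from the chromosome start; the interval
#'   `[start_mb, start_mb + size_mb)` must be fully covered by valid bins.
#' @param size_mb CNV size `n` in Mb.
#' @param cn Integer copy number (0, 1, 3, 4, ...; 2 means no CNV and is
#'   rejected).
#' @param inherited Has the fetus inherited the CNV? Default `FALSE`.
#' @return One-row tibble suitable for `sim_params(maternal_cnvs = )`.
#' @export
maternal_cnv <- function(chrom, start_mb, size_mb, cn, inherited = FALSE) {
  tibble::tibble(chrom = chrom, start_mb = start_mb, size_mb = size_mb,
                 cn = cn, inherited = inherited)
}

#' Place a CNV in a contiguous valid region of a chromosome
#'
#' Convenience for simulations: finds the first run of valid bins on
#' `chrom` long enough to hold a CNV of `size_mb` starting `offset_mb`
#' into the run, and returns the corresponding [maternal_cnv()] row.
#'
#' @inheritParams maternal_cnv
#' @param genome A `nipt_genome` tibble.
#' @param offset_mb Offset of the CNV start into the valid run (default 5).
#' @return One-row tibble as [maternal_cnv()].
#' @export
place_cnv <- function(genome, chrom, size_mb, cn, inherited = FALSE,
                      offset_mb = 5) {
  bs <- attr(genome, "bin_size")
  gb <- genome[genome$chrom == chrom & genome$valid, ]
  if (nrow(gb) == 0) rlang::abort(sprintf("no valid bins on %s", chrom))
  runs <- split(gb, cumsum(c(1, diff(gb$bin) != 1)))
  need <- ceiling((offset_mb + size_mb) * 1e6 / bs)
  run <- purrr::detect(runs, ~ nrow(.x) >= need)
  if (is.null(run)) {
    rlang::abort(sprintf("no valid run on %s can hold a %.2f Mb CNV at offset %.1f Mb",
                         chrom, size_mb, offset_mb))
  }
  start_mb <- (run$start[1] + round(offset_mb * 1e6 / bs) * bs) / 1e6
  maternal_cnv(chrom, start_mb, size_mb, cn, inherited)
}

#' Unimodal GC bias multiplier
#'
#' Smooth quadratic efficiency curve peaking at `peak` (default GC 0.42)
#' with configurable amplitude: bins at the peak are over-represented by up
#' to `amplitude`, extreme-GC bins under-represented by the same amount.
#' Injected by the simulator so the LOWESS correction stage has real work
#' to do.
#'
#' @param gc Numeric vector of GC fractions.
#' @param amplitude Peak-to-trough half-range (default 0.2).
#' @param peak GC fraction of maximum efficiency.
#' @param width GC distance over which the multiplier falls from `1 +
#'   amplitude` back to 1.
#' @return Multipliers clipped to `[1 - amplitude, 1 + amplitude]`.
#' @export
gc_bias_multiplier <- function(gc, amplitude = 0.2, peak = 0.42, width = 0.15) {
  m <- 1 + amplitude * (1 - ((gc - peak) / width)^2)
  pmin(pmax(m, 1 - amplitude), 1 + amplitude)
}

#' Expected per-bin read rates for a simulated sample
#'
#' The generative mean of each valid bin: a baseline proportional to
#' `total_reads * mappability * gc_bias`, normalised so baselines sum to
#' `total_reads`, times the copy-number dosage
#' `f * cn_f/2 + (1 - f) * cn_m/2` of the bin. `cn_m` is the maternal copy
#' number (2 outside maternal CNVs), `cn_f` the fetal one (trisomy adds a
#' chromosome-wide copy; a male fetus has one X; an inherited CNV carries
#' the maternal copy number).
#'
#' @param genome A `nipt_genome` tibble.
#' @param params A [sim_params()] object.
#' @return Tibble of valid bins with columns `chrom`, `bin`, `start`, `end`,
#'   `gc`, `mappability`, `base`, `dosage`, `lambda`.
#' @export
expected_bin_rates <- function(genome, params) {
  stopifnot(inherits(params, "sim_params"))
  g <- genome[genome$valid, ]
  w <- g$mappability * gc_bias_multiplier(g$gc, params$gc_bias_amplitude)
  base <- params$total_reads * w / sum(w)

  f <- params$fetal_fraction
  cn_m <- rep(2, nrow(g))
  cn_f <- rep(2, nrow(g))

  xc <- x_chromosome(genome)
  if (!is.na(xc) && params$fetus_sex == "male") cn_f[g$chrom == xc] <- 1
  if (!is.null(params$trisomy_chrom)) {
    if (!params$trisomy_chrom %in% g$chrom) {
      rlang::abort(sprintf("trisomy chromosome %s not in genome", params$trisomy_chrom))
    }
    cn_f[g$chrom == params$trisomy_chrom] <- cn_f[g$chrom == params$trisomy_chrom] + 1L
  }
  if (!is.null(params$maternal_cnvs)) {
    for (i in seq_len(nrow(params$maternal_cnvs))) {
      cv <- params$maternal_cnvs[i, ]
      sel <- which(g$chrom == cv$chrom &
                     g$start >= cv$start_mb * 1e6 - 1e-6 &
                     g$end <= (cv$start_mb + cv$size_mb) * 1e6 + 1e-6)
      if (length(sel) == 0) {
        rlang::abort(sprintf("maternal CNV on %s covers no valid bins", cv$chrom))
      }
      gaps <- genome$chrom == cv$chrom & !genome$valid &
        genome$start >= cv$start_mb * 1e6 & genome$end <= (cv$start_mb + cv$size_mb) * 1e6
      if (any(gaps)) {
        rlang::abort("maternal CNV interval must lie within valid bins.")
      }
      cn_m[sel] <- cv$cn
      if (isTRUE(cv$inherited)) cn_f[sel] <- cv$cn
    }
  }

  dosage <- f * cn_f / 2 + (1 - f) * cn_m / 2
  tibble::tibble(
    chrom = g$chrom, bin = g$bin, start = g$start, end = g$end,
    gc = g$gc, mappability = g$mappability,
    base = base, dosage = dosage, lambda = base * dosage
  )
}

#' Simulate bin counts for one maternal plasma sample
#'
#' Draws each valid bin independently from a Poisson distribution with the
#' mean given by [expected_bin_rates()]: shallow-sequencing read counts in
#' 100-kb windows are well approximated as Poisson at these depths.
#'
#' @inheritParams expected_bin_rates
#' @param sample_id Sample identifier stored on the result.
#' @return Tibble of class `nipt_counts` over valid bins with columns
#'   `chrom`, `bin`, `start`, `end`, `raw_count`, plus attributes
#'   `sample_id` and `total_reads`.
#' @examples
#' g <- make_genome_fixture(c(chrA = 40, chrX = 30), seed = 1)
#' s <- simulate_sample(g, sim_params(total_reads = 1e5, seed = 7))
#' sum(s$raw_count)
#' @export
simulate_sample <- function(genome, params, sample_id = "sim") {
  er <- expected_bin_rates(genome, params)
  if (!is.null(params$seed)) set.seed(as.integer(params$seed))
  counts <- tibble::tibble(
    chrom = er$chrom, bin = er$bin, start = er$start, end = er$end,
    raw_count = stats::rpois(nrow(er), er$lambda)
  )
  new_nipt_counts(counts, sample_id = sample_id,
                  total_reads = params$total_reads)
}

new_nipt_counts <- function(df, sample_id, total_reads = NA_real_) {
  df <- tibble::as_tibble(df)
  attr(df, "sample_id") <- sample_id
  attr(df, "total_reads") <- total_reads
  class(df) <- unique(c("nipt_counts", class(df)))
  df
}

#' Simulate a euploid reference panel
#'
#' Reference-panel samples are euploid female pregnancies with no maternal
#' CNV and fetal fraction 0, i.e. unit dosage everywhere: the background
#' against which per-bin and per-chromosome statistics are computed.
#' Per-sample seeds are derived deterministically from the master seed.
#'
#' @param genome A `nipt_genome` tibble.
#' @param n_samples Number of panel samples (at least 2; 10+ recommended).
#' @param total_reads Expected reads per sample.
#' @param seed Master integer seed.
#' @param gc_bias_amplitude As in [sim_params()].
#' @return List of `nipt_counts` tibbles.
#' @export
simulate_reference_panel <- function(genome, n_samples, total_reads = 7.5e6,
                                     seed = 1L, gc_bias_amplitude = 0.2) {
  if (n_samples < 2) rlang::abort("`n_samples` must be at least 2 (SD undefined below that).")
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
  purrr::map2(seeds, seq_len(n_samples), function(s, i) {
    p <- sim_params(fetal_fraction = 0, fetus_sex = "female",
                    total_reads = total_reads,
                    gc_bias_amplitude = gc_bias_amplitude, seed = s)
    simulate_sample(genome, p, sample_id = sprintf("panel%03d", i))
  })
}

#' The simulation study grid
#'
#' One-call description of the validation design: three screened
#' chromosomes times duplication/deletion, maternal CNV sizes 0.5-5 Mb in
#' 0.25 Mb steps, fetal fractions 5/10/15%. Returns the parameter grid as a
#' tibble; pair with [simulate_sample()] or [alpha_effect_grid()] to run it.
#'
#' @param chroms Chromosomes carrying the maternal CNV.
#' @param directions `"dup"` (cn 3) and/or `"del"` (cn 1).
#' @param sizes_mb CNV sizes in Mb.
#' @param fetal_fractions Fetal fractions.
#' @return Tibble with columns `chrom`, `direction`, `cn`, `size_mb`, `f`.
#' @export
simulation_grid <- function(chroms = c("chr13", "chr18", "chr21"),
                            directions = c("dup", "del"),
                            sizes_mb = seq(0.5, 5, by = 0.25),
                            fetal_fractions = c(0.05, 0.10, 0.15)) {
  tidyr::expand_grid(
    chrom = chroms,
    direction = directions,
    size_mb = sizes_mb,
    f = fetal_fractions
  ) |>
    dplyr::mutate(cn = ifelse(.data$direction == "dup", 3L, 1L)) |>
    dplyr::select("chrom", "direction", "cn", "size_mb", "f")
}
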