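# Shared simulation fixtures. Heavy objects are built lazily and cached for
# the session so each test file pays nothing extra.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small genome for unit tests: one background chromosome plus the three
# screened chromosomes and an X, ~535 Mb total.
test_genome <- function() {
  cached("test_genome", make_genome_fixture(
    c(chrO1 = 200, chr13 = 100, chr18 = 75, chr21 = 40, chrX = 120),
    gap_fraction = 0.05, seed = 101
  ))
}

test_reads <- 2e6

test_panel <- function(n = 30) {
  cached(sprintf("test_panel_%d", n), {
    samples <- simulate_reference_panel(test_genome(), n,
                                        total_reads = test_reads, seed = 102)
    suppressWarnings(build_reference_panel(samples, test_genome()))
  })
}

# Study-scale fixtures (hg19-like genome, deep panel) for acceptance tests.
study_genome <- function() cached("study_genome", default_genome(seed = 201))

study_reads <- 7.5e6

study_panel <- function(n = 100) {
  cached(sprintf("study_panel_%d", n), {
    samples <- simulate_reference_panel(study_genome(), n,
                                        total_reads = study_reads, seed = 202)
    suppressWarnings(build_reference_panel(samples, study_genome()))
  })
}

# Exhaustive least-squares changepoint oracle for <= 2 changepoints:
# minimises residual sum of squares over all breakpoint placements for a
# given number of changepoints. Independent of segment_signal().
oracle_breakpoints <- function(x, k, min_width = 2) {
  n <- length(x)
  S <- cumsum(x)
  S2 <- cumsum(x^2)
  seg_rss <- function(i, j) {
    s <- S[j] - if (i > 1) S[i - 1] else 0
    s2 <- S2[j] - if (i > 1) S2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  if (k == 0) return(integer())
  if (k == 1) {
    ks <- min_width:(n - min_width)
    rss <- vapply(ks, function(b) seg_rss(1, b) + seg_rss(b + 1, n), 0)
    return(ks[which.min(rss)])
  }
  best <- NULL; best_rss <- Inf
  for (b1 in min_width:(n - 2 * min_width)) {
    for (b2 in (b1 + min_width):(n - min_width)) {
      rss <- seg_rss(1, b1) + seg_rss(b1 + 1, b2) + seg_rss(b2 + 1, n)
      if (rss < best_rss) { best_rss <- rss; best <- c(b1, b2) }
    }
  }
  best
}
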