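# Shared fixtures and independent oracles for the suite.

# Small single-rate genome for unit tests.
tiny_genome <- function(n_chrom = 1, mb = 1, rate = 2, hotspots = NULL) {
  genome_spec(
    tibble::tibble(
      chrom = sprintf("c%02d", seq_len(n_chrom)),
      length_bp = round(mb * 1e6)
    ),
    rate_cm_mb = rate, hotspots = hotspots
  )
}

# Build a genotype tibble from a character matrix (markers x samples).
geno_from_calls <- function(calls, chrom = "c01", pos = NULL) {
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(n) * 1e4
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("L%03d", seq_len(ncol(calls)))
  dplyr::bind_cols(
    tibble::tibble(
      marker_id = sprintf("M%04d", seq_len(n)),
      chrom = rep_len(chrom, n),
      pos = pos
    ),
    tibble::as_tibble(calls)
  )
}

# The full-scale seeded world used by the acceptance-style checks: 200 F6
# lines on 20 chromosomes of 10 Mb with one planted fold-20 hotspot window
# (100 kb) per chromosome. Simulated once per session and cached.
full_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- scaled_peanut_genome()
      sim <- simulate_ril(genome, sim_config(
        n_lines = 200, generations = 6, n_markers = 600,
        missing_rate = 0.05, seed = 42
      ))
      events <- call_crossovers(segment_blocks(sim$genotypes))
      cache <<- list(genome = genome, sim = sim, events = events)
    }
    cache
  }
})

# Hotspot-free world with a realistic (1 cM/Mb) uniform landscape: 200 F6
# lines on 3 chromosomes of 50 Mb. Crossovers here are sparse enough that
# the flank/small-block filters barely bite, matching the regime the
# recovery guarantees are stated for.
sparse_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- genome_spec(
        tibble::tibble(
          chrom = sprintf("chr%02d", 1:3), length_bp = 50e6
        ),
        rate_cm_mb = 1
      )
      sim <- simulate_ril(genome, sim_config(
        n_lines = 200, generations = 6, n_markers = 600,
        missing_rate = 0.05, seed = 314
      ))
      events <- call_crossovers(segment_blocks(sim$genotypes))
      cache <<- list(genome = genome, sim = sim, events = events)
    }
    cache
  }
})

# --- independent oracles ---------------------------------------------------

# Poisson upper-tail threshold by explicit pmf summation (no ppois).
bf_poisson_threshold <- function(lambda, alpha) {
  kmax <- 500L
  pmf <- exp(-lambda + (0:kmax) * log(lambda) - lgamma((0:kmax) + 1))
  tail_p <- rev(cumsum(rev(pmf))) # P(X >= k), k = 0..kmax (truncated)
  which(tail_p <= alpha)[1] - 1L
}

# Plain-loop evaluation of the G statistic and mLOD transform.
bf_g <- function(o, e) {
  s <- 0
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(ncol(o))) {
      if (o[i, j] > 0) s <- s + o[i, j] * log(o[i, j] / e[i, j])
    }
  }
  sqrt(2 * s)
}
bf_mlod <- function(G, d) {
  q <- exp(-(G * G) / (2 * (d - 1)))
  (((4 - q) * q - 3) * (d - 1) + G * G) / (2 * log(10))
}

# Brute-force recombination fraction between two marker rows.
bf_recfrac <- function(x, y) {
  ok <- x %in% c("a", "b") & y %in% c("a", "b")
  if (!any(ok)) return(NA_real_)
  mean(x[ok] != y[ok])
}
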