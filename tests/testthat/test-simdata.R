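test_that("zero-rate landscape yields a crossover-free gamete equal to one input", {
  g <- tiny_genome(n_chrom = 2, mb = 5, rate = 0)
  parents <- parental_haplotypes(g)
  set.seed(1)
  gam <- simulate_gamete(parents, g)
  expect_equal(nrow(gam$crossovers), 0)
  for (ch in names(gam$haplotype)) {
    h <- gam$haplotype[[ch]]
    expect_length(h$alleles, 1)
    expect_true(h$alleles %in% c("a", "b"))
  }
})

test_that("crossover counts are Poisson with the landscape's genetic length as mean", {
  # 100 Mb at 1 cM/Mb -> 1 Morgan -> mean 1 crossover per gamete
  g <- tiny_genome(n_chrom = 1, mb = 100, rate = 1)
  expect_equal(chrom_genetic_length(g)$morgans, 1)
  parents <- parental_haplotypes(g)
  set.seed(99)
  counts <- vapply(
    seq_len(10000),
    function(i) nrow(simulate_gamete(parents, g)$crossovers),
    numeric(1)
  )
  # 3-sigma band around the Poisson mean (sd/sqrt(n) = 0.01)
  expect_gt(mean(counts), 0.97)
  expect_lt(mean(counts), 1.03)
  # goodness of fit against Poisson(1) at alpha = 0.01
  kmax <- max(counts)
  obs <- tabulate(counts + 1, nbins = kmax + 1)
  p <- dpois(0:kmax, 1)
  p[kmax + 1] <- p[kmax + 1] + ppois(kmax, 1, lower.tail = FALSE)
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("crossovers concentrate in hotspots per the landscape-mass ratio", {
  # fold-10 hotspot over 1% of the chromosome: expected share
  # 0.1 / (0.99 + 0.1) ~ 9.17% of all crossovers
  g <- tiny_genome(
    n_chrom = 1, mb = 10, rate = 1,
    hotspots = data.frame(chrom = "c01", start = 4e6, end = 41e5, fold = 10)
  )
  share_expected <- (0.1 * 10) / (9.9 * 1 + 0.1 * 10) # mass ratio = 1/10.9
  expect_equal(share_expected, 0.1 / 1.09, tolerance = 1e-12)
  parents <- parental_haplotypes(g)
  set.seed(7)
  pos <- unlist(lapply(seq_len(4000), function(i) {
    simulate_gamete(parents, g)$crossovers$pos
  }))
  share <- mean(pos >= 4e6 & pos < 41e5)
  expect_equal(share, 0.1 / 1.09, tolerance = 0.15)
})

test_that("F2 heterozygosity is 1/2 and selfing halves it each generation", {
  g <- tiny_genome(n_chrom = 2, mb = 5, rate = 10)
  sim <- simulate_ril(g, sim_config(
    n_lines = 150, generations = 2, n_markers = 200,
    missing_rate = 0, seed = 11
  ))
  m <- as.matrix(sim$genotypes[, sample_ids(sim$genotypes)])
  expect_equal(mean(m == "h"), 0.5, tolerance = 0.12)

  sim4 <- simulate_ril(g, sim_config(
    n_lines = 150, generations = 4, n_markers = 200,
    missing_rate = 0, seed = 11
  ))
  m4 <- as.matrix(sim4$genotypes[, sample_ids(sim4$genotypes)])
  expect_equal(mean(m4 == "h"), 0.5^3, tolerance = 0.25)
})

test_that("RIL simulation is deterministic under a fixed seed", {
  g <- tiny_genome(n_chrom = 2, mb = 2)
  cfg <- sim_config(n_lines = 10, n_markers = 50, seed = 123)
  s1 <- simulate_ril(g, cfg)
  s2 <- simulate_ril(g, cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth, s2$truth)
})

test_that("truth track conserves crossover counts and orders positions", {
  w <- sparse_world()
  bp <- w$sim$truth$breakpoints
  per <- dplyr::count(bp, sample, chrom)
  expect_equal(sum(per$n), nrow(bp))
  ordered <- bp %>%
    dplyr::group_by(sample, chrom, hap) %>%
    dplyr::summarise(ok = !is.unsorted(pos, strictly = TRUE), .groups = "drop")
  expect_true(all(ordered$ok))
  # meioses across the pedigree are at least as many as surviving breakpoints
  expect_gte(nrow(w$sim$truth$meioses), nrow(bp))
})

test_that("single-founder panels are uniform with zero switch points", {
  g <- tiny_genome(n_chrom = 1, mb = 2)
  p <- simulate_panel(g,
    n_founders = 1,
    cfg = sim_config(n_lines = 8, n_markers = 60, missing_rate = 0, seed = 5),
    filter = FALSE
  )
  expect_equal(nrow(p$truth$breakpoints), 0)
  calls <- as.matrix(p$genotypes[, sample_ids(p$genotypes)])
  expect_true(all(calls == calls[, 1]))
})

test_that("a landscape concentrated in one window confines switch points to it", {
  g <- tiny_genome(
    n_chrom = 1, mb = 1, rate = 1e-4,
    hotspots = data.frame(chrom = "c01", start = 4e5, end = 5e5, fold = 1e6)
  )
  p <- simulate_panel(g,
    n_founders = 4,
    cfg = sim_config(n_lines = 10, n_markers = 100, missing_rate = 0, seed = 3),
    historical_meioses = 10, filter = FALSE
  )
  sw <- p$truth$breakpoints
  expect_gt(nrow(sw), 0)
  expect_true(all(sw$pos >= 4e5 & sw$pos < 5e5))
})

test_that("panel output is reproducible and respects the emission filters", {
  g <- tiny_genome(n_chrom = 2, mb = 5)
  cfg <- sim_config(n_lines = 49, n_markers = 150, missing_rate = 0.1, seed = 17)
  p1 <- simulate_panel(g, n_founders = 6, cfg = cfg)
  p2 <- simulate_panel(g, n_founders = 6, cfg = cfg)
  expect_identical(nrow(p1$genotypes), nrow(p2$genotypes))
  expect_identical(p1$genotypes, p2$genotypes)
  # emitted markers all satisfy the panel filters
  refiltered <- filter_panel_markers(p1$genotypes)
  expect_identical(refiltered, p1$genotypes)
  expect_lt(nrow(p1$genotypes), 300) # some markers dropped
})

test_that("degenerate configurations are rejected up front", {
  expect_error(sim_config(generations = 1), "generations")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_markers = 0), "unobservable")
  expect_error(
    genome_spec(data.frame(chrom = "c1", length_bp = 0)),
    "zero-length"
  )
  expect_error(
    genome_spec(
      data.frame(chrom = "c1", length_bp = 100),
      hotspots = data.frame(chrom = "c1", start = 50, end = 200, fold = 2)
    ),
    "within"
  )
  expect_error(
    genome_spec(
      data.frame(chrom = "c1", length_bp = 1000),
      hotspots = data.frame(chrom = "c1", start = 10, end = 20, fold = 0.5)
    ),
    "fold"
  )
})
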