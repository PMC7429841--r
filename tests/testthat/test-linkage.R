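test_that("G statistic matches hand-computed values and its scaling law", {
  o <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  expect_equal(g_statistic(o), 4.574924, tolerance = 1e-6)
  expect_equal(g_statistic(o, classic = TRUE), 4.574924^2, tolerance = 1e-5)
  # independence -> 0
  e <- matrix(c(20, 20, 20, 20), 2)
  expect_equal(g_statistic(e), 0)
  # scaling all o and e by 10 multiplies G by sqrt(10)
  expect_equal(g_statistic(10 * o), sqrt(10) * g_statistic(o))
  expect_error(g_statistic(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  # zero cells contribute zero under the limit convention
  oz <- matrix(c(0, 10, 10, 0), 2)
  expect_true(is.finite(g_statistic(oz)))
})

test_that("mLOD transform evaluates, vanishes at G = 0 and increases in G", {
  expect_equal(mlod(0, 2), 0)
  expect_equal(mlod(0, 7), 0)
  expect_equal(mlod(3, 2), 1.312506, tolerance = 1e-6)
  for (d in c(2, 4, 9)) {
    vals <- mlod(seq(0.1, 20, by = 0.1), d)
    expect_true(all(diff(vals) > 0))
  }
  # large-G asymptote (G^2 - 3(d-1)) / (2 ln 10)
  expect_equal(mlod(50, 4), (2500 - 9) / (2 * log(10)), tolerance = 1e-10)
  expect_error(mlod(3, 1), "d")
  expect_error(mlod(-1, 3), "G")
})

test_that("G and mLOD agree with an independent plain-loop evaluation", {
  set.seed(31)
  for (rep in seq_len(100)) {
    nr <- sample(2:3, 1)
    nc <- sample(2:3, 1)
    o <- matrix(rpois(nr * nc, 12) + 1, nr, nc)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    G <- g_statistic(o)
    expect_equal(G, bf_g(o, e), tolerance = 1e-10)
    d <- (nr - 1) * (nc - 1) + 1 # any valid df >= 2
    expect_equal(mlod(G, d), bf_mlod(G, d), tolerance = 1e-10)
  }
})

test_that("single-linkage grouping separates chromosomes and matches graph components", {
  sim <- simulate_ril(
    tiny_genome(n_chrom = 2, mb = 5, rate = 3),
    sim_config(n_lines = 60, n_markers = 12, missing_rate = 0, seed = 21)
  )
  lg <- group_markers(sim$genotypes, threshold = 3)
  tg <- tidy(lg)
  expect_equal(dplyr::n_distinct(tg$lg), 2)
  # groups coincide with physical chromosomes
  expect_equal(dplyr::n_distinct(paste(tg$chrom, tg$lg)), 2)
  expect_equal(glance(lg)$n_markers, 24)

  # an absurd threshold isolates every marker
  lg_inf <- group_markers(sim$genotypes, threshold = 1e6)
  expect_equal(dplyr::n_distinct(tidy(lg_inf)$lg), 24)

  # oracle: connected components of the thresholded mLOD graph (igraph)
  skip_if_not_installed("igraph")
  m <- lg$mlod
  adj <- (m >= 3) * 1
  diag(adj) <- 0
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  )$membership
  split_pkg <- split(tg$marker_id, tg$lg)
  split_ora <- split(rownames(m), comp)
  canon <- function(s) unname(lapply(s[order(vapply(s, min, ""))], sort))
  expect_equal(canon(split_pkg), canon(split_ora))
})

test_that("genetic distances follow the RIL correction and mapping functions", {
  # identical columns -> 0 cM
  same <- geno_from_calls(matrix(rep(c("a", "b"), each = 2, times = 5), nrow = 2))
  d0 <- genetic_distances(same)
  expect_equal(d0$cm, c(0, 0))

  # exactly 2 recombinant of 10 informative lines: R = 0.2
  x <- rep(c("a", "b"), each = 5)
  y <- c(rep("a", 4), "b", "a", rep("b", 4)) # differs in positions 5 and 6
  gm <- geno_from_calls(rbind(x, y))
  dh <- genetic_distances(gm, mapping = "haldane", ril_correction = TRUE)
  # r = 0.2 / 1.6 = 0.125; Haldane -50 ln(0.75) = 14.384
  expect_equal(dh$r_obs[2], 0.2)
  expect_equal(dh$cm[2], -50 * log(0.75), tolerance = 1e-9)
  dk <- genetic_distances(gm, mapping = "kosambi", ril_correction = TRUE)
  expect_equal(dk$cm[2], 25 * log(1.25 / 0.75), tolerance = 1e-9)
  # without correction, r = R = 0.2
  dn <- genetic_distances(gm, ril_correction = FALSE)
  expect_equal(dn$cm[2], -50 * log(0.6), tolerance = 1e-9)

  # saturated pair capped with a warning
  z <- rev(x) # perfectly repulsed: R = 1 -> r capped
  expect_warning(genetic_distances(geno_from_calls(rbind(x, z))), "capped")
})

test_that("finite-generation RIL theory matches F2 closed form and simulation", {
  # F2: conditional recombinant fraction among double homozygotes is
  # r^2 / (r^2 + (1-r)^2)
  for (r in c(0.01, 0.1, 0.3)) {
    expect_equal(
      ril_expected_r(r, 2), r^2 / (r^2 + (1 - r)^2),
      tolerance = 1e-12
    )
  }
  # F6 realises ~85.6% of the fully inbred expansion (frozen from an
  # independent 400k-line Monte Carlo of the two-locus selfing process)
  expect_equal(
    ril_expected_r(0.01, 6) / (2 * 0.01 / 1.02), 0.856,
    tolerance = 0.02
  )
  # large generation count converges to 2r/(1+2r)
  expect_equal(ril_expected_r(0.1, 40), 0.2 / 1.2, tolerance = 1e-8)
})

test_that("a dense F6 map recovers the simulated genome length", {
  w <- sparse_world()
  gm <- filter_map_markers(w$sim$genotypes)
  map6 <- genetic_distances(gm, generations = 6)
  truth_cm <- sum(chrom_genetic_length(w$genome)$cm)
  rec6 <- sum(dplyr::summarise(dplyr::group_by(map6, lg), cm = max(cm))$cm)
  expect_lt(abs(rec6 - truth_cm) / truth_cm, 0.15)
  # the fully-inbred closed form is systematically shorter at F6
  mapinf <- genetic_distances(gm)
  recinf <- sum(dplyr::summarise(dplyr::group_by(mapinf, lg), cm = max(cm))$cm)
  expect_lt(recinf, rec6)
})

test_that("map summaries compute lengths, gaps and densities", {
  map <- tibble::tibble(
    marker_id = sprintf("m%d", 1:5),
    lg = c(rep("LG01", 4), "LG02"),
    cm = c(0, 2, 8, 9, 0)
  )
  ms <- map_summary(map, c(LG01 = 2, LG02 = 1))
  lg1 <- ms[ms$lg == "LG01", ]
  expect_equal(lg1$n_markers, 4)
  expect_equal(lg1$genetic_length_cm, 9)
  expect_equal(lg1$max_gap_cm, 6)
  expect_equal(lg1$gap_lt5_pct, 100 * 2 / 3)
  expect_equal(lg1$density_markers_cm, 4 / 9)
  expect_equal(lg1$markers_per_mb, 2)
  expect_equal(lg1$cm_per_mb, 4.5)
  # single-marker group: gaps and density undefined
  lg2 <- ms[ms$lg == "LG02", ]
  expect_true(is.na(lg2$max_gap_cm) && is.na(lg2$genetic_length_cm))
  expect_error(map_summary(map[0, ]), "empty")
})

test_that("pairwise recombination fractions match brute-force counting", {
  # self distance zero; perfect repulsion one
  x <- rep(c("a", "b"), each = 5)
  gm2 <- geno_from_calls(rbind(x, rev(x)))
  pr <- pairwise_recfrac(gm2, min_lines = 5)
  expect_equal(pr$recfrac[pr$marker1 == pr$marker2], c(0, 0))
  expect_equal(pr$recfrac[pr$marker1 != pr$marker2], 1)

  sim <- simulate_ril(
    tiny_genome(mb = 3, rate = 5),
    sim_config(n_lines = 50, n_markers = 20, missing_rate = 0.1, seed = 77)
  )
  pr <- pairwise_recfrac(sim$genotypes)
  calls <- as.matrix(sim$genotypes[, sample_ids(sim$genotypes)])
  rownames(calls) <- sim$genotypes$marker_id
  for (k in sample(nrow(pr), 40)) {
    expect_equal(
      pr$recfrac[k],
      bf_recfrac(calls[pr$marker1[k], ], calls[pr$marker2[k], ])
    )
  }
  # unreliable flag for sparse pairs
  sp <- matrix("-", 2, 20)
  sp[1, 1:5] <- "a"
  sp[2, 1:5] <- c("a", "a", "b", "a", "a")
  prs <- pairwise_recfrac(geno_from_calls(sp), min_lines = 10)
  expect_false(any(prs$reliable[prs$marker1 != prs$marker2]))
})
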