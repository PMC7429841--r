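test_that("window grids tile each chromosome exactly once", {
  g <- genome_spec(data.frame(
    chrom = c("c1", "c2"), length_bp = c(1.23e6, 4e5)
  ))
  win <- make_windows(g, 1e5)
  expect_equal(sum(win$chrom == "c1"), 13) # last window truncated
  expect_equal(max(win$end[win$chrom == "c1"]), 1.23e6)
  by_chrom <- split(win, win$chrom)
  for (w in by_chrom) {
    expect_true(all(w$start[-1] == utils::head(w$end, -1))) # no gap/overlap
  }
  expect_equal(sum(win$end - win$start), sum(g$chromosomes$length_bp))
  expect_error(make_windows(g, 0), "width")
})

test_that("events land in the window containing their breakpoint midpoint", {
  g <- tiny_genome(n_chrom = 1, mb = 1)
  ev <- tibble::tibble(
    chrom = "c01", start = 1.4e5, end = 1.6e5, status = "pass", sample = "L001"
  )
  tr <- window_counts(ev, g, 1e5)
  expect_equal(tr$n[tr$start == 1e5], 1)
  expect_equal(sum(tr$n), 1)
  # no events -> all-zero track
  tr0 <- window_counts(ev[0, ], g, 1e5)
  expect_true(all(tr0$n == 0))
})

test_that("window counts conserve passing events and rates average exactly", {
  w <- sparse_world()
  tr <- window_rates(window_counts(w$events, w$genome, 1e5))
  expect_equal(sum(tr$n), sum(w$events$status == "pass"))
  widths_mb <- (tr$end - tr$start) / 1e6
  expect_equal(
    sum(tr$rate * widths_mb) / sum(widths_mb),
    attr(tr, "mean_rate")
  )
  expect_true(all(tr$rate[tr$n == 0] == 0))
  # per-sample normalisation just rescales
  trs <- window_rates(window_counts(w$events, w$genome, 1e5), n_samples = 200)
  expect_equal(trs$rate * 200, tr$rate)
})

test_that("the recovered rate track correlates with the planted landscape", {
  w <- full_world()
  tr <- window_rates(window_counts(w$events, w$genome, 1e5))
  segs <- landscape_segments(w$genome)
  truth_rate <- purrr::map2_dbl(tr$chrom, tr$start, function(ch, s) {
    seg <- segs[segs$chrom == ch & segs$start <= s & segs$end > s, ]
    seg$rate_cm_mb[1]
  })
  expect_gt(cor(tr$rate, truth_rate), 0.8)
})

test_that("count-length correlation matches the closed-form Pearson formula", {
  expect_equal(
    unname(tidy(length_correlation(1:10 * 3, 1:10))$estimate), 1
  )
  expect_error(length_correlation(rep(2, 5), 1:5), "Constant")
  expect_error(length_correlation(1:2, 1:2), ">= 3")

  set.seed(12)
  x <- rpois(15, 800)
  y <- runif(15, 40, 150)
  td <- tidy(length_correlation(x, y))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(13 / (1 - r^2))
  expect_equal(unname(td$estimate), r, tolerance = 1e-12)
  expect_equal(td$p.value, 2 * pt(-abs(tstat), 13), tolerance = 1e-12)
  expect_equal(td$df, 13)
})

test_that("conservation scores the modal-haplotype line fraction per window", {
  g <- tiny_genome(n_chrom = 1, mb = 0.4)
  win <- make_windows(g, 2e5)
  # window 1: all 6 lines identical -> 1; window 2: 3 a-lines vs 3 b-lines -> 0.5
  calls <- rbind(
    rep("a", 6), rep("a", 6), # markers in window 1
    c("a", "a", "a", "b", "b", "b"), c("a", "a", "a", "b", "b", "b")
  )
  gm <- geno_from_calls(calls, pos = c(5e4, 1e5, 2.5e5, 3e5))
  cs <- conservation_score(gm, win)
  expect_equal(cs$conservation, c(1, 0.5))
  # windows without markers are unscored
  win3 <- make_windows(tiny_genome(n_chrom = 1, mb = 0.6), 2e5)
  cs3 <- conservation_score(gm, win3)
  expect_true(is.na(cs3$conservation[3]))
})

test_that("conservation anticorrelates with the switch-point landscape in a panel", {
  # 2 cM/Mb baseline with fold-50 hotspot windows: roughly half of all
  # historical switch points land in the four planted 100-kb hotspots
  g <- genome_spec(
    tibble::tibble(chrom = c("c01", "c02"), length_bp = 1e7),
    rate_cm_mb = 2,
    hotspots = tidyr::expand_grid(
      chrom = c("c01", "c02"), start = c(2.4e6, 6.4e6)
    ) %>% dplyr::mutate(end = start + 1e5, fold = 50)
  )
  p <- simulate_panel(g,
    n_founders = 6,
    cfg = sim_config(n_lines = 49, n_markers = 400, missing_rate = 0.02, seed = 8),
    historical_meioses = 20
  )
  win <- make_windows(g, 1e6)
  sw <- p$truth$breakpoints
  rate <- window_counts(
    tibble::tibble(chrom = sw$chrom, start = sw$pos, end = sw$pos),
    g, 1e6, status = NULL
  )
  cons <- conservation_score(p$genotypes, win)
  ok <- !is.na(cons$conservation)
  rho <- cor(cons$conservation[ok], rate$n[ok], method = "spearman")
  expect_lt(rho, 0)
})

test_that("window map rates integrate the genetic map over each window", {
  g <- tiny_genome(n_chrom = 1, mb = 1)
  # linear map: 10 cM over 1 Mb -> every full window 1 cM / 0.1 Mb = 10 cM/Mb
  map <- tibble::tibble(
    chrom = "c01", pos = seq(0, 1e6, length.out = 11),
    cm = seq(0, 10, length.out = 11)
  )
  tr <- window_map_rates(map, g, 1e5)
  expect_equal(tr$rate, rep(10, 10), tolerance = 1e-9)
})
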