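make_blocks <- function(spans, states, sample = "L001", chrom = "c01",
                        gap = 2000) {
  # consecutive blocks tiling [0, sum(spans)); breakpoint markers `gap` bp
  # inside each block edge
  end <- cumsum(spans)
  start <- c(0, utils::head(end, -1))
  tibble::tibble(
    sample = sample, chrom = chrom, start = start, end = end,
    state = states, n_markers = 5L,
    first_marker = start + gap, last_marker = end - gap
  )
}

test_that("block segmentation merges runs and skips missing calls", {
  gm <- geno_from_calls(matrix(c("a", "a", "a"), ncol = 1),
    pos = c(1e4, 2e4, 3e4)
  )
  b <- segment_blocks(gm)
  expect_equal(nrow(b), 1)
  expect_equal(b$state, "a")
  expect_equal(b$n_markers, 3L)
  expect_equal(c(b$start, b$end), c(1e4, 3e4 + 1))

  # a, -, a, b: missing skipped, boundary at midpoint of markers 3 and 4
  gm2 <- geno_from_calls(matrix(c("a", "-", "a", "b"), ncol = 1),
    pos = c(1e4, 2e4, 3e4, 4e4)
  )
  b2 <- segment_blocks(gm2)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$state, c("a", "b"))
  expect_equal(b2$n_markers, c(2L, 1L))
  expect_equal(b2$end[1], floor((3e4 + 4e4) / 2))
  expect_equal(b2$start[2], b2$end[1])

  # all-missing chromosome yields no blocks
  gm3 <- geno_from_calls(matrix("-", 3, 2))
  expect_message(b3 <- segment_blocks(gm3), "No non-missing")
  expect_equal(nrow(b3), 0)
})

test_that("crossover calling applies flank-span and small-block rules", {
  # single block: no events
  expect_equal(nrow(call_crossovers(make_blocks(5e5, "a"))), 0)

  # a(50 kb) | b(5 kb) | a(50 kb): both transitions fail the 10 kb flank rule
  ev <- call_crossovers(make_blocks(c(5e4, 5e3, 5e4), c("a", "b", "a"), gap = 500))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$status, c("flank_fail", "flank_fail"))
  expect_equal(sum(ev$status == "pass"), 0)

  # flank of exactly 10 kb passes the flank rule but is a small block
  ev2 <- call_crossovers(make_blocks(c(5e5, 1e4, 5e5), c("a", "h", "a"), gap = 100))
  expect_equal(ev2$status, c("small_block_flag", "small_block_flag"))
  expect_equal(nrow(call_crossovers(
    make_blocks(c(5e5, 1e4, 5e5), c("a", "h", "a"), gap = 100),
    drop_small_blocks = TRUE
  )), 0)

  # block just above the small-block limit passes
  ev3 <- call_crossovers(make_blocks(c(5e5, 2e5 + 1, 5e5), c("a", "b", "a"), gap = 100))
  expect_equal(ev3$status, c("pass", "pass"))
  # breakpoint interval spans the flanking markers
  expect_equal(ev3$start[1], 5e5 - 100)
  expect_equal(ev3$end[1], 5e5 + 100)

  # heterozygous state on both sides is ambiguous
  amb <- call_crossovers(make_blocks(c(5e5, 5e5), c("h", "h"), gap = 100))
  expect_equal(amb$status, "ambiguous_excluded")
})

test_that("raising the flank threshold never increases passing events", {
  w <- sparse_world()
  blocks <- segment_blocks(w$sim$genotypes, samples = sprintf("L%03d", 1:40))
  n_pass <- vapply(
    c(0, 5e3, 1e4, 5e4, 1e5, 5e5),
    function(f) sum(call_crossovers(blocks, min_flank_span = f)$status == "pass"),
    numeric(1)
  )
  expect_true(all(diff(n_pass) <= 0))
})

test_that("event counts are conserved across grouping levels", {
  w <- sparse_world()
  ev <- w$events
  total <- count_events(ev, "genome")$n_events
  expect_equal(sum(count_events(ev, "sample")$n_events), total)
  expect_equal(sum(count_events(ev, "chrom")$n_events), total)
  # brute-force recount
  expect_equal(total, sum(ev$status == "pass"))
  # empty input
  expect_equal(count_events(ev[0, ], "genome")$n_events, 0)
})

test_that("with filters off and dense markers, blocks and events recover the truth track", {
  genome <- tiny_genome(n_chrom = 1, mb = 5, rate = 20)
  sim <- simulate_ril(genome, sim_config(
    n_lines = 40, n_markers = 2500, missing_rate = 0, seed = 6
  ))
  blocks <- segment_blocks(sim$genotypes)
  ev <- call_crossovers(blocks, min_flank_span = 0, small_block = 0)
  truth <- sim$truth$breakpoints %>%
    dplyr::distinct(sample, chrom, pos) %>%
    dplyr::count(sample, name = "n_true")
  got <- dplyr::count(ev, sample, name = "n_seen")
  cmp <- dplyr::full_join(truth, got, by = "sample") %>%
    dplyr::mutate(dplyr::across(c(n_true, n_seen), ~ tidyr::replace_na(.x, 0L)))
  expect_equal(cmp$n_seen, cmp$n_true)
  # block count per sample = switches + 1
  nb <- dplyr::count(blocks, sample, name = "n_blocks")
  cmp2 <- dplyr::left_join(cmp, nb, by = "sample")
  expect_equal(cmp2$n_blocks, cmp2$n_true + 1L)
})

test_that("passing events per line track the truth mean in a dense F6", {
  w <- sparse_world()
  per_line <- count_events(w$events, "sample")$n_events
  truth_per_line <- w$sim$truth$breakpoints %>%
    dplyr::distinct(sample, chrom, pos) %>%
    dplyr::count(sample) %>%
    dplyr::pull(n)
  expect_lt(abs(mean(per_line) - mean(truth_per_line)) / mean(truth_per_line), 0.1)
})
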