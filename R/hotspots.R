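#' Poisson count threshold for hotspot windows
#'
#' Smallest integer `k*` whose upper-tail probability under a Poisson null
#' with mean `lambda` (the genome-mean events per window) does not exceed
#' `alpha`: windows with at least `k*` events are unlikely (at level
#' `alpha`) to arise from the uniform background.
#'
#' @param lambda Mean events per window, > 0.
#' @param alpha Tail probability, in (0, 1).
#' @return Integer `k*` = min k such that P(X >= k) <= alpha.
#' @examples
#' poisson_threshold(2, 0.01) # 7
#' @export
poisson_threshold <- function(lambda, alpha = 0.01) {
  if (lambda <= 0) abort("`lambda` must be positive.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1).")
  k <- 0L
  # P(X >= k) = ppois(k - 1, lambda, lower.tail = FALSE); P(X >= 0) = 1
  while (ppois(k - 1, lambda, lower.tail = FALSE) > alpha) k <- k + 1L
  k
}

new_hotspot_calls <- function(track, fired, rule, threshold) {
  out <- as_tibble(track)[fired, , drop = FALSE] %>%
    mutate(rules_fired = rule, threshold = threshold)
  class(out) <- c("hotspot_calls", class(out))
  out
}

#' Call hotspot windows by Poisson threshold
#'
#' Flags windows whose event count reaches the [poisson_threshold()] for
#' the track's mean count per window. `bonferroni = TRUE` divides `alpha`
#' by the number of windows.
#'
#' @param track A [window_counts()] track (column `n`).
#' @param alpha Tail probability.
#' @param bonferroni Correct `alpha` for the number of windows.
#' @return A `hotspot_calls` tibble (the flagged windows with
#'   `rules_fired = "poisson"` and the count threshold used).
#' @export
call_poisson_hotspots <- function(track, alpha = 0.01, bonferroni = FALSE) {
  track <- as_tibble(track)
  lambda <- mean(track$n)
  a <- if (bonferroni) alpha / nrow(track) else alpha
  k <- poisson_threshold(lambda, a)
  new_hotspot_calls(track, track$n >= k, "poisson", k)
}

#' Call hotspot windows by fold over the genome mean rate
#'
#' Flags windows whose rate is at least `fold` times the genome mean rate
#' (`mode = "derived"`), or at least a fixed literal threshold
#' (`mode = "paper"`, default 25 events/Mb — the published "threefold of
#' average" cutoff for a 49-accession panel averaging 8.40 n/Mb).
#'
#' @param track A [window_rates()] track (column `rate`; attribute
#'   `mean_rate` used when present).
#' @param fold Fold over the mean (derived mode).
#' @param mode `"derived"` or `"paper"`.
#' @param fixed_threshold Literal rate threshold for paper mode.
#' @return A `hotspot_calls` tibble with `rules_fired = "fold3x"`.
#' @export
call_fold_hotspots <- function(track, fold = 3, mode = c("derived", "paper"),
                               fixed_threshold = 25) {
  mode <- match.arg(mode)
  tr <- as_tibble(track)
  if (!"rate" %in% names(tr)) abort("`track` needs a `rate` column; see window_rates().")
  mean_rate <- attr(track, "mean_rate") %||%
    (sum(tr$n) / sum((tr$end - tr$start) / 1e6))
  thr <- switch(mode, derived = fold * mean_rate, paper = fixed_threshold)
  new_hotspot_calls(tr, !is.na(tr$rate) & tr$rate >= thr, "fold3x", thr)
}

#' Call RIL hotspot windows by absolute map rate
#'
#' Flags windows whose map-based rate is strictly greater than `threshold`
#' cM/Mb (default 50, the RIL-population hotspot definition).
#'
#' @param track A [window_map_rates()] track (column `rate`, cM/Mb).
#' @param threshold Strict lower bound in cM/Mb.
#' @return A `hotspot_calls` tibble with `rules_fired = "ril50"`.
#' @export
call_ril_hotspots <- function(track, threshold = 50) {
  tr <- as_tibble(track)
  if (!"rate" %in% names(tr)) abort("`track` needs a `rate` column.")
  new_hotspot_calls(tr, !is.na(tr$rate) & tr$rate > threshold, "ril50", threshold)
}

#' Multi-principle consensus hotspots
#'
#' Combines the four published principles on a shared window grid: (1) a
#' weakly conserved marker-haplotype region (conservation below the
#' `conservation_q` quantile), (2) RIL map rate > 50 cM/Mb, (3) weak
#' pairwise linkage in the heat map (mean within-window recombination
#' fraction above the `weakness_q` quantile), and (4) panel rate at least
#' `panel_fold` times the panel mean. Each criterion can be toggled; a
#' window is a consensus hotspot iff every enabled criterion holds, so the
#' consensus set is contained in each component set.
#'
#' @param ril_track [window_map_rates()] track of the RIL map (cM/Mb).
#' @param panel_track [window_rates()] track of the panel (n/Mb).
#' @param conservation [conservation_score()] output on the same grid.
#' @param weakness [window_linkage_weakness()] output on the same grid.
#' @param ril_threshold Strict cM/Mb cutoff for the RIL rule.
#' @param panel_fold Fold over the panel mean rate.
#' @param conservation_q,weakness_q Quantiles defining "low" conservation
#'   and "high" weakness.
#' @param use Character subset of
#'   `c("conservation", "ril50", "weakness", "panel_fold")` to enable.
#' @return A `hotspot_calls` tibble; `rules_fired` concatenates the
#'   enabled criteria.
#' @export
consensus_hotspots <- function(ril_track, panel_track, conservation, weakness,
                               ril_threshold = 50, panel_fold = 3,
                               conservation_q = 0.25, weakness_q = 0.75,
                               use = c("conservation", "ril50", "weakness", "panel_fold")) {
  use <- match.arg(use, several.ok = TRUE)
  grids <- list(ril_track, panel_track, conservation, weakness)
  key <- function(x) paste(x$chrom, x$start, x$end)
  k0 <- key(as_tibble(grids[[1]]))
  for (g in grids[-1]) {
    if (!identical(key(as_tibble(g)), k0)) {
      abort("All component tracks must share one window grid (same chrom/start/end rows).")
    }
  }
  ok <- rep(TRUE, length(k0))
  if ("conservation" %in% use) {
    cut <- stats::quantile(conservation$conservation, conservation_q, na.rm = TRUE)
    ok <- ok & !is.na(conservation$conservation) & conservation$conservation <= cut
  }
  if ("ril50" %in% use) {
    ok <- ok & !is.na(ril_track$rate) & ril_track$rate > ril_threshold
  }
  if ("weakness" %in% use) {
    cut <- stats::quantile(weakness$weakness, weakness_q, na.rm = TRUE)
    ok <- ok & !is.na(weakness$weakness) & weakness$weakness >= cut
  }
  if ("panel_fold" %in% use) {
    mean_rate <- attr(panel_track, "mean_rate") %||% mean(panel_track$rate, na.rm = TRUE)
    ok <- ok & !is.na(panel_track$rate) & panel_track$rate >= panel_fold * mean_rate
  }
  out <- as_tibble(panel_track)[ok, c("chrom", "start", "end"), drop = FALSE] %>%
    mutate(
      panel_rate = panel_track$rate[ok],
      ril_rate = ril_track$rate[ok],
      rules_fired = paste(use, collapse = "+"),
      threshold = NA_real_
    )
  class(out) <- c("hotspot_calls", class(out))
  out
}

#' Hotspot fraction of total regions
#'
#' Percentage of regions (or events) that are hotspots, reported to two
#' decimals — e.g. 210 hotspot loci among 4837 crossover events is 4.34%.
#'
#' @param calls A `hotspot_calls` tibble or an integer count.
#' @param total Total number of regions/events, > 0.
#' @return Percentage rounded to 2 decimals.
#' @export
hotspot_fraction <- function(calls, total) {
  if (total <= 0) abort("`total` must be positive.")
  n <- if (is.data.frame(calls)) nrow(calls) else as.numeric(calls)
  round(100 * n / total, 2)
}
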