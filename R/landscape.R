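#' Fixed-width window grid over a genome
#'
#' Non-overlapping windows of `width` bp tiling each chromosome, 0-based
#' half-open, the last window truncated at the chromosome end.
#'
#' @param genome A [genome_spec()].
#' @param width Window width in bp (100 kb for event-locus scans, 1000 kb
#'   for rate landscapes).
#' @return Tibble `chrom`, `start`, `end`.
#' @export
make_windows <- function(genome, width = 1e5) {
  stopifnot(inherits(genome, "genome_spec"))
  if (width <= 0) abort("`width` must be positive.")
  purrr::pmap_dfr(
    genome$chromosomes[, c("chrom", "length_bp")],
    function(chrom, length_bp) {
      start <- seq(0, length_bp - 1, by = width)
      tibble(chrom = chrom, start = start, end = pmin(start + width, length_bp))
    }
  )
}

#' Windowed crossover counts
#'
#' Assigns each passing crossover event to exactly one window by the
#' midpoint of its breakpoint interval and counts events per window, so
#' window counts sum to the number of passing events.
#'
#' @param events Output of [call_crossovers()] (or any tibble with `chrom`,
#'   `start`, `end` and optionally `status`/`sample`).
#' @param genome A [genome_spec()].
#' @param width Window width in bp.
#' @param status Event statuses to count (default passing only); `NULL`
#'   counts everything.
#' @return Tibble of class `window_track`: `chrom`, `start`, `end`, `n`
#'   and `n_samples` (distinct samples contributing).
#' @export
window_counts <- function(events, genome, width = 1e5, status = "pass") {
  win <- make_windows(genome, width)
  ev <- as_tibble(events)
  if (!is.null(status) && "status" %in% names(ev)) {
    ev <- filter(ev, .data$status %in% !!status)
  }
  mid <- (ev$start + ev$end) / 2
  ev$win_start <- floor(mid / width) * width
  agg <- ev %>%
    group_by(.data$chrom, .data$win_start) %>%
    summarise(
      n = n(),
      n_samples = if ("sample" %in% names(ev)) n_distinct(.data$sample) else NA_integer_,
      .groups = "drop"
    )
  out <- win %>%
    left_join(agg, by = c("chrom", start = "win_start")) %>%
    mutate(
      n = if_else(is.na(.data$n), 0L, as.integer(.data$n)),
      n_samples = if_else(is.na(.data$n_samples), 0L, as.integer(.data$n_samples))
    )
  class(out) <- c("window_track", class(out))
  out
}

#' Window recombination rates
#'
#' Adds a rate column to a window track: events per Mb using each window's
#' true (possibly truncated) width, optionally divided by the number of
#' samples. The width-weighted mean of the rates equals the genome mean
#' rate (total events / total Mb) exactly.
#'
#' @param track A [window_counts()] track.
#' @param n_samples Optional; when supplied, rates are per sample.
#' @return The track with `rate` (n/Mb, or n/Mb/sample) added, plus the
#'   genome mean as attribute `mean_rate`.
#' @export
window_rates <- function(track, n_samples = NULL) {
  track <- mutate(as_tibble(track),
    rate = .data$n / ((.data$end - .data$start) / 1e6)
  )
  if (!is.null(n_samples)) track$rate <- track$rate / n_samples
  mean_rate <- sum(track$n) / sum((track$end - track$start) / 1e6)
  if (!is.null(n_samples)) mean_rate <- mean_rate / n_samples
  attr(track, "mean_rate") <- mean_rate
  class(track) <- unique(c("window_track", class(track)))
  track
}

#' Window genetic-map rates (cM/Mb)
#'
#' Interpolates a genetic map linearly at window boundaries and reports
#' each window's cM span divided by its Mb width — the per-window map-based
#' recombination rate used for the RIL hotspot rule.
#'
#' @param map Tibble with `chrom`, `pos` (bp) and `cm` (e.g.
#'   [genetic_distances()] output).
#' @param genome A [genome_spec()].
#' @param width Window width in bp.
#' @return A `window_track` tibble with `rate` in cM/Mb (`NA` outside the
#'   mapped span of a chromosome).
#' @export
window_map_rates <- function(map, genome, width = 1e6) {
  win <- make_windows(genome, width)
  out <- win %>%
    group_by(.data$chrom) %>%
    group_modify(function(w, key) {
      m <- filter(as_tibble(map), .data$chrom == key$chrom)
      if (nrow(m) < 2) {
        w$rate <- NA_real_
        return(w)
      }
      m <- arrange(m, .data$pos)
      cm_at <- function(p) approx(m$pos, m$cm, xout = p, rule = 2, ties = "ordered")$y
      w$rate <- (cm_at(w$end) - cm_at(w$start)) / ((w$end - w$start) / 1e6)
      # windows wholly outside the mapped span carry no information
      w$rate[w$end < min(m$pos) | w$start > max(m$pos)] <- NA_real_
      w
    }) %>%
    ungroup() %>%
    select("chrom", "start", "end", "rate")
  class(out) <- c("window_track", class(out))
  out
}

#' Correlation between chromosome event counts and physical length
#'
#' Pearson correlation (with the two-sided t-test p-value on n - 2 degrees
#' of freedom) between per-chromosome crossover counts and physical
#' lengths — the standard check that longer chromosomes accumulate more
#' crossovers.
#'
#' @param counts Numeric vector of per-chromosome event counts (or a
#'   tibble with `n_events`).
#' @param lengths Numeric vector of physical lengths (same order), or a
#'   tibble with `mb`.
#' @return Object of class `length_correlation`; `tidy()` gives a one-row
#'   tibble with `estimate`, `p.value`, `statistic`, `df`, `conf.low`,
#'   `conf.high`.
#' @export
length_correlation <- function(counts, lengths) {
  if (is.data.frame(counts)) counts <- counts$n_events
  if (is.data.frame(lengths)) lengths <- lengths$mb
  if (length(counts) != length(lengths)) abort("`counts` and `lengths` differ in length.")
  if (length(counts) < 3) abort("Need >= 3 chromosomes for a correlation.")
  if (stats::sd(counts) == 0 || stats::sd(lengths) == 0) {
    abort("Constant vector: correlation undefined.")
  }
  ct <- stats::cor.test(counts, lengths)
  structure(list(test = ct, n = length(counts)), class = "length_correlation")
}

#' @export
print.length_correlation <- function(x, ...) {
  cat(sprintf(
    "<length_correlation> r = %.4f, p = %.3g over %d chromosomes\n",
    unname(x$test$estimate), x$test$p.value, x$n
  ))
  invisible(x)
}

#' @rdname length_correlation
#' @param x A `length_correlation` object.
#' @param ... Unused.
#' @export
tidy.length_correlation <- function(x, ...) {
  broom::tidy(x$test) %>%
    select("estimate", "statistic", "p.value", "conf.low", "conf.high") %>%
    mutate(df = x$n - 2)
}

#' @rdname length_correlation
#' @export
glance.length_correlation <- function(x, ...) {
  tidy.length_correlation(x)
}

#' Haplotype conservation score per window
#'
#' For each window: each line votes its majority non-missing state across
#' the window's markers, and the score is the fraction of voting lines
#' carrying the modal state. High values mean a conserved haplotype (few
#' historical recombinations); recombination-rich windows score low, so
#' the score anticorrelates with the window recombination rate. Windows
#' without markers (or without any call) are unscored (`NA`).
#'
#' @param gm Genotype tibble.
#' @param windows Window grid tibble (`chrom`, `start`, `end`).
#' @return The window tibble with `conservation` and `n_markers` added.
#' @export
conservation_score <- function(gm, windows) {
  check_genotypes(gm)
  calls <- geno_call_matrix(gm)
  out <- as_tibble(windows)
  out$n_markers <- 0L
  out$conservation <- NA_real_
  for (w in seq_len(nrow(out))) {
    sel <- gm$chrom == out$chrom[w] & gm$pos >= out$start[w] & gm$pos < out$end[w]
    if (!any(sel)) next
    out$n_markers[w] <- sum(sel)
    sub <- calls[sel, , drop = FALSE]
    votes <- apply(sub, 2, function(col) {
      col <- col[col != "-"]
      if (!length(col)) return(NA_character_)
      tab <- table(col)
      names(tab)[which.max(tab)] # deterministic tie-break: first state
    })
    votes <- votes[!is.na(votes)]
    if (!length(votes)) next
    out$conservation[w] <- max(table(votes)) / length(votes)
  }
  out
}

#' Mean within-window pairwise recombination fraction
#'
#' The "heat-map weakness" of a window: the mean pairwise recombination
#' fraction among the markers it contains (subsampled to at most
#' `max_markers` for speed). High values mean weak local linkage, one of
#' the consensus hotspot criteria. Windows with fewer than two markers are
#' `NA`.
#'
#' @param gm Genotype tibble.
#' @param windows Window grid tibble.
#' @param max_markers Cap on markers per window entering the pairwise
#'   computation (evenly thinned, deterministic).
#' @return The window tibble with `weakness` and `n_markers` added.
#' @export
window_linkage_weakness <- function(gm, windows, max_markers = 12) {
  check_genotypes(gm)
  out <- as_tibble(windows)
  out$n_markers <- 0L
  out$weakness <- NA_real_
  for (w in seq_len(nrow(out))) {
    sel <- which(gm$chrom == out$chrom[w] & gm$pos >= out$start[w] & gm$pos < out$end[w])
    out$n_markers[w] <- length(sel)
    if (length(sel) < 2) next
    if (length(sel) > max_markers) {
      sel <- sel[round(seq(1, length(sel), length.out = max_markers))]
    }
    pr <- pairwise_recfrac(gm[sel, , drop = FALSE], min_lines = 1)
    pr <- filter(pr, .data$marker1 != .data$marker2, !is.na(.data$recfrac))
    if (nrow(pr)) out$weakness[w] <- mean(pr$recfrac)
  }
  out
}
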