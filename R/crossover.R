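#' Segment a sample's genotypes into parental blocks
#'
#' Converts the ordered marker calls of each chromosome into maximal runs
#' of identical non-missing state (`a`, `b` or `h`). Missing calls are
#' skipped and do not break a run. Block boundaries are placed at the
#' midpoint between the bounding markers of adjacent runs; the first and
#' last blocks end at the outermost non-missing markers, so blocks tile the
#' marker-covered span. Chromosomes whose calls are all missing yield no
#' blocks.
#'
#' @param gm Genotype tibble.
#' @param samples Samples to segment; default all.
#' @return Tibble of class `geno_blocks`: `sample`, `chrom`, `start`,
#'   `end` (0-based half-open bp), `state`, `n_markers`, `first_marker`,
#'   `last_marker` (bp positions of the outermost supporting markers).
#' @export
segment_blocks <- function(gm, samples = NULL) {
  check_genotypes(gm)
  samples <- samples %||% sample_ids(gm)
  calls <- geno_call_matrix(gm)
  gm <- arrange(mutate(gm, .row = row_number()), .data$chrom, .data$pos)
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    per_chrom <- lapply(split(gm$.row, gm$chrom), function(rows) {
      x <- calls[rows, s]
      pos <- gm$pos[match(rows, gm$.row)]
      keep <- x != "-"
      if (!any(keep)) return(NULL)
      x <- unname(x[keep])
      pos <- pos[keep]
      r <- rle(x)
      k <- length(r$values)
      iend <- cumsum(r$lengths) # index of last marker of each run
      istart <- c(1L, head(iend, -1L) + 1L)
      first_m <- pos[istart]
      last_m <- pos[iend]
      # boundaries: midpoints between runs; outer edges at outer markers
      cuts <- if (k > 1) floor((last_m[-k] + first_m[-1]) / 2) else numeric(0)
      tibble(
        start = c(first_m[1], cuts),
        end = c(cuts, last_m[k] + 1),
        state = r$values,
        n_markers = as.integer(unname(r$lengths)),
        first_marker = first_m,
        last_marker = last_m
      )
    })
    per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
    if (!length(per_chrom)) next
    out[[si]] <- bind_rows(per_chrom, .id = "chrom") %>%
      mutate(sample = s, .before = 1)
  }
  blocks <- bind_rows(out)
  if (!nrow(blocks)) {
    inform("No non-missing calls; no blocks produced.")
    blocks <- tibble(
      sample = character(), chrom = character(), start = numeric(),
      end = numeric(), state = character(), n_markers = integer(),
      first_marker = numeric(), last_marker = numeric()
    )
  }
  class(blocks) <- c("geno_blocks", class(blocks))
  blocks
}

#' Call crossover events from genotype blocks
#'
#' Every state change between consecutive blocks of one sample on one
#' chromosome is a candidate crossover, localised to the breakpoint
#' interval between the last marker of the left block and the first marker
#' of the right block. Filters mirror standard crossover-calling practice
#' in RIL genotyping:
#'
#' * `pass` — both flanking blocks span at least `min_flank_span` bp (the
#'   ">= 10 kb on both sides of the breakpoint" rule) and neither flank is
#'   a small block;
#' * `flank_fail` — a flanking block spans less than `min_flank_span`;
#' * `small_block_flag` — a flanking block spans at most `small_block` bp
#'   (<= 200 kb blocks are candidate false positives: retained, flagged
#'   for review, and droppable with `drop_small_blocks = TRUE`);
#' * `ambiguous_excluded` — the allelic relationship across the breakpoint
#'   is ambiguous (heterozygous state on both sides).
#'
#' Raising `min_flank_span` never increases the number of passing events.
#'
#' @param blocks Output of [segment_blocks()].
#' @param min_flank_span Minimum span (bp) of both flanking blocks.
#' @param small_block Span (bp) at or below which a flanking block flags
#'   the event.
#' @param drop_small_blocks Drop (rather than flag) events whose flank is a
#'   small block.
#' @return Tibble of class `crossover_events`: `sample`, `chrom`, `start`,
#'   `end` (breakpoint interval, bp), `left_state`, `right_state`,
#'   `left_span`, `right_span`, `status`.
#' @export
call_crossovers <- function(blocks, min_flank_span = 1e4, small_block = 2e5,
                            drop_small_blocks = FALSE) {
  stopifnot(is.data.frame(blocks))
  if (min_flank_span < 0 || small_block < 0) abort("Spans must be non-negative.")
  ev <- as_tibble(blocks) %>%
    arrange(.data$sample, .data$chrom, .data$start) %>%
    group_by(.data$sample, .data$chrom) %>%
    mutate(
      nxt_state = lead(.data$state),
      nxt_first = lead(.data$first_marker),
      nxt_span = lead(.data$end) - lead(.data$start),
      span = .data$end - .data$start
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$nxt_state)) %>%
    transmute(
      sample = .data$sample, chrom = .data$chrom,
      start = .data$last_marker, end = .data$nxt_first,
      left_state = .data$state, right_state = .data$nxt_state,
      left_span = .data$span, right_span = .data$nxt_span
    )
  min_span <- pmin(ev$left_span, ev$right_span)
  status <- dplyr::case_when(
    ev$left_state == "h" & ev$right_state == "h" ~ "ambiguous_excluded",
    min_span < min_flank_span ~ "flank_fail",
    min_span <= small_block ~ "small_block_flag",
    TRUE ~ "pass"
  )
  ev$status <- status
  if (drop_small_blocks) ev <- filter(ev, .data$status != "small_block_flag")
  class(ev) <- c("crossover_events", class(ev))
  ev
}

#' Count passing crossover events
#'
#' Tallies events with `status == "pass"` by sample, chromosome, or for
#' the whole genome; per-chromosome (and per-sample) counts sum to the
#' genome total.
#'
#' @param events Output of [call_crossovers()].
#' @param by `"sample"`, `"chrom"` or `"genome"`.
#' @return Tibble with the grouping column(s) and `n_events`.
#' @export
count_events <- function(events, by = c("sample", "chrom", "genome")) {
  by <- match.arg(by)
  passing <- filter(as_tibble(events), .data$status == "pass")
  switch(by,
    sample = count(passing, .data$sample, name = "n_events"),
    chrom = count(passing, .data$chrom, name = "n_events"),
    genome = tibble(n_events = nrow(passing))
  )
}
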