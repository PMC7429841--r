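#' Describe a genome and its recombination landscape
#'
#' A genome specification holds the chromosome layout (name, physical length
#' in bp), a per-chromosome baseline recombination rate in cM/Mb, and an
#' optional set of hotspot intervals in which the baseline is multiplied by
#' a fold factor. Together these define a piecewise-constant crossover
#' density used by the meiosis simulator: the genetic length of a chromosome
#' in Morgans is the integral of the landscape over its physical length.
#'
#' @param chromosomes A data frame with columns `chrom` and `length_bp`
#'   (positive integers), optionally `rate_cm_mb`.
#' @param rate_cm_mb Baseline rate in cM/Mb; a scalar recycled to all
#'   chromosomes, or a vector of length `nrow(chromosomes)`. Ignored when
#'   `chromosomes` carries its own `rate_cm_mb` column.
#' @param hotspots Optional data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open bp) and `fold` (multiplier over baseline, >= 1).
#'   Intervals must lie within their chromosome and must not overlap one
#'   another on the same chromosome.
#' @return An object of class `genome_spec`: a list with tibbles
#'   `chromosomes` (`chrom`, `length_bp`, `rate_cm_mb`) and `hotspots`.
#' @examples
#' g <- genome_spec(
#'   data.frame(chrom = "chr1", length_bp = 10e6), rate_cm_mb = 2,
#'   hotspots = data.frame(chrom = "chr1", start = 4e6, end = 4.1e6, fold = 20)
#' )
#' chrom_genetic_length(g)
#' @export
genome_spec <- function(chromosomes, rate_cm_mb = 2, hotspots = NULL) {
  chromosomes <- as_tibble(chromosomes)
  if (!all(c("chrom", "length_bp") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns `chrom` and `length_bp`.")
  }
  if (anyDuplicated(chromosomes$chrom)) {
    abort("Chromosome names must be unique.")
  }
  if (any(chromosomes$length_bp <= 0)) {
    abort("Chromosome lengths must be positive (zero-length chromosome rejected).")
  }
  if (!"rate_cm_mb" %in% names(chromosomes)) {
    if (!length(rate_cm_mb) %in% c(1L, nrow(chromosomes))) {
      abort("`rate_cm_mb` must be scalar or one value per chromosome.")
    }
    chromosomes$rate_cm_mb <- rep_len(as.numeric(rate_cm_mb), nrow(chromosomes))
  }
  if (any(chromosomes$rate_cm_mb < 0)) abort("Baseline rates must be >= 0.")
  chromosomes <- select(chromosomes, "chrom", "length_bp", "rate_cm_mb")

  if (is.null(hotspots) || nrow(as_tibble(hotspots)) == 0) {
    hotspots <- tibble(
      chrom = character(), start = numeric(), end = numeric(), fold = numeric()
    )
  } else {
    hotspots <- as_tibble(hotspots)
    need <- c("chrom", "start", "end", "fold")
    if (!all(need %in% names(hotspots))) {
      abort("`hotspots` needs columns chrom, start, end, fold.")
    }
    hotspots <- arrange(select(hotspots, all_of(need)), .data$chrom, .data$start)
    if (any(hotspots$fold < 1)) abort("Hotspot fold multipliers must be >= 1.")
    if (any(hotspots$end <= hotspots$start)) abort("Hotspot intervals must have end > start.")
    hotspots <- left_join(hotspots,
      select(chromosomes, "chrom", "length_bp"),
      by = "chrom"
    )
    if (any(is.na(hotspots$length_bp))) {
      abort("Hotspot on unknown chromosome.")
    }
    if (any(hotspots$start < 0 | hotspots$end > hotspots$length_bp)) {
      abort("Hotspot intervals must lie within their chromosome.")
    }
    overlap <- hotspots %>%
      group_by(.data$chrom) %>%
      summarise(bad = any(.data$start < lag(.data$end, default = -Inf))) %>%
      pull(.data$bad)
    if (any(overlap)) abort("Hotspot intervals on one chromosome must not overlap.")
    hotspots$length_bp <- NULL
  }
  structure(
    list(chromosomes = chromosomes, hotspots = hotspots),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  tot_mb <- sum(x$chromosomes$length_bp) / 1e6
  cat(sprintf(
    "<genome_spec> %d chromosome(s), %.1f Mb, %d hotspot interval(s)\n",
    nrow(x$chromosomes), tot_mb, nrow(x$hotspots)
  ))
  invisible(x)
}

#' Piecewise-constant landscape segments of a genome
#'
#' Expands a [genome_spec()] into non-overlapping segments of constant
#' recombination rate (baseline outside hotspots, baseline x fold inside).
#'
#' @param genome A `genome_spec`.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open bp) and
#'   `rate_cm_mb`; segments tile each chromosome.
#' @export
landscape_segments <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  purrr::pmap_dfr(genome$chromosomes, function(chrom, length_bp, rate_cm_mb) {
    hs <- filter(genome$hotspots, .data$chrom == !!chrom)
    bounds <- sort(unique(c(0, hs$start, hs$end, length_bp)))
    seg <- tibble(
      chrom = chrom,
      start = head(bounds, -1),
      end = tail(bounds, -1)
    )
    mid <- (seg$start + seg$end) / 2
    fold <- rep(1, nrow(seg))
    if (nrow(hs)) {
      idx <- findInterval(mid, hs$start)
      inside <- idx >= 1 & mid < hs$end[pmax(idx, 1)]
      fold[inside] <- hs$fold[idx[inside]]
    }
    seg$rate_cm_mb <- rate_cm_mb * fold
    seg
  })
}

#' Genetic length of each chromosome implied by the landscape
#'
#' @param genome A `genome_spec`.
#' @return Tibble with `chrom`, `cm` (centiMorgans) and `morgans`.
#' @export
chrom_genetic_length <- function(genome) {
  landscape_segments(genome) %>%
    group_by(.data$chrom) %>%
    summarise(cm = sum((.data$end - .data$start) / 1e6 * .data$rate_cm_mb)) %>%
    mutate(morgans = .data$cm / 100)
}

# Per-chromosome sampling tables for inverse-CDF crossover placement.
# Returns a named list: for each chromosome, list(start, end, rate, cum)
# where cum is the cumulative genetic mass (Morgans) at segment ends.
landscape_sampler <- function(genome) {
  segs <- landscape_segments(genome)
  split(segs, segs$chrom)[unique(segs$chrom)] %>%
    purrr::map(function(s) {
      mass <- (s$end - s$start) / 1e6 * s$rate_cm_mb / 100
      list(
        start = s$start, end = s$end, rate = s$rate_cm_mb,
        mass = mass, cum = cumsum(mass), total = sum(mass)
      )
    })
}

# Draw n crossover positions (bp, unsorted) from one chromosome's landscape.
draw_positions <- function(sampler, n) {
  if (n == 0L) return(numeric(0))
  if (sampler$total <= 0) return(numeric(0))
  u <- runif(n) * sampler$total
  seg <- findInterval(u, sampler$cum, left.open = TRUE) + 1L
  seg <- pmin(seg, length(sampler$cum))
  lo <- sampler$cum[seg] - sampler$mass[seg]
  frac <- (u - lo) / sampler$mass[seg]
  sampler$start[seg] + frac * (sampler$end[seg] - sampler$start[seg])
}

#' Built-in peanut genome layouts
#'
#' `peanut_genome()` returns the 20-chromosome layout of cultivated peanut
#' (A01–A10, B01–B10) with physical lengths and per-chromosome baseline
#' rates taken from the shipped F6 map reference table
#' ([peanut_map_reference()]): rate = genetic length (cM) / physical length
#' (Mb), i.e. 1.26–1.76 cM/Mb genome-wide.
#'
#' `scaled_peanut_genome()` is a scaled-down stand-in used for simulation
#' studies: `n_chrom` chromosomes of `chrom_mb` megabases whose baseline
#' rate preserves the reference map's mean per-chromosome genetic length
#' (2915.46 cM / 20 = 145.77 cM) despite the shorter physical length, plus
#' `hotspots_per_chrom` planted hotspot windows of `hotspot_width` bp at
#' `hotspot_fold` times the baseline, placed at fixed relative positions.
#'
#' @param hotspots Optional hotspot data frame passed to [genome_spec()].
#' @param n_chrom,chrom_mb Number of chromosomes and physical length (Mb).
#' @param cm_per_chrom Genetic length (cM) each scaled chromosome should
#'   have outside hotspots; default derives from the reference map.
#' @param hotspots_per_chrom,hotspot_width,hotspot_fold Planted hotspot
#'   count per chromosome, width (bp) and fold over baseline.
#' @return A [genome_spec()].
#' @export
peanut_genome <- function(hotspots = NULL) {
  ref <- peanut_map_reference("chromosome")
  genome_spec(
    tibble(
      chrom = ref$group,
      length_bp = round(ref$physical_mb * 1e6),
      rate_cm_mb = ref$genetic_cm / ref$physical_mb
    ),
    hotspots = hotspots
  )
}

#' @rdname peanut_genome
#' @export
scaled_peanut_genome <- function(n_chrom = 20, chrom_mb = 10,
                                 cm_per_chrom = NULL,
                                 hotspots_per_chrom = 1,
                                 hotspot_width = 1e5, hotspot_fold = 20) {
  if (is.null(cm_per_chrom)) {
    ref <- peanut_map_reference("chromosome")
    cm_per_chrom <- mean(ref$genetic_cm)
  }
  len <- round(chrom_mb * 1e6)
  chroms <- tibble(
    chrom = sprintf("chr%02d", seq_len(n_chrom)),
    length_bp = len,
    rate_cm_mb = cm_per_chrom / chrom_mb
  )
  hs <- NULL
  if (hotspots_per_chrom > 0) {
    # fixed relative positions, clear of chromosome ends, snapped to the
    # hotspot-width grid so planted windows align with 100-kb scan windows
    at <- seq(0.25, 0.75, length.out = hotspots_per_chrom)
    hs <- tidyr::expand_grid(chrom = chroms$chrom, rel = at) %>%
      mutate(
        start = floor(.data$rel * (len - hotspot_width) / hotspot_width) * hotspot_width,
        end = .data$start + hotspot_width,
        fold = hotspot_fold
      ) %>%
      select("chrom", "start", "end", "fold")
  }
  genome_spec(chroms, hotspots = hs)
}
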