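#' Simulation configuration
#'
#' Bundles the knobs of the forward meiosis simulator. Defaults emulate the
#' populations the package targets: an F6 RIL of 200 lines genotyped at
#' hemi-SNP-like biallelic markers with up to 5% missing calls.
#'
#' @param n_lines Number of RIL lines / panel accessions to simulate.
#' @param generations Filial generation of the selfing pedigree (6 = F6,
#'   i.e. five selfing meioses past F1). Must be >= 2.
#' @param n_markers Markers per chromosome.
#' @param missing_rate Per-call probability of a missing genotype, in [0, 1).
#' @param marker_type `"snp"` (biallelic, hemi-SNP-like) or `"indel"`
#'   (InDel-like panel markers); affects marker naming only.
#' @param seed Integer seed; every random draw of a simulation flows from it.
#' @param marker_spacing `"even"` (deterministic, equally spaced) or
#'   `"uniform"` (positions drawn uniformly without replacement).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 200, generations = 6, n_markers = 500,
                       missing_rate = 0.05,
                       marker_type = c("snp", "indel"), seed = 1,
                       marker_spacing = c("even", "uniform")) {
  marker_type <- match.arg(marker_type)
  marker_spacing <- match.arg(marker_spacing)
  if (generations < 2) abort("`generations` must be >= 2 (F2 or later).")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  if (n_lines < 1) abort("`n_lines` must be positive.")
  if (n_markers < 1) abort("`n_markers` must be positive on every chromosome (a chromosome without markers is unobservable).")
  structure(
    list(
      n_lines = as.integer(n_lines), generations = as.integer(generations),
      n_markers = as.integer(n_markers), missing_rate = missing_rate,
      marker_type = marker_type, seed = as.integer(seed),
      marker_spacing = marker_spacing
    ),
    class = "sim_config"
  )
}

# --- haplotype mosaics ------------------------------------------------------
# A haplotype is a named list (one element per chromosome), each element
# list(ends, alleles): segment j covers [ends[j-1], ends[j]) with 0 implied
# before the first end; alleles are founder labels ("a"/"b" for RIL parents,
# integer founder index for panel founders).

#' Founder haplotype pair of a biparental cross
#'
#' The two parental haplotypes ("a" and "b" throughout the genome) in the
#' mosaic representation consumed by [simulate_gamete()]: one element per
#' chromosome, each `list(ends, alleles)` where segment `j` covers
#' `[ends[j-1], ends[j])` bp.
#'
#' @param genome A [genome_spec()].
#' @return List of two haplotypes.
#' @export
parental_haplotypes <- function(genome) {
  list(founder_haplotype(genome, "a"), founder_haplotype(genome, "b"))
}

founder_haplotype <- function(genome, allele) {
  set_names(
    purrr::map(genome$chromosomes$length_bp, ~ list(ends = .x, alleles = allele)),
    genome$chromosomes$chrom
  )
}

hap_allele_at <- function(h, pos) {
  h$alleles[findInterval(pos, h$ends) + 1L]
}

# Interior segment boundaries (every one is an allele switch after collapse).
hap_breakpoints <- function(h) {
  if (length(h$ends) <= 1L) numeric(0) else head(h$ends, -1L)
}

collapse_hap <- function(ends, alleles) {
  if (length(alleles) > 1L) {
    keep <- c(alleles[-1] != alleles[-length(alleles)], TRUE)
    ends <- ends[keep]
    alleles <- alleles[keep]
  }
  list(ends = ends, alleles = alleles)
}

# Sub-segments of haplotype h overlapping [lo, hi), ends capped to hi.
slice_hap <- function(h, lo, hi) {
  i1 <- findInterval(lo, h$ends) + 1L   # segment containing lo
  i2 <- findInterval(hi, h$ends, left.open = TRUE) + 1L # segment containing hi (as right end)
  i2 <- min(i2, length(h$ends))
  idx <- i1:i2
  list(ends = c(head(h$ends[idx], -1L), hi), alleles = h$alleles[idx])
}

recombine_chrom <- function(h1, h2, xs, first) {
  L <- h1$ends[length(h1$ends)]
  cuts <- c(0, xs, L)
  src <- rep(c(first, 3L - first), length.out = length(cuts) - 1L)
  ends <- vector("list", length(src))
  alleles <- vector("list", length(src))
  for (i in seq_along(src)) {
    piece <- slice_hap(if (src[i] == 1L) h1 else h2, cuts[i], cuts[i + 1L])
    ends[[i]] <- piece$ends
    alleles[[i]] <- piece$alleles
  }
  collapse_hap(unlist(ends), unlist(alleles))
}

#' Simulate one gamete from a pair of parental haplotypes
#'
#' Draws the crossover count of each chromosome from a Poisson distribution
#' with mean equal to the chromosome's genetic length in Morgans under the
#' genome's landscape (no interference, no obligate chiasma), places the
#' crossovers by inverse-CDF sampling of the normalized landscape density,
#' and returns the resulting mosaic of the two input haplotypes. The
#' starting haplotype of each chromosome is chosen at random, so with zero
#' crossovers the gamete is one of the inputs unchanged.
#'
#' @param parent List of two haplotypes as produced by the simulator
#'   internals (one element per chromosome, each `list(ends, alleles)`).
#' @param genome A [genome_spec()]. Uses the session RNG; seed upstream.
#' @return List with `haplotype` (the gamete) and `crossovers`
#'   (tibble `chrom`, `pos`).
#' @export
simulate_gamete <- function(parent, genome) {
  sampler <- landscape_sampler(genome)
  sim_gamete(parent, sampler)
}

sim_gamete <- function(parent, sampler) {
  chroms <- names(sampler)
  hap <- vector("list", length(chroms))
  names(hap) <- chroms
  xs_all <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    s <- sampler[[i]]
    n <- rpois(1L, s$total)
    xs <- sort(draw_positions(s, n))
    first <- sample.int(2L, 1L)
    h1 <- parent[[1L]][[chroms[i]]]
    h2 <- parent[[2L]][[chroms[i]]]
    hap[[i]] <- if (n == 0L) {
      if (first == 1L) h1 else h2
    } else {
      recombine_chrom(h1, h2, xs, first)
    }
    xs_all[[i]] <- xs
  }
  list(
    haplotype = hap,
    crossovers = tibble(
      chrom = rep(chroms, lengths(xs_all)),
      pos = unlist(xs_all) %||% numeric(0)
    )
  )
}

marker_positions <- function(genome, cfg) {
  purrr::pmap_dfr(
    genome$chromosomes[, c("chrom", "length_bp")],
    function(chrom, length_bp) {
      n <- cfg$n_markers
      if (n >= length_bp) abort("More markers than base pairs on a chromosome.")
      pos <- switch(cfg$marker_spacing,
        even = round((seq_len(n) - 0.5) / n * length_bp),
        uniform = sort(sample.int(length_bp, n) - 1L)
      )
      prefix <- if (cfg$marker_type == "snp") "S" else "I"
      tibble(
        marker_id = sprintf("%s_%s_%05d", prefix, chrom, seq_len(n)),
        chrom = chrom, pos = as.numeric(pos)
      )
    }
  )
}

# Genotype one individual (two haplotypes) at the marker table -> codes.
genotype_individual <- function(ind, markers) {
  out <- character(nrow(markers))
  for (ch in unique(markers$chrom)) {
    sel <- markers$chrom == ch
    pos <- markers$pos[sel]
    a1 <- hap_allele_at(ind[[1L]][[ch]], pos)
    a2 <- hap_allele_at(ind[[2L]][[ch]], pos)
    out[sel] <- if_else(a1 == a2, as.character(a1), "h")
  }
  out
}

apply_missingness <- function(calls, rate) {
  if (rate > 0) calls[runif(length(calls)) < rate] <- "-"
  calls
}

#' Simulate a recombinant inbred line (RIL) population
#'
#' Forward simulation of a biparental selfing pedigree: an F1 heterozygous
#' for parents "a" and "b" everywhere is selfed for `generations - 1`
#' rounds, each round drawing two independent gametes (see
#' [simulate_gamete()]) per line. Residual heterozygosity therefore halves
#' each generation (expected fraction `0.5^(generations-1)`, ~3.1% at F6).
#' Lines are genotyped at `cfg$n_markers` markers per chromosome, coded
#' `"a"`/`"b"`/`"h"` with missing calls `"-"` planted at
#' `cfg$missing_rate`.
#'
#' @param genome A [genome_spec()].
#' @param cfg A [sim_config()]. All randomness flows from `cfg$seed`; a
#'   fixed seed gives byte-identical output.
#' @return A list of class `ril_sim`:
#' \describe{
#'   \item{genotypes}{tibble `marker_id`, `chrom`, `pos`, then one column
#'     per line.}
#'   \item{truth}{list with `breakpoints` (tibble `sample`, `chrom`, `pos`,
#'     `hap`; the crossover breakpoints that survive into the final line's
#'     two chromosome copies) and `meioses` (tibble `sample`, `generation`,
#'     `chrom`, `pos`; every crossover of every meiosis in the pedigree).}
#'   \item{genome, config}{the inputs.}
#' }
#' @export
simulate_ril <- function(genome, cfg = sim_config()) {
  stopifnot(inherits(genome, "genome_spec"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sampler <- landscape_sampler(genome)
  markers <- marker_positions(genome, cfg)
  fA <- founder_haplotype(genome, "a")
  fB <- founder_haplotype(genome, "b")

  samples <- sprintf("L%03d", seq_len(cfg$n_lines))
  calls <- matrix("", nrow(markers), cfg$n_lines, dimnames = list(NULL, samples))
  bp <- vector("list", cfg$n_lines)
  mei <- vector("list", cfg$n_lines)

  for (i in seq_len(cfg$n_lines)) {
    ind <- list(fA, fB) # F1
    events <- vector("list", cfg$generations - 1L)
    for (g in seq_len(cfg$generations - 1L)) {
      g1 <- sim_gamete(ind, sampler)
      g2 <- sim_gamete(ind, sampler)
      ind <- list(g1$haplotype, g2$haplotype)
      ev <- bind_rows(g1$crossovers, g2$crossovers)
      ev$generation <- g + 1L # meiosis producing the F(g+1)
      events[[g]] <- ev
    }
    mei[[i]] <- bind_rows(events)
    bp[[i]] <- purrr::map_dfr(1:2, function(k) {
      purrr::map_dfr(names(ind[[k]]), function(ch) {
        p <- hap_breakpoints(ind[[k]][[ch]])
        tibble(chrom = rep(ch, length(p)), pos = p, hap = rep(k, length(p)))
      })
    })
    calls[, i] <- apply_missingness(genotype_individual(ind, markers), cfg$missing_rate)
  }

  breakpoints <- bind_rows(set_names(bp, samples), .id = "sample")
  meioses <- bind_rows(set_names(mei, samples), .id = "sample")
  genotypes <- bind_cols(markers, as_tibble(calls))
  structure(
    list(
      genotypes = genotypes,
      truth = list(breakpoints = breakpoints, meioses = meioses),
      genome = genome, config = cfg
    ),
    class = "ril_sim"
  )
}

#' Simulate a founder-mosaic natural panel
#'
#' Each accession's (homozygous) genome is a mosaic of `n_founders` ancestral
#' haplotypes: switch points accumulate over `historical_meioses` rounds of
#' the genome's landscape (count per chromosome ~ Poisson(meioses x Morgans)),
#' and at each switch the donor jumps to a different founder chosen uniformly.
#' Founder marker alleles come from piecewise-constant biallelic haplotype
#' tracks (so nearby markers are in LD along a founder); genotypes are
#' coded `"a"`/`"b"` (accessions are inbred, so no `"h"` calls arise). After missingness is planted, markers failing the
#' panel filters (call frequency > `min_call`, minor allele frequency >
#' `min_maf`; see [filter_panel_markers()]) are dropped from the output, and
#' an error naming the filter is raised if nothing survives.
#'
#' @inheritParams simulate_ril
#' @param n_founders Number of ancestral haplotypes (>= 2 for mosaics; with
#'   1 founder all accessions are identical and no switch points exist).
#' @param historical_meioses Effective number of meioses the landscape acted
#'   over; scales the switch-point density.
#' @param founder_block_mb Mean segment length (Mb) of the piecewise
#'   founder haplotype tracks (controls marker LD along founders).
#' @param min_call,min_maf Marker filters applied to the emitted matrix.
#' @param filter Apply the panel filters to the emitted matrix (`FALSE`
#'   keeps every simulated marker, e.g. for degenerate single-founder
#'   panels where all markers are monomorphic).
#' @return A list of class `panel_sim` with `genotypes`, `truth` (list with
#'   `breakpoints`: tibble `sample`, `chrom`, `pos` of true switch points),
#'   `founder_alleles`, `genome`, `config`.
#' @export
simulate_panel <- function(genome, n_founders = 8, cfg = sim_config(
                             n_lines = 49, marker_type = "indel"
                           ),
                           historical_meioses = 20, founder_block_mb = 2,
                           min_call = 0.8, min_maf = 0.05, filter = TRUE) {
  stopifnot(inherits(genome, "genome_spec"), inherits(cfg, "sim_config"))
  if (n_founders < 1) abort("`n_founders` must be >= 1.")
  set.seed(cfg$seed)
  sampler <- landscape_sampler(genome)
  markers <- marker_positions(genome, cfg)

  # Founder haplotypes are piecewise-constant biallelic tracks (segment
  # length ~ Exp(founder_block_mb)), so nearby markers on one founder
  # segment are in LD, as on real ancestral haplotypes. The matrix below
  # evaluates each founder's track at the marker positions.
  founder_alleles <- matrix(
    0L, nrow(markers), n_founders,
    dimnames = list(markers$marker_id, sprintf("F%02d", seq_len(n_founders)))
  )
  for (f in seq_len(n_founders)) {
    for (ch in genome$chromosomes$chrom) {
      L <- genome$chromosomes$length_bp[genome$chromosomes$chrom == ch]
      cuts <- cumsum(stats::rexp(ceiling(L / (founder_block_mb * 1e6)) * 4 + 8,
        rate = 1 / (founder_block_mb * 1e6)
      ))
      cuts <- cuts[cuts < L]
      track <- list(ends = c(cuts, L), alleles = rbinom(length(cuts) + 1L, 1L, 0.5))
      sel <- markers$chrom == ch
      founder_alleles[sel, f] <- hap_allele_at(track, markers$pos[sel])
    }
  }

  samples <- sprintf("ACC%03d", seq_len(cfg$n_lines))
  calls <- matrix("", nrow(markers), cfg$n_lines, dimnames = list(NULL, samples))
  sw <- vector("list", cfg$n_lines)
  chroms <- names(sampler)

  for (i in seq_len(cfg$n_lines)) {
    hap <- vector("list", length(chroms))
    names(hap) <- chroms
    xs_all <- vector("list", length(chroms))
    for (j in seq_along(chroms)) {
      s <- sampler[[j]]
      L <- s$end[length(s$end)]
      if (n_founders == 1L) {
        hap[[j]] <- list(ends = L, alleles = 1L)
        xs_all[[j]] <- numeric(0)
        next
      }
      n <- rpois(1L, s$total * historical_meioses)
      xs <- sort(draw_positions(s, n))
      donors <- integer(n + 1L)
      donors[1L] <- sample.int(n_founders, 1L)
      if (n > 0L) {
        for (k in seq_len(n)) {
          donors[k + 1L] <- sample.int(n_founders - 1L, 1L)
          if (donors[k + 1L] >= donors[k]) donors[k + 1L] <- donors[k + 1L] + 1L
        }
      }
      hap[[j]] <- collapse_hap(c(xs, L), donors)
      xs_all[[j]] <- xs
    }
    sw[[i]] <- tibble(
      chrom = rep(chroms, lengths(xs_all)),
      pos = unlist(xs_all) %||% numeric(0)
    )
    # homozygous mosaic: genotype = founder allele at each marker
    g <- integer(nrow(markers))
    for (ch in chroms) {
      sel <- markers$chrom == ch
      donor <- hap_allele_at(hap[[ch]], markers$pos[sel])
      g[sel] <- founder_alleles[cbind(which(sel), donor)]
    }
    calls[, i] <- apply_missingness(if_else(g == 0L, "a", "b"), cfg$missing_rate)
  }

  genotypes <- bind_cols(markers, as_tibble(calls))
  kept <- if (filter) {
    filter_panel_markers(genotypes, min_call = min_call, min_maf = min_maf)
  } else {
    genotypes
  }
  if (nrow(kept) == 0) {
    abort(sprintf(
      "All %d simulated markers were removed by the panel filters (call frequency > %g, MAF > %g).",
      nrow(genotypes), min_call, min_maf
    ))
  }
  structure(
    list(
      genotypes = kept,
      truth = list(breakpoints = bind_rows(set_names(sw, samples), .id = "sample")),
      founder_alleles = founder_alleles,
      genome = genome, config = cfg
    ),
    class = "panel_sim"
  )
}
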