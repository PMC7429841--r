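#' Genetic distances between adjacent markers
#'
#' Orders the markers of each linkage group by physical position, estimates
#' the observed recombinant fraction `R` between adjacent markers (fraction
#' of lines carrying opposite homozygous calls among lines homozygous and
#' non-missing at both markers), optionally inverts the RIL-by-selfing map
#' expansion `R = 2r / (1 + 2r)` to the per-meiosis fraction
#' `r = R / (2 - 2R)`, and converts to centiMorgans with Haldane
#' (`-50 ln(1 - 2r)`) or Kosambi (`25 ln((1+2r)/(1-2r))`) mapping.
#' Fractions that reach 0.5 after correction are capped at 0.49 with a
#' warning. Cumulative positions start at 0 per group and are
#' non-decreasing.
#'
#' The closed-form inverse is the fully inbred (F-infinity) limit. A finite
#' selfing pedigree has not yet realised that full map expansion — at F6
#' the homozygote-pair recombinant fraction is only about 86% of
#' `2r/(1+2r)` — so maps of an F5/F6 population come out correspondingly
#' short under the closed form. Supplying a finite `generations` instead
#' inverts the exact two-locus selfing recursion ([ril_expected_r()]) for
#' that generation, removing the bias.
#'
#' @param gm Genotype tibble.
#' @param groups Optional `linkage_groups` object (or tibble with
#'   `marker_id`, `lg`); default treats each chromosome as one group.
#' @param mapping Mapping function, `"haldane"` (default) or `"kosambi"`.
#' @param ril_correction Apply the RIL-by-selfing correction (default
#'   `TRUE`; turn off for populations scored per meiosis).
#' @param generations Filial generation of the RIL correction: `Inf`
#'   (default) uses the closed-form fully-inbred inverse; a finite value
#'   (e.g. 6 for F6) inverts the exact finite-generation relation.
#' @return Map tibble `marker_id`, `lg`, `cm` plus `chrom`, `pos`, `r_obs`
#'   (observed adjacent fraction) and `n_inf` (informative lines).
#' @export
genetic_distances <- function(gm, groups = NULL,
                              mapping = c("haldane", "kosambi"),
                              ril_correction = TRUE, generations = Inf) {
  check_genotypes(gm)
  mapping <- match.arg(mapping)
  grp <- if (is.null(groups)) {
    tibble(marker_id = gm$marker_id, lg = gm$chrom)
  } else if (inherits(groups, "linkage_groups")) {
    select(groups$groups, "marker_id", "lg")
  } else {
    select(as_tibble(groups), "marker_id", "lg")
  }
  calls <- geno_call_matrix(gm)
  dat <- left_join(gm[, GENO_META], grp, by = "marker_id") %>%
    arrange(.data$lg, .data$pos)
  capped <- FALSE
  invert_R <- if (ril_correction && is.finite(generations)) {
    ril_r_inverter(generations)
  } else if (ril_correction) {
    function(R) R / (2 - 2 * R)
  } else {
    identity
  }

  out <- dat %>%
    group_by(.data$lg) %>%
    group_modify(function(d, key) {
      idx <- match(d$marker_id, rownames(calls))
      k <- length(idx)
      r_obs <- n_inf <- rep(NA_real_, k)
      cm_step <- rep(0, k)
      if (k > 1) {
        for (j in 2:k) {
          x <- calls[idx[j - 1], ]
          y <- calls[idx[j], ]
          ok <- x %in% c("a", "b") & y %in% c("a", "b")
          n_inf[j] <- sum(ok)
          R <- if (any(ok)) mean(x[ok] != y[ok]) else 0
          r_obs[j] <- R
          r <- invert_R(R)
          if (r >= 0.5) {
            r <- 0.49
            capped <<- TRUE
          }
          cm_step[j] <- switch(mapping,
            haldane = -50 * log(1 - 2 * r),
            kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r))
          )
        }
      }
      d$cm <- cumsum(cm_step)
      d$r_obs <- r_obs
      d$n_inf <- n_inf
      d
    }) %>%
    ungroup()
  if (capped) {
    warn("Recombination fraction >= 0.5 after correction; capped at 0.49.")
  }
  select(out, "marker_id", "lg", "cm", "chrom", "pos", "r_obs", "n_inf")
}

#' Expected recombinant fraction among RIL homozygotes at finite generation
#'
#' Exact two-locus theory for a selfing pedigree: starting from the F1
#' double heterozygote in coupling, lines are advanced by
#' `generations - 1` rounds of selfing, each offspring being two
#' independent gametes of its parent (recombination probability `r` between
#' the loci per meiosis). Returns the probability that a line homozygous at
#' both loci carries the recombinant haplotype — the quantity a genotype
#' matrix shows between two markers. As `generations` grows this approaches
#' the classical fully inbred limit `2r/(1+2r)`; at F6 it is ~86% of it.
#'
#' @param r Per-meiosis recombination fraction in `[0, 0.5]` (vectorised).
#' @param generations Filial generation (2 = F2, 6 = F6).
#' @return Expected conditional recombinant fraction, same length as `r`.
#' @examples
#' ril_expected_r(0.01, 6) / (2 * 0.01 / 1.02) # ~0.856
#' @export
ril_expected_r <- function(r, generations = 6) {
  if (generations < 2) abort("`generations` must be >= 2.")
  vapply(r, function(ri) {
    # gametes 1:4 = AB, Ab, aB, ab; ordered-pair state distribution
    gam_dist <- function(g1, g2) {
      out <- numeric(4)
      out[g1] <- out[g1] + (1 - ri) / 2
      out[g2] <- out[g2] + (1 - ri) / 2
      cross <- c(
        (g1 - 1) %/% 2 * 2 + (g2 - 1) %% 2 + 1, # A from g1, B from g2
        (g2 - 1) %/% 2 * 2 + (g1 - 1) %% 2 + 1
      )
      out[cross[1]] <- out[cross[1]] + ri / 2
      out[cross[2]] <- out[cross[2]] + ri / 2
      out
    }
    # state = ordered gamete pair (16 states); offspring of state (i,j) is
    # an independent pair drawn from gam_dist(i,j)
    p <- matrix(0, 4, 4)
    p[1, 4] <- 1 # F1 = AB/ab
    for (g in seq_len(generations - 1)) {
      pn <- matrix(0, 4, 4)
      for (i in 1:4) {
        for (j in 1:4) {
          if (p[i, j] > 0) {
            gd <- gam_dist(i, j)
            pn <- pn + p[i, j] * outer(gd, gd)
          }
        }
      }
      p <- pn
    }
    hom <- diag(p) # AB/AB, Ab/Ab, aB/aB, ab/ab
    sum(hom[2:3]) / sum(hom)
  }, numeric(1))
}

# Numeric inverse of ril_expected_r for one generation, used by the
# finite-generation RIL map correction.
ril_r_inverter <- function(generations) {
  rmax <- ril_expected_r(0.5, generations)
  function(R) {
    if (R <= 0) return(0)
    if (R >= rmax) return(0.5) # saturated; caller caps and warns
    stats::uniroot(
      function(x) ril_expected_r(x, generations) - R,
      interval = c(0, 0.5), tol = 1e-9
    )$root
  }
}

#' Map summary statistics
#'
#' `summarize_map_stats()` computes the derived cells of a map summary from
#' its primitive inputs: marker density (markers/cM), markers per Mb and
#' cM per Mb. Published linkage-map tables often label the markers-per-Mb
#' column "recombination rate (cM/Mb)"; both quantities are therefore
#' reported, explicitly named.
#'
#' `map_summary()` computes the full per-group summary from a map tibble:
#' marker count, genetic length (max - min cM), density, maximum adjacent
#' gap, percentage of gaps < 5 cM and, when physical lengths are supplied,
#' the per-Mb columns. Single-marker groups report `NA` gaps and density.
#'
#' @param n_markers,genetic_length_cm,physical_mb Vectors of marker counts,
#'   genetic lengths (cM) and physical lengths (Mb).
#' @return A tibble with the derived statistics.
#' @export
summarize_map_stats <- function(n_markers, genetic_length_cm, physical_mb = NA) {
  tibble(
    n_markers = n_markers,
    genetic_length_cm = genetic_length_cm,
    density_markers_cm = n_markers / genetic_length_cm,
    physical_mb = physical_mb,
    markers_per_mb = n_markers / physical_mb,
    cm_per_mb = genetic_length_cm / physical_mb
  )
}

#' @rdname summarize_map_stats
#' @param map Map tibble (`marker_id`, `lg`, `cm`).
#' @param physical_lengths Optional tibble (`lg`, `mb`) or named vector of
#'   physical lengths in Mb.
#' @export
map_summary <- function(map, physical_lengths = NULL) {
  if (!nrow(map)) abort("`map` is empty.")
  phys <- if (is.null(physical_lengths)) {
    tibble(lg = character(), mb = numeric())
  } else if (is.data.frame(physical_lengths)) {
    as_tibble(physical_lengths)
  } else {
    tibble(lg = names(physical_lengths), mb = as.numeric(physical_lengths))
  }
  map %>%
    group_by(.data$lg) %>%
    summarise(
      n_markers = n(),
      genetic_length_cm = if (n() > 1) max(.data$cm) - min(.data$cm) else NA_real_,
      max_gap_cm = if (n() > 1) max(diff(sort(.data$cm))) else NA_real_,
      gap_lt5_pct = if (n() > 1) 100 * mean(diff(sort(.data$cm)) < 5) else NA_real_
    ) %>%
    left_join(phys, by = "lg") %>%
    mutate(
      density_markers_cm = .data$n_markers / .data$genetic_length_cm,
      mb = .data$mb %||% NA_real_,
      markers_per_mb = .data$n_markers / .data$mb,
      cm_per_mb = .data$genetic_length_cm / .data$mb
    ) %>%
    select(
      "lg", "n_markers", "genetic_length_cm", "density_markers_cm",
      "max_gap_cm", "gap_lt5_pct",
      physical_mb = "mb", "markers_per_mb", "cm_per_mb"
    )
}

#' Pairwise recombination fractions within a linkage group
#'
#' For every marker pair of one group, the observed recombinant fraction
#' over co-called homozygous lines — the matrix displayed as a linkage heat
#' map. Entries supported by fewer than `min_lines` informative lines are
#' flagged unreliable.
#'
#' @param gm Genotype tibble (>= 2 markers after subsetting).
#' @param markers Optional character vector restricting to one group's
#'   marker ids.
#' @param min_lines Minimum informative lines for a reliable entry.
#' @return Tibble of unordered pairs (`marker1`, `marker2`, including the
#'   zero diagonal) with `recfrac`, `n_lines`, `reliable`; use
#'   [recfrac_matrix()] for the symmetric matrix form.
#' @export
pairwise_recfrac <- function(gm, markers = NULL, min_lines = 10) {
  check_genotypes(gm)
  if (!is.null(markers)) gm <- gm[gm$marker_id %in% markers, , drop = FALSE]
  if (nrow(gm) < 2) abort("Need >= 2 markers for pairwise recombination fractions.")
  calls <- geno_call_matrix(gm)
  n <- nrow(calls)
  hom <- calls == "a" | calls == "b"
  res <- vector("list", n * (n + 1) / 2)
  k <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      k <- k + 1L
      if (i == j) {
        res[[k]] <- list(i = i, j = j, rf = 0, nl = sum(hom[i, ]))
        next
      }
      ok <- hom[i, ] & hom[j, ]
      nl <- sum(ok)
      rf <- if (nl > 0) mean(calls[i, ok] != calls[j, ok]) else NA_real_
      res[[k]] <- list(i = i, j = j, rf = rf, nl = nl)
    }
  }
  res <- bind_rows(res)
  tibble(
    marker1 = gm$marker_id[res$i],
    marker2 = gm$marker_id[res$j],
    recfrac = res$rf,
    n_lines = res$nl,
    reliable = res$nl >= min_lines
  )
}

#' @rdname pairwise_recfrac
#' @param pairs Output of `pairwise_recfrac()`.
#' @export
recfrac_matrix <- function(pairs) {
  ids <- unique(c(pairs$marker1, pairs$marker2))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(pairs$marker1, ids)
  j <- match(pairs$marker2, ids)
  m[cbind(i, j)] <- pairs$recfrac
  m[cbind(j, i)] <- pairs$recfrac
  m
}
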