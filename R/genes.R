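#' Genes near hotspot windows
#'
#' Returns the genes whose span overlaps any hotspot window expanded by
#' `flank` bp on each side (the "genes in the 100-kb interval of a hotspot
#' locus" collection; `flank = 0` gives strict overlap). Coordinates are
#' 0-based half-open, so a gene starting exactly at `window_end + flank`
#' does not overlap. Results are deduplicated by `gene_id` and ordered as
#' in `genes`, hence invariant to hotspot ordering.
#'
#' @param calls A `hotspot_calls` tibble (columns `chrom`, `start`, `end`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, 0-based
#'   half-open; see [read_genes()]).
#' @param flank Symmetric expansion of each hotspot window in bp.
#' @return The overlapping subset of `genes`.
#' @export
genes_near_hotspots <- function(calls, genes, flank = 1e5) {
  calls <- as_tibble(calls)
  genes <- as_tibble(genes)
  if (!nrow(calls)) return(genes[0, , drop = FALSE])
  if (flank < 0) abort("`flank` must be >= 0.")
  # 0-based half-open -> IRanges 1-based closed
  hs <- GenomicRanges::GRanges(
    calls$chrom,
    IRanges::IRanges(
      start = pmax(calls$start - flank, 0) + 1,
      end = calls$end + flank
    )
  )
  gn <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1, end = genes$end)
  )
  hit <- GenomicRanges::findOverlaps(gn, hs)
  idx <- sort(unique(S4Vectors::queryHits(hit)))
  out <- genes[idx, , drop = FALSE]
  out[!duplicated(out$gene_id), , drop = FALSE]
}

#' GO term frequency among a gene set
#'
#' Tallies functional-category annotations of a gene set against a
#' user-supplied GO mapping: per-term gene counts with the fraction of
#' annotated genes carrying the term (terms overlap, so fractions do not
#' sum to 1), plus per-aspect subtotals when the mapping carries an
#' `aspect` column. Genes without any mapping entry are reported in an
#' `unannotated` row.
#'
#' @param genes Gene tibble (`gene_id`, ...), e.g. from
#'   [genes_near_hotspots()].
#' @param go_map Mapping tibble (`gene_id`, `term_id`, optionally `aspect`,
#'   `label`); see [read_go_map()].
#' @return List with `terms` (tibble `term_id`, [`aspect`, `label`,]
#'   `count`, `fraction`), `aspects` (tibble of per-aspect distinct-gene
#'   subtotals, possibly empty) and `n_annotated`/`n_unannotated` counts.
#' @export
go_frequency <- function(genes, go_map) {
  genes <- distinct(as_tibble(genes), .data$gene_id)
  go_map <- as_tibble(go_map)
  hits <- inner_join(genes, go_map, by = "gene_id")
  n_annot <- n_distinct(hits$gene_id)
  n_unannot <- nrow(genes) - n_annot
  grp_cols <- intersect(c("term_id", "aspect", "label"), names(hits))
  terms <- hits %>%
    group_by(across(all_of(grp_cols))) %>%
    summarise(count = n_distinct(.data$gene_id), .groups = "drop") %>%
    mutate(fraction = if (n_annot > 0) .data$count / n_annot else NA_real_) %>%
    arrange(dplyr::desc(.data$count), .data$term_id)
  if (n_unannot > 0) {
    unrow <- tibble(term_id = "unannotated", count = n_unannot, fraction = NA_real_)
    terms <- bind_rows(terms, unrow)
  }
  aspects <- if ("aspect" %in% names(hits)) {
    hits %>%
      group_by(.data$aspect) %>%
      summarise(n_genes = n_distinct(.data$gene_id), .groups = "drop") %>%
      mutate(pct_of_genes = 100 * .data$n_genes / nrow(genes))
  } else {
    tibble(aspect = character(), n_genes = integer(), pct_of_genes = numeric())
  }
  list(
    terms = terms, aspects = aspects,
    n_annotated = n_annot, n_unannotated = n_unannot
  )
}
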