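#' Marker-selection filters
#'
#' `filter_map_markers()` keeps markers whose missing-call fraction is at
#' most `max_missing` (inclusive, matching the "<= 5% missing data"
#' selection used for linkage-map markers). `filter_panel_markers()` keeps
#' markers whose call frequency is strictly greater than `min_call` and
#' whose minor allele frequency (MAF) is strictly greater than `min_maf`
#' (matching the "call frequency > 0.8 and MAF > 0.05" panel selection).
#' MAF counts two alleles per sample, heterozygous calls contributing one of
#' each; markers with no non-missing call are excluded, not an error. Both
#' filters are idempotent and preserve marker order and the sample set.
#'
#' @param gm Genotype tibble (see [sample_ids()]).
#' @param max_missing Maximum tolerated missing fraction, in [0, 1].
#' @param min_call,min_maf Strict lower bounds in (0, 1) for call frequency
#'   and minor allele frequency.
#' @return The filtered genotype tibble.
#' @export
filter_map_markers <- function(gm, max_missing = 0.05) {
  check_genotypes(gm)
  if (max_missing < 0 || max_missing > 1) abort("`max_missing` must be in [0, 1].")
  calls <- geno_call_matrix(gm)
  miss <- rowMeans(calls == "-")
  gm[miss <= max_missing, , drop = FALSE]
}

#' @rdname filter_map_markers
#' @export
filter_panel_markers <- function(gm, min_call = 0.8, min_maf = 0.05) {
  check_genotypes(gm)
  if (min_call <= 0 || min_call >= 1 || min_maf <= 0 || min_maf >= 1) {
    abort("`min_call` and `min_maf` must lie in (0, 1).")
  }
  calls <- geno_call_matrix(gm)
  called <- calls != "-"
  call_freq <- rowMeans(called)
  # two alleles per called sample; h contributes one of each
  n_a <- 2 * rowSums(calls == "a") + rowSums(calls == "h")
  n_b <- 2 * rowSums(calls == "b") + rowSums(calls == "h")
  tot <- n_a + n_b
  maf <- if_else(tot > 0, pmin(n_a, n_b) / pmax(tot, 1), 0)
  gm[call_freq > min_call & maf > min_maf, , drop = FALSE]
}
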