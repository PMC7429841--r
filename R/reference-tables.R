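#' Reference summary tables for the peanut F6 map and accession panel
#'
#' Two small tables of published summary statistics for cultivated peanut
#' ship with the package and are used as arithmetic references in the test
#' suite and as the default chromosome layout of [peanut_genome()]:
#'
#' * `peanut_map_reference()` — per linkage group of a 4837-marker F6 SLAF
#'   linkage map: marker count, genetic length (cM), marker density
#'   (markers/cM), maximum adjacent gap (cM), percentage of gaps < 5 cM,
#'   physical length (Mb), and the map's printed per-Mb rate column (which
#'   numerically equals markers per Mb; see [summarize_map_stats()]).
#' * `peanut_panel_reference()` — per chromosome of a 49-accession natural
#'   panel: crossover-event count, first/last marker positions (bp), spanned
#'   distance (bp and Mb), and recombination rate in events per Mb.
#'
#' Both tables carry 20 chromosome rows (A01–A10, B01–B10) plus
#' `A_subgenome`, `B_subgenome` and `Total` rows, flagged by `row_type`.
#'
#' @param rows Which rows to return: chromosome rows only, summary rows
#'   only, or everything.
#' @return A tibble; see Details for columns.
#' @export
peanut_map_reference <- function(rows = c("chromosome", "summary", "all")) {
  rows <- match.arg(rows)
  ref_table("peanut_f6_map_stats.tsv", rows)
}

#' @rdname peanut_map_reference
#' @export
peanut_panel_reference <- function(rows = c("chromosome", "summary", "all")) {
  rows <- match.arg(rows)
  ref_table("peanut_panel_recombination.tsv", rows)
}

ref_table <- function(file, rows) {
  path <- system.file("extdata", file, package = "recohot", mustWork = TRUE)
  tb <- readr::read_tsv(path, col_types = readr::cols(
    group = readr::col_character(),
    .default = readr::col_double()
  ))
  tb <- mutate(tb,
    row_type = if_else(.data$group %in% c("A_subgenome", "B_subgenome", "Total"),
      "summary", "chromosome"
    )
  )
  switch(rows,
    chromosome = filter(tb, .data$row_type == "chromosome"),
    summary = filter(tb, .data$row_type == "summary"),
    all = tb
  )
}
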