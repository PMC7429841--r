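#' Read and write genotype matrices
#'
#' The native format is a TSV with header `marker_id`, `chrom`, `pos`
#' (0-based bp) followed by one column per sample, calls coded
#' `a`/`b`/`h`/`-`; `write_genotypes()` then `read_genotypes()` round-trips
#' byte-identically. VCF 4.2 is supported with the GT mapping
#' `0/0` = `a`, `1/1` = `b`, `0/1` (or `1/0`) = `h`, `./.` = `-`
#' (reading uses \pkg{VariantAnnotation}; writing emits a minimal
#' sites-plus-GT VCF).
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`; default guesses from the extension.
#' @param gm Genotype tibble.
#' @return `read_genotypes()`: a genotype tibble. `write_genotypes()`: the
#'   input, invisibly.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  gm <- switch(format,
    tsv = read_genotypes_tsv(path),
    vcf = read_genotypes_vcf(path)
  )
  check_genotypes(gm, arg = path)
  validate_calls(gm)
  gm
}

read_genotypes_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_double(),
    .default = readr::col_character()
  ))
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("Reading VCF requires the VariantAnnotation package.")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  code <- function(x) {
    dplyr::case_when(
      x %in% c("0/0", "0|0") ~ "a",
      x %in% c("1/1", "1|1") ~ "b",
      x %in% c("0/1", "1/0", "0|1", "1|0") ~ "h",
      TRUE ~ "-"
    )
  }
  calls <- apply(gt, 2, code)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt), dimnames = dimnames(gt))
  bind_cols(
    tibble(
      marker_id = rownames(gt),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr) - 1 # VCF is 1-based
    ),
    as_tibble(calls)
  )
}

validate_calls <- function(gm) {
  calls <- geno_call_matrix(gm)
  bad <- which(matrix(!(calls %in% GENO_CODES), nrow(calls)), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Unknown genotype code '%s' at marker '%s', sample '%s'.",
      calls[bad[1, 1], bad[1, 2]], gm$marker_id[bad[1, 1]],
      colnames(calls)[bad[1, 2]]
    ))
  }
  invisible(gm)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(gm, path, format = c("auto", "tsv", "vcf")) {
  check_genotypes(gm)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    readr::write_tsv(gm, path)
  } else {
    write_genotypes_vcf(gm, path)
  }
  invisible(gm)
}

write_genotypes_vcf <- function(gm, path) {
  ids <- sample_ids(gm)
  calls <- geno_call_matrix(gm)
  gt <- matrix("./.", nrow(calls), ncol(calls))
  gt[calls == "a"] <- "0/0"
  gt[calls == "b"] <- "1/1"
  gt[calls == "h"] <- "0/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=recohot",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- paste(
    gm$chrom, format(gm$pos + 1, scientific = FALSE, trim = TRUE),
    gm$marker_id, "A", "T", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
}

#' Read and write genetic map files
#'
#' A map file is a TSV with columns `marker_id`, `lg` (linkage group) and
#' `cm` (cumulative genetic position, non-decreasing within a group).
#'
#' @param path File path.
#' @param map Map tibble.
#' @return `read_map()`: the map tibble; `write_map()`: the input, invisibly.
#' @export
read_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    lg = readr::col_character(),
    cm = readr::col_double()
  ))
  bad <- map %>%
    group_by(.data$lg) %>%
    summarise(ok = !is.unsorted(.data$cm)) %>%
    filter(!.data$ok)
  if (nrow(bad)) {
    abort(sprintf("cM positions must be non-decreasing within group '%s'.", bad$lg[1]))
  }
  map
}

#' @rdname read_map
#' @export
write_map <- function(map, path) {
  readr::write_tsv(map[, c("marker_id", "lg", "cm")], path)
  invisible(map)
}

#' Write intervals as BED
#'
#' Writes a 6-column BED (0-based half-open): `chrom`, `start`, `end`,
#' `name`, `score`, `strand` ("."). Used for truth crossovers (name =
#' sample, score = haplotype copy) and hotspot calls.
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  name <- x$name %||% x$sample %||% "."
  score <- x$score %||% x$hap %||% 0
  readr::write_tsv(
    tibble(
      chrom = x$chrom, start = as.integer(round(x$start)),
      end = as.integer(round(x$end)), name = name, score = score,
      strand = "."
    ),
    path,
    col_names = FALSE
  )
  invisible(x)
}

#' Read gene annotations
#'
#' Reads gene records from GFF3 (via \pkg{rtracklayer}; features of type
#' `gene`, or all features if none are typed `gene`) or from a TSV with
#' columns `gene_id`, `chrom`, `start`, `end`, `strand`. Coordinates are
#' returned 0-based half-open.
#'
#' @param path File path (`.gff`/`.gff3` or TSV).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("Reading GFF3 requires the rtracklayer package.")
    }
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    id <- gr$ID %||% gr$gene_id %||% gr$Name %||% as.character(seq_along(gr))
    tibble(
      gene_id = as.character(id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1, # GFF3 is 1-based closed
      end = as.numeric(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(), chrom = readr::col_character(),
      start = readr::col_double(), end = readr::col_double(),
      strand = readr::col_character()
    ))
  }
}

#' Read a GO term-to-gene mapping
#'
#' A two-column TSV `gene_id`, `term_id`, optionally with `aspect`
#' (`BP`/`CC`/`MF`) and `label` columns (an OBO-lite label table may be
#' supplied separately and joined by `term_id`).
#'
#' @param path Mapping TSV path.
#' @param labels Optional label table path (TSV `term_id`, `aspect`,
#'   `label`).
#' @return Tibble with `gene_id`, `term_id` and, when available, `aspect`
#'   and `label`.
#' @export
read_go_map <- function(path, labels = NULL) {
  go <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), term_id = readr::col_character(),
    .default = readr::col_character()
  ))
  if (!is.null(labels)) {
    lab <- readr::read_tsv(labels, col_types = readr::cols(
      term_id = readr::col_character(), .default = readr::col_character()
    ))
    go <- left_join(go, lab, by = "term_id")
  }
  go
}
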