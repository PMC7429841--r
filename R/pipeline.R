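#' Default pipeline configuration
#'
#' Returns the full default configuration of [run_pipeline()] as a nested
#' list; pass overrides as a (possibly partial) list or a YAML file with
#' the same structure. The default world is the scaled-down peanut stand-in
#' of [scaled_peanut_genome()]: 20 chromosomes of 10 Mb keeping the
#' reference map's mean per-chromosome genetic length, one planted 20x
#' hotspot window of 100 kb per chromosome, an F6 RIL of 200 lines and a
#' 49-accession founder-mosaic panel.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    genome = list(
      n_chrom = 20L, chrom_mb = 10, cm_per_chrom = NULL,
      hotspots_per_chrom = 1L, hotspot_width = 1e5, hotspot_fold = 20
    ),
    ril = list(
      n_lines = 200L, generations = 6L, n_markers = 1000L,
      missing_rate = 0.05
    ),
    panel = list(
      n_accessions = 49L, n_founders = 8L, n_markers = 600L,
      missing_rate = 0.05, historical_meioses = 20, founder_block_mb = 2
    ),
    filters = list(max_missing = 0.05, min_call = 0.8, min_maf = 0.05),
    crossover = list(min_flank_span = 1e4, small_block = 2e5),
    windows = list(count_width = 1e5, rate_width = 1e6),
    hotspots = list(alpha = 0.01, fold = 3, ril_threshold = 50, mode = "derived"),
    genes = list(gff = NULL, go_map = NULL, flank = 1e5)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full simulate-to-hotspots pipeline
#'
#' Orchestrates one reproducible run: simulate the RIL and panel
#' populations, apply the marker filters, segment blocks and call
#' crossovers, build windowed landscapes, call hotspots (fold rule on the
#' panel, absolute-rate rule on the RIL map, Poisson threshold on window
#' counts), and, when an annotation is configured, collect genes near
#' hotspots with their GO category tallies. All stage outputs are written
#' to `out_dir` as TSV/BED text files, a machine-readable `report.json`
#' summarises map-style and panel-style statistics and hotspot fractions,
#' and `manifest.json` records the configuration, seed, package version
#' and MD5 checksum of every output, so a rerun with the same manifest
#' reproduces identical files.
#'
#' @param config Partial configuration list, or path to a YAML file; see
#'   [default_pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return List (class `recohot_run`) with `report`, `manifest`, `config`
#'   and the in-memory stage objects (`ril`, `panel`, `events`, `tracks`,
#'   `hotspots`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("recohot_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  genome <- stage("genome", do.call(scaled_peanut_genome, cfg$genome))

  ril <- stage("simulate_ril", simulate_ril(genome, sim_config(
    n_lines = cfg$ril$n_lines, generations = cfg$ril$generations,
    n_markers = cfg$ril$n_markers, missing_rate = cfg$ril$missing_rate,
    marker_type = "snp", seed = cfg$seed
  )))
  panel <- stage("simulate_panel", simulate_panel(
    genome,
    n_founders = cfg$panel$n_founders,
    cfg = sim_config(
      n_lines = cfg$panel$n_accessions, n_markers = cfg$panel$n_markers,
      missing_rate = cfg$panel$missing_rate, marker_type = "indel",
      seed = cfg$seed + 1L
    ),
    historical_meioses = cfg$panel$historical_meioses,
    founder_block_mb = cfg$panel$founder_block_mb,
    min_call = cfg$filters$min_call, min_maf = cfg$filters$min_maf
  ))

  gm_ril <- stage("filter_map_markers",
    filter_map_markers(ril$genotypes, cfg$filters$max_missing))

  ev_ril <- stage("crossovers_ril", {
    segment_blocks(gm_ril) %>%
      call_crossovers(
        min_flank_span = cfg$crossover$min_flank_span,
        small_block = cfg$crossover$small_block
      )
  })
  ev_panel <- stage("crossovers_panel", {
    segment_blocks(panel$genotypes) %>%
      call_crossovers(
        min_flank_span = cfg$crossover$min_flank_span,
        small_block = cfg$crossover$small_block
      )
  })

  tracks <- stage("landscape", {
    cw <- cfg$windows$count_width
    list(
      ril_counts = window_rates(window_counts(ev_ril, genome, cw)),
      panel_counts = window_rates(window_counts(ev_panel, genome, cw))
    )
  })
  map <- stage("genetic_map", genetic_distances(gm_ril))
  ril_map_track <- stage("map_rates", window_map_rates(
    map, genome, cfg$windows$count_width
  ))

  hs <- stage("hotspots", {
    mode <- cfg$hotspots$mode
    list(
      panel_fold = call_fold_hotspots(tracks$panel_counts,
        fold = cfg$hotspots$fold, mode = mode
      ),
      panel_poisson = call_poisson_hotspots(tracks$panel_counts,
        alpha = cfg$hotspots$alpha
      ),
      ril_rate = call_ril_hotspots(ril_map_track,
        threshold = cfg$hotspots$ril_threshold
      )
    )
  })

  genes_out <- NULL
  if (!is.null(cfg$genes$gff)) {
    genes_out <- stage("genes", {
      gn <- read_genes(cfg$genes$gff)
      near <- genes_near_hotspots(hs$panel_fold, gn, flank = cfg$genes$flank)
      freq <- if (!is.null(cfg$genes$go_map)) {
        go_frequency(near, read_go_map(cfg$genes$go_map))
      }
      list(genes = near, go = freq)
    })
  }

  # ---- summaries --------------------------------------------------------
  phys <- set_names(genome$chromosomes$length_bp / 1e6, genome$chromosomes$chrom)
  map_stats <- map_summary(map, phys)
  panel_chrom <- count_events(ev_panel, "chrom") %>%
    left_join(tibble(chrom = names(phys), mb = unname(phys)), by = "chrom") %>%
    mutate(rate_n_mb = .data$n_events / .data$mb)
  # equal-length chromosomes (as in the scaled stand-in genome) leave the
  # count-length correlation undefined; report NA rather than fail
  corr_tidy <- tryCatch(
    tidy(length_correlation(panel_chrom$n_events, panel_chrom$mb)),
    error = function(e) tibble(estimate = NA_real_, p.value = NA_real_)
  )
  n_pass_ril <- nrow(filter(ev_ril, .data$status == "pass"))
  n_pass_panel <- nrow(filter(ev_panel, .data$status == "pass"))

  report <- list(
    ril_map_summary = map_stats,
    panel_chromosomes = panel_chrom,
    panel_length_correlation = corr_tidy,
    n_crossovers = list(ril = n_pass_ril, panel = n_pass_panel),
    crossovers_per_line = n_pass_ril / cfg$ril$n_lines,
    hotspot_fractions = list(
      panel_fold_pct_of_windows = hotspot_fraction(hs$panel_fold, nrow(tracks$panel_counts)),
      panel_fold_pct_of_events = hotspot_fraction(hs$panel_fold, max(n_pass_panel, 1)),
      ril_rate_pct_of_windows = hotspot_fraction(hs$ril_rate, nrow(ril_map_track))
    ),
    thresholds = list(
      fold = cfg$hotspots$fold, alpha = cfg$hotspots$alpha,
      poisson_k = hs$panel_poisson$threshold[1] %||% NA,
      ril_threshold = cfg$hotspots$ril_threshold,
      min_flank_span = cfg$crossover$min_flank_span,
      small_block = cfg$crossover$small_block
    )
  )

  # ---- write outputs ----------------------------------------------------
  files <- c(
    genotypes_ril = "genotypes_ril.tsv", genotypes_panel = "genotypes_panel.tsv",
    events_ril = "events_ril.tsv", events_panel = "events_panel.tsv",
    map = "map_ril.tsv", map_summary = "map_summary.tsv",
    track_ril = "track_ril.bedgraph", track_panel = "track_panel.bedgraph",
    hotspots_panel = "hotspots_panel.tsv", hotspots_ril = "hotspots_ril.tsv",
    truth_ril = "truth_ril.bed", report_tsv = "report.tsv",
    report_json = "report.json"
  )
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write_genotypes(gm_ril, paths["genotypes_ril"])
  write_genotypes(panel$genotypes, paths["genotypes_panel"])
  readr::write_tsv(ev_ril, paths["events_ril"])
  readr::write_tsv(ev_panel, paths["events_panel"])
  write_map(map, paths["map"])
  readr::write_tsv(map_stats, paths["map_summary"])
  write_bedgraph <- function(tr, path) {
    readr::write_tsv(
      as_tibble(tr)[, c("chrom", "start", "end", if ("rate" %in% names(tr)) "rate" else "n")],
      path,
      col_names = FALSE
    )
  }
  write_bedgraph(tracks$ril_counts, paths["track_ril"])
  write_bedgraph(tracks$panel_counts, paths["track_panel"])
  readr::write_tsv(as_tibble(hs$panel_fold), paths["hotspots_panel"])
  readr::write_tsv(as_tibble(hs$ril_rate), paths["hotspots_ril"])
  write_bed(
    transmute(ril$truth$breakpoints,
      chrom = .data$chrom, start = floor(.data$pos), end = floor(.data$pos) + 1,
      name = .data$sample, score = .data$hap
    ),
    paths["truth_ril"]
  )
  readr::write_tsv(map_stats, paths["report_tsv"])
  jsonlite::write_json(report, paths["report_json"],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("recohot")),
    seed = cfg$seed,
    config = cfg,
    thresholds = report$thresholds,
    checksums = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  structure(
    list(
      report = report, manifest = manifest, config = cfg, out_dir = out_dir,
      ril = ril, panel = panel,
      events = list(ril = ev_ril, panel = ev_panel),
      tracks = c(tracks, list(ril_map = ril_map_track)),
      hotspots = hs, genes = genes_out, map = map
    ),
    class = "recohot_run"
  )
}

#' @export
print.recohot_run <- function(x, ...) {
  cat(sprintf(
    "<recohot_run> seed %d: %d RIL crossovers (%.1f/line), %d panel crossovers, %d+%d hotspot windows\n  outputs: %s\n",
    x$config$seed, x$report$n_crossovers$ril, x$report$crossovers_per_line,
    x$report$n_crossovers$panel, nrow(x$hotspots$panel_fold),
    nrow(x$hotspots$ril_rate), x$out_dir
  ))
  invisible(x)
}
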