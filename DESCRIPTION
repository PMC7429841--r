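Package: recohot
Title: Meiotic Crossover Detection and Recombination Hotspot Mapping in
    Allotetraploid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossover events and recombination hotspots from
    marker genotypes of recombinant inbred line (RIL) populations and natural
    panels of allotetraploid crops such as peanut. Provides a forward
    simulator of meiosis through a selfing pedigree and of founder-mosaic
    panels over a configurable recombination landscape; marker-selection
    filters (missingness, call rate, minor allele frequency); the
    independence G statistic and modified LOD linkage metric with
    single-linkage grouping; genotype-block segmentation and crossover
    calling with flank-span and small-block filters; windowed recombination
    landscapes with Poisson, fold-over-mean and absolute-rate hotspot rules
    plus a multi-principle consensus; and hotspot-to-gene annotation with GO
    category tallies. Functions take and return tibbles so analyses compose
    with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    broom,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    igraph,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    withr
Config/testthat/edition: 3
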