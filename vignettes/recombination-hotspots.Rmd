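---
title: "Mapping meiotic crossovers and recombination hotspots with recohot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping meiotic crossovers and recombination hotspots with recohot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recohot)
library(dplyr)
```

## The problem

Meiotic crossovers reshuffle parental alleles and are the raw material of
plant breeding; their genomic placement is strongly non-uniform, with
*hotspots* — windows whose crossover density far exceeds the genome
average — concentrated near genes that often relate to environmental
response. In an allotetraploid crop such as cultivated peanut
(*Arachis hypogaea*, AABB, 2n = 4x = 40), crossovers can be observed in two
complementary designs:

* a **recombinant inbred line (RIL) population**: ~200 F6 lines from a
  biparental cross, genotyped at thousands of (hemi-)SNP markers, where
  each line's genome is a mosaic of the two parental genomes and every
  mosaic switch is an accumulated crossover;
* a **natural panel**: a few dozen accessions whose genomes are mosaics of
  ancestral founder haplotypes, where historical recombination leaves both
  switch points and eroded local haplotype conservation.

recohot implements the full path from genotype matrix to annotated
hotspot, plus a forward simulator of both designs so every step can be
validated against a known truth.

## The genotype model

Calls are coded against the two parents: `a` (homozygous first parent),
`b` (homozygous second parent), `h` (heterozygous), `-` (missing). A
genotype table is a tibble with one row per marker (`marker_id`, `chrom`,
`pos` in 0-based bp) and one column per sample; all coordinates in the
package are 0-based and half-open, converted at the VCF/GFF3 boundary.

Two marker-selection filters mirror common practice: map markers keep a
missing fraction **at most** 5% (inclusive), panel markers keep call
frequency **strictly above** 0.8 and minor allele frequency strictly above
0.05, with heterozygous calls contributing one copy of each allele. The
asymmetry (inclusive vs strict) is deliberate and matched to how such
thresholds are conventionally quoted.

## Linkage grouping: the G statistic and the modified LOD

Marker pairs are scored for linkage with an independence test on their
genotype contingency table. With observed counts $o$ and expected counts
$e$ (row total × column total / grand total),

$$G = \sqrt{2\sum o \ln(o/e)},$$

and the modified LOD transform, with $d$ the table's degrees of freedom
$(r-1)(c-1)$ and $q = e^{-G^2/(2(d-1))}$,

$$\mathrm{mLOD} = \frac{[(4-q)\,q - 3](d-1) + G^2}{2\ln 10}.$$

`mlod(0, d) = 0`, and for strong linkage the transform approaches the
familiar $G^2/(2\ln 10)$ scale. Three numerical choices are worth noting:

* cells with $o = 0$ contribute zero (the $x\log x$ limit);
* for $d = 1$ (a 2×2 table, common between two purely homozygous
  biallelic markers) the transform's $d \to 1$ limit is used, which is
  exactly the classical LOD approximation $G^2 / (2 \ln 10)$;
* because some established pipelines feed the *unrooted* statistic
  $2\sum o\ln(o/e)$ into the same transform, `classic_g = TRUE` provides
  that variant; the default uses the rooted form.

`group_markers()` then clusters markers by single linkage with mLOD as
similarity. Cutting single-linkage agglomeration at the threshold is
mathematically the connected-components partition of the thresholded
pairwise graph, which the test suite verifies against an independent graph
implementation. Marker *ordering* within a group deliberately defaults to
physical position: iterative map-ordering algorithms are a separate
contribution of dedicated mapping software, while the grouping metric
above is fully specified and reimplemented here.

## Genetic distances and the finite-generation correction

Adjacent-marker recombinant fractions $R$ are estimated from lines
homozygous at both markers, then mapped to centiMorgans by Haldane
(default) or Kosambi. For RILs by selfing the observed $R$ is inflated by
map expansion; the classical fully inbred inverse is
$r = R/(2-2R)$ (from $R_\infty = 2r/(1+2r)$). A finite pedigree, however,
has not realised the full expansion: the exact two-locus selfing
recursion implemented in `ril_expected_r()` shows that at F6 the
homozygote-pair recombinant fraction is only ≈ 86% of $R_\infty$, so maps
corrected with the closed form come out ≈ 15% short. Passing
`generations = 6` to `genetic_distances()` inverts the exact finite
relation instead and removes the bias (verified by simulation recovery in
the test suite). The closed form remains the default because it is the
form conventionally quoted; fractions that saturate ($r \ge 0.5$) are
capped at 0.49 with a warning rather than producing infinite distances.

`map_summary()` reports the usual per-group map statistics (genetic
length, markers/cM, maximum gap, % gaps < 5 cM) and **both** per-Mb
columns — markers/Mb and cM/Mb — because published map tables sometimes
label the former as a "recombination rate"; keeping both avoids
propagating that ambiguity.

## Crossover calling

`segment_blocks()` converts each sample's ordered calls per chromosome
into maximal runs of identical non-missing state; missing calls are
skipped and never break a run; boundaries sit at the midpoint between the
bounding markers. `call_crossovers()` emits one candidate event per state
change, localised between the flanking markers, and classifies it:

* `pass` — both flanking blocks span ≥ 10 kb (`min_flank_span`) and
  neither flank is small;
* `flank_fail` — a flank spans < 10 kb (the status enum needs this case:
  an event with a 5 kb flank is neither passing nor merely "small");
* `small_block_flag` — a flank spans ≤ 200 kb (`small_block`): such
  events are candidate false positives, retained but separable, and
  `drop_small_blocks = TRUE` automates their exclusion;
* `ambiguous_excluded` — heterozygous state on both sides of the
  breakpoint.

Only `pass` events enter counts and landscapes. Raising `min_flank_span`
can only shrink the passing set (a property test).

## Landscapes and hotspot rules

Windows tile each chromosome without overlap (100 kb for event-locus
scans, 1000 kb for rate landscapes; the truncated last window uses its
true width). "Sliding" windows are implemented as this non-overlapping
tiling so that window counts conserve events exactly; each passing event
is assigned to the single window containing its breakpoint midpoint.
Rates are events per Mb (or cM per Mb when integrated from a genetic map
with `window_map_rates()`), and the width-weighted mean of window rates
equals the genome mean rate as an exact identity.

Four hotspot rules are provided:

1. **Poisson threshold** (`call_poisson_hotspots()`): the smallest count
   $k^*$ with $P(X \ge k^*) \le \alpha$ under a Poisson null with the
   genome-mean count per window. The level $\alpha$ is not fixed by
   convention in this literature; the default is 0.01, logged in the
   output, with optional Bonferroni correction across windows.
2. **Fold over mean** (`call_fold_hotspots()`): rate ≥ 3× the genome mean
   ("derived" mode), or a literal fixed cutoff such as 25 n/Mb ("paper"
   mode) for reproducing published thresholds.
3. **RIL absolute rate** (`call_ril_hotspots()`): map-based window rate
   strictly > 50 cM/Mb.
4. **Consensus** (`consensus_hotspots()`): the conjunction of low
   haplotype conservation (below a configurable quantile, default 0.25),
   the RIL rule, weak within-window pairwise linkage (mean recombination
   fraction above a quantile, default 0.75) and panel rate ≥ 3× the panel
   mean — each criterion individually toggleable, and the consensus set is
   by construction contained in every component set. Quantile defaults are
   design choices, not published constants.

Haplotype conservation (`conservation_score()`) is the fraction of lines
carrying the modal local haplotype (majority vote per line across the
window's markers, deterministic first-state tie-break); it anticorrelates
with the switch-point density, which the suite checks on a planted
landscape.

`genes_near_hotspots()` expands each hotspot window by a symmetric 100-kb
flank (interpreting "the 100-kb interval of a hotspot locus"; `flank = 0`
gives strict overlap) and intersects gene annotations;
`go_frequency()` tallies functional categories against a user-supplied GO
mapping only — no enrichment p-values are computed, matching the
frequency-style reporting this analysis descends from, and reproducing any
particular published gene count would require the real peanut annotation,
which is external data.

## The simulator: what it emulates, and what it does not

`simulate_ril()` advances an F1 through `generations - 1` rounds of
selfing, drawing each gamete's crossover count per chromosome from a
Poisson with mean equal to the landscape's genetic length in Morgans and
placing crossovers by inverse-CDF sampling of the landscape density.
Defaults state the emulated world: 200 lines, F6, ≤ 5% missing calls,
biallelic hemi-SNP-like markers. `simulate_panel()` builds each accession
as a homozygous founder mosaic whose switch points accumulate over an
effective number of historical meioses (default 20, a deliberate
order-of-magnitude choice for a breeding-program panel), with founder
alleles drawn from piecewise-constant haplotype tracks (mean segment 2 Mb)
so that markers are in LD along founders — without this, block
segmentation on panel genotypes would be meaningless. Emitted panel
markers are passed through the panel filters, as real InDel marker sets
are.

Deliberate simplifications: **no crossover interference** (Poisson
placement matches the Poisson-threshold logic used downstream), **no
obligate chiasma**, no gene conversion, no sequencing-read simulation, no
genotyping error beyond missingness, and no modelling of homoeologous
collapse between the A and B subgenomes. A green recovery test therefore
establishes that the detection arithmetic is right under clean
Mendelian-with-missingness data, not that it is robust to, e.g., reference
bias or paralogous markers.

The built-in genome layouts encode two scales. `peanut_genome()` carries
the 20-chromosome physical lengths and per-chromosome cM/Mb of a published
peanut F6 reference map. `scaled_peanut_genome()` is the simulation
stand-in used by the tests and the acceptance script: 20 chromosomes of
10 Mb whose baseline rate preserves the reference map's *mean
per-chromosome genetic length* (2915.46 cM / 20 ≈ 145.8 cM, hence
≈ 14.6 cM/Mb), with one planted fold-20 hotspot window of 100 kb per
chromosome, snapped to the 100-kb scan grid. Preserving genetic rather
than physical length when scaling down keeps per-line crossover counts —
and therefore the power of every downstream rule — at realistic levels;
window-level event densities are ~10× the full-genome values, which makes
the planted-hotspot recovery check conservative with respect to false
positives and is the regime in which the 200 kb small-block flag bites
visibly (clustered hotspot crossovers are flagged, not lost).

## Reproducibility

All randomness in a simulation flows from the single `seed` in
`sim_config()`; `run_pipeline()` derives its panel seed as `seed + 1` and
writes a manifest with the configuration, every threshold used, and MD5
checksums of every output file, so a rerun with the same manifest
reproduces identical bytes. The pipeline's equal-length scaled
chromosomes leave the count-vs-length correlation undefined; the report
then carries `NA` rather than failing, since the correlation is meaningful
only for genomes with varying chromosome lengths.

## Known limitations

* Marker ordering within linkage groups is positional; no de novo
  ordering or error-correction of marker order is attempted.
* Panel crossover events are detected with the same block logic as RIL
  events; for very low-LD panels the flank filters dominate and counts
  should be read as relative, not absolute, densities.
* The Poisson hotspot null assumes exchangeable windows; chromosome-level
  rate heterogeneity inflates its tail slightly, which is why the fold
  rule is the default in the pipeline.
* GO tallies are frequencies over a user-supplied mapping; enrichment
  testing is out of scope.
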