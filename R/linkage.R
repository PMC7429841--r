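#' Independence G statistic for a genotype contingency table
#'
#' For observed counts `o` and expected counts `e` (row total x column
#' total / grand total when not supplied), computes
#' \deqn{G = \sqrt{2 \sum o \ln(o/e)}}
#' the square-rooted form used as input to the modified LOD transform
#' ([mlod()]). Cells with `o = 0` contribute 0 (the `x log x` limit
#' convention). `classic = TRUE` returns the classical likelihood-ratio
#' statistic `2 sum o ln(o/e)` (i.e. `G^2`) instead, since some linkage
#' pipelines feed that form into the transform.
#'
#' @param observed Matrix (or table) of non-negative genotype-pair counts.
#' @param expected Optional matrix of positive expected counts, same shape;
#'   defaults to the independence expectation from the margins.
#' @param classic If `TRUE` return `2 sum o ln(o/e)` without the square
#'   root.
#' @return A single non-negative number; 0 iff `o = e` in every cell.
#' @examples
#' o <- matrix(c(30, 10, 10, 30), 2)
#' g_statistic(o) # ~4.575
#' @export
g_statistic <- function(observed, expected = NULL, classic = FALSE) {
  o <- as.matrix(observed)
  if (any(o < 0)) abort("Observed counts must be non-negative.")
  if (is.null(expected)) {
    tot <- sum(o)
    if (tot <= 0) abort("Observed table is empty.")
    expected <- outer(rowSums(o), colSums(o)) / tot
  }
  e <- as.matrix(expected)
  pos <- o > 0
  if (any(e[pos] <= 0)) abort("Expected counts must be positive wherever o > 0.")
  inner <- 2 * sum(o[pos] * log(o[pos] / e[pos]))
  inner <- max(inner, 0) # numerical guard; >= 0 when e comes from margins
  if (classic) inner else sqrt(inner)
}

#' Modified LOD score from a G statistic
#'
#' Approximate transformation of the independence G statistic into a LOD
#' scale for linkage grouping:
#' \deqn{mLOD = \frac{[(4 - q) q - 3](d - 1) + G^2}{2 \ln 10},
#'   \quad q = e^{-G^2 / (2(d-1))}}
#' where `d` is the degrees of freedom of the contingency table
#' (taken as (rows-1)(cols-1)). `mLOD(0, d) = 0` and for large `G` it
#' approaches `(G^2 - 3(d-1)) / (2 ln 10)`.
#'
#' @param G Non-negative G statistic (vectorised).
#' @param d Degrees of freedom, >= 2 (`d = 1` would divide by zero).
#' @return The modified LOD score(s).
#' @examples
#' mlod(3, 2) # ~1.3125
#' @export
mlod <- function(G, d) {
  if (any(d < 2)) abort("`d` must be >= 2 (d = 1 makes the exponent undefined).")
  if (any(G < 0)) abort("`G` must be >= 0.")
  q <- exp(-G^2 / (2 * (d - 1)))
  (((4 - q) * q - 3) * (d - 1) + G^2) / (2 * log(10))
}

# Pairwise mLOD matrix between markers of a genotype tibble.
# Calls are integer-coded; per pair a contingency table over co-called
# samples is built, empty rows/columns dropped, d = (r-1)(c-1); pairs with
# d < 1 (either marker effectively monomorphic among co-called samples)
# get mLOD 0.
pairwise_mlod <- function(gm, classic_g = FALSE) {
  check_genotypes(gm)
  calls <- geno_call_matrix(gm)
  n <- nrow(calls)
  if (n < 2) abort("Need >= 2 markers for pairwise linkage.")
  code <- matrix(match(calls, c("a", "b", "h")), nrow = n) # NA = missing
  m <- matrix(0, n, n, dimnames = list(gm$marker_id, gm$marker_id))
  for (i in seq_len(n - 1)) {
    xi <- code[i, ]
    for (j in (i + 1):n) {
      xj <- code[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      if (!any(ok)) next
      tab <- tabulate((xi[ok] - 1L) * 3L + xj[ok], nbins = 9L)
      tab <- matrix(tab, 3, 3, byrow = TRUE)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      d <- (nrow(tab) - 1) * (ncol(tab) - 1)
      if (d < 1) next # a marker monomorphic among co-called samples
      # classic_g substitutes the classical (un-rooted) likelihood-ratio
      # statistic for G in the transform; default uses the rooted form
      stat <- g_statistic(tab, classic = classic_g)
      # d = 1 (2x2 table): use the d -> 1 limit of the transform, which is
      # the classical LOD approximation G^2 / (2 ln 10)
      val <- if (d >= 2) mlod(stat, d) else stat^2 / (2 * log(10))
      m[i, j] <- m[j, i] <- val
    }
  }
  m
}

#' Cluster markers into linkage groups
#'
#' Single-linkage clustering with the pairwise modified LOD ([mlod()]) as
#' similarity: two markers end up in the same group iff they are connected
#' by a chain of marker pairs with mLOD >= `threshold`. Implemented via
#' single-linkage agglomeration on the negated mLOD, whose cut at the
#' threshold is exactly the connected-components partition of the
#' thresholded pairwise graph. Deterministic for fixed input.
#'
#' @param gm Genotype tibble with >= 2 markers.
#' @param threshold Positive mLOD threshold (inclusive).
#' @param classic_g Use the classical (un-rooted) G form inside the metric;
#'   see [g_statistic()].
#' @return An object of class `linkage_groups`: list with `groups` (tibble
#'   `marker_id`, `chrom`, `pos`, `lg`; groups numbered by first marker in
#'   input order and labelled `LG01`, ...), `mlod` (the pairwise matrix)
#'   and `threshold`. Use [tidy()]/[glance()] to extract tibbles.
#' @export
group_markers <- function(gm, threshold = 5, classic_g = FALSE) {
  check_genotypes(gm)
  if (threshold <= 0) abort("`threshold` must be positive.")
  m <- pairwise_mlod(gm, classic_g = classic_g)
  n <- nrow(m)
  hc <- hclust(as.dist(-m), method = "single")
  cl <- cutree(hc, h = -threshold)
  # renumber groups by first occurrence so labels are stable
  lev <- unique(cl)
  lg <- sprintf("LG%02d", match(cl, lev))
  groups <- tibble(
    marker_id = gm$marker_id, chrom = gm$chrom, pos = gm$pos, lg = lg
  )
  structure(
    list(groups = groups, mlod = m, threshold = threshold),
    class = "linkage_groups"
  )
}

#' @export
print.linkage_groups <- function(x, ...) {
  cat(sprintf(
    "<linkage_groups> %d markers in %d group(s) at mLOD >= %g\n",
    nrow(x$groups), n_distinct(x$groups$lg), x$threshold
  ))
  invisible(x)
}

#' Tidy linkage-grouping results
#'
#' `tidy()` returns the per-marker group assignment; `glance()` a one-row
#' summary (marker count, group count, threshold, size of the largest
#' group).
#'
#' @param x A `linkage_groups` object.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom broom tidy glance
#' @export
tidy.linkage_groups <- function(x, ...) {
  x$groups
}

#' @rdname tidy.linkage_groups
#' @export
glance.linkage_groups <- function(x, ...) {
  sizes <- count(x$groups, .data$lg)
  tibble(
    n_markers = nrow(x$groups),
    n_groups = nrow(sizes),
    threshold = x$threshold,
    largest_group = max(sizes$n)
  )
}
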