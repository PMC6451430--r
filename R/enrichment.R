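#' Upper-tail hypergeometric probability
#'
#' Exact probability of drawing at least `k` marked items in `n` draws
#' without replacement from a universe of `N` items of which `K` are
#' marked. Summation is carried out in log space (lgamma-based binomial
#' coefficients with a log-sum-exp reduction), so magnitudes like 1e-57
#' survive; `k = 0` returns exactly 1.
#'
#' @param k observed overlap.
#' @param N universe size.
#' @param K marked items in the universe.
#' @param n sample size.
#' @param log.p return the natural-log probability instead.
#' @return `P(X >= k)`, a number in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_sf(5, 10, 5, 5) * 252  # == 1
hypergeom_sf <- function(k, N, K, n, log.p = FALSE) {
  stopifnot(length(k) == 1L, length(N) == 1L, length(K) == 1L,
            length(n) == 1L)
  if (any(c(k, N, K, n) < 0) || K > N || n > N)
    stop("hypergeom_sf: bounds violated (need 0 <= K, n <= N)")
  if (k <= 0) return(if (log.p) 0 else 1)
  if (k > min(K, n)) stop("hypergeom_sf: k exceeds min(K, n)")
  kk <- k:min(K, n)
  lp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  m <- max(lp)
  lsum <- m + log(sum(exp(lp - m)))
  lsum <- min(lsum, 0)  # guard rounding above 1
  if (log.p) lsum else exp(lsum)
}

# log-space hypergeometric PMF over all support points (internal; used by
# tests to check the PMF sums to one).
hypergeom_pmf <- function(N, K, n) {
  kk <- max(0L, n - (N - K)):min(K, n)
  lp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  setNames(exp(lp), kk)
}

#' Marker-list enrichment in a differentially expressed gene list
#'
#' Hypergeometric enrichment of a marker gene list (e.g. Paneth-cell
#' markers) within a differentially expressed gene list, against a stated
#' universe: `k` is the marker/DE overlap, `K` the markers present in the
#' universe, `n` the DE list size, `N` the universe size. Inputs are
#' deduplicated; results are invariant to ordering. Markers absent from the
#' universe are logged and excluded from `K`.
#'
#' @param markers,de_genes,universe character vectors of gene identifiers.
#' @return object of class `enrichment_result`: list with `overlap_k`,
#'   `markers_K`, `list_n`, `universe_N`, `p_value`, and
#'   `markers_outside_universe`.
#' @export
marker_enrichment <- function(markers, de_genes, universe) {
  markers <- unique(markers)
  de_genes <- unique(de_genes)
  universe <- unique(universe)
  outside <- setdiff(markers, universe)
  if (length(outside))
    message("marker_enrichment: ", length(outside),
            " marker(s) absent from universe; excluded from K")
  markers <- intersect(markers, universe)
  de_genes <- intersect(de_genes, universe)
  k <- length(intersect(markers, de_genes))
  res <- list(overlap_k = k,
              markers_K = length(markers),
              list_n = length(de_genes),
              universe_N = length(universe),
              p_value = hypergeom_sf(k, length(universe), length(markers),
                                     length(de_genes)),
              markers_outside_universe = outside)
  structure(res, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Marker enrichment: %d/%d markers in list of %d (universe %d), P = %.3g\n",
    x$overlap_k, x$markers_K, x$list_n, x$universe_N, x$p_value))
  invisible(x)
}
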