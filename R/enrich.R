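#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing `k` or more annotated genes in a query of
#' size `n` drawn from a universe of `N` genes of which `K` carry the
#' annotation:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' Computed through the hypergeometric distribution function, which is
#' numerically stable well past universes of \eqn{10^5} genes.
#'
#' @param k Overlap count.
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The one-sided upper-tail p-value in (0, 1].
#' @export
hypergeom_test <- function(k, K, n, N) {
  cx_assert(k >= 0 && K <= N && n <= N && k <= min(K, n),
            "hypergeom_test: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement; the input
#' order is preserved in the output.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return FDR values in the same order.
#' @export
bh_adjust <- function(p_values) {
  cx_assert(all(p_values > 0 & p_values <= 1), "p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a query gene set
#'
#' Tests the query against every set in a GMT-style collection with the
#' one-sided hypergeometric test and BH correction. The universe
#' defaults to all genes appearing in the collection — a choice that
#' changes every p-value and is therefore explicit and overridable.
#' Query genes outside the universe are dropped with a warning; sets
#' with no members inside the universe are skipped. Significance is
#' flagged both on raw p and on FDR at the same `alpha` (default 0.05,
#' i.e. -log10 p > 1.3).
#'
#' @param query Character vector of gene symbols.
#' @param collection Named list of character vectors (see
#'   [read_gmt()]).
#' @param universe Character vector, or `NULL` for the collection
#'   union.
#' @param alpha Significance threshold on p (and FDR).
#' @return A tibble sorted by p ascending (ties broken by set name):
#'   `set_name`, `k`, `K`, `n`, `N`, `p_value`, `fdr`, `neg_log10_p`,
#'   `significant`, `significant_fdr`.
#' @export
run_ora <- function(query, collection, universe = NULL, alpha = 0.05) {
  cx_assert(length(collection) > 0, "empty gene-set collection")
  if (is.null(universe)) universe <- unique(unlist(collection))
  universe <- unique(normalize_id(universe, "mRNA"))
  if (length(universe) == 0) cx_abort("empty universe")
  query <- unique(normalize_id(query, "mRNA"))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("run_ora: %d query gene(s) outside the universe dropped", length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::map_dfr(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(query, members))
    tibble(set_name = nm, k = k, K = K, n = n, N = N,
           p_value = hypergeom_test(k, K, n, N))
  })
  if (nrow(rows) == 0) cx_abort("no gene set overlaps the universe")
  rows$fdr <- bh_adjust(rows$p_value)
  rows$neg_log10_p <- -log10(rows$p_value)
  rows$significant <- rows$p_value < alpha
  rows$significant_fdr <- rows$fdr < alpha
  dplyr::arrange(rows, .data$p_value, .data$set_name)
}
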