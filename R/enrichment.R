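#' Hypergeometric gene-set overlap test
#'
#' Exact upper-tail probability of observing at least `k` query genes inside
#' a gene set, drawing `n` query genes without replacement from a universe
#' of `N` genes of which `K` belong to the set:
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. Symbols are upper-cased
#' and de-duplicated before counting; query genes outside the universe are
#' dropped with a warning.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param gene_set Character vector, the gene-set members.
#' @param universe Character vector, the background gene universe.
#' @return One-row tibble: `universe_size`, `set_size`, `query_size`,
#'   `overlap`, `p_value`.
#' @examples
#' overlap_test(letters[1:5], letters[1:5], letters[1:20]) # 1/choose(20,5)
#' @export
overlap_test <- function(query_genes, gene_set, universe) {
  norm <- function(x) unique(toupper(x))
  universe <- norm(universe)
  if (length(universe) == 0) stop("empty gene universe")
  query <- norm(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  set <- intersect(norm(gene_set), universe)
  k <- length(intersect(query, set))
  N <- length(universe); K <- length(set); n <- length(query)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(universe_size = N, set_size = K, query_size = n,
         overlap = k, p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of raw p-values; adjusted values are monotone in the
#' p-value ranking.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return q-values in the input order.
#' @export
adjust_fdr <- function(p_values) {
  p.adjust(p_values, method = "BH")
}

#' Test a query list against every set of a GMT collection
#'
#' Runs [overlap_test()] per set and appends BH-adjusted q-values; results
#' are sorted by p-value. Up- and down-regulated query lists should be
#' tested separately.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Background universe; defaults to the union of all set
#'   members and the query.
#' @return Tibble with one row per gene set: `set_name`, sizes, `overlap`,
#'   `p_value`, `q_value`.
#' @export
enrich_sets <- function(query_genes, gene_sets, universe = NULL) {
  if (is.null(universe)) {
    universe <- unique(c(unlist(gene_sets, use.names = FALSE), query_genes))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    mutate(overlap_test(query_genes, gene_sets[[nm]], universe),
           set_name = nm)
  })
  bind_rows(rows) %>%
    mutate(q_value = adjust_fdr(p_value)) %>%
    select(set_name, universe_size, set_size, query_size, overlap,
           p_value, q_value) %>%
    arrange(p_value)
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to a plain-text file.
#' @return Character vector (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
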