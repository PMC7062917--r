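## Term over-representation testing.
##
## A generic hypergeometric test of a hit set (e.g. the DMGs of one
## contrast) against a term-to-gene map over a background universe, with
## Benjamini-Hochberg correction. Database-specific machinery (ontology
## propagation, gene-length bias correction) is deliberately out of scope.

#' Read a term-to-gene map
#'
#' @param path Two-column TSV `term_id, gene_id` (a `#` header line is
#'   skipped).
#' @param descriptionsPath Optional TSV `term_id, description`.
#' @param background Gene universe; defaults to all genes in the map.
#' @return List with `map` (`data.table(term_id, gene_id)`),
#'   `descriptions`, and `background` (character vector).
#' @export
readTermMap <- function(path, descriptionsPath = NULL, background = NULL) {
  map <- readTsv(path)
  data.table::setnames(map, c("term_id", "gene_id"))
  desc <- if (!is.null(descriptionsPath)) {
    d <- readTsv(descriptionsPath)
    data.table::setnames(d, c("term_id", "description"))
    d
  } else {
    data.table(term_id = unique(map$term_id),
               description = NA_character_)
  }
  if (is.null(background)) background <- sort(unique(map$gene_id))
  bad <- setdiff(map$gene_id, background)
  if (length(bad))
    stop("term genes outside background: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  list(map = map[], descriptions = desc[], background = background)
}

#' Hypergeometric term over-representation test
#'
#' Per term with `K` genes in a background of `N`, given `n` hits of which
#' `k` fall in the term: upper-tail `p = P[X >= k]`,
#' `X ~ Hypergeometric(K, N - K, n)`. BH correction across all terms with
#' `K >= 1`; output sorted by `q`, then `term_id`.
#'
#' @param hits Character vector of hit gene ids (must be a subset of the
#'   background).
#' @param termMap List as returned by [readTermMap()] or
#'   [simulateTermMap()] plus a `background`.
#' @return `data.table(term_id, description, k, K, n, N, p, q)`.
#' @export
enrichTerms <- function(hits, termMap) {
  bg <- termMap$background
  if (is.null(bg)) bg <- sort(unique(termMap$map$gene_id))
  hits <- unique(hits)
  offenders <- setdiff(hits, bg)
  if (length(offenders))
    stop("hits outside background: ",
         paste(utils::head(offenders, 10L), collapse = ", "))
  N <- length(bg)
  n <- length(hits)
  map <- as.data.table(termMap$map)
  map <- unique(map[, .(term_id, gene_id)])
  stat <- map[, .(K = .N, k = sum(gene_id %in% hits)), by = term_id]
  stat <- stat[K >= 1L]
  stat[, `:=`(n = n, N = N)]
  stat[, p := stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)]
  stat[, q := stats::p.adjust(p, method = "BH")]
  desc <- termMap$descriptions
  if (!is.null(desc))
    stat <- merge(stat, as.data.table(desc), by = "term_id", all.x = TRUE)
  else stat[, description := NA_character_]
  setorder(stat, q, term_id)
  stat[, .(term_id, description, k, K, n, N, p, q)]
}
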