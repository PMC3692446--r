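#' Hypergeometric over-representation test of a query gene set
#'
#' Upper-tail hypergeometric probability of the observed overlap between a
#' query (e.g. the genes of one module x layer cell) and each term of a
#' collection, against a stated gene universe. Terms are intersected with
#' the universe before testing; p-values are Benjamini-Hochberg adjusted
#' across all terms tested for this query (one family per query). The
#' optional EASE variant deflates the overlap count by one before testing,
#' for fidelity with the DAVID-style score.
#'
#' @param query character vector of genes (must lie within `universe`).
#' @param collection named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector: the testable gene population.
#' @param fdr_cutoff cells with `q < fdr_cutoff` are flagged significant.
#' @param ease use the EASE count deflation (overlap - 1).
#' @param cluster_id,layer optional labels recorded on every cell.
#' @return data.frame of `EnrichmentCell`s: `term_id`, `cluster_id`,
#'   `layer`, `overlap`, `set_size`, `query_size`, `universe_size`, `p`,
#'   `q`, `significant`.
#' @export
hypergeom_enrich <- function(query, collection, universe, fdr_cutoff = 0.01,
                             ease = FALSE, cluster_id = NA, layer = NA) {
  if (!length(query)) stopf("empty query gene set")
  if (!length(universe)) stopf("empty universe")
  query <- unique(query)
  universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra))
    stopf("query gene(s) outside the universe: %s",
          paste(utils::head(extra, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    set <- intersect(unique(collection[[term]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    k_test <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(k_test - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, cluster_id = cluster_id, layer = layer,
               overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr_cutoff
  out
}

#' Enrich every (module x layer) gene set
#'
#' Splits the annotated network's module members by assigned layer and
#' runs [hypergeom_enrich()] per non-empty cell.
#'
#' @param modules named integer vector gene -> module id.
#' @param assignment data.frame from [assign_layers()].
#' @param collection named list of gene sets.
#' @param universe character vector of testable genes.
#' @param fdr_cutoff significance cutoff on BH-adjusted p.
#' @param ease EASE count deflation flag.
#' @param min_query_size skip cells smaller than this.
#' @return data.frame of enrichment cells across all (module, layer)
#'   queries.
#' @export
enrich_module_layers <- function(modules, assignment, collection, universe,
                                 fdr_cutoff = 0.01, ease = FALSE,
                                 min_query_size = 3L) {
  layer_of <- stats::setNames(assignment$layer, assignment$node)
  cells <- list()
  for (m in sort(unique(modules))) {
    members <- intersect(names(modules)[modules == m], universe)
    for (ly in LAYER_LEVELS) {
      q <- members[layer_of[members] == ly & !is.na(layer_of[members])]
      if (length(q) < min_query_size) next
      cells[[sprintf("%s_%s", m, ly)]] <-
        hypergeom_enrich(q, collection, universe, fdr_cutoff, ease,
                         cluster_id = m, layer = ly)
    }
  }
  if (!length(cells))
    return(data.frame(term_id = character(0), cluster_id = integer(0),
                      layer = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Clustered heatmap matrix of enrichment results
#'
#' Rows are (cluster, layer) pairs, columns are terms; values are
#' `-log10(q)` where `q < cutoff` and 0 elsewhere. Rows/columns with at
#' least one significant cell are kept; both margins are ordered by
#' average-linkage agglomerative clustering on Euclidean distance.
#'
#' @param cells data.frame of enrichment cells.
#' @param cutoff significance cutoff on `q`.
#' @return list with `matrix`, `row_order`, `col_order`, `row_hclust`,
#'   `col_hclust`, and `empty` flag (TRUE when no cell is significant).
#' @export
build_heatmap <- function(cells, cutoff = 0.01) {
  sig <- cells[cells$q < cutoff, , drop = FALSE]
  if (!nrow(sig))
    return(list(matrix = matrix(0, 0, 0), row_order = integer(0),
                col_order = integer(0), row_hclust = NULL,
                col_hclust = NULL, empty = TRUE))
  cells$row <- sprintf("cluster%s_%s", cells$cluster_id, cells$layer)
  rows <- sort(unique(cells$row[cells$q < cutoff]))
  terms <- sort(unique(cells$term_id[cells$q < cutoff]))
  mat <- matrix(0, length(rows), length(terms),
                dimnames = list(rows, terms))
  hit <- cells[cells$q < cutoff & cells$row %in% rows &
                 cells$term_id %in% terms, , drop = FALSE]
  mat[cbind(match(hit$row, rows), match(hit$term_id, terms))] <-
    -log10(pmax(hit$q, .Machine$double.xmin))
  cluster_margin <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), hclust = NULL))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    list(order = hc$order, hclust = hc)
  }
  rc <- cluster_margin(mat)
  cc <- cluster_margin(t(mat))
  list(matrix = mat, row_order = rc$order, col_order = cc$order,
       row_hclust = rc$hclust, col_hclust = cc$hclust, empty = FALSE)
}
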