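#' Load and clean an interaction network
#'
#' Reads a SIF or 2/3-column edge list and applies the standard cleanup:
#' interaction direction dropped, duplicate edges (including reversed
#' duplicates) collapsed, self-loops removed, and nodes left isolated by
#' the cleanup discarded. Node and edge counts are reported in the load
#' log attribute.
#'
#' @param edge_source path to a SIF/edge-list file, or a data.frame with
#'   columns `from`, `to`.
#' @return a simple undirected igraph; attribute `load_log` records counts.
#' @export
load_network <- function(edge_source) {
  edges <- if (is.character(edge_source)) read_sif(edge_source)
           else as.data.frame(edge_source)[, 1:2] |>
             stats::setNames(c("from", "to"))
  g <- igraph::graph_from_edgelist(as.matrix(edges[, c("from", "to")]),
                                   directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (igraph::vcount(g) == 0) stopf("network is empty after cleanup")
  g$load_log <- sprintf("loaded network: %d nodes, %d edges",
                        igraph::vcount(g), igraph::ecount(g))
  message(g$load_log)
  g
}

#' Largest connected component
#'
#' Induced subgraph on the maximum-cardinality connected component; ties
#' are broken toward the component containing the lexicographically
#' smallest node name, for determinism.
#'
#' @param net an igraph.
#' @return the induced subgraph.
#' @export
largest_component <- function(net) {
  if (igraph::vcount(net) == 0) stopf("empty network")
  comp <- igraph::components(net)
  maxsize <- max(comp$csize)
  cand <- which(comp$csize == maxsize)
  if (length(cand) > 1) {
    first_member <- vapply(cand, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, "")
    cand <- cand[order(first_member)[1]]
  }
  igraph::induced_subgraph(net, igraph::V(net)[comp$membership == cand])
}

#' k-core decomposition
#'
#' Core index per node: the largest k such that the node survives
#' iterative removal of all vertices of degree < k.
#'
#' @param net an igraph.
#' @return named integer vector of core numbers.
#' @export
core_numbers <- function(net) {
  igraph::coreness(net)
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' For each vertex v, take the closed neighborhood (v plus its neighbors),
#' find the highest k-core of that induced subgraph, and set
#' `weight(v) = k * density(highest k-core subgraph)`, with density
#' `2E/(N(N-1))` for simple graphs.
#'
#' @param net an igraph.
#' @return named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(net) {
  vs <- igraph::V(net)$name
  adj <- igraph::adjacent_vertices(net, vs)
  w <- vapply(seq_along(vs), function(i) {
    nbhd <- unique(c(vs[i], names(adj[[i]])))
    sub <- igraph::induced_subgraph(net, nbhd)
    cores <- igraph::coreness(sub)
    k <- max(cores)
    if (k == 0) return(0)
    core_sub <- igraph::induced_subgraph(sub, which(cores == k))
    k * graph_density(core_sub)
  }, numeric(1))
  stats::setNames(w, vs)
}

#' MCODE parameters
#'
#' @param degree_cutoff vertices below this degree get weight 0 (excluded
#'   from seeding dense regions).
#' @param node_score_cutoff vertex weight percentage (VWP): a neighbor
#'   joins a complex when its weight >= seed weight * (1 - VWP).
#' @param k_core haircut core level; complexes lacking a `k_core`-core are
#'   dropped.
#' @param haircut remove complex members outside the complex's
#'   `k_core`-core.
#' @param fluff add neighbors whose neighborhood density exceeds
#'   `fluff_density_cutoff` (fluffed nodes may repeat across complexes).
#' @param fluff_density_cutoff density threshold for fluff.
#' @param max_depth breadth-first expansion depth limit from the seed.
#' @param score_threshold keep complexes with score strictly above this
#'   (score = density x size).
#' @return an `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, haircut = TRUE, fluff = FALSE,
                         fluff_density_cutoff = 0.5, max_depth = 100L,
                         score_threshold = 2.0) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1)
    stopf("node_score_cutoff (VWP) must lie in [0, 1)")
  if (k_core < 2) stopf("k_core must be >= 2")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core), haircut = haircut,
                 fluff = fluff,
                 fluff_density_cutoff = fluff_density_cutoff,
                 max_depth = as.integer(max_depth),
                 score_threshold = score_threshold),
            class = "mcode_params")
}

# iterative peel to the k-core of a member set within the parent graph
complex_kcore <- function(net, members, k) {
  repeat {
    if (!length(members)) return(members)
    sub <- igraph::induced_subgraph(net, members)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg < k]
    if (!length(drop)) return(members)
    members <- setdiff(members, drop)
  }
}

#' Detect dense network modules with the MCODE algorithm
#'
#' Seeds at the unvisited vertex of highest weight (ties broken by node
#' name), grows the complex breadth-first by including unvisited neighbors
#' whose weight is at least `seed_weight * (1 - VWP)` up to `max_depth`,
#' then applies the haircut (restrict to the complex's k-core) and
#' optional fluff. Complexes are scored `density * size`, sorted by score
#' descending (ties by seed name), and filtered to score strictly above
#' `score_threshold`.
#'
#' @param net an igraph with named vertices.
#' @param params an [mcode_params()].
#' @return list of `mcode_complex` lists (`members`, `seed_node`,
#'   `density`, `score`), filtered and sorted.
#' @export
mcode_complexes <- function(net, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  vs <- igraph::V(net)$name
  w <- mcode_vertex_weights(net)
  w[igraph::degree(net)[vs] < params$degree_cutoff] <- 0
  visited <- stats::setNames(rep(FALSE, length(vs)), vs)
  ord <- vs[order(-w[vs], vs)]
  out <- list()
  for (seed in ord) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    thr <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- character(0)
      for (u in sort(frontier)) {
        nbs <- sort(names(igraph::neighbors(net, u)))
        for (v in nbs) {
          if (!visited[v] && w[v] >= thr) {
            visited[v] <- TRUE
            members <- c(members, v)
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    if (params$haircut)
      members <- complex_kcore(net, members, params$k_core)
    if (params$fluff && length(members)) {
      nb <- setdiff(unique(names(unlist(
        igraph::adjacent_vertices(net, members)))), members)
      add <- nb[vapply(nb, function(v) {
        nbhd <- unique(c(v, names(igraph::neighbors(net, v))))
        graph_density(igraph::induced_subgraph(net, nbhd)) >
          params$fluff_density_cutoff
      }, logical(1))]
      members <- c(members, sort(add))
    }
    if (length(members) < 2) next
    members <- sort(members)
    dens <- graph_density(igraph::induced_subgraph(net, members))
    out[[length(out) + 1]] <- structure(
      list(members = members, seed_node = seed, density = dens,
           score = dens * length(members)),
      class = "mcode_complex")
  }
  out <- Filter(function(cx) cx$score > params$score_threshold, out)
  ord2 <- order(-vapply(out, `[[`, 0, "score"),
                vapply(out, `[[`, "", "seed_node"))
  out[ord2]
}

#' Complexes as a tidy table
#'
#' @param complexes list from [mcode_complexes()].
#' @return data.frame with `complex_id`, `score`, `density`, `size`,
#'   `seed_node`, `members` (comma-joined).
#' @export
complexes_table <- function(complexes) {
  if (!length(complexes))
    return(data.frame(complex_id = integer(0), score = numeric(0),
                      density = numeric(0), size = integer(0),
                      seed_node = character(0), members = character(0)))
  data.frame(
    complex_id = seq_along(complexes),
    score = vapply(complexes, `[[`, 0, "score"),
    density = vapply(complexes, `[[`, 0, "density"),
    size = vapply(complexes, function(cx) length(cx$members), 0L),
    seed_node = vapply(complexes, `[[`, "", "seed_node"),
    members = vapply(complexes, function(cx)
      paste(cx$members, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

#' Module membership map from detected complexes
#'
#' @param complexes list from [mcode_complexes()].
#' @return named integer vector gene -> complex id (first complex wins for
#'   fluffed duplicates).
#' @export
complex_membership <- function(complexes) {
  out <- integer(0)
  for (i in seq_along(complexes)) {
    new <- setdiff(complexes[[i]]$members, names(out))
    out <- c(out, stats::setNames(rep(i, length(new)), new))
  }
  out
}

#' Annotate the network with modules, drivers and degree
#'
#' Sets per-node attributes (`module`, `driver`, `degree`) and emits a
#' per-module driver report (cohort recurrence -> driver genes -> module),
#' including an `unassigned` section for drivers outside every detected
#' module. Drivers absent from the network are reported, not dropped
#' silently.
#'
#' @param net an igraph.
#' @param modules named integer vector gene -> module id.
#' @param robustness a `robustness` object from [robust_drivers()].
#' @return list with `graph` (annotated igraph), `report` (data.frame:
#'   gene, n_rds_called, module), `missing_drivers` (drivers not in the
#'   network).
#' @export
map_drivers <- function(net, modules, robustness) {
  vs <- igraph::V(net)$name
  drivers <- robustness$genes$gene[robustness$genes$n_rds_called > 0]
  missing <- setdiff(drivers, vs)
  if (length(missing))
    message(sprintf("%d driver gene(s) absent from the network: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")))
  mod_attr <- modules[vs]
  igraph::V(net)$module <- ifelse(is.na(mod_attr), 0L, mod_attr)
  igraph::V(net)$driver <- vs %in% drivers
  igraph::V(net)$degree <- igraph::degree(net)
  rep_rows <- robustness$genes[robustness$genes$n_rds_called > 0, ,
                               drop = FALSE]
  rep_rows$module <- ifelse(is.na(rep_rows$module), "unassigned",
                            as.character(rep_rows$module))
  rep_rows <- rep_rows[order(rep_rows$module, -rep_rows$n_rds_called,
                             rep_rows$gene), ]
  rownames(rep_rows) <- NULL
  list(graph = net, report = rep_rows, missing_drivers = missing)
}
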