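# Brute-force graph oracles, written literally from the definitions on
# plain adjacency matrices -- deliberately independent of the igraph-based
# implementation under test.

# symmetric 0/1 adjacency matrix with dimnames
random_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("N%02d", seq_len(n)),
                      sprintf("N%02d", seq_len(n)))
  a
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# the i-th labeled graph on n nodes: bits of (i-1) fill the upper triangle
indexed_adj <- function(n, i) {
  nbits <- n * (n - 1) / 2
  bits <- as.integer(intToBits(i - 1))[seq_len(nbits)]
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- bits
  a <- a + t(a)
  dimnames(a) <- list(sprintf("N%02d", seq_len(n)),
                      sprintf("N%02d", seq_len(n)))
  a
}

# k-core by literal minimum-degree peeling
bf_core_numbers <- function(adj) {
  nodes <- rownames(adj)
  core <- stats::setNames(integer(length(nodes)), nodes)
  remaining <- nodes
  k <- 0L
  while (length(remaining)) {
    deg <- rowSums(adj[remaining, remaining, drop = FALSE])
    if (min(deg) > k) k <- as.integer(min(deg))
    v <- remaining[which(deg <= k)[1]]
    core[v] <- k
    remaining <- setdiff(remaining, v)
  }
  core
}

bf_density <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  sum(adj) / (n * (n - 1))   # sum counts each edge twice
}

# highest k-core of a subgraph: vertices whose core number equals the max
bf_highest_core <- function(adj) {
  core <- bf_core_numbers(adj)
  k <- max(core)
  keep <- names(core)[core == k]
  list(k = k, adj = adj[keep, keep, drop = FALSE])
}

bf_vertex_weights <- function(adj) {
  nodes <- rownames(adj)
  w <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    nbhd <- c(v, nodes[adj[v, ] > 0])
    sub <- adj[nbhd, nbhd, drop = FALSE]
    hc <- bf_highest_core(sub)
    w[v] <- if (hc$k == 0) 0 else hc$k * bf_density(hc$adj)
  }
  w
}

# literal MCODE seeding/expansion/haircut on the adjacency matrix
bf_mcode <- function(adj, degree_cutoff = 2, vwp = 0.2, k_core = 2,
                     haircut = TRUE, max_depth = 100,
                     score_threshold = 2.0) {
  nodes <- rownames(adj)
  w <- bf_vertex_weights(adj)
  w[rowSums(adj) < degree_cutoff] <- 0
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  out <- list()
  for (seed in nodes[order(-w, nodes)]) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    thr <- w[seed] * (1 - vwp)
    members <- seed
    frontier <- seed
    depth <- 0
    while (length(frontier) && depth < max_depth) {
      nxt <- character(0)
      for (u in sort(frontier)) {
        for (v in sort(nodes[adj[u, ] > 0])) {
          if (!visited[v] && w[v] >= thr) {
            visited[v] <- TRUE
            members <- c(members, v)
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    if (haircut) {
      repeat {
        if (!length(members)) break
        deg <- rowSums(adj[members, members, drop = FALSE])
        drop <- members[deg < k_core]
        if (!length(drop)) break
        members <- setdiff(members, drop)
      }
    }
    if (length(members) < 2) next
    members <- sort(members)
    dens <- bf_density(adj[members, members, drop = FALSE])
    out[[length(out) + 1]] <- list(members = members, seed_node = seed,
                                   density = dens,
                                   score = dens * length(members))
  }
  out <- Filter(function(cx) cx$score > score_threshold, out)
  ord <- order(-vapply(out, `[[`, 0, "score"),
               vapply(out, `[[`, "", "seed_node"))
  out[ord]
}

# small helpers used across test files ---------------------------------

two_clique_graph <- function() {
  el <- rbind(t(utils::combn(sprintf("A%d", 1:5), 2)),
              t(utils::combn(sprintf("B%d", 1:4), 2)))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# matrix with a planted two-group mean shift, no batch structure
planted_matrix <- function(n_genes, n_per_group, n_de, effect, noise_sd,
                           seed) {
  set.seed(seed)
  de <- sample(n_genes, n_de)
  beta <- numeric(n_genes)
  beta[de] <- effect * sample(c(-1, 1), n_de, replace = TRUE)
  m <- matrix(stats::rnorm(n_genes * 2 * n_per_group, 7, noise_sd),
              n_genes, 2 * n_per_group)
  crc <- (n_per_group + 1):(2 * n_per_group)
  m[, crc] <- m[, crc] + beta
  rownames(m) <- sprintf("G%04d", seq_len(n_genes))
  colnames(m) <- sprintf("S%02d", seq_len(2 * n_per_group))
  list(matrix = m, labels = rep(c("UC", "CRC"), each = n_per_group),
       de = rownames(m)[de], beta = stats::setNames(beta, rownames(m)))
}
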