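# Fixture builders and independent brute-force oracles. Everything here is
# deliberately naive (pure-R recursion / enumeration) so it shares no code
# path with the implementations it checks.

# build a named undirected graph from "u-v" edge strings
named_graph <- function(...) {
  ends <- do.call(rbind, strsplit(c(...), "-", fixed = TRUE))
  igraph::graph_from_edgelist(ends, directed = FALSE)
}

path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}

star_graph <- function(n_leaves) {
  g <- igraph::make_star(n_leaves + 1, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("c", paste0("l", seq_len(n_leaves)))
  g
}

# random connected G(n, p) graph with vertex names, for property sweeps
random_connected_graph <- function(n, p = 0.45) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# pure-R BFS hop distances from one vertex (indices)
bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.infinite(d[nxt])]
    d[nxt] <- d[frontier[1]] + 1
    frontier <- nxt
  }
  d
}

adj_list <- function(g) lapply(igraph::as_adj_list(g, mode = "all"), as.integer)

# enumerate ALL shortest s-t paths by depth-first descent of the BFS DAG
enumerate_shortest_paths <- function(adj, d_to_t, s, t) {
  if (s == t) return(list(s))
  out <- list()
  for (w in adj[[s]]) {
    if (d_to_t[w] == d_to_t[s] - 1) {
      for (tail in enumerate_shortest_paths(adj, d_to_t, w, t)) {
        out[[length(out) + 1]] <- c(s, tail)
      }
    }
  }
  out
}

# betweenness by explicit path enumeration: for every unordered pair,
# fraction of shortest paths through each interior vertex
oracle_betweenness <- function(g) {
  adj <- adj_list(g)
  n <- length(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      d_to_t <- bfs_dist(adj, t)
      if (is.infinite(d_to_t[s])) next
      paths <- enumerate_shortest_paths(adj, d_to_t, s, t)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(paths)
      }
    }
  }
  bc
}

# load centrality by per-ordered-pair forward flow: a unit leaves s for t and
# splits evenly among neighbours closer to t at every hop; halved at the end
# for the undirected double count
oracle_load <- function(g) {
  adj <- adj_list(g)
  n <- length(adj)
  ld <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      d_to_t <- bfs_dist(adj, t)
      if (is.infinite(d_to_t[s])) next
      flow <- numeric(n)
      flow[s] <- 1
      for (lev in seq(d_to_t[s], 1)) {
        for (v in which(flow > 0 & d_to_t == lev)) {
          down <- adj[[v]][d_to_t[adj[[v]]] == lev - 1]
          flow[down] <- flow[down] + flow[v] / length(down)
        }
      }
      interior <- setdiff(which(flow > 0), c(s, t))
      ld[interior] <- ld[interior] + flow[interior]
    }
  }
  ld / 2
}

# eccentricity by pure-R BFS; ties resolved like the detector (ascending index)
oracle_jordan <- function(g, k) {
  adj <- adj_list(g)
  ecc <- vapply(seq_along(adj), function(v) {
    d <- bfs_dist(adj, v)
    max(d[is.finite(d)])
  }, numeric(1))
  igraph::V(g)$name[order(ecc, seq_along(ecc))][seq_len(k)]
}

# Stephenson-Zelen information centrality via the (L + J)^-1 matrix formula
oracle_information_centrality <- function(g) {
  L <- as.matrix(igraph::laplacian_matrix(g, sparse = FALSE))
  n <- nrow(L)
  C <- solve(L + 1)
  1 / (diag(C) + (sum(diag(C)) - 2 * colSums(C)) / n)
}

rank_of <- function(s) rank(as.numeric(s), ties.method = "min")
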