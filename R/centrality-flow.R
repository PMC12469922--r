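# Electrical (current-flow / resistive) centralities and spectral helpers.
# All computations work per connected component through the Moore-Penrose
# pseudoinverse of the component's combinatorial Laplacian.

# second-smallest Laplacian eigenvalue; 0 for disconnected or trivial graphs
algebraic_connectivity <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  L <- as.matrix(igraph::laplacian_matrix(g, sparse = FALSE))
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  max(ev[length(ev) - 1L], 0) # ascending position n-1 from decreasing order
}

# pseudoinverse of the Laplacian of a CONNECTED graph with >= 2 nodes
laplacian_pinv <- function(g) {
  L <- as.matrix(igraph::laplacian_matrix(g, sparse = FALSE))
  e <- eigen(L, symmetric = TRUE)
  nz <- seq_len(ncol(e$vectors) - 1L) # drop the single zero eigenvalue
  V <- e$vectors[, nz, drop = FALSE]
  V %*% (t(V) / e$values[nz])
}

# Current-flow (random-walk) betweenness. For a unit s->t current, the flow
# on edge (u,w) is T[u,s]-T[u,t]-T[w,s]+T[w,t] with T the Laplacian
# pseudoinverse; a node's throughput is half the sum of absolute flows on its
# incident edges, minus 1/2 when it is an endpoint. Summing |q_s - q_t| over
# all pairs for an edge difference vector q reduces to a sorted weighted sum
# (Brandes & Fleischer), giving O(m n log n) overall.
current_flow_betweenness <- function(g, ctx = NULL) {
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  out <- numeric(n)
  for (cmp in seq_len(comp$no)) {
    idx <- which(comp$membership == cmp)
    nc <- length(idx)
    if (nc < 3) next                       # no interior throughput possible
    sub <- igraph::induced_subgraph(g, idx)
    T_ <- laplacian_pinv(sub)
    el <- igraph::as_edgelist(sub, names = FALSE)
    w <- 2 * seq_len(nc) - nc - 1          # rank weights, ascending order
    edge_sum <- vapply(seq_len(nrow(el)), function(e) {
      q <- T_[el[e, 1], ] - T_[el[e, 2], ]
      sum(w * sort(q))
    }, numeric(1))
    acc <- numeric(nc)
    for (e in seq_len(nrow(el))) {
      acc[el[e, 1]] <- acc[el[e, 1]] + edge_sum[e]
      acc[el[e, 2]] <- acc[el[e, 2]] + edge_sum[e]
    }
    out[idx] <- acc / 2 - (nc - 1) / 2
  }
  pmax(out, 0)
}

# Current-flow closeness, computed so it coincides EXACTLY with
# Stephenson-Zelen information centrality: n divided by the sum of effective
# resistances to all other nodes (the identity info(v) = n / (n*T[v,v] +
# trace(T)) with T the Laplacian pseudoinverse). Row sums of T vanish, so
# the resistive farness collapses to n*T[v,v] + trace(T). An (n-1)/farness
# convention differs only by a per-graph constant and yields identical
# rankings and min-max normalized scores.
current_flow_closeness <- function(g, ctx = NULL) {
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  out <- numeric(n)
  for (cmp in seq_len(comp$no)) {
    idx <- which(comp$membership == cmp)
    nc <- length(idx)
    if (nc < 2) next
    sub <- igraph::induced_subgraph(g, idx)
    T_ <- laplacian_pinv(sub)
    farness <- nc * diag(T_) + sum(diag(T_))
    out[idx] <- nc / farness
  }
  out
}
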