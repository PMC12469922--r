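#' Top-k source detection from a centrality score map
#'
#' Estimates the source set as the `k` nodes with the largest scores, ties
#' broken by ascending node index (position in the score map), so detection
#' is deterministic and invariant under monotone rescaling of the scores.
#'
#' @param s A `score_map` over the infection-subgraph nodes.
#' @param k Number of sources to return (the benchmark uses the true source
#'   count, "oracle k").
#' @return A `detection` object: list with `method`, `estimated` (character
#'   vector of node names), `k_requested`, and `scores`.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' igraph::V(g)$name <- letters[1:5]
#' detect_topk(compute_centrality(g, "DE"), 1)$estimated # "a"
#' @export
detect_topk <- function(s, k) {
  stopifnot(inherits(s, "score_map"))
  n <- length(s)
  if (k < 1 || k > n) stop("k must be in 1..", n, call. = FALSE)
  ord <- order(-as.numeric(s), seq_len(n))
  structure(list(
    method = attr(s, "measure"),
    estimated = names(s)[ord[seq_len(k)]],
    k_requested = as.integer(k),
    scores = s
  ), class = "detection")
}

#' Jordan-center source detection
#'
#' Ranks the nodes of the infection subgraph by ascending eccentricity (the
#' maximum hop distance to any other node; computed within each connected
#' component on disconnected inputs) and returns the `k` best, ties broken by
#' ascending node index. The single Jordan center minimizes the maximum
#' distance to all infected nodes.
#'
#' @param gi The infection subgraph (nonempty igraph).
#' @param k Number of sources to return.
#' @return A `detection` object (method `"JC"`); `scores` holds negated
#'   eccentricities so that larger = better, consistent with the catalog.
#' @export
jordan_center <- function(gi, k) {
  n <- igraph::vcount(gi)
  if (n == 0) stop("empty infection subgraph", call. = FALSE)
  if (k < 1 || k > n) stop("k must be in 1..", n, call. = FALSE)
  if (is.null(igraph::V(gi)$name)) igraph::V(gi)$name <- as.character(seq_len(n))
  D <- igraph::distances(gi)
  D[!is.finite(D)] <- NA
  ecc <- apply(D, 1, max, na.rm = TRUE)
  ord <- order(ecc, seq_len(n))
  structure(list(
    method = "JC",
    estimated = igraph::V(gi)$name[ord[seq_len(k)]],
    k_requested = as.integer(k),
    scores = structure(-ecc, names = igraph::V(gi)$name, measure = "JC",
                       normalized = FALSE, class = "score_map")
  ), class = "detection")
}

#' Netsleuth-style seed identification with MDL stopping
#'
#' Iteratively scores the infected nodes by the smallest-eigenvalue
#' eigenvector of the infected-submatrix Laplacian `L[A, A]`, where `L` is
#' the Laplacian of the FULL network (so diagonal entries count edges to the
#' uninfected frontier — a Dirichlet boundary that makes the submatrix
#' positive definite whenever some frontier exists). Each round the
#' largest-magnitude component becomes the next seed and is removed from the
#' infected set. The seed count is chosen by a two-part minimum description
#' length: the encoding cost of the seed set plus the cost of the most likely
#' deterministic "ripple" re-infecting the rest of the subgraph; the search
#' stops at the first cost increase, or at `max_seeds`.
#'
#' When the infection covers the whole network the submatrix equals the full
#' Laplacian, whose smallest eigenvector is constant and carries no ranking
#' information; nodes are then ranked by degree (hubs first).
#'
#' @param gi The infection subgraph.
#' @param g The full network (`gi` must be a subgraph of it). Defaults to
#'   `gi`.
#' @param max_seeds Upper bound on the number of seeds; `NULL` means
#'   unrestricted (MDL decides alone).
#' @param beta Transmission probability used in the ripple likelihood.
#' @param force_k If given, exactly `force_k` seeds are returned and the MDL
#'   stop is ignored ("oracle k" mode).
#' @return A `detection` object (method `"NT"`); `|estimated|` is chosen by
#'   the method itself unless `force_k` is supplied.
#' @export
netsleuth <- function(gi, g = gi, max_seeds = NULL, beta = 0.1,
                      force_k = NULL) {
  n_gi <- igraph::vcount(gi)
  if (n_gi == 0) stop("empty infection subgraph", call. = FALSE)
  if (is.null(igraph::V(gi)$name)) igraph::V(gi)$name <- as.character(seq_len(n_gi))
  inf_names <- igraph::V(gi)$name
  idx_in_g <- match(inf_names, igraph::V(g)$name)
  if (anyNA(idx_in_g)) stop("gi must be a subgraph of g", call. = FALSE)
  L <- as.matrix(igraph::laplacian_matrix(g, sparse = FALSE))
  LA <- L[idx_in_g, idx_in_g, drop = FALSE]
  adj_gi <- lapply(igraph::as_adj_list(gi, mode = "all"), as.integer)
  deg_gi <- igraph::degree(gi)
  cap <- if (!is.null(force_k)) force_k else (max_seeds %||% n_gi)
  cap <- min(cap, n_gi)

  active <- seq_len(n_gi)
  seeds <- integer(0)
  best_cost <- Inf
  best_len <- 1L
  repeat {
    if (length(seeds) >= cap || length(active) == 0) break
    sub <- LA[active, active, drop = FALSE]
    if (length(active) == 1L) {
      pick_local <- 1L
    } else {
      e <- eigen(sub, symmetric = TRUE)
      v <- e$vectors[, ncol(sub)]           # smallest eigenvalue last
      if (max(abs(v)) - min(abs(v)) < 1e-12) {
        pick_local <- which.max(deg_gi[active])  # constant vector: no signal
      } else {
        pick_local <- which.max(abs(v))
      }
    }
    seeds <- c(seeds, active[pick_local])
    active <- active[-pick_local]
    if (is.null(force_k)) {
      cost <- netsleuth_mdl_cost(seeds, n_gi, adj_gi, beta)
      if (cost < best_cost) {
        best_cost <- cost
        best_len <- length(seeds)
      } else if (length(seeds) > best_len) {
        break                                # first cost increase: stop
      }
    }
  }
  k_out <- if (is.null(force_k)) best_len else length(seeds)
  structure(list(
    method = "NT",
    estimated = inf_names[seeds[seq_len(k_out)]],
    k_requested = as.integer(k_out),
    scores = NULL
  ), class = "detection")
}

# two-part MDL cost: seed-set encoding + deterministic ML ripple over gi
netsleuth_mdl_cost <- function(seeds, n, adj, beta) {
  model_cost <- log2_star(length(seeds)) + lchoose(n, length(seeds)) / log(2)
  infected <- logical(n)
  infected[seeds] <- TRUE
  data_cost <- 0
  n_inf <- sum(infected)
  while (n_inf < n) {
    cand <- which(!infected)
    m_v <- vapply(cand, function(v) sum(infected[adj[[v]]]), numeric(1))
    p_v <- 1 - (1 - beta)^m_v
    take <- cand[p_v >= 0.5]
    if (length(take) == 0) {
      reach <- cand[p_v > 0]
      if (length(reach) == 0) return(Inf)    # seeds cannot explain gi
      take <- reach[which.max(p_v[p_v > 0])]
    }
    pt <- 1 - (1 - beta)^vapply(take, function(v) sum(infected[adj[[v]]]), numeric(1))
    stay <- setdiff(cand, take)
    ps <- 1 - (1 - beta)^vapply(stay, function(v) sum(infected[adj[[v]]]), numeric(1))
    data_cost <- data_cost - sum(log2(pt)) - sum(log2(1 - ps[ps < 1]))
    infected[take] <- TRUE
    n_inf <- n_inf + length(take)
  }
  model_cost + data_cost
}

# universal integer code length (Rissanen)
log2_star <- function(k) {
  cost <- log2(2.865064)
  x <- k
  while (x > 1) {
    x <- log2(x)
    cost <- cost + x
  }
  cost
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection> method %s: %d node(s): %s\n", x$method,
              length(x$estimated),
              paste(utils::head(x$estimated, 10), collapse = ", ")))
  invisible(x)
}

#' Run any catalog method or baseline as a detector on an infection subgraph
#'
#' Convenience dispatcher used by the experiment grid: centrality codes go
#' through [compute_centrality()] + [detect_topk()], `"JC"` through
#' [jordan_center()], `"NT"` through [netsleuth()].
#'
#' @param gi Infection subgraph.
#' @param method A centrality code, `"JC"`, or `"NT"`.
#' @param k Oracle source count.
#' @param g Full network (used by `"NT"` only).
#' @param params Centrality parameters.
#' @param nt_oracle_k If `TRUE` (default) Netsleuth also returns exactly `k`
#'   seeds; if `FALSE` its MDL criterion chooses the count.
#' @return A `detection` object.
#' @export
detect_sources <- function(gi, method, k, g = gi, params = list(),
                           nt_oracle_k = TRUE) {
  if (method == "JC") {
    jordan_center(gi, k)
  } else if (method == "NT") {
    if (nt_oracle_k) netsleuth(gi, g, force_k = k)
    else netsleuth(gi, g, max_seeds = max(2L * k, 2L))
  } else {
    detect_topk(compute_centrality(gi, method, params), k)
  }
}
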