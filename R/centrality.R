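#' The centrality-measure catalog
#'
#' Twenty-five node centrality measures applicable to undirected graphs,
#' identified by short codes. All measures are oriented so that larger
#' values mean "more source-like" under top-k detection, with one documented
#' exception: `AV` (average shortest-path distance) is kept raw — it ranks
#' peripheral nodes last only if inverted, which is controlled by the
#' `invert_av` parameter (default off).
#'
#' @return Character vector of the 25 measure codes.
#' @export
centrality_codes <- function() {
  c("AL", "AV", "BR", "BC", "CL", "CR", "CO", "CFB", "CFC", "DC",
    "DE", "DD", "EI", "GK", "HA", "HE", "LE", "LIN", "LD", "MNC",
    "PR", "PE", "RA", "SU", "TO")
}

#' All-pairs shortest-path (hop) distances
#'
#' @param g An igraph object.
#' @return A symmetric numeric matrix with zero diagonal; unreachable pairs
#'   are `Inf`.
#' @export
all_pairs_distances <- function(g) {
  igraph::distances(g)
}

#' Compute a raw centrality score map
#'
#' Scores every node of `g` under the measure named by `code`. Distance-based
#' measures use per-component semantics on disconnected graphs (sums run over
#' reachable nodes only; radiality uses the component diameter), so every
#' score is finite.
#'
#' Measure-specific parameters (all overridable via `params`):
#' \describe{
#'   \item{DC}{`delta` — decay factor, default 0.5.}
#'   \item{GK}{`k` — geodesic radius, default 3.}
#'   \item{PR}{`damping` — default 0.85.}
#'   \item{DD}{`lambda` — per-node propagation weights, default 1 for all
#'     nodes (score = deg(v) + sum of neighbour degrees).}
#'   \item{PE}{`states` — per-node percolation states, default uniform
#'     (which makes PE score-proportional to BC).}
#'   \item{AL}{`variant` — `"absolute"` (default) or `"relative"` drop in
#'     algebraic connectivity.}
#'   \item{AV}{`invert_av` — if `TRUE` score is 1/average distance.}
#' }
#'
#' @param g An igraph object (nonempty; EI and PR require at least one edge).
#' @param code One of [centrality_codes()].
#' @param params Named list of measure parameters.
#' @return A `score_map`: named numeric vector (names = node names) with
#'   attributes `measure` and `normalized = FALSE`.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' igraph::V(g)$name <- letters[1:5]
#' compute_centrality(g, "DE")
#' @export
compute_centrality <- function(g, code, params = list()) {
  if (!code %in% centrality_codes()) {
    stop("unknown centrality code: ", code, call. = FALSE)
  }
  n <- igraph::vcount(g)
  if (n == 0) stop("graph is empty", call. = FALSE)
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(seq_len(n))
  if (code %in% c("EI", "PR") && igraph::ecount(g) == 0) {
    stop(code, " requires a graph with at least one edge", call. = FALSE)
  }
  ctx <- new.env(parent = emptyenv())
  ctx$g <- g; ctx$n <- n
  fn <- centrality_impl_table()[[code]]
  sc <- as.numeric(fn(g, params, ctx))
  names(sc) <- igraph::V(g)$name
  structure(sc, measure = code, normalized = FALSE, class = "score_map")
}

#' Min-max rescale a score map to the unit interval
#'
#' Rescales so the smallest score maps to 0 and the largest to 1, preserving
#' the ranking; a constant input maps every node to 1 (all tied at the top).
#'
#' @param s A `score_map` (raw).
#' @return A normalized `score_map`.
#' @export
normalize_scores <- function(s) {
  stopifnot(inherits(s, "score_map"))
  v <- as.numeric(s)
  rng <- range(v)
  out <- if (rng[1] == rng[2]) rep(1, length(v)) else (v - rng[1]) / diff(rng)
  structure(out, names = names(s), measure = attr(s, "measure"),
            normalized = TRUE, class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map> %s (%s), %d nodes\n", attr(x, "measure"),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw",
              length(x)))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Export one or more score maps as a delimited table
#'
#' @param maps A list of `score_map` objects (raw); normalized values are
#'   computed alongside.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(maps, path) {
  rows <- lapply(maps, function(s) {
    ns <- normalize_scores(s)
    data.frame(node = names(s), measure_code = attr(s, "measure"),
               raw = as.numeric(s), normalized = as.numeric(ns))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- shared lazily cached per-graph context --------------------------------

ctx_dist <- function(ctx) {
  if (is.null(ctx$D)) ctx$D <- igraph::distances(ctx$g)
  ctx$D
}
ctx_deg <- function(ctx) {
  if (is.null(ctx$deg)) ctx$deg <- igraph::degree(ctx$g)
  ctx$deg
}
ctx_adj <- function(ctx) {
  if (is.null(ctx$adj)) {
    ctx$adj <- lapply(igraph::as_adj_list(ctx$g, mode = "all"), as.integer)
  }
  ctx$adj
}
ctx_adj0 <- function(ctx) {
  if (is.null(ctx$adj0)) ctx$adj0 <- lapply(ctx_adj(ctx), function(x) x - 1L)
  ctx$adj0
}
ctx_A <- function(ctx) {
  if (is.null(ctx$A)) {
    ctx$A <- igraph::as_adjacency_matrix(ctx$g, sparse = FALSE)
  }
  ctx$A
}
ctx_comp <- function(ctx) {
  if (is.null(ctx$comp)) ctx$comp <- igraph::components(ctx$g)$membership
  ctx$comp
}

# farness restricted to reachable nodes, plus reachable counts (incl. self)
farness_reach <- function(D) {
  fin <- is.finite(D)
  list(farness = rowSums(D * fin, na.rm = TRUE) - 0, # diag contributes 0
       reach = rowSums(fin))
}

# ---- measure implementations ----------------------------------------------

centrality_impl_table <- function() list(

  DE = function(g, p, ctx) ctx_deg(ctx),

  BC = function(g, p, ctx) igraph::betweenness(g, directed = FALSE),

  LD = function(g, p, ctx) cpp_load_centrality(ctx_adj0(ctx), ctx$n),

  PE = function(g, p, ctx) {
    x <- p$states %||% rep(1, ctx$n)
    stopifnot(length(x) == ctx$n, all(x >= 0))
    dep <- cpp_weighted_dependency(ctx_adj0(ctx), ctx$n, as.numeric(x))
    denom <- sum(x) - x
    out <- ifelse(denom > 0, dep / denom, 0)
    out / 2
  },

  CL = function(g, p, ctx) {
    fr <- farness_reach(ctx_dist(ctx))
    ifelse(fr$farness > 0, (fr$reach - 1) / fr$farness, 0)
  },

  AV = function(g, p, ctx) {
    fr <- farness_reach(ctx_dist(ctx))
    avg <- ifelse(fr$reach > 1, fr$farness / (fr$reach - 1), 0)
    if (isTRUE(p$invert_av)) ifelse(avg > 0, 1 / avg, 0) else avg
  },

  BR = function(g, p, ctx) {
    fr <- farness_reach(ctx_dist(ctx))
    ifelse(fr$farness > 0, 1 / fr$farness, 0)
  },

  HA = function(g, p, ctx) {
    igraph::harmonic_centrality(g, normalized = FALSE)
  },

  LIN = function(g, p, ctx) {
    fr <- farness_reach(ctx_dist(ctx))
    # nodes with no coreachable set score 1 by definition
    ifelse(fr$farness > 0, fr$reach^2 / fr$farness, 1)
  },

  RA = function(g, p, ctx) {
    D <- ctx_dist(ctx)
    comp <- ctx_comp(ctx)
    out <- numeric(ctx$n)
    for (cmp in unique(comp)) {
      idx <- which(comp == cmp)
      if (length(idx) < 2) next
      Dc <- D[idx, idx, drop = FALSE]
      diam <- max(Dc)
      out[idx] <- (rowSums(diam + 1 - Dc) - (diam + 1)) / (length(idx) - 1)
    }
    out
  },

  DC = function(g, p, ctx) {
    delta <- p$delta %||% 0.5
    D <- ctx_dist(ctx)
    P <- delta^D                      # delta^Inf = 0, delta^0 = 1 on diagonal
    rowSums(P) - 1
  },

  GK = function(g, p, ctx) {
    k <- p$k %||% 3
    D <- ctx_dist(ctx)
    rowSums(D > 0 & D <= k)
  },

  HE = function(g, p, ctx) {
    fr <- farness_reach(ctx_dist(ctx))
    adj <- ctx_adj(ctx)
    vapply(seq_len(ctx$n), function(v) {
      nb <- adj[[v]]
      if (length(nb) == 0) return(0)
      mean(fr$farness[nb]) - fr$farness[v]
    }, numeric(1))
  },

  LE = function(g, p, ctx) {
    deg <- ctx_deg(ctx)
    adj <- ctx_adj(ctx)
    vapply(seq_len(ctx$n), function(v) {
      if (deg[v] == 0) return(0)
      mean((deg[v] - deg[adj[[v]]]) / (deg[v] + deg[adj[[v]]]))
    }, numeric(1))
  },

  CR = function(g, p, ctx) {
    cc <- igraph::transitivity(g, type = "local")
    cc[is.nan(cc) | is.na(cc)] <- 0
    deg <- ctx_deg(ctx)
    adj <- ctx_adj(ctx)
    vapply(seq_len(ctx$n), function(v) {
      10^(-cc[v]) * sum(deg[adj[[v]]] + 1)
    }, numeric(1))
  },

  CO = function(g, p, ctx) {
    ks <- igraph::coreness(g)
    adj <- ctx_adj(ctx)
    vapply(seq_len(ctx$n), function(v) sum(ks[adj[[v]]]), numeric(1))
  },

  DD = function(g, p, ctx) {
    deg <- ctx_deg(ctx)
    lam <- p$lambda %||% rep(1, ctx$n)
    stopifnot(length(lam) == ctx$n)
    adj <- ctx_adj(ctx)
    vapply(seq_len(ctx$n), function(v) {
      lam[v] * deg[v] + sum(lam[adj[[v]]] * deg[adj[[v]]])
    }, numeric(1))
  },

  EI = function(g, p, ctx) {
    v <- igraph::eigen_centrality(g, directed = FALSE,
      options = list(maxiter = p$maxiter %||% 10000,
                     tol = p$tol %||% 1e-10))$vector
    v <- abs(v)                       # principal eigenvector, sign-fixed
    v / sqrt(sum(v^2))                # unit norm before min-max rescaling
  },

  PR = function(g, p, ctx) {
    igraph::page_rank(g, damping = p$damping %||% 0.85)$vector
  },

  SU = function(g, p, ctx) igraph::subgraph_centrality(g, diag = FALSE),

  MNC = function(g, p, ctx) {
    adj <- ctx_adj(ctx)
    vapply(seq_len(ctx$n), function(v) {
      nb <- adj[[v]]
      if (length(nb) == 0) return(0)
      sub <- igraph::induced_subgraph(g, nb)
      max(igraph::components(sub)$csize)
    }, numeric(1))
  },

  TO = function(g, p, ctx) {
    A <- ctx_A(ctx)
    deg <- ctx_deg(ctx)
    A2 <- A %*% A
    vapply(seq_len(ctx$n), function(v) {
      if (deg[v] == 0) return(0)
      partners <- which(A2[v, ] > 0)
      partners <- partners[partners != v]
      if (length(partners) == 0) return(0)
      mean((A2[v, partners] + A[v, partners]) / deg[v])
    }, numeric(1))
  },

  AL = function(g, p, ctx) {
    variant <- p$variant %||% "absolute"
    lam2 <- algebraic_connectivity(g)
    out <- vapply(seq_len(ctx$n), function(v) {
      lam2 - algebraic_connectivity(igraph::delete_vertices(g, v))
    }, numeric(1))
    if (identical(variant, "relative") && lam2 > 0) out <- out / lam2
    out
  },

  CFB = function(g, p, ctx) current_flow_betweenness(g, ctx),

  CFC = function(g, p, ctx) current_flow_closeness(g, ctx)
)
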