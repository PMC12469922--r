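#' Read an undirected simple graph from a whitespace-delimited edge list
#'
#' One edge per line, two (or more; extra tokens ignored) whitespace-separated
#' node labels. Duplicate edges are collapsed and self-loops dropped; both are
#' reported via [message()] so that silent data loss is visible. Node labels
#' are preserved verbatim as the `name` vertex attribute.
#'
#' @param path Path to the edge-list file.
#' @param comment_prefix Lines starting with this prefix are skipped.
#' @return An undirected simple [igraph::graph] object.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c"), f)
#' g <- load_edge_list(f)
#' igraph::vcount(g) # 3
#' @export
load_edge_list <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) {
    stop("edge-list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_prefix) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  toks <- strsplit(trimws(lines[idx]), "[[:space:]]+")
  bad <- lengths(toks) < 2L
  if (any(bad)) {
    stop("malformed edge-list line ", idx[which(bad)[1L]], " in ", path,
         ": expected at least two tokens", call. = FALSE)
  }
  ends <- t(vapply(toks, function(x) x[1:2], character(2)))
  loops <- ends[, 1] == ends[, 2]
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s) while reading ", path)
  }
  verts <- unique(c(ends[, 1], ends[, 2]))
  ends <- ends[!loops, , drop = FALSE]
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  # keep endpoints of dropped self-loops as isolated vertices
  missing <- setdiff(verts, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  n_dup <- igraph::ecount(g) - igraph::ecount(igraph::simplify(g))
  if (n_dup > 0) {
    message("collapsing ", n_dup, " duplicate edge(s) while reading ", path)
  }
  igraph::simplify(g)
}

#' Write a graph as a sorted plain-text edge list
#'
#' Each edge appears once, endpoints in lexicographic order, lines sorted, so
#' that identical graphs always serialize to identical files.
#'
#' @param g An igraph object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  el <- apply(el, 2, as.character)
  if (length(el) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(dim(el))) el <- matrix(el, ncol = 2)
  swap <- el[, 1] > el[, 2]
  tmp <- el[swap, 1]; el[swap, 1] <- el[swap, 2]; el[swap, 2] <- tmp
  lines <- sort(paste(el[, 1], el[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic network generators used by the benchmark
#'
#' Two families:
#' \describe{
#'   \item{`small_world`}{Watts–Strogatz: a ring lattice of `n` nodes each
#'     joined to its `k` nearest neighbours (`k/2` on each side), then every
#'     edge has its far endpoint rewired with probability `rewire_p` to a
#'     uniformly chosen node, skipping rewirings that would create a self-loop
#'     or duplicate edge. The edge count is exactly `n*k/2`.}
#'   \item{`scale_free`}{Growing preferential attachment: `m` initial isolated
#'     nodes, then each incoming node attaches `m` edges to distinct existing
#'     nodes chosen with probability proportional to their current degree
#'     (the first incoming node attaches to all `m` seeds). The edge count is
#'     exactly `m*(n-m)` and every non-seed node has degree at least `m`.}
#' }
#'
#' @param family `"small_world"` or `"scale_free"`.
#' @param n Number of nodes.
#' @param k_or_m Ring-neighbour count `k` (small world; must be even) or
#'   attachment count `m` (scale free).
#' @param rewire_p Rewiring probability in `[0, 1]` (small world only).
#' @param seed Optional integer seed; when given the generated edge set is a
#'   deterministic function of the arguments.
#' @return An undirected simple igraph with vertex names `"1" ... "n"`.
#' @examples
#' g <- generate_network("small_world", n = 100, k_or_m = 10, seed = 1)
#' igraph::ecount(g) # 500
#' @export
generate_network <- function(family = c("small_world", "scale_free"),
                             n, k_or_m, rewire_p = 0.4, seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(n) || n < 2 || !is.numeric(k_or_m) || k_or_m < 1 ||
      n <= k_or_m) {
    stop("invalid generator parameters: need n > k_or_m >= 1", call. = FALSE)
  }
  if (rewire_p < 0 || rewire_p > 1) {
    stop("rewire_p must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  g <- switch(family,
    small_world = watts_strogatz_edges(n, k_or_m, rewire_p),
    scale_free  = preferential_attachment_edges(n, k_or_m)
  )
  gg <- igraph::graph_from_edgelist(g, directed = FALSE)
  gg <- igraph::add_vertices(gg, n - igraph::vcount(gg))
  igraph::V(gg)$name <- as.character(seq_len(n))
  gg
}

# ring lattice + independent far-endpoint rewiring; preserves edge count
watts_strogatz_edges <- function(n, k, p) {
  if (k %% 2 != 0) stop("small_world k must be even", call. = FALSE)
  half <- k / 2
  u <- rep(seq_len(n), each = half)
  v <- ((u - 1 + rep(seq_len(half), times = n)) %% n) + 1
  el <- cbind(u, v)
  adj <- vector("list", n)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  rewire <- stats::runif(nrow(el)) < p
  for (i in which(rewire)) {
    a <- el[i, 1]; b <- el[i, 2]
    w <- sample.int(n, 1L)
    if (w == a || w %in% adj[[a]]) next # keep original edge; no loop/duplicate
    adj[[a]] <- c(setdiff(adj[[a]], b), w)
    adj[[b]] <- setdiff(adj[[b]], a)
    adj[[w]] <- c(adj[[w]], a)
    el[i, 2] <- w
  }
  el
}

# Barabasi-Albert growth from m isolated seeds (first arrival links to all m);
# targets drawn degree-proportionally via a repeated-endpoints urn
preferential_attachment_edges <- function(n, m) {
  el <- matrix(0L, nrow = m * (n - m), ncol = 2)
  urn <- integer(0)          # every edge endpoint appears once per incidence
  targets <- seq_len(m)      # the seed nodes, for the first arrival
  row <- 1L
  for (v in (m + 1L):n) {
    for (t in targets) {
      el[row, ] <- c(v, t)
      row <- row + 1L
    }
    urn <- c(urn, targets, rep(v, m))
    # m distinct degree-proportional targets for the next arrival
    targets <- integer(0)
    while (length(targets) < m) {
      cand <- urn[sample.int(length(urn), 1L)]
      if (!(cand %in% targets)) targets <- c(targets, cand)
    }
  }
  enforce_min_degree(el, n, m)
}

# Every non-seed node attaches m edges, but a seed node can end with degree
# < m if preferential attachment never revisits it. The family contract is a
# minimum degree of m, so deficient nodes steal endpoints from edges whose
# ends both exceed m: (a, b) -> (v, b). Edge count is preserved and no
# degree drops below m.
enforce_min_degree <- function(el, n, m) {
  deg <- tabulate(el, nbins = n)
  for (v in which(deg < m)) {
    while (deg[v] < m) {
      ok <- which(deg[el[, 1]] > m & deg[el[, 2]] > m &
                    el[, 1] != v & el[, 2] != v)
      nbr_v <- c(el[el[, 1] == v, 2], el[el[, 2] == v, 1])
      ok <- ok[!(el[ok, 2] %in% nbr_v)]
      if (length(ok) == 0) break     # degenerate parameters; leave as built
      i <- ok[1L]
      deg[el[i, 1]] <- deg[el[i, 1]] - 1L
      el[i, 1] <- v
      deg[v] <- deg[v] + 1L
    }
  }
  el
}

#' Descriptive statistics of a network
#'
#' Computes the roster statistics used to characterize benchmark networks:
#' size, density, degree assortativity, mean local clustering coefficient
#' (nodes of degree < 2 contribute 0) and the degree range.
#'
#' @param g An igraph object with at least 2 nodes.
#' @return A one-row `data.frame` with columns `n_nodes`, `n_edges`,
#'   `density`, `assortativity`, `avg_clustering`, `degree_min`, `degree_avg`,
#'   `degree_max`. `assortativity` is `NA` on regular graphs (zero degree
#'   variance).
#' @export
compute_stats <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("compute_stats needs at least 2 nodes", call. = FALSE)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  if (!is.finite(assort)) assort <- NA_real_
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  data.frame(
    n_nodes = n,
    n_edges = m,
    density = 2 * m / (n * (n - 1)),
    assortativity = assort,
    avg_clustering = cc,
    degree_min = min(deg),
    degree_avg = 2 * m / n,
    degree_max = max(deg)
  )
}

#' Analytic density and mean degree from node/edge counts
#'
#' The closed forms `2m / (n(n-1))` and `2m / n` for an undirected simple
#' graph, so roster tables can be checked without materializing the graphs.
#'
#' @param n_nodes,n_edges Counts.
#' @return A numeric value.
#' @export
density_from_counts <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 2)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' @rdname density_from_counts
#' @export
mean_degree_from_counts <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 1)
  2 * n_edges / n_nodes
}

#' Benchmark network roster
#'
#' The eight networks of the benchmark design: four real-world networks (loadable
#' from user-supplied edge lists; not bundled) and four synthetic ones with
#' their generator families. Node and edge counts are the reference roster
#' values; for the synthetic families they are exact generator outputs.
#'
#' @return A `data.frame` with columns `network`, `kind`, `family`, `n_nodes`,
#'   `n_edges`, and generator parameters `k_or_m` (NA for real networks).
#' @export
network_roster <- function() {
  data.frame(
    network = c("Dolphin", "Football", "SF-1", "SW-1",
                "SF-2", "SW-2", "Facebook", "Social"),
    kind    = c("real", "real", "synthetic", "synthetic",
                "synthetic", "synthetic", "real", "real"),
    family  = c(NA, NA, "scale_free", "small_world",
                "scale_free", "small_world", NA, NA),
    n_nodes = c(62, 115, 500, 500, 1000, 1000, 4039, 12600),
    n_edges = c(159, 613, 2475, 2500, 4975, 5000, 88234, 671000),
    k_or_m  = c(NA, NA, 5, 10, 5, 10, NA, NA),
    stringsAsFactors = FALSE
  )
}

# restore (or clear) the global RNG state after a locally seeded section
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run expr under a local seed (NULL = use current RNG stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}
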