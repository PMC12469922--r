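#' Simulation configuration for cascade generation
#'
#' Bundles the parameters of one simulated outbreak. Defaults are the
#' benchmark's reference conditions: SIR with per-edge per-step infection
#' probability `beta = 0.1` and per-step recovery probability `gamma = 0.05`
#' (rumor-propagation dynamics), Independent Cascade transmission probability
#' `p_ic = 0.4`, and a minimum outbreak coverage of 40% of the nodes enforced
#' by re-seeding and re-running failed cascades.
#'
#' @param model `"SIR"` or `"IC"`.
#' @param beta SIR per-edge per-step infection probability.
#' @param gamma SIR per-step recovery probability.
#' @param p_ic IC per-edge transmission probability.
#' @param source_fraction Fraction of nodes initially infected.
#' @param fallback_ratio Fraction used by the fallback seeding rule when the
#'   rounded source count is degenerate; defaults to `source_fraction`.
#' @param coverage_target Minimum fraction of nodes ever infected for a
#'   cascade to be accepted.
#' @param max_attempts Number of fresh-source retries before giving up.
#' @param max_steps Step budget per attempt.
#' @param seed Optional integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model = c("SIR", "IC"), beta = 0.1, gamma = 0.05,
                       p_ic = 0.4, source_fraction = 0.01,
                       fallback_ratio = NULL, coverage_target = 0.4,
                       max_attempts = 100, max_steps = 10000, seed = NULL) {
  model <- match.arg(model)
  probs <- c(beta = beta, gamma = gamma, p_ic = p_ic,
             source_fraction = source_fraction,
             coverage_target = coverage_target)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (coverage_target <= 0) stop("coverage_target must be in (0, 1]", call. = FALSE)
  if (max_attempts < 1) stop("max_attempts must be >= 1", call. = FALSE)
  structure(list(
    model = model, beta = beta, gamma = gamma, p_ic = p_ic,
    source_fraction = source_fraction,
    fallback_ratio = if (is.null(fallback_ratio)) source_fraction else fallback_ratio,
    coverage_target = coverage_target,
    max_attempts = max_attempts, max_steps = max_steps, seed = seed
  ), class = "sim_config")
}

#' Number of seed nodes for a given source fraction
#'
#' The requested count is `round(n_nodes * source_fraction)`. When that count
#' is zero, or when it collides with the count implied by another fraction of
#' the configured ladder (so two nominally different infection levels would
#' seed identically), the fallback rule applies: the greater of 2 and
#' `ceiling(n_nodes * fallback_ratio)`.
#'
#' @param n_nodes Number of nodes in the network (>= 2).
#' @param source_fraction Requested fraction of seed nodes.
#' @param fallback_ratio Fraction used by the fallback rule.
#' @param ladder Optional numeric vector of all fractions in use for this
#'   network, used to detect rounding collisions.
#' @return An integer seed count, at most `n_nodes`.
#' @examples
#' pick_source_count(62, 0.0001)    # 2 (fallback)
#' pick_source_count(1000, 0.10)    # 100
#' @export
pick_source_count <- function(n_nodes, source_fraction,
                              fallback_ratio = source_fraction,
                              ladder = NULL) {
  if (n_nodes < 2) stop("need at least 2 nodes", call. = FALSE)
  k <- round(n_nodes * source_fraction)
  ok <- k >= 1
  if (ok && !is.null(ladder)) {
    all_k <- round(n_nodes * ladder)
    ok <- sum(all_k == k) <= 1   # distinct across the ladder
  }
  if (!ok) k <- max(2, ceiling(n_nodes * fallback_ratio))
  as.integer(min(k, n_nodes))
}

#' Draw seed nodes uniformly at random
#'
#' @param g The network.
#' @param count Number of sources to draw (without replacement).
#' @param seed Optional integer seed.
#' @return A character vector of node names.
#' @export
pick_sources <- function(g, count, seed = NULL) {
  n <- igraph::vcount(g)
  if (count > n) stop("cannot draw more sources than nodes", call. = FALSE)
  with_seed(seed, {
    if (count == 0) character(0) else
      igraph::V(g)$name[sample.int(n, count)]
  })
}

#' Simulate one outbreak and extract its propagation record
#'
#' Runs a discrete-time SIR or Independent Cascade process from the given (or
#' freshly drawn) sources. If the cascade covers less than
#' `cfg$coverage_target` of the nodes, the whole cascade is retried with
#' fresh uniformly drawn sources (same count), up to `cfg$max_attempts`
#' times; exceeding the budget is an error carrying the best attempt.
#'
#' Dynamics:
#' \describe{
#'   \item{SIR}{Synchronous steps. Every infected node independently attempts
#'     to infect each susceptible neighbour with probability `beta`; then
#'     every node that was already infected before the step recovers with
#'     probability `gamma` (a node cannot recover in the step it is
#'     infected). Stops when the coverage target is reached, no infected
#'     nodes remain, or `max_steps` is hit.}
#'   \item{IC}{A node activated at step t gets exactly one attempt, at step
#'     t+1, to activate each inactive neighbour with probability `p_ic`;
#'     the cascade runs until no new activations occur.}
#' }
#'
#' @param g The network (undirected simple igraph with vertex names).
#' @param sources Character vector of seed node names, or `NULL` to draw
#'   `pick_source_count()` sources from `cfg`.
#' @param cfg A [sim_config()].
#' @param record_attempts Logical; for IC, keep a log of every directed
#'   activation attempt (columns `from`, `to`, `success`).
#' @return A `propagation` object: list with `graph`, `true_sources`,
#'   `ever_infected`, `history` (integer matrix, rows = steps incl. step 0,
#'   columns = nodes; 0 = susceptible/inactive, 1 = infected/active,
#'   2 = recovered), `infection_graph` (induced subgraph on the
#'   ever-infected set), `attempts_used`, `model`, and `coverage`.
#' @examples
#' g <- generate_network("small_world", 100, 10, seed = 1)
#' p <- simulate_cascade(g, cfg = sim_config("SIR", seed = 7))
#' p$coverage >= 0.4
#' @export
simulate_cascade <- function(g, sources = NULL, cfg = sim_config(),
                             record_attempts = FALSE) {
  n <- igraph::vcount(g)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(n))
  }
  with_seed(cfg$seed, {
    k <- if (is.null(sources)) {
      pick_source_count(n, cfg$source_fraction, cfg$fallback_ratio)
    } else {
      length(sources)
    }
    if (k < 1) stop("sources must be nonempty", call. = FALSE)
    adj <- igraph::as_adj_list(g, mode = "all")
    adj <- lapply(adj, as.integer)
    best <- NULL
    for (attempt in seq_len(cfg$max_attempts)) {
      src <- if (attempt == 1 && !is.null(sources)) {
        match(sources, igraph::V(g)$name)
      } else {
        sample.int(n, k)
      }
      if (anyNA(src)) stop("sources must be nodes of g", call. = FALSE)
      run <- if (cfg$model == "SIR") {
        run_sir(adj, n, src, cfg)
      } else {
        run_ic(adj, n, src, cfg, record_attempts)
      }
      run$attempts_used <- attempt
      run$true_sources <- igraph::V(g)$name[src]
      if (is.null(best) || run$coverage > best$coverage) best <- run
      if (run$coverage >= cfg$coverage_target) break
    }
    if (best$coverage < cfg$coverage_target) {
      cond <- structure(
        class = c("sourcetrace_sim_failure", "error", "condition"),
        list(message = sprintf(
          "coverage target %.2f not reached in %d attempts (best %.3f)",
          cfg$coverage_target, cfg$max_attempts, best$coverage),
          call = sys.call(-1), best_attempt = best))
      stop(cond)
    }
    finish_propagation(best, g, cfg)
  })
}

#' @rdname simulate_cascade
#' @export
simulate_sir <- function(g, sources = NULL, cfg = sim_config("SIR")) {
  stopifnot(cfg$model == "SIR")
  simulate_cascade(g, sources, cfg)
}

#' @rdname simulate_cascade
#' @export
simulate_ic <- function(g, sources = NULL, cfg = sim_config("IC"),
                        record_attempts = FALSE) {
  stopifnot(cfg$model == "IC")
  simulate_cascade(g, sources, cfg, record_attempts = record_attempts)
}

run_sir <- function(adj, n, src, cfg) {
  state <- integer(n)          # 0 = S, 1 = I, 2 = R
  state[src] <- 1L
  hist <- list(state)
  for (step in seq_len(cfg$max_steps)) {
    infected <- which(state == 1L)
    if (length(infected) == 0L) break
    # per-edge infection attempts from every infected node
    targets <- unlist(adj[infected], use.names = FALSE)
    if (length(targets)) {
      hit <- targets[stats::runif(length(targets)) < cfg$beta]
      newly <- unique(hit[state[hit] == 0L])
    } else {
      newly <- integer(0)
    }
    recov <- infected[stats::runif(length(infected)) < cfg$gamma]
    state[newly] <- 1L
    state[recov] <- 2L
    hist[[step + 1L]] <- state
    if (sum(state != 0L) / n >= cfg$coverage_target) break
    if (length(newly) == 0L && all(state != 1L)) break
  }
  ever <- which(state != 0L)
  list(history = do.call(rbind, hist), ever_idx = ever,
       coverage = length(ever) / n, model = "SIR", attempt_log = NULL)
}

run_ic <- function(adj, n, src, cfg, record_attempts) {
  state <- integer(n)          # 0 = inactive, 1 = active
  state[src] <- 1L
  frontier <- src
  hist <- list(state)
  log_from <- integer(0); log_to <- integer(0); log_ok <- logical(0)
  step <- 0L
  while (length(frontier) > 0L && step < cfg$max_steps) {
    step <- step + 1L
    from <- rep.int(frontier, lengths(adj[frontier]))
    to <- unlist(adj[frontier], use.names = FALSE)
    live <- state[to] == 0L    # one attempt per directed pair: frontier is new
    from <- from[live]; to <- to[live]
    ok <- stats::runif(length(to)) < cfg$p_ic
    if (record_attempts) {
      log_from <- c(log_from, from); log_to <- c(log_to, to)
      log_ok <- c(log_ok, ok)
    }
    newly <- unique(to[ok])
    state[newly] <- 1L
    frontier <- newly
    hist[[step + 1L]] <- state
  }
  ever <- which(state == 1L)
  attempt_log <- if (record_attempts) {
    data.frame(from = log_from, to = log_to, success = log_ok)
  } else NULL
  list(history = do.call(rbind, hist), ever_idx = ever,
       coverage = length(ever) / n, model = "IC", attempt_log = attempt_log)
}

finish_propagation <- function(run, g, cfg) {
  names_v <- igraph::V(g)$name
  ever <- names_v[run$ever_idx]
  colnames(run$history) <- names_v
  gi <- igraph::induced_subgraph(g, run$ever_idx)
  structure(list(
    graph = g,
    true_sources = run$true_sources,
    ever_infected = ever,
    history = run$history,
    infection_graph = gi,
    attempts_used = run$attempts_used,
    model = run$model,
    coverage = run$coverage,
    attempt_log = run$attempt_log,
    config = cfg
  ), class = "propagation")
}

#' @export
print.propagation <- function(x, ...) {
  cat(sprintf(
    "<propagation> %s cascade: %d/%d nodes ever infected (%.1f%%), %d source(s), %d attempt(s)\n",
    x$model, length(x$ever_infected), igraph::vcount(x$graph),
    100 * x$coverage, length(x$true_sources), x$attempts_used))
  invisible(x)
}

#' Infection subgraph of a propagation
#'
#' The node-induced subgraph of the full network on the ever-infected set:
#' all edges of the network between ever-infected nodes, not only the edges
#' the contagion actually crossed. This is the graph on which source
#' detection operates.
#'
#' @param p A `propagation` object.
#' @return An igraph object.
#' @export
extract_infection_graph <- function(p) {
  stopifnot(inherits(p, "propagation"))
  if (length(p$ever_infected) == 0) stop("no infected nodes", call. = FALSE)
  p$infection_graph
}

#' Serialize a propagation to plain-text files
#'
#' Writes the infection-subgraph edge list, the true sources (one label per
#' line), and the per-step state table (`step`, `node`, `state`).
#'
#' @param p A `propagation` object.
#' @param prefix Path prefix; files `<prefix>_gi.edges`, `<prefix>_sources.txt`
#'   and `<prefix>_history.tsv` are created.
#' @return The three paths, invisibly.
#' @export
write_propagation <- function(p, prefix) {
  stopifnot(inherits(p, "propagation"))
  f1 <- paste0(prefix, "_gi.edges")
  f2 <- paste0(prefix, "_sources.txt")
  f3 <- paste0(prefix, "_history.tsv")
  write_edge_list(p$infection_graph, f1)
  writeLines(p$true_sources, f2)
  h <- p$history
  df <- data.frame(
    step = rep(seq_len(nrow(h)) - 1L, each = ncol(h)),
    node = rep(colnames(h), times = nrow(h)),
    state = c(t(h))
  )
  utils::write.table(df, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
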