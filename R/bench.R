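#' Specify an experiment grid
#'
#' The benchmark design is a full factorial over networks, diffusion models
#' and repeated runs: each network–model combination gets
#' `length(source_fractions) * reps_per_fraction` independent cascades, and
#' every cascade is scored by every method at every hop radius. The reference
#' design (8 networks, 2 models, 4 fractions x 3 reps, 25 methods) yields 96
#' propagation schemes per model, 192 propagation graphs and 4800
#' method-experiments.
#'
#' @param networks Named list; each element is an igraph object, a function
#'   `function(seed)` returning one, or `NA` (roster placeholder, usable for
#'   grid enumeration only).
#' @param models Character subset of `c("SIR", "IC")`.
#' @param source_fractions Numeric vector of seed fractions (the benchmark ladder
#'   is `c(1e-4, 1e-3, 0.01, 0.10)`).
#' @param reps_per_fraction Cascade repetitions per fraction (reference design: 3).
#' @param methods Character vector of centrality codes and/or `"JC"`, `"NT"`.
#' @param hops_levels Integer vector of expansion radii.
#' @param master_seed Integer seed from which all per-run seeds derive.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(networks, models = c("SIR", "IC"),
                      source_fractions = c(1e-4, 1e-3, 0.01, 0.10),
                      reps_per_fraction = 3,
                      methods = centrality_codes(),
                      hops_levels = c(0, 1), master_seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  known <- c(centrality_codes(), "JC", "NT")
  if (!all(methods %in% known)) {
    stop("unknown method(s): ",
         paste(setdiff(methods, known), collapse = ", "), call. = FALSE)
  }
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    stop("networks must be a named list", call. = FALSE)
  }
  structure(list(networks = networks, models = models,
                 source_fractions = source_fractions,
                 reps_per_fraction = reps_per_fraction,
                 methods = methods, hops_levels = hops_levels,
                 master_seed = master_seed), class = "grid_spec")
}

#' Enumerate the experiment descriptors of a grid
#'
#' One descriptor per (network, model, run); runs sweep the source-fraction
#' ladder, `reps_per_fraction` cascades each. Child seeds are drawn once from
#' the master seed, so the enumeration (and everything downstream) is a
#' deterministic function of the spec.
#'
#' @param spec A [grid_spec()].
#' @return A `data.frame` with columns `network`, `model`, `run`,
#'   `source_fraction`, `seed`; attribute `n_experiments` gives
#'   `nrow * length(methods)`.
#' @examples
#' spec <- grid_spec(setNames(as.list(rep(NA, 8)), paste0("net", 1:8)))
#' nrow(build_grid(spec)) # 192 = 8 networks x 2 models x 12 runs
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  runs_per_combo <- length(spec$source_fractions) * spec$reps_per_fraction
  d <- expand.grid(
    run = seq_len(runs_per_combo),
    model = spec$models,
    network = names(spec$networks),
    stringsAsFactors = FALSE
  )[, c("network", "model", "run")]
  d$source_fraction <- rep(
    rep(spec$source_fractions, each = spec$reps_per_fraction),
    times = nrow(d) / runs_per_combo)
  d$seed <- with_seed(spec$master_seed,
                      sample.int(.Machine$integer.max - 1L, nrow(d)))
  attr(d, "n_experiments") <- nrow(d) * length(spec$methods)
  attr(d, "methods") <- spec$methods
  d
}

#' Run an experiment grid
#'
#' For each descriptor: materialize the network, pick the oracle source
#' count for its fraction (with the fallback rule applied against the full
#' fraction ladder), simulate the cascade (with coverage retries), extract
#' the infection subgraph, run every method at oracle k, and evaluate at
#' every hop radius. Cascades that fail to reach coverage are recorded as
#' failed and skipped; methods whose wall-clock exceeds `time_budget`
#' seconds on a propagation are marked skipped and excluded from aggregates.
#'
#' @param spec A [grid_spec()].
#' @param cfg_template A [sim_config()] whose model/source fields are
#'   overridden per descriptor.
#' @param time_budget Per-method per-propagation wall-clock cap in seconds
#'   (`Inf` = none).
#' @param nt_oracle_k Passed to [detect_sources()].
#' @param verbose Print per-propagation progress to stderr.
#' @return A `data.frame` of evaluation records, one row per
#'   (propagation, method, hops), with provenance columns (`network`,
#'   `model`, `run`, `source_fraction`, `seed`, `attempts`, `status`).
#' @export
run_grid <- function(spec, cfg_template = sim_config(),
                     time_budget = Inf, nt_oracle_k = TRUE,
                     verbose = FALSE) {
  grid <- build_grid(spec)
  out <- vector("list", nrow(grid))
  graph_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    g <- materialize_network(spec$networks[[row$network]], row$network,
                             row$seed, graph_cache)
    n <- igraph::vcount(g)
    k <- pick_source_count(n, row$source_fraction,
                           fallback_ratio = row$source_fraction,
                           ladder = spec$source_fractions)
    cfg <- cfg_template
    cfg$model <- row$model
    cfg$seed <- row$seed
    prop <- tryCatch(
      simulate_cascade(g, sources = pick_sources(g, k, seed = row$seed),
                       cfg = cfg),
      sourcetrace_sim_failure = function(e) NULL)
    if (is.null(prop)) {
      out[[i]] <- cbind(row, data.frame(method = NA, hops = NA, status = "sim_failed"))
      next
    }
    gi <- prop$infection_graph
    k_true <- length(prop$true_sources)
    recs <- lapply(spec$methods, function(m) {
      t0 <- proc.time()[["elapsed"]]
      det <- tryCatch(detect_sources(gi, m, k_true, g = g,
                                     nt_oracle_k = nt_oracle_k),
                      error = function(e) NULL)
      elapsed <- proc.time()[["elapsed"]] - t0
      if (is.null(det) || elapsed >= time_budget) {
        return(cbind(row, data.frame(method = m, hops = NA,
                                     status = "skipped")))
      }
      evals <- do.call(rbind, lapply(spec$hops_levels, function(h) {
        evaluate_detection(det, prop, hops = h)
      }))
      cbind(row[rep(1, nrow(evals)), ], evals, status = "ok")
    })
    out[[i]] <- do.call(rbind_fill, recs)
    out[[i]]$attempts <- prop$attempts_used
    if (verbose) {
      message(sprintf("[%d/%d] %s %s run %d: |GI|=%d k=%d attempts=%d",
                      i, nrow(grid), row$network, row$model, row$run,
                      igraph::vcount(gi), k_true, prop$attempts_used))
    }
  }
  res <- do.call(rbind_fill, out)
  rownames(res) <- NULL
  res
}

materialize_network <- function(src, name, seed, cache) {
  if (igraph::is_igraph(src)) return(src)
  if (is.function(src)) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    g <- src(seed)
    cache[[name]] <- g
    return(g)
  }
  stop("network '", name, "' is a placeholder and cannot be materialized",
       call. = FALSE)
}

# rbind data.frames with unequal column sets (missing columns become NA)
rbind_fill <- function(...) {
  dfs <- Filter(Negate(is.null), list(...))
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  }))
}

#' Aggregate evaluation records into ranked method tables
#'
#' Per-method, per-hop-radius means of TP, F1, TPR, PPV and GADE over
#' completed experiments, sorted by TPR descending (ties by F1, then code) —
#' the layout of the benchmark's summary tables.
#'
#' @param records Output of [run_grid()] (or any data.frame with `method`,
#'   `hops`, `tp`, `f1`, `tpr`, `ppv`, `gade`, `status` columns).
#' @return A `data.frame` with columns `method`, `hops`, `n`, `mean_tp`,
#'   `mean_f1`, `mean_tpr`, `mean_ppv`, `mean_gade`.
#' @export
aggregate_records <- function(records) {
  ok <- records[!is.na(records$method) & records$status == "ok", ]
  if (nrow(ok) == 0) stop("no completed experiments", call. = FALSE)
  sp <- split(ok, list(ok$method, ok$hops), drop = TRUE)
  agg <- do.call(rbind, lapply(sp, function(d) {
    data.frame(method = d$method[1], hops = d$hops[1], n = nrow(d),
               mean_tp = mean(d$tp), mean_f1 = mean(d$f1),
               mean_tpr = mean(d$tpr), mean_ppv = mean(d$ppv),
               mean_gade = mean(d$gade[is.finite(d$gade)]))
  }))
  agg <- agg[order(agg$hops, -agg$mean_tpr, -agg$mean_f1, agg$method), ]
  rownames(agg) <- NULL
  agg
}

#' Generator-backed synthetic benchmark networks
#'
#' Convenience constructor for the default desk-scale network suite: the
#' benchmark's synthetic small-world and scale-free families, optionally at
#' reduced sizes, as generator closures consumable by [grid_spec()].
#'
#' @param sizes Named integer vector `c(small = ..., large = ...)` of node
#'   counts; the benchmark sizes are 500 and 1000.
#' @param seed_offset Integer added to the grid seed for network generation,
#'   so networks are fixed per grid rather than per run.
#' @return Named list of generator functions.
#' @export
synthetic_network_suite <- function(sizes = c(small = 500, large = 1000),
                                    seed_offset = 0) {
  mk <- function(family, n, km) {
    force(family); force(n); force(km)
    function(seed) generate_network(family, n, km,
                                    seed = (seed_offset + n + km) %% 2^31)
  }
  nets <- list()
  for (i in seq_along(sizes)) {
    n <- sizes[[i]]
    tag <- i
    nets[[paste0("SW-", tag)]] <- mk("small_world", n, 10)
    nets[[paste0("SF-", tag)]] <- mk("scale_free", n, 5)
  }
  nets
}
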