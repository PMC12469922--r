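#' Expand a suspected-source set by a hop radius
#'
#' Returns every node of `gi` within hop distance `hops` of any detected
#' node. Radius 0 is the identity; the result always contains the input.
#' Expansion runs inside the infection subgraph by default (true sources are
#' infected by definition, so no recall is lost); pass the full network as
#' `gi` to expand through uninfected nodes instead.
#'
#' @param detected Character vector of node names, subset of `gi`'s nodes.
#' @param gi The graph to expand within.
#' @param hops Non-negative expansion radius (the benchmark uses 0, 1, 2).
#' @return Character vector of node names (superset of `detected`).
#' @export
expand_hops <- function(detected, gi, hops) {
  vn <- igraph::V(gi)$name
  if (!all(detected %in% vn)) {
    stop("detected nodes must belong to the graph", call. = FALSE)
  }
  if (hops == 0 || length(detected) == 0) return(detected)
  D <- igraph::distances(gi, v = detected)
  vn[apply(D, 2, min) <= hops]
}

#' Confusion-matrix evaluation of a suspected-source set
#'
#' Counts TP/FP/FN/TN against the true sources over a node universe (the
#' infection-subgraph nodes in the benchmark) and derives precision (PPV),
#' recall (TPR) and F1. Zero-denominator conventions: `ppv = 0` for an empty
#' suspected set, `tpr = 0` for an empty truth set, `f1 = 0` when `tp = 0`.
#'
#' @param suspected,true_sources Character vectors, subsets of `universe`.
#' @param universe Character vector of all evaluable nodes.
#' @return A one-row `data.frame` with columns `tp`, `fp`, `fn`, `tn`,
#'   `ppv`, `tpr`, `f1`.
#' @examples
#' confusion("a", "a", letters[1:5])$f1 # 1
#' @export
confusion <- function(suspected, true_sources, universe) {
  if (!all(suspected %in% universe) || !all(true_sources %in% universe)) {
    stop("suspected and true sources must lie in the universe", call. = FALSE)
  }
  suspected <- unique(suspected); true_sources <- unique(true_sources)
  tp <- length(intersect(suspected, true_sources))
  fp <- length(setdiff(suspected, true_sources))
  fn <- length(setdiff(true_sources, suspected))
  tn <- length(universe) - tp - fp - fn
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (tp > 0) 2 * ppv * tpr / (ppv + tpr) else 0
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn, ppv = ppv, tpr = tpr, f1 = f1)
}

#' Global average distance error (GADE) between true and estimated sources
#'
#' The symmetric nearest-counterpart distance: each estimated node
#' contributes its hop distance to the nearest true source, each missed true
#' source its distance to the nearest estimate, and the total is divided by
#' the number of estimates. Zero exactly when the two sets coincide.
#' Distances are measured in `gi`; node pairs in different components of a
#' disconnected `gi` contribute `Inf`.
#'
#' @param true_sources,estimated Nonempty character vectors of node names in
#'   `gi`.
#' @param gi The infection subgraph.
#' @return A non-negative number of hops.
#' @examples
#' g <- igraph::make_ring(3)
#' igraph::V(g)$name <- c("a", "b", "c")
#' gade("a", "a", g) # 0
#' @export
gade <- function(true_sources, estimated, gi) {
  vn <- igraph::V(gi)$name
  if (length(true_sources) == 0 || length(estimated) == 0) {
    stop("both node sets must be nonempty", call. = FALSE)
  }
  if (!all(c(true_sources, estimated) %in% vn)) {
    stop("nodes must belong to the infection subgraph", call. = FALSE)
  }
  D <- igraph::distances(gi, v = estimated, to = true_sources)
  term1 <- sum(apply(D, 1, min))                 # estimates -> nearest truth
  missed <- setdiff(true_sources, estimated)
  term2 <- if (length(missed)) {
    Dm <- igraph::distances(gi, v = missed, to = estimated)
    sum(apply(Dm, 1, min))                       # missed truths -> nearest estimate
  } else 0
  (term1 + term2) / length(estimated)
}

#' Average detection error (ADE) over a set of experiments
#'
#' Mean absolute difference between the number of detected and true sources.
#' Identically zero for oracle-k detectors; informative for Netsleuth's
#' MDL-chosen seed counts.
#'
#' @param n_detected,n_true Integer vectors of equal length, one entry per
#'   experiment.
#' @return A non-negative number.
#' @export
ade <- function(n_detected, n_true) {
  if (length(n_detected) == 0) stop("no experiments", call. = FALSE)
  stopifnot(length(n_detected) == length(n_true))
  mean(abs(n_detected - n_true))
}

#' Evaluate one detection against a propagation at a given hop radius
#'
#' Expands the detected set by `hops` within the infection subgraph, scores
#' the EXPANDED set with [confusion()] over the infection-subgraph universe,
#' and computes [gade()] on the unexpanded estimate.
#'
#' @param det A `detection` object.
#' @param prop A `propagation` object.
#' @param hops Expansion radius.
#' @return A one-row `data.frame`: `method`, `hops`, confusion columns,
#'   `gade`, `n_detected`, `n_true`.
#' @export
evaluate_detection <- function(det, prop, hops = 0) {
  gi <- prop$infection_graph
  universe <- igraph::V(gi)$name
  suspected <- expand_hops(det$estimated, gi, hops)
  cm <- confusion(suspected, prop$true_sources, universe)
  gd <- gade(prop$true_sources, det$estimated, gi)
  cbind(data.frame(method = det$method, hops = hops), cm,
        data.frame(gade = gd, n_detected = length(det$estimated),
                   n_true = length(prop$true_sources)))
}
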