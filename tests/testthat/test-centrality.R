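test_that("catalog basics on hand-checkable graphs", {
  star <- star_graph(4)
  expect_equal(as.numeric(compute_centrality(star, "DE")),
               c(4, 1, 1, 1, 1))

  p3 <- path_graph(3)
  expect_equal(compute_centrality(p3, "BC")[["b"]], 1)

  ring <- igraph::make_ring(8)      # 2-regular: all degree differences vanish
  expect_true(all(abs(as.numeric(compute_centrality(ring, "LE"))) < 1e-12))

  k2 <- named_graph("x-y")        # adjacency eigenvalues +-1
  expect_equal(as.numeric(compute_centrality(k2, "SU")),
               rep(cosh(1), 2), tolerance = 1e-8)

  # neighbourhood of the hub of K4 induces a triangle
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(compute_centrality(k4, "MNC")[["a"]], 3)

  expect_error(compute_centrality(p3, "XX"), "unknown centrality")
  expect_error(compute_centrality(igraph::make_empty_graph(3, directed = FALSE),
                                  "EI"), "at least one edge")
})

test_that("min-max normalization rescales, keeps the argmax, and handles ties", {
  s <- structure(c(a = 2, b = 4, c = 6), measure = "DE", normalized = FALSE,
                 class = "score_map")
  ns <- normalize_scores(s)
  expect_equal(as.numeric(ns), c(0, 0.5, 1))
  expect_true(attr(ns, "normalized"))

  const <- structure(c(a = 3, b = 3), measure = "DE", normalized = FALSE,
                     class = "score_map")
  expect_equal(as.numeric(normalize_scores(const)), c(1, 1))

  set.seed(1)
  for (i in 1:10) {
    g <- random_connected_graph(sample(4:9, 1))
    raw <- compute_centrality(g, sample(c("DE", "CL", "HA", "PR"), 1))
    expect_equal(which.max(as.numeric(normalize_scores(raw))),
                 which.max(as.numeric(raw)))
    expect_true(all(as.numeric(normalize_scores(raw)) >= 0 &
                      as.numeric(normalize_scores(raw)) <= 1))
  }
})

test_that("betweenness and load match explicit path-enumeration oracles", {
  set.seed(42)
  graphs <- c(
    list(path_graph(5), star_graph(5), igraph::make_ring(6),
         igraph::make_full_graph(5),
         named_graph("a-b", "a-c", "b-d", "c-d", "d-e")), # diamond + tail
    lapply(1:12, function(i) random_connected_graph(sample(4:7, 1)))
  )
  for (g in graphs) {
    if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    expect_equal(as.numeric(compute_centrality(g, "BC")), oracle_betweenness(g),
                 tolerance = 1e-10)
    expect_equal(as.numeric(compute_centrality(g, "LD")), oracle_load(g),
                 tolerance = 1e-10)
  }
})

test_that("load deviates from betweenness exactly where uneven splitting bites", {
  # classic example: even splitting sends flow along non-shortest-path counts
  g <- named_graph("s-a", "s-b", "a-c", "b-c", "c-t", "a-t2", "t2-t")
  ld <- as.numeric(compute_centrality(g, "LD"))
  bc <- as.numeric(compute_centrality(g, "BC"))
  expect_equal(ld, oracle_load(g), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(ld, bc)))
})

test_that("current-flow betweenness equals betweenness on trees", {
  set.seed(7)
  for (i in 1:6) {
    tr <- igraph::sample_tree(sample(5:14, 1))
    igraph::V(tr)$name <- as.character(seq_len(igraph::vcount(tr)))
    cfb <- as.numeric(compute_centrality(tr, "CFB"))
    bc <- as.numeric(compute_centrality(tr, "BC"))
    expect_equal(cfb, bc, tolerance = 1e-8)
  }
})

test_that("current-flow closeness equals information centrality", {
  set.seed(8)
  graphs <- c(lapply(c(6, 10, 15, 20), random_connected_graph),
              list(path_graph(6), star_graph(6)))
  for (g in graphs) {
    cfc <- as.numeric(compute_centrality(g, "CFC"))
    expect_equal(cfc, unname(oracle_information_centrality(g)),
                 tolerance = 1e-8)
  }
})

test_that("percolation with uniform states is score-proportional to betweenness", {
  set.seed(9)
  for (i in 1:8) {
    g <- random_connected_graph(sample(6:15, 1), p = 0.3)
    pe <- as.numeric(compute_centrality(g, "PE"))
    bc <- as.numeric(compute_centrality(g, "BC"))
    nz <- bc > 1e-12
    if (any(nz)) {
      expect_lt(diff(range(pe[nz] / bc[nz])), 1e-10)
    }
    expect_true(all(pe[!nz] < 1e-12))
    expect_equal(as.numeric(normalize_scores(compute_centrality(g, "PE"))),
                 as.numeric(normalize_scores(compute_centrality(g, "BC"))),
                 tolerance = 1e-10)
  }
})

test_that("closeness, radiality and Lin rank identically; AV is the exact reverse", {
  set.seed(10)
  for (i in 1:8) {
    g <- random_connected_graph(sample(6:15, 1), p = 0.3)
    cl <- rank_of(compute_centrality(g, "CL"))
    expect_equal(rank_of(compute_centrality(g, "RA")), cl)
    expect_equal(rank_of(compute_centrality(g, "LIN")), cl)
    av <- rank_of(-as.numeric(compute_centrality(g, "AV")))
    expect_equal(av, cl)
    br <- rank_of(compute_centrality(g, "BR"))
    expect_equal(br, cl) # on connected graphs barycenter is 1/farness too
  }
})

test_that("distance-based measures stay finite on disconnected graphs", {
  ring3 <- igraph::make_ring(3)
  igraph::V(ring3)$name <- c("e", "f", "g")
  g <- igraph::disjoint_union(path_graph(4), ring3)
  for (code in c("HA", "CL", "AV", "BR", "LIN", "RA", "DC", "GK", "CFC", "CFB")) {
    s <- compute_centrality(g, code)
    expect_true(all(is.finite(s)), info = code)
  }
  # harmonic handles the split: 1/Inf contributes 0 across components
  ha <- compute_centrality(g, "HA")
  expect_equal(ha[["a"]], 1 + 1 / 2 + 1 / 3)
})

test_that("eigenvector scores are non-negative with unit norm before rescaling", {
  set.seed(11)
  for (i in 1:5) {
    g <- random_connected_graph(sample(5:12, 1))
    ei <- as.numeric(compute_centrality(g, "EI"))
    expect_true(all(ei >= 0))
    expect_equal(sqrt(sum(ei^2)), 1, tolerance = 1e-8)
  }
})

test_that("algebraic centrality scores the drop in algebraic connectivity", {
  p3 <- path_graph(3)
  # lambda2(P3) = 1; removing the middle disconnects (lambda2 = 0),
  # removing a leaf gives K2 (lambda2 = 2)
  expect_equal(as.numeric(compute_centrality(p3, "AL")), c(-1, 1, -1),
               tolerance = 1e-10)
  # relative variant rescales by lambda2(G)
  expect_equal(as.numeric(compute_centrality(p3, "AL",
                                             params = list(variant = "relative"))),
               c(-1, 1, -1), tolerance = 1e-10)
})

test_that("coreness, decay, k-path, heatmap and topological follow their formulas", {
  g <- named_graph("a-b", "b-c", "c-d", "b-d", "d-e")
  D <- all_pairs_distances(g)
  deg <- igraph::degree(g)
  ks <- igraph::coreness(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  co <- compute_centrality(g, "CO")
  dc <- compute_centrality(g, "DC", params = list(delta = 0.5))
  gk <- compute_centrality(g, "GK", params = list(k = 2))
  he <- compute_centrality(g, "HE")
  for (v in igraph::V(g)$name) {
    nb <- names(adj[[v]])
    expect_equal(co[[v]], sum(ks[nb]))
    expect_equal(dc[[v]], sum(0.5^D[v, setdiff(colnames(D), v)]))
    expect_equal(gk[[v]], sum(D[v, ] > 0 & D[v, ] <= 2))
    expect_equal(he[[v]], mean(rowSums(D)[nb]) - sum(D[v, ]))
  }
})

test_that("all-pairs distances: symmetry, diagonal, infinity flag, triangle inequality", {
  g <- igraph::disjoint_union(random_connected_graph(6), path_graph(3))
  igraph::V(g)$name <- as.character(seq_len(9))
  D <- all_pairs_distances(g)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(any(is.infinite(D)))
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    expect_lte(D[i, j], D[i, k] + D[k, j])
  }
})
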