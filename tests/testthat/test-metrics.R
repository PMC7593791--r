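test_that("clustering coefficient on canonical graphs", {
  expect_equal(clustering_coefficient(k4())$nodal, rep(1, 4))
  expect_equal(clustering_coefficient(k4())$Cp, 1)
  expect_equal(clustering_coefficient(star5())$Cp, 0)
  # 4-cycle plus chord (1-3): frozen from brute-force triangle enumeration
  cc <- clustering_coefficient(cycle4_chord())
  expect_equal(cc$nodal, c(2 / 3, 1, 2 / 3, 1))
  expect_equal(cc$Cp, 5 / 6)
})

test_that("shortest paths, Lp, efficiencies on canonical graphs", {
  D <- shortest_paths_matrix(path3())
  expect_equal(D[1, 3], 2)
  expect_equal(characteristic_path_length(D), 4 / 3)
  expect_equal(global_efficiency(D), 5 / 6)

  # two components: cross distances infinite, Lp over reachable pairs only
  two_edges <- adj_from_edges(4, list(c(1, 2), c(3, 4)))
  D2 <- shortest_paths_matrix(two_edges)
  expect_equal(D2[1, 3], Inf)
  expect_equal(characteristic_path_length(D2), 1.0)
  expect_equal(global_efficiency(D2), 4 / 12)

  # Petersen graph: diameter 2
  Dp <- shortest_paths_matrix(petersen())
  offdiag <- Dp[row(Dp) != col(Dp)]
  expect_true(all(offdiag %in% c(1, 2)))

  expect_equal(characteristic_path_length(shortest_paths_matrix(k4())), 1)
  expect_error(characteristic_path_length(matrix(Inf, 2, 2) - diag(c(Inf, Inf))),
               "no reachable pairs")
})

test_that("local efficiency on canonical graphs", {
  expect_equal(local_efficiency(k4())$Eloc, 1)
  expect_equal(local_efficiency(star5())$Eloc, 0)
  # K4 minus edge (1,2): frozen from induced-subgraph brute force
  B <- k4(); B[1, 2] <- B[2, 1] <- 0L
  le <- local_efficiency(B)
  expect_equal(le$nodal, c(1, 1, 5 / 6, 5 / 6))
  expect_equal(le$Eloc, 11 / 12)
})

test_that("nodal metrics of the 5-star", {
  nm <- nodal_metrics(star5())
  expect_equal(nm$betweenness[1], 1.0)
  expect_equal(nm$betweenness[2], 0.0)
  expect_equal(nm$nodal_efficiency[1], 1.0)
  expect_equal(nm$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(nodal_metrics(k4())$nodal_Lp, rep(1, 4))
})

test_that("metrics agree with independent references on 50 random graphs", {
  for (i in 1:50) {
    n <- sample(5:12, 1)
    A <- random_connectedish_graph(n, runif(1, 0.25, 0.7), seed = 1000 + i)
    g <- igraph_of(A)

    expect_equal(shortest_paths_matrix(A),
                 unname(igraph::distances(g)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(clustering_coefficient(A)$nodal,
                 ifelse(is.nan(igraph::transitivity(g, "local")), 0,
                        igraph::transitivity(g, "local")),
                 tolerance = 1e-12)
    expect_equal(betweenness_centrality(A),
                 unname(igraph::betweenness(g, normalized = TRUE)),
                 tolerance = 1e-12)
    D <- igraph::distances(g)
    inv <- 1 / D; diag(inv) <- 0
    expect_equal(global_efficiency(shortest_paths_matrix(A)),
                 sum(inv) / (n * (n - 1)), tolerance = 1e-12)
  }
})

test_that("Eg >= 1/Lp for connected graphs (Jensen)", {
  for (i in 1:20) {
    A <- random_connectedish_graph(10, 0.5, seed = 300 + i)
    D <- shortest_paths_matrix(A)
    if (any(is.infinite(D))) next
    expect_gte(global_efficiency(D), 1 / characteristic_path_length(D))
  }
})

test_that("metrics are invariant under node relabeling", {
  A <- random_connectedish_graph(10, 0.4, seed = 77)
  set.seed(8)
  perm <- sample(10)
  B <- A[perm, perm]
  expect_equal(clustering_coefficient(A)$Cp, clustering_coefficient(B)$Cp)
  expect_equal(characteristic_path_length(shortest_paths_matrix(A)),
               characteristic_path_length(shortest_paths_matrix(B)))
  expect_equal(local_efficiency(A)$Eloc, local_efficiency(B)$Eloc)
  expect_equal(sort(betweenness_centrality(A)), sort(betweenness_centrality(B)))
})

test_that("null ensemble preserves degrees exactly and is seeded", {
  A <- random_connectedish_graph(30, 0.2, seed = 5)
  g <- igraph_of(A)
  set.seed(123)
  r <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * sum(A) / 2))
  expect_equal(igraph::degree(r), igraph::degree(g))

  e1 <- null_ensemble(A, n_null = 5, seed = 4)
  e2 <- null_ensemble(A, n_null = 5, seed = 4)
  expect_identical(e1$Cp_rand, e2$Cp_rand)
  expect_identical(e1$Lp_rand, e2$Lp_rand)
  expect_error(null_ensemble(adj_from_edges(3, list(c(1, 2))), 3, 1),
               "at least 2 edges")
})

test_that("gamma of an Erdos-Renyi graph is near 1", {
  A <- random_connectedish_graph(50, 0.2, seed = 99)
  ens <- null_ensemble(A, n_null = 100, seed = 10)
  cl <- clustering_coefficient(A)
  sw <- small_world(cl$Cp, characteristic_path_length(shortest_paths_matrix(A)),
                    ens)
  expect_gt(sw$gamma, 0.8); expect_lt(sw$gamma, 1.2)
  expect_gt(sw$lambda, 0.8); expect_lt(sw$lambda, 1.2)
})

test_that("small_world arithmetic and error handling", {
  ens <- structure(list(Cp_rand = 0.5, Lp_rand = 2), class = "null_ensemble")
  sw <- small_world(1.0, 2.0, ens)
  expect_equal(sw$gamma, 2)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 2)
  expect_equal(small_world(0.5, 2, ens)$sigma, small_world(0.5, 2, ens)$gamma)
  expect_error(small_world(1, 1, structure(list(Cp_rand = 0, Lp_rand = 1),
                                           class = "null_ensemble")),
               "positive")
})

test_that("AUC over the sparsity grid is the trapezoid integral", {
  grid <- sparsity_grid()
  expect_equal(auc_over_sparsity(rep(1, 10), grid), 0.45)
  expect_equal(auc_over_sparsity(rep(0, 10), grid), 0)
  ramp <- seq(0, 1, length.out = 10)
  expect_equal(auc_over_sparsity(ramp, grid), 0.225)
  expect_error(auc_over_sparsity(1:3, grid), "3 values")
})
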