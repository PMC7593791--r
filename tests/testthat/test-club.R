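test_that("club selection takes the top floor(fraction N) with atlas-order ties", {
  atlas <- region_atlas()
  set.seed(1)
  scores <- runif(90)
  club <- select_club(scores, 0.15, atlas, "degree")
  expect_length(club$club_nodes, 13)
  expect_setequal(club$club_nodes, order(-scores)[1:13])

  # all-equal scores: first 13 atlas-order nodes
  tied <- select_club(rep(1, 90), 0.15, atlas)
  expect_equal(tied$club_nodes, 1:13)

  # N = 10, fraction 0.5, distinct scores: the 5 largest
  a10 <- region_atlas(paste0("r", 1:10))
  s10 <- c(5, 9, 1, 7, 3, 10, 2, 8, 4, 6)
  expect_setequal(select_club(s10, 0.5, a10)$club_nodes,
                  c(6, 2, 8, 4, 10))

  expect_error(select_club(rep(1, 10), 0.05, a10), "selects no nodes")
  expect_error(select_club(c(rep(1, 89), NA), 0.15, atlas), "finite")
})

test_that("average_ranking_scores is an unweighted order-invariant mean", {
  expect_equal(average_ranking_scores(list(c(2, 4))), c(2, 4))
  expect_equal(average_ranking_scores(list(c(2, 0), c(4, 2))), c(3, 1))
  expect_equal(average_ranking_scores(list(c(2, 0), c(4, 2))),
               average_ranking_scores(list(c(4, 2), c(2, 0))))
  expect_error(average_ranking_scores(list()), "empty reference")
  expect_error(average_ranking_scores(list(1:3, 1:2)), "length")
})

test_that("edge classification is an exhaustive partition", {
  # triangle with one club node: feeder, feeder, local
  A <- adj_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3)))
  cls <- classify_edges(A, 1L)
  expect_equal(sort(as.character(cls$class)), c("feeder", "feeder", "local"))

  # club-club and feeder labels
  cls2 <- classify_edges(A, c(1L, 2L))
  got <- setNames(as.character(cls2$class), paste(cls2$i, cls2$j))
  expect_equal(got[["1 2"]], "club")
  expect_equal(got[["1 3"]], "feeder")
  expect_equal(got[["2 3"]], "feeder")

  # partition property on a random graph
  A3 <- random_connectedish_graph(20, 0.3, seed = 2)
  cls3 <- classify_edges(A3, c(3L, 7L, 11L))
  expect_equal(nrow(cls3), sum(A3) / 2)
  expect_true(all(table(cls3$class) >= 0))
})

test_that("connection strengths sum over classes and conserve total weight", {
  set.seed(4)
  m <- matrix(rnorm(200 * 12), 200, 12)
  m <- m + rowMeans(m)
  C <- pearson_connectivity(ts_matrix(m, paste0("r", 1:12)))
  G <- binarize_by_sparsity(C, 0.4)
  cls <- classify_edges(G, c(1L, 2L, 3L))
  st <- connection_strengths(C, G, cls)
  total <- sum(C[upper.tri(C)][G$adjacency[upper.tri(C)] == 1])
  expect_equal(st$club_strength + st$feeder_strength + st$local_strength,
               total, tolerance = 1e-9)

  # binary weighting counts edges
  stb <- connection_strengths(C, G, cls, weighting = "binary")
  expect_equal(stb$club_strength + stb$feeder_strength + stb$local_strength,
               nrow(cls))
  expect_equal(stb$club_strength, sum(cls$class == "club"))

  # empty club: everything is local
  st0 <- connection_strengths(C, G, classify_edges(G, integer()))
  expect_equal(st0$club_strength, 0)
  expect_equal(st0$feeder_strength, 0)
  expect_equal(st0$local_strength, total, tolerance = 1e-9)

  expect_error(connection_strengths(C[1:5, 1:5], G, cls), "dimensions differ")
})

test_that("overlap analysis does disjoint set algebra and set means", {
  atlas <- region_atlas(paste0("r", 1:10))
  rich <- select_club(c(10, 9, 8, 1:7), 0.3, atlas)        # nodes 1,2,3
  diverse <- select_club(c(0, 10, 9, 8, rep(1, 6)), 0.3, atlas)  # nodes 2,3,4
  ov <- overlap_analysis(rich, diverse, atlas = atlas)
  expect_equal(ov$overlap, c("r2", "r3"))
  expect_equal(ov$rich_only, "r1")
  expect_equal(ov$diverse_only, "r4")

  # identical clubs: full overlap
  ov2 <- overlap_analysis(rich, rich, atlas = atlas)
  expect_length(ov2$overlap, 3)
  expect_length(ov2$rich_only, 0)

  # per-subject set means
  nm <- nodal_metrics(random_connectedish_graph(10, 0.5, seed = 3))
  ov3 <- overlap_analysis(rich, diverse, list(s1 = nm), atlas)
  sm <- ov3$set_means
  got <- sm$mean_value[sm$set == "overlap" & sm$metric == "degree"]
  expect_equal(got, mean(nm$degree[2:3]))
  got_ro <- sm$mean_value[sm$set == "rich_only" & sm$metric == "nodal_Lp"]
  expect_equal(got_ro, nm$nodal_Lp[1])
})
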