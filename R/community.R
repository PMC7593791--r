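#' Detect network communities (seeded Louvain + consensus)
#'
#' Runs Louvain modularity maximization `n_runs` times under seeds derived
#' deterministically from `seed`, then builds a consensus partition from
#' the co-assignment matrix: node pairs assigned together in more than half
#' the runs are linked, and the connected components of that agreement
#' graph are the consensus communities.  If the consensus is degenerate
#' (a single community, or all singletons, while individual runs were not)
#' the best-modularity run is returned instead.
#'
#' @param G A `binary_network` or adjacency matrix with at least 1 edge.
#' @param n_runs Number of Louvain restarts (default 100).
#' @param seed Integer seed; fixed seed gives an identical partition.
#' @return List of class `community_partition`: `assignment` (per-node
#'   integer labels, contiguous from 1), `n_communities`, `modularity`,
#'   `seed`, `n_runs`.
#' @export
detect_communities <- function(G, n_runs = 100, seed = 1) {
  A <- as_adjacency(G)
  if (sum(A) == 0) stopf("community detection needs at least one edge")
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  memberships <- matrix(0L, n_runs, n)
  qs <- numeric(n_runs)
  for (b in seq_len(n_runs)) {
    set.seed(derive_seed(seed, 1000L + b))
    cl <- igraph::cluster_louvain(g)
    memberships[b, ] <- as.integer(igraph::membership(cl))
    qs[b] <- igraph::modularity(g, igraph::membership(cl))
  }
  # co-assignment agreement graph, majority threshold
  co <- matrix(0, n, n)
  for (b in seq_len(n_runs)) {
    m <- memberships[b, ]
    co <- co + outer(m, m, "==")
  }
  agree <- (co / n_runs) > 0.5
  diag(agree) <- FALSE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(agree, mode = "undirected"))
  assignment <- as.integer(comp$membership)
  best <- which.max(qs)
  k_runs <- max(memberships[best, ])
  degenerate <- (max(assignment) == 1L && k_runs > 1L) ||
    (max(assignment) == n && k_runs < n)
  if (degenerate) {
    clubnet_log("consensus partition degenerate; falling back to best-Q run")
    assignment <- memberships[best, ]
  }
  assignment <- match(assignment, sort(unique(assignment)))  # contiguous
  structure(list(
    assignment = assignment,
    n_communities = max(assignment),
    modularity = igraph::modularity(g, assignment),
    seed = seed, n_runs = n_runs
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", x$n_communities, " communities, Q = ",
      round(x$modularity, 4), "\n", sep = "")
  invisible(x)
}

#' Participation coefficient
#'
#' The Guimera-Amaral measure of how evenly a node's edges span
#' communities: `pc_i = 1 - sum_s (k_is / k_i)^2`, where `k_is` counts
#' node i's edges into community s and `k_i` is its degree.  A node whose
#' edges all stay inside its own community scores exactly 0; the maximum
#' attainable with m communities is `1 - 1/m` (reached when edges are
#' split evenly), so values never reach 1.  Isolated nodes score 0 by
#' convention.
#'
#' @param G A `binary_network` or adjacency matrix.
#' @param partition A `community_partition` (or a plain integer label
#'   vector covering all nodes).
#' @return Per-node numeric vector in \\[0, 1 - 1/m\\].
#' @export
participation_coefficient <- function(G, partition) {
  A <- as_adjacency(G)
  m <- if (inherits(partition, "community_partition")) {
    partition$assignment
  } else {
    as.integer(partition)
  }
  if (length(m) != nrow(A)) stopf("partition must cover all %d nodes", nrow(A))
  k <- rowSums(A)
  coms <- sort(unique(m))
  # k_is: edges from each node into each community
  kis <- vapply(coms, function(s) rowSums(A[, m == s, drop = FALSE]),
                numeric(nrow(A)))
  frac2 <- (kis / pmax(k, 1))^2
  pc <- 1 - rowSums(frac2)
  pc[k == 0] <- 0
  as.numeric(pc)
}
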