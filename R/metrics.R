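# Global and nodal topological metrics on binary networks, plus the
# degree-preserving null ensemble used to normalize them.
#
# All functions accept either a `binary_network` or a plain 0/1 adjacency
# matrix.  Conventions for disconnected graphs: characteristic path length
# averages reachable pairs only; efficiencies score unreachable pairs as
# 1/Inf = 0.  This keeps every metric finite at the sparse end of the grid.

#' Clustering coefficient
#'
#' Per-node transitivity `2 T_i / (k_i (k_i - 1))` where `T_i` counts
#' triangles through node i; nodes of degree < 2 score 0.  `Cp` is the
#' unweighted mean over all nodes.
#'
#' @param G A `binary_network` or adjacency matrix.
#' @return List with `nodal` (per-node values) and `Cp` (their mean).
#' @export
clustering_coefficient <- function(G) {
  A <- as_adjacency(G)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2     # closed triangles through each node
  denom <- k * (k - 1)
  nodal <- ifelse(denom > 0, 2 * tri / denom, 0)
  list(nodal = as.numeric(nodal), Cp = mean(nodal))
}

#' All-pairs shortest-path distances of an unweighted network
#'
#' Breadth-first distances computed by iterated boolean products of the
#' adjacency matrix; unreachable pairs are `Inf`, the diagonal is 0.
#'
#' @param G A `binary_network` or adjacency matrix.
#' @return N x N numeric distance matrix.
#' @export
shortest_paths_matrix <- function(G) {
  A <- as_adjacency(G) > 0
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  D[A] <- 1
  reach <- A | diag(TRUE, n)
  frontier <- A
  d <- 1L
  while (any(frontier) && d < n) {
    nxt <- (frontier %*% A) > 0
    new <- nxt & !reach
    if (!any(new)) break
    d <- d + 1L
    D[new] <- d
    reach <- reach | new
    frontier <- new
  }
  D
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered *reachable* pairs; infinite
#' distances (disconnected pairs) are excluded from the average.
#'
#' @param D Distance matrix from [shortest_paths_matrix()], or a network.
#' @return Scalar Lp.
#' @export
characteristic_path_length <- function(D) {
  if (!is.matrix(D) || any(D < 0, na.rm = TRUE) || inherits(D, "binary_network")) {
    D <- shortest_paths_matrix(D)
  }
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  if (!length(fin)) stopf("no reachable pairs: cannot define a path length")
  mean(fin)
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over all ordered pairs, with
#' `1/Inf = 0` for unreachable pairs.
#'
#' @param D Distance matrix or network.
#' @return Scalar Eg in \\[0, 1\\].
#' @export
global_efficiency <- function(D) {
  if (inherits(D, "binary_network") || all(D %in% c(0, 1))) {
    D <- shortest_paths_matrix(D)
  }
  inv <- 1 / D
  diag(inv) <- 0
  n <- nrow(D)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (0 when the node has fewer than 2 neighbors); Eloc is the
#' unweighted mean over nodes.
#'
#' @param G A `binary_network` or adjacency matrix.
#' @return List with `nodal` and `Eloc`.
#' @export
local_efficiency <- function(G) {
  A <- as_adjacency(G)
  n <- nrow(A)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) >= 2) nodal[i] <- global_efficiency(A[nb, nb, drop = FALSE])
  }
  list(nodal = nodal, Eloc = mean(nodal))
}

# Brandes' algorithm for betweenness centrality on an unweighted graph.
brandes_betweenness <- function(A) {
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    stack <- integer(0)
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      stack <- c(stack, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(stack)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2  # undirected: each pair counted twice
}

#' Betweenness centrality
#'
#' Brandes' exact algorithm, normalized by `(N-1)(N-2)/2` so values lie in
#' \\[0, 1\\] (a star center scores exactly 1).
#'
#' @param G A `binary_network` or adjacency matrix.
#' @return Per-node numeric vector.
#' @export
betweenness_centrality <- function(G) {
  A <- as_adjacency(G)
  n <- nrow(A)
  if (n < 3) return(numeric(n))
  brandes_betweenness(A) / ((n - 1) * (n - 2) / 2)
}

#' All nodal metrics of one network
#'
#' @param G A `binary_network` or adjacency matrix.
#' @return Data.frame with columns `region`, `degree`, `nodal_efficiency`,
#'   `nodal_clustering`, `nodal_Lp` (mean distance to *reachable* others;
#'   0 for isolated nodes), `betweenness`.
#' @export
nodal_metrics <- function(G) {
  A <- as_adjacency(G)
  n <- nrow(A)
  D <- shortest_paths_matrix(A)
  inv <- 1 / D; diag(inv) <- 0
  eff <- rowSums(inv) / (n - 1)
  lp <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]; d <- d[is.finite(d)]
    if (length(d)) mean(d) else 0
  }, numeric(1))
  data.frame(
    region = if (!is.null(rownames(A))) rownames(A) else as.character(seq_len(n)),
    degree = as.integer(rowSums(A)),
    nodal_efficiency = eff,
    nodal_clustering = clustering_coefficient(A)$nodal,
    nodal_Lp = lp,
    betweenness = betweenness_centrality(A),
    stringsAsFactors = FALSE
  )
}

#' Degree-preserving random-network null ensemble
#'
#' Generates `n_null` rewired versions of `G` by Maslov-Sneppen double-edge
#' swaps (10 x E attempted swaps each), which preserve every node's degree
#' exactly, and returns the ensemble means of the clustering coefficient
#' and characteristic path length used to normalize the small-world
#' metrics.
#'
#' @param G A `binary_network` or adjacency matrix with at least 2 edges.
#' @param n_null Number of null networks (the reference analysis uses 1000;
#'   100 is adequate for testing).
#' @param seed Integer seed; fixed seed gives an identical ensemble.
#' @return List of class `null_ensemble`: `Cp_rand`, `Lp_rand`, `n_null`,
#'   `seed`.
#' @export
null_ensemble <- function(G, n_null = 1000, seed = 1) {
  A <- as_adjacency(G)
  E <- sum(A) / 2
  if (E < 2) stopf("null ensemble needs a graph with at least 2 edges")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cps <- numeric(n_null); lps <- numeric(n_null)
  for (b in seq_len(n_null)) {
    set.seed(derive_seed(seed, b))
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * E))
    Ar <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
    cps[b] <- clustering_coefficient(Ar)$Cp
    lps[b] <- characteristic_path_length(shortest_paths_matrix(Ar))
  }
  structure(list(Cp_rand = mean(cps), Lp_rand = mean(lps),
                 n_null = n_null, seed = seed),
            class = "null_ensemble")
}

#' Small-world metrics
#'
#' `gamma = Cp / Cp_rand`, `lambda = Lp / Lp_rand`, `sigma = gamma /
#' lambda`, with the null means taken from a degree-matched
#' [null_ensemble()].  `sigma > 1` indicates small-world topology.
#'
#' @param Cp,Lp Observed clustering coefficient and path length.
#' @param ens A `null_ensemble`.
#' @return Named list `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(Cp, Lp, ens) {
  if (ens$Cp_rand <= 0 || ens$Lp_rand <= 0) {
    stopf("null ensemble means must be positive")
  }
  gamma <- Cp / ens$Cp_rand
  lambda <- Lp / ens$Lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of per-threshold metric values over the sparsity
#' grid; the paper-standard scalar summary that removes the arbitrariness
#' of a single threshold.
#'
#' @param values Metric values, one per grid point.
#' @param grid Sparsity grid (strictly increasing, length >= 2).
#' @return Scalar AUC.
#' @export
auc_over_sparsity <- function(values, grid) {
  if (length(values) != length(grid)) {
    stopf("got %d values for %d grid points", length(values), length(grid))
  }
  if (length(grid) < 2) stopf("AUC needs at least 2 grid points")
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}
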