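# Shared fixtures: tiny graphs and cohort builders.  All randomness is
# seeded; nothing touches the network or the file system outside tempdir.

options(clubnet.verbose = FALSE)

adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  A
}

star5 <- function() adj_from_edges(5, lapply(2:5, function(i) c(1L, i)))
path3 <- function() adj_from_edges(3, list(c(1, 2), c(2, 3)))
k4 <- function() matrix(1L, 4, 4) - diag(4L)
cycle4_chord <- function() {
  adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))
}
petersen <- function() {
  outer <- lapply(1:5, function(i) c(i, i %% 5 + 1))
  spokes <- lapply(1:5, function(i) c(i, i + 5))
  inner <- lapply(1:5, function(i) c(i + 5, (i + 1) %% 5 + 6))
  adj_from_edges(10, c(outer, spokes, inner))
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# guaranteed to have at least one edge
random_connectedish_graph <- function(n, p, seed) {
  A <- random_graph(n, p, seed)
  if (sum(A) == 0) A[1, 2] <- A[2, 1] <- 1L
  A
}

igraph_of <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

tiny_spec <- function(seed = 42, npg = c(HC = 4L, SCD = 3L, aMCI = 4L), ...) {
  cohort_spec(seed = seed, n_per_group = npg, n_timepoints = 120L, ...)
}

write_tiny_cohort <- function(dir, seed = 42, ...) {
  co <- generate_cohort(tiny_spec(seed, ...))
  write_cohort(co, dir)
  co
}

demo_manifest <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- c("sub-a,HC,70.5,F,29,0,14,13.5",
              "sub-b,SCD,72.1,M,28,1,15,12.0",
              "sub-c,aMCI,68.9,F,27,2,8,5.2")
  }
  writeLines(c("subject_id,group,age,sex,mmse,gds,lmt_immediate,lmt_delayed",
               rows), path)
  path
}
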