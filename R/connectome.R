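#' Pearson connectivity matrix of one subject
#'
#' Computes the N x N matrix of sample Pearson correlations between every
#' pair of regional time series.  The diagonal is set to 0, the convention
#' used throughout the package so that self-connections never enter any
#' network quantity.
#'
#' @param ts A `clubnet_ts` object (see [ts_matrix()]) or a plain T x N
#'   numeric matrix with column names.
#' @return An N x N symmetric numeric matrix of class `connectivity_matrix`
#'   with zero diagonal, region labels as dimnames and the subject id in
#'   attribute `subject_id`.
#' @export
#' @examples
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' C <- pearson_connectivity(ts_matrix(x, subject_id = "demo"))
#' range(C)
pearson_connectivity <- function(ts) {
  if (inherits(ts, "clubnet_ts")) {
    m <- ts$values; sid <- ts$subject_id
  } else {
    m <- as.matrix(ts); sid <- "subject"
  }
  if (nrow(m) < 3L) stopf("need at least 3 timepoints for a correlation")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance time series for region(s): %s",
          paste(colnames(m)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(m)
  diag(r) <- 0
  structure(r, class = c("connectivity_matrix", "matrix", "array"),
            subject_id = sid)
}

#' The default sparsity grid
#'
#' Binarization thresholds expressed as the fraction of possible edges
#' retained, by default 5% to 50% in 5% steps (10 values).
#'
#' @param from,to,by Grid limits and step, fractions in (0, 1].
#' @return Numeric vector of strictly increasing sparsity values.
#' @export
sparsity_grid <- function(from = 0.05, to = 0.50, by = 0.05) {
  s <- seq(from, to, by)
  if (any(s <= 0) || any(s > 1) || is.unsorted(s, strictly = TRUE)) {
    stopf("sparsity values must be strictly increasing and in (0, 1]")
  }
  round(s, 10)
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Keeps the `K = round(S * N(N-1)/2)` largest off-diagonal correlations
#' (upper triangle) and sets them to 1, the rest to 0.  Negative or zero
#' correlations are never retained: if fewer than `K` positive entries
#' exist the network simply has fewer edges and a warning reports the
#' shortfall.  Ties are resolved deterministically by ascending (row,
#' column) index so that outputs are bit-stable.
#'
#' @param C Connectivity matrix from [pearson_connectivity()] (any
#'   symmetric numeric matrix with zero diagonal works).
#' @param S Sparsity fraction in (0, 1].
#' @return A `binary_network`: list with `adjacency` (N x N 0/1 matrix,
#'   symmetric, zero diagonal) and `sparsity`.
#' @export
binarize_by_sparsity <- function(C, S) {
  if (S <= 0 || S > 1) stopf("sparsity must be in (0, 1], got %g", S)
  check_symmetric(C, "connectivity matrix")
  n <- nrow(C)
  n_pairs <- n * (n - 1) / 2
  K <- round(S * n_pairs)
  if (K < 1) stopf("sparsity %g too low for N = %d (no edges)", S, n)
  ut <- which(upper.tri(C))
  vals <- C[ut]
  # order by descending value, ties by ascending linear (column-major) index,
  # i.e. ascending (j, i) upper-triangle position -- deterministic
  ord <- order(-vals, ut)
  keep <- ord[seq_len(K)]
  keep <- keep[vals[keep] > 0]
  if (length(keep) < K) {
    clubnet_log(sprintf(
      "binarize: %d of %d requested edges dropped (non-positive correlations)",
      K - length(keep), K))
  }
  A <- matrix(0L, n, n, dimnames = dimnames(C))
  A[ut[keep]] <- 1L
  A <- A + t(A)
  structure(list(adjacency = A, sparsity = S,
                 subject_id = attr(C, "subject_id")),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat("<binary_network> ", nrow(x$adjacency), " nodes, ",
      sum(x$adjacency) / 2, " edges (S = ", x$sparsity, ")\n", sep = "")
  invisible(x)
}

# accept a binary_network or a raw adjacency matrix everywhere
as_adjacency <- function(G) {
  A <- if (inherits(G, "binary_network")) G$adjacency else as.matrix(G)
  if (!is_square_matrix(A)) stopf("adjacency must be square")
  A
}

#' Edge density of a binary network
#'
#' @param G A `binary_network` or adjacency matrix.
#' @return `2E / (N(N-1))`, the realized fraction of possible edges.
#' @export
network_density <- function(G) {
  A <- as_adjacency(G)
  n <- nrow(A)
  sum(A) / (n * (n - 1))
}
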