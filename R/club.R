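# Rich-club / diverse-club definition, edge classification, connection
# strengths and overlapping-node analysis.
#
# A club is a fixed-size node set selected once from a reference group
# (healthy controls by default) and then applied to every subject: the
# top floor(fraction * N) regions by mean nodal degree (rich club) or by
# mean participation coefficient (diverse club) at the reference sparsity.

#' Average per-node ranking scores over reference-group subjects
#'
#' @param score_list List of per-node numeric vectors (one per subject of
#'   the reference group), all the same length.
#' @return Per-node mean scores.
#' @export
average_ranking_scores <- function(score_list) {
  if (!length(score_list)) stopf("empty reference group: no scores to average")
  lens <- lengths(score_list)
  if (length(unique(lens)) != 1) stopf("score vectors differ in length")
  rowMeans(do.call(cbind, score_list))
}

#' Select a club from per-node ranking scores
#'
#' Returns the `floor(fraction * N)` highest-scoring regions.  With the
#' defaults (N = 90, fraction = 0.15) that is exactly 13 regions.  Ties
#' are broken by ascending atlas index (deterministic); exact ties at the
#' boundary are reported with a warning since they make the cut order
#' conventional.
#'
#' @param ranking_scores Per-node numeric vector, finite, length N.
#' @param fraction Fraction of regions in the club, in (0, 1); default 0.15.
#' @param atlas A [region_atlas()] providing node labels.
#' @param criterion Label recorded for provenance: `"degree"` (rich club)
#'   or `"participation"` (diverse club).
#' @return List of class `club_definition`: `club_nodes` (indices, ordered
#'   by rank), `club_labels`, `fraction`, `criterion`, `ranking_scores`.
#' @export
select_club <- function(ranking_scores, fraction = 0.15,
                        atlas = region_atlas(),
                        criterion = c("degree", "participation")) {
  criterion <- match.arg(criterion)
  n <- length(ranking_scores)
  if (n != atlas$n) stopf("got %d scores for an atlas of %d regions", n, atlas$n)
  if (!all(is.finite(ranking_scores))) stopf("ranking scores must be finite")
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  size <- floor(fraction * n)
  if (size < 1) stopf("fraction %g of %d regions selects no nodes", fraction, n)
  ord <- order(-ranking_scores, seq_len(n))  # ties: ascending atlas index
  club <- ord[seq_len(size)]
  cutoff <- ranking_scores[club[size]]
  if (sum(ranking_scores == cutoff) > 1 && size < n &&
      ranking_scores[ord[size + 1]] == cutoff) {
    clubnet_log(sprintf(
      "club selection: tie at the boundary score %g broken by atlas order", cutoff))
  }
  structure(list(club_nodes = club, club_labels = atlas$labels[club],
                 fraction = fraction, criterion = criterion,
                 ranking_scores = ranking_scores),
            class = "club_definition")
}

#' @export
print.club_definition <- function(x, ...) {
  cat("<club_definition> ", length(x$club_nodes), " regions by ",
      x$criterion, ": ", paste(x$club_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify every edge as club, feeder or local
#'
#' Club connections link two club nodes, feeder connections link one club
#' node to one peripheral node, local connections link two peripheral
#' nodes.  The three labels partition the edge set.
#'
#' @param G A `binary_network` or adjacency matrix.
#' @param club A `club_definition` (or an integer vector of club node
#'   indices).
#' @return Data.frame with columns `i`, `j` (node indices, i < j) and
#'   `class` (factor club/feeder/local), one row per edge.
#' @export
classify_edges <- function(G, club) {
  A <- as_adjacency(G)
  nodes <- if (inherits(club, "club_definition")) club$club_nodes else as.integer(club)
  if (length(nodes) && max(nodes) > nrow(A)) stopf("club node index out of range")
  in_club <- seq_len(nrow(A)) %in% nodes
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  n_in <- in_club[ut[, 1]] + in_club[ut[, 2]]
  cls <- factor(c("local", "feeder", "club")[n_in + 1],
                levels = c("club", "feeder", "local"))
  data.frame(i = ut[, 1], j = ut[, 2], class = cls)
}

#' Connection strengths by edge class
#'
#' Sums, per class, the correlation weights of the edges retained in the
#' thresholded network: a per-subject summary of how strongly the club
#' core, its feeders and the periphery are connected.  With the default
#' (positive-only) thresholding all retained weights are positive, and the
#' three strengths always add up to the network's total retained weight.
#'
#' @param C The subject's connectivity matrix (weights).
#' @param G The binary network thresholded *from C*.
#' @param cls Edge classification from [classify_edges()].
#' @param weighting `"pearson"` (default) sums correlation weights;
#'   `"binary"` counts edges.
#' @return Named list `club_strength`, `feeder_strength`, `local_strength`.
#' @export
connection_strengths <- function(C, G, cls, weighting = c("pearson", "binary")) {
  weighting <- match.arg(weighting)
  A <- as_adjacency(G)
  if (!identical(dim(as.matrix(C)), dim(A))) {
    stopf("connectivity (%d x %d) and network (%d x %d) dimensions differ",
          nrow(C), ncol(C), nrow(A), ncol(A))
  }
  w <- if (weighting == "pearson") C[cbind(cls$i, cls$j)] else rep(1, nrow(cls))
  s <- vapply(c("club", "feeder", "local"),
              function(lab) sum(w[cls$class == lab]), numeric(1))
  list(club_strength = unname(s["club"]),
       feeder_strength = unname(s["feeder"]),
       local_strength = unname(s["local"]))
}

#' Overlapping-node analysis of the rich and diverse clubs
#'
#' Overlapping nodes are regions belonging to both clubs (highest degree
#' *and* highest participation): candidate integrative cores.  The three
#' disjoint sets -- overlap, rich-only, diverse-only -- each get the
#' unweighted mean of every nodal metric, per subject.
#'
#' @param rich,diverse `club_definition` objects on the same atlas.
#' @param nodal_list Named list (by subject id) of data.frames from
#'   [nodal_metrics()]; may be `NULL` to get the sets only.
#' @param atlas The shared [region_atlas()].
#' @return List of class `overlap_analysis`: `overlap`, `rich_only`,
#'   `diverse_only` (label vectors) and `set_means` (long data.frame
#'   subject x set x metric, when `nodal_list` is given).
#' @export
overlap_analysis <- function(rich, diverse, nodal_list = NULL,
                             atlas = region_atlas()) {
  ov <- intersect(rich$club_nodes, diverse$club_nodes)
  ro <- setdiff(rich$club_nodes, ov)
  do <- setdiff(diverse$club_nodes, ov)
  sets <- list(overlap = sort(ov), rich_only = sort(ro), diverse_only = sort(do))
  set_means <- NULL
  if (!is.null(nodal_list)) {
    metric_cols <- c("degree", "nodal_efficiency", "nodal_clustering",
                     "nodal_Lp", "betweenness")
    rows <- list()
    for (sid in names(nodal_list)) {
      nm <- nodal_list[[sid]]
      for (set_name in names(sets)) {
        idx <- sets[[set_name]]
        if (!length(idx)) {
          clubnet_log(sprintf("overlap analysis: set '%s' empty for subject %s",
                              set_name, sid))
          vals <- rep(NA_real_, length(metric_cols))
        } else {
          vals <- colMeans(nm[idx, metric_cols, drop = FALSE])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, set = set_name,
          metric = metric_cols, mean_value = as.numeric(vals),
          stringsAsFactors = FALSE)
      }
    }
    set_means <- do.call(rbind, rows)
  }
  structure(list(overlap = atlas$labels[sets$overlap],
                 rich_only = atlas$labels[sets$rich_only],
                 diverse_only = atlas$labels[sets$diverse_only],
                 overlap_idx = sets$overlap, rich_only_idx = sets$rich_only,
                 diverse_only_idx = sets$diverse_only,
                 set_means = set_means),
            class = "overlap_analysis")
}
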