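# End-to-end orchestration: cohort directory in, result bundle out.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with the reference
#' defaults: sparsity grid 5-50% in 5% steps, clubs defined from the HC
#' group at 15% sparsity as the top 15% of regions, 1000 degree-preserving
#' nulls per network, 100 Louvain restarts.
#'
#' @param cohort_dir Directory with `manifest.csv` and one time-series
#'   file per subject (`<subject_id>.tsv`).
#' @param grid Sparsity grid, see [sparsity_grid()].
#' @param reference_sparsity Sparsity at which clubs, communities and
#'   strengths are computed (default 0.15; must be on the grid).
#' @param club_fraction Fraction of regions per club (default 0.15).
#' @param reference_group Group whose averaged rankings define the clubs
#'   (default `"HC"`).
#' @param n_null Null networks per (subject, threshold) for the
#'   small-world normalization (default 1000; use far fewer for smoke
#'   tests).
#' @param community_runs Louvain restarts for the consensus partition.
#' @param seed Master seed for nulls and community detection.
#' @param strength_weighting `"pearson"` or `"binary"`, see
#'   [connection_strengths()].
#' @param correlation_groups Groups pooled for the behavioral partial
#'   correlations (default SCD and aMCI, the patient groups).
#' @param force_all_correlations Compute behavioral correlations for all
#'   metrics, not only those with a Bonferroni-significant group effect.
#' @param output_dir Optional; when set, [run_pipeline()] writes the
#'   result files there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir,
                            grid = sparsity_grid(),
                            reference_sparsity = 0.15,
                            club_fraction = 0.15,
                            reference_group = "HC",
                            n_null = 1000,
                            community_runs = 100,
                            seed = 1,
                            strength_weighting = c("pearson", "binary"),
                            correlation_groups = c("SCD", "aMCI"),
                            force_all_correlations = FALSE,
                            output_dir = NULL) {
  strength_weighting <- match.arg(strength_weighting)
  if (!any(abs(grid - reference_sparsity) < 1e-9)) {
    stopf("reference sparsity %g is not on the grid", reference_sparsity)
  }
  if (club_fraction <= 0 || club_fraction >= 1) {
    stopf("club_fraction must be in (0, 1)")
  }
  structure(list(cohort_dir = cohort_dir, grid = grid,
                 reference_sparsity = reference_sparsity,
                 club_fraction = club_fraction,
                 reference_group = reference_group,
                 n_null = n_null, community_runs = community_runs,
                 seed = as.integer(seed),
                 strength_weighting = strength_weighting,
                 correlation_groups = correlation_groups,
                 force_all_correlations = isTRUE(force_all_correlations),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full connectome analysis
#'
#' Executes, in order: Pearson connectivity per subject; binarization over
#' the sparsity grid; global metrics (Cp, Lp, Eg, Eloc) with
#' degree-preserving null normalization (gamma, lambda, sigma) and their
#' AUCs; nodal metrics, Louvain consensus communities and participation
#' coefficients at the reference sparsity; reference-group-averaged
#' rankings; rich- and diverse-club selection; edge classification and
#' connection strengths for both clubs; overlapping-node analysis;
#' covariate-adjusted (age, sex) group statistics with Bonferroni
#' pairwise post hocs; and behavioral partial correlations against the
#' cognitive scores.  Identical config and cohort give identical output.
#'
#' @param config A [pipeline_config()].
#' @return Result bundle (list): `metrics`, `metrics_by_threshold`,
#'   `nodal_metrics`, `clubs`, `rich_club`, `diverse_club`, `overlap`,
#'   `strengths`, `stats`, `correlations`, `config`.  Written to
#'   `config$output_dir` when set (see [write_results()]).
#' @export
run_pipeline <- function(config) {
  stage <- "read manifest"
  res <- tryCatch(
    run_pipeline_impl(config, function(s) stage <<- s),
    error = function(e) {
      stopf("pipeline failed at stage [%s]: %s", stage, conditionMessage(e))
    })
  res
}

run_pipeline_impl <- function(config, set_stage) {
  atlas <- region_atlas()
  man <- read_manifest(file.path(config$cohort_dir, "manifest.csv"))
  n_sub <- nrow(man)
  clubnet_log(sprintf("cohort: %d subjects (%s)", n_sub,
                      paste(sprintf("%s=%d", names(table(man$group)),
                                    table(man$group)), collapse = ", ")))
  grid <- config$grid
  S_ref <- config$reference_sparsity
  covs <- cbind(age = man$age, sex = as.numeric(man$sex == "M"))

  set_stage("connectivity and thresholding")
  global_names <- c("Cp", "Lp", "Eg", "Eloc", "gamma", "lambda", "sigma")
  per_thr <- array(NA_real_, c(n_sub, length(grid), length(global_names)),
                   dimnames = list(man$subject_id, NULL, global_names))
  nodal_list <- list()
  strengths_rows <- list()
  pcs <- degs <- matrix(NA_real_, atlas$n, n_sub,
                        dimnames = list(atlas$labels, man$subject_id))
  C_ref <- vector("list", n_sub)
  G_ref <- vector("list", n_sub)

  for (s in seq_len(n_sub)) {
    sid <- man$subject_id[s]
    ts <- read_timeseries(file.path(config$cohort_dir, paste0(sid, ".tsv")),
                          atlas, subject_id = sid)
    C <- pearson_connectivity(ts)
    set_stage(paste("graph metrics for", sid))
    for (k in seq_along(grid)) {
      G <- binarize_by_sparsity(C, grid[k])
      cl <- clustering_coefficient(G)
      D <- shortest_paths_matrix(G)
      Lp <- characteristic_path_length(D)
      ens <- null_ensemble(G, config$n_null,
                           seed = derive_seed(config$seed, s * 1000L + k))
      sw <- small_world(cl$Cp, Lp, ens)
      per_thr[s, k, ] <- c(cl$Cp, Lp, global_efficiency(D),
                           local_efficiency(G)$Eloc,
                           sw$gamma, sw$lambda, sw$sigma)
      if (abs(grid[k] - S_ref) < 1e-9) {
        C_ref[[s]] <- C
        G_ref[[s]] <- G
      }
    }
    set_stage(paste("communities for", sid))
    nm <- nodal_metrics(G_ref[[s]])
    part <- detect_communities(G_ref[[s]], config$community_runs,
                               seed = derive_seed(config$seed, 500000L + s))
    nm$pc <- participation_coefficient(G_ref[[s]], part)
    nm$subject_id <- sid
    nodal_list[[sid]] <- nm
    pcs[, s] <- nm$pc
    degs[, s] <- nm$degree
  }

  set_stage("AUC summaries")
  auc_rows <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    data.frame(subject_id = man$subject_id[s], group = man$group[s],
               metric = global_names,
               auc = vapply(global_names, function(m)
                 auc_over_sparsity(per_thr[s, , m], grid), numeric(1)),
               stringsAsFactors = FALSE)
  }))

  set_stage("club selection")
  ref_idx <- which(man$group == config$reference_group)
  if (!length(ref_idx)) stopf("no subjects in reference group '%s'",
                              config$reference_group)
  mean_deg <- average_ranking_scores(lapply(ref_idx, function(s) degs[, s]))
  mean_pc <- average_ranking_scores(lapply(ref_idx, function(s) pcs[, s]))
  rich <- select_club(mean_deg, config$club_fraction, atlas, "degree")
  diverse <- select_club(mean_pc, config$club_fraction, atlas, "participation")
  clubnet_log("rich club: ", paste(rich$club_labels, collapse = ", "))
  clubnet_log("diverse club: ", paste(diverse$club_labels, collapse = ", "))

  set_stage("connection strengths")
  for (s in seq_len(n_sub)) {
    for (def in list(rich, diverse)) {
      cls <- classify_edges(G_ref[[s]], def)
      st <- connection_strengths(C_ref[[s]], G_ref[[s]], cls,
                                 config$strength_weighting)
      strengths_rows[[length(strengths_rows) + 1L]] <- data.frame(
        subject_id = man$subject_id[s], group = man$group[s],
        criterion = def$criterion,
        club_strength = st$club_strength,
        feeder_strength = st$feeder_strength,
        local_strength = st$local_strength, stringsAsFactors = FALSE)
    }
  }
  strengths <- do.call(rbind, strengths_rows)

  set_stage("overlap analysis")
  ov <- overlap_analysis(rich, diverse, nodal_list, atlas)

  set_stage("group statistics")
  stats_rows <- list()
  add_stat <- function(metric, contrast, sr, p_b = NA_real_) {
    stats_rows[[length(stats_rows) + 1L]] <<- data.frame(
      metric = metric, contrast = contrast,
      statistic_name = sr$statistic_name, value = sr$value,
      df1 = sr$df[1], df2 = if (length(sr$df) > 1) sr$df[2] else NA_real_,
      p_raw = sr$p_raw, p_bonferroni = p_b, n = sr$n,
      covariates = paste(sr$covariates, collapse = "+"),
      stringsAsFactors = FALSE)
  }
  pairs <- list(c("HC", "SCD"), c("HC", "aMCI"), c("SCD", "aMCI"))
  group_tests <- function(metric_name, y) {
    ok <- tryCatch({
      fr <- ancova_group_test(y, man$group, covs)
      add_stat(metric_name, "HC:SCD:aMCI", fr)
      for (pr in pairs) {
        keep <- man$group %in% pr
        if (length(unique(man$group[keep])) == 2) {
          tr <- adjusted_pairwise_t(y[keep], man$group[keep],
                                    covs[keep, , drop = FALSE])
          add_stat(metric_name, paste(pr, collapse = ":"), tr,
                   bonferroni(tr$p_raw, length(pairs)))
        }
      }
      fr$p_raw
    }, error = function(e) {
      clubnet_log("skipping group test for ", metric_name, ": ",
                  conditionMessage(e))
      NA_real_
    })
    ok
  }

  anova_p <- c()
  for (m in global_names) {
    y <- auc_rows$auc[auc_rows$metric == m]
    anova_p[paste0("auc_", m)] <- group_tests(paste0("auc_", m), y)
  }
  for (crit in c("degree", "participation")) {
    sub <- strengths[strengths$criterion == crit, ]
    for (cls in c("club_strength", "feeder_strength", "local_strength")) {
      mname <- paste0(if (crit == "degree") "rich_" else "diverse_", cls)
      anova_p[mname] <- group_tests(mname, sub[[cls]])
    }
  }
  if (!is.null(ov$set_means)) {
    for (set_name in unique(ov$set_means$set)) {
      for (m in c("nodal_efficiency", "nodal_Lp")) {
        sel <- ov$set_means$set == set_name & ov$set_means$metric == m
        y <- ov$set_means$mean_value[sel][match(man$subject_id,
                                                ov$set_means$subject_id[sel])]
        mname <- paste0(set_name, "_", m)
        anova_p[mname] <- group_tests(mname, y)
      }
    }
  }
  # demographics: age ANOVA (no covariates), sex chi-square
  add_stat("age", "HC:SCD:aMCI", ancova_group_test(man$age, man$group))
  sex_tab <- table(man$sex, man$group)
  if (all(rowSums(sex_tab) > 0) && all(colSums(sex_tab) > 0) &&
      nrow(sex_tab) == 2) {
    add_stat("sex", "HC:SCD:aMCI", chi_square_independence(sex_tab))
  }
  for (sc in c("mmse", "gds", "lmt_immediate", "lmt_delayed")) {
    if (!all(is.na(man[[sc]]))) group_tests(sc, man[[sc]])
  }

  set_stage("behavioral correlations")
  m_family <- sum(!is.na(anova_p))
  altered <- names(anova_p)[!is.na(anova_p) &
                              bonferroni(anova_p, m_family) < 0.05]
  wanted <- if (config$force_all_correlations) names(anova_p)[!is.na(anova_p)] else altered
  corr_rows <- list()
  keep <- man$group %in% config$correlation_groups
  metric_value <- function(mname) {
    if (startsWith(mname, "auc_")) {
      return(auc_rows$auc[auc_rows$metric == sub("auc_", "", mname)])
    }
    if (grepl("strength", mname)) {
      crit <- if (startsWith(mname, "rich_")) "degree" else "participation"
      col <- sub("^(rich|diverse)_", "", mname)
      return(strengths[strengths$criterion == crit, col])
    }
    for (set_name in c("overlap", "rich_only", "diverse_only")) {
      for (m in c("nodal_efficiency", "nodal_Lp")) {
        if (mname == paste0(set_name, "_", m)) {
          sel <- ov$set_means$set == set_name & ov$set_means$metric == m
          return(ov$set_means$mean_value[sel][match(man$subject_id,
                                                    ov$set_means$subject_id[sel])])
        }
      }
    }
    NULL
  }
  for (mname in wanted) {
    y <- metric_value(mname)
    if (is.null(y)) next
    for (sc in c("mmse", "gds", "lmt_immediate", "lmt_delayed")) {
      r <- tryCatch(
        partial_correlation(y[keep], man[[sc]][keep], covs[keep, , drop = FALSE]),
        error = function(e) NULL)
      if (is.null(r)) next
      corr_rows[[length(corr_rows) + 1L]] <- data.frame(
        metric = mname, contrast = paste0("corr_", sc),
        statistic_name = "r", value = r$value, df1 = r$df[1], df2 = NA_real_,
        p_raw = r$p_raw, p_bonferroni = bonferroni(r$p_raw, 4), n = r$n,
        covariates = paste(r$covariates, collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  stats <- do.call(rbind, c(stats_rows, corr_rows))

  nodal_out <- do.call(rbind, lapply(nodal_list, function(nm) {
    nm[c("subject_id", "region", "degree", "nodal_efficiency",
         "nodal_clustering", "nodal_Lp", "betweenness", "pc")]
  }))
  rownames(nodal_out) <- NULL

  res <- list(
    metrics = auc_rows,
    metrics_by_threshold = per_thr,
    nodal_metrics = nodal_out,
    clubs = list(rich_club = rich$club_labels,
                 diverse_club = diverse$club_labels,
                 overlap = ov$overlap),
    rich_club = rich, diverse_club = diverse, overlap = ov,
    strengths = strengths, stats = stats,
    anova_p = anova_p, altered = altered,
    config = config
  )
  if (!is.null(config$output_dir)) {
    set_stage("writing results")
    write_results(res, config$output_dir)
    cfg <- config
    cfg$grid <- as.numeric(cfg$grid)
    jsonlite::write_json(cfg[setdiff(names(cfg), "output_dir")],
                         file.path(config$output_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Single-threshold analysis of an in-memory cohort
#'
#' A reduced version of [run_pipeline()] for simulation studies: computes
#' connectivity, binarizes at one sparsity, selects the rich (and
#' optionally diverse) club from the reference group, and returns
#' per-subject connection strengths together with the mean overlap-node
#' metrics.  No null ensembles, no AUCs -- this is the cheap core used in
#' calibration and power replicates.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or a
#'   cohort directory path.
#' @param sparsity Threshold (default 0.15).
#' @param club_fraction Fraction of regions per club (default 0.15).
#' @param reference_group Group defining the clubs (default `"HC"`).
#' @param with_pc Also detect communities and the diverse club (slower).
#' @param community_runs,seed Louvain restarts and seed when `with_pc`.
#' @param overlap_nodes Optional region labels (or indices) to use as the
#'   overlap set for the mean overlap-node metrics; defaults to the
#'   detected rich-diverse intersection (or the rich club when `with_pc`
#'   is off).  Simulation studies pass the planted overlap here.
#' @return List: `table` (one row per subject: group, age, sex, cognitive
#'   scores, rich-club strengths, mean overlap-node `nodal_Lp` and
#'   `nodal_efficiency`, and diverse strengths when `with_pc`),
#'   `rich_club`, `diverse_club` (or NULL), `overlap_labels`.
#' @export
analyze_at_sparsity <- function(cohort, sparsity = 0.15,
                                club_fraction = 0.15,
                                reference_group = "HC",
                                with_pc = FALSE,
                                community_runs = 20, seed = 1,
                                overlap_nodes = NULL) {
  atlas <- region_atlas()
  if (is.character(cohort)) {
    man <- read_manifest(file.path(cohort, "manifest.csv"))
    ts_list <- lapply(man$subject_id, function(sid)
      read_timeseries(file.path(cohort, paste0(sid, ".tsv")), atlas, sid))
    names(ts_list) <- man$subject_id
  } else {
    man <- cohort$manifest
    ts_list <- cohort$timeseries
  }
  n_sub <- nrow(man)
  Cs <- lapply(ts_list, pearson_connectivity)
  Gs <- lapply(Cs, binarize_by_sparsity, S = sparsity)
  degs <- vapply(Gs, function(g) rowSums(g$adjacency), numeric(atlas$n))
  ref <- which(man$group == reference_group)
  if (!length(ref)) stopf("no subjects in reference group '%s'", reference_group)
  rich <- select_club(average_ranking_scores(lapply(ref, function(s) degs[, s])),
                      club_fraction, atlas, "degree")
  diverse <- NULL
  pcs <- NULL
  if (with_pc) {
    pcs <- vapply(seq_len(n_sub), function(s) {
      part <- detect_communities(Gs[[s]], community_runs,
                                 seed = derive_seed(seed, s))
      participation_coefficient(Gs[[s]], part)
    }, numeric(atlas$n))
    diverse <- select_club(
      average_ranking_scores(lapply(ref, function(s) pcs[, s])),
      club_fraction, atlas, "participation")
  }
  ov_idx <- if (!is.null(overlap_nodes)) {
    if (is.character(overlap_nodes)) atlas_index(atlas, overlap_nodes)
    else as.integer(overlap_nodes)
  } else if (!is.null(diverse)) {
    intersect(rich$club_nodes, diverse$club_nodes)
  } else {
    rich$club_nodes
  }
  tab <- man
  tab$sex_num <- as.numeric(man$sex == "M")
  for (col in c("rich_club_strength", "rich_feeder_strength",
                "rich_local_strength", "overlap_Lp", "overlap_efficiency",
                "diverse_club_strength", "diverse_feeder_strength",
                "diverse_local_strength")) {
    tab[[col]] <- NA_real_
  }
  for (s in seq_len(n_sub)) {
    st <- connection_strengths(Cs[[s]], Gs[[s]], classify_edges(Gs[[s]], rich))
    tab$rich_club_strength[s] <- st$club_strength
    tab$rich_feeder_strength[s] <- st$feeder_strength
    tab$rich_local_strength[s] <- st$local_strength
    if (!is.null(diverse)) {
      std <- connection_strengths(Cs[[s]], Gs[[s]],
                                  classify_edges(Gs[[s]], diverse))
      tab$diverse_club_strength[s] <- std$club_strength
      tab$diverse_feeder_strength[s] <- std$feeder_strength
      tab$diverse_local_strength[s] <- std$local_strength
    }
    D <- shortest_paths_matrix(Gs[[s]])
    inv <- 1 / D; diag(inv) <- 0
    tab$overlap_Lp[s] <- mean(vapply(ov_idx, function(i) {
      d <- D[i, -i]; d <- d[is.finite(d)]
      if (length(d)) mean(d) else 0
    }, numeric(1)))
    tab$overlap_efficiency[s] <- mean(rowSums(inv)[ov_idx] / (atlas$n - 1))
  }
  list(table = tab, rich_club = rich, diverse_club = diverse,
       overlap_labels = atlas$labels[ov_idx])
}
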