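# Synthetic cohort generator.
#
# The generator builds, per subject, a latent nonnegative weight matrix
# with five planted communities, a set of planted hub regions (elevated
# weights, highest expected degree), a set of planted connector regions
# (weights spread evenly across all communities, highest expected
# participation), and a group-dependent attenuation of hub-hub weights
# (the planted disease effect).
#
# The weights come from a factor (Gram) construction so that, apart from
# the zeroed diagonal, the matrix is positive semidefinite by design:
# every node loads on a global factor, community members load on their
# community factor, hubs additionally load on per-community and
# cross-community hub factors whose variances carry the group
# attenuation, and connectors load evenly on a few community factors,
# spreading their edges across modules.  Keeping the matrix near-PSD
# keeps the positive-definiteness shift small, which is what preserves
# strong, well-separated correlations after the shift.
#
# Time series are drawn from a zero-mean multivariate normal whose
# covariance is the latent matrix shifted to positive definiteness, so
# the sample Pearson matrix converges to the latent correlation structure
# as T grows.  Delayed-recall memory scores are coupled to each subject's
# latent overlap-node communication distance, giving the behavioral
# correlation a known ground truth.

#' Specification of a synthetic cohort
#'
#' Default group sizes (28 HC / 19 SCD / 29 aMCI, 76 subjects) and the
#' hub-hub attenuation profile (HC 1.0, SCD 0.9, aMCI 0.7) define the
#' planted disease effect; everything downstream is free of it.  The
#' default planted hubs and connectors are 13 regions each, sharing 4
#' regions (INS.L, ACG.L, ROL.L, STG.R) so that the rich and diverse
#' clubs have a planted overlap.
#'
#' @param n_regions Number of regions (default 90, the AAL atlas).
#' @param n_communities Number of planted communities (default 5).
#' @param planted_hubs,planted_connectors Region labels (or indices) of
#'   the planted high-degree hubs and high-participation connectors.
#' @param n_per_group Named integer vector, subjects per group.
#' @param club_attenuation Named multipliers in (0, 1] applied to hub-hub
#'   weights per group.
#' @param n_timepoints Time-series length T (default 140).
#' @param noise_sd Standard deviation of the white observation noise
#'   added to the latent covariance diagonal (default 0.2).
#' @param cognition_slope Slope coupling the delayed-recall score to the
#'   subject's latent overlap-node path length (default calibrated so the
#'   population correlation is about 0.75 when group offsets are off).
#' @param subject_sd Log-normal spread of the per-subject jitter on the
#'   hub-hub attenuation around its group value (default 0.08).
#' @param hub_scale_sd Log-normal spread of the per-subject multiplier on
#'   the whole hub elevation (default 0.15): the "hub vulnerability" axis
#'   that makes overlap-node connectivity, and hence the coupled memory
#'   score, vary between subjects of one group.
#' @param var_floor Lower bound on the variance shift applied before
#'   time-series sampling (default 2.0); a fixed floor keeps the group
#'   attenuation from rescaling correlations unrelated to hubs.
#' @param lmt_group_offset Named additive group offsets on the
#'   delayed-recall score (default mirrors an impaired aMCI group).
#' @param seed Master integer seed; every subject-level draw is derived
#'   from it deterministically.
#' @param s_global,s_comm Factor variances of the global and
#'   community factors (off-diagonal baseline `s_global` between
#'   communities, `s_comm + s_global` within).
#' @param hub_boost Multiplier on planted hubs' community/global loadings.
#' @param s_hub_within,s_hub_cross Variances of the per-community hub
#'   factors (linking hubs inside one community) and of the shared
#'   cross-community hub factor; both scale with the group attenuation,
#'   so together they carry the planted disease effect on hub-hub
#'   weights.
#' @param s_conn Connector loading variance on each of its `conn_comms`
#'   community factors.
#' @param conn_comms Number of communities (sampled per connector) that a
#'   connector's edges are spread over, default 3 of 5; see the package
#'   vignette for why full evenness over all communities is not used.
#' @param w_noise Standard deviation of the symmetric structural noise
#'   added to the weights.
#' @param lmt_intercept Intercept of the delayed-recall model.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 90L,
                        n_communities = 5L,
                        planted_hubs = default_planted_hubs(),
                        planted_connectors = default_planted_connectors(),
                        n_per_group = c(HC = 28L, SCD = 19L, aMCI = 29L),
                        club_attenuation = c(HC = 1.0, SCD = 0.9, aMCI = 0.7),
                        n_timepoints = 140L,
                        noise_sd = 0.2,
                        cognition_slope = 4.3,
                        subject_sd = 0.08,
                        hub_scale_sd = 0.15,
                        lmt_group_offset = c(HC = 0, SCD = -1, aMCI = -10),
                        seed = 1L,
                        s_global = 0.03, s_comm = 0.35, w_noise = 0.01,
                        hub_boost = 1.45, s_hub_within = 0.65,
                        s_hub_cross = 0.32,
                        s_conn = 0.15, conn_comms = 3L,
                        var_floor = 2.0,
                        lmt_intercept = 1.5) {
  atlas <- if (n_regions == 90L) region_atlas() else
    region_atlas(paste0("R", seq_len(n_regions)))
  to_idx <- function(x) {
    if (is.character(x)) atlas_index(atlas, x) else as.integer(x)
  }
  hubs <- to_idx(planted_hubs)
  conns <- to_idx(planted_connectors)
  if (any(c(hubs, conns) < 1) || any(c(hubs, conns) > n_regions)) {
    stopf("planted node indices must lie in 1..%d", n_regions)
  }
  if (!all(names(n_per_group) %in% c("HC", "SCD", "aMCI")) ||
      any(n_per_group < 1)) {
    stopf("n_per_group must be positive counts named HC, SCD, aMCI")
  }
  if (any(club_attenuation <= 0) || any(club_attenuation > 1)) {
    stopf("club_attenuation multipliers must lie in (0, 1]")
  }
  if (n_timepoints < 3) stopf("n_timepoints must be at least 3")
  structure(list(
    n_regions = as.integer(n_regions), n_communities = as.integer(n_communities),
    planted_hubs = hubs, planted_connectors = conns, atlas = atlas,
    n_per_group = n_per_group, club_attenuation = club_attenuation,
    n_timepoints = as.integer(n_timepoints), noise_sd = noise_sd,
    cognition_slope = cognition_slope, subject_sd = subject_sd,
    lmt_group_offset = lmt_group_offset, seed = as.integer(seed),
    hub_scale_sd = hub_scale_sd,
    s_global = s_global, s_comm = s_comm, w_noise = w_noise,
    hub_boost = hub_boost, s_hub_within = s_hub_within,
    s_hub_cross = s_hub_cross,
    s_conn = s_conn, conn_comms = as.integer(conn_comms),
    var_floor = var_floor,
    lmt_intercept = lmt_intercept
  ), class = "cohort_spec")
}

#' Default planted hub regions
#'
#' Thirteen regions with planted high degree: bilateral postcentral,
#' insula, superior temporal, rolandic operculum, precentral and anterior
#' cingulate cortices plus the left caudate -- the canonical sensorimotor
#' and paralimbic hub set of resting-state connectomes.
#' @return Character vector of 13 AAL labels.
#' @export
default_planted_hubs <- function() {
  c("PoCG.L", "PoCG.R", "INS.L", "INS.R", "STG.L", "STG.R",
    "ROL.L", "ROL.R", "PreCG.L", "PreCG.R", "ACG.L", "ACG.R", "CAU.L")
}

#' Default planted connector regions
#'
#' Thirteen regions with planted cross-community edges (temporal poles,
#' association cortices and paralimbic regions); four of them (INS.L,
#' ACG.L, ROL.L, STG.R) are also planted hubs, giving a planted
#' rich/diverse-club overlap.
#' @return Character vector of 13 AAL labels.
#' @export
default_planted_connectors <- function() {
  c("TPOmid.L", "TPOmid.R", "TPOsup.R", "ROL.L", "ACG.L", "INS.L",
    "CAU.R", "MTG.R", "STG.R", "ORBinf.R", "IPL.L", "SMG.L", "OLF.L")
}

# community labels: contiguous blocks as equal as possible
community_blocks <- function(n_regions, n_communities) {
  sizes <- rep(n_regions %/% n_communities, n_communities)
  extra <- n_regions %% n_communities
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_communities), times = sizes)
}

#' Generate one subject's latent connectome
#'
#' Factor construction of the latent weights.  Every node loads
#' `sqrt(s_global)` on a global factor; community members load
#' `sqrt(s_comm)` on their community factor (so within-community weight
#' `s_comm + s_global` exceeds the between-community baseline `s_global`);
#' planted hubs have their community and global loadings multiplied by
#' `hub_boost` (elevated weights to all nodes) and additionally load on a
#' per-community hub factor and on a shared cross-community hub factor,
#' both with variance proportional to the group attenuation, so hub-hub
#' weights scale with the planted disease effect; planted connectors drop
#' their community membership and instead load evenly on `conn_comms`
#' randomly chosen community factors, spreading their edges across
#' communities.  `W = B B^T` with zeroed diagonal plus small symmetric
#' noise is close to PSD, so the positive-definiteness shift applied
#' before sampling stays small and the latent structure survives in the
#' correlations.
#'
#' @param spec A [cohort_spec()].
#' @param group Group label (`HC`, `SCD`, `aMCI`), selects the attenuation.
#' @param seed Integer seed for the structural noise and connector target
#'   placement.
#' @param attenuation Optional override of the group attenuation (used
#'   internally to add subject-level jitter).
#' @param hub_scale Multiplier on the hub elevation (subject-level hub
#'   vulnerability; default 1).
#' @return List of class `latent_connectome`: `weights` (symmetric
#'   nonnegative N x N, zero diagonal), `community_assignment`, `labels`,
#'   `attenuation`, `hub_scale`.
#' @export
generate_latent_connectome <- function(spec, group = "HC", seed = spec$seed,
                                       attenuation = NULL, hub_scale = 1) {
  if (is.null(attenuation)) attenuation <- spec$club_attenuation[[group]]
  n <- spec$n_regions
  set.seed(seed)
  comm <- community_blocks(n, spec$n_communities)
  hubs <- spec$planted_hubs
  conns <- spec$planted_connectors
  n_comm <- spec$n_communities

  # loading matrix: global + community factors + per-community hub
  # factors + shared cross-community hub factor
  B <- matrix(0, n, 1L + 2L * n_comm + 1L)
  B[, 1L] <- sqrt(spec$s_global)
  for (s in seq_len(n_comm)) {
    members <- setdiff(which(comm == s), conns)  # connectors drop community id
    B[members, 1L + s] <- sqrt(spec$s_comm)
  }
  for (cn in conns) {
    cs <- sample.int(n_comm, min(spec$conn_comms, n_comm))
    B[cn, 1L + cs] <- sqrt(spec$s_conn)
  }
  B[hubs, ] <- B[hubs, , drop = FALSE] * spec$hub_boost * sqrt(hub_scale)
  for (s in seq_len(n_comm)) {
    hs <- hubs[comm[hubs] == s]
    if (length(hs)) B[hs, 1L + n_comm + s] <- sqrt(spec$s_hub_within * attenuation)
  }
  B[hubs, 2L + 2L * n_comm] <- sqrt(spec$s_hub_cross * attenuation)

  W <- B %*% t(B)
  noise <- matrix(stats::rnorm(n * n, 0, spec$w_noise), n, n)
  W <- W + (noise + t(noise)) / 2
  W[W < 0] <- 0
  diag(W) <- 0
  dimnames(W) <- list(spec$atlas$labels, spec$atlas$labels)
  structure(list(weights = W, community_assignment = comm,
                 labels = spec$atlas$labels, attenuation = attenuation,
                 hub_scale = hub_scale),
            class = "latent_connectome")
}

#' Draw a time series from a latent connectome
#'
#' Samples `T` iid timepoints from a zero-mean multivariate normal whose
#' covariance is the latent weight matrix made positive definite by a
#' uniform diagonal shift `max(|lambda_min| + 0.01, var_floor)` plus
#' `noise_sd^2 I`.  The floor (default 2.0) keeps the shift -- and hence
#' the overall correlation scale -- the same for every subject, so that
#' planted group effects alter only the targeted correlations.  The
#' sample Pearson matrix converges to the latent correlation structure as
#' T grows, while short series give realistic sampling noise.
#'
#' @param latent A `latent_connectome`.
#' @param T Number of timepoints; a warning is logged below N/2.
#' @param noise_sd Observation noise standard deviation.
#' @param seed Integer seed.
#' @param subject_id Identifier attached to the series.
#' @param var_floor Minimum diagonal shift (see above).
#' @return A `clubnet_ts`.
#' @export
generate_timeseries <- function(latent, T = 140, noise_sd = 0.2, seed = 1,
                                subject_id = "synthetic", var_floor = 2.0) {
  W <- latent$weights
  n <- nrow(W)
  if (T < n / 2) {
    clubnet_log(sprintf("T = %d is below N/2 = %g; correlations will be noisy",
                        T, n / 2))
  }
  ev_min <- min(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  shift <- max(abs(min(ev_min, 0)) + 0.01, var_floor)
  sigma <- W
  diag(sigma) <- diag(sigma) + shift + noise_sd^2
  ch <- tryCatch(chol(sigma), error = function(e)
    stopf("internal error: shifted covariance not positive definite"))
  set.seed(seed)
  Z <- matrix(stats::rnorm(T * n), T, n)
  ts_matrix(Z %*% ch, latent$labels, subject_id)
}

# Subject's latent overlap-node communication distance: the inverse mean
# latent row weight of each planted overlap node (planted hubs stand in
# when the planted sets are disjoint).  A continuous path-length proxy:
# it rises smoothly as an overlap node's total connectivity weakens,
# which is exactly when its thresholded-network path length rises.
latent_path_proxy <- function(latent, spec) {
  ov <- intersect(spec$planted_hubs, spec$planted_connectors)
  if (!length(ov)) ov <- spec$planted_hubs
  W <- latent$weights
  mean(vapply(ov, function(o) 1 / mean(W[o, -o]), numeric(1)))
}

#' Generate a full synthetic cohort
#'
#' Subjects are generated group by group (HC, then SCD, then aMCI), each
#' from a seed derived deterministically from `spec$seed` and the subject
#' index.  Ages are Normal(71, 5) truncated to \\[55, 90\\], sex is
#' Bernoulli(0.5).  The delayed-recall score is
#' `intercept + cognition_slope * latent overlap path length + group
#' offset + Normal(0, 1)`; the remaining scores are group-mean normals
#' emulating a typical preclinical-AD cohort.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_cohort`: `manifest` (data.frame),
#'   `timeseries` (named list of `clubnet_ts`), `truth` (planted sets,
#'   per-subject latent proxies and attenuations), `spec`.
#' @export
generate_cohort <- function(spec) {
  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  n_sub <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n_sub))
  score_means <- list(  # HC / SCD / aMCI location parameters, cohort-typical
    mmse = c(HC = 28.8, SCD = 28.9, aMCI = 28.0),
    gds = c(HC = 0.4, SCD = 1.2, aMCI = 1.4),
    lmt_immediate = c(HC = 14.7, SCD = 14.3, aMCI = 7.7)
  )
  manifest <- data.frame(subject_id = ids, group = groups,
                         age = NA_real_, sex = NA_character_,
                         mmse = NA_real_, gds = NA_real_,
                         lmt_immediate = NA_real_, lmt_delayed = NA_real_,
                         stringsAsFactors = FALSE)
  timeseries <- vector("list", n_sub); names(timeseries) <- ids
  proxies <- numeric(n_sub); attens <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    g <- groups[s]
    sseed <- derive_seed(spec$seed, s)
    set.seed(sseed)
    age <- stats::rnorm(1, 71, 5)
    while (age < 55 || age > 90) age <- stats::rnorm(1, 71, 5)
    sex <- if (stats::runif(1) < 0.5) "F" else "M"
    jitter <- exp(stats::rnorm(1, 0, spec$subject_sd))
    hub_scale <- exp(stats::rnorm(1, 0, spec$hub_scale_sd))
    atten <- min(spec$club_attenuation[[g]] * jitter, 1.3)
    latent <- generate_latent_connectome(spec, g, seed = derive_seed(sseed, 1),
                                         attenuation = atten,
                                         hub_scale = hub_scale)
    timeseries[[s]] <- generate_timeseries(latent, spec$n_timepoints,
                                           spec$noise_sd,
                                           seed = derive_seed(sseed, 2),
                                           subject_id = ids[s],
                                           var_floor = spec$var_floor)
    proxy <- latent_path_proxy(latent, spec)
    set.seed(derive_seed(sseed, 3))
    manifest$age[s] <- round(age, 1)
    manifest$sex[s] <- sex
    manifest$mmse[s] <- round(min(30, stats::rnorm(1, score_means$mmse[[g]], 1.5)), 1)
    manifest$gds[s] <- round(max(0, stats::rnorm(1, score_means$gds[[g]], 1.0)), 1)
    manifest$lmt_immediate[s] <- round(max(0, stats::rnorm(1, score_means$lmt_immediate[[g]], 3.0)), 1)
    manifest$lmt_delayed[s] <- round(
      spec$lmt_intercept + spec$cognition_slope * proxy +
        spec$lmt_group_offset[[g]] + stats::rnorm(1, 0, 1), 2)
    proxies[s] <- proxy
    attens[s] <- atten
  }
  structure(list(
    manifest = manifest, timeseries = timeseries,
    truth = list(planted_hubs = spec$atlas$labels[spec$planted_hubs],
                 planted_connectors = spec$atlas$labels[spec$planted_connectors],
                 proxies = stats::setNames(proxies, ids),
                 attenuations = stats::setNames(attens, ids)),
    spec = spec
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$manifest), " subjects (",
      paste(sprintf("%s=%d", names(table(x$manifest$group)),
                    table(x$manifest$group)), collapse = ", "),
      "), ", x$spec$n_regions, " regions\n", sep = "")
  invisible(x)
}

#' Write a cohort directory (manifest + per-subject time series)
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  for (sid in names(cohort$timeseries)) {
    write_timeseries(cohort$timeseries[[sid]], file.path(dir, paste0(sid, ".tsv")))
  }
  jsonlite::write_json(cohort$truth[c("planted_hubs", "planted_connectors")],
                       file.path(dir, "truth.json"))
  clubnet_log(sprintf("wrote cohort of %d subjects to %s",
                      nrow(cohort$manifest), dir))
  invisible(dir)
}
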