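test_that("cohort spec validates its inputs", {
  expect_error(cohort_spec(club_attenuation = c(HC = 1, SCD = 0.9, aMCI = 1.2)),
               "\\(0, 1\\]")
  expect_error(cohort_spec(n_per_group = c(HC = 0L, SCD = 1L, aMCI = 1L)),
               "positive")
  expect_error(cohort_spec(planted_hubs = c("INS.L", "NOPE")), "NOPE")
  spec <- cohort_spec()
  expect_equal(sum(spec$n_per_group), 76)
  expect_length(intersect(spec$planted_hubs, spec$planted_connectors), 4)
})

test_that("latent connectome: structure, symmetry, determinism", {
  spec <- tiny_spec()
  l1 <- generate_latent_connectome(spec, "HC", seed = 5)
  l2 <- generate_latent_connectome(spec, "HC", seed = 5)
  expect_identical(l1$weights, l2$weights)
  W <- l1$weights
  expect_equal(W, t(W))
  expect_equal(diag(W), setNames(rep(0, 90), rownames(W)))
  expect_true(all(W >= 0))

  # within-community mean weight exceeds between-community mean weight
  comm <- l1$community_assignment
  same <- outer(comm, comm, "==") & upper.tri(W)
  cross <- !outer(comm, comm, "==") & upper.tri(W)
  expect_gt(mean(W[same]), mean(W[cross]))

  # equal attenuation + equal seed: group label is irrelevant
  spec0 <- tiny_spec(club_attenuation = c(HC = 1, SCD = 1, aMCI = 1))
  expect_identical(generate_latent_connectome(spec0, "HC", seed = 9)$weights,
                   generate_latent_connectome(spec0, "aMCI", seed = 9)$weights)
})

test_that("planted hubs have elevated row sums", {
  spec <- tiny_spec()
  W <- generate_latent_connectome(spec, "HC", seed = 42)$weights
  rs <- rowSums(W)
  expect_true(all(rs[spec$planted_hubs] > median(rs)))
})

test_that("connector weight mass is even across its loaded communities", {
  spec <- tiny_spec()
  lat <- generate_latent_connectome(spec, "HC", seed = 42)
  W <- lat$weights
  comm <- lat$community_assignment
  pure_conn <- setdiff(spec$planted_connectors, spec$planted_hubs)
  # hubs are excluded: their boosted loadings are planted unevenness
  plain <- setdiff(1:90, c(spec$planted_hubs, spec$planted_connectors))
  for (cn in pure_conn[1:5]) {
    keep <- setdiff(plain, cn)
    mass <- tapply(W[cn, keep], comm[keep], mean)
    loaded <- sort(mass, decreasing = TRUE)[1:spec$conn_comms]
    expect_lt((max(loaded) - min(loaded)) / mean(loaded), 0.10)
  }
})

test_that("attenuation lowers hub-hub weights and nothing else", {
  spec <- tiny_spec()
  W1 <- generate_latent_connectome(spec, "HC", seed = 3, attenuation = 1)$weights
  W2 <- generate_latent_connectome(spec, "HC", seed = 3, attenuation = 0.7)$weights
  h <- spec$planted_hubs
  expect_true(all(W2[h, h][upper.tri(W2[h, h])] <
                    W1[h, h][upper.tri(W1[h, h])]))
  keep <- setdiff(1:90, h)
  expect_equal(W1[keep, keep], W2[keep, keep])
})

test_that("time series sampling converges to the latent structure", {
  spec <- tiny_spec()
  # diagonal latent: mean |off-diagonal r| shrinks below 0.1 at T = 2000
  diag_lat <- structure(list(weights = matrix(0, 30, 30),
                             labels = paste0("r", 1:30)),
                        class = "latent_connectome")
  ts <- generate_timeseries(diag_lat, T = 2000, noise_sd = 0.2, seed = 8)
  C <- pearson_connectivity(ts)
  expect_lt(mean(abs(C[upper.tri(C)])), 0.1)

  # strong block latent: within-block r exceeds between-block r
  lat <- generate_latent_connectome(spec, "HC", seed = 4)
  ts2 <- generate_timeseries(lat, T = 300, noise_sd = 0.2, seed = 9)
  C2 <- pearson_connectivity(ts2)
  comm <- lat$community_assignment
  same <- outer(comm, comm, "==") & upper.tri(C2)
  cross <- !outer(comm, comm, "==") & upper.tri(C2)
  expect_gt(mean(C2[same]), mean(C2[cross]) + 0.1)

  # determinism
  expect_identical(generate_timeseries(lat, 50, 0.2, seed = 7)$values,
                   generate_timeseries(lat, 50, 0.2, seed = 7)$values)
})

test_that("generate_cohort reproduces the reference cohort structure", {
  spec <- cohort_spec(seed = 2, n_timepoints = 10L)  # tiny T: manifest only
  co <- generate_cohort(spec)
  expect_equal(nrow(co$manifest), 76)
  expect_equal(as.vector(table(factor(co$manifest$group,
                                      c("HC", "SCD", "aMCI")))),
               c(28, 19, 29))
  expect_true(all(co$manifest$age >= 55 & co$manifest$age <= 90))
  expect_true(all(co$manifest$sex %in% c("F", "M")))
  expect_length(co$timeseries, 76)

  co2 <- generate_cohort(spec)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$timeseries[[40]]$values, co2$timeseries[[40]]$values)
})

test_that("zero cognition slope decouples memory scores from the network", {
  spec <- cohort_spec(seed = 6, cognition_slope = 0, n_timepoints = 10L,
                      lmt_group_offset = c(HC = 0, SCD = 0, aMCI = 0))
  co <- generate_cohort(spec)
  r <- cor(co$manifest$lmt_delayed, co$truth$proxies)
  expect_lt(abs(r), 0.2)
})

test_that("cohort round-trips through a directory", {
  d <- withr::local_tempdir()
  co <- write_tiny_cohort(d, seed = 5)
  man <- read_manifest(file.path(d, "manifest.csv"))
  expect_equal(man$subject_id, co$manifest$subject_id)
  ts <- read_timeseries(file.path(d, paste0(man$subject_id[1], ".tsv")),
                        subject_id = man$subject_id[1])
  expect_equal(ts$values, co$timeseries[[1]]$values, tolerance = 1e-8,
               ignore_attr = TRUE)
})
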