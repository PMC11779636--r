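test_that("rmsf is zero for identical members and matches known jitter", {
  same <- conformer_ensemble(lapply(1:4, function(i) {
    toy_conformer(8, sprintf("m%d", i), seed = 50)
  }))
  expect_lt(max(per_residue_rmsf(same)), 1e-10)

  # one residue jittered with per-axis sigma = 2 over many members:
  # rmsf = 2 * sqrt(3) (superposition disabled so the closed form is exact)
  base <- toy_conformer(12, seed = 1, scale = 20)
  members <- withr::with_seed(2, lapply(1:2000, function(m) {
    cf <- base
    cf$id <- sprintf("m%04d", m)
    cf$coords[7, ] <- cf$coords[7, ] + stats::rnorm(3, 0, 2)
    cf
  }))
  rmsf <- per_residue_rmsf(conformer_ensemble(members), superpose = FALSE)
  expect_equal(unname(rmsf[7]), 2 * sqrt(3), tolerance = 0.05)
  expect_lt(max(rmsf[-7]), 1e-10)
})

test_that("rmsf is invariant to a common rigid transform of all members", {
  gen <- generate_hinge_ensemble(rigid_flexible_spec(seed = 2, n_members = 10L))
  ens <- gen$ensemble
  moved <- conformer_ensemble(lapply(ens$members, apply_rigid,
    angle = 0.9, axis = c(1, -1, 2), shift = c(12, 0, -5)
  ))
  expect_equal(per_residue_rmsf(ens), per_residue_rmsf(moved),
    tolerance = 1e-6
  )
})

test_that("invariant-core pruning removes the argmax volume residue first", {
  gen <- generate_hinge_ensemble(rigid_flexible_spec(seed = 3, n_members = 20L))
  core <- find_invariant_core(gen$ensemble, 150)

  # single-step oracle: recompute per-residue ellipsoid volumes directly
  fitted <- superpose_ensemble(gen$ensemble)
  xyz <- ensemble_xyz(fitted)
  dev <- sweep(xyz, 2, colMeans(xyz))
  vols <- vapply(1:60, function(i) {
    cols <- (3 * (i - 1) + 1):(3 * i)
    ev <- eigen(stats::cov(dev[, cols]), symmetric = TRUE)$values
    4 / 3 * pi * sqrt(prod(pmax(ev, 0)))
  }, numeric(1))
  expect_identical(core$iterations$removed_residue[1], which.max(vols))
  expect_equal(core$iterations$max_volume[1], max(vols), tolerance = 1e-8)
})

test_that("invariant core recovers the rigid domain of hinge ensembles", {
  gen <- generate_hinge_ensemble(rigid_flexible_spec(seed = 4))
  core <- find_invariant_core(gen$ensemble, 150)
  expect_gte(mean(1:30 %in% core$core_residues), 0.9)
  expect_true(all(core$core_residues <= 30))

  # pruning order is a permutation; total volume is non-increasing
  removed <- core$iterations$removed_residue
  removed <- removed[!is.na(removed)]
  expect_false(anyDuplicated(removed) > 0)
  expect_true(all(diff(core$iterations$total_volume) <= 1e-6))
})

test_that("identical conformers yield a full zero-volume core", {
  same <- conformer_ensemble(lapply(1:5, function(i) {
    toy_conformer(10, sprintf("m%d", i), seed = 77)
  }))
  core <- find_invariant_core(same, 150)
  expect_identical(core$core_residues, 1:10)
  expect_lt(core$iterations$total_volume[1], 1e-12)
  expect_true(all(is.na(core$iterations$removed_residue)))
})

test_that("automatic cutoff lands at the flat tail of the volume curve", {
  gen <- generate_hinge_ensemble(rigid_flexible_spec(seed = 6))
  core <- find_invariant_core(gen$ensemble, volume_cutoff = "auto")
  expect_gte(mean(1:30 %in% core$core_residues), 0.9)
  expect_lte(mean(core$core_residues > 30), 0.1)
})

test_that("ensemble PCA matches a brute-force eigendecomposition", {
  ens <- conformer_ensemble(lapply(1:5, function(i) {
    toy_conformer(10, sprintf("m%d", i), seed = 30 + i)
  }))
  pca <- ensemble_pca(ens, superpose = FALSE)
  xyz <- ensemble_xyz(ens)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE)
  k <- length(pca$eigenvalues)
  expect_equal(pca$eigenvalues, ev$values[seq_len(k)], tolerance = 1e-8)
  for (j in seq_len(k)) {
    expect_equal(abs(sum(pca$eigenvectors[, j] * ev$vectors[, j])), 1,
      tolerance = 1e-6
    )
  }
  # orthonormality and variance conservation
  gram <- crossprod(pca$eigenvectors)
  expect_equal(gram, diag(k), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(pca$eigenvalues), sum(diag(stats::cov(xyz))),
    tolerance = 1e-8
  )
})

test_that("rank-1 ensembles give PC1 everything and amplitudes match", {
  base <- toy_conformer(20, seed = 3, scale = 15)
  mode <- withr::with_seed(4, stats::rnorm(60))
  mode <- mode / sqrt(sum(mode^2))
  amps <- withr::with_seed(5, stats::rnorm(30, 0, 3))
  ens <- generate_mode_ensemble(base, mode, amps, jitter = 0)
  pca <- ensemble_pca(ens, superpose = FALSE)
  expect_gt(pca$variance_fractions[1], 0.99)
  expect_gt(abs(sum(pca$eigenvectors[, 1] * mode)), 0.999)

  # per-residue amplitude: norm^2 equals the eigenvalue; doubling the
  # displacement amplitudes doubles the per-residue amplitudes
  amp1 <- per_residue_pc_amplitude(pca, 1)
  expect_equal(sum(amp1^2), pca$eigenvalues[1], tolerance = 1e-9)
  ens2 <- generate_mode_ensemble(base, mode, 2 * amps, jitter = 0)
  amp2 <- per_residue_pc_amplitude(ensemble_pca(ens2, superpose = FALSE), 1)
  expect_equal(unname(amp2), unname(2 * amp1), tolerance = 1e-8)
  expect_error(per_residue_pc_amplitude(pca, 99), "out of range")

  # a mode moving only residue 7 concentrates the amplitude there
  mode7 <- rep(0, 60)
  mode7[19:21] <- c(1, 2, -1) / sqrt(6)
  ens7 <- generate_mode_ensemble(base, mode7, amps, jitter = 0)
  amp7 <- per_residue_pc_amplitude(ensemble_pca(ens7, superpose = FALSE), 1)
  expect_gt(amp7[7]^2 / sum(amp7^2), 0.99)
})

test_that("PCA reconstruction with all components reproduces every member", {
  gen <- generate_hinge_ensemble(rigid_flexible_spec(seed = 9, n_members = 8L))
  ens <- superpose_ensemble(gen$ensemble)
  pca <- ensemble_pca(ens, superpose = FALSE)
  xyz <- ensemble_xyz(ens)
  centre <- as.numeric(t(pca$mean_coords))
  recon <- sweep(pca$projections %*% t(pca$eigenvectors), 2, centre, `+`)
  expect_lt(max(abs(recon - xyz)), 1e-6)
})

test_that("PC trajectories span the observed projections linearly", {
  gen <- generate_hinge_ensemble(rigid_flexible_spec(seed = 10, n_members = 12L))
  pca <- ensemble_pca(gen$ensemble)
  tr <- interpolate_pc_trajectory(pca, 1, n_frames = 7)
  centre <- as.numeric(t(pca$mean_coords))
  proj <- unname(vapply(tr$members, function(f) {
    sum((as.numeric(t(f$coords)) - centre) * pca$eigenvectors[, 1])
  }, numeric(1)))
  expect_equal(proj[1], min(pca$projections[, 1]), tolerance = 1e-8)
  expect_equal(proj[7], max(pca$projections[, 1]), tolerance = 1e-8)
  expect_equal(diff(proj), rep(diff(proj)[1], 6), tolerance = 1e-8)

  # frames stay at the mean's projection (~0) on every other component
  proj2 <- vapply(tr$members, function(f) {
    sum((as.numeric(t(f$coords)) - centre) * pca$eigenvectors[, 2])
  }, numeric(1))
  expect_lt(max(abs(proj2)), 1e-8)
})

test_that("AMSM reports exact correlations for constructed motions", {
  base <- toy_conformer(12, seed = 8, scale = 10)
  members <- withr::with_seed(14, lapply(1:1000, function(m) {
    cf <- base
    cf$id <- sprintf("m%04d", m)
    d <- stats::rnorm(3)
    cf$coords[1, ] <- cf$coords[1, ] + d
    cf$coords[2, ] <- cf$coords[2, ] + d # identical motion to residue 1
    cf$coords[3, ] <- cf$coords[3, ] - d # exactly opposed
    cf$coords[4:12, ] <- cf$coords[4:12, ] +
      matrix(stats::rnorm(27, 0, 1), ncol = 3) # independent jitter
    cf
  }))
  am <- movement_similarity_matrix(conformer_ensemble(members),
    superpose = FALSE
  )
  expect_equal(am$values[1, 2], 1, tolerance = 1e-12)
  expect_equal(am$values[1, 3], -1, tolerance = 1e-12)
  expect_equal(unname(diag(am$values)), rep(1, 12))
  expect_equal(am$values, t(am$values))
  expect_true(all(am$values >= -1 - 1e-12 & am$values <= 1 + 1e-12))

  # independent-jitter block: off-diagonal correlations near zero
  off <- am$values[4:12, 4:12]
  expect_lt(max(abs(off[upper.tri(off)])), 0.1)
})

test_that("AMSM flags zero-fluctuation residues instead of dividing by zero", {
  base <- toy_conformer(6, seed = 2)
  members <- withr::with_seed(3, lapply(1:50, function(m) {
    cf <- base
    cf$id <- sprintf("m%d", m)
    cf$coords[2:6, ] <- cf$coords[2:6, ] + matrix(stats::rnorm(15), ncol = 3)
    cf # residue 1 never moves
  }))
  am <- movement_similarity_matrix(conformer_ensemble(members),
    superpose = FALSE
  )
  expect_identical(am$zero_fluctuation, 1L)
  expect_equal(unname(am$values[1, 2:6]), rep(0, 5))
  expect_equal(am$values[1, 1], 1)
})

test_that("AMSM of a two-domain hinge shows block structure", {
  # the arm moves as a rigid block through per-member hinge-angle spread
  spec <- hinge_ensemble_spec(
    n_residues = 60L, core_range = c(1L, 30L),
    arm_definitions = list(list(residues = c(31L, 60L), attachment = 30L)),
    class_params = data.frame(
      hinge_mean_deg = 45, hinge_sd_deg = 12, arm_jitter_sd = 0.3
    ),
    class_counts = 60L, arm_shape = "coil",
    core_radius = 30, arm_radius = 12, arm_offset = 20, seed = 16
  )
  gen <- generate_hinge_ensemble(spec)
  am <- movement_similarity_matrix(gen$ensemble,
    superpose_subset = 1:30
  )
  arm <- am$values[31:60, 31:60]
  expect_gt(mean(arm[upper.tri(arm)]), 0.9)
})

test_that("clustering in PC space recovers generated classes", {
  spec <- hinge_ensemble_spec(
    class_counts = c(8L, 8L, 8L),
    class_params = data.frame(
      hinge_mean_deg = c(90, 55, 0), hinge_sd_deg = 2, arm_jitter_sd = 1
    ),
    seed = 19
  )
  gen <- generate_hinge_ensemble(spec)
  pca <- ensemble_pca(gen$ensemble, superpose_subset = gen$truth$core_residues)
  k <- n_components_for_variance(pca, 0.7)
  labels <- cluster_pc_space(pca, n_components = k, n_clusters = 3)
  truth <- gen$truth$labels$class
  # exact recovery up to label permutation
  tab <- table(labels, truth)
  expect_equal(sum(apply(tab, 1, max)), length(truth))

  # one cluster: everything together; more clusters than members: error
  expect_length(unique(cluster_pc_space(pca, k, 1)), 1)
  expect_error(cluster_pc_space(pca, k, 999), "more clusters")
})

test_that("rmsf/B-factor correlation matches the textbook formula", {
  x <- c(1, 2, 3, 4, 10)
  expect_equal(rmsf_bfactor_correlation(x, x)$r, 1)
  expect_equal(rmsf_bfactor_correlation(x, -x)$r, -1)

  y <- c(2, 1, 4, 3, 8)
  got <- rmsf_bfactor_correlation(x, y)$r
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got, hand)

  # normalisation does not change r; NAs are masked; constants error
  with_na <- c(y[1:4], NA)
  expect_equal(rmsf_bfactor_correlation(x, with_na)$r, stats::cor(x[1:4], y[1:4]))
  expect_error(rmsf_bfactor_correlation(x, rep(1, 5)), "constant")
})
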