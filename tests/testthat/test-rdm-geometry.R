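# a noiseless dataset whose 8 conditions sit at chosen coordinates in the
# first two voxels (remaining voxels zero); identical across runs
fixed_geometry_dataset <- function(coords2d, n_runs = 2, P = 5) {
  lab <- make_design_labels(n_runs)
  key <- paste(lab$sequence, lab$phase)
  conds <- unique(key)
  stopifnot(nrow(coords2d) == length(conds))
  X <- matrix(0, nrow(lab), P)
  X[, 1:2] <- coords2d[match(key, conds), ]
  pattern_dataset(X, lab)
}

test_that("noise covariance estimation and whitening behave on known structure", {
  # i.i.d. unit-variance residuals -> covariance near identity
  set.seed(60)
  ds <- pattern_dataset(matrix(rnorm(48 * 40), 48), make_design_labels(6))
  nc <- estimate_noise_covariance(ds, shrinkage = 0)
  expect_lt(max(abs(diag(nc$covariance) - 1)), 0.8)
  expect_lt(mean(abs(nc$covariance[upper.tri(nc$covariance)])), 0.2)

  # full shrinkage -> exactly diagonal
  nc1 <- estimate_noise_covariance(ds, shrinkage = 1)
  off <- nc1$covariance; diag(off) <- 0
  expect_equal(max(abs(off)), 0)

  # whitening oracle: AR(1)-structured noise, many residual rows
  P <- 20; rho <- 0.6
  Sigma <- rho^abs(outer(1:P, 1:P, "-"))
  L <- chol(Sigma)
  set.seed(61)
  E <- matrix(rnorm(1000 * P), 1000) %*% L
  nc2 <- noise_covariance(crossprod(E) / (nrow(E) - 1))
  W <- nc2$whitener
  whitened_cov <- W %*% (crossprod(E) / (nrow(E) - 1)) %*% t(W)
  expect_lt(norm(whitened_cov - diag(P), "F"), 0.1)
})

test_that("crossnobis distances are translation invariant and match the closed form", {
  lab <- make_design_labels(3)
  P <- 6
  set.seed(62)
  delta <- 2
  key <- paste(lab$sequence, lab$phase)
  conds <- unique(key)
  # noiseless limit: all conditions share one pattern in every run, except
  # condition 2 which is shifted by delta in voxel 1
  base <- rnorm(P)
  X <- matrix(base, nrow(lab), P, byrow = TRUE)
  X[key == conds[2], 1] <- X[key == conds[2], 1] + delta
  ds <- pattern_dataset(X, lab)
  id <- noise_covariance(diag(P))
  rdm <- crossnobis_rdm(ds, id)
  expect_equal(rdm$distances[1, 2], delta^2 / P, tolerance = 1e-10)
  # translation invariance: add a common vector to every condition
  ds2 <- pattern_dataset(sweep(X, 2, rnorm(P), "+"), lab)
  rdm2 <- crossnobis_rdm(ds2, id)
  expect_equal(rdm2$distances, rdm$distances, tolerance = 1e-10)
  # symmetry, zero diagonal
  expect_equal(rdm$distances, t(rdm$distances))
  expect_equal(diag(rdm$distances), rep(0, 8))
})

test_that("crossnobis estimator is unbiased for identical condition patterns", {
  set.seed(67)
  means <- replicate(300, {
    ds <- simulate_subject_patterns(null_config(n_voxels = 25, n_runs = 4))
    rdm <- crossnobis_rdm(ds)   # leave-pair-out noise estimation
    mean(rdm$distances[upper.tri(rdm$distances)])
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-12)
  # fewer than 4 runs without an explicit covariance is refused
  ds2 <- simulate_subject_patterns(null_config(n_voxels = 10, n_runs = 2))
  expect_error(crossnobis_rdm(ds2), "insufficient data")
})

test_that("classical MDS reproduces noiseless configurations exactly", {
  set.seed(63)
  coords <- matrix(rnorm(16), 8, 2)
  ds <- fixed_geometry_dataset(coords)
  emb <- classical_mds(ds)
  D_in <- dist(coords)
  D_out <- dist(emb$coordinates)
  expect_lt(max(abs(D_in - D_out)), 1e-8)
  expect_lt(max(abs(colMeans(emb$coordinates))), 1e-7)
  expect_true(all(diff(emb$eigenvalues) <= 1e-8))

  # square configuration: two equal nonzero eigenvalues
  sq <- matrix(c(0, 0, 0, 1, 1, 1, 1, 0), 4, 2, byrow = TRUE)
  lab4 <- make_design_labels(1, phases = "preparation")
  X <- cbind(sq, matrix(0, 4, 3))
  emb_sq <- classical_mds(pattern_dataset(X, lab4))
  expect_equal(emb_sq$eigenvalues[1], emb_sq$eigenvalues[2], tolerance = 1e-10)
  expect_gt(emb_sq$eigenvalues[1], 0)
  expect_lt(emb_sq$eigenvalues[3], 1e-10)

  # all conditions identical -> all-zero coordinates
  emb0 <- classical_mds(fixed_geometry_dataset(matrix(1, 8, 2)))
  expect_lt(max(abs(emb0$coordinates)), 1e-10)
})

test_that("a large phase offset dominates the first MDS component", {
  cfg <- sim_config(n_voxels = 80, snr_prep = 0.5, snr_prod = 0.5,
                    phase_offset = 5, seed = 64)
  ds <- simulate_subject_patterns(cfg)
  emb <- classical_mds(ds, estimate_noise_covariance(ds))
  expect_gt(emb$variance_explained[1], max(emb$variance_explained[-1]))
  # PC1 separates the phases
  pc1 <- emb$coordinates[, 1]
  prep <- emb$conditions$phase == "preparation"
  expect_true(all(pc1[prep] > max(pc1[!prep])) ||
                all(pc1[prep] < min(pc1[!prep])))
})

test_that("cross-phase distances on components 2-3 follow plane geometry", {
  # prep at (., 3, 4), prod at (., 0, 0) for each sequence -> distance 5
  lab <- make_design_labels(1)
  key <- paste(lab$sequence, lab$phase)
  conds <- unique(key)
  emb <- structure(list(
    coordinates = cbind(rnorm(8), ifelse(grepl("preparation", conds), 3, 0),
                        ifelse(grepl("preparation", conds), 4, 0)),
    eigenvalues = c(3, 2, 1),
    variance_explained = c(0.5, 0.3, 0.2),
    conditions = unique(lab[, c("order", "timing", "phase", "sequence")])),
    class = "mds_embedding")
  d <- cross_phase_distance(emb)
  expect_equal(unname(d), rep(5, 4))
})

test_that("cross-phase normalization has the stated scale behavior", {
  set.seed(65)
  lab <- make_design_labels(1)
  conds <- unique(lab[, c("order", "timing", "phase", "sequence")])
  co <- cbind(rnorm(8), rnorm(8), rnorm(8))
  emb <- structure(list(coordinates = co, eigenvalues = c(3, 2, 1),
                        variance_explained = c(.5, .3, .2),
                        conditions = conds), class = "mds_embedding")
  d <- cross_phase_distance(emb)
  r <- normalize_cross_phase(d, emb)
  # doubling all coordinates leaves the ratio unchanged
  emb2 <- emb; emb2$coordinates <- 2 * co
  expect_equal(normalize_cross_phase(cross_phase_distance(emb2), emb2), r,
               tolerance = 1e-12)
  # cross-phase distances all zero -> 0
  emb3 <- emb
  prep <- conds$phase == "preparation"
  emb3$coordinates[!prep, ] <-
    emb3$coordinates[prep, ][match(conds$sequence[!prep],
                                   conds$sequence[prep]), ]
  expect_equal(normalize_cross_phase(cross_phase_distance(emb3), emb3), 0)
  # degenerate within-phase geometry is flagged
  emb4 <- emb; emb4$coordinates[, 2:3] <- 0
  expect_error(normalize_cross_phase(cross_phase_distance(emb4), emb4),
               "undefined normalization")
})

test_that("the full statistic is invariant to uniform pattern rescaling", {
  cfg <- sim_config(n_voxels = 40, snr_prep = 0.5, snr_prod = 0.5, seed = 66)
  ds <- simulate_subject_patterns(cfg)
  s1 <- cross_phase_statistic(ds, shrinkage = 0.5)
  ds2 <- pattern_dataset(3 * ds$patterns, ds$labels)
  expect_equal(cross_phase_statistic(ds2, shrinkage = 0.5), s1,
               tolerance = 1e-8)
})

test_that("switch simulations separate from the matched no-switch baseline", {
  base <- simulate_cross_phase_baseline(n_voxels = 60, n_subjects = 8,
                                        snr_prep = 0.5, snr_prod = 0.5,
                                        switch = FALSE, n_sims = 8, seed = 70)
  sw <- simulate_cross_phase_baseline(n_voxels = 60, n_subjects = 8,
                                      snr_prep = 0.5, snr_prod = 0.5,
                                      switch = TRUE, n_sims = 8, seed = 71)
  # noise-driven positive bias of the no-switch null
  expect_gt(base$mean, 0)
  # switch regime sits strictly above it
  expect_gt(sw$mean, base$mean)
  st <- test_against_baseline(sw$subject_values[1, ], base)
  expect_gt(st$t, 0)
  expect_equal(st$bonferroni_m, 7L)
})
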