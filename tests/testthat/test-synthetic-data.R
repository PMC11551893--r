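test_that("a complete design has 8 condition labels per run and n_runs x 8 rows", {
  ds <- simulate_subject_patterns(sim_config(n_voxels = 10, seed = 1))
  expect_equal(nrow(ds$patterns), 48)
  per_run <- table(ds$labels$run)
  expect_true(all(per_run == 8))
  for (r in 1:6) {
    lab <- ds$labels[ds$labels$run == r, ]
    expect_equal(nrow(unique(lab[, c("order", "timing", "phase")])), 8)
  }
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_voxels = 0), "invalid config")
  expect_error(sim_config(n_runs = 0), "invalid config")
  expect_error(sim_config(var_s = -1), "nonnegative")
  expect_error(sim_config(snr_prep = 0), "invalid config")
  expect_error(sim_config(prod_scale = -2), "invalid config")
})

test_that("noiseless no-switch production equals preparation plus the offset", {
  cfg <- sim_config(n_voxels = 25, n_runs = 3, var_e_prep = 0, var_e_prod = 0,
                    phase_offset = 5, switch = FALSE, prod_scale = 1, seed = 3)
  ds <- simulate_subject_patterns(cfg)
  lab <- ds$labels
  for (r in 1:3) for (o in 1:2) for (tm in 1:2) {
    prep <- ds$patterns[lab$run == r & lab$order == o & lab$timing == tm &
                          lab$phase == "preparation", ]
    prod <- ds$patterns[lab$run == r & lab$order == o & lab$timing == tm &
                          lab$phase == "production", ]
    expect_equal(prod, prep + 5, tolerance = 1e-12)
  }
})

test_that("with zero component variances all conditions of a run-phase share one expected pattern", {
  cfg <- null_config(n_voxels = 20, n_runs = 4, seed = 11)
  cfg$var_e_prep <- 0; cfg$var_e_prod <- 0
  ds <- simulate_subject_patterns(cfg, seed = 11)
  lab <- ds$labels
  for (r in 1:4) {
    X <- ds$patterns[lab$run == r & lab$phase == "preparation", ]
    expect_lt(max(abs(sweep(X, 2, X[1, ]))), 1e-12)
  }
})

test_that("simulate_group is seeded, reproducible, and sized", {
  cfg <- sim_config(n_voxels = 12, n_subjects = 5, seed = 99)
  g1 <- simulate_group(cfg)
  g2 <- simulate_group(cfg)
  expect_length(g1, 5)
  expect_identical(g1, g2)
  expect_false(identical(g1[[1]]$patterns, g1[[2]]$patterns))
  expect_length(simulate_group(sim_config(n_voxels = 12, n_subjects = 1,
                                          seed = 2)), 1)
})

test_that("signal components are orthogonal in expectation at large voxel counts", {
  set.seed(4)
  cfg <- sim_config(n_voxels = 10000, n_runs = 2, seed = 4)
  ds <- simulate_subject_patterns(cfg)
  # correlations between rows sharing no component should vanish
  lab <- ds$labels
  a <- ds$patterns[which(lab$run == 1 & lab$phase == "preparation")[1], ]
  b <- ds$patterns[which(lab$run == 2 & lab$phase == "preparation")[4], ]
  # rows share no s/t/i/r component only across runs and opposite cells
  expect_lt(abs(cor(a - mean(a), b - mean(b))), 0.05)
})

test_that("per-voxel variance matches the sum of component variances", {
  cfg <- sim_config(n_voxels = 4000, n_runs = 6, var_s = 1, var_t = 2,
                    var_i = 0.5, var_r = 1.5, var_e_prep = 1,
                    phase_offset = 0, seed = 8)
  ds <- simulate_subject_patterns(cfg)
  prep <- ds$patterns[ds$labels$phase == "preparation", ]
  # each row is a sum of independent zero-mean component vectors, so the
  # across-voxel variance of any row estimates the summed component variance
  v <- mean(apply(prep, 1, var))
  expect_equal(v, 1 + 2 + 0.5 + 1.5 + 1, tolerance = 0.05)
})

test_that("switch flag controls whether production re-uses preparation signal", {
  base <- list(n_voxels = 400, n_runs = 2, var_e_prep = 0, var_e_prod = 0,
               var_r = 0, phase_offset = 0, prod_scale = 1)
  no_sw <- simulate_subject_patterns(
    do.call(sim_config, c(base, switch = FALSE)), seed = 21)
  sw <- simulate_subject_patterns(
    do.call(sim_config, c(base, switch = TRUE)), seed = 21)
  cors <- function(ds) {
    lab <- ds$labels
    vapply(unique(lab$sequence), function(sq) {
      prep <- ds$patterns[lab$sequence == sq & lab$phase == "preparation" &
                            lab$run == 1, ]
      prod <- ds$patterns[lab$sequence == sq & lab$phase == "production" &
                            lab$run == 1, ]
      cor(prep, prod)
    }, numeric(1))
  }
  expect_equal(unname(cors(no_sw)), rep(1, 4), tolerance = 1e-10)
  expect_lt(max(abs(cors(sw))), 0.2)
})

test_that("the SNR estimator is calibrated against the generative model", {
  # signal variance / noise variance = 0.5 by construction
  cfg <- sim_config(n_voxels = 160, n_runs = 6, snr_prep = 0.5,
                    snr_prod = 0.5, n_subjects = 200, seed = 31)
  group <- simulate_group(cfg)
  snr <- vapply(group, estimate_snr, numeric(1), phase = "preparation")
  expect_equal(mean(snr), 0.5, tolerance = 0.05)
  snr_prod <- vapply(group, estimate_snr, numeric(1), phase = "production")
  expect_equal(mean(snr_prod), 0.5, tolerance = 0.05)
})

test_that("SNR estimation handles edge cases", {
  noiseless <- sim_config(n_voxels = 30, n_runs = 3, var_e_prep = 0,
                          var_e_prod = 0, var_r = 0, seed = 5)
  ds <- simulate_subject_patterns(noiseless)
  expect_equal(estimate_snr(ds, "preparation"), Inf)

  nul <- simulate_group(null_config(n_voxels = 60, n_subjects = 50, seed = 6))
  snr <- vapply(nul, estimate_snr, numeric(1), phase = "preparation")
  expect_lt(abs(mean(snr)), 0.05)

  one_run <- sim_config(n_voxels = 10, n_runs = 1, seed = 7)
  expect_error(estimate_snr(simulate_subject_patterns(one_run)),
               "insufficient data")
})

test_that("embed_in_volume places signal voxels and noise fill correctly", {
  cfg <- sim_config(n_voxels = 8, n_runs = 2, seed = 13)
  ds <- simulate_subject_patterns(cfg)
  mask <- box_mask(c(2, 2, 2))
  # signal everywhere: pure relabeling of columns
  vds <- embed_in_volume(ds, mask, mask, seed = 1)
  expect_equal(unname(vds$patterns), unname(ds$patterns))
  expect_equal(nrow(vds$voxel_coordinates), 8)
  # signal in a sub-box: remaining voxels are noise with matched scale
  signal <- box_mask(c(2, 2, 2), box = cbind(c(1, 1, 1), c(2, 2, 1)))
  vds2 <- embed_in_volume(ds, mask, signal, seed = 1)
  expect_equal(ncol(vds2$patterns), 8)
  in_sig <- signal$grid[vds2$voxel_coordinates]
  expect_equal(sum(in_sig), 4)
  # signal region larger than the dataset
  big <- box_mask(c(4, 4, 4))
  dsn <- simulate_subject_patterns(sim_config(n_voxels = 8, n_runs = 2,
                                              seed = 13))
  expect_error(embed_in_volume(dsn, big, big), "mismatch")
})
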