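#' Configuration of the generative pattern simulation
#'
#' The simulator draws condition-by-run voxel patterns from the additive model
#'
#'   y[i,j,k] = s_i + t_j + i_ij + r_k + e_ijk
#'
#' where s (spatial/order), t (temporal/timing), i (integrated, one per
#' order-by-timing cell) and r (run) are independent zero-mean normal vectors
#' over voxels, and e is fresh white noise per observation. Production-phase
#' signal components are either re-used from preparation (`switch = FALSE`,
#' scaled by `prod_scale`) or drawn independently (`switch = TRUE`). A uniform
#' `phase_offset` models the large overall activity increase from preparation
#' to production.
#'
#' Noise can be given directly (`var_e_prep`, `var_e_prod`) or via target
#' signal-to-noise ratios (`snr_prep`, `snr_prod`), SNR being the ratio of
#' total signal component variance (var_s + var_t + var_i, times
#' `prod_scale^2` in production) to noise variance. When both SNR targets are
#' supplied and `prod_scale` is not, `prod_scale` is set to
#' `snr_prod / snr_prep`, so the signal scale factor between phases equals the
#' SNR ratio.
#'
#' @param n_voxels voxels per pattern (default 160, a typical subcortical ROI
#'   searchlight size).
#' @param n_runs imaging runs (default 6).
#' @param var_s,var_t,var_i variances of the order, timing and integrated
#'   components (defaults 1; only ratios to noise matter downstream).
#' @param var_r run-effect variance (default 1); the run vector is shared by
#'   both phases of a run.
#' @param var_e_prep,var_e_prod white-noise variances per phase.
#' @param snr_prep,snr_prod alternative noise specification as target
#'   signal-to-noise ratios per phase; overrides `var_e_*` when given.
#' @param phase_offset constant added to every production voxel (default 5,
#'   i.e. 5 component SDs, so the first principal component of the joint
#'   geometry captures phase).
#' @param switch logical; if TRUE production draws fresh signal components.
#' @param prod_scale multiplier applied to production s/t/i components.
#' @param n_subjects group size for [simulate_group()] (default 24).
#' @param seed integer seed; `NA` leaves the RNG stream untouched.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_voxels = 160, n_runs = 6,
                       var_s = 1, var_t = 1, var_i = 1, var_r = 1,
                       var_e_prep = 1, var_e_prod = 1,
                       snr_prep = NULL, snr_prod = NULL,
                       phase_offset = 5, switch = FALSE, prod_scale = NULL,
                       n_subjects = 24, seed = NA_integer_) {
  if (n_voxels < 2 || n_runs < 1 || n_subjects < 1)
    stop("invalid config: n_voxels, n_runs and n_subjects must be positive (n_voxels >= 2)")
  vars <- c(var_s = var_s, var_t = var_t, var_i = var_i, var_r = var_r,
            var_e_prep = var_e_prep, var_e_prod = var_e_prod)
  if (any(vars < 0) || any(is.na(vars)))
    stop("invalid config: variances must be nonnegative")
  var_signal <- var_s + var_t + var_i
  if (!is.null(snr_prep)) {
    if (snr_prep <= 0) stop("invalid config: snr_prep must be positive")
    var_e_prep <- var_signal / snr_prep
  }
  if (is.null(prod_scale)) {
    prod_scale <- if (!is.null(snr_prep) && !is.null(snr_prod))
      snr_prod / snr_prep else 1
  }
  if (prod_scale <= 0) stop("invalid config: prod_scale must be positive")
  if (!is.null(snr_prod)) {
    if (snr_prod <= 0) stop("invalid config: snr_prod must be positive")
    var_e_prod <- var_signal * prod_scale^2 / snr_prod
  }
  structure(list(n_voxels = as.integer(n_voxels), n_runs = as.integer(n_runs),
                 var_s = var_s, var_t = var_t, var_i = var_i, var_r = var_r,
                 var_e_prep = var_e_prep, var_e_prod = var_e_prod,
                 phase_offset = phase_offset, switch = isTRUE(switch),
                 prod_scale = prod_scale,
                 n_subjects = as.integer(n_subjects),
                 seed = seed),
            class = "sim_config")
}

rnormvec <- function(p, var) {
  if (var == 0) numeric(p) else stats::rnorm(p, sd = sqrt(var))
}

#' Simulate one subject's condition-by-run patterns
#'
#' Draws a complete design (`n_runs` x 8 rows) from the additive generative
#' model described in [sim_config()].
#'
#' @param cfg a `sim_config`.
#' @param seed optional integer overriding `cfg$seed`.
#' @return a [pattern_dataset()] with `n_runs * 8` rows.
#' @export
simulate_subject_patterns <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  P <- cfg$n_voxels
  # preparation-phase components; integrated component indexed [order, timing]
  comp <- list(
    s = lapply(1:2, function(i) rnormvec(P, cfg$var_s)),
    t = lapply(1:2, function(j) rnormvec(P, cfg$var_t)),
    i = lapply(1:4, function(ij) rnormvec(P, cfg$var_i)))
  if (cfg$switch) {
    comp_prod <- list(
      s = lapply(1:2, function(i) rnormvec(P, cfg$var_s)),
      t = lapply(1:2, function(j) rnormvec(P, cfg$var_t)),
      i = lapply(1:4, function(ij) rnormvec(P, cfg$var_i)))
  } else {
    comp_prod <- comp
  }
  run_eff <- lapply(seq_len(cfg$n_runs), function(k) rnormvec(P, cfg$var_r))

  labels <- make_design_labels(cfg$n_runs)
  X <- matrix(0, nrow(labels), P)
  for (row in seq_len(nrow(labels))) {
    o <- labels$order[row]; tm <- labels$timing[row]
    k <- labels$run[row]; ph <- labels$phase[row]
    cell <- (o - 1L) * 2L + tm
    if (ph == "preparation") {
      sig <- comp$s[[o]] + comp$t[[tm]] + comp$i[[cell]]
      y <- sig + run_eff[[k]] + rnormvec(P, cfg$var_e_prep)
    } else {
      sig <- comp_prod$s[[o]] + comp_prod$t[[tm]] + comp_prod$i[[cell]]
      y <- cfg$prod_scale * sig + run_eff[[k]] +
        rnormvec(P, cfg$var_e_prod) + cfg$phase_offset
    }
    X[row, ] <- y
  }
  pattern_dataset(X, labels)
}

#' Simulate an independent group of subjects
#'
#' @param cfg a `sim_config`; `cfg$n_subjects` datasets are produced with
#'   per-subject seeds derived from `cfg$seed`, so the group is reproducible.
#' @param seed optional integer overriding `cfg$seed`.
#' @return a list of [pattern_dataset()] objects, one per subject.
#' @export
simulate_group <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max, cfg$n_subjects)
  lapply(subject_seeds, function(s) simulate_subject_patterns(cfg, seed = s))
}

#' Estimate the signal-to-noise ratio of one phase of a pattern dataset
#'
#' Signal is the cross-run covariance of a condition's patterns (sample
#' covariance over voxels between the patterns of the same condition in two
#' different runs), averaged over all run pairs and conditions; run effects
#' and noise are independent across runs, so only reproducible condition
#' structure contributes. Noise is the two-way (condition + run) residual
#' variance, which is unbiased for the white-noise variance in the presence
#' of additive run effects. The ratio is clipped at zero; a noiseless dataset
#' yields `Inf`.
#'
#' @param ds a `pattern_dataset`.
#' @param phase phase to assess ("preparation" or "production").
#' @return nonnegative scalar SNR (possibly `Inf`).
#' @export
estimate_snr <- function(ds, phase = "preparation") {
  lab <- ds$labels
  rows <- which(lab$phase == phase)
  if (length(rows) == 0L) stop("no rows for phase ", phase)
  lab <- lab[rows, , drop = FALSE]
  X <- ds$patterns[rows, , drop = FALSE]
  runs <- sort(unique(lab$run))
  if (length(runs) < 2L) stop("insufficient data: SNR estimation needs >= 2 runs")
  conds <- unique(lab$sequence)
  # signal: mean cross-run covariance per condition
  covs <- c()
  for (cond in conds) {
    Xi <- X[lab$sequence == cond, , drop = FALSE][order(lab$run[lab$sequence == cond]), ,
                                                  drop = FALSE]
    K <- nrow(Xi)
    if (K < 2L) stop("insufficient data: SNR estimation needs >= 2 runs")
    cm <- stats::cov(t(Xi))          # K x K covariance over voxels
    covs <- c(covs, cm[upper.tri(cm)])
  }
  signal <- mean(covs)
  # noise: two-way residual variance (condition + run effects removed)
  C <- length(conds); K <- length(runs)
  cond_f <- factor(lab$sequence, conds); run_f <- factor(lab$run, runs)
  cond_means <- rowsum(X, cond_f) / as.vector(table(cond_f))
  run_means <- rowsum(X, run_f) / as.vector(table(run_f))
  grand <- colMeans(X)
  resid <- X - cond_means[as.integer(cond_f), , drop = FALSE] -
    run_means[as.integer(run_f), , drop = FALSE] +
    matrix(grand, nrow(X), ncol(X), byrow = TRUE)
  noise <- sum(resid^2) / (ncol(X) * (C - 1) * (K - 1))
  if (noise <= .Machine$double.eps * max(1, abs(signal))) return(Inf)
  max(signal / noise, 0)
}

#' Embed a pattern dataset in a 3D volume
#'
#' Places the dataset's voxels inside a designated signal region of a volume
#' mask; all remaining in-mask voxels receive white noise matched in variance
#' to the dataset's own residual noise, so searchlights outside the signal
#' region decode at chance. Used to build volumetric fixtures for searchlight
#' analyses.
#'
#' @param ds a `pattern_dataset` whose columns carry the signal.
#' @param mask a [volume_mask()] defining the full analysis volume.
#' @param signal_region a [volume_mask()] (subset of `mask`) that receives the
#'   dataset's columns in lexicographic voxel order; must not contain more
#'   voxels than `ds` has.
#' @param seed optional integer seed for the noise fill.
#' @return a volumetric `pattern_dataset` with one column per in-mask voxel
#'   and `voxel_coordinates` attached.
#' @export
embed_in_volume <- function(ds, mask, signal_region, seed = NULL) {
  stopifnot(inherits(mask, "volume_mask"), inherits(signal_region, "volume_mask"))
  if (!identical(dim(mask$grid), dim(signal_region$grid)))
    stop("mask and signal_region must share a grid")
  if (any(signal_region$grid & !mask$grid))
    stop("signal_region must be contained in mask")
  if (!is.null(seed)) set.seed(seed)
  coords <- which(mask$grid, arr.ind = TRUE)
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  coords <- coords[ord, , drop = FALSE]
  in_signal <- signal_region$grid[coords]
  n_sig <- sum(in_signal)
  if (n_sig > n_voxels(ds))
    stop("mismatch: signal_region has more voxels (", n_sig,
         ") than the dataset (", n_voxels(ds), ")")
  n <- nrow(ds$patterns)
  X <- matrix(0, n, nrow(coords))
  if (n_sig > 0)
    X[, in_signal] <- ds$patterns[, seq_len(n_sig), drop = FALSE]
  n_noise <- sum(!in_signal)
  if (n_noise > 0) {
    sd_noise <- sqrt(mean(residual_variance_by_phase(ds)))
    X[, !in_signal] <- stats::rnorm(n * n_noise, sd = sd_noise)
  }
  pattern_dataset(X, ds$labels, voxel_coordinates = coords)
}

# pooled two-way residual variance per phase (run + condition effects removed)
residual_variance_by_phase <- function(ds) {
  vapply(unique(ds$labels$phase), function(ph) {
    rows <- ds$labels$phase == ph
    X <- ds$patterns[rows, , drop = FALSE]
    lab <- ds$labels[rows, , drop = FALSE]
    cond_f <- factor(lab$sequence); run_f <- factor(lab$run)
    C <- nlevels(cond_f); K <- nlevels(run_f)
    if (K < 2L || C < 2L) return(stats::var(as.vector(X)))
    cond_means <- rowsum(X, cond_f) / as.vector(table(cond_f))
    run_means <- rowsum(X, run_f) / as.vector(table(run_f))
    resid <- X - cond_means[as.integer(cond_f), , drop = FALSE] -
      run_means[as.integer(run_f), , drop = FALSE] +
      matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
    sum(resid^2) / (ncol(X) * (C - 1) * (K - 1))
  }, numeric(1))
}
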