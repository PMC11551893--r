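#' Construct a noise covariance object
#'
#' Wraps a symmetric positive-definite voxel covariance together with its
#' inverse principal square root (the whitening matrix). Mostly produced by
#' [estimate_noise_covariance()]; the constructor is exported so analytic
#' covariances (e.g. the identity) can be injected.
#'
#' @param covariance P x P symmetric positive semi-definite matrix.
#' @param shrinkage_intensity shrinkage used to build it (bookkeeping only).
#' @return an object of class `noise_covariance` with elements `covariance`,
#'   `whitener` and `shrinkage_intensity`.
#' @export
noise_covariance <- function(covariance, shrinkage_intensity = NA_real_) {
  S <- as.matrix(covariance)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("covariance must be a symmetric square matrix")
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  floor_val <- max(e$values) * 1e-10
  if (any(e$values < floor_val)) {
    if (min(e$values) < -1e-8 * max(abs(e$values)))
      warning("covariance has negative eigenvalues; floored")
    e$values <- pmax(e$values, max(floor_val, .Machine$double.eps))
  }
  W <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  structure(list(covariance = S, whitener = W,
                 shrinkage_intensity = shrinkage_intensity),
            class = "noise_covariance")
}

#' Estimate a regularized voxel noise covariance for prewhitening
#'
#' The noise covariance is estimated from the within-condition, across-run
#' residuals of the patterns (each condition's mean over runs subtracted) and
#' shrunk toward its own diagonal. Multiplying patterns by the returned
#' whitener (inverse principal square root) renders voxel noise approximately
#' isotropic, which stabilizes Mahalanobis-type distances.
#'
#' @param ds a `pattern_dataset` with >= 2 runs.
#' @param shrinkage "auto" (analytic intensity) or a number in [0, 1].
#' @return a [noise_covariance()].
#' @export
estimate_noise_covariance <- function(ds, shrinkage = "auto") {
  lab <- ds$labels
  if (length(unique(lab$run)) < 2L)
    stop("insufficient data: noise covariance needs >= 2 runs")
  cond <- factor(paste(lab$sequence, lab$phase))
  means <- rowsum(ds$patterns, cond) / as.vector(table(cond))
  resid <- ds$patterns - means[as.integer(cond), , drop = FALSE]
  df <- nrow(resid) - nlevels(cond)
  if (df < 1L) stop("insufficient data: no residual degrees of freedom")
  S <- crossprod(resid) / df
  zero_var <- diag(S) <= .Machine$double.eps
  if (any(zero_var)) {
    warning(sum(zero_var), " voxel(s) with zero residual variance; floored")
    diag(S)[zero_var] <- max(mean(diag(S)), .Machine$double.eps)
  }
  lambda <- if (identical(shrinkage, "auto")) analytic_shrinkage(resid)
            else as.numeric(shrinkage)
  if (is.na(lambda) || lambda < 0 || lambda > 1)
    stop("shrinkage must be 'auto' or in [0, 1]")
  noise_covariance(shrink_covariance(S, lambda), lambda)
}

#' Prewhiten a pattern dataset
#' @param ds a `pattern_dataset`.
#' @param noise a [noise_covariance()] matching the dataset's voxel count.
#' @return a `pattern_dataset` of whitened patterns.
#' @export
whiten_patterns <- function(ds, noise) {
  stopifnot(inherits(noise, "noise_covariance"))
  if (ncol(ds$patterns) != nrow(noise$whitener))
    stop("noise covariance dimension does not match voxel count")
  pattern_dataset(ds$patterns %*% noise$whitener, ds$labels,
                  ds$voxel_coordinates)
}

#' Cross-validated Mahalanobis (crossnobis) dissimilarity matrix
#'
#' For conditions a, b the distance is the average over ordered run pairs
#' (m != n) of the inner product of the whitened pattern differences,
#' `(x_a^m - x_b^m)' S^-1 (x_a^n - x_b^n) / P`. Because the two factors come
#' from independent runs the estimator is unbiased: identical condition
#' patterns give expected distance zero, and individual entries may be
#' negative.
#'
#' @param ds a `pattern_dataset` with a complete design over >= 2 runs.
#' @param noise a [noise_covariance()] (the identity yields cross-validated
#'   Euclidean distances), or `NULL` (default) to estimate the noise
#'   covariance for every run pair from the remaining runs. A covariance
#'   estimated from the same runs that enter a distance is correlated with
#'   the pattern differences and biases the estimator, so when the covariance
#'   must come from the patterns themselves the leave-pair-out route is the
#'   unbiased one (it needs >= 3 runs).
#' @param shrinkage shrinkage for the leave-pair-out covariance estimates.
#' @return an `rdm` object: `distances` (C x C symmetric, zero diagonal) and
#'   `conditions` (data.frame with order, timing, phase, sequence).
#' @export
crossnobis_rdm <- function(ds, noise = NULL, shrinkage = "auto") {
  lab <- ds$labels
  runs <- sort(unique(lab$run))
  if (length(runs) < 2L) stop("insufficient data: crossnobis needs >= 2 runs")
  if (is.null(noise) && length(runs) < 4L)
    stop("insufficient data: leave-pair-out noise estimation needs >= 4 runs; ",
         "pass an explicit noise covariance for fewer")
  key <- paste(lab$sequence, lab$phase)
  conds <- unique(data.frame(order = lab$order, timing = lab$timing,
                             phase = lab$phase, sequence = lab$sequence,
                             key = key, stringsAsFactors = FALSE))
  C <- nrow(conds); K <- length(runs); P <- ncol(ds$patterns)
  # Xk[[k]]: C x P matrix of condition patterns in run k, rows in conds order
  Xk <- lapply(runs, function(r) {
    rows <- match(conds$key, key[lab$run == r])
    ds$patterns[which(lab$run == r)[rows], , drop = FALSE]
  })
  pair_idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)  # cond pairs
  deltas <- lapply(Xk, function(X)
    X[pair_idx[, 1], , drop = FALSE] - X[pair_idx[, 2], , drop = FALSE])
  acc <- numeric(nrow(pair_idx))
  n_pairs <- 0L
  for (m in seq_len(K - 1)) for (n in (m + 1):K) {
    W <- if (!is.null(noise)) noise$whitener else {
      rest <- which(lab$run %in% runs[-c(m, n)])
      estimate_noise_covariance(subset_dataset(ds, rows = rest),
                                shrinkage = shrinkage)$whitener
    }
    acc <- acc + rowSums((deltas[[m]] %*% W) * (deltas[[n]] %*% W))
    n_pairs <- n_pairs + 1L
  }
  D <- matrix(0, C, C)
  D[upper.tri(D)] <- acc / n_pairs / P
  D <- D + t(D)
  structure(list(distances = D,
                 conditions = conds[, c("order", "timing", "phase", "sequence")]),
            class = "rdm")
}

#' Classical (Torgerson) multidimensional scaling of condition geometry
#'
#' Averages each condition's whitened patterns over runs, double-centers the
#' resulting Gram matrix and eigendecomposes it. Coordinates are eigenvectors
#' scaled by the square root of their eigenvalues, so pairwise embedding
#' distances reproduce the whitened-pattern Euclidean distances exactly for
#' full-rank configurations. Negative eigenvalues (numerical, or induced by
#' cross-validated input) are clipped to zero with a warning.
#'
#' @param ds a `pattern_dataset`.
#' @param noise a [noise_covariance()] used to prewhiten before averaging;
#'   `NULL` skips whitening.
#' @return an `mds_embedding`: `coordinates` (C x C matrix, components in
#'   columns), `eigenvalues`, `variance_explained` and `conditions`.
#' @export
classical_mds <- function(ds, noise = NULL) {
  wds <- if (is.null(noise)) ds else whiten_patterns(ds, noise)
  lab <- wds$labels
  key <- paste(lab$sequence, lab$phase)
  conds <- unique(data.frame(order = lab$order, timing = lab$timing,
                             phase = lab$phase, sequence = lab$sequence,
                             key = key, stringsAsFactors = FALSE))
  M <- rowsum(wds$patterns, factor(key, conds$key)) /
    as.vector(table(factor(key, conds$key)))
  Mc <- sweep(M, 2, colMeans(M))
  G <- tcrossprod(Mc)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- e$values
  tol <- max(abs(lam)) * 1e-10
  if (any(lam < -max(tol, 1e-8 * max(abs(lam), 1))))
    warning("negative eigenvalues clipped to zero")
  lam <- pmax(lam, 0)
  coords <- e$vectors %*% diag(sqrt(lam), nrow = length(lam))
  total <- sum(lam)
  structure(list(coordinates = coords, eigenvalues = lam,
                 variance_explained = if (total > 0) lam / total else lam,
                 conditions = conds[, c("order", "timing", "phase", "sequence")]),
            class = "mds_embedding")
}

#' Cross-phase distance per sequence on embedding components 2-3
#'
#' The first component of the joint preparation/production geometry is
#' dominated by the overall activity offset between phases, so sequence-level
#' change is measured on components 2 and 3 only: for each sequence, the
#' Euclidean distance between its preparation and production coordinates
#' restricted to those components.
#'
#' @param emb an `mds_embedding` over 4 sequences x 2 phases.
#' @param components integer vector of components to use (default 2:3).
#' @return named numeric vector of 4 per-sequence distances.
#' @export
cross_phase_distance <- function(emb, components = 2:3) {
  stopifnot(inherits(emb, "mds_embedding"))
  if (ncol(emb$coordinates) < max(components))
    stop("embedding has fewer components than requested")
  conds <- emb$conditions
  seqs <- unique(conds$sequence)
  vapply(seqs, function(sq) {
    prep <- which(conds$sequence == sq & conds$phase == "preparation")
    prod <- which(conds$sequence == sq & conds$phase == "production")
    if (length(prep) != 1L || length(prod) != 1L)
      stop("label error: sequence ", sq, " must appear once per phase")
    sqrt(sum((emb$coordinates[prep, components] -
                emb$coordinates[prod, components])^2))
  }, numeric(1))
}

#' Normalize the cross-phase distance by the within-phase geometry scale
#'
#' Divides the mean cross-phase distance by the grand mean of all
#' within-phase pairwise sequence distances (k(k-1)/2 = 6 pairs per phase,
#' pooled over both phases), computed on the same embedding components. The
#' ratio is invariant to uniform rescaling of the patterns, so it reflects a
#' change in representational structure rather than overall signal scale.
#'
#' @param distances per-sequence cross-phase distances from
#'   [cross_phase_distance()].
#' @param emb the `mds_embedding` they came from.
#' @param components components used (must match; default 2:3).
#' @return scalar normalized cross-phase distance.
#' @export
normalize_cross_phase <- function(distances, emb, components = 2:3) {
  conds <- emb$conditions
  within <- c()
  for (ph in unique(conds$phase)) {
    idx <- which(conds$phase == ph)
    co <- emb$coordinates[idx, components, drop = FALSE]
    within <- c(within, as.vector(stats::dist(co)))
  }
  denom <- mean(within)
  if (denom <= .Machine$double.eps)
    stop("undefined normalization: within-phase distances are all zero")
  mean(distances) / denom
}

#' Normalized cross-phase distance of one subject's dataset
#'
#' Runs the full geometry pipeline on a dataset: estimate the noise
#' covariance, prewhiten, classical MDS, cross-phase distances on components
#' 2-3, normalization by the within-phase scale.
#'
#' @param ds a `pattern_dataset`.
#' @param shrinkage passed to [estimate_noise_covariance()].
#' @return scalar normalized cross-phase distance.
#' @export
cross_phase_statistic <- function(ds, shrinkage = "auto") {
  noise <- estimate_noise_covariance(ds, shrinkage = shrinkage)
  emb <- classical_mds(ds, noise)
  normalize_cross_phase(cross_phase_distance(emb), emb)
}

#' Simulate the no-switch baseline (or switch reference) of the cross-phase
#' statistic
#'
#' With noisy data the cross-phase distance is positively biased even when
#' preparation and production share identical sequence representations, so
#' the empirical statistic must be tested against a simulated no-switch
#' baseline matched in voxel count, run count, sample size and per-phase
#' signal-to-noise ratio. Each simulated group is pushed through the same
#' pipeline as the data (whiten, MDS, normalize) and the distribution of the
#' statistic is summarized.
#'
#' @param n_voxels,n_runs,n_subjects matched design parameters.
#' @param snr_prep,snr_prod matched per-phase signal-to-noise ratios; the
#'   production signal is scaled by `snr_prod / snr_prep`.
#' @param switch FALSE for the no-switch baseline, TRUE for the switch
#'   reference.
#' @param n_sims number of simulated groups.
#' @param phase_offset,shrinkage passed through to the simulator / pipeline.
#' @param seed integer seed.
#' @return a `cross_phase_baseline` list: `mean`, `sd` (of subject values),
#'   `group_means`, `subject_values`, and the matched parameters.
#' @export
simulate_cross_phase_baseline <- function(n_voxels = 160, n_runs = 6,
                                          snr_prep = 0.5, snr_prod = 0.5,
                                          n_subjects = 24, switch = FALSE,
                                          n_sims = 20, phase_offset = 5,
                                          shrinkage = "auto", seed = NA_integer_) {
  cfg <- sim_config(n_voxels = n_voxels, n_runs = n_runs,
                    snr_prep = snr_prep, snr_prod = snr_prod,
                    phase_offset = phase_offset, switch = switch,
                    n_subjects = n_subjects, seed = seed)
  values <- matrix(NA_real_, n_sims, n_subjects)
  if (!is.na(seed)) set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max, n_sims)
  for (s in seq_len(n_sims)) {
    group <- simulate_group(cfg, seed = sim_seeds[s])
    values[s, ] <- vapply(group, cross_phase_statistic, numeric(1),
                          shrinkage = shrinkage)
  }
  structure(list(mean = mean(values), sd = stats::sd(as.vector(values)),
                 group_means = rowMeans(values), subject_values = values,
                 switch = switch, n_sims = n_sims,
                 params = list(n_voxels = n_voxels, n_runs = n_runs,
                               snr_prep = snr_prep, snr_prod = snr_prod,
                               n_subjects = n_subjects)),
            class = "cross_phase_baseline")
}

#' Test subject-level cross-phase statistics against a simulated baseline
#'
#' One-sided one-sample t-test of the per-subject normalized cross-phase
#' distances against the matched no-switch baseline mean (equivalently,
#' baseline-subtracted values against zero), with Cohen's d and Bonferroni
#' correction over regions.
#'
#' @param values numeric vector of per-subject statistics.
#' @param baseline_mean scalar no-switch baseline mean (or a
#'   `cross_phase_baseline` object).
#' @param bonferroni_m correction factor (default 7, one per region tested).
#' @return a `group_stat_result` (see [one_sample_t()]).
#' @export
test_against_baseline <- function(values, baseline_mean, bonferroni_m = 7) {
  if (inherits(baseline_mean, "cross_phase_baseline"))
    baseline_mean <- baseline_mean$mean
  one_sample_t(values, mu = baseline_mean, tails = "one",
               bonferroni_m = bonferroni_m)
}
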