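#' Factorized cross-decoding folds for sequence order or timing
#'
#' Builds the cross-validation folds of the factorized decoding scheme. For
#' `feature = "order"`, each fold trains a two-class order decoder on the two
#' orders under ONE timing level across all but one run, and tests on the two
#' orders under the OTHER timing level in the held-out run; generalization to
#' the untrained pairing level is what makes the decoded feature independent
#' of what it was paired with. Enumerating all held-out runs and both training
#' levels gives `2 * n_runs` folds (12 folds for 6 runs). `feature = "timing"`
#' is symmetric with the roles of order and timing exchanged.
#'
#' @param labels label data.frame (see [make_design_labels()]).
#' @param feature feature to decode: "order" or "timing".
#' @param phase phase whose patterns are used.
#' @return list of folds; each fold has `train`, `test` (row indices into
#'   `labels`), `train_classes`, `test_classes` and `n_classes = 2`.
#' @export
make_factorized_folds <- function(labels, feature = c("order", "timing"),
                                  phase = "preparation") {
  feature <- match.arg(feature)
  runs <- check_complete_design(labels, phase = phase)
  if (length(runs) < 2L) stop("factorized folds need >= 2 runs")
  other <- if (feature == "order") "timing" else "order"
  in_phase <- labels$phase == phase
  folds <- list()
  for (heldout in runs) {
    for (train_level in 1:2) {
      test_level <- 3L - train_level
      train <- which(in_phase & labels$run != heldout &
                       labels[[other]] == train_level)
      test <- which(in_phase & labels$run == heldout &
                      labels[[other]] == test_level)
      folds[[length(folds) + 1L]] <- list(
        train = train, test = test,
        train_classes = labels[[feature]][train],
        test_classes = labels[[feature]][test],
        n_classes = 2L, heldout_run = heldout)
    }
  }
  folds
}

#' Leave-one-run-out folds for the integrated (four-class) decoder
#'
#' The integrated decoder distinguishes all four sequences from the residual
#' patterns left after [remove_marginal_means()]; folds are plain
#' leave-one-run-out splits within a phase.
#'
#' @inheritParams make_factorized_folds
#' @return list of `n_runs` folds with `n_classes = 4`.
#' @export
make_integrated_folds <- function(labels, phase = "preparation") {
  runs <- check_complete_design(labels, phase = phase)
  if (length(runs) < 2L) stop("integrated folds need >= 2 runs")
  in_phase <- labels$phase == phase
  lapply(runs, function(heldout) {
    train <- which(in_phase & labels$run != heldout)
    test <- which(in_phase & labels$run == heldout)
    list(train = train, test = test,
         train_classes = labels$sequence[train],
         test_classes = labels$sequence[test],
         n_classes = 4L, heldout_run = heldout)
  })
}

#' Remove order- and timing-marginal means within each run
#'
#' For each run of the given phase, replaces the four sequence patterns by
#' their two-way interaction residual: the order-marginal and timing-marginal
#' means are subtracted and the run grand mean added back, per voxel. What
#' remains is the sequence-unique, non-additive ("integrated") component: the
#' residuals of a run sum to zero over the four cells and have zero marginal
#' means in both factors.
#'
#' @param ds a `pattern_dataset` with a complete 2 x 2 design per run.
#' @param phase phase whose rows are residualized; other rows pass through.
#' @return a `pattern_dataset` of the same shape.
#' @export
remove_marginal_means <- function(ds, phase = "preparation") {
  lab <- ds$labels
  check_complete_design(lab, phase = phase)
  X <- ds$patterns
  for (r in unique(lab$run[lab$phase == phase])) {
    idx <- which(lab$run == r & lab$phase == phase)
    Y <- X[idx, , drop = FALSE]
    o <- lab$order[idx]; tm <- lab$timing[idx]
    o_means <- rowsum(Y, o) / as.vector(table(o))
    t_means <- rowsum(Y, tm) / as.vector(table(tm))
    grand <- colMeans(Y)
    X[idx, ] <- Y - o_means[as.character(o), , drop = FALSE] -
      t_means[as.character(tm), , drop = FALSE] +
      matrix(grand, length(idx), ncol(Y), byrow = TRUE)
  }
  pattern_dataset(X, lab, ds$voxel_coordinates)
}

# Schafer-Strimmer-style analytic shrinkage intensity toward the diagonal,
# computed from centered residual rows.
analytic_shrinkage <- function(resid) {
  n <- nrow(resid)
  if (n < 2L) return(1)
  sds <- sqrt(pmax(colMeans(resid^2), .Machine$double.eps))
  Xs <- resid / rep(sds, each = n)
  R <- crossprod(Xs) / n
  R2 <- crossprod(Xs^2) / n
  var_r <- (R2 - R^2) / n
  off <- upper.tri(R)
  num <- sum(var_r[off])
  den <- sum(R[off]^2)
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

shrink_covariance <- function(S, lambda) {
  Sl <- (1 - lambda) * S
  diag(Sl) <- diag(S)
  Sl
}

#' Train a Gaussian linear discriminant classifier
#'
#' Fits per-class mean patterns and a single covariance pooled across classes,
#' regularized by shrinkage toward its own diagonal:
#' `S_lambda = (1 - lambda) * S + lambda * diag(S)`. With few training rows
#' and many voxels the raw pooled covariance is singular, so shrinkage is on
#' by default ("auto" uses an analytic intensity estimated from the training
#' residuals). Prediction assigns the class maximizing the Gaussian
#' discriminant under equal priors; ties break deterministically to the
#' lowest class index.
#'
#' @param train_patterns numeric matrix of training rows.
#' @param train_classes class label per row (any atomic type).
#' @param shrinkage "auto" for the analytic intensity, or a number in [0, 1].
#' @return an object of class `lda_classifier`.
#' @export
train_lda <- function(train_patterns, train_classes, shrinkage = "auto") {
  X <- if (is.matrix(train_patterns)) train_patterns
       else as.matrix(train_patterns)
  y <- factor(train_classes)
  if (nlevels(y) < 2L) stop("training error: need >= 2 classes")
  counts <- tabulate(y, nbins = nlevels(y))
  if (any(counts < 1L)) stop("training error: a class has no training rows")
  means <- rowsum(X, y) / counts
  resid <- X - means[as.integer(y), , drop = FALSE]
  df <- nrow(X) - nlevels(y)
  if (df < 1L) stop("training error: need more rows than classes")
  S <- crossprod(resid) / df
  lambda <- if (identical(shrinkage, "auto")) analytic_shrinkage(resid)
            else as.numeric(shrinkage)
  if (is.na(lambda) || lambda < 0 || lambda > 1)
    stop("shrinkage must be 'auto' or in [0, 1]")
  Sl <- shrink_covariance(S, lambda)
  diag(Sl) <- pmax(diag(Sl), .Machine$double.eps)
  ch <- tryCatch(chol(Sl), error = function(e)
    stop("numerical error: pooled covariance is singular; raise shrinkage",
         call. = FALSE))
  structure(list(means = means, classes = levels(y), chol = ch,
                 shrinkage = lambda), class = "lda_classifier")
}

#' Predict classes with a trained LDA classifier
#' @param object an `lda_classifier`.
#' @param newdata matrix of test rows.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.lda_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  # A = S^-1 M', via the stored Cholesky factor
  A <- backsolve(object$chol,
                 forwardsolve(t(object$chol), t(object$means)))
  scores <- X %*% A -
    matrix(0.5 * colSums(t(object$means) * A), nrow(X),
           length(object$classes), byrow = TRUE)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Convert a correct-guess count to a binomial z score
#'
#' Normalizes decoding accuracy by the binomial null: with `n_total`
#' independent guesses at chance probability `chance`,
#' `z = (n_correct - n_total * chance) / sqrt(n_total * chance * (1 - chance))`.
#'
#' @param n_correct number of correct guesses.
#' @param n_total total guesses (> 0).
#' @param chance chance probability in (0, 1).
#' @return z score (0 exactly at chance accuracy).
#' @export
accuracy_to_z <- function(n_correct, n_total, chance) {
  if (n_total <= 0) stop("undefined: n_total must be positive")
  if (chance <= 0 || chance >= 1) stop("chance must be in (0, 1)")
  if (n_correct < 0 || n_correct > n_total)
    stop("n_correct must lie in [0, n_total]")
  (n_correct - n_total * chance) / sqrt(n_total * chance * (1 - chance))
}

#' Cross-validated decoding accuracy and binomial z
#'
#' Trains and tests an LDA classifier on every fold, pools correct-guess
#' counts across folds (one accuracy and one z per dataset), and normalizes
#' by the binomial null at `chance = 1 / n_classes`.
#'
#' @param ds a `pattern_dataset`.
#' @param folds folds from [make_factorized_folds()] or
#'   [make_integrated_folds()].
#' @param shrinkage passed to [train_lda()].
#' @return a `decoding_result` list: `accuracy`, `z`, `chance`,
#'   `n_correct`, `n_total`, `per_fold_correct`.
#' @export
crossvalidated_accuracy <- function(ds, folds, shrinkage = "auto") {
  stopifnot(length(folds) > 0)
  n_classes <- folds[[1]]$n_classes
  per_fold <- integer(length(folds))
  n_total <- 0L
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    clf <- train_lda(ds$patterns[fold$train, , drop = FALSE],
                     fold$train_classes, shrinkage = shrinkage)
    pred <- predict(clf, ds$patterns[fold$test, , drop = FALSE])
    per_fold[f] <- sum(pred == as.character(fold$test_classes))
    n_total <- n_total + length(fold$test)
  }
  n_correct <- sum(per_fold)
  chance <- 1 / n_classes
  structure(list(accuracy = n_correct / n_total,
                 z = accuracy_to_z(n_correct, n_total, chance),
                 chance = chance, n_correct = n_correct, n_total = n_total,
                 per_fold_correct = per_fold),
            class = "decoding_result")
}

#' Run one of the three sequence decoders on a dataset
#'
#' Convenience wrapper tying together fold construction, marginal-mean
#' removal (for the integrated decoder) and [crossvalidated_accuracy()].
#'
#' @param ds a `pattern_dataset`.
#' @param feature "order", "timing" or "integrated".
#' @param phase phase to decode.
#' @param shrinkage passed to [train_lda()].
#' @return a `decoding_result`.
#' @export
decode_sequences <- function(ds, feature = c("order", "timing", "integrated"),
                             phase = "preparation", shrinkage = "auto") {
  feature <- match.arg(feature)
  if (feature == "integrated") {
    ds <- remove_marginal_means(ds, phase = phase)
    folds <- make_integrated_folds(ds$labels, phase = phase)
  } else {
    folds <- make_factorized_folds(ds$labels, feature = feature, phase = phase)
  }
  crossvalidated_accuracy(ds, folds, shrinkage = shrinkage)
}
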