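#' Train a one-vs-rest linear SVM (squared hinge)
#'
#' Minimizes `0.5 ||w||^2 + C * sum_i max(0, 1 - y_i (w'x_i + b))^2` per
#' class with L-BFGS (the squared hinge makes the objective smooth; the
#' intercept is unpenalized).  Multi-class prediction is by the largest
#' decision value.  `C = 1` is the protocol default.
#'
#' @param X n x d numeric training matrix.
#' @param y integer class labels `1..r`.
#' @param C soft-margin cost.
#' @return a `linear_svm` model (list of per-class `(w, b)`).
#' @export
linear_svm <- function(X, y, C = 1) {
  X <- as.matrix(X)
  r <- max(y)
  classes <- seq_len(r)
  models <- lapply(classes, function(cl) {
    s <- ifelse(y == cl, 1, -1)
    obj <- function(par) {
      w <- par[-length(par)]; b <- par[length(par)]
      m <- 1 - s * (X %*% w + b)
      0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
    }
    grad <- function(par) {
      w <- par[-length(par)]; b <- par[length(par)]
      m <- as.numeric(1 - s * (X %*% w + b))
      act <- m > 0
      gcoef <- -2 * C * s[act] * m[act]
      c(w + crossprod(X[act, , drop = FALSE], gcoef)[, 1L], sum(gcoef))
    }
    fit <- stats::optim(numeric(ncol(X) + 1L), obj, grad, method = "L-BFGS-B",
                        control = list(maxit = 200L))
    list(w = fit$par[-length(fit$par)], b = fit$par[length(fit$par)])
  })
  structure(list(models = models, r = r), class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  dec <- vapply(object$models,
                function(m) as.numeric(newdata %*% m$w + m$b),
                numeric(nrow(newdata)))
  dec <- matrix(dec, nrow = nrow(newdata))
  max.col(dec, ties.method = "first")
}

#' 1-nearest-neighbour classification
#'
#' Brute-force Euclidean 1-NN; distance ties go to the earliest training
#' sample.
#'
#' @param Xtrain,ytrain training matrix and labels.
#' @param Xtest test matrix.
#' @return predicted integer labels.
#' @export
one_nn <- function(Xtrain, ytrain, Xtest) {
  Xtrain <- as.matrix(Xtrain); Xtest <- as.matrix(Xtest)
  tr2 <- rowSums(Xtrain^2)
  D2 <- outer(rowSums(Xtest^2), tr2, "+") - 2 * Xtest %*% t(Xtrain)
  ytrain[max.col(-D2, ties.method = "first")]
}

#' Seed-deterministic stratified fold assignment
#'
#' Shuffles each class's samples with the seeded generator and deals them
#' to folds round-robin, so every fold has near-proportional class
#' composition.  If the smallest class has fewer members than `n_folds`,
#' the fold count is reduced to that size with a warning.
#'
#' @param labels integer class labels `1..r`.
#' @param n_folds requested number of folds.
#' @param seed RNG seed.
#' @return integer fold id per sample (in `1..n_folds_effective`).
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 0L) {
  min_count <- min(tabulate(labels))
  if (min_count < n_folds) {
    warning("smallest class has ", min_count, " samples; reducing folds to ",
            min_count, call. = FALSE)
    n_folds <- min_count
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated accuracy on a fixed feature subset
#'
#' Stratified k-fold mean test accuracy of a linear SVM (C = 1) or 1-NN on
#' the given columns.  The subset is a fixed input: feature selection
#' happens outside this call, so selecting on the full data and then
#' cross-validating (as the standard protocol does) carries an optimistic
#' bias that callers should keep in mind.
#'
#' @param x a [drfs_data()] object.
#' @param feature_subset integer column indices (non-empty).
#' @param classifier `"svm"` or `"1nn"`.
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param C SVM cost (default 1).
#' @return mean test accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(x, feature_subset, classifier = c("svm", "1nn"),
                        folds = 5L, seed = 0L, C = 1) {
  stopifnot(inherits(x, "drfs_data"), length(feature_subset) >= 1L)
  classifier <- match.arg(classifier)
  if (any(feature_subset < 1L) || any(feature_subset > x$d)) {
    stop("feature subset indices out of range", call. = FALSE)
  }
  X <- x$values[, feature_subset, drop = FALSE]
  y <- x$labels
  fold <- stratified_folds(y, folds, seed)
  accs <- vapply(seq_len(max(fold)), function(f) {
    tr <- fold != f; te <- !tr
    pred <- if (classifier == "svm") {
      m <- linear_svm(X[tr, , drop = FALSE], y[tr], C = C)
      predict(m, X[te, , drop = FALSE])
    } else {
      one_nn(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
    }
    mean(pred == y[te])
  }, numeric(1))
  mean(accs)
}

#' Accuracy as a function of the number of selected features
#'
#' Evaluates [cv_accuracy()] at each top-k prefix of a ranking over the
#' standard grid 10, 20, ..., 100 (clipped to d with a warning).
#'
#' @param x a [drfs_data()] object.
#' @param ranking permutation from [rank_features()].
#' @param grid feature counts to evaluate.
#' @param classifiers subset of `c("svm", "1nn")`.
#' @param folds,seed,C passed to [cv_accuracy()].
#' @return data frame with `n_features`, `classifier`, `accuracy`.
#' @export
accuracy_curve <- function(x, ranking, grid = seq(10L, 100L, by = 10L),
                           classifiers = c("svm", "1nn"), folds = 5L,
                           seed = 0L, C = 1) {
  stopifnot(inherits(x, "drfs_data"))
  if (max(grid) > x$d) {
    warning("grid clipped to d = ", x$d, call. = FALSE)
    grid <- grid[grid <= x$d]
  }
  rows <- expand.grid(n_features = grid, classifier = classifiers,
                      stringsAsFactors = FALSE)
  rows$accuracy <- mapply(function(kk, cls) {
    cv_accuracy(x, top_k(ranking, kk), cls, folds = folds, seed = seed, C = C)
  }, rows$n_features, rows$classifier)
  rows
}

#' Recovery AUROC of importance scores against a planted feature set
#'
#' The probability that a random planted feature outscores a random
#' unplanted one, with ties counted half — the Mann-Whitney statistic
#' computed from mid-ranks.
#'
#' @param scores length-d numeric scores.
#' @param ground_truth indices of planted features (neither empty nor all).
#' @return AUROC in `[0, 1]`.
#' @export
recovery_auroc <- function(scores, ground_truth) {
  d <- length(scores)
  pos <- logical(d); pos[ground_truth] <- TRUE
  n1 <- sum(pos); n0 <- d - n1
  if (n1 == 0L || n0 == 0L) {
    stop("ground truth must be a proper non-empty subset", call. = FALSE)
  }
  rk <- rank(scores, ties.method = "average")
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Protocol parameter grid for alpha and beta
#'
#' The published protocol searches both regularization weights over
#' `10^(-3..3)`; `"desk"` is a shrunken grid for quick local runs.
#'
#' @param scale `"full"` (7 points) or `"desk"` (3 points).
#' @return numeric vector of candidate values.
#' @export
drfs_param_grid <- function(scale = c("full", "desk")) {
  scale <- match.arg(scale)
  if (scale == "full") 10^seq(-3, 3) else c(0.01, 1, 100)
}

#' Grid search over (alpha, beta) by cross-validated accuracy
#'
#' Fits the model at every combination, scores each fit by [cv_accuracy()]
#' on its top-`n_features` subset, and reports the best (ties go to the
#' first combination in grid order).  Selection runs on the full dataset
#' before cross-validation, as in the published protocol; the resulting
#' optimistic bias is inherited deliberately.
#'
#' @param x a [drfs_data()] object.
#' @param alphas,betas candidate values (default desk-scale grid).
#' @param n_features subset size used for scoring.
#' @param classifier,folds,seed passed to [cv_accuracy()].
#' @param control base [drfs_control()] overridden per combination.
#' @return list with `table` (one row per combination) and `best` (the
#'   winning `drfs_fit`).
#' @export
tune_drfs <- function(x, alphas = drfs_param_grid("desk"),
                      betas = drfs_param_grid("desk"), n_features = 10L,
                      classifier = "svm", folds = 5L, seed = 0L,
                      control = drfs_control()) {
  combos <- expand.grid(alpha = alphas, beta = betas)
  fits <- vector("list", nrow(combos))
  combos$accuracy <- NA_real_
  for (i in seq_len(nrow(combos))) {
    ctrl <- control
    ctrl$alpha <- combos$alpha[i]
    ctrl$beta <- combos$beta[i]
    fits[[i]] <- drfs_fit(x, ctrl)
    combos$accuracy[i] <- cv_accuracy(
      x, top_k(fits[[i]]$ranking, n_features), classifier,
      folds = folds, seed = seed)
  }
  best <- which.max(combos$accuracy)
  list(table = combos, best = fits[[best]],
       best_alpha = combos$alpha[best], best_beta = combos$beta[best])
}
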