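#' Solver configuration
#'
#' Collects every tunable of the augmented-Lagrangian solver.  `alpha`
#' controls row sparsity of W (the l2,1 penalty), `beta` the strength of
#' the dual regularizer.  `lambda1`/`lambda2` expose the two-parameter
#' variant in which the class-specific and global terms are weighted
#' separately; both default to `beta` (single-parameter objective).
#' The penalty schedule (`mu0 = 1`, `rho = 1.1`, `mu_max = 1e8`) follows
#' the published algorithm; `k = 10` feature neighbours is the protocol
#' default.
#'
#' @param alpha sparsity weight (> 0).
#' @param beta dual-regularizer weight (>= 0).
#' @param lambda1,lambda2 optional separate weights for the local/global
#'   terms; `NULL` means inherit `beta`.
#' @param k neighbour count for graph construction.
#' @param mu0 initial ALM penalty.
#' @param rho penalty growth factor (> 1).
#' @param mu_max penalty cap.
#' @param max_iter iteration cap.
#' @param tol_obj relative change threshold on the augmented objective.
#' @param tol_primal threshold on `||W - Z||_F / max(1, ||W||_F)`.
#' @param eps_reweight smoothing inside the l2,1 reweighting diagonal.
#' @param eps_denominator guard added to the multiplicative-update
#'   denominator.
#' @param seed seed for the random initialization of W.
#' @param standardize preprocessing mode passed to [standardize()].
#' @return a `drfs_control` list.
#' @export
drfs_control <- function(alpha = 1, beta = 1, lambda1 = NULL, lambda2 = NULL,
                         k = 10L, mu0 = 1, rho = 1.1, mu_max = 1e8,
                         max_iter = 100L, tol_obj = 1e-5, tol_primal = 1e-4,
                         eps_reweight = 1e-10, eps_denominator = 1e-12,
                         seed = 0L, standardize = "zscore") {
  stopifnot(alpha > 0, beta >= 0, rho > 1, mu_max >= mu0, mu0 > 0,
            tol_obj > 0, tol_primal > 0, max_iter >= 1L, k >= 1L)
  if (!is.null(lambda1)) stopifnot(lambda1 >= 0)
  if (!is.null(lambda2)) stopifnot(lambda2 >= 0)
  structure(list(alpha = alpha, beta = beta,
                 lambda1 = lambda1, lambda2 = lambda2,
                 k = as.integer(k), mu0 = mu0, rho = rho, mu_max = mu_max,
                 max_iter = as.integer(max_iter), tol_obj = tol_obj,
                 tol_primal = tol_primal, eps_reweight = eps_reweight,
                 eps_denominator = eps_denominator, seed = as.integer(seed),
                 standardize = standardize),
            class = "drfs_control")
}

resolve_lambdas <- function(control) {
  list(lambda1 = if (is.null(control$lambda1)) control$beta else control$lambda1,
       lambda2 = if (is.null(control$lambda2)) control$beta else control$lambda2)
}

#' Initialize the solver state
#'
#' W is drawn i.i.d. uniform on (0.1, 1): strictly positive because the
#' multiplicative update preserves zeros, and non-constant because constant
#' initialization creates persistent ties.  Z starts as a copy of W, the
#' multiplier at zero, the penalty at `mu0`.
#'
#' @param d,r dimensions of W.
#' @param control a [drfs_control()].
#' @return list with `W`, `Z`, `Lambda`, `mu`, `iteration`.
#' @export
init_state <- function(d, r, control = drfs_control()) {
  W <- with_seed(control$seed, matrix(stats::runif(d * r, 0.1, 1), d, r))
  list(W = W, Z = W, Lambda = matrix(0, d, r), mu = control$mu0,
       iteration = 0L)
}

#' l2,1 reweighting diagonal
#'
#' Returns `1 / (2 * sqrt(||w^i||_2^2 + eps))` per row i — the diagonal of
#' the matrix D that turns the l2,1 penalty into the smooth surrogate
#' `alpha * Tr(W' D W)`, smoothed so zero rows stay finite.
#'
#' @param W d x r weight matrix.
#' @param eps smoothing constant.
#' @return length-d numeric vector.
#' @export
update_reweight <- function(W, eps = 1e-10) {
  0.5 / sqrt(rowSums(as.matrix(W)^2) + eps)
}

#' Multiplicative update of W
#'
#' One KKT-derived multiplicative step on the W subproblem (regression +
#' smoothed l2,1 + ALM coupling, with Z, Lambda, mu and the reweighting
#' diagonal frozen):
#' `W <- W * (A^- W + B^+) / (A^+ W + B^- + eps)` with
#' `A = X'X + mu I + alpha D` and `B = X'Y + mu Z - Lambda`, where
#' `O^+ = (|O| + O)/2`, `O^- = (|O| - O)/2`.  The update never increases
#' the subproblem objective and preserves non-negativity and zeros.
#'
#' Note the published pseudo-code prints `X'Y - mu Z + Lambda` for B; the
#' derivation from the stationarity condition gives `X'Y + mu Z - Lambda`,
#' which is what is implemented.
#'
#' @param state solver state (uses `W`, `Z`, `Lambda`, `mu`).
#' @param X n x d data matrix.
#' @param Y n x r one-hot label matrix.
#' @param control a [drfs_control()].
#' @param reweight length-d diagonal from [update_reweight()].
#' @param XtX optional cached `crossprod(X)`.
#' @param XtY optional cached `crossprod(X, Y)`.
#' @return updated d x r non-negative W.
#' @export
update_W <- function(state, X, Y, control = drfs_control(),
                     reweight = update_reweight(state$W, control$eps_reweight),
                     XtX = crossprod(X), XtY = crossprod(X, Y)) {
  mu <- state$mu
  A <- XtX
  diag(A) <- diag(A) + mu + control$alpha * reweight
  B <- XtY + mu * state$Z - state$Lambda
  Ap <- (abs(A) + A) / 2
  Am <- (abs(A) - A) / 2
  Bp <- (abs(B) + B) / 2
  Bm <- (abs(B) - B) / 2
  num <- Am %*% state$W + Bp
  den <- Ap %*% state$W + Bm + control$eps_denominator
  state$W * num / den
}

#' Closed-form update of the slack variable Z
#'
#' For each class l in order 1..r solves the stationarity system
#' \deqn{(\tfrac{\beta\lambda_1'}{r} L_{M^{(l)}} + \mu I)\, z_l =
#'   \mu w_l + \Lambda_l - \tfrac{\beta\lambda_2'}{r(r-1)}
#'   \sum_{q \ne l} M z_q}
#' (a symmetric positive-definite solve; Gauss-Seidel sweep, i.e. the most
#' recent `z_q` are used), then projects `z_l <- max(z_l, 0)`.  With
#' `beta = 0` the pre-projection solution is `w_l + Lambda_l / mu` exactly.
#'
#' @param state solver state (uses `W`, `Z`, `Lambda`, `mu`).
#' @param class_laps list of r [laplacian()] objects.
#' @param M global `feature_graph` (or d x d matrix); ignored when r = 1.
#' @param control a [drfs_control()].
#' @return list with `Z` (projected, >= 0) and `Z_pre` (pre-projection
#'   solutions, for stationarity diagnostics).
#' @export
update_Z <- function(state, class_laps, M, control = drfs_control()) {
  lam <- resolve_lambdas(control)
  mu <- state$mu
  r <- ncol(state$W)
  d <- nrow(state$W)
  S <- if (inherits(M, "feature_graph")) M$sim else M
  Z <- state$Z
  Z_pre <- matrix(NA_real_, d, r)
  c_loc <- lam$lambda1 / r
  c_glob <- if (r >= 2L) lam$lambda2 / (r * (r - 1)) else 0
  I_d <- Matrix::Diagonal(d)
  for (l in seq_len(r)) {
    A_l <- c_loc * class_laps[[l]]$lap + mu * I_d
    rhs <- mu * state$W[, l] + state$Lambda[, l]
    if (c_glob > 0) {
      rhs <- rhs - c_glob * as.numeric(S %*% (rowSums(Z) - Z[, l]))
    }
    z <- as.numeric(Matrix::solve(A_l, rhs))
    Z_pre[, l] <- z
    Z[, l] <- pmax(z, 0)
  }
  list(Z = Z, Z_pre = Z_pre)
}

#' Exact objective value
#'
#' `||XW - Y||_F^2 + alpha ||W||_{2,1} + R(W)` with the true (unsmoothed)
#' l2,1 norm and the dual regularizer at the configured
#' `lambda1`/`lambda2` weights (both `beta` by default).
#'
#' @param W d x r weight matrix.
#' @param X n x d data matrix.
#' @param Y n x r label matrix.
#' @param control a [drfs_control()].
#' @param class_laps list of r [laplacian()] objects.
#' @param M global `feature_graph` or matrix.
#' @return a scalar.
#' @export
objective_value <- function(W, X, Y, control, class_laps, M) {
  lam <- resolve_lambdas(control)
  res <- X %*% W - Y
  sum(res^2) + control$alpha * sum(sqrt(rowSums(as.matrix(W)^2))) +
    dual_regularizer(W, class_laps, M, lam$lambda1, lam$lambda2)
}

#' Augmented-Lagrangian objective value
#'
#' The quantity the inner loop actually decreases: regression + l2,1 on W,
#' penalty `mu ||W - Z + Lambda/mu||_F^2`, and the dual regularizer
#' evaluated on Z.
#'
#' @inheritParams objective_value
#' @param state solver state.
#' @return a scalar.
#' @export
augmented_objective <- function(state, X, Y, control, class_laps, M) {
  lam <- resolve_lambdas(control)
  res <- X %*% state$W - Y
  pen <- state$W - state$Z + state$Lambda / state$mu
  sum(res^2) + control$alpha * sum(sqrt(rowSums(state$W^2))) +
    state$mu * sum(pen^2) +
    dual_regularizer(state$Z, class_laps, M, lam$lambda1, lam$lambda2)
}

#' KKT complementarity residual of the W subproblem
#'
#' `max_ij |(A W - B)_ij * W_ij|` with A and B as in [update_W()]; zero at
#' a fixed point of the multiplicative update.
#'
#' @inheritParams update_W
#' @return a non-negative scalar.
#' @export
kkt_residual <- function(state, X, Y, control = drfs_control(),
                         reweight = update_reweight(state$W, control$eps_reweight),
                         XtX = crossprod(X), XtY = crossprod(X, Y)) {
  A <- XtX
  diag(A) <- diag(A) + state$mu + control$alpha * reweight
  B <- XtY + state$mu * state$Z - state$Lambda
  max(abs((A %*% state$W - B) * state$W))
}

#' Fit the dual-regularized feature-selection model
#'
#' Full pipeline: standardize, build the one-hot label matrix and the
#' class-specific and global feature graphs, then run the ALM loop
#' (reweight, multiplicative W update, per-class Z solves + projection,
#' multiplier step `Lambda <- Lambda + mu (W - Z)`, penalty growth
#' `mu <- min(rho mu, mu_max)`) until both the relative change of the
#' augmented objective drops below `tol_obj` and the primal residual
#' `||W - Z||_F / max(1, ||W||_F)` drops below `tol_primal`, or `max_iter`
#' is reached.
#'
#' @param x a [drfs_data()] object.
#' @param control a [drfs_control()].
#' @return a `drfs_fit` object: `W`, `Z`, `Lambda`, `mu`, `scores`
#'   (per-feature importance, row sums of W), `ranking` (1-based feature
#'   indices by descending score), `trace` (per-iteration data frame),
#'   `converged`, `iterations`, `control`, `feature_names`.
#' @examples
#' ref <- reference_instance()
#' fit <- drfs_fit(ref$data, drfs_control(alpha = 1, beta = 1, max_iter = 30))
#' head(fit$ranking, 10)
#' @export
drfs_fit <- function(x, control = drfs_control()) {
  stopifnot(inherits(x, "drfs_data"))
  xs <- standardize(x, control$standardize)
  X <- xs$values
  Y <- one_hot(xs$labels, xs$r)
  class_graphs <- build_class_graphs(xs, control$k)
  class_laps <- lapply(class_graphs, laplacian)
  M <- build_global_graph(xs, control$k)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)

  state <- init_state(xs$d, xs$r, control)
  trace <- vector("list", control$max_iter)
  prev_aug <- Inf
  converged <- FALSE

  for (it in seq_len(control$max_iter)) {
    rw <- update_reweight(state$W, control$eps_reweight)
    state$W <- update_W(state, X, Y, control, rw, XtX, XtY)
    zu <- update_Z(state, class_laps, M, control)
    state$Z <- zu$Z

    aug <- augmented_objective(state, X, Y, control, class_laps, M)
    obj <- objective_value(state$W, X, Y, control, class_laps, M)
    if (!is.finite(aug) || !is.finite(obj)) {
      stop("non-finite objective at iteration ", it,
           " (alpha=", control$alpha, ", beta=", control$beta, ")",
           call. = FALSE)
    }
    primal <- norm(state$W - state$Z, "F") / max(1, norm(state$W, "F"))
    kkt <- kkt_residual(state, X, Y, control, rw, XtX, XtY)
    trace[[it]] <- data.frame(
      iteration = it, objective = obj, augmented = aug,
      primal_residual = primal,
      omega_local = omega_local(state$Z, class_laps),
      omega_global = omega_global(state$Z, M),
      mu = state$mu, kkt_residual = kkt)

    state$Lambda <- state$Lambda + state$mu * (state$W - state$Z)
    state$mu <- min(control$rho * state$mu, control$mu_max)
    state$iteration <- it

    rel <- if (is.finite(prev_aug)) {
      abs(prev_aug - aug) / max(1, abs(prev_aug))
    } else Inf
    if (rel < control$tol_obj && primal < control$tol_primal) {
      converged <- TRUE
      break
    }
    prev_aug <- aug
  }

  scores <- feature_scores(state$W)
  structure(
    list(W = state$W, Z = state$Z, Lambda = state$Lambda, mu = state$mu,
         scores = scores, ranking = rank_features(scores),
         trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]),
         converged = converged, iterations = state$iteration,
         control = control, feature_names = x$feature_names,
         standardize_mode = control$standardize),
    class = "drfs_fit")
}

#' @export
print.drfs_fit <- function(x, ...) {
  cat(sprintf("drfs_fit: d=%d, r=%d, %d iterations (%s)\n",
              nrow(x$W), ncol(x$W), x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  tail_tr <- x$trace[nrow(x$trace), ]
  cat(sprintf("objective %.6g, primal residual %.3g\n",
              tail_tr$objective, tail_tr$primal_residual))
  cat("top features:", paste(utils::head(x$feature_names[x$ranking], 5),
                             collapse = " "), "\n")
  invisible(x)
}
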