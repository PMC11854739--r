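#' Class-specific manifold regularizer
#'
#' \eqn{\Omega_{local}(W) = \sum_l w_l^\top L_{M^{(l)}} w_l}: the sum over
#' classes of the Laplacian quadratic form of that class's feature graph on
#' that class's weight column.  Non-negative because each Laplacian is PSD;
#' small when features that are similar within a class receive similar
#' weights in that class's column.
#'
#' @param W d x r weight matrix.
#' @param class_laps list of r [laplacian()] objects (each d x d).
#' @return a non-negative scalar.
#' @export
omega_local <- function(W, class_laps) {
  W <- as.matrix(W)
  r <- ncol(W)
  if (length(class_laps) != r) stop("need one Laplacian per class", call. = FALSE)
  total <- 0
  for (l in seq_len(r)) {
    L <- class_laps[[l]]$lap
    if (nrow(L) != nrow(W)) stop("Laplacian/W shape mismatch", call. = FALSE)
    wl <- W[, l]
    total <- total + sum(wl * as.numeric(L %*% wl))
  }
  total
}

#' Global redundancy regularizer
#'
#' \eqn{\Omega_{global}(W) = \sum_p \sum_{q \ne p} w_p^\top M w_q}: the sum
#' over ordered pairs of distinct class columns of the global-similarity
#' bilinear form.  With `W >= 0` this penalizes assigning weight, in any
#' two class columns, to features the global graph deems similar.  For a
#' single class the sum is empty and the value is 0.
#'
#' @param W d x r weight matrix.
#' @param M a `feature_graph` or a d x d similarity matrix.
#' @return a scalar (non-negative when `W >= 0` and `M >= 0`).
#' @export
omega_global <- function(W, M) {
  W <- as.matrix(W)
  S <- if (inherits(M, "feature_graph")) M$sim else M
  if (nrow(S) != nrow(W)) stop("M/W shape mismatch", call. = FALSE)
  r <- ncol(W)
  if (r < 2L) return(0)
  G <- as.matrix(Matrix::crossprod(W, S %*% W))   # G[p, q] = w_p' M w_q
  sum(G) - sum(diag(G))
}

#' Expanded form of the global redundancy regularizer
#'
#' The explicit sum
#' \deqn{\sum_{ij} |w_i| |w_j| M_{ij} - \sum_{ij} \sum_p W_{ip} W_{jp} M_{ij}}
#' with \eqn{|w_i| = \sum_p W_{ip}} the importance of feature i.  Evaluated
#' as literal loops over feature pairs; algebraically identical to
#' [omega_global()] and kept as its independent oracle.  The first term
#' drives down the smaller of two importance scores on globally similar
#' features; the second rewards dissimilar features for contributing to
#' different classes.
#'
#' @inheritParams omega_global
#' @return a scalar.
#' @export
omega_global_expansion <- function(W, M) {
  W <- as.matrix(W)
  S <- as.matrix(if (inherits(M, "feature_graph")) M$sim else M)
  d <- nrow(W); r <- ncol(W)
  a <- rowSums(W)                      # |w_i|
  total <- 0
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      cross <- 0
      for (p in seq_len(r)) cross <- cross + W[i, p] * W[j, p]
      total <- total + a[i] * a[j] * S[i, j] - cross * S[i, j]
    }
  }
  total
}

#' Combined dual regularizer
#'
#' \eqn{R(W) = \frac{\lambda_1}{r}\Omega_{local}(W) +
#' \frac{\lambda_2}{r(r-1)}\Omega_{global}(W)}.  With
#' `lambda1 == lambda2 == beta` this is beta times the normalized dual
#' term of the main objective; unequal values expose the two-parameter
#' sensitivity variant.  For r = 1 the global term is identically zero and
#' its divisor is never formed.
#'
#' @param W d x r weight matrix.
#' @param class_laps list of r [laplacian()] objects.
#' @param M global `feature_graph` or matrix.
#' @param lambda1,lambda2 non-negative weights of the local and global terms.
#' @return a scalar.
#' @export
dual_regularizer <- function(W, class_laps, M, lambda1, lambda2) {
  if (lambda1 < 0 || lambda2 < 0) stop("lambda must be >= 0", call. = FALSE)
  r <- ncol(as.matrix(W))
  val <- (lambda1 / r) * omega_local(W, class_laps)
  if (r >= 2L && lambda2 > 0) {
    val <- val + (lambda2 / (r * (r - 1))) * omega_global(W, M)
  }
  val
}
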