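#' Squared pairwise distances between feature columns
#' @param F numeric matrix, samples x features.
#' @return d x d matrix of squared Euclidean distances between columns.
#' @keywords internal
#' @noRd
feature_dist2 <- function(F) {
  D2 <- as.matrix(stats::dist(t(F)))^2
  dimnames(D2) <- NULL
  D2
}

#' RBF bandwidth from mean pairwise squared feature distance
#'
#' Returns the mean over unordered feature pairs i < j of
#' \eqn{\|x^i - x^j\|_2^2}.  Zero self-distances are excluded from the
#' average, otherwise the bandwidth is systematically deflated.
#'
#' @param F numeric matrix, samples x features (at least 2 features).
#' @return a positive scalar.
#' @export
compute_sigma2 <- function(F) {
  F <- as.matrix(F)
  if (ncol(F) < 2L) stop("need at least 2 features", call. = FALSE)
  d2 <- stats::dist(t(F))^2
  s2 <- mean(d2)
  if (!is.finite(s2) || s2 <= 0) {
    stop("all features identical: sigma^2 = 0; drop duplicate features or ",
         "supply sigma2 manually", call. = FALSE)
  }
  s2
}

#' k-nearest-neighbour RBF feature-similarity graph
#'
#' Nodes are features; `M[i, j] = exp(-||x^i - x^j||^2 / sigma2)` iff
#' `i != j` and feature i is among the k nearest neighbours of feature j
#' *or* vice versa (union symmetrization), else 0.  Neighbour sets exclude
#' the feature itself; k is capped at d - 1, in which case the off-diagonal
#' graph is complete ("dense mode").  Distance ties are broken by ascending
#' feature index.
#'
#' @param F numeric matrix, samples x features.
#' @param k neighbour count (>= 1).
#' @param sigma2 positive RBF bandwidth; defaults to [compute_sigma2()].
#' @param scope label recorded on the graph (`"global"` or `"class l"`).
#' @return a `feature_graph`: list with `sim` (d x d symmetric matrix,
#'   sparse [Matrix::sparseMatrix()] when k < d - 1), `sigma2`, `k`
#'   (effective, after cap) and `scope`.
#' @export
knn_feature_graph <- function(F, k, sigma2 = compute_sigma2(F),
                              scope = "global") {
  F <- as.matrix(F)
  d <- ncol(F)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("sigma2 must be positive", call. = FALSE)
  }
  k <- min(as.integer(k), d - 1L)
  D2 <- feature_dist2(F)
  # neighbour indicator: N[i, j] = TRUE iff i is one of j's k nearest
  N <- matrix(FALSE, d, d)
  for (j in seq_len(d)) {
    dj <- D2[, j]
    dj[j] <- Inf                       # self excluded from neighbour set
    ord <- order(dj, seq_len(d))       # stable tie-break by feature index
    N[ord[seq_len(k)], j] <- TRUE
  }
  A <- N | t(N)                        # union rule gives symmetry directly
  S <- exp(-D2 / sigma2)
  S[!A] <- 0
  diag(S) <- 0
  sim <- if (k < d - 1L) Matrix::Matrix(S, sparse = TRUE) else S
  structure(list(sim = sim, sigma2 = sigma2, k = k, scope = scope),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("feature_graph (%s): d=%d, k=%d, sigma2=%.4g, %d edges\n",
              x$scope, nrow(x$sim), x$k, x$sigma2,
              sum(as.matrix(x$sim) > 0) / 2))
  invisible(x)
}

#' Class-specific feature graphs
#'
#' Builds one k-NN RBF feature graph per class from the class's own sample
#' rows, each with its own bandwidth \eqn{\sigma_l^2} (mean pairwise squared
#' feature distance within the class).
#'
#' @param x a [drfs_data()] object.
#' @param k neighbour count.
#' @param sigma2 optional shared bandwidth overriding the per-class ones
#'   (used by the product-identity check).
#' @return list of r `feature_graph` objects.
#' @export
build_class_graphs <- function(x, k, sigma2 = NULL) {
  stopifnot(inherits(x, "drfs_data"))
  parts <- split_by_class(x)
  lapply(seq_len(x$r), function(l) {
    s2 <- if (is.null(sigma2)) {
      tryCatch(compute_sigma2(parts[[l]]),
               error = function(e) stop("class ", l, ": ", conditionMessage(e),
                                        call. = FALSE))
    } else sigma2
    knn_feature_graph(parts[[l]], k, s2, scope = paste0("class ", l))
  })
}

#' Global feature graph
#'
#' The k-NN RBF feature graph built from all samples, with bandwidth from
#' [compute_sigma2()] unless supplied.
#'
#' @param x a [drfs_data()] object.
#' @param k neighbour count.
#' @param sigma2 optional bandwidth override.
#' @return a `feature_graph`.
#' @export
build_global_graph <- function(x, k, sigma2 = NULL) {
  stopifnot(inherits(x, "drfs_data"))
  if (is.null(sigma2)) sigma2 <- compute_sigma2(x$values)
  knn_feature_graph(x$values, k, sigma2, scope = "global")
}

#' Graph Laplacian of a feature graph
#'
#' `L = Deg - M` with `Deg[i, i] = sum_j M[i, j]`.  L is symmetric positive
#' semidefinite with zero row sums, and for any weight vector w,
#' \eqn{w^\top L w = \tfrac12 \sum_{ij} M_{ij} (w_i - w_j)^2}.
#'
#' @param g a `feature_graph`.
#' @return a `graph_laplacian`: list with `lap` (d x d, sparse when the
#'   graph is sparse) and `degrees`.
#' @export
laplacian <- function(g) {
  stopifnot(inherits(g, "feature_graph"))
  deg <- Matrix::rowSums(g$sim)
  L <- Matrix::Diagonal(x = deg) - g$sim
  if (is.matrix(g$sim)) L <- as.matrix(L)
  structure(list(lap = L, degrees = as.numeric(deg)),
            class = "graph_laplacian")
}

#' Check the dense-mode product identity between global and class graphs
#'
#' With a single bandwidth shared by all classes and the global graph, and
#' with complete (k = d - 1) graphs, the global similarity factorizes over
#' classes: \eqn{M_{ij} = \prod_l M^{(l)}_{ij}}, because the squared
#' Euclidean distance over all samples decomposes as the sum of per-class
#' squared distances.  With k-NN truncation or per-class bandwidths the
#' identity fails, which is why this check forces dense mode.
#'
#' @param x a [drfs_data()] object.
#' @param shared_sigma2 the common bandwidth; defaults to the global one.
#' @return max absolute off-diagonal deviation `|M - prod_l M^(l)|`.
#' @export
verify_product_identity <- function(x, shared_sigma2 = NULL) {
  stopifnot(inherits(x, "drfs_data"))
  if (is.null(shared_sigma2)) shared_sigma2 <- compute_sigma2(x$values)
  kd <- x$d - 1L
  gl <- build_global_graph(x, kd, sigma2 = shared_sigma2)
  cls <- build_class_graphs(x, kd, sigma2 = shared_sigma2)
  P <- Reduce(`*`, lapply(cls, function(g) as.matrix(g$sim)))
  Dev <- abs(as.matrix(gl$sim) - P)
  diag(Dev) <- 0
  max(Dev)
}

#' Dump a feature graph to Matrix Market format
#'
#' Writes the similarity matrix as `<path>.mtx` and the scalar metadata
#' (sigma2, k, scope) as `<path>.meta.txt`.
#'
#' @param g a `feature_graph`.
#' @param path output path stem (without extension).
#' @return `path`, invisibly.
#' @export
write_feature_graph <- function(g, path) {
  stopifnot(inherits(g, "feature_graph"))
  Matrix::writeMM(methods::as(Matrix::Matrix(g$sim, sparse = TRUE),
                              "generalMatrix"),
                  paste0(path, ".mtx"))
  writeLines(c(paste("sigma2", format(g$sigma2, digits = 17)),
               paste("k", g$k), paste("scope", g$scope)),
             paste0(path, ".meta.txt"))
  invisible(path)
}
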