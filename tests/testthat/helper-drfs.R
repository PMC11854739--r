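# shared fixtures and independent oracles (kept deliberately naive)

local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  withr::defer({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  }, envir = env)
  set.seed(seed)
}

# random symmetric non-negative similarity with zero diagonal
random_sim <- function(d) {
  S <- matrix(stats::runif(d * d), d, d)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  S
}

random_labels <- function(n, r) {
  # every class occurs at least once
  y <- c(seq_len(r), sample.int(r, n - r, replace = TRUE))
  sample(y)
}

# brute-force k-NN RBF graph: full distance rows, sort with index tie-break,
# union symmetrization -- independent of the package's construction path
oracle_knn_graph <- function(F, k, sigma2) {
  d <- ncol(F)
  k <- min(k, d - 1L)
  D2 <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    D2[i, j] <- sum((F[, i] - F[, j])^2)
  }
  M <- matrix(0, d, d)
  for (j in seq_len(d)) {
    others <- setdiff(seq_len(d), j)
    nb <- others[order(D2[others, j], others)][seq_len(k)]
    for (i in nb) {
      M[i, j] <- exp(-D2[i, j] / sigma2)
      M[j, i] <- exp(-D2[i, j] / sigma2)
    }
  }
  M
}

# half-weighted sum of squared differences (Laplacian quadratic form oracle)
oracle_quadform <- function(M, w) {
  total <- 0
  d <- nrow(M)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    total <- total + M[i, j] * (w[i] - w[j])^2
  }
  total / 2
}

# pairwise-comparison AUROC with half-credit for ties
oracle_auroc <- function(scores, truth) {
  pos <- which(seq_along(scores) %in% truth)
  neg <- setdiff(seq_along(scores), pos)
  wins <- 0
  for (i in pos) for (j in neg) {
    wins <- wins + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  wins / (length(pos) * length(neg))
}

# W-subproblem objective with the reweight diagonal frozen
frozen_subproblem <- function(W, X, Y, Z, Lambda, mu, alpha, dvec) {
  sum((X %*% W - Y)^2) + mu * sum((W - Z + Lambda / mu)^2) +
    alpha * sum(dvec * rowSums(W^2))
}

random_state <- function(d, r, mu = 1) {
  list(W = matrix(stats::runif(d * r, 0.05, 1), d, r),
       Z = matrix(stats::runif(d * r, 0.05, 1), d, r),
       Lambda = matrix(stats::rnorm(d * r, sd = 0.3), d, r),
       mu = mu, iteration = 0L)
}

# small dataset with a class-specific correlated pair (features 1, 2)
small_planted <- function(seed) {
  generate_synthetic(synthetic_spec(
    r = 2L, n_per_class = 40L, d_informative = 4L, block_size = 2L,
    within_block_corr = 0.85, n_redundant = 0L, d_noise = 8L,
    class_shift = 1.5, seed = seed))
}

# strong-signal instance for initialization-robustness checks
easy_instance <- function(seed = 0L) {
  generate_synthetic(synthetic_spec(
    r = 2L, n_per_class = 50L, d_informative = 10L, block_size = 5L,
    within_block_corr = 0.6, n_redundant = 0L, d_noise = 20L,
    class_shift = 3, seed = seed))
}
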