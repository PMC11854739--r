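test_that("init_state is seed-deterministic with support in (0.1, 1)", {
  ctrl <- drfs_control(seed = 7)
  s1 <- init_state(20, 3, ctrl)
  s2 <- init_state(20, 3, ctrl)
  expect_identical(s1, s2)
  expect_true(all(s1$W > 0.1 & s1$W < 1))
  expect_identical(s1$Z, s1$W)
  expect_equal(s1$Lambda, matrix(0, 20, 3))
  expect_equal(s1$mu, 1)
  s3 <- init_state(20, 3, drfs_control(seed = 8))
  expect_false(identical(s1$W, s3$W))
})

test_that("update_reweight matches hand values and the l2,1 surrogate", {
  W <- rbind(c(3, 4), c(0, 0))
  dv <- update_reweight(W, eps = 1e-18)
  expect_equal(dv[1], 0.1, tolerance = 1e-9)        # 1 / (2 * 5)
  expect_true(is.finite(dv[2]))
  expect_equal(dv[2], 0.5 / sqrt(1e-18))
  # 2 * Tr(W' D W) recovers the l2,1 norm as eps -> 0
  local_seed(20)
  W <- matrix(runif(24, 0.2, 2), 8, 3)
  dv <- update_reweight(W, eps = 1e-14)
  expect_equal(2 * sum(dv * rowSums(W^2)), sum(sqrt(rowSums(W^2))),
               tolerance = 1e-8)
})

test_that("update_W fixes stationary points and preserves zeros", {
  local_seed(21)
  n <- 12; d <- 6; r <- 2
  X <- matrix(rnorm(n * d), n, d)
  ctrl <- drfs_control()
  st <- random_state(d, r, mu = 2)
  st$W[3, 1] <- 0
  rw <- update_reweight(st$W, ctrl$eps_reweight)
  # engineer B = A W so the multiplicative factor is exactly 1
  A <- crossprod(X); diag(A) <- diag(A) + st$mu + ctrl$alpha * rw
  Y <- matrix(0, n, r)
  st$Lambda <- crossprod(X, Y) + st$mu * st$Z - A %*% st$W
  W2 <- update_W(st, X, Y, ctrl, rw)
  expect_equal(W2, st$W, tolerance = 1e-9)
  # zeros stay zero under any data
  st2 <- random_state(d, r)
  st2$W[cbind(c(1, 4), c(2, 1))] <- 0
  Y2 <- one_hot(random_labels(n, r), r)
  W3 <- update_W(st2, X, Y2, ctrl)
  expect_equal(W3[cbind(c(1, 4), c(2, 1))], c(0, 0))
  expect_true(all(W3 >= 0))
})

test_that("one multiplicative step never increases the frozen subproblem", {
  local_seed(22)
  for (i in 1:5) {
    n <- 25; d <- 12; r <- 3
    X <- matrix(rnorm(n * d), n, d)
    Y <- one_hot(random_labels(n, r), r)
    ctrl <- drfs_control(alpha = runif(1, 0.1, 5))
    st <- random_state(d, r, mu = runif(1, 0.5, 5))
    rw <- update_reweight(st$W, ctrl$eps_reweight)
    before <- frozen_subproblem(st$W, X, Y, st$Z, st$Lambda, st$mu,
                                ctrl$alpha, rw)
    W2 <- update_W(st, X, Y, ctrl, rw)
    after <- frozen_subproblem(W2, X, Y, st$Z, st$Lambda, st$mu,
                               ctrl$alpha, rw)
    expect_lte(after, before + 1e-8)
  }
})

test_that("update_Z collapses to W + Lambda/mu at beta=0 and stays feasible", {
  local_seed(23)
  d <- 10; r <- 3
  Ms <- replicate(r, random_sim(d), simplify = FALSE)
  laps <- lapply(Ms, function(M) laplacian(structure(
    list(sim = M, sigma2 = 1, k = d - 1L, scope = "t"),
    class = "feature_graph")))
  M <- random_sim(d)
  st <- random_state(d, r, mu = 3)
  z0 <- update_Z(st, laps, M, drfs_control(beta = 0))
  expect_equal(z0$Z_pre, st$W + st$Lambda / st$mu, tolerance = 1e-12)
  z1 <- update_Z(st, laps, M, drfs_control(beta = 2))
  expect_true(all(z1$Z >= 0))
  expect_equal(z1$Z, pmax(z1$Z_pre, 0))
})

test_that("pre-projection Z solves the per-class stationarity equation", {
  local_seed(24)
  for (i in 1:5) {
    d <- 9; r <- 3
    laps <- replicate(r, laplacian(structure(
      list(sim = random_sim(d), sigma2 = 1, k = d - 1L, scope = "t"),
      class = "feature_graph")), simplify = FALSE)
    M <- random_sim(d)
    ctrl <- drfs_control(beta = runif(1, 0.5, 3))
    st <- random_state(d, r, mu = runif(1, 1, 4))
    res <- update_Z(st, laps, M, ctrl)
    c_loc <- ctrl$beta / r
    c_glob <- ctrl$beta / (r * (r - 1))
    # Gauss-Seidel: class l sees fresh z_q for q < l, old for q > l
    Zrun <- st$Z
    for (l in seq_len(r)) {
      others <- rowSums(Zrun[, -l, drop = FALSE])
      lhs <- (c_loc * as.matrix(laps[[l]]$lap) + st$mu * diag(d)) %*% res$Z_pre[, l]
      rhs <- st$mu * st$W[, l] + st$Lambda[, l] - c_glob * (M %*% others)
      expect_lt(max(abs(lhs - rhs)), 1e-8)
      Zrun[, l] <- res$Z[, l]
    }
  }
})

test_that("objective_value matches closed forms", {
  local_seed(25)
  n <- 8; d <- 5; r <- 2
  x <- drfs_data(matrix(rnorm(n * d), n, d), random_labels(n, r))
  Y <- one_hot(x$labels, r)
  laps <- lapply(build_class_graphs(x, 2), laplacian)
  M <- build_global_graph(x, 2)
  ctrl <- drfs_control(alpha = 0.9, beta = 0.4)
  # W = 0: only the label norm survives (= n for one-hot Y)
  expect_equal(objective_value(matrix(0, d, r), x$values, Y, ctrl, laps, M), n)
  # identity instance: X = Y = W = I, beta = 0 -> alpha * r
  xi <- diag(3)
  lapsi <- replicate(3, laplacian(structure(
    list(sim = random_sim(3), sigma2 = 1, k = 2L, scope = "t"),
    class = "feature_graph")), simplify = FALSE)
  ctrl0 <- drfs_control(alpha = 0.9, beta = 0)
  expect_equal(objective_value(diag(3), xi, diag(3), ctrl0, lapsi,
                               random_sim(3)), 0.9 * 3)
  # alpha, beta -> 0: unconstrained least squares residual via normal equations
  n2 <- 5; d2 <- 3
  X2 <- matrix(rnorm(n2 * d2), n2, d2)
  Y2 <- one_hot(random_labels(n2, 2), 2)
  Wls <- solve(crossprod(X2), crossprod(X2, Y2))
  ctrl_tiny <- drfs_control(alpha = 1e-12, beta = 0)
  laps2 <- replicate(2, laplacian(structure(
    list(sim = random_sim(d2), sigma2 = 1, k = 2L, scope = "t"),
    class = "feature_graph")), simplify = FALSE)
  expect_equal(objective_value(Wls, X2, Y2, ctrl_tiny, laps2, random_sim(d2)),
               sum((X2 %*% Wls - Y2)^2), tolerance = 1e-8)
})

test_that("kkt_residual is zero at fixed points and scales quadratically", {
  local_seed(26)
  n <- 10; d <- 6; r <- 2
  X <- matrix(rnorm(n * d), n, d)
  ctrl <- drfs_control()
  st <- random_state(d, r, mu = 2)
  rw <- update_reweight(st$W, ctrl$eps_reweight)
  A <- crossprod(X); diag(A) <- diag(A) + st$mu + ctrl$alpha * rw
  Y0 <- matrix(0, n, r)
  st$Lambda <- st$mu * st$Z - A %*% st$W   # makes B = A W exactly
  expect_equal(kkt_residual(st, X, Y0, ctrl, rw), 0, tolerance = 1e-10)
  # quadratic scaling with A and the reweight diagonal frozen
  st2 <- random_state(d, r, mu = 2)
  rw2 <- update_reweight(st2$W, ctrl$eps_reweight)
  base <- kkt_residual(st2, X, Y0, ctrl, rw2)
  cc <- 3
  st3 <- st2
  st3$W <- cc * st2$W; st3$Z <- cc * st2$Z; st3$Lambda <- cc * st2$Lambda
  expect_equal(kkt_residual(st3, X, Y0, ctrl, rw2), cc^2 * base,
               tolerance = 1e-8)
})

test_that("fit converges on a small instance with a well-behaved trace", {
  gen <- easy_instance(0)
  fit <- drfs_fit(gen$data, drfs_control(alpha = 1, beta = 1))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 100L)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$Z >= 0))
  tr <- fit$trace
  expect_true(all(diff(tr$mu) >= 0))
  expect_true(all(tr$mu <= fit$control$mu_max))
  expect_lt(tr$primal_residual[nrow(tr)], fit$control$tol_primal)
  # complementarity residual falls by at least 10x over the run
  expect_lt(tr$kkt_residual[nrow(tr)], tr$kkt_residual[1] / 10)
  expect_true(all(is.finite(tr$objective)))
})

test_that("extreme sparsity drives all importance scores to zero", {
  gen <- easy_instance(1)
  fit <- drfs_fit(gen$data, drfs_control(alpha = 1e6, beta = 1, max_iter = 60))
  expect_true(all(fit$scores < 1e-3))
})

test_that("the selected set is robust to the initialization seed", {
  gen <- easy_instance(0)
  tops <- vapply(0:4, function(s) {
    f <- drfs_fit(gen$data, drfs_control(seed = s))
    sort(top_k(f$ranking, 10))
  }, integer(10))
  expect_true(all(apply(tops, 1, function(rr) length(unique(rr)) == 1)))
})
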