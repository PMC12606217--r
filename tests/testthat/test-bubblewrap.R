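test_that("initialization satisfies every structural invariant", {
  set.seed(1)
  pts <- matrix(rnorm(40), 20, 2)
  st <- bw_init(pts, N = 50L)
  A <- st$A
  expect_equal(rowSums(A), rep(1, 50), tolerance = 1e-9)
  expect_simplex(st$alpha)
  expect_equal(bw_entropy(st), log2(50), tolerance = 1e-9)
  for (j in 1:50) {
    ev <- eigen(st$Sigma[, , j], symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(bw_init(matrix(1, 1, 2)), "2 initial points")
})

test_that("invariants hold after every streaming update", {
  set.seed(2)
  X <- matrix(rnorm(600), 300, 2)
  st <- bw_init(X[1:20, ], N = 20L)
  for (t in 21:300) {
    res <- bw_update(st, X[t, ])
    st <- res$state
    expect_equal(rowSums(st$A), rep(1, 20), tolerance = 1e-9)
    expect_simplex(st$alpha)
    expect_true(all(apply(st$Sigma, 3, function(S) {
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0
    })))
    expect_true(is.finite(res$log_pred))
  }
  # non-finite inputs are skipped, not fatal
  res <- bw_update(st, c(NA, 1))
  expect_true(is.na(res$log_pred))
})

test_that("on stationary Gaussian data the one-step score approaches the truth", {
  set.seed(3)
  mu <- c(1, -2); sds <- c(0.7, 0.4)
  X <- cbind(rnorm(2020, mu[1], sds[1]), rnorm(2020, mu[2], sds[2]))
  res <- bw_stream(X, n_init = 20L)
  true_expected <- -log(2 * pi) - 0.5 * log(prod(sds^2)) - 1
  got <- mean(tail(res$metrics$log_pred, 1000))
  expect_lt(abs(got - true_expected), 0.5)
})

test_that("deterministic alternation between two tiles is learned as a flip", {
  set.seed(4)
  X <- matrix(rep(c(0, 0, 10, 10), 1000), ncol = 2, byrow = TRUE) +
    rnorm(4000, sd = 0.1)
  res <- bw_stream(X, n_init = 20L, N = 2L)
  st <- res$state
  # each tile sits on one cluster and A concentrates off-diagonal
  expect_gt(min(st$A[1, 2], st$A[2, 1]), 0.9)
  expect_lt(bw_entropy(st), 1)
  expect_equal(tail(res$metrics$entropy, 1) < 1, TRUE)
})

test_that("with redundant tiles the cluster-to-cluster structure still dominates", {
  set.seed(5)
  X <- matrix(rep(c(0, 0, 10, 10), 1500), ncol = 2, byrow = TRUE) +
    rnorm(6000, sd = 0.1)
  res <- bw_stream(X, n_init = 20L, N = 50L)
  st <- res$state
  grp <- apply(st$mu, 1, function(m) sum(m^2) < sum((m - 10)^2))
  occ <- st$occupancy / sum(st$occupancy)
  cross12 <- sum(occ[grp] * rowSums(st$A[grp, !grp, drop = FALSE])) /
    sum(occ[grp])
  expect_gt(cross12, 0.95)
  expect_lt(bw_entropy(st), log2(50) - 0.5)
})

test_that("k-step prediction propagates the filter through the chain", {
  set.seed(6)
  st <- bw_init(matrix(rnorm(40), 20, 2), N = 10L)
  st$alpha <- c(0.5, 0.5, rep(0, 8))
  expect_equal(bw_predict(st, 1), drop(crossprod(st$alpha, st$A)))
  st$A <- diag(10)
  for (h in c(1, 5, 50)) expect_equal(bw_predict(st, h), st$alpha)
  set.seed(7)
  A <- matrix(runif(100), 10); A <- A / rowSums(A)
  st$A <- A
  for (h in c(1, 7, 100)) {
    expect_equal(sum(bw_predict(st, h)), 1, tolerance = 1e-9)
  }
})

test_that("horizon-k log scores match a naive mixture evaluation", {
  set.seed(8)
  X <- matrix(rnorm(400), 200, 2)
  res <- bw_stream(X, n_init = 20L, N = 8L)
  st <- res$state
  for (h in c(1, 3, 10)) {
    x <- rnorm(2)
    w <- bw_predict(st, h)
    expect_equal(bw_logpred(st, x, h),
                 oracle_mixture_logdens(w, st$mu, st$Sigma, x),
                 tolerance = 1e-10)
  }
})

test_that("horizon profiles are flat for exchangeable data, decaying for dynamics", {
  set.seed(9)
  # stationary iid: mean score roughly constant across horizons
  Xs <- matrix(rnorm(3000, sd = 1), 1500, 2)
  ps <- bw_horizon_profile(Xs, horizons = c(1, 20, 60), eval_every = 25L)
  expect_lt(diff(range(ps$profile$mean_log_pred)), 0.6)
  # noisy limit cycle: predictions degrade as the look-ahead grows
  lc <- gen_limit_cycle(T_steps = 4000, dims = 2, noise_sd = 0.05, seed = 10)
  pl <- bw_horizon_profile(lc$X, horizons = c(1, 10, 50), eval_every = 25L)
  mlp <- pl$profile$mean_log_pred
  expect_gt(mlp[1], mlp[3])
  expect_gte(pl$profile$n_eval[1], 50)
})

test_that("transition entropy follows the textbook cases and monotonicity", {
  A <- matrix(1 / 6, 6, 6)
  expect_equal(bw_entropy(A), log2(6))
  P <- diag(6)[c(2:6, 1), ]
  expect_equal(bw_entropy(P), 0)
  # sharpening any row never increases the occupancy-weighted entropy
  set.seed(11)
  A2 <- matrix(runif(36), 6); A2 <- A2 / rowSums(A2)
  pi <- rep(1 / 6, 6)
  h0 <- bw_entropy(A2, pi)
  for (j in 1:6) {
    A3 <- A2
    m <- which.max(A2[j, ])
    A3[j, ] <- 0.001 / 5
    A3[j, m] <- 1 - 0.001
    expect_lte(bw_entropy(A3, pi), h0 + 1e-12)
    h0 <- bw_entropy(A3, pi)
    A2 <- A3
  }
})

test_that("state memory does not grow with the stream", {
  set.seed(12)
  X <- matrix(rnorm(2000), 1000, 2)
  st <- bw_init(X[1:20, ], N = 10L)
  for (t in 21:120) st <- bw_update(st, X[t, ])$state
  s1 <- as.numeric(object.size(st))
  for (t in 121:1000) st <- bw_update(st, X[t, ])$state
  expect_equal(as.numeric(object.size(st)), s1)
})
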