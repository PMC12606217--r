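test_that("rates follow the exponential nonlinearity exactly", {
  p <- lnp_params(3, b = rep(log(0.5), 3))
  r <- lnp_rate(p, rep(0, 8), matrix(0, 3, 4), rep(0, 3))
  expect_equal(r, rep(0.5, 3))
  p2 <- lnp_params(1, b = 0)
  p2$K[1, 3] <- 1
  s <- rep(0, 8); s[3] <- 1
  expect_equal(lnp_rate(p2, s, matrix(0, 1, 4), 0), exp(1))
  # coupling-only model against direct evaluation
  set.seed(1)
  n <- 5
  W <- matrix(rnorm(n * n, sd = 0.3), n, n); diag(W) <- 0
  p3 <- lnp_params(n, b = rep(0, n), W = W)
  y_prev <- rpois(n, 1)
  expect_equal(lnp_rate(p3, rep(0, 8), matrix(0, n, 4), y_prev),
               exp(drop(W %*% y_prev)), tolerance = 1e-12)
  expect_warning(lnp_rate(lnp_params(1, b = 50), rep(0, 8),
                          matrix(0, 1, 4), 0), "clip")
})

test_that("window log-likelihood matches analytic and brute-force values", {
  # zero spikes, rate 0.5, 1 neuron: -sum(lambda) over 10 scoring frames
  p <- lnp_params(1, b = log(0.5))
  spikes <- matrix(0L, 14, 1)
  stim <- matrix(0, 14, 8)
  expect_equal(lnp_loglik(p, spikes, stim), -5)
  # y = 1 each frame, lambda = 1: log 1 - 1 = -1 per scored frame
  p1 <- lnp_params(1, b = 0, H = matrix(0, 1, 4))
  expect_equal(lnp_loglik(p1, matrix(1L, 14, 1), stim), -10)
  # random small instances against the double-loop oracle
  set.seed(2)
  for (rep in 1:4) {
    n <- sample(2:4, 1)
    p2 <- gen_lnp_params(n, seed = rep)
    sim <- gen_lnp_population(p2, T_frames = 30, seed = rep + 10)
    expect_equal(lnp_loglik(p2, sim$spikes, sim$stim),
                 oracle_lnp_loglik(p2, sim$spikes, sim$stim),
                 tolerance = 1e-10)
  }
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(3)
  p <- gen_lnp_params(4, seed = 5)
  sim <- gen_lnp_population(p, T_frames = 40, seed = 6)
  sp <- sim$spikes[1:30, ]; stm <- sim$stim[1:30, ]
  g <- lnp_gradient(p, sp, stm)
  checks <- list(
    list("b", 2, NULL, g$b[2]),
    list("b", 4, NULL, g$b[4]),
    list("K", 1, 3, g$K[1, 3]),
    list("K", 3, 7, g$K[3, 7]),
    list("H", 2, 1, g$H[2, 1]),
    list("H", 4, 4, g$H[4, 4]),
    list("W", 1, 2, g$W[1, 2]),
    list("W", 3, 4, g$W[3, 4])
  )
  for (ck in checks) {
    fd <- fd_lnp_grad(p, sp, stm, ck[[1]], ck[[2]], ck[[3]])
    expect_equal(ck[[4]], fd, tolerance = 1e-5)
  }
  # the diagonal coupling gradient is structurally zero
  expect_equal(diag(g$W), rep(0, 4))
})

test_that("an SGD step moves parameters along the gradient and rezeroes diag(W)", {
  set.seed(4)
  p <- gen_lnp_params(3, seed = 7)
  sim <- gen_lnp_population(p, T_frames = 30, seed = 8)
  g <- lnp_gradient(p, sim$spikes, sim$stim)
  p2 <- lnp_sgd_step(p, sim$spikes, sim$stim, step = 1e-5)
  expect_equal(p2$b - p$b, 1e-5 * g$b)
  expect_equal(diag(p2$W), rep(0, 3))
  # near a batch optimum the gradient norm is tiny and a step barely moves
  bat <- lnp_fit_batch(sim$spikes, sim$stim, max_iter = 400)
  g_opt <- lnp_gradient(bat$params, sim$spikes, sim$stim)
  p3 <- lnp_sgd_step(bat$params, sim$spikes, sim$stim, step = 1e-5)
  delta <- sqrt(sum((p3$b - bat$params$b)^2) + sum((p3$W - bat$params$W)^2) +
                  sum((p3$K - bat$params$K)^2) + sum((p3$H - bat$params$H)^2))
  gnorm <- sqrt(sum(g_opt$b^2) + sum(g_opt$W^2) + sum(g_opt$K^2) +
                  sum(g_opt$H^2))
  expect_lte(delta, 1e-5 * gnorm + 1e-12)
  expect_lt(gnorm, 1)
})

test_that("window length limits are enforced and memory stays bounded", {
  expect_error(lnp_params(2, window_len = 5L), "10")
  expect_error(lnp_params(2, window_len = 200L), "10")
  set.seed(5)
  p <- gen_lnp_params(3, seed = 9)
  sim <- gen_lnp_population(p, T_frames = 400, seed = 10)
  fit <- lnp_fit_stream(sim$spikes, sim$stim,
                        params = lnp_params(3, window_len = 50L))
  expect_s3_class(fit$params, "lnp_params")
  expect_equal(fit$params$window_len, 50L)
})

test_that("top connections sort by coupling magnitude with index tie-breaks", {
  W <- rbind(c(0, 3, -5, 1),
             c(0, 0, 0, 0),
             c(1, 1, 0, 1),
             c(2, 2, 2, 0))
  expect_equal(top_connections(W, 1, m = 3), c(3L, 2L, 4L))
  expect_equal(top_connections(W, 2, m = 3), c(1L, 3L, 4L))  # zeros: by index
  expect_equal(top_connections(W, 1, m = 1), 3L)
  log <- run_log()
  expect_equal(top_connections(W, 1, m = 10, log = log), c(3L, 2L, 4L))
  expect_equal(log_count(log, "warning"), 1L)
})
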