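# Independent oracles used across tests. These deliberately use naive
# formulations (dense solves, double loops, exhaustive search) so they stay
# independent of the streaming implementations they check.

# exhaustive Otsu: try every histogram cut, maximize between-class variance
oracle_otsu <- function(img, n_bins = 256L) {
  rng <- range(img)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bins <- findInterval(img, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  best_t <- NA
  best_v <- -Inf
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  for (t in 1:(n_bins - 1)) {
    lo <- bins <= t
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) next
    v <- w0 * (1 - w0) * (mean(mids[bins[lo]]) - mean(mids[bins[!lo]]))^2
    if (v > best_v) {
      best_v <- v
      best_t <- breaks[t + 1L]
    }
  }
  best_t
}

# dense GP solve with one row per observation (no aggregation)
oracle_gp <- function(idx, y, kernel, noise) {
  K <- kernel$K
  Koo <- K[idx, idx, drop = FALSE] + diag(noise, length(idx))
  Ki <- solve(Koo)
  f <- drop(K[, idx, drop = FALSE] %*% Ki %*% y)
  s2 <- vapply(seq_len(nrow(K)), function(g) {
    K[g, g] - drop(K[g, idx] %*% Ki %*% K[idx, g])
  }, numeric(1))
  list(f = f, s2 = pmax(s2, 0))
}

# naive double-loop mixture log density
oracle_mixture_logdens <- function(w, mu, Sigma, x) {
  total <- 0
  for (j in seq_along(w)) {
    k <- length(x)
    d <- x - mu[j, ]
    Si <- solve(Sigma[, , j])
    dens <- exp(-0.5 * drop(t(d) %*% Si %*% d)) /
      sqrt((2 * pi)^k * det(Sigma[, , j]))
    total <- total + w[j] * dens
  }
  log(total)
}

# naive per-frame, per-neuron Poisson log-likelihood (double loop)
oracle_lnp_loglik <- function(params, spikes, stim) {
  n <- params$n
  total <- 0
  for (t in 5:nrow(spikes)) {
    for (i in seq_len(n)) {
      eta <- params$b[i] + sum(params$K[i, ] * stim[t, ]) +
        sum(params$H[i, ] * spikes[t - (1:4), i]) +
        sum(params$W[i, ] * spikes[t - 1, ])
      total <- total + spikes[t, i] * eta - exp(eta)
    }
  }
  total
}

# central finite differences of the window log-likelihood
fd_lnp_grad <- function(params, spikes, stim, field, i, j = NULL,
                        eps = 1e-6) {
  bump <- function(p, e) {
    if (field == "b") p$b[i] <- p$b[i] + e
    else p[[field]][i, j] <- p[[field]][i, j] + e
    p
  }
  (lnp_loglik(bump(params, eps), spikes, stim) -
     lnp_loglik(bump(params, -eps), spikes, stim)) / (2 * eps)
}

expect_simplex <- function(v, tol = 1e-9) {
  expect_true(all(v >= -tol))
  expect_equal(sum(v), 1, tolerance = tol)
}
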