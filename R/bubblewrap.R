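#' Initialize a streaming Gaussian-mixture HMM ("tile") model
#'
#' The model coarsely tiles a low-dimensional state space with N Gaussian
#' tiles and learns a row-stochastic transition matrix A between tiles, all
#' online: each new point is scored by the one-step predictive mixture
#' density before being absorbed into the tile sufficient statistics
#' (exponential forgetting `lam`, prior strength `nu`) and a gradient step
#' on A (step `eta`). Tile means are seeded from the first points (with
#' jitter when N exceeds the number of points), covariances from the data
#' scale, and A and the filtered state alpha start uniform.
#'
#' @param first_points m x k matrix of initial points (m >= 2; default use
#'   is the first 20 time points).
#' @param N Number of tiles (default 50).
#' @param lam Forgetting rate for tile statistics (default 1e-3).
#' @param nu Prior strength on tile statistics (default 1e-3).
#' @param eta Transition-matrix gradient step (default 8e-3).
#' @param seed Seed for the jitter used to spread tile means.
#' @return A `bw_state`.
#' @export
bw_init <- function(first_points, N = 50L, lam = 1e-3, nu = 1e-3,
                    eta = 8e-3, seed = 42L) {
  stopifnot(is.matrix(first_points))
  m <- nrow(first_points)
  k <- ncol(first_points)
  if (m < 2L) stop("need at least 2 initial points", call. = FALSE)
  set.seed(seed)
  ctr <- colMeans(first_points)
  sdv <- apply(first_points, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1e-3
  idx <- rep_len(seq_len(m), N)
  mu <- first_points[idx, , drop = FALSE] +
    matrix(stats::rnorm(N * k), N, k) * rep(sdv / 2, each = N)
  Sigma0 <- diag(sdv^2, k)
  var_floor <- 1e-6 * mean(sdv^2)
  Sig <- array(rep(Sigma0, N), dim = c(k, k, N))
  structure(
    list(
      N = as.integer(N), k = k,
      mu = mu, Sigma = Sig,
      A = matrix(1 / N, N, N),           # uniform transitions at start
      alpha = rep(1 / N, N),
      lam = lam, nu = nu, eta = eta,
      mu0 = mu, Sigma0 = Sigma0, var_floor = var_floor,
      sw = rep(nu, N),                    # per-tile stat weights
      sx = mu * nu,                       # weighted sums of x
      sxx = array(vapply(seq_len(N), function(j) {
        Sigma0 * nu + nu * tcrossprod(mu[j, ])
      }, matrix(0, k, k)), dim = c(k, k, N)),
      occupancy = rep(1 / N, N),          # for entropy weighting
      resp_ewma = rep(1 / N, N),          # dead-tile detector (window ~500)
      t = 0L, n_teleports = 0L
    ),
    class = "bw_state"
  )
}

bw_A <- function(state) state$A

# per-tile Gaussian log-densities at x, with cached cholesky-free solve
bw_logdens <- function(state, x) {
  k <- state$k
  vapply(seq_len(state$N), function(j) {
    S <- state$Sigma[, , j]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    d <- x - state$mu[j, ]
    z <- backsolve(ch, d, transpose = TRUE)
    -0.5 * k * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
  }, numeric(1))
}

#' Stream one point through the mixture-HMM
#'
#' Performs, in order: (1) evaluation of the one-step log predictive
#' probability of `x` under the pre-update model (the returned score);
#' (2) the HMM filter update of alpha (predict through A, weight by tile
#' likelihoods, renormalize); (3) tile sufficient-statistic updates with
#' exponential forgetting and prior regularization, with covariance
#' eigenvalues floored to stay positive definite; (4) one gradient step on
#' the transition matrix increasing the log predictive probability,
#' followed by row renormalization; (5) relocation of long-dead tiles to the
#' most recent observation (logged in the state's teleport counter).
#' Non-finite inputs are skipped.
#'
#' @param state A `bw_state`.
#' @param x New k-vector.
#' @return List: `state` (updated), `log_pred` (one-step log predictive
#'   probability of `x` under the pre-update model).
#' @export
bw_update <- function(state, x) {
  stopifnot(inherits(state, "bw_state"))
  x <- as.numeric(x)
  if (length(x) != state$k) stop("dimension mismatch", call. = FALSE)
  if (!all(is.finite(x))) {
    return(list(state = state, log_pred = NA_real_))
  }
  N <- state$N
  A <- bw_A(state)
  w <- drop(crossprod(state$alpha, A))          # predicted tile weights
  ld <- bw_logdens(state, x)
  lp_terms <- log(pmax(w, 1e-300)) + ld
  log_pred <- logsumexp(lp_terms)

  # (2) filter update
  la <- lp_terms - log_pred
  alpha_new <- exp(la)
  alpha_new <- alpha_new / sum(alpha_new)

  # (3) tile statistics with forgetting; responsibilities = filtered alpha
  g <- alpha_new
  dec <- 1 - state$lam
  state$sw <- dec * state$sw + g
  state$sx <- dec * state$sx + tcrossprod(g, x)
  state$sxx <- state$sxx * dec
  xx <- tcrossprod(x)
  nu <- state$nu
  # only tiles that received appreciable responsibility change materially
  upd <- which(g > 1e-8)
  for (j in upd) {
    state$sxx[, , j] <- state$sxx[, , j] + g[j] * xx
  }
  for (j in upd) {
    wj <- state$sw[j] + nu
    muj <- (state$sx[j, ] + nu * state$mu0[j, ]) / wj
    Sj <- (state$sxx[, , j] + nu * (state$Sigma0 +
             tcrossprod(state$mu0[j, ]))) / wj - tcrossprod(muj)
    Sj <- (Sj + t(Sj)) / 2
    ev <- eigen(Sj, symmetric = TRUE)
    vals <- pmax(ev$values, state$var_floor)
    state$mu[j, ] <- muj
    state$Sigma[, , j] <- ev$vectors %*% (vals * t(ev$vectors))
  }

  # (4) one gradient step on A: d log p / dA_jm = alpha_j L_m / p,
  # computed on the scale-free likelihood profile (the density scale
  # cancels in the ratio), then projected back to the simplex rows
  Lrel <- exp(ld - max(ld))
  p_rel <- sum(w * Lrel)
  if (p_rel > 0) {
    Anew <- A + state$eta * tcrossprod(state$alpha, Lrel) / p_rel
    Anew <- pmax(Anew, 1e-12)
    state$A <- Anew / rowSums(Anew)
  }

  # bookkeeping and (5) dead-tile teleportation
  state$alpha <- alpha_new
  state$occupancy <- state$occupancy + g
  ew <- 1 / 500
  state$resp_ewma <- (1 - ew) * state$resp_ewma + ew * g
  state$t <- state$t + 1L
  if (state$t > 500L) {
    dead <- which(state$resp_ewma < 1e-4)
    if (length(dead) > 0L) {
      j <- dead[which.min(state$resp_ewma[dead])]
      state$mu[j, ] <- x
      state$mu0[j, ] <- x
      state$Sigma[, , j] <- 4 * state$Sigma0
      state$sw[j] <- nu
      state$sx[j, ] <- nu * x
      state$sxx[, , j] <- nu * (4 * state$Sigma0 + tcrossprod(x))
      state$resp_ewma[j] <- 1 / state$N
      state$n_teleports <- state$n_teleports + 1L
    }
  }
  list(state = state, log_pred = log_pred)
}

#' k-step-ahead tile weights
#'
#' Propagates the filtered state `horizon` steps through the transition
#' matrix: `weights = alpha' A^horizon`, a distribution over tiles whose
#' mixture (with the current tile Gaussians) is the k-step-ahead
#' predictive density.
#'
#' @param state A `bw_state`.
#' @param horizon Steps ahead (>= 1).
#' @return Length-N weight vector on the simplex.
#' @export
bw_predict <- function(state, horizon = 1L) {
  stopifnot(horizon >= 1L)
  A <- bw_A(state)
  w <- state$alpha
  for (i in seq_len(horizon)) w <- drop(crossprod(w, A))
  w
}

#' Log predictive probability of a future point
#'
#' Log density of `x_future` under the horizon-step predictive mixture.
#'
#' @param state A `bw_state`.
#' @param x_future k-vector observed `horizon` steps later.
#' @param horizon Steps ahead.
#' @return Scalar log density.
#' @export
bw_logpred <- function(state, x_future, horizon = 1L) {
  w <- bw_predict(state, horizon)
  ld <- bw_logdens(state, as.numeric(x_future))
  logsumexp(log(pmax(w, 1e-300)) + ld)
}

#' Transition-matrix entropy
#'
#' Occupancy-weighted mean row entropy of the learned transition matrix in
#' bits: `H = sum_j pi_j (-sum_m A_jm log2 A_jm)` with `pi` the normalized
#' tile occupancy. Uniform A gives `log2 N`; a deterministic (permutation)
#' matrix gives 0.
#'
#' @param state A `bw_state`, or a row-stochastic matrix (then `pi` must
#'   be supplied or defaults to uniform).
#' @param pi Optional occupancy weights.
#' @return Entropy in bits.
#' @export
bw_entropy <- function(state, pi = NULL) {
  if (inherits(state, "bw_state")) {
    A <- bw_A(state)
    pi <- pi %||% (state$occupancy / sum(state$occupancy))
  } else {
    A <- state
    pi <- pi %||% rep(1 / nrow(A), nrow(A))
  }
  rowH <- -rowSums(ifelse(A > 0, A * log2(A), 0))
  sum(pi * rowH)
}

#' Run a full stream through the mixture-HMM
#'
#' Convenience driver: initializes from the first `n_init` points and
#' updates once per remaining point, recording per-step metrics.
#'
#' @param X T x k data matrix.
#' @param n_init Points used for initialization (default 20).
#' @param ... Passed to [bw_init()].
#' @return List: `state`, `metrics` (tibble: step, log_pred, entropy).
#' @export
bw_stream <- function(X, n_init = 20L, ...) {
  stopifnot(nrow(X) > n_init)
  state <- bw_init(X[seq_len(n_init), , drop = FALSE], ...)
  steps <- (n_init + 1L):nrow(X)
  lp <- numeric(length(steps))
  ent <- numeric(length(steps))
  for (i in seq_along(steps)) {
    res <- bw_update(state, X[steps[i], ])
    state <- res$state
    lp[i] <- res$log_pred
    ent[i] <- bw_entropy(state)
  }
  list(state = state,
       metrics = tibble::tibble(step = steps, log_pred = lp, entropy = ent))
}

#' Horizon profile of predictive performance over a stream
#'
#' Streams `X` through the model and, at regularly spaced evaluation
#' points, scores the log predictive probability of the actual future
#' observation at each requested horizon using the filter state *at that
#' moment* (predictions are made forward from the current phase of the
#' trajectory, then compared with what actually happened).
#'
#' @param X T x k data matrix.
#' @param horizons Integer vector of look-ahead steps (default 1:100).
#' @param n_init Initialization points (default 20).
#' @param burn_in Updates to absorb before scoring (default half the
#'   stream).
#' @param eval_every Stride between evaluation points.
#' @param ... Passed to [bw_init()].
#' @return List: `state`, `profile` (tibble: horizon, mean_log_pred,
#'   sd_log_pred, n_eval).
#' @export
bw_horizon_profile <- function(X, horizons = 1:100, n_init = 20L,
                               burn_in = nrow(X) %/% 2, eval_every = 50L,
                               ...) {
  T_ <- nrow(X)
  hmax <- max(horizons)
  state <- bw_init(X[seq_len(n_init), , drop = FALSE], ...)
  scores <- matrix(NA_real_, 0, length(horizons))
  for (t in (n_init + 1L):T_) {
    state <- bw_update(state, X[t, ])$state
    if (t > burn_in && (t - n_init) %% eval_every == 0L && t + hmax <= T_) {
      # cache per-tile cholesky factors once for this filter state
      chols <- lapply(seq_len(state$N), function(j) {
        tryCatch(chol(state$Sigma[, , j]), error = function(e) NULL)
      })
      logdens_at <- function(x) {
        vapply(seq_len(state$N), function(j) {
          ch <- chols[[j]]
          if (is.null(ch)) return(-1e10)
          d <- x - state$mu[j, ]
          z <- backsolve(ch, d, transpose = TRUE)
          -0.5 * state$k * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
        }, numeric(1))
      }
      A <- state$A
      w <- state$alpha
      row <- numeric(length(horizons))
      hi <- 1L
      for (h in seq_len(hmax)) {
        w <- drop(crossprod(w, A))
        if (h %in% horizons) {
          ld <- logdens_at(as.numeric(X[t + h, ]))
          row[hi] <- logsumexp(log(pmax(w, 1e-300)) + ld)
          hi <- hi + 1L
        }
      }
      scores <- rbind(scores, row)
    }
  }
  list(
    state = state,
    profile = tibble::tibble(
      horizon = horizons,
      mean_log_pred = colMeans(scores),
      sd_log_pred = apply(scores, 2, stats::sd),
      n_eval = nrow(scores)
    )
  )
}

#' @export
print.bw_state <- function(x, ...) {
  cat(sprintf("<bw_state: %d tiles in %d dims, %d points seen, %d teleports>\n",
              x$N, x$k, x$t, x$n_teleports))
  invisible(x)
}
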