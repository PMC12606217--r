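#' Linear-nonlinear-Poisson population model parameters
#'
#' A streaming Poisson GLM of a population of n neurons observed at the
#' imaging frame rate. Each neuron's per-frame rate is
#' `exp(b_i + K_i . s_t + H_i . y_hist_i + sum_j W_ij y_prev_j)`:
#' a baseline log-rate, an 8-dimensional stimulus-direction response, a
#' self-history term over the previous 4 frames, and pairwise coupling
#' weights to every other neuron's previous-frame activity (the functional
#' connectivity estimate). `diag(W)` is identically zero: same-neuron
#' lag-1 effects belong to the history term.
#'
#' @param n Number of neurons.
#' @param b Length-n baseline log-rates (default `log(0.5)`).
#' @param K n x 8 stimulus weights.
#' @param H n x 4 self-history weights (lags 1..4 frames).
#' @param W n x n coupling weights, zero diagonal.
#' @param step SGD step size (default 1e-5).
#' @param window_len Sliding-window length in frames, within \[10, 100\]
#'   (default 100).
#' @return An `lnp_params` object.
#' @export
lnp_params <- function(n, b = rep(log(0.5), n), K = matrix(0, n, 8),
                       H = matrix(0, n, 4), W = matrix(0, n, n),
                       step = 1e-5, window_len = 100L) {
  stopifnot(length(b) == n, all(dim(K) == c(n, 8)), all(dim(H) == c(n, 4)),
            all(dim(W) == c(n, n)))
  if (window_len < 10L || window_len > 100L) {
    stop("window length must lie in [10, 100] frames", call. = FALSE)
  }
  diag(W) <- 0
  structure(
    list(n = n, b = b, K = K, H = H, W = W,
         step = step, window_len = as.integer(window_len)),
    class = "lnp_params"
  )
}

#' Per-neuron Poisson rate for one frame
#'
#' Exponential nonlinearity over the model's linear drive. Rates are
#' clipped at `exp(30)` (with a warning) to avoid overflow during early,
#' badly scaled fitting steps.
#'
#' @param params An [lnp_params()].
#' @param s_t 8-dim stimulus indicator (one-hot during motion, zeros when
#'   the grating is stationary).
#' @param y_hist n x 4 matrix of each neuron's own spike counts at lags
#'   1..4 (column 1 = previous frame).
#' @param y_prev Length-n population spike counts at the previous frame.
#' @return Length-n positive rate vector (spikes/frame).
#' @export
lnp_rate <- function(params, s_t, y_hist, y_prev) {
  stopifnot(length(s_t) == 8L, length(y_prev) == params$n)
  if (is.null(dim(y_hist))) y_hist <- matrix(y_hist, params$n, 4)
  eta <- params$b + drop(params$K %*% s_t) + rowSums(params$H * y_hist) +
    drop(params$W %*% y_prev)
  if (any(eta > 30)) {
    warning("linear drive > 30; rates clipped at exp(30)")
    eta <- pmin(eta, 30)
  }
  exp(eta)
}

# build lagged design pieces from a window of (spikes, stimulus) frames.
# spikes: T x n counts; stim: T x 8. Frame t uses history from t-1..t-4,
# so the first 4 frames of the window serve only as history.
lnp_window_design <- function(spikes, stim) {
  T_ <- nrow(spikes)
  n <- ncol(spikes)
  if (T_ < 5L) stop("window too short for 4-frame history", call. = FALSE)
  idx <- 5:T_
  lag <- function(l) spikes[idx - l, , drop = FALSE]
  list(
    y = spikes[idx, , drop = FALSE],
    s = stim[idx, , drop = FALSE],
    y1 = lag(1), y2 = lag(2), y3 = lag(3), y4 = lag(4),
    t_used = length(idx)
  )
}

lnp_eta_window <- function(params, d) {
  # T' x n linear drive for all usable frames of a window
  eta <- matrix(params$b, d$t_used, params$n, byrow = TRUE) +
    d$s %*% t(params$K) +
    d$y1 * matrix(params$H[, 1], d$t_used, params$n, byrow = TRUE) +
    d$y2 * matrix(params$H[, 2], d$t_used, params$n, byrow = TRUE) +
    d$y3 * matrix(params$H[, 3], d$t_used, params$n, byrow = TRUE) +
    d$y4 * matrix(params$H[, 4], d$t_used, params$n, byrow = TRUE) +
    d$y1 %*% t(params$W)
  pmin(eta, 30)
}

#' Poisson log-likelihood over a window
#'
#' `sum_t sum_i [y log(lambda) - lambda]`, dropping the `log y!` constant
#' (irrelevant to gradients and comparisons). The first four frames of the
#' window provide history only.
#'
#' @param params An [lnp_params()].
#' @param spikes T x n spike-count matrix (the window).
#' @param stim T x 8 stimulus-indicator matrix aligned with `spikes`.
#' @return Scalar log-likelihood.
#' @export
lnp_loglik <- function(params, spikes, stim) {
  d <- lnp_window_design(spikes, stim)
  eta <- lnp_eta_window(params, d)
  sum(d$y * eta - exp(eta))
}

#' Log-likelihood gradient over a window
#'
#' Analytic gradient of [lnp_loglik()] with respect to all parameters.
#' The diagonal of the coupling gradient is zeroed: `diag(W) = 0` is a
#' structural constraint.
#'
#' @inheritParams lnp_loglik
#' @return List with components `b`, `K`, `H`, `W` matching the parameter
#'   shapes.
#' @export
lnp_gradient <- function(params, spikes, stim) {
  d <- lnp_window_design(spikes, stim)
  eta <- lnp_eta_window(params, d)
  resid <- d$y - exp(eta)                    # T' x n
  gW <- t(resid) %*% d$y1                    # n x n: dL/dW_ij = sum resid_i y1_j
  diag(gW) <- 0
  list(
    b = colSums(resid),
    K = t(resid) %*% d$s,
    H = cbind(colSums(resid * d$y1), colSums(resid * d$y2),
              colSums(resid * d$y3), colSums(resid * d$y4)),
    W = gW
  )
}

#' One stochastic-gradient ascent step on a data window
#'
#' Takes a single gradient ascent step on the window log-likelihood, the
#' per-frame update of online fitting. A non-finite gradient skips the step
#' (logged as a warning when a log is given).
#'
#' @inheritParams lnp_loglik
#' @param step Step size; defaults to `params$step`.
#' @param log Optional [run_log()].
#' @return Updated `lnp_params`.
#' @export
lnp_sgd_step <- function(params, spikes, stim, step = params$step, log = NULL) {
  g <- lnp_gradient(params, spikes, stim)
  if (!all(vapply(g, function(x) all(is.finite(x)), logical(1)))) {
    if (!is.null(log)) {
      log_event(log, "<lnp>", "warning", "non-finite gradient; step skipped")
    }
    return(params)
  }
  params$b <- params$b + step * g$b
  params$K <- params$K + step * g$K
  params$H <- params$H + step * g$H
  params$W <- params$W + step * g$W
  diag(params$W) <- 0
  params
}

#' Fit an LNP model online over a stream of frames
#'
#' Maintains a sliding window (ring buffer) of the most recent frames and
#' takes one SGD step per new frame once the window holds at least 10
#' frames. Memory is bounded by the window length regardless of stream
#' length.
#'
#' @param spikes T x n spike counts (streamed row by row).
#' @param stim T x 8 stimulus indicators.
#' @param params Initial [lnp_params()] (default: zero-weight model).
#' @param track_loglik Record the per-frame window log-likelihood
#'   (normalized per frame-neuron) every `track_every` frames.
#' @param track_every Tracking stride (default 50).
#' @return List: `params` (final), `trace` (tibble: frame, loglik_per_bin).
#' @export
lnp_fit_stream <- function(spikes, stim, params = NULL,
                           track_loglik = TRUE, track_every = 50L) {
  n <- ncol(spikes)
  params <- params %||% lnp_params(n)
  wlen <- params$window_len
  T_ <- nrow(spikes)
  frames <- integer(0)
  lls <- numeric(0)
  for (t in seq_len(T_)) {
    lo <- max(1L, t - wlen + 1L)
    if (t - lo + 1L >= 10L) {
      win_s <- spikes[lo:t, , drop = FALSE]
      win_x <- stim[lo:t, , drop = FALSE]
      params <- lnp_sgd_step(params, win_s, win_x)
      if (track_loglik && t %% track_every == 0L) {
        frames <- c(frames, t)
        lls <- c(lls, lnp_loglik(params, win_s, win_x) /
                   ((t - lo + 1L - 4L) * n))
      }
    }
  }
  list(params = params,
       trace = tibble::tibble(frame = frames, loglik_per_bin = lls))
}

#' Offline LNP fit by full-data gradient ascent
#'
#' Batch reference fit: repeated full-data gradient ascent steps with a
#' backtracking step size, run to (approximate) convergence. Serves as the
#' offline optimum the online fit is compared against.
#'
#' @param spikes T x n spike counts.
#' @param stim T x 8 stimulus indicators.
#' @param params Initial [lnp_params()].
#' @param max_iter Iteration cap.
#' @param tol Relative log-likelihood improvement tolerance.
#' @return List: `params`, `loglik` (final full-data value).
#' @export
lnp_fit_batch <- function(spikes, stim, params = NULL, max_iter = 500L,
                          tol = 1e-8) {
  n <- ncol(spikes)
  params <- params %||% lnp_params(n, window_len = 100L)
  ll <- lnp_loglik_full(params, spikes, stim)
  step <- 1 / nrow(spikes)
  for (it in seq_len(max_iter)) {
    g <- lnp_gradient_full(params, spikes, stim)
    repeat {
      cand <- params
      cand$b <- cand$b + step * g$b
      cand$K <- cand$K + step * g$K
      cand$H <- cand$H + step * g$H
      cand$W <- cand$W + step * g$W
      diag(cand$W) <- 0
      ll_new <- lnp_loglik_full(cand, spikes, stim)
      if (is.finite(ll_new) && ll_new >= ll) break
      step <- step / 2
      if (step < 1e-14) break
    }
    if (!is.finite(ll_new) || ll_new < ll) break
    improved <- ll_new - ll
    params <- cand
    ll <- ll_new
    step <- step * 1.2
    if (improved < tol * (abs(ll) + 1)) break
  }
  list(params = params, loglik = ll)
}

# full-data versions reuse the window machinery on the entire matrix
lnp_loglik_full <- function(params, spikes, stim) {
  d <- lnp_window_design(spikes, stim)
  eta <- lnp_eta_window(params, d)
  sum(d$y * eta - exp(eta))
}

lnp_gradient_full <- function(params, spikes, stim) {
  lnp_gradient(params, spikes, stim)
}

#' Strongest functional connections of one neuron
#'
#' The `m` coupling weights of largest magnitude in row `i` of `W`,
#' returned as target-neuron indices in descending order of `|W_ij|`
#' (ties broken toward the lower index). With `m` larger than `n - 1`
#' all other neurons are returned (logged when a log is given).
#'
#' @param W n x n coupling matrix.
#' @param i Neuron index (1-based).
#' @param m Number of connections (default 10).
#' @param log Optional [run_log()].
#' @return Integer vector of neuron indices.
#' @export
top_connections <- function(W, i, m = 10L, log = NULL) {
  n <- ncol(W)
  stopifnot(i >= 1L, i <= n)
  if (m > n - 1L) {
    if (!is.null(log)) {
      log_event(log, "<lnp>", "warning",
                sprintf("m=%d exceeds n-1=%d; returning all", m, n - 1L))
    }
    m <- n - 1L
  }
  others <- setdiff(seq_len(n), i)
  mag <- abs(W[i, others])
  others[order(-mag, others)][seq_len(m)]
}

#' @export
print.lnp_params <- function(x, ...) {
  cat(sprintf("<lnp_params: %d neurons, window %d frames, step %g>\n",
              x$n, x$window_len, x$step))
  invisible(x)
}
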