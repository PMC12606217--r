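# ---- 24 x 24 toroidal binocular-stimulus grid ------------------------------
#
# Stimuli are (left-eye angle, right-eye angle) pairs at 15-degree spacing,
# 24 angles per eye, 576 combinations. Both axes wrap: the grid is a torus.
# Linear indices are 1-based and column-major over a 24 x 24 matrix whose
# row is the left-eye angle index and column the right-eye angle index
# (0-based angle indices; angle = 15 * index degrees).

GRID_N <- 24L

#' Grid index from 0-based angle indices
#' @param il,ir Left/right-eye angle indices in 0..23.
#' @return 1-based linear grid index in 1..576.
#' @export
grid_index <- function(il, ir) {
  stopifnot(all(il >= 0 & il < GRID_N), all(ir >= 0 & ir < GRID_N))
  as.integer(ir) * GRID_N + as.integer(il) + 1L
}

#' 0-based angle indices from a grid index
#' @param idx 1-based linear grid index.
#' @return Two-column matrix (il, ir) of 0-based angle indices.
#' @export
grid_coords <- function(idx) {
  idx0 <- as.integer(idx) - 1L
  cbind(il = idx0 %% GRID_N, ir = idx0 %/% GRID_N)
}

#' Stimulus angles (degrees) for a grid index
#' @param idx 1-based linear grid index.
#' @return Two-column matrix (angle_left, angle_right) in degrees.
#' @export
grid_angles <- function(idx) {
  co <- grid_coords(idx)
  cbind(angle_left = 15 * co[, 1], angle_right = 15 * co[, 2])
}

torus_axis_dist <- function(d, n = GRID_N) {
  ad <- abs(d)
  pmin(ad, n - ad)
}

#' Toroidal distance between two grid points
#'
#' Euclidean distance in grid-step units with circular boundary conditions
#' on both axes: each axis contributes `min(|delta|, 24 - |delta|)`.
#'
#' @param p,q Grid points: 1-based linear indices, or length-2 vectors of
#'   0-based (il, ir) angle indices.
#' @return Non-negative distance in grid steps.
#' @export
peak_distance <- function(p, q) {
  as_co <- function(z) {
    if (length(z) == 1L) drop(grid_coords(z)) else as.numeric(z)
  }
  a <- as_co(p)
  b <- as_co(q)
  sqrt(sum(torus_axis_dist(a - b)^2))
}

# ---- toroidal RBF kernel ---------------------------------------------------

kernel_cache <- new.env(parent = emptyenv())

#' Toroidal RBF kernel for the stimulus grid
#'
#' Squared-exponential kernel over grid coordinates normalized to `[0, 1)`
#' (spacing 1/24) with per-axis circular distance. The full 576 x 576 grid
#' kernel matrix is computed once per (length scale, signal variance) pair
#' and cached.
#'
#' @param length_scale Kernel length scale on the normalized torus. The
#'   default `3/24` corresponds to 3 grid steps, the middle of the range
#'   of tuning widths the surfaces are expected to have.
#' @param signal_var Prior (signal) variance (default 1).
#' @param noise_var Observation-noise variance; `NULL` (default) defers to
#'   [gp_fit()]'s data-driven default.
#' @return A `stim_kernel`: the parameters plus the precomputed grid
#'   matrix `K`.
#' @export
stim_kernel <- function(length_scale = 3 / 24, signal_var = 1,
                        noise_var = NULL) {
  stopifnot(length_scale > 0, signal_var > 0)
  key <- sprintf("%.12g|%.12g", length_scale, signal_var)
  K <- kernel_cache[[key]]
  if (is.null(K)) {
    co <- grid_coords(seq_len(GRID_N^2)) / GRID_N
    d1 <- torus_axis_dist(outer(co[, 1], co[, 1], "-"), n = 1)
    d2 <- torus_axis_dist(outer(co[, 2], co[, 2], "-"), n = 1)
    K <- signal_var * exp(-(d1^2 + d2^2) / (2 * length_scale^2))
    kernel_cache[[key]] <- K
  }
  structure(list(length_scale = length_scale, signal_var = signal_var,
                 noise_var = noise_var, K = K),
            class = "stim_kernel")
}

#' Exact GP regression over the stimulus grid
#'
#' Fits a Gaussian-process posterior over all 576 grid points from
#' (grid index, response) observations, using the toroidal RBF kernel and
#' the standard dense-solve equations. Repeated observations at one grid
#' point are handled natively (aggregated to their mean with noise variance
#' scaled by the repeat count, which is algebraically identical to the
#' naive solve with one row per observation).
#'
#' @param observations Data frame or list with elements/columns `idx`
#'   (1-based grid index) and `y` (response). May be empty.
#' @param kernel A [stim_kernel()].
#' @return A `gp_posterior`: `f` and `sigma` (24 x 24 matrices of posterior
#'   mean and sd), `observations`, `kernel`, `noise_var`.
#' @export
gp_fit <- function(observations, kernel = stim_kernel()) {
  idx <- as.integer(observations$idx %||% integer(0))
  y <- as.numeric(observations$y %||% numeric(0))
  stopifnot(length(idx) == length(y))
  G <- GRID_N^2
  prior_sd <- sqrt(kernel$signal_var)
  if (length(idx) == 0L) {
    return(structure(
      list(f = matrix(0, GRID_N, GRID_N),
           sigma = matrix(prior_sd, GRID_N, GRID_N),
           observations = tibble::tibble(idx = integer(0), y = numeric(0)),
           kernel = kernel, noise_var = kernel$noise_var %||% 1e-6),
      class = "gp_posterior"
    ))
  }
  noise <- kernel$noise_var
  if (is.null(noise)) {
    # trial-to-trial noise estimated from replicate presentations at the
    # same grid point (pooled within-point variance); without replicates
    # fall back to a fraction of the overall response variance
    reps <- split(y, idx)
    reps <- reps[vapply(reps, length, integer(1)) >= 2L]
    if (length(reps) > 0L) {
      ss <- sum(vapply(reps, function(v) sum((v - mean(v))^2), numeric(1)))
      df <- sum(vapply(reps, length, integer(1))) - length(reps)
      noise <- max(ss / df, 1e-6)
    } else {
      noise <- max(0.1 * stats::var(y), 1e-6)
    }
    if (!is.finite(noise)) noise <- 1e-6
  }
  if (noise <= 0 && anyDuplicated(idx)) {
    stop("singular GP system: repeated observations with zero noise; set a noise floor",
         call. = FALSE)
  }
  uidx <- sort(unique(idx))
  m <- vapply(uidx, function(u) sum(idx == u), numeric(1))
  ybar <- vapply(uidx, function(u) mean(y[idx == u]), numeric(1))
  Koo <- kernel$K[uidx, uidx, drop = FALSE] + diag(noise / m,
                                                   length(uidx))
  ch <- NULL
  for (jit in c(0, 1e-8, 1e-6, 1e-4) * kernel$signal_var) {
    ch <- tryCatch(chol(Koo + diag(jit, length(uidx))),
                   error = function(e) NULL)
    if (!is.null(ch)) break
  }
  if (is.null(ch)) {
    stop("singular GP system; increase the noise floor", call. = FALSE)
  }
  Kstar <- kernel$K[uidx, , drop = FALSE]          # m x 576
  alpha <- backsolve(ch, backsolve(ch, ybar, transpose = TRUE))
  f <- drop(crossprod(Kstar, alpha))
  V <- backsolve(ch, Kstar, transpose = TRUE)
  s2 <- pmax(kernel$signal_var - colSums(V^2), 0)
  structure(
    list(f = matrix(f, GRID_N, GRID_N),
         sigma = matrix(sqrt(s2), GRID_N, GRID_N),
         observations = tibble::tibble(idx = idx, y = y),
         kernel = kernel, noise_var = noise),
    class = "gp_posterior"
  )
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior: %d observations, peak mean %.3f at index %d>\n",
              nrow(x$observations), max(x$f), which.max(x$f)))
  invisible(x)
}

# ---- deterministic side RNG (repeat-cap fallback etc.) ---------------------

#' Self-contained pseudorandom stream
#'
#' A small RNG object carrying its own state so adaptive-design draws are
#' reproducible (default seed 1337) without disturbing the session RNG.
#'
#' @param seed Integer seed.
#' @return A `side_rng` with methods `$draw_index(n)` (uniform integer in
#'   1..n) and `$runif(k)`.
#' @export
side_rng <- function(seed = 1337L) {
  env <- new.env(parent = emptyenv())
  with_state <- function(fn) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    if (is.null(env$state)) set.seed(seed) else {
      assign(".Random.seed", env$state, globalenv())
    }
    out <- fn()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    out
  }
  structure(
    list(
      draw_index = function(n) with_state(function() sample.int(n, 1L)),
      runif = function(k = 1L) with_state(function() stats::runif(k)),
      permute = function(x) with_state(function() sample(x))
    ),
    class = "side_rng"
  )
}

# ---- acquisition and stopping ----------------------------------------------

#' Upper-confidence-bound stimulus selection
#'
#' Returns the grid index maximizing `f + kappa * sigma` (ties to the
#' lowest linear index). If that candidate has already been sampled more
#' than `repeat_cap` times for this neuron, a uniformly random grid index
#' is returned instead, drawn from `rng`.
#'
#' @param post A `gp_posterior`.
#' @param kappa Exploration weight (default 2).
#' @param sample_counts Length-576 integer vector of per-point sample
#'   counts for the neuron being optimized.
#' @param rng A [side_rng()] used for the random fallback.
#' @param repeat_cap Samples allowed at one point before the fallback
#'   (default 5).
#' @return 1-based grid index.
#' @export
ucb_select <- function(post, kappa = 2, sample_counts = NULL, rng = NULL,
                       repeat_cap = 5L) {
  score <- as.numeric(post$f) + kappa * as.numeric(post$sigma)
  cand <- which.max(score)
  if (!is.null(sample_counts) && sample_counts[cand] > repeat_cap) {
    if (is.null(rng)) rng <- side_rng()
    return(rng$draw_index(GRID_N^2))
  }
  cand
}

#' Expected improvement over the grid
#'
#' Standard closed form `EI = s (z Phi(z) + phi(z))`, `z = (f - best) / s`,
#' with `EI = 0` wherever the posterior sd is 0.
#'
#' @param post A `gp_posterior`.
#' @param best_observed Best (largest) observed response.
#' @return Length-576 numeric vector.
#' @export
expected_improvement <- function(post, best_observed) {
  f <- as.numeric(post$f)
  s <- as.numeric(post$sigma)
  z <- (f - best_observed) / s
  ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
  ei[s <= 0] <- 0
  ei
}

#' Expected-improvement stopping rule
#'
#' Stop when the maximum expected improvement over the whole grid drops
#' below `threshold` (default 1e-2).
#'
#' @inheritParams expected_improvement
#' @param threshold EI threshold.
#' @return `TRUE` to stop, else `FALSE`.
#' @export
ei_stop <- function(post, best_observed, threshold = 1e-2) {
  max(expected_improvement(post, best_observed)) < threshold
}
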