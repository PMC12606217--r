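#' Initialize streaming ridge regression
#'
#' Streaming ridge keeps the sufficient statistics `P = lambda I + sum x x'`
#' (k x k) and `C = sum x y'` (k x n) so each datum is seen exactly once;
#' the coefficients solving `P beta = C` are identical to the batch ridge
#' solution on the data streamed so far.
#'
#' @param k Feature dimension (e.g. the proSVD dimension).
#' @param n Target dimension (e.g. number of neural traces).
#' @param lambda Ridge penalty (default 1e-5).
#' @return A `ridge_state`.
#' @export
ridge_init <- function(k, n, lambda = 1e-5) {
  stopifnot(k >= 1, n >= 1, lambda > 0)
  structure(
    list(P = diag(lambda, k), C = matrix(0, k, n),
         lambda = lambda, n_obs = 0L),
    class = "ridge_state"
  )
}

#' Stream one observation into a ridge state
#'
#' @param state A `ridge_state`.
#' @param x Feature k-vector.
#' @param y Target n-vector.
#' @return Updated `ridge_state`.
#' @export
ridge_update <- function(state, x, y) {
  stopifnot(inherits(state, "ridge_state"))
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot_finite(x, "x"); stopifnot_finite(y, "y")
  stopifnot(length(x) == nrow(state$P), length(y) == ncol(state$C))
  state$P <- state$P + tcrossprod(x)
  state$C <- state$C + tcrossprod(x, y)
  state$n_obs <- state$n_obs + 1L
  state
}

#' Current ridge coefficients
#'
#' @param state A `ridge_state`.
#' @return k x n coefficient matrix `beta` with `P beta = C`.
#' @export
ridge_coef <- function(state) {
  solve(state$P, state$C)
}

#' Batch ridge regression (reference solution)
#'
#' Direct dense solve of `(lambda I + X'X) beta = X'Y` used as the offline
#' counterpart of the streaming update.
#'
#' @param X T x k feature matrix (rows are observations).
#' @param Y T x n target matrix.
#' @param lambda Ridge penalty.
#' @return k x n coefficient matrix.
#' @export
ridge_batch <- function(X, Y, lambda = 1e-5) {
  solve(diag(lambda, ncol(X)) + crossprod(X), crossprod(X, Y))
}

#' Project regression coefficients back to pixel space
#'
#' Maps coefficients fit in a proSVD feature basis back onto the original
#' image geometry via `Q beta`, normalized to the top coefficient
#' (maximum absolute entry becomes 1) so weight maps are comparable across
#' targets.
#'
#' @param beta k x n coefficient matrix.
#' @param Q d x k basis (e.g. `prosvd_state$Q`).
#' @param normalize Divide by the maximum absolute entry (default `TRUE`).
#' @return d x n pixel-weight matrix.
#' @export
project_coefficients_to_pixels <- function(beta, Q, normalize = TRUE) {
  stopifnot(ncol(Q) == nrow(beta))
  map <- Q %*% beta
  if (normalize) {
    m <- max(abs(map))
    if (m > 0) map <- map / m
  }
  map
}

#' @export
print.ridge_state <- function(x, ...) {
  cat(sprintf("<ridge_state: k=%d features, n=%d targets, %d obs, lambda=%g>\n",
              nrow(x$P), ncol(x$C), x$n_obs, x$lambda))
  invisible(x)
}
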