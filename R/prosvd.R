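#' Initialize a proSVD subspace tracker
#'
#' proSVD maintains an orthonormal basis `Q` (d x k) tracking the dominant
#' left singular subspace of a growing data matrix, updating one column at a
#' time while minimizing rotation of the basis between steps (a procrustean
#' alignment), so that individual basis vectors are stable and
#' interpretable during an experiment. Initialization takes a first block
#' of `l >= k` columns and seeds `Q` with its top-k left singular vectors.
#'
#' @param first_block d x l numeric matrix (columns are the first samples).
#' @param k Target dimension.
#' @return A `prosvd_state`: `Q` (d x k, orthonormal columns), `B` (k x k
#'   internal singular-structure accumulator), `k`, `seen`.
#' @export
prosvd_init <- function(first_block, k) {
  stopifnot(is.matrix(first_block))
  d <- nrow(first_block)
  l <- ncol(first_block)
  if (l < k) stop("initial block needs at least k columns", call. = FALSE)
  if (k < 1L || k > d) stop("require 1 <= k <= d", call. = FALSE)
  sv <- svd(first_block, nu = min(d, l), nv = 0)
  if (sum(sv$d > max(d, l) * max(sv$d) * 1e-12) < k || max(sv$d) == 0) {
    stop(sprintf("initial block has rank < k = %d", k), call. = FALSE)
  }
  structure(
    list(
      Q = sv$u[, seq_len(k), drop = FALSE],
      B = diag(sv$d[seq_len(k)], k),
      k = k,
      seen = l
    ),
    class = "prosvd_state"
  )
}

#' Stream one sample into a proSVD state
#'
#' Expands the basis with the component of `x` orthogonal to `Q`, takes the
#' SVD of the small (k+1) x (k+1) core, truncates back to k dimensions, and
#' rotates the truncated basis to be as close as possible to the previous
#' `Q` (orthogonal procrustes), keeping basis vectors from spinning while
#' still tracking the top-k subspace. A sample already in `span(Q)` leaves
#' `Q` unchanged.
#'
#' @param state A `prosvd_state`.
#' @param x New d-vector (one sample/frame).
#' @return Updated `prosvd_state`.
#' @export
prosvd_update <- function(state, x) {
  stopifnot(inherits(state, "prosvd_state"))
  x <- as.numeric(x)
  if (length(x) != nrow(state$Q)) {
    stop("dimension mismatch: x must have length d", call. = FALSE)
  }
  stopifnot_finite(x, "x")
  Q <- state$Q
  k <- state$k
  r <- drop(crossprod(Q, x))
  e <- x - Q %*% r
  rho <- sqrt(sum(e^2))
  xnorm <- sqrt(sum(x^2))
  if (rho <= 1e-12 * max(xnorm, 1)) {
    # in-span sample: no basis rotation; fold energy into B
    B1 <- cbind(state$B, r)
    sv <- svd(B1, nu = k, nv = 0)
    state$B <- diag(sv$d[seq_len(k)], k)
    state$seen <- state$seen + 1L
    return(state)
  }
  qh <- e / rho
  B1 <- rbind(cbind(state$B, r), c(numeric(k), rho))   # (k+1) x (k+1)
  sv <- svd(B1, nu = k + 1L, nv = 0)
  U1 <- sv$u[, seq_len(k), drop = FALSE]
  # procrustes: rotate the truncated basis toward the previous Q.
  # Q^T [Q qh] U1 = U1[1:k, ], so align via the polar factor of U1's top block
  M <- t(U1[seq_len(k), , drop = FALSE])               # k x k
  pm <- svd(M)
  G <- pm$u %*% t(pm$v)
  Qnew <- cbind(Q, qh) %*% U1 %*% G
  state$Q <- Qnew
  state$B <- t(G) %*% diag(sv$d[seq_len(k)], k)
  state$seen <- state$seen + 1L
  state
}

#' Project samples onto a proSVD basis
#'
#' @param state A `prosvd_state`.
#' @param x d-vector or d x m matrix of samples.
#' @return k-vector or k x m matrix of coordinates in the tracked basis.
#' @export
prosvd_project <- function(state, x) {
  crossprod(state$Q, x)
}

#' Largest principal angle between two subspaces
#'
#' Numerical diagnostic comparing a tracked basis to a reference basis
#' (both with orthonormal columns).
#'
#' @param Q1,Q2 Matrices with orthonormal columns, same shape.
#' @return Largest principal angle in radians.
#' @export
principal_angle <- function(Q1, Q2) {
  s <- svd(crossprod(Q1, Q2), nu = 0, nv = 0)$d
  acos(min(1, max(0, min(s))))
}

#' @export
print.prosvd_state <- function(x, ...) {
  cat(sprintf("<prosvd_state: d=%d, k=%d, %d samples seen>\n",
              nrow(x$Q), x$k, x$seen))
  invisible(x)
}
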