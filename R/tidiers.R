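#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a GP tuning-surface posterior
#'
#' @param x A `gp_posterior`.
#' @param ... Unused.
#' @return Tibble: `idx`, `angle_left`, `angle_right`, `mean`, `sd`.
#' @method tidy gp_posterior
#' @export
tidy.gp_posterior <- function(x, ...) {
  ang <- grid_angles(seq_len(GRID_N^2))
  tibble::tibble(
    idx = seq_len(GRID_N^2),
    angle_left = ang[, 1], angle_right = ang[, 2],
    mean = as.numeric(x$f), sd = as.numeric(x$sigma)
  )
}

#' @method glance gp_posterior
#' @export
glance.gp_posterior <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$observations),
    peak_idx = which.max(x$f),
    peak_mean = max(x$f),
    max_sd = max(x$sigma),
    noise_var = x$noise_var
  )
}

#' @method tidy ridge_state
#' @export
tidy.ridge_state <- function(x, ...) {
  beta <- ridge_coef(x)
  tibble::tibble(
    feature = rep(seq_len(nrow(beta)), ncol(beta)),
    target = rep(seq_len(ncol(beta)), each = nrow(beta)),
    estimate = as.numeric(beta)
  )
}

#' @method glance ridge_state
#' @export
glance.ridge_state <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, lambda = x$lambda,
                 k = nrow(x$P), n_targets = ncol(x$C))
}

#' @method tidy lnp_params
#' @export
tidy.lnp_params <- function(x, ...) {
  n <- x$n
  tibble::tibble(
    term = c(rep("baseline", n), rep("stimulus", n * 8),
             rep("history", n * 4), rep("coupling", n * n)),
    neuron = c(seq_len(n), rep(seq_len(n), 8), rep(seq_len(n), 4),
               rep(seq_len(n), n)),
    index = c(rep(NA_integer_, n), rep(seq_len(8), each = n),
              rep(seq_len(4), each = n), rep(seq_len(n), each = n)),
    estimate = c(x$b, as.numeric(x$K), as.numeric(x$H), as.numeric(x$W))
  )
}

#' @method glance lnp_params
#' @export
glance.lnp_params <- function(x, ...) {
  tibble::tibble(n_neurons = x$n, window = x$window_len, step = x$step,
                 mean_baseline_rate = mean(exp(x$b)))
}

#' @method glance bw_state
#' @export
glance.bw_state <- function(x, ...) {
  tibble::tibble(n_tiles = x$N, dims = x$k, points_seen = x$t,
                 entropy_bits = bw_entropy(x), teleports = x$n_teleports)
}

#' @method glance prosvd_state
#' @export
glance.prosvd_state <- function(x, ...) {
  tibble::tibble(d = nrow(x$Q), k = x$k, seen = x$seen,
                 orthonormality_err = max(abs(crossprod(x$Q) - diag(x$k))))
}

#' Heatmaps of a GP posterior mean and uncertainty
#'
#' @param object A `gp_posterior`.
#' @param ... Unused.
#' @return A ggplot object (mean surface; add `sd` via the `which`
#'   argument).
#' @param which `"mean"` or `"sd"`.
#' @method autoplot gp_posterior
#' @export
autoplot.gp_posterior <- function(object, which = c("mean", "sd"), ...) {
  which <- match.arg(which)
  df <- tidy.gp_posterior(object)
  df$value <- if (which == "mean") df$mean else df$sd
  ggplot2::ggplot(df, ggplot2::aes(x = angle_right,
                                   y = angle_left,
                                   fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = which) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "right-eye angle (deg)", y = "left-eye angle (deg)",
                  title = sprintf("GP posterior %s over the stimulus torus",
                                  which))
}

#' Trace plot of streaming prediction metrics
#'
#' @param object Metrics tibble from [bw_stream()] (columns `step`,
#'   `log_pred`, `entropy`).
#' @param ... Unused.
#' @return A ggplot object with EWMA overlays.
#' @export
plot_bw_metrics <- function(object, ...) {
  ew <- function(v, a = 0.01) {
    out <- v
    for (i in seq_along(v)[-1]) out[i] <- (1 - a) * out[i - 1] + a * v[i]
    out
  }
  df <- rbind(
    data.frame(step = object$step, value = object$log_pred,
               ewma = ew(object$log_pred), metric = "log predictive prob"),
    data.frame(step = object$step, value = object$entropy,
               ewma = ew(object$entropy), metric = "transition entropy (bits)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = step)) +
    ggplot2::geom_line(ggplot2::aes(y = value), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = ewma), linewidth = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "stream step", y = NULL)
}

#' Pixel weight-map image
#'
#' @param map d x 1 (or d x n, first column used) weight map from
#'   [project_coefficients_to_pixels()].
#' @param H,W Image geometry.
#' @return A ggplot heatmap.
#' @export
plot_weight_map <- function(map, H, W) {
  v <- as.numeric(map[, 1])
  df <- data.frame(row = rep(seq_len(H), W), col = rep(seq_len(W), each = H),
                   weight = v)
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row,
                                   fill = weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "regression weights projected to pixels")
}
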