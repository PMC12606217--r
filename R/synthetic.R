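# Synthetic-data generators. Every generator is deterministic under its
# seed and returns the latent ground truth needed to score the estimators,
# so the whole pipeline is testable end to end without any recording.

#' Stimulus protocol specification
#'
#' Defaults emulate the imaging protocol: 8 motion directions at 45-degree
#' spacing, 4.2 s moving / 5.3 s stationary gratings, 3.6 frames/s.
#'
#' @param n_directions Number of directions (default 8).
#' @param moving_s,stationary_s Segment durations in seconds.
#' @param frame_rate_hz Imaging frame rate.
#' @param repetitions Repetitions of each direction.
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(n_directions = 8L, moving_s = 4.2,
                          stationary_s = 5.3, frame_rate_hz = 3.6,
                          repetitions = 3L) {
  stopifnot(moving_s > 0, stationary_s > 0, frame_rate_hz > 0)
  structure(list(n_directions = as.integer(n_directions),
                 moving_s = moving_s, stationary_s = stationary_s,
                 frame_rate_hz = frame_rate_hz,
                 repetitions = as.integer(repetitions)),
            class = "protocol_spec")
}

#' Generate a randomized stimulus protocol
#'
#' Tiles the session with stationary-then-moving trials, one per
#' (direction, repetition), in pseudorandom direction order. Frame indices
#' are `round(time x frame rate)` (1-based).
#'
#' @param spec A [protocol_spec()].
#' @param seed Integer seed.
#' @return Tibble of stimulus events: `angle_left`, `angle_right`
#'   (degrees, whole-field so equal), `onset_frame` (first moving frame),
#'   `moving_frames`, `stationary_frames`.
#' @export
gen_stim_protocol <- function(spec = protocol_spec(), seed = 1L) {
  set.seed(seed)
  dirs <- seq(0, 360 - 360 / spec$n_directions,
              by = 360 / spec$n_directions)
  order <- as.vector(replicate(spec$repetitions, sample(dirs)))
  trial_s <- spec$stationary_s + spec$moving_s
  t_onset <- (seq_along(order) - 1L) * trial_s + spec$stationary_s
  tibble::tibble(
    angle_left = order,
    angle_right = order,
    onset_frame = as.integer(round(t_onset * spec$frame_rate_hz)) + 1L,
    moving_frames = as.integer(round(spec$moving_s * spec$frame_rate_hz)),
    stationary_frames = as.integer(round(spec$stationary_s * spec$frame_rate_hz))
  )
}

#' Total frame count of a protocol
#' @param events Output of [gen_stim_protocol()].
#' @return Number of frames covering all trials plus one trailing
#'   stationary period.
#' @export
protocol_frames <- function(events) {
  max(events$onset_frame + events$moving_frames) +
    max(events$stationary_frames)
}

# stimulus one-hot design: T x 8 indicator of the moving direction
protocol_design <- function(events, T_frames) {
  dirs <- seq(0, 315, by = 45)
  S <- matrix(0, T_frames, 8L)
  for (r in seq_len(nrow(events))) {
    if (events$onset_frame[r] > T_frames) next
    fr <- events$onset_frame[r]:min(T_frames, events$onset_frame[r] +
                                      events$moving_frames[r] - 1L)
    d <- match(events$angle_left[r] %% 360, dirs)
    if (!is.na(d)) S[fr, d] <- 1
  }
  S
}

place_disjoint_disks <- function(n, H, W, radius, max_tries = 2000L) {
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ROIs disjointly; reduce n_rois or radius",
           call. = FALSE)
    }
    c_new <- c(stats::runif(1, radius + 1, H - radius),
               stats::runif(1, radius + 1, W - radius))
    if (placed == 0L ||
        all(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                          matrix(c_new, placed, 2, byrow = TRUE))^2)) >
            2 * radius + 1)) {
      placed <- placed + 1L
      centers[placed, ] <- c_new
    }
  }
  lapply(seq_len(n), function(i) {
    rr <- round(centers[i, 1]); cc <- round(centers[i, 2])
    g <- expand.grid(row = (rr - radius):(rr + radius),
                     col = (cc - radius):(cc + radius))
    g <- g[(g$row - rr)^2 + (g$col - cc)^2 <= radius^2, ]
    list(id = i, pixels = as.matrix(g), center = c(x = cc, y = rr))
  })
}

#' Generate a synthetic calcium movie with known ROIs and spikes
#'
#' Places disjoint disk ROIs, draws per-ROI Poisson spike trains whose
#' rates are modulated by each ROI's direction tuning and the stimulus
#' protocol, convolves spikes with a single-exponential calcium kernel
#' (GCaMP6s-like decay), and paints frames with optional Gaussian pixel
#' noise.
#'
#' @param n_rois Number of ROIs.
#' @param events Protocol from [gen_stim_protocol()].
#' @param T_frames Movie length (default: covers the protocol).
#' @param H,W Frame size in pixels.
#' @param roi_radius ROI disk radius in pixels.
#' @param decay_tau_frames Calcium decay time constant (default 7 frames,
#'   GCaMP6s-like at 3.6 Hz).
#' @param base_rate Baseline spike rate per frame.
#' @param tuned_rate Added rate at the preferred direction during motion.
#' @param tuning_width_deg Wrapped-Gaussian tuning width.
#' @param noise_sd Pixel noise sd (0 for noise-free construction checks).
#' @param seed Integer seed.
#' @return List: `movie` (T x H x W array), `masks`, `spikes` (T x n),
#'   `fluor` (T x n noise-free ROI signals), `pref_dirs` (degrees),
#'   `events`.
#' @export
gen_calcium_movie <- function(n_rois = 6L, events = gen_stim_protocol(),
                              T_frames = NULL, H = 48L, W = 48L,
                              roi_radius = 3L, decay_tau_frames = 7,
                              base_rate = 0.05, tuned_rate = 1.2,
                              tuning_width_deg = 45, noise_sd = 0.02,
                              seed = 1L) {
  set.seed(seed)
  T_frames <- T_frames %||% protocol_frames(events)
  masks <- place_disjoint_disks(n_rois, H, W, roi_radius)
  pref <- sample(seq(0, 315, by = 45), n_rois, replace = TRUE)
  S <- protocol_design(events, T_frames)
  dirs <- seq(0, 315, by = 45)
  rates <- matrix(base_rate, T_frames, n_rois)
  for (i in seq_len(n_rois)) {
    dd <- pmin(abs(dirs - pref[i]), 360 - abs(dirs - pref[i]))
    gain <- tuned_rate * exp(-dd^2 / (2 * tuning_width_deg^2))
    rates[, i] <- rates[, i] + drop(S %*% gain)
  }
  spikes <- matrix(stats::rpois(T_frames * n_rois, rates), T_frames, n_rois)
  # exponential calcium kernel applied as a recursive (AR-1) filter
  fluor <- apply(spikes, 2, function(s) {
    as.numeric(stats::filter(s, exp(-1 / decay_tau_frames),
                             method = "recursive"))
  })
  movie <- array(if (noise_sd > 0) {
    stats::rnorm(T_frames * H * W, sd = noise_sd)
  } else 0, dim = c(T_frames, H, W))
  for (i in seq_len(n_rois)) {
    px <- masks[[i]]$pixels
    for (p in seq_len(nrow(px))) {
      movie[, px[p, 1], px[p, 2]] <- movie[, px[p, 1], px[p, 2]] + fluor[, i]
    }
  }
  list(movie = movie, masks = masks, spikes = spikes, fluor = fluor,
       pref_dirs = pref, events = events)
}

#' Wrapped-Gaussian tuning surface on the stimulus torus
#'
#' A unimodal bump on the 24 x 24 toroidal grid: amplitude 1, width drawn
#' in \[2, 4\] grid steps, random peak, optional baseline. The returned
#' `respond` closure adds Gaussian trial noise (sd = `noise_sd` x
#' amplitude, drawn from the session RNG).
#'
#' @param seed Integer seed.
#' @param width Bump width in grid steps; default drawn uniformly in
#'   \[2, 4\].
#' @param amplitude Bump amplitude (default 1).
#' @param baseline Added constant (default 0).
#' @param noise_sd Trial noise sd as a fraction of amplitude (default 0.2).
#' @param peak_idx Optional fixed peak (1-based grid index) for
#'   shared-peak populations.
#' @return List: `surface` (24 x 24), `peak_idx`, `width`, `respond(idx)`.
#' @export
gen_tuning_surface <- function(seed = 1L, width = NULL, amplitude = 1,
                               baseline = 0, noise_sd = 0.2,
                               peak_idx = NULL) {
  set.seed(seed)
  width <- width %||% stats::runif(1, 2, 4)
  peak_idx <- peak_idx %||% sample.int(GRID_N^2, 1L)
  pc <- drop(grid_coords(peak_idx))
  co <- grid_coords(seq_len(GRID_N^2))
  d2 <- torus_axis_dist(co[, 1] - pc[1])^2 + torus_axis_dist(co[, 2] - pc[2])^2
  surface <- matrix(baseline + amplitude * exp(-d2 / (2 * width^2)),
                    GRID_N, GRID_N)
  list(
    surface = surface, peak_idx = as.integer(peak_idx), width = width,
    respond = function(idx) {
      surface[idx] + stats::rnorm(length(idx), sd = noise_sd * amplitude)
    }
  )
}

#' Population of tuned neurons with a shared response function
#'
#' @param n Number of neurons.
#' @param seed Integer seed.
#' @param shared_peak_groups Optional integer: neurons are split into this
#'   many groups sharing a tuning peak (for population-sharing tests).
#' @param ... Passed to [gen_tuning_surface()].
#' @return List: `surfaces` (24 x 24 x n array), `peaks` (length n),
#'   `respond(idx)` returning all n noisy responses to one presentation.
#' @export
gen_tuning_population <- function(n, seed = 1L, shared_peak_groups = NULL,
                                  noise_sd = 0.2, ...) {
  set.seed(seed)
  peak_pool <- if (!is.null(shared_peak_groups)) {
    sample.int(GRID_N^2, shared_peak_groups)
  } else NULL
  surfaces <- array(0, dim = c(GRID_N, GRID_N, n))
  peaks <- integer(n)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    pk <- if (is.null(peak_pool)) NULL else {
      peak_pool[((i - 1L) %% length(peak_pool)) + 1L]
    }
    ts <- gen_tuning_surface(seed = derive_seed(seed, i), noise_sd = noise_sd,
                             peak_idx = pk, ...)
    surfaces[, , i] <- ts$surface
    peaks[i] <- ts$peak_idx
    widths[i] <- ts$width
  }
  amp <- 1
  list(
    surfaces = surfaces, peaks = peaks, widths = widths,
    respond = function(idx) {
      surfaces[cbind(rep(grid_coords(idx)[, 1] + 1L, n),
                     rep(grid_coords(idx)[, 2] + 1L, n),
                     seq_len(n))] +
        stats::rnorm(n, sd = noise_sd * amp)
    }
  )
}

#' Random LNP ground-truth parameters
#'
#' A realistic population: modest baseline rates, one-hot direction
#' tuning, weakly suppressive self-history, and sparse coupling scaled to
#' a safe spectral radius.
#'
#' @param n Number of neurons.
#' @param seed Integer seed.
#' @param b_mean Baseline log-rate (default `log(0.4)` spikes/frame).
#' @param k_gain Stimulus weight at the preferred direction.
#' @param coupling_density Fraction of nonzero off-diagonal couplings.
#' @param coupling_radius Target spectral radius of `|W|` (< 0.9).
#' @return An [lnp_params()] object.
#' @export
gen_lnp_params <- function(n, seed = 1L, b_mean = log(0.4), k_gain = 0.8,
                           coupling_density = 0.25, coupling_radius = 0.5) {
  set.seed(seed)
  b <- b_mean + stats::rnorm(n, sd = 0.1)
  K <- matrix(0, n, 8)
  K[cbind(seq_len(n), sample.int(8, n, replace = TRUE))] <- k_gain
  H <- matrix(rep(c(-0.3, -0.15, -0.05, 0), each = n), n, 4) +
    matrix(stats::rnorm(n * 4, sd = 0.02), n, 4)
  W <- matrix(stats::rnorm(n * n, sd = 1), n, n) *
    matrix(stats::runif(n * n) < coupling_density, n, n)
  diag(W) <- 0
  sr <- max(abs(eigen(abs(W), only.values = TRUE)$values))
  if (sr > 0) W <- W * (coupling_radius / sr)
  lnp_params(n, b = b, K = K, H = H, W = W)
}

#' Simulate spikes from an LNP population
#'
#' Iterates the rate equation frame by frame and draws Poisson counts.
#' Diverging rates (mean > 100 spikes/frame) abort with advice to reduce
#' the weights.
#'
#' @param params True [lnp_params()].
#' @param events Protocol from [gen_stim_protocol()].
#' @param T_frames Number of frames (default: protocol length).
#' @param seed Integer seed.
#' @return List: `spikes` (T x n), `stim` (T x 8), `params`.
#' @export
gen_lnp_population <- function(params, events = NULL, T_frames = NULL,
                               seed = 1L) {
  sr <- max(abs(eigen(abs(params$W), only.values = TRUE)$values))
  if (sr >= 0.9) {
    stop("spectral radius of |W| must be < 0.9 for stable simulation",
         call. = FALSE)
  }
  set.seed(seed)
  events <- events %||% gen_stim_protocol(seed = derive_seed(seed, 7L))
  T_frames <- T_frames %||% protocol_frames(events)
  S <- protocol_design(events, T_frames)
  n <- params$n
  y <- matrix(0L, T_frames, n)
  hist4 <- matrix(0, n, 4)
  y_prev <- numeric(n)
  for (t in seq_len(T_frames)) {
    lam <- lnp_rate(params, S[t, ], hist4, y_prev)
    if (mean(lam) > 100) {
      stop("diverging rates in LNP simulation; reduce coupling/stimulus weights",
           call. = FALSE)
    }
    y[t, ] <- stats::rpois(n, lam)
    hist4 <- cbind(y[t, ], hist4[, 1:3])
    y_prev <- y[t, ]
  }
  list(spikes = y, stim = S, params = params)
}

#' Paired behavior-video and neural-trace streams
#'
#' Low-rank video: spatially localized loadings times smooth latent time
#' courses, plus noise; neural traces are a linear readout `B' z_t` of the
#' same latents plus noise. The loading patches are recorded so weight
#' maps projected back to pixels can be scored against ground truth.
#'
#' @param H,W Frame size.
#' @param rank Latent dimension.
#' @param n_neurons Number of neural traces.
#' @param T_frames Stream length.
#' @param true_B Optional rank x n readout (default random).
#' @param noise Video/trace noise sd.
#' @param seed Integer seed.
#' @return List: `frames` (d x T with d = H*W, columns are vectorized
#'   frames), `traces` (n x T), `latents` (rank x T), `loadings`
#'   (d x rank), `true_B`, `patch_pixels` (list of linear pixel indices
#'   per component), `H`, `W`.
#' @export
gen_behavior_neural_pair <- function(H = 24L, W = 32L, rank = 3L,
                                     n_neurons = 10L, T_frames = 400L,
                                     true_B = NULL, noise = 0.01,
                                     seed = 1L) {
  stopifnot(rank <= min(H * W, T_frames))
  set.seed(seed)
  d <- H * W
  loadings <- matrix(0, d, rank)
  patch_pixels <- vector("list", rank)
  for (r in seq_len(rank)) {
    cr <- stats::runif(1, 5, H - 4)
    cc <- stats::runif(1, 5, W - 4)
    rows <- matrix(rep(seq_len(H), W), H, W)
    cols <- matrix(rep(seq_len(W), each = H), H, W)
    bump <- exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * 3^2))
    loadings[, r] <- as.numeric(bump)
    patch_pixels[[r]] <- which(as.numeric(bump) > 0.3)
  }
  loadings <- qr.Q(qr(loadings)) * rep(seq(rank, 1), each = d)
  # smooth latents: randomly phased sinusoids with distinct frequencies
  tt <- seq_len(T_frames)
  latents <- t(vapply(seq_len(rank), function(r) {
    sin(2 * pi * tt / (40 + 17 * r) + stats::runif(1, 0, 2 * pi))
  }, numeric(T_frames)))
  true_B <- true_B %||% matrix(stats::rnorm(rank * n_neurons), rank, n_neurons)
  frames <- loadings %*% latents +
    matrix(stats::rnorm(d * T_frames, sd = noise), d, T_frames)
  traces <- t(true_B) %*% latents +
    matrix(stats::rnorm(n_neurons * T_frames, sd = noise), n_neurons, T_frames)
  list(frames = frames, traces = traces, latents = latents,
       loadings = loadings, true_B = true_B, patch_pixels = patch_pixels,
       H = H, W = W)
}

#' Noisy limit-cycle trajectory in higher dimensions
#'
#' A harmonic limit cycle (fixed period) embedded in `dims` dimensions by
#' a random rotation, with additive Gaussian noise, standing in for
#' low-dimensional neural trajectories.
#'
#' @param T_steps Number of samples.
#' @param dims Embedding dimension (>= 2).
#' @param period Cycle period in samples (default 100).
#' @param noise_sd Additive noise sd (default 0.05; the cycle radius is 1).
#' @param seed Integer seed.
#' @return List: `X` (T x dims), `latents` (T x 2 noise-free), `period`,
#'   `basis` (dims x 2 embedding).
#' @export
gen_limit_cycle <- function(T_steps = 2000L, dims = 2L, period = 100L,
                            noise_sd = 0.05, seed = 1L) {
  stopifnot(dims >= 2L)
  set.seed(seed)
  th <- 2 * pi * seq_len(T_steps) / period
  Z <- cbind(cos(th), sin(th))
  basis <- qr.Q(qr(matrix(stats::rnorm(dims * 2), dims, 2)))
  X <- Z %*% t(basis) + matrix(stats::rnorm(T_steps * dims, sd = noise_sd),
                               T_steps, dims)
  list(X = X, latents = Z, period = period, basis = basis)
}

#' Photostimulation network with ground-truth coupling
#'
#' Neurons carry positions, direction-selectivity colors, visual tuning
#' peaks, and opsin intensities; stimulating a target evokes responses
#' equal to the target's coupling row plus noise.
#'
#' @param n Number of neurons.
#' @param coupling Optional non-negative n x n matrix with zero diagonal
#'   (default sparse random).
#' @param noise_sd Response noise sd (default 0.02).
#' @param fov Field-of-view width in pixels (x spans `+/- fov/2`).
#' @param seed Integer seed.
#' @return List: `records` (tibble: id, x, y, r, g, b, opsin_intensity,
#'   peak_dir), `coupling`, `respond(target_id)`.
#' @export
gen_photostim_network <- function(n = 20L, coupling = NULL, noise_sd = 0.02,
                                  fov = 256, seed = 1L) {
  set.seed(seed)
  if (is.null(coupling)) {
    coupling <- matrix(stats::runif(n * n) *
                         (stats::runif(n * n) < 0.2), n, n)
    diag(coupling) <- 0
  }
  stopifnot(all(coupling >= 0), all(diag(coupling) == 0))
  peak_dir <- sample(seq(0, 315, by = 45), n, replace = TRUE)
  col <- t(vapply(seq_len(n), function(i) {
    cv <- tuning_curve8()
    cv$mean_response[as.character(peak_dir[i])] <- 1
    cv$trial_counts[as.character(peak_dir[i])] <- 1L
    tuning_to_color(cv)
  }, numeric(3)))
  records <- tibble::tibble(
    id = seq_len(n),
    x = stats::runif(n, -fov / 2, fov / 2),
    y = stats::runif(n, -fov / 2, fov / 2),
    r = col[, 1], g = col[, 2], b = col[, 3],
    opsin_intensity = stats::runif(n, 0, 200),
    peak_dir = peak_dir
  )
  list(
    records = records, coupling = coupling,
    respond = function(target_id) {
      coupling[target_id, ] + stats::rnorm(n, sd = noise_sd)
    }
  )
}
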