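#' Otsu threshold binarization
#'
#' Chooses the intensity threshold maximizing between-class variance over a
#' histogram of the image (exhaustive search over candidate bin edges) and
#' maps pixels strictly above the threshold to 1. Used to binarize imaging
#' planes before Dice-coefficient alignment.
#'
#' @param img Numeric matrix of non-negative intensities.
#' @param n_bins Number of histogram bins (default 256, 8-bit style).
#' @return A list of class `binary_image`: `pixels` (0/1 matrix, same shape)
#'   and `threshold_used`.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  stopifnot(is.matrix(img))
  stopifnot_finite(img, "img")
  rng <- range(img)
  if (rng[1] == rng[2]) {
    stop("degenerate input: constant image has no Otsu threshold", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(img, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)                 # class-0 mass up to bin t
  mu <- cumsum(p * mids)             # class-0 first moment
  mu_t <- mu[n_bins]
  # between-class variance for threshold after bin t (t = 1..n_bins-1)
  w0 <- omega[-n_bins]
  m0 <- mu[-n_bins]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_best <- which.max(sigma_b)
  thr <- breaks[t_best + 1L]
  structure(
    list(pixels = (img > thr) * 1, threshold_used = thr),
    class = "binary_image"
  )
}

#' Sorensen-Dice coefficient of two binary images
#'
#' `2|X intersect Y| / (|X| + |Y|)` counting foreground pixels. Used to score
#' candidate imaging planes against the reference plane captured at
#' experiment start. Two empty masks score 1 by convention (logged as a
#' warning event if a log is supplied).
#'
#' @param a,b Binary images ([otsu_threshold()] output or 0/1 matrices of
#'   equal shape).
#' @param log Optional [run_log()].
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b, log = NULL) {
  pa <- if (inherits(a, "binary_image")) a$pixels else a
  pb <- if (inherits(b, "binary_image")) b$pixels else b
  if (!all(dim(pa) == dim(pb))) {
    stop("shape mismatch between binary images", call. = FALSE)
  }
  na <- sum(pa != 0)
  nb <- sum(pb != 0)
  if (na + nb == 0L) {
    if (!is.null(log)) {
      log_event(log, "<dice>", "warning", "both masks empty; DSC := 1")
    }
    return(1)
  }
  2 * sum(pa != 0 & pb != 0) / (na + nb)
}

#' Select the best-aligned imaging plane
#'
#' Binarizes each candidate plane with an Otsu threshold and returns the
#' index of the plane whose mask best matches the binarized reference image
#' by Dice coefficient. This drives automatic z-drift correction: a small
#' stack is acquired around the current plane (offsets in micrometres) and
#' the stage moves to the winner. Ties go to the smallest absolute offset,
#' then the lower index.
#'
#' @param planes List of intensity matrices.
#' @param target A `binary_image` (the binarized reference).
#' @param offsets_um Numeric vector of per-plane offsets, same length as
#'   `planes` (default symmetric around 0).
#' @return Integer plane index (1-based), with attribute `"dsc"` holding all
#'   scores.
#' @export
select_best_plane <- function(planes, target,
                              offsets_um = seq(-3 * (length(planes) - 1) / 2,
                                               by = 3,
                                               length.out = length(planes))) {
  if (length(planes) == 0L) stop("empty plane stack", call. = FALSE)
  stopifnot(length(offsets_um) == length(planes))
  scores <- vapply(planes, function(p) {
    dice_coefficient(otsu_threshold(p), target)
  }, numeric(1))
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  if (length(cand) > 1L) {
    cand <- cand[order(abs(offsets_um[cand]), cand)]
  }
  structure(cand[1L], dsc = scores)
}

#' Block-mean downsampling
#'
#' Replaces each `factor x factor` block by its mean; trailing rows/columns
#' not filling a block are cropped (with a warning event when a log is
#' given). A 240 x 320 frame at factor 2 becomes 120 x 160.
#'
#' @param img Numeric matrix.
#' @param factor Integer per-axis downsampling factor (>= 1).
#' @param log Optional [run_log()].
#' @return Downsampled matrix.
#' @export
block_downsample <- function(img, factor, log = NULL) {
  stopifnot(is.matrix(img))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(img)
  h <- nrow(img) %/% factor * factor
  w <- ncol(img) %/% factor * factor
  if (h < nrow(img) || w < ncol(img)) {
    if (!is.null(log)) {
      log_event(log, "<downsample>", "warning",
                sprintf("cropped %dx%d to %dx%d before downsampling",
                        nrow(img), ncol(img), h, w))
    }
    img <- img[seq_len(h), seq_len(w), drop = FALSE]
  }
  # average rows within blocks, then columns
  ri <- rep(seq_len(h %/% factor), each = factor)
  ci <- rep(seq_len(w %/% factor), each = factor)
  out <- t(rowsum(t(rowsum(img, ri)), ci)) / factor^2
  dimnames(out) <- NULL
  out
}

#' Mean fluorescence over ROI masks
#'
#' A deliberately simple trace-extraction stage: the mean frame intensity
#' over each ROI's pixel footprint, in mask order. It stands in for a full
#' online source-extraction algorithm; no deconvolution is performed.
#'
#' @param frame Intensity matrix.
#' @param masks List of ROI masks, each a list with `pixels` (n x 2 matrix
#'   of (row, col), 1-based), `id`, and optionally `center`.
#' @return Numeric vector, one mean per ROI.
#' @export
extract_traces <- function(frame, masks) {
  vapply(masks, function(m) {
    px <- m$pixels
    if (is.null(px) || nrow(px) == 0L) {
      stop(sprintf("ROI %s has an empty mask", m$id %||% "?"), call. = FALSE)
    }
    if (any(px[, 1] < 1L | px[, 1] > nrow(frame) |
            px[, 2] < 1L | px[, 2] > ncol(frame))) {
      stop(sprintf("ROI %s mask out of frame bounds", m$id %||% "?"),
           call. = FALSE)
    }
    mean(frame[px])
  }, numeric(1))
}

#' Bin spike times into counts
#'
#' Half-open bins `[k w, (k+1) w)`; an event exactly on a boundary falls in
#' the later bin. Counts over `[0, t_end)` sum to the number of events in
#' that interval.
#'
#' @param events Sorted non-negative spike times in seconds.
#' @param bin_width Bin width in seconds (e.g. 0.010 for 10 ms bins).
#' @param t_end End of the binned interval in seconds.
#' @return Integer vector of length `ceiling(t_end / bin_width)`.
#' @export
bin_spikes <- function(events, bin_width, t_end) {
  stopifnot(bin_width > 0, t_end > 0)
  if (length(events) > 0 && any(events < 0)) {
    stop("negative spike times", call. = FALSE)
  }
  n_bins <- as.integer(ceiling(t_end / bin_width))
  ev <- events[events < t_end]
  if (length(ev) == 0L) return(integer(n_bins))
  tabulate(floor(ev / bin_width) + 1L, nbins = n_bins)
}

#' Gaussian kernel smoothing of binned counts
#'
#' Convolution with a truncated Gaussian kernel normalized to unit sum,
#' giving a continuous firing-rate estimate from binned spike counts.
#' Boundaries are reflect-padded so the output has the input's length;
#' total mass is conserved on interior bins.
#'
#' @param counts Numeric vector of per-bin counts.
#' @param window Kernel support in bins (default 50, as for 10 ms bins of
#'   electrophysiology data); made odd internally by adding one if needed.
#' @param sigma Kernel standard deviation in bins; defaults to `window / 10`.
#' @return Numeric vector, same length as `counts`.
#' @export
gaussian_smooth <- function(counts, window = 50L, sigma = window / 10) {
  stopifnot(sigma > 0)
  n <- length(counts)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n) stop("window longer than the series", call. = FALSE)
  half <- (window - 1L) %/% 2L
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  padded <- c(rev(counts[seq_len(half)]), counts,
              rev(counts[(n - half + 1L):n]))
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Eight-direction tuning curve
#'
#' Running per-direction mean responses for one neuron, updated one
#' stimulus trial at a time.
#'
#' @return A `tuning_curve8`: `mean_response` and `trial_counts`, both
#'   length 8 and named by direction (0, 45, ..., 315 degrees), plus a
#'   `color` slot filled by [tuning_to_color()].
#' @export
tuning_curve8 <- function() {
  dirs <- seq(0, 315, by = 45)
  structure(
    list(
      mean_response = stats::setNames(numeric(8), dirs),
      trial_counts = stats::setNames(integer(8), dirs),
      color = c(0, 0, 0)
    ),
    class = "tuning_curve8"
  )
}

#' Update a direction-tuning curve from one stimulus trial
#'
#' The trial response is the mean fluorescence over the response window
#' (default 15 frames from stimulus onset) minus the mean over the baseline
#' window (default the 10 frames directly before onset, excluding the onset
#' frame). The running per-direction mean and trial count are updated for
#' the trial's motion direction. Whole-field trials only (both eyes at the
#' same angle); trials with insufficient pre-onset history are skipped with
#' a log event.
#'
#' @param trace Numeric fluorescence series for one ROI (frame-indexed,
#'   1-based).
#' @param event Stimulus event: list with `angle_left`, `angle_right`
#'   (degrees), `onset_frame` (1-based).
#' @param curve A [tuning_curve8()].
#' @param response_frames,baseline_frames Window lengths in frames.
#' @param log Optional [run_log()].
#' @return The updated `tuning_curve8`, with attribute `"last_response"`.
#' @export
update_direction_tuning <- function(trace, event, curve,
                                    response_frames = 15L,
                                    baseline_frames = 10L, log = NULL) {
  stopifnot(inherits(curve, "tuning_curve8"))
  if (event$angle_left != event$angle_right) {
    stop("8-direction curves use whole-field trials (equal angles)",
         call. = FALSE)
  }
  on <- event$onset_frame
  if (on - baseline_frames < 1L || on + response_frames - 1L > length(trace)) {
    if (!is.null(log)) {
      log_event(log, "<tuning>", "warning",
                sprintf("trial at frame %d skipped: insufficient history", on))
    }
    return(curve)
  }
  base <- mean(trace[(on - baseline_frames):(on - 1L)])
  resp <- mean(trace[on:(on + response_frames - 1L)]) - base
  dir <- as.character(event$angle_left %% 360)
  if (!dir %in% names(curve$mean_response)) {
    stop(sprintf("direction %s not on the 45-degree wheel", dir), call. = FALSE)
  }
  n <- curve$trial_counts[dir] + 1L
  curve$mean_response[dir] <- curve$mean_response[dir] +
    (resp - curve$mean_response[dir]) / n
  curve$trial_counts[dir] <- n
  attr(curve, "last_response") <- resp
  curve
}

#' Direction-selectivity color code
#'
#' Maps a tuning curve to an RGB color: hue encodes the preferred direction
#' (circular mean of direction weighted by rectified responses; forward
#' motion maps to green) and brightness encodes the peak response magnitude
#' relative to a population maximum. All-zero curves map to black.
#'
#' @param curve A `tuning_curve8`.
#' @param pop_max Population-wide maximum peak response used to normalize
#'   brightness (default: this curve's own peak).
#' @param forward_deg Which direction (degrees) counts as forward motion,
#'   anchored to green hue (default 0).
#' @return Numeric RGB triple in \[0, 1\].
#' @export
tuning_to_color <- function(curve, pop_max = NULL, forward_deg = 0) {
  r <- pmax(curve$mean_response, 0)
  if (all(r == 0)) return(c(0, 0, 0))
  dirs_deg <- as.numeric(names(curve$mean_response))
  th <- dirs_deg * pi / 180
  z <- sum(r * exp(1i * th))
  pref <- if (Mod(z) < 1e-12) {
    dirs_deg[which.max(r)]          # tie: first maximum by direction index
  } else {
    (Arg(z) * 180 / pi) %% 360
  }
  # hue wheel anchored so forward_deg -> green (hue 1/3)
  hue <- ((pref - forward_deg) / 360 + 1 / 3) %% 1
  peak <- max(r)
  pop_max <- pop_max %||% peak
  val <- if (pop_max > 0) min(1, peak / pop_max) else 0
  as.numeric(grDevices::col2rgb(grDevices::hsv(hue, s = 1, v = val)) / 255)
}
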