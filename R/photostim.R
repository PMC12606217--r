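#' Select a photostimulation target
#'
#' Filters the tracked neurons by horizontal position (relative to the
#' field-of-view center) and functional type, then chooses among
#' opsin-expressing candidates. The functional-type score is the inner
#' product of each neuron's direction-selectivity color array (r, g, b)
#' with `criteria_basis`; the default `[-1, 1, -1]` down-weights red and
#' blue and prefers green, i.e. forward-tuned neurons. Candidates must
#' score positively and have opsin intensity above `intensity_threshold`.
#' Neurons in `exclusions` (e.g. already stimulated) are avoided
#' preferentially but not absolutely: with probability `prefer_new_prob`
#' the choice is restricted to unexcluded candidates when any exist.
#'
#' @param records Data frame with columns `id`, `x` (pixels relative to
#'   FOV center), `r`, `g`, `b` (color array in \[0,1\]),
#'   `opsin_intensity`.
#' @param criteria_basis Length-3 numeric basis for the color inner
#'   product (default `c(-1, 1, -1)`).
#' @param x_range Allowed x interval (default `c(-75, 75)`, exclusive).
#' @param intensity_threshold Minimum opsin intensity (default 50,
#'   exclusive).
#' @param exclusions Ids to avoid (default none).
#' @param mode `"max_intensity"` picks the highest-intensity candidate;
#'   `"random"` picks uniformly among candidates above threshold.
#' @param rng A [side_rng()] used for `"random"` mode and the exclusion
#'   preference draw.
#' @param prefer_new_prob Probability of restricting to unexcluded
#'   candidates when some exist (default 0.9).
#' @return The selected neuron id, or `NA` (with a message) when no
#'   candidate passes the filters.
#' @export
select_photostim_target <- function(records, criteria_basis = c(-1, 1, -1),
                                    x_range = c(-75, 75),
                                    intensity_threshold = 50,
                                    exclusions = integer(0),
                                    mode = c("max_intensity", "random"),
                                    rng = NULL, prefer_new_prob = 0.9) {
  mode <- match.arg(mode)
  stopifnot(nrow(records) > 0)
  score <- records$r * criteria_basis[1] + records$g * criteria_basis[2] +
    records$b * criteria_basis[3]
  ok <- records$x > x_range[1] & records$x < x_range[2] &
    score > 0 & records$opsin_intensity > intensity_threshold
  cand <- records[ok, , drop = FALSE]
  if (nrow(cand) == 0L) {
    message("no photostimulation target passes the filters")
    return(NA_integer_)
  }
  fresh <- !(cand$id %in% exclusions)
  if (any(fresh) && any(!fresh)) {
    rng <- rng %||% side_rng()
    if (rng$runif(1) < prefer_new_prob) cand <- cand[fresh, , drop = FALSE]
  } else if (any(fresh)) {
    cand <- cand[fresh, , drop = FALSE]
  }
  if (mode == "max_intensity") {
    cand$id[which.max(cand$opsin_intensity)]
  } else {
    rng <- rng %||% side_rng()
    cand$id[rng$draw_index(nrow(cand))]
  }
}

#' Run a photostimulation protocol on one target
#'
#' Emits the timed photostimulation events for one target (default 5
#' repetitions spaced 15 s apart, 200-300 ms spiral duration, 1 ms dwell)
#' and scores every neuron's response to each event as the mean
#' fluorescence over the response window minus the mean over the
#' pre-event baseline window (the same 15-frame/10-frame convention used
#' for visual stimuli).
#'
#' @param target List or one-row data frame with `id`, `x`, `y`.
#' @param traces T x n fluorescence matrix covering the protocol.
#' @param frame_rate_hz Imaging frame rate.
#' @param start_frame Frame of the first event onset (1-based); must leave
#'   room for the baseline window.
#' @param repetitions Number of events (default 5).
#' @param spacing_s Seconds between event onsets (default 15).
#' @param duration_ms,dwell_ms Spiral parameters recorded on each event.
#' @param response_frames,baseline_frames Scoring windows in frames.
#' @return List: `events` (tibble: target_id, x, y, repetition, time_s,
#'   onset_frame, duration_ms, dwell_ms), `responses` (repetitions x n
#'   matrix), `mean_response` (length-n).
#' @export
run_photostim_protocol <- function(target, traces, frame_rate_hz = 3.6,
                                   start_frame = 11L, repetitions = 5L,
                                   spacing_s = 15, duration_ms = 250,
                                   dwell_ms = 1, response_frames = 15L,
                                   baseline_frames = 10L) {
  stopifnot(repetitions >= 1L)
  n <- ncol(traces)
  times <- (seq_len(repetitions) - 1L) * spacing_s
  onsets <- start_frame + round(times * frame_rate_hz)
  if (onsets[1] - baseline_frames < 1L ||
      max(onsets) + response_frames - 1L > nrow(traces)) {
    stop("traces do not cover the protocol windows", call. = FALSE)
  }
  resp <- matrix(NA_real_, repetitions, n)
  for (r in seq_len(repetitions)) {
    on <- onsets[r]
    base <- colMeans(traces[(on - baseline_frames):(on - 1L), , drop = FALSE])
    post <- colMeans(traces[on:(on + response_frames - 1L), , drop = FALSE])
    resp[r, ] <- post - base
  }
  events <- tibble::tibble(
    target_id = target$id, x = target$x, y = target$y,
    repetition = seq_len(repetitions), time_s = times,
    onset_frame = onsets, duration_ms = duration_ms, dwell_ms = dwell_ms
  )
  list(events = events, responses = resp, mean_response = colMeans(resp))
}

#' Photostimulation tuning curve of one neuron
#'
#' Groups a neuron's photostimulation-evoked responses by the visual
#' tuning-peak direction of the stimulated target, giving the mean
#' response per direction bin. Bins without any event are `NA` and
#' flagged.
#'
#' @param responses Numeric vector: the neuron's response to each
#'   photostimulation event.
#' @param target_peak_dirs Degrees (on the 45-degree wheel) of each
#'   event's target visual tuning peak; same length as `responses`.
#' @return Tibble: `direction` (0, 45, ..., 315), `mean_response`
#'   (`NA` where empty), `n_events`.
#' @export
compute_photostim_tuning <- function(responses, target_peak_dirs) {
  stopifnot(length(responses) == length(target_peak_dirs))
  dirs <- seq(0, 315, by = 45)
  bin <- (as.numeric(target_peak_dirs) %% 360)
  if (length(bin) > 0 && !all(bin %in% dirs)) {
    stop("target peak directions must lie on the 45-degree wheel", call. = FALSE)
  }
  mean_response <- vapply(dirs, function(d) {
    v <- responses[bin == d]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  n_events <- vapply(dirs, function(d) sum(bin == d), integer(1))
  tibble::tibble(direction = dirs, mean_response = mean_response,
                 n_events = n_events)
}

#' Experiment phase controller
#'
#' One-way switch from the visual-characterization phase to the
#' closed-loop photostimulation phase, taken when the fraction of tracked
#' neurons with at least one trial in every one of the 8 directions
#' reaches the configured threshold. Once switched, later drops in
#' completeness never revert the phase.
#'
#' @param state List with element `phase` (`"characterization"` or
#'   `"photostimulation"`); use `phase_state()` for a fresh one.
#' @param completeness Fraction in \[0, 1\] of fully characterized neurons.
#' @param threshold Switch threshold (default 0.9).
#' @param log Optional [run_log()].
#' @return Updated state list.
#' @export
phase_controller <- function(state, completeness, threshold = 0.9,
                             log = NULL) {
  stopifnot(completeness >= 0, completeness <= 1)
  if (state$phase == "characterization" && completeness >= threshold) {
    state$phase <- "photostimulation"
    if (!is.null(log)) {
      log_event(log, "<phase>", "phase-switch",
                sprintf("characterization -> photostimulation at completeness %.2f",
                        completeness))
    }
  }
  state
}

#' @rdname phase_controller
#' @export
phase_state <- function() list(phase = "characterization")
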