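#' Closed-loop Bayesian-optimization configuration
#'
#' Defaults follow the experiment design: 8 whole-field initial stimuli at
#' 45-degree spacing (same angle to both eyes) presented in random order,
#' UCB acquisition, a random fallback once a point has been sampled more
#' than 5 times for a neuron, an expected-improvement stopping threshold of
#' 1e-2, a 30-stimulus cap per optimization attempt, at most 2 attempts per
#' neuron, and a deterministic side RNG seeded 1337.
#'
#' @param kappa UCB exploration weight.
#' @param ei_threshold EI stopping threshold.
#' @param n_max Maximum stimuli per optimization attempt.
#' @param repeat_cap Per-point repeat cap before random fallback.
#' @param max_attempts Optimization attempts allowed per neuron.
#' @param seed Seed of the side RNG.
#' @return A `bo_config` list.
#' @export
bo_config <- function(kappa = 2, ei_threshold = 1e-2, n_max = 30L,
                      repeat_cap = 5L, max_attempts = 2L, seed = 1337L) {
  stopifnot(kappa >= 0, ei_threshold > 0, n_max >= 1, repeat_cap >= 1)
  structure(list(kappa = kappa, ei_threshold = ei_threshold,
                 n_max = as.integer(n_max), repeat_cap = as.integer(repeat_cap),
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "bo_config")
}

init_stimuli <- function(rng) {
  a <- seq(0L, 21L, by = 3L)        # 8 whole-field angles at 45-degree spacing
  rng$permute(grid_index(a, a))
}

#' Online Bayesian optimization of one neuron's tuning peak
#'
#' Runs the acquire-analyze-update-select cycle for a single neuron:
#' initialize the GP from all responses already in `history` (presenting
#' the 8 whole-field initial stimuli first if the history is empty), then
#' repeat UCB selection, stimulus presentation, and GP update until the
#' expected-improvement stopping rule fires or the stimulus cap is
#' reached. Every presented stimulus is recorded in `history` for this
#' neuron; a population driver (see [bo_population()]) additionally
#' records the simultaneous responses of all other neurons.
#'
#' @param oracle Function `oracle(idx)` returning this neuron's response to
#'   one presentation of grid stimulus `idx` (and performing any
#'   population-level recording as a side effect).
#' @param config A [bo_config()].
#' @param history Optional shared history environment from [bo_history()];
#'   created fresh (single neuron) when `NULL`.
#' @param neuron Neuron id used to address `history`.
#' @param kernel A [stim_kernel()].
#' @param rng A [side_rng()]; defaults to a fresh one seeded from `config`.
#' @return List: `posterior` (final `gp_posterior`), `peak_idx` (argmax of
#'   the posterior mean), `stimuli_used` (presentations made during this
#'   call), `converged` (`TRUE` if EI stopped below threshold).
#' @export
bo_loop <- function(oracle, config = bo_config(), history = NULL,
                    neuron = 1L, kernel = stim_kernel(), rng = NULL) {
  rng <- rng %||% side_rng(config$seed)
  own <- is.null(history)
  if (own) history <- bo_history(1L)
  used <- 0L
  present <- function(idx) {
    y <- oracle(idx)
    history_append(history, neuron, idx, y)
    used <<- used + 1L
    y
  }
  if (length(history$obs_idx[[neuron]]) == 0L) {
    for (idx in init_stimuli(rng)) present(idx)
  }
  post <- NULL
  converged <- FALSE
  repeat {
    obs <- list(idx = history$obs_idx[[neuron]], y = history$obs_y[[neuron]])
    post <- gp_fit(obs, kernel)
    # plug-in incumbent for noisy observations: posterior mean at the best
    # observed point, not the (noise-inflated) best raw response
    best <- max(post$f[unique(obs$idx)])
    if (ei_stop(post, best, config$ei_threshold)) {
      converged <- TRUE
      break
    }
    if (used >= config$n_max) break
    counts <- tabulate(obs$idx, nbins = GRID_N^2)
    idx <- ucb_select(post, config$kappa, counts, rng, config$repeat_cap)
    present(idx)
  }
  list(posterior = post, peak_idx = which.max(post$f),
       stimuli_used = used, converged = converged)
}

#' Shared population response history
#'
#' Stores, per neuron, every (stimulus, response) pair observed so far.
#' Because all neurons are imaged simultaneously, each presented stimulus
#' contributes an observation to every neuron's history, which is what
#' lets later optimizations start nearly (or fully) characterized.
#'
#' @param n_neurons Number of neurons tracked.
#' @return A `bo_history` environment with parallel lists `obs_idx`,
#'   `obs_y`, and a total presentation counter `n_presented`.
#' @export
bo_history <- function(n_neurons) {
  h <- new.env(parent = emptyenv())
  h$obs_idx <- replicate(n_neurons, integer(0), simplify = FALSE)
  h$obs_y <- replicate(n_neurons, numeric(0), simplify = FALSE)
  h$n_presented <- 0L
  h$stim_log <- integer(0)
  class(h) <- "bo_history"
  h
}

#' @rdname bo_history
#' @param h A `bo_history`.
#' @param neuron Neuron id.
#' @param idx Grid index presented.
#' @param y Observed response.
#' @export
history_append <- function(h, neuron, idx, y) {
  h$obs_idx[[neuron]] <- c(h$obs_idx[[neuron]], as.integer(idx))
  h$obs_y[[neuron]] <- c(h$obs_y[[neuron]], as.numeric(y))
  invisible(h)
}

#' Population-wide closed-loop optimization
#'
#' Optimizes neurons one after another with a shared response history:
#' when any stimulus is presented, the simultaneous responses of *all*
#' neurons are appended to their histories, so each optimization leverages
#' everything already shown. Neurons whose attempt hits the stimulus cap
#' without the EI rule firing are re-queued once (two attempts total).
#'
#' @param respond Function `respond(idx)` returning the length-n vector of
#'   all neurons' responses to one presentation of grid stimulus `idx`.
#' @param n_neurons Number of neurons to optimize.
#' @param config A [bo_config()].
#' @param kernel A [stim_kernel()].
#' @return List: `results` (tibble: neuron, peak_idx, stimuli_used,
#'   attempts, converged), `history`, `total_presentations`.
#' @export
bo_population <- function(respond, n_neurons, config = bo_config(),
                          kernel = stim_kernel()) {
  history <- bo_history(n_neurons)
  rng <- side_rng(config$seed)
  peak <- integer(n_neurons)
  used <- integer(n_neurons)
  attempts <- integer(n_neurons)
  converged <- logical(n_neurons)
  run_one <- function(i) {
    oracle <- function(idx) {
      y_all <- respond(idx)
      history$n_presented <- history$n_presented + 1L
      history$stim_log <- c(history$stim_log, as.integer(idx))
      for (j in seq_len(n_neurons)) {
        if (j != i) history_append(history, j, idx, y_all[j])
      }
      y_all[i]
    }
    bo_loop(oracle, config, history, neuron = i, kernel = kernel, rng = rng)
  }
  queue <- seq_len(n_neurons)
  requeued <- integer(0)
  for (pass in seq_len(config$max_attempts)) {
    for (i in queue) {
      res <- tryCatch(run_one(i), error = function(e) e)
      attempts[i] <- attempts[i] + 1L
      if (inherits(res, "error")) {
        converged[i] <- FALSE
        if (attempts[i] < config$max_attempts) requeued <- c(requeued, i)
        next
      }
      peak[i] <- res$peak_idx
      used[i] <- used[i] + res$stimuli_used
      converged[i] <- res$converged
      if (!res$converged && attempts[i] < config$max_attempts) {
        requeued <- c(requeued, i)
      }
    }
    queue <- requeued
    requeued <- integer(0)
    if (length(queue) == 0L) break
  }
  list(
    results = tibble::tibble(neuron = seq_len(n_neurons), peak_idx = peak,
                             stimuli_used = used, attempts = attempts,
                             converged = converged),
    history = history,
    total_presentations = history$n_presented
  )
}
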