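# Demo pipelines: desk-scale end-to-end runs of the five experiment
# archetypes, each wired through the actor framework from a packaged YAML
# config and writing CSV / JSON-lines / PNG artifacts.

demo_names <- c("fig2_lnp", "fig3_behavior", "fig4_bubblewrap",
                "fig5_bo", "fig6_photostim")

register_model_actors <- function() {
  # streams simulated LNP population spikes, one frame per step
  register_actor("lnp_spike_source", actor_impl(
    setup = function(ctx) {
      p <- ctx$params
      tp <- gen_lnp_params(p$n_neurons %||% 15L, seed = p$seed %||% 1L)
      ev <- gen_stim_protocol(protocol_spec(repetitions = p$repetitions %||% 2L),
                              seed = derive_seed(p$seed %||% 1L, 3L))
      sim <- gen_lnp_population(tp, ev, seed = derive_seed(p$seed %||% 1L, 4L))
      ctx$state$spikes <- sim$spikes
      ctx$state$stim <- sim$stim
      ctx$state$true_params <- tp
      ctx$state$t <- 0L
    },
    step = function(ctx, msg) {
      t <- ctx$state$t + 1L
      if (t > nrow(ctx$state$spikes)) return(FALSE)
      ctx$state$t <- t
      key <- ctx$put("spike_frames",
                     list(spikes = ctx$state$spikes[t, ],
                          stim = ctx$state$stim[t, ]))
      ctx$emit(list(key))
      TRUE
    }
  ))

  # online LNP fitting: sliding window, one SGD step per frame
  register_actor("lnp_model", actor_impl(
    setup = function(ctx) {
      ctx$state$params <- NULL
      ctx$state$buf_s <- NULL
      ctx$state$buf_x <- NULL
      ctx$state$trace <- list()
      ctx$state$t <- 0L
    },
    step = function(ctx, msg) {
      pay <- ctx$get(msg$keys[[1]])
      st <- ctx$state
      if (is.null(st$params)) {
        n <- length(pay$spikes)
        st$params <- lnp_params(n, window_len = ctx$params$window %||% 100L)
        st$buf_s <- matrix(0, 0, n)
        st$buf_x <- matrix(0, 0, 8)
      }
      st$t <- st$t + 1L
      wlen <- st$params$window_len
      st$buf_s <- rbind(st$buf_s, pay$spikes)
      st$buf_x <- rbind(st$buf_x, pay$stim)
      if (nrow(st$buf_s) > wlen) {
        keep <- (nrow(st$buf_s) - wlen + 1L):nrow(st$buf_s)
        st$buf_s <- st$buf_s[keep, , drop = FALSE]
        st$buf_x <- st$buf_x[keep, , drop = FALSE]
      }
      if (nrow(st$buf_s) >= 10L) {
        st$params <- lnp_sgd_step(st$params, st$buf_s, st$buf_x)
        if (st$t %% (ctx$params$track_every %||% 25L) == 0L) {
          ll <- lnp_loglik(st$params, st$buf_s, st$buf_x) /
            ((nrow(st$buf_s) - 4L) * st$params$n)
          st$trace[[length(st$trace) + 1L]] <- c(frame = st$t, loglik = ll)
          key <- ctx$put("lnp_metrics", c(frame = st$t, loglik = ll))
          ctx$emit(list(key))
        }
      }
    }
  ))

  # streams paired (behavior frame, neural trace) samples
  register_actor("behavior_pair_source", actor_impl(
    setup = function(ctx) {
      p <- ctx$params
      gt <- gen_behavior_neural_pair(
        H = p$h %||% 24L, W = p$w %||% 32L, rank = p$rank %||% 3L,
        n_neurons = p$n_neurons %||% 10L, T_frames = p$frames %||% 400L,
        noise = p$noise %||% 0.01, seed = p$seed %||% 1L)
      ctx$state$gt <- gt
      ctx$state$t <- 0L
    },
    step = function(ctx, msg) {
      t <- ctx$state$t + 1L
      if (t > ncol(ctx$state$gt$frames)) return(FALSE)
      ctx$state$t <- t
      key <- ctx$put("behavior_pairs",
                     list(frame = ctx$state$gt$frames[, t],
                          trace = ctx$state$gt$traces[, t]))
      ctx$emit(list(key))
      TRUE
    }
  ))

  # proSVD subspace tracking + streaming ridge readout
  register_actor("prosvd_ridge", actor_impl(
    setup = function(ctx) {
      ctx$state$init_buf <- list()
      ctx$state$svd <- NULL
      ctx$state$ridge <- NULL
      ctx$state$basis_change <- numeric(0)
    },
    step = function(ctx, msg) {
      pay <- ctx$get(msg$keys[[1]])
      st <- ctx$state
      k <- ctx$params$k %||% 10L
      init_n <- ctx$params$init_frames %||% 10L
      if (is.null(st$svd)) {
        st$init_buf[[length(st$init_buf) + 1L]] <- pay$frame
        if (length(st$init_buf) >= max(init_n, k)) {
          st$svd <- prosvd_init(do.call(cbind, st$init_buf), k)
          st$ridge <- ridge_init(k, length(pay$trace),
                                 lambda = ctx$params$lambda %||% 1e-5)
          st$init_buf <- list()
        }
        return(invisible(NULL))
      }
      Q_old <- st$svd$Q
      st$svd <- prosvd_update(st$svd, pay$frame)
      st$basis_change <- c(st$basis_change,
                           sqrt(sum((st$svd$Q - Q_old)^2)))
      x <- drop(prosvd_project(st$svd, pay$frame))
      st$ridge <- ridge_update(st$ridge, x, pay$trace)
      key <- ctx$put("latents", x)
      ctx$emit(list(key))
    }
  ))

  # streams a low-dimensional trajectory
  register_actor("trajectory_source", actor_impl(
    setup = function(ctx) {
      p <- ctx$params
      gt <- gen_limit_cycle(T_steps = p$frames %||% 3000L,
                            dims = p$dims %||% 3L,
                            noise_sd = p$noise %||% 0.05,
                            seed = p$seed %||% 1L)
      ctx$state$X <- gt$X
      ctx$state$t <- 0L
    },
    step = function(ctx, msg) {
      t <- ctx$state$t + 1L
      if (t > nrow(ctx$state$X)) return(FALSE)
      ctx$state$t <- t
      key <- ctx$put("trajectory", ctx$state$X[t, ])
      ctx$emit(list(key))
      TRUE
    }
  ))

  # streaming mixture-HMM trajectory prediction
  register_actor("bubblewrap_model", actor_impl(
    setup = function(ctx) {
      ctx$state$init_buf <- list()
      ctx$state$bw <- NULL
      ctx$state$log_pred <- numeric(0)
      ctx$state$entropy <- numeric(0)
      ctx$state$recent <- list()
    },
    step = function(ctx, msg) {
      x <- ctx$get(msg$keys[[1]])
      st <- ctx$state
      if (is.null(st$bw)) {
        st$init_buf[[length(st$init_buf) + 1L]] <- x
        if (length(st$init_buf) >= (ctx$params$init_points %||% 20L)) {
          st$bw <- bw_init(do.call(rbind, st$init_buf),
                           N = ctx$params$tiles %||% 50L,
                           seed = ctx$params$seed %||% 42L)
          st$init_buf <- list()
        }
        return(invisible(NULL))
      }
      res <- bw_update(st$bw, x)
      st$bw <- res$state
      st$log_pred <- c(st$log_pred, res$log_pred)
      st$entropy <- c(st$entropy, bw_entropy(st$bw))
      key <- ctx$put("bw_metrics",
                     c(log_pred = res$log_pred,
                       entropy = st$entropy[length(st$entropy)]))
      ctx$emit(list(key))
    }
  ))

  # one kickoff message to start a closed loop
  register_actor("trigger_source", actor_impl(
    step = function(ctx, msg) {
      key <- ctx$put("trigger", "go")
      ctx$emit(list(key))
      FALSE
    }
  ))

  # answers stimulus requests with the simulated population's responses
  register_actor("visual_stimuli", actor_impl(
    setup = function(ctx) {
      p <- ctx$params
      ctx$state$pop <- gen_tuning_population(
        p$n_neurons %||% 20L, seed = p$seed %||% 1L,
        noise_sd = p$noise_sd %||% 0.2)
    },
    step = function(ctx, msg) {
      pay <- ctx$get(msg$keys[[1]])
      if (identical(pay, "go")) return(invisible(NULL))
      y_all <- ctx$state$pop$respond(pay$idx)
      key <- ctx$put("responses", list(idx = pay$idx, y_all = y_all))
      ctx$emit(list(key))
    }
  ))

  # event-driven closed-loop Bayesian optimizer over the population
  register_actor("bo_optimizer", actor_impl(
    setup = function(ctx) {
      p <- ctx$params
      n <- p$n_neurons %||% 20L
      st <- ctx$state
      st$n <- n
      st$config <- bo_config(n_max = p$n_max %||% 30L,
                             seed = p$rng_seed %||% 1337L)
      st$kernel <- stim_kernel()
      st$rng <- side_rng(st$config$seed)
      st$history <- bo_history(n)
      st$queue <- seq_len(n)
      st$pos <- 1L
      st$used <- 0L
      st$attempts <- integer(n)
      st$init_queue <- init_stimuli(st$rng)
      st$requeued <- integer(0)
      st$results <- list()
      st$trace <- list()
    },
    step = function(ctx, msg) {
      st <- ctx$state
      pay <- ctx$get(msg$keys[[1]])
      if (!identical(pay, "go")) {
        # record a response for every simultaneously imaged neuron
        for (j in seq_len(st$n)) {
          history_append(st$history, j, pay$idx, pay$y_all[j])
        }
        st$history$n_presented <- st$history$n_presented + 1L
        st$used <- st$used + 1L
        st$trace[[length(st$trace) + 1L]] <-
          list(neuron = st$queue[st$pos], iteration = st$used,
               idx = pay$idx, response = pay$y_all[st$queue[st$pos]])
      }
      nxt <- bo_next_request(st)
      if (!is.null(nxt)) {
        key <- ctx$put("stim_requests", list(idx = nxt))
        ctx$emit(list(key))
      }
    }
  ))

  # closed-loop photostimulation phase controller
  register_actor("photostim_controller", actor_impl(
    setup = function(ctx) {
      p <- ctx$params
      ctx$state$net <- gen_photostim_network(p$n_neurons %||% 20L,
                                             seed = p$seed %||% 1L)
      ctx$state$n_targets <- p$n_targets %||% 5L
    },
    step = function(ctx, msg) {
      st <- ctx$state
      net <- st$net
      phase <- phase_state()
      phase <- phase_controller(phase, completeness = 1, log = NULL)
      stimulated <- integer(0)
      out <- list()
      rng <- side_rng(1337L)
      for (t in seq_len(st$n_targets)) {
        id <- select_photostim_target(net$records, exclusions = stimulated,
                                      rng = rng, prefer_new_prob = 1)
        if (is.na(id) || id %in% stimulated) break   # candidate pool exhausted
        proto <- simulate_photostim_traces(net, id,
                                           seed = derive_seed(1L, 100L + t))
        out[[t]] <- list(target = id, events = proto$events,
                         mean_response = proto$mean_response,
                         peak_dir = net$records$peak_dir[id])
        stimulated <- c(stimulated, id)
      }
      st$phase <- phase
      st$stim_results <- out
      key <- ctx$put("photostim_results", out)
      ctx$emit(list(key))
    }
  ))
}

# shared between the BO actor and tests: decide the next stimulus request,
# finalizing neurons as their EI stopping rule fires or budget runs out
bo_next_request <- function(st) {
  if (length(st$init_queue) > 0L) {
    idx <- st$init_queue[1L]
    st$init_queue <- st$init_queue[-1L]
    return(idx)
  }
  repeat {
    if (st$pos > length(st$queue)) {
      if (length(st$requeued) > 0L) {
        st$queue <- st$requeued
        st$requeued <- integer(0)
        st$pos <- 1L
        st$used <- 0L
        next
      }
      return(NULL)
    }
    i <- st$queue[st$pos]
    obs <- list(idx = st$history$obs_idx[[i]], y = st$history$obs_y[[i]])
    post <- gp_fit(obs, st$kernel)
    best <- max(post$f[unique(obs$idx)])
    if (ei_stop(post, best, st$config$ei_threshold)) {
      st$attempts[i] <- st$attempts[i] + 1L
      st$results[[length(st$results) + 1L]] <-
        list(neuron = i, peak_idx = which.max(post$f), converged = TRUE)
      st$pos <- st$pos + 1L
      st$used <- 0L
      next
    }
    if (st$used >= st$config$n_max) {
      st$attempts[i] <- st$attempts[i] + 1L
      st$results[[length(st$results) + 1L]] <-
        list(neuron = i, peak_idx = which.max(post$f), converged = FALSE)
      if (st$attempts[i] < st$config$max_attempts) {
        st$requeued <- c(st$requeued, i)
      }
      st$pos <- st$pos + 1L
      st$used <- 0L
      next
    }
    counts <- tabulate(obs$idx, nbins = GRID_N^2)
    return(ucb_select(post, st$config$kappa, counts, st$rng,
                      st$config$repeat_cap))
  }
}

# photostim-evoked fluorescence traces consistent with the network's
# ground-truth coupling (5 events, 15 s apart, 3.6 Hz)
simulate_photostim_traces <- function(net, target_id, repetitions = 5L,
                                      spacing_s = 15, frame_rate_hz = 3.6,
                                      noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  n <- nrow(net$records)
  onsets <- 11L + round((seq_len(repetitions) - 1L) * spacing_s * frame_rate_hz)
  T_ <- max(onsets) + 20L
  traces <- matrix(stats::rnorm(T_ * n, sd = noise_sd), T_, n)
  drive <- net$coupling[target_id, ]
  drive[target_id] <- max(drive, 1)      # the target itself responds strongly
  for (on in onsets) {
    for (dt in 0:14) {
      traces[on + dt, ] <- traces[on + dt, ] + drive * exp(-dt / 7)
    }
  }
  run_photostim_protocol(
    list(id = target_id, x = net$records$x[target_id],
         y = net$records$y[target_id]),
    traces, frame_rate_hz = frame_rate_hz, start_frame = 11L,
    repetitions = repetitions, spacing_s = spacing_s)
}

demo_config_path <- function(name) {
  system.file("configs", paste0(name, ".yaml"), package = "streamloop")
}

#' Validate a pipeline config file
#'
#' @param path Config file path.
#' @return List: `ok` (logical), `issues` (character), `graph` (on
#'   success).
#' @export
cli_validate <- function(path) {
  res <- tryCatch(
    list(ok = TRUE, issues = character(0),
         graph = {
           g <- parse_config(file = path)
           validate_graph(g, check_impls = TRUE)
           g
         }),
    error = function(e) list(ok = FALSE, issues = conditionMessage(e),
                             graph = NULL)
  )
  res
}

#' Run a pipeline config and write artifacts
#'
#' Parses and validates the config, executes the pipeline, and writes the
#' run log (JSON-lines) and queue statistics (CSV) to `out_dir`.
#'
#' @param path Config file path.
#' @param frames Frames each source emits.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return List: `exit_code` (0 clean, 1 config error, 2 completed with
#'   faults), `run` (the `pipeline_run`, when executed).
#' @export
cli_run <- function(path, frames = 100L, seed = 1L, out_dir = tempfile("run")) {
  val <- cli_validate(path)
  if (!val$ok) {
    message(paste(val$issues, collapse = "\n"))
    return(list(exit_code = 1L, run = NULL))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- run_pipeline(val$graph, stop = frames, seed = seed)
  write_runlog(run$log, file.path(out_dir, "runlog.jsonl"))
  utils::write.csv(run$queue_stats, file.path(out_dir, "queue_stats.csv"),
                   row.names = FALSE)
  faults <- log_count(run$log, "fault")
  list(exit_code = if (faults > 0) 2L else 0L, run = run)
}

#' Run a packaged demo end to end
#'
#' Generates synthetic inputs, executes the demo's pipeline, and writes
#' metrics CSVs, JSON-lines logs, and summary PNGs to `out_dir`.
#'
#' @param name One of `"fig2_lnp"`, `"fig3_behavior"`, `"fig4_bubblewrap"`,
#'   `"fig5_bo"`, `"fig6_photostim"`.
#' @param scale `"small"` (fast, default) or `"full"` (desk-scale).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return List of demo artifacts (paths and headline metrics), invisibly
#'   printed.
#' @export
cli_demo <- function(name, scale = c("small", "full"), seed = 1L,
                     out_dir = tempfile("demo")) {
  scale <- match.arg(scale)
  if (!name %in% demo_names) {
    stop(sprintf("unknown demo '%s'; available: %s", name,
                 paste(demo_names, collapse = ", ")), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(name,
         fig2_lnp = demo_fig2_lnp(scale, seed, out_dir),
         fig3_behavior = demo_fig3_behavior(scale, seed, out_dir),
         fig4_bubblewrap = demo_fig4_bubblewrap(scale, seed, out_dir),
         fig5_bo = demo_fig5_bo(scale, seed, out_dir),
         fig6_photostim = demo_fig6_photostim(scale, seed, out_dir))
}

save_png <- function(plot, path, width = 900, height = 600) {
  grDevices::png(path, width = width, height = height)
  print(plot)
  grDevices::dev.off()
  path
}

demo_fig2_lnp <- function(scale, seed, out_dir) {
  n <- if (scale == "small") 10L else 20L
  reps <- if (scale == "small") 2L else 4L
  g <- parse_config(file = demo_config_path("fig2_lnp"))
  g$nodes$acquirer$params$n_neurons <- n
  g$nodes$acquirer$params$repetitions <- reps
  g$nodes$acquirer$params$seed <- seed
  run <- run_pipeline(g, stop = 10000L, seed = seed)
  tr <- do.call(rbind, run$actor_state$lnp$trace)
  df <- tibble::tibble(frame = tr[, "frame"], loglik_per_bin = tr[, "loglik"])
  a <- 0.2
  df$ewma <- Reduce(function(p, v) (1 - a) * p + a * v, df$loglik_per_bin,
                    accumulate = TRUE)
  utils::write.csv(df, file.path(out_dir, "loglik.csv"), row.names = FALSE)
  write_runlog(run$log, file.path(out_dir, "runlog.jsonl"))
  p <- ggplot2::ggplot(df, ggplot2::aes(frame, loglik_per_bin)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = ewma)) +
    ggplot2::labs(title = "online LNP window log-likelihood per bin",
                  x = "frame", y = "log-likelihood / (frame x neuron)")
  save_png(p, file.path(out_dir, "loglik.png"))
  invisible(list(out_dir = out_dir, final_loglik = utils::tail(df$ewma, 1),
                 run = run))
}

demo_fig3_behavior <- function(scale, seed, out_dir) {
  frames <- if (scale == "small") 300L else 1500L
  g <- parse_config(file = demo_config_path("fig3_behavior"))
  g$nodes$video$params$frames <- frames
  g$nodes$video$params$seed <- seed
  run <- run_pipeline(g, stop = frames + 10L, seed = seed)
  st <- run$actor_state$model
  gt <- run$actor_state$video$gt
  beta <- ridge_coef(st$ridge)
  map <- project_coefficients_to_pixels(beta, st$svd$Q)
  # overlap of the top-5% weight mass with the generator's loading patches
  target_px <- unique(unlist(gt$patch_pixels))
  w <- rowSums(abs(map))
  top <- order(w, decreasing = TRUE)[seq_len(ceiling(0.05 * length(w)))]
  overlap <- mean(top %in% target_px)
  utils::write.csv(
    tibble::tibble(step = seq_along(st$basis_change),
                   basis_change = st$basis_change),
    file.path(out_dir, "basis_change.csv"), row.names = FALSE)
  save_png(plot_weight_map(map, gt$H, gt$W),
           file.path(out_dir, "weight_map.png"))
  write_runlog(run$log, file.path(out_dir, "runlog.jsonl"))
  message(sprintf("top-5%% weight overlap with ground-truth patches: %.2f",
                  overlap))
  invisible(list(out_dir = out_dir, overlap = overlap, run = run))
}

demo_fig4_bubblewrap <- function(scale, seed, out_dir) {
  frames <- if (scale == "small") 2000L else 8000L
  g <- parse_config(file = demo_config_path("fig4_bubblewrap"))
  g$nodes$source$params$frames <- frames
  g$nodes$source$params$seed <- seed
  run <- run_pipeline(g, stop = frames + 10L, seed = seed)
  st <- run$actor_state$bubblewrap
  metrics <- tibble::tibble(step = seq_along(st$log_pred),
                            log_pred = st$log_pred, entropy = st$entropy)
  utils::write.csv(metrics, file.path(out_dir, "bubblewrap_metrics.csv"),
                   row.names = FALSE)
  # horizon sweep: re-stream and score futures from the filter state at
  # each evaluation moment (prediction forward from the current phase)
  X <- run$actor_state$source$X
  hp <- bw_horizon_profile(X, horizons = 1:100, eval_every = 50L,
                           seed = g$nodes$bubblewrap$params$seed %||% 42L)
  utils::write.csv(hp$profile, file.path(out_dir, "horizon_log_pred.csv"),
                   row.names = FALSE)
  save_png(plot_bw_metrics(metrics), file.path(out_dir, "bw_metrics.png"))
  write_runlog(run$log, file.path(out_dir, "runlog.jsonl"))
  invisible(list(out_dir = out_dir, metrics = metrics,
                 horizon = tibble::tibble(horizon = horizons,
                                          mean_log_pred = hz),
                 run = run))
}

demo_fig5_bo <- function(scale, seed, out_dir) {
  n <- if (scale == "small") 20L else 200L
  g <- parse_config(file = demo_config_path("fig5_bo"))
  g$nodes$stimuli$params$n_neurons <- n
  g$nodes$stimuli$params$seed <- seed
  g$nodes$optimizer$params$n_neurons <- n
  run <- run_pipeline(g, stop = 1L, seed = seed)
  st <- run$actor_state$optimizer
  trace <- do.call(rbind, lapply(st$trace, function(r) {
    ang <- grid_angles(r$idx)
    tibble::tibble(neuron = r$neuron, iteration = r$iteration, idx = r$idx,
                   angle_left = ang[1], angle_right = ang[2],
                   response = r$response)
  }))
  utils::write.csv(trace, file.path(out_dir, "bo_trace.csv"),
                   row.names = FALSE)
  results <- do.call(rbind, lapply(st$results, function(r) {
    tibble::tibble(neuron = r$neuron, peak_idx = r$peak_idx,
                   converged = r$converged)
  }))
  # a re-queued neuron appears twice; keep its final estimate
  results <- results[!duplicated(results$neuron, fromLast = TRUE), ]
  # score against the generator's ground truth (same seed reconstruction)
  pop <- gen_tuning_population(n, seed = seed)
  results$true_peak <- pop$peaks[results$neuron]
  results$peak_dist <- mapply(peak_distance, results$peak_idx,
                              results$true_peak)
  utils::write.csv(results, file.path(out_dir, "bo_results.csv"),
                   row.names = FALSE)
  write_runlog(run$log, file.path(out_dir, "runlog.jsonl"))
  acc <- mean(results$peak_dist <= 1)
  message(sprintf("peak within 1 grid step for %.0f%% of %d neurons (%d stimuli total)",
                  100 * acc, n, st$history$n_presented))
  invisible(list(out_dir = out_dir, accuracy = acc,
                 total_stimuli = st$history$n_presented, results = results,
                 run = run))
}

demo_fig6_photostim <- function(scale, seed, out_dir) {
  n <- if (scale == "small") 20L else 60L
  g <- parse_config(file = demo_config_path("fig6_photostim"))
  g$nodes$controller$params$n_neurons <- n
  g$nodes$controller$params$seed <- seed
  run <- run_pipeline(g, stop = 1L, seed = seed)
  st <- run$actor_state$controller
  events <- do.call(rbind, lapply(st$stim_results, `[[`, "events"))
  con <- file(file.path(out_dir, "photostim_events.jsonl"), "w")
  for (r in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[r, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  close(con)
  # photostim tuning of neuron 1 across all targets
  resp1 <- vapply(st$stim_results, function(s) s$mean_response[1],
                  numeric(1))
  dirs <- vapply(st$stim_results, `[[`, numeric(1), "peak_dir")
  tuning <- compute_photostim_tuning(resp1, dirs)
  utils::write.csv(tuning, file.path(out_dir, "photostim_tuning.csv"),
                   row.names = FALSE)
  write_runlog(run$log, file.path(out_dir, "runlog.jsonl"))
  invisible(list(out_dir = out_dir, events = events, tuning = tuning,
                 run = run))
}
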