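test_that("stimulus protocols tile the session with balanced random directions", {
  ev <- gen_stim_protocol(protocol_spec(repetitions = 3L), seed = 1)
  expect_equal(nrow(ev), 24L)
  expect_equal(as.numeric(table(ev$angle_left)), rep(3, 8))
  expect_equal(ev$angle_left, ev$angle_right)
  expect_equal(unique(ev$moving_frames), round(4.2 * 3.6))   # 15 frames
  expect_equal(unique(ev$moving_frames), 15)
  expect_true(all(diff(ev$onset_frame) > 0))
  expect_identical(ev, gen_stim_protocol(protocol_spec(repetitions = 3L),
                                         seed = 1))
  ev2 <- gen_stim_protocol(protocol_spec(repetitions = 3L), seed = 2)
  expect_false(identical(ev$angle_left, ev2$angle_left))
})

test_that("noise-free calcium movies reproduce their ROI signals exactly", {
  ev <- gen_stim_protocol(protocol_spec(repetitions = 1L), seed = 3)
  mov <- gen_calcium_movie(n_rois = 4L, events = ev, H = 40L, W = 40L,
                           noise_sd = 0, seed = 4)
  expect_equal(dim(mov$movie), c(protocol_frames(ev), 40, 40))
  for (t in c(1, 50, 100)) {
    tr <- extract_traces(mov$movie[t, , ], mov$masks)
    expect_equal(tr, mov$fluor[t, ], tolerance = 1e-12)
  }
})

test_that("tuned ROIs show their preferred direction in the running tuning curve", {
  ev <- gen_stim_protocol(protocol_spec(repetitions = 4L), seed = 5)
  mov <- gen_calcium_movie(n_rois = 3L, events = ev, noise_sd = 0,
                           tuned_rate = 3, base_rate = 0.02, seed = 6)
  for (i in 1:3) {
    curve <- tuning_curve8()
    for (r in seq_len(nrow(ev))) {
      curve <- update_direction_tuning(mov$fluor[, i], as.list(ev[r, ]), curve)
    }
    peak_dir <- as.numeric(names(which.max(curve$mean_response)))
    dd <- min(abs(peak_dir - mov$pref_dirs[i]),
              360 - abs(peak_dir - mov$pref_dirs[i]))
    expect_lte(dd, 45)
  }
})

test_that("tuning surfaces are unimodal wrapped bumps with stored peaks", {
  ts <- gen_tuning_surface(seed = 7, width = 3)
  expect_equal(which.max(ts$surface), ts$peak_idx)
  anti <- grid_coords(ts$peak_idx) + 12L
  anti_idx <- grid_index(anti[1] %% 24L, anti[2] %% 24L)
  expect_lt(ts$surface[anti_idx], 0.05)
  two <- gen_tuning_population(4, seed = 8, shared_peak_groups = 2L)
  expect_equal(two$peaks[1], two$peaks[3])
  expect_equal(two$peaks[2], two$peaks[4])
})

test_that("LNP simulations match their nominal rates and couplings", {
  # zero-weight population: empirical mean within 3 standard errors of 0.5
  p0 <- lnp_params(3, b = rep(log(0.5), 3))
  sim <- gen_lnp_population(p0, T_frames = 10000, seed = 9)
  se <- sqrt(0.5 / 10000)
  for (i in 1:3) {
    expect_lt(abs(mean(sim$spikes[, i]) - 0.5), 3 * se * sqrt(2))
  }
  # Poisson margins: variance tracks the mean
  expect_lt(abs(var(sim$spikes[, 1]) / mean(sim$spikes[, 1]) - 1), 0.15)
  # a strong positive coupling appears as a lag-1 cross-correlation
  W <- matrix(0, 3, 3); W[2, 1] <- 0.8     # neuron 1 drives neuron 2
  p1 <- lnp_params(3, b = rep(log(0.3), 3), W = W)
  sim2 <- gen_lnp_population(p1, T_frames = 8000, seed = 10)
  x <- sim2$spikes[, 1]; y <- sim2$spikes[, 2]
  lag1 <- cor(x[-length(x)], y[-1])
  null_sd <- 1 / sqrt(length(x))
  expect_gt(lag1, 5 * null_sd)
  expect_identical(sim2$spikes,
                   gen_lnp_population(p1, T_frames = 8000, seed = 10)$spikes)
  # spectral-radius guard
  Wbig <- matrix(0.5, 4, 4); diag(Wbig) <- 0
  expect_error(gen_lnp_population(lnp_params(4, W = Wbig * 0.9),
                                  T_frames = 10),
               "spectral radius")
})

test_that("behavior-neural pairs are low-rank with recoverable readouts", {
  gt <- gen_behavior_neural_pair(H = 16L, W = 20L, rank = 2L, n_neurons = 5L,
                                 T_frames = 200L, noise = 0, seed = 11)
  sv <- svd(gt$frames, nu = 0, nv = 0)$d
  expect_gt(sv[2], 1e-6)
  expect_lt(sv[3] / sv[1], 1e-10)
  # ridge on the true latents recovers the true readout
  B_hat <- ridge_batch(t(gt$latents), t(gt$traces), lambda = 1e-12)
  expect_equal(B_hat, gt$true_B, tolerance = 1e-6)
})

test_that("limit cycles are planar when noise-free with the stored period", {
  lc <- gen_limit_cycle(T_steps = 800, dims = 5, noise_sd = 0, seed = 12)
  sv <- svd(scale(lc$X, scale = FALSE), nu = 0, nv = 0)$d
  expect_lt(sv[3], 1e-10)
  spec <- Mod(stats::fft(lc$X[, 1] - mean(lc$X[, 1])))[2:(400)]
  f_peak <- which.max(spec)
  period_fft <- 800 / f_peak
  expect_lte(abs(period_fft - lc$period), 1)
  expect_identical(lc$X, gen_limit_cycle(T_steps = 800, dims = 5,
                                         noise_sd = 0, seed = 12)$X)
})

test_that("photostim networks are reproducible with consistent metadata", {
  net <- gen_photostim_network(15, seed = 13)
  expect_equal(nrow(net$records), 15L)
  expect_true(all(net$records$opsin_intensity >= 0))
  expect_true(all(diag(net$coupling) == 0))
  set.seed(99)
  y1 <- net$respond(3L)
  set.seed(99)
  y2 <- net$respond(3L)
  expect_identical(y1, y2)
})

test_that("movies round-trip through multi-page TIFF", {
  ev <- gen_stim_protocol(protocol_spec(repetitions = 1L), seed = 20)
  mov <- gen_calcium_movie(n_rois = 2L, events = ev, T_frames = 6L,
                           H = 16L, W = 16L, seed = 21)
  path <- tempfile(fileext = ".tif")
  write_movie_tiff(mov$movie, path)
  back <- read_movie_tiff(path)
  expect_equal(dim(back), dim(mov$movie))
  expect_equal(back, mov$movie, tolerance = 1e-6)   # float32 pages
})
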