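records_fixture <- function() {
  tibble::tibble(
    id = 1:4,
    x = c(0, 80, 10, -20),
    y = c(0, 0, 5, 5),
    r = c(0, 1, 0, 0), g = c(1, 0, 1, 1), b = c(0, 0, 0, 0),
    opsin_intensity = c(100, 120, 40, 90)
  )
}

test_that("target selection scores colors against the criteria basis", {
  rec <- records_fixture()[1:2, ]
  rec$x <- c(0, 10)
  rec$opsin_intensity <- c(100, 100)
  # green [0,1,0] scores +1, red [1,0,0] scores -1 under [-1, 1, -1]
  expect_equal(select_photostim_target(rec), 1L)
})

test_that("position, score, and opsin-intensity filters are all enforced", {
  rec <- records_fixture()
  picked <- select_photostim_target(rec)
  expect_false(picked %in% c(2L, 3L))  # x = 80 out of range; intensity 40 too dim
  expect_true(picked %in% c(1L, 4L))
  expect_equal(picked, 1L)             # max intensity among candidates
  # no candidate at all -> NA with a message
  rec2 <- rec
  rec2$opsin_intensity <- rep(10, 4)
  expect_message(out <- select_photostim_target(rec2), "no photostimulation")
  expect_true(is.na(out))
})

test_that("already-stimulated neurons are avoided when alternatives exist", {
  rec <- records_fixture()
  got <- select_photostim_target(rec, exclusions = 1L, prefer_new_prob = 1)
  expect_equal(got, 4L)
  # with every candidate excluded the exclusion list is ignored
  got2 <- select_photostim_target(rec, exclusions = c(1L, 4L),
                                  prefer_new_prob = 1)
  expect_true(got2 %in% c(1L, 4L))
})

test_that("selection on generated networks never violates the filters", {
  for (seed in 1:5) {
    net <- gen_photostim_network(25, seed = seed)
    id <- select_photostim_target(net$records, rng = side_rng(seed))
    if (!is.na(id)) {
      rec <- net$records[net$records$id == id, ]
      expect_gt(rec$x, -75); expect_lt(rec$x, 75)
      expect_gt(rec$opsin_intensity, 50)
      expect_gt(rec$g - rec$r - rec$b, 0)
    }
  }
})

test_that("the protocol emits 5 events 15 s apart and scores responses exactly", {
  n <- 3L
  frame_rate <- 3.6
  onsets <- 11L + round((0:4) * 15 * frame_rate)
  T_ <- max(onsets) + 20L
  traces <- matrix(1, T_, n)
  for (on in onsets) traces[on:(on + 14), 2] <- 3   # neuron 2 responds by +2
  out <- run_photostim_protocol(list(id = 7L, x = 12, y = -3), traces,
                                frame_rate_hz = frame_rate)
  expect_equal(out$events$time_s, c(0, 15, 30, 45, 60))
  expect_equal(nrow(out$events), 5L)
  expect_equal(unique(out$events$target_id), 7L)
  expect_equal(out$mean_response, c(0, 2, 0))       # noise-free hand calculation
  expect_error(run_photostim_protocol(list(id = 1, x = 0, y = 0),
                                      traces[1:40, ]), "cover")
})

test_that("coupled neurons respond to photostimulation, uncoupled ones do not", {
  n <- 6L
  coupling <- matrix(0, n, n)
  coupling[2, 5] <- 1.5                 # stimulating 2 drives 5 only
  net <- gen_photostim_network(n, coupling = coupling, noise_sd = 0, seed = 1)
  y <- net$respond(2L)
  expect_equal(y[5], 1.5)
  expect_equal(y[-5], rep(0, n - 1))
})

test_that("photostim tuning groups responses by the targets' peak directions", {
  tun <- compute_photostim_tuning(c(2, 2, 2), c(45, 45, 45))
  expect_equal(tun$mean_response[tun$direction == 45], 2)
  expect_true(all(is.na(tun$mean_response[tun$direction != 45])))
  expect_equal(tun$n_events[tun$direction == 45], 3L)
  # random tables against a group-by-mean oracle
  set.seed(2)
  for (rep in 1:5) {
    k <- 30L
    dirs <- sample(seq(0, 315, by = 45), k, replace = TRUE)
    resp <- rnorm(k)
    tun2 <- compute_photostim_tuning(resp, dirs)
    for (d in unique(dirs)) {
      expect_equal(tun2$mean_response[tun2$direction == d],
                   mean(resp[dirs == d]))
    }
  }
  empty <- compute_photostim_tuning(numeric(0), numeric(0))
  expect_true(all(is.na(empty$mean_response)))
})

test_that("the phase switch is threshold-gated and one-way", {
  st <- phase_state()
  st <- phase_controller(st, 0.5)
  expect_equal(st$phase, "characterization")
  log <- run_log()
  st <- phase_controller(st, 0.95, log = log)
  expect_equal(st$phase, "photostimulation")
  expect_equal(log_count(log, "phase-switch"), 1L)
  st <- phase_controller(st, 0.1)
  expect_equal(st$phase, "photostimulation")   # never reverts
})
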