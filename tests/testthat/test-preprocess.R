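test_that("Otsu separates a two-valued image and is idempotent on binaries", {
  img <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  b <- otsu_threshold(img)
  expect_gt(b$threshold_used, 10)
  expect_lt(b$threshold_used, 200)
  expect_equal(mean(b$pixels), 0.4)
  rebin <- otsu_threshold(b$pixels)
  expect_equal(rebin$pixels, b$pixels)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate")
})

test_that("Otsu matches the exhaustive between-class-variance maximizer", {
  set.seed(7)
  for (rep in 1:5) {
    img <- matrix(c(rnorm(300, 50, 10), rnorm(200, 160, 25)), 25, 20)
    b <- otsu_threshold(img)
    t_oracle <- oracle_otsu(img)
    bin_w <- diff(range(img)) / 256
    expect_lt(abs(b$threshold_used - t_oracle), bin_w + 1e-12)
  }
})

test_that("Otsu agrees with an independent implementation on [0,1] images", {
  set.seed(8)
  img <- matrix(c(runif(150, 0, 0.3), runif(106, 0.6, 1)), 16, 16)
  b <- otsu_threshold(img)
  ref <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  expect_equal(b$pixels, (img > ref) * 1)
})

test_that("Dice coefficient matches hand counts and is a similarity score", {
  m1 <- matrix(0, 3, 4); m1[1, 1:4] <- 1                  # |X| = 4
  m2 <- matrix(0, 3, 4); m2[1, 1:3] <- 1; m2[2, 1:3] <- 1 # |Y| = 6, overlap 3
  expect_equal(dice_coefficient(m1, m2), 0.6)
  expect_equal(dice_coefficient(m1, m2), dice_coefficient(m2, m1))
  expect_equal(dice_coefficient(m1, m1), 1)
  m3 <- matrix(0, 3, 4); m3[3, ] <- 1
  expect_equal(dice_coefficient(m1, m3), 0)
  expect_error(dice_coefficient(m1, matrix(0, 2, 2)), "shape")
  log <- run_log()
  expect_equal(dice_coefficient(matrix(0, 2, 2), matrix(0, 2, 2), log), 1)
  expect_equal(log_count(log, "warning"), 1L)
  set.seed(1)
  for (i in 1:10) {
    a <- matrix(rbinom(64, 1, 0.4), 8)
    b <- matrix(rbinom(64, 1, 0.4), 8)
    d <- dice_coefficient(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, dice_coefficient(b, a))
  }
})

test_that("plane alignment picks the undrifted plane, ties to smallest offset", {
  set.seed(2)
  base <- matrix(rnorm(40 * 40, 100, 5), 40, 40)
  base[10:20, 12:30] <- 220                   # bright structure
  target <- otsu_threshold(base)
  shift_img <- function(img, k) {
    if (k == 0) return(img)
    rbind(img[-seq_len(abs(k)), , drop = FALSE],
          matrix(100, abs(k), ncol(img)))
  }
  planes <- lapply(c(-6, -3, 0, 3, 6) / 1.5, function(k) shift_img(base, abs(k)))
  planes[[3]] <- base
  idx <- select_best_plane(planes, target, offsets_um = c(-6, -3, 0, 3, 6))
  # explicit oracle: score every plane
  scores <- vapply(planes, function(p) dice_coefficient(otsu_threshold(p), target),
                   numeric(1))
  expect_equal(as.integer(idx), which.max(scores))
  expect_equal(as.integer(idx), 3L)
  # all planes identical: tie resolves to the zero-offset plane
  same <- replicate(5, base, simplify = FALSE)
  expect_equal(as.integer(select_best_plane(same, target,
                                            offsets_um = c(-6, -3, 0, 3, 6))), 3L)
  expect_error(select_best_plane(list(), target), "empty")
})

test_that("plane alignment survives drifts up to 20% of image height", {
  set.seed(3)
  base <- matrix(rnorm(50 * 50, 80, 4), 50, 50)
  base[15:30, 10:40] <- 200
  target <- otsu_threshold(base)
  for (drift in c(2, 5, 10)) {           # up to 20% of 50 rows
    planes <- lapply(c(drift, 0, -drift), function(k) {
      if (k == 0) base else if (k > 0) {
        rbind(base[-(1:k), ], matrix(80, k, 50))
      } else {
        rbind(matrix(80, -k, 50), base[1:(50 + k), ])
      }
    })
    expect_equal(as.integer(select_best_plane(planes, target,
                                              offsets_um = c(-3, 0, 3))), 2L)
  }
})

test_that("block downsampling averages blocks and halves a 240x320 frame", {
  img <- matrix(runif(240 * 320), 240, 320)
  out <- block_downsample(img, 2)
  expect_equal(dim(out), c(120, 160))
  expect_equal(out[1, 1], mean(img[1:2, 1:2]))
  expect_equal(block_downsample(matrix(7, 8, 8), 4), matrix(7, 2, 2))
  expect_equal(as.numeric(block_downsample(matrix(c(1, 5, 3, 7), 2, 2), 2)), 4)
  expect_error(block_downsample(img, 0), "factor")
  log <- run_log()
  out2 <- block_downsample(matrix(1, 5, 5), 2, log = log)
  expect_equal(dim(out2), c(2, 2))
  expect_equal(log_count(log, "warning"), 1L)
})

test_that("trace extraction averages over masks and validates bounds", {
  fr <- matrix(50, 20, 20)
  mask <- list(id = 1L, pixels = cbind(5:8, 5:8))
  expect_equal(extract_traces(fr, list(mask)), 50)
  expect_error(extract_traces(fr, list(list(id = 9L, pixels = cbind(25, 1)))),
               "9")
  expect_error(extract_traces(fr, list(list(id = 2L,
                                            pixels = matrix(0, 0, 2)))),
               "empty")
})

test_that("spike binning uses half-open bins and conserves counts", {
  expect_equal(bin_spikes(c(0.001, 0.004, 0.012), 0.010, 0.020), c(2L, 1L))
  expect_equal(bin_spikes(numeric(0), 0.010, 0.050), integer(5))
  expect_equal(bin_spikes(0.010, 0.010, 0.020), c(0L, 1L))   # boundary -> later bin
  expect_error(bin_spikes(c(-0.1, 0.2), 0.01, 1), "negative")
  set.seed(4)
  ev <- sort(runif(500, 0, 3))
  expect_equal(sum(bin_spikes(ev, 0.01, 3)), sum(ev < 3))
})

test_that("Gaussian smoothing preserves constants, unit mass and interior totals", {
  expect_equal(gaussian_smooth(rep(3, 200)), rep(3, 200))
  imp <- c(rep(0, 100), 1, rep(0, 100))
  sm <- gaussian_smooth(imp)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(which.max(sm), 101L)
  set.seed(5)
  counts <- rpois(400, 2)
  sm2 <- gaussian_smooth(counts)
  interior <- 60:340
  expect_equal(sum(sm2[interior]), sum(counts[interior]), tolerance = 0.5)
  expect_equal(sum(sm2), sum(counts), tolerance = 1e-9)  # reflect padding conserves mass
  expect_error(gaussian_smooth(rep(1, 20), window = 50), "window")
})

test_that("direction tuning accumulates baseline-subtracted running means", {
  curve <- tuning_curve8()
  trace <- c(rep(1, 10), rep(3, 15))
  ev <- list(angle_left = 90, angle_right = 90, onset_frame = 11L)
  curve <- update_direction_tuning(trace, ev, curve)
  expect_equal(unname(curve$mean_response["90"]), 2)
  expect_equal(unname(curve$trial_counts["90"]), 1L)
  # a second trial with response 1: running mean (3 + 1)/2 = 2 -> stays 2
  trace2 <- c(rep(1, 10), rep(2, 15))
  curve2 <- update_direction_tuning(trace2, ev,
                                    update_direction_tuning(trace, ev,
                                                            tuning_curve8()))
  expect_equal(unname(curve2$mean_response["90"]), 1.5)
  expect_equal(unname(curve2$trial_counts["90"]), 2L)
  # flat trace: response 0
  flat <- update_direction_tuning(rep(2, 30), ev, tuning_curve8())
  expect_equal(unname(flat$mean_response["90"]), 0)
  # insufficient history skips with a log event
  log <- run_log()
  skipped <- update_direction_tuning(rep(1, 12),
                                     list(angle_left = 0, angle_right = 0,
                                          onset_frame = 3L),
                                     tuning_curve8(), log = log)
  expect_equal(sum(skipped$trial_counts), 0L)
  expect_equal(log_count(log, "warning"), 1L)
})

test_that("the running tuning mean equals the batch mean over the same trials", {
  set.seed(6)
  curve <- tuning_curve8()
  responses <- list()
  for (i in 1:40) {
    dir <- sample(seq(0, 315, by = 45), 1)
    tr <- c(rnorm(10, 1), rnorm(15, 1 + runif(1, 0, 2)))
    ev <- list(angle_left = dir, angle_right = dir, onset_frame = 11L)
    curve <- update_direction_tuning(tr, ev, curve)
    responses[[i]] <- c(dir, mean(tr[11:25]) - mean(tr[1:10]))
  }
  df <- do.call(rbind, responses)
  for (dir in unique(df[, 1])) {
    expect_equal(unname(curve$mean_response[as.character(dir)]),
                 mean(df[df[, 1] == dir, 2]), tolerance = 1e-12)
  }
})

test_that("tuning colors encode direction as hue and magnitude as brightness", {
  fwd <- tuning_curve8()
  fwd$mean_response["0"] <- 1
  fwd$trial_counts["0"] <- 1L
  col <- tuning_to_color(fwd)
  expect_gt(col[2], col[1])       # forward preference -> green dominant
  expect_gt(col[2], col[3])
  expect_true(all(col >= 0 & col <= 1))
  expect_equal(tuning_to_color(tuning_curve8()), c(0, 0, 0))
  # opposite equal responses: circular mean cancels; hue from first max
  opp <- tuning_curve8()
  opp$mean_response[c("0", "180")] <- 0.5
  opp$trial_counts[c("0", "180")] <- 1L
  col2 <- tuning_to_color(opp, pop_max = 1)
  expect_true(all(col2 >= 0 & col2 <= 1))
  expect_gt(max(col2), 0)         # brightness reflects magnitude
  # brightness scales with the population max
  dim_col <- tuning_to_color(fwd, pop_max = 4)
  expect_lt(max(dim_col), max(col) + 1e-12)
})
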