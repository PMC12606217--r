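cfg_path <- function(name) {
  system.file("configs", paste0(name, ".yaml"), package = "streamloop")
}

test_that("packaged configs validate, including the closed-loop one", {
  for (nm in c("linear_demo", "fig2_lnp", "fig3_behavior", "fig4_bubblewrap",
               "fig5_bo", "fig6_photostim")) {
    res <- cli_validate(cfg_path(nm))
    expect_true(res$ok, info = nm)
  }
  # the optimization demo is genuinely cyclic
  g <- parse_config(file = cfg_path("fig5_bo"))
  expect_true(any(g$edges$from == "stimuli" & g$edges$to == "optimizer"))
  expect_true(any(g$edges$from == "optimizer" & g$edges$to == "stimuli"))
})

test_that("validation failures carry actionable messages and nonzero status", {
  bad <- tempfile(fileext = ".yaml")
  writeLines("
actors:
  src: {impl: count_source}
connections:
  - src.out -> ghost.in
", bad)
  res <- cli_validate(bad)
  expect_false(res$ok)
  expect_match(res$issues, "ghost")
  run <- cli_run(bad)
  expect_equal(run$exit_code, 1L)
})

test_that("cli_run writes a run log and reports faults in the exit code", {
  out <- tempfile("run")
  res <- cli_run(cfg_path("linear_demo"), frames = 20L, seed = 1L,
                 out_dir = out)
  expect_equal(res$exit_code, 0L)
  expect_true(file.exists(file.path(out, "runlog.jsonl")))
  expect_true(file.exists(file.path(out, "queue_stats.csv")))
  lines <- readLines(file.path(out, "runlog.jsonl"))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("t_mono", "actor", "kind") %in% names(rec)))

  faulty <- tempfile(fileext = ".yaml")
  writeLines("
actors:
  src: {impl: count_source}
  bad: {impl: fault_injector, params: {fail_at: 5}}
  sink: {impl: count_sink}
connections:
  - src.out -> bad.in
  - bad.out -> sink.in
", faulty)
  res2 <- cli_run(faulty, frames = 20L)
  expect_equal(res2$exit_code, 2L)       # completed, but with a fault
  expect_equal(log_count(res2$run$log, "fault"), 1L)
})

test_that("the photostimulation demo writes events with 5 repetitions per target", {
  out <- tempfile("demo")
  d <- cli_demo("fig6_photostim", seed = 1L, out_dir = out)
  lines <- readLines(file.path(out, "photostim_events.jsonl"))
  ev <- do.call(rbind, lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l))
  }))
  expect_equal(nrow(ev) %% 5L, 0L)
  for (tid in unique(ev$target_id)) {
    sub <- ev[ev$target_id == tid, ]
    expect_equal(nrow(sub), 5L)
    expect_equal(sub$time_s, c(0, 15, 30, 45, 60))
  }
  expect_true(file.exists(file.path(out, "photostim_tuning.csv")))
  expect_error(cli_demo("nonsense"), "available")
})

test_that("demo outputs are bit-reproducible under a fixed seed", {
  o1 <- tempfile(); o2 <- tempfile()
  cli_demo("fig6_photostim", seed = 7L, out_dir = o1)
  cli_demo("fig6_photostim", seed = 7L, out_dir = o2)
  expect_identical(readLines(file.path(o1, "photostim_events.jsonl")),
                   readLines(file.path(o2, "photostim_events.jsonl")))
  expect_identical(readLines(file.path(o1, "photostim_tuning.csv")),
                   readLines(file.path(o2, "photostim_tuning.csv")))
})

test_that("the streaming LNP demo tracks an improving likelihood", {
  out <- tempfile("demo")
  d <- cli_demo("fig2_lnp", seed = 1L, out_dir = out)
  ll <- utils::read.csv(file.path(out, "loglik.csv"))
  expect_true(all(c("frame", "loglik_per_bin", "ewma") %in% names(ll)))
  expect_gt(nrow(ll), 5L)
  # EWMA trends upward as the online fit improves
  expect_gt(tail(ll$ewma, 1), head(ll$ewma, 1))
  expect_true(file.exists(file.path(out, "loglik.png")))
})

test_that("the behavior-regression demo localizes weights on true patches", {
  out <- tempfile("demo")
  d <- cli_demo("fig3_behavior", seed = 1L, out_dir = out)
  expect_gte(d$overlap, 0.8)
  expect_true(file.exists(file.path(out, "weight_map.png")))
  expect_true(file.exists(file.path(out, "basis_change.csv")))
})
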