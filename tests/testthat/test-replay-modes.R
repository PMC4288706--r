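test_that("schedule validation rejects malformed input", {
  cfg <- sim_config(duration = 1, mode = "replay")
  expect_error(run_replay(data.frame(channel = 1, t_open = 0.5,
                                     t_close = 0.4), cfg), "malformed")
  expect_error(run_replay(data.frame(channel = 1, t_open = 0, t_close = 2),
                          cfg), "duration")
  expect_error(run_replay(data.frame(channel = 99, t_open = 0,
                                     t_close = 0.5), cfg), "range")
  expect_error(run_replay(data.frame(channel = c(1, 1),
                                     t_open = c(0, 0.2),
                                     t_close = c(0.3, 0.5)),
                          cfg), "overlapping")
})

test_that("an empty schedule leaves the system at rest", {
  cfg <- sim_config(duration = 0.5, mode = "replay")
  tr <- run_replay(data.frame(channel = integer(0), t_open = numeric(0),
                              t_close = numeric(0)), cfg)
  expect_true(all(tr$n_open == 0))
  expect_equal(max(abs(tr$box_avg_ca - cfg$flux$c0)), 0, tolerance = 1e-9)
  expect_true(all(is.na(tr$n_activatable)))
})

test_that("a single opening gives a pulse-decay box profile", {
  cfg <- sim_config(duration = 0.4, cadence = 0.005, mode = "replay")
  tr <- run_replay(data.frame(channel = 6, t_open = 0.05, t_close = 0.2), cfg)
  peak_i <- which.max(tr$box_avg_ca)
  expect_gt(tr$box_avg_ca[peak_i], 0.15)
  expect_true(tr$time[peak_i] >= 0.05 && tr$time[peak_i] <= 0.21)
  # monotone-ish rise during the opening, decay back toward rest after
  expect_lt(tr$box_avg_ca[length(tr$time)], 0.1)
  expect_equal(tr$box_avg_ca[tr$time == 0.04], cfg$flux$c0, tolerance = 1e-6)
  # open/close events logged at the scheduled times
  expect_equal(tr$open_log$time, c(0.05, 0.2), tolerance = 1e-9)
  expect_equal(tr$open_log$open, c(1, 0))
})

test_that("reduced mode reproduces the grid box average on a 2-s burst replay", {
  # trace comparisons are measured relative to the excursion peak (the
  # same convention as the mesh-convergence check): a pointwise-relative
  # metric would be dominated by the near-rest tail, where the absolute
  # error is ~0.015 uM (see the limitations section of the vignette)
  g <- pw_grid_burst()
  cfg <- sim_config(mode = "reduced", duration = 2, cadence = 2e-3)
  r <- run_replay(pw_sched_burst(), cfg)
  rms <- sqrt(mean((r$box_avg_ca - g$box_avg_ca)^2)) / max(g$box_avg_ca)
  expect_lt(rms, 0.15)
  # the active phase also agrees pointwise (90th percentile: single
  # samples on steep opening/closing edges carry alignment spikes)
  act <- g$box_avg_ca > 0.2
  rel <- abs(r$box_avg_ca[act] - g$box_avg_ca[act]) / g$box_avg_ca[act]
  expect_lt(unname(quantile(rel, 0.9)), 0.3)
})

test_that("grid-mode hybrid runs are reproducible", {
  cfg <- sim_config(ip3 = 0.05, duration = 0.2, seed = 21, mode = "grid",
                    cadence = 0.01)
  tr1 <- run_simulation(cfg)
  tr2 <- run_simulation(cfg)
  expect_identical(tr1$n_open, tr2$n_open)
  expect_equal(tr1$box_avg_ca, tr2$box_avg_ca, tolerance = 1e-12)
  expect_true(all(tr1$n_activatable >= 0 & tr1$n_activatable <= 16))
})
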