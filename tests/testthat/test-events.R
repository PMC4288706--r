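test_that("detection recovers planted events exactly and filters blips", {
  tr <- make_fixture(ppwp_spec())
  ct <- detect_events(tr)
  gt <- attr(tr, "ground_truth")
  expect_equal(nrow(ct), 4)
  expect_equal(ct$t_start, gt$t_start_detect)
  expect_equal(ct$t_end, gt$t_end_detect)
  expect_equal(ct$peak_n_open, gt$amplitude)
  expect_equal(ct$n_openings, gt$n_openings)
  # a flat trace yields an empty catalog
  flat <- make_fixture(fixture_spec(events = data.frame(
    t_start = numeric(0), duration = numeric(0), amplitude = numeric(0),
    label = character(0)), duration = 30))
  expect_equal(nrow(detect_events(flat)), 0)
  # single-opening blips are filtered out
  blip <- make_fixture(fixture_spec(events = data.frame(
    t_start = 5, duration = 0.3, amplitude = 1, label = "puff",
    n_openings = 1), duration = 30))
  expect_equal(nrow(detect_events(blip)), 0)
  expect_equal(nrow(detect_events(blip, min_openings = 1)), 1)
  # low-amplitude noise alone never crosses the threshold
  noisy <- make_fixture(fixture_spec(events = data.frame(
    t_start = numeric(0), duration = numeric(0), amplitude = numeric(0),
    label = character(0)), duration = 30, noise_sd = 0.01), seed = 4)
  expect_equal(nrow(detect_events(noisy)), 0)
})

test_that("raising the threshold shrinks and nests events", {
  cfg <- sim_config(ip3 = 0.06, duration = 400, seed = 31, mode = "reduced")
  tr <- run_simulation(cfg)
  thresholds <- c(0.1, 0.15, 0.2, 0.3)
  cats <- lapply(thresholds, function(th)
    detect_events(tr, threshold = th, debounce = 0,
                  min_openings = 1, discard = 0))
  # total threshold-exceedance time is non-increasing
  tot <- vapply(cats, function(x) sum(x$duration), numeric(1))
  expect_true(all(diff(tot) <= 1e-9))
  # every higher-threshold event nests inside a lower-threshold event
  for (i in 2:length(cats)) {
    lo <- cats[[i - 1]]; hi <- cats[[i]]
    for (r in seq_len(nrow(hi))) {
      expect_true(any(lo$t_start <= hi$t_start[r] + 1e-9 &
                        lo$t_end >= hi$t_end[r] - 1e-9))
    }
  }
})

test_that("classification splits events at the domain-wide trigger level", {
  tr <- make_fixture(ppwp_spec())
  ct <- classify_events(detect_events(tr), tr)
  expect_equal(ct$label, c("puff", "puff", "wave", "puff"))
  # every event is exactly one of puff/wave
  expect_true(all(ct$label %in% c("puff", "wave")))
  # wave count is non-increasing in the classification threshold
  nw <- vapply(c(0.1, 0.25, 0.31, 1), function(th)
    sum(classify_events(detect_events(tr), tr,
                        wave_threshold = th)$label == "wave"), numeric(1))
  expect_true(all(diff(nw) <= 0))
})

test_that("histogram summaries reproduce hand-computed statistics", {
  tr <- make_fixture(ppwp_spec())
  ct <- classify_events(detect_events(tr), tr)
  ds <- duration_histogram(list(`35` = ct))
  expect_equal(ds$n_events, 4)
  expect_equal(ds$mean_duration, mean(ct$duration))
  expect_equal(ds$sd_duration, sd(ct$duration))
  h <- attr(ds, "histograms")[[1]]
  expect_equal(sum(h$counts), 4)
  as <- activatable_histogram(ct)
  expect_equal(as$mean_activatable, mean(ct$n_activatable_start))
  dva <- duration_vs_activatable(ct)
  expect_equal(sum(dva$by_start$n), 4)
  expect_true(all(c("n_activatable_start", "mean_duration")
                  %in% names(dva$by_start)))
})

test_that("average event shapes are peak-normalized and reproducible", {
  tr <- make_fixture(ppwp_spec())
  ct <- detect_events(tr)
  sh1 <- average_event_shape(ct[1, ], tr, t_max = 1)
  expect_equal(max(sh1$n_open), 1)
  # two identical planted events average to the same normalized shape
  two <- fixture_spec(events = data.frame(
    t_start = c(5, 20), duration = c(0.5, 0.5), amplitude = c(3, 3),
    label = c("puff", "puff")), duration = 40)
  tr2 <- make_fixture(two)
  ct2 <- detect_events(tr2)
  shA <- average_event_shape(ct2[1, ], tr2, t_max = 1)
  shB <- average_event_shape(ct2, tr2, t_max = 1)
  expect_equal(shA$n_open, shB$n_open)
})

test_that("IWI and IPI follow the anchor and wave-split rules", {
  tr <- make_fixture(ppwp_spec())
  ct <- classify_events(detect_events(tr), tr)
  ints <- iwi_ipi(ct)
  # a single wave yields no IWI; one IPI between the first two puffs, the
  # pair split by the wave is excluded
  expect_equal(length(ints$iwi), 0)
  expect_equal(length(ints$ipi), 1)
  expect_equal(ints$ipi, ct$t_start[2] - ct$t_end[1])
  # planted regular waves give the exact interval set
  reg <- fixture_spec(events = data.frame(
    t_start = c(10, 40, 70), duration = rep(3, 3), amplitude = rep(6, 3),
    label = rep("wave", 3), n_openings = rep(8, 3)), duration = 100)
  trw <- make_fixture(reg)
  ctw <- classify_events(detect_events(trw), trw)
  iw <- iwi_ipi(ctw)
  expect_equal(iw$iwi, c(30, 30), tolerance = 1e-9)
  expect_equal(iw$iwi_sd, 0, tolerance = 1e-9)
  # end-to-start anchoring subtracts the wave duration
  iw2 <- iwi_ipi(ctw, anchor = "end_to_start")
  expect_equal(mean(iw2$iwi), 27, tolerance = 0.01)
  expect_error(iwi_ipi(detect_events(trw)), "classify")
})

test_that("IWI regression recovers a constructed line", {
  stats <- data.frame(mean = c(20, 40, 60, 90),
                      sd = 0.9 * (c(20, 40, 60, 90) - 17))
  reg <- iwi_regression(stats)
  expect_equal(reg$slope, 0.9, tolerance = 1e-9)
  expect_equal(reg$x_intercept, 17, tolerance = 1e-9)
  expect_equal(reg$cv, stats$sd / stats$mean)
  expect_error(iwi_regression(stats[1, , drop = FALSE]), "two conditions")
})

test_that("phase statistics place puffs between waves correctly", {
  # waves at 10 and 50; puffs at 30 (midway) and 12 (just after the wave)
  spec <- fixture_spec(events = data.frame(
    t_start = c(10, 12, 30, 50),
    duration = c(1, 0.5, 0.5, 1),
    amplitude = c(6, 2, 4, 6),
    label = c("wave", "puff", "puff", "wave"),
    n_openings = c(8, 2, 2, 8)), duration = 80)
  tr <- make_fixture(spec)
  ct <- classify_events(detect_events(tr), tr)
  ph <- phase_statistics(ct)
  expect_equal(nrow(ph$records), 2)
  expect_equal(sort(ph$records$phase), c(0.05, 0.5), tolerance = 0.01)
  expect_true(all(ph$records$phase > 0 & ph$records$phase < 1))
  expect_equal(sum(ph$bins$count), nrow(ph$records))
  # amplitudes rescaled by the dataset mean
  expect_equal(mean(ph$records$rescaled), 1)
  # fewer than two waves: empty result with a warning
  expect_warning(ph0 <- phase_statistics(ct[ct$label == "puff", ]),
                 "fewer than two waves")
  expect_equal(nrow(ph0$records), 0)
})

test_that("events tile the analyzed span without overlap", {
  set.seed(17)
  cfg <- sim_config(ip3 = 0.07, duration = 500, seed = 17, mode = "reduced")
  tr <- run_simulation(cfg)
  ct <- detect_events(tr)
  if (nrow(ct) > 1) {
    expect_true(all(ct$t_start[-1] >= ct$t_end[-nrow(ct)]))
    expect_true(all(ct$duration > 0))
    expect_equal(ct$duration, ct$t_end - ct$t_start)
  }
  win <- attr(ct, "window")
  expect_true(all(ct$t_start >= win[1] & ct$t_end <= win[2]))
})
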