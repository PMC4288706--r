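# Memoized expensive artifacts shared between test files (grid replays and
# the long-trace statistics protocol). Each is computed at most once per
# test run.

.pw_cache <- new.env(parent = emptyenv())

pw_cached <- function(key, expr) {
  if (!exists(key, envir = .pw_cache)) {
    assign(key, force(expr), envir = .pw_cache)
  }
  get(key, envir = .pw_cache)
}

# scripted 3-channel event used for grid/reduced comparisons
pw_sched3 <- function() {
  data.frame(channel = c(6, 7, 10),
             t_open = c(0.005, 0.02, 0.035),
             t_close = c(0.08, 0.09, 0.10))
}

pw_grid_replay3 <- function() {
  pw_cached("grid_replay3", {
    cfg <- sim_config(mode = "grid", duration = 0.15, cadence = 2e-3)
    run_replay(pw_sched3(), cfg)
  })
}

pw_grid_replay3_fine <- function() {
  pw_cached("grid_replay3_fine", {
    cfg <- sim_config(mode = "grid", duration = 0.15, cadence = 2e-3,
                      grid_control = list(h_min = 3, slope = 0.25,
                                          h_max = 75))
    run_replay(pw_sched3(), cfg)
  })
}

# staggered burst-and-decay schedule for the mode-consistency check
pw_sched_burst <- function() {
  data.frame(channel = c(6, 7, 10, 11, 6, 7),
             t_open  = c(0.005, 0.020, 0.040, 0.060, 0.120, 0.150),
             t_close = c(0.100, 0.080, 0.110, 0.140, 0.180, 0.200))
}

pw_grid_burst <- function() {
  pw_cached("grid_burst", {
    cfg <- sim_config(mode = "grid", duration = 2, cadence = 2e-3,
                      grid_control = list(max_change = 0.1))
    run_replay(pw_sched_burst(), cfg)
  })
}

# classified catalogs for the statistics protocol: 3 seeds per condition,
# 5100 s each (first 100 s discarded); conditions in uM
pw_protocol <- function(ip3_values = c(0.01, 0.02, 0.035, 0.05, 0.06,
                                       0.065, 0.07, 0.08),
                        seeds = 1:3, duration = 5100) {
  lapply(setNames(ip3_values, ip3_values), function(ip3)
    pw_cached(sprintf("cat_%g", ip3), {
      lapply(seeds, function(s) quick_catalog(ip3, s, duration))
    }))
}
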