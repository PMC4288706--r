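# Independent oracles and shared fixtures for the test suite.

# closed-form stationary distribution of the 8-state subunit chain under
# detailed balance: activation site independent, (IP3, inhibition) joint
# weights from equilibrium constants (independent of the dynamic solve in
# the package, which uses the generator null space)
stationary_closed_form <- function(ca, p) {
  w <- c(`00` = 1,
         `10` = p$ip3 / p$d[1],
         `01` = ca / p$d[4],
         `11` = p$ip3 * ca / (p$d[1] * p$d[2]))
  w <- w / sum(w)
  qa <- ca / (ca + p$d[5])
  out <- numeric(8)
  for (s in 0:7) {
    i <- s %/% 4L; j <- (s %/% 2L) %% 2L; k <- s %% 2L
    out[s + 1] <- w[[paste0(i, k)]] * if (j == 1) qa else 1 - qa
  }
  names(out) <- state_label(0:7)
  out
}

# a small planted-event layout used across the analysis tests:
# puff, puff, wave, puff
ppwp_spec <- function() {
  fixture_spec(events = data.frame(
    t_start = c(10, 20, 40, 60),
    duration = c(0.5, 1.0, 4.0, 0.8),
    amplitude = c(2, 3, 6, 2),
    label = c("puff", "puff", "wave", "puff"),
    n_openings = c(3, 4, 12, 2)),
    duration = 100)
}

# catalogs from short reduced-mode runs (shared across analysis tests)
quick_catalog <- function(ip3, seed, duration = 600) {
  cfg <- sim_config(ip3 = ip3, duration = duration, seed = seed,
                    mode = "reduced")
  tr <- run_simulation(cfg)
  classify_events(detect_events(tr), tr)
}
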