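test_that("off-rates derive from the dissociation-constant identity", {
  p <- gating_params()
  expect_equal(p$b[1], 0.20 * 0.001)   # 2e-4 / s
  expect_equal(p$b[4], 0.10 * 0.039)   # 3.9e-3 / s
  expect_equal(p$b[5], 25)             # equals the printed cell
  expect_equal(p$b[2], 1.56)
  expect_equal(p$b[3], 0.80)
})

test_that("detailed balance holds for defaults and is enforced", {
  p <- gating_params()
  expect_equal(p$d[1] * p$d[2], 0.078)
  expect_equal(p$d[3] * p$d[4], 0.078)
  expect_error(gating_params(d = c(0.002, 78, 2, 0.039, 0.25)),
               "detailed balance")
  expect_error(gating_params(b = c(NA, 2.0, 0.8, NA, 25)), "inconsistent")
})

test_that("subunit propensities follow the DYK cube rate indices", {
  p <- gating_params(ip3 = 0.01)
  # rest state X000 at 1 uM Ca: binding-only transitions
  tr <- subunit_propensities(state_index("X000"), ca = 1, p)
  rates <- setNames(tr$rate, state_label(tr$target))
  expect_equal(rates[["X100"]], 0.20 * 0.01)  # a1 * ip3
  expect_equal(rates[["X010"]], 100 * 1)      # a5 * ca
  expect_equal(rates[["X001"]], 0.10 * 1)     # a4 * ca
  # fully bound X111 at zero Ca: unbinding only
  tr <- subunit_propensities(state_index("X111"), ca = 0, p)
  rates <- setNames(tr$rate, state_label(tr$target))
  expect_equal(rates[["X011"]], 0.80)  # b3: IP3 leaves while inhibited
  expect_equal(rates[["X101"]], 25)    # b5
  expect_equal(rates[["X110"]], 1.56)  # b2: inhibition leaves with IP3
  # zero ligands: every binding propensity is exactly zero
  p0 <- gating_params(ip3 = 0)
  for (s in 0:7) {
    tr <- subunit_propensities(s, 0, p0)
    bound <- c(state_ip3_bound(s), state_activated(s), state_inhibited(s))
    expect_identical(tr$rate[!bound], rep(0, sum(!bound)))
  }
  expect_error(subunit_propensities(0L, -1, p), "negative")
})

test_that("channel predicates implement the 3-of-4 rules", {
  open_ch <- c(6L, 6L, 6L, 0L)
  expect_true(channel_open(open_ch))
  expect_true(channel_activatable(open_ch))
  expect_false(channel_open(c(6L, 6L, 4L, 0L)))
  # inhibited but still activatable: two X110 + two X111
  expect_true(channel_activatable(c(6L, 6L, 7L, 7L)))
  expect_false(channel_open(c(6L, 6L, 7L, 7L)))
  # open implies activatable on random ensembles
  set.seed(42)
  m <- matrix(sample(0:7, 400, replace = TRUE), ncol = 4)
  expect_true(all(!channel_open(m) | channel_activatable(m)))
})

test_that("stationary distribution matches the detailed-balance closed form", {
  for (ip3 in c(0.01, 0.05, 0.1)) {
    p <- gating_params(ip3 = ip3)
    for (ca in c(0.02, 0.5, 5)) {
      pi_solve <- stationary_subunit_distribution(ca, p)
      expect_equal(sum(pi_solve), 1)
      expect_equal(pi_solve, stationary_closed_form(ca, p),
                   tolerance = 1e-10)
      # pairwise detailed balance on every edge of the cube
      Q <- subunit_generator(ca, p)
      for (s in 0:7) for (tg in 0:7) {
        if (Q[s + 1, tg + 1] > 0 && tg > s) {
          expect_equal(unname(pi_solve[s + 1] * Q[s + 1, tg + 1]),
                       unname(pi_solve[tg + 1] * Q[tg + 1, s + 1]),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("stationary edge cases behave", {
  p0 <- gating_params(ip3 = 0)
  pi0 <- stationary_subunit_distribution(0, p0)
  expect_equal(unname(pi0[["X000"]]), 1)
  # the activation-site marginal factorizes: half saturation at ca = d5
  p <- gating_params(ip3 = 0.05)
  pi_half <- stationary_subunit_distribution(p$d[5], p)
  expect_equal(sum(pi_half[state_activated(0:7)]), 0.5, tolerance = 1e-9)
})

test_that("open probability follows the >=3-of-4 rule and shifts with IP3", {
  p <- gating_params(ip3 = 0.05)
  expect_equal(open_probability(0, p), 0)
  # q = 0.5 synthetic: binomial tail 4 q^3 (1-q) + q^4
  expect_equal(4 * 0.5^3 * 0.5 + 0.5^4, 0.3125)
  ca_grid <- c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8, 1.2, 2)
  ip3s <- c(0.02, 0.05, 0.1, 0.5)
  curves <- sapply(ip3s, function(i)
    open_probability(ca_grid, gating_params(ip3 = i)))
  # nondecreasing in IP3 at fixed Ca
  for (r in seq_along(ca_grid))
    expect_true(all(diff(curves[r, ]) >= -1e-12))
  # the Ca maximizing the open probability moves right with IP3
  argmax <- ca_grid[apply(curves, 2, which.max)]
  expect_true(all(diff(argmax) >= 0))
  expect_gt(argmax[length(argmax)], argmax[1])
})

test_that("IP3 binding is weaker under prolonged inhibition", {
  p <- gating_params(ip3 = 0.05)
  p_bound <- function(ca) {
    pi <- stationary_subunit_distribution(ca, p)
    sum(pi[state_ip3_bound(0:7)])
  }
  expect_lt(p_bound(500), p_bound(1))  # ca >> d2 vs ca << d2
})

test_that("CTMC advance is exact for frozen rates", {
  p <- gating_params(ip3 = 0.05)
  # zero propensities leave channels untouched and the log empty
  p0 <- gating_params(ip3 = 0)
  ch <- matrix(0L, 4, 4)
  res <- advance_channels(ch, 1, rep(0, 4), p0)
  expect_identical(res$channels, ch)
  expect_equal(nrow(res$log), 0)
  expect_error(advance_channels(ch, -1, rep(0, 4), p0), "positive")

  # single-site exponential: activation alone, P(flip) = 1 - exp(-r dt)
  pa <- gating_params(ip3 = 1e-12, a = c(1e-12, 1e-12, 1e-12, 1e-12, 100),
                      b = rep(NA, 5), d = c(1, 1, 1, 1, 0.25),
                      check_balance = FALSE)
  set.seed(7)
  n <- 4000
  dt <- 0.005
  ca <- 0.5
  ch <- matrix(0L, n, 4)
  res <- advance_channels(ch, dt, rep(ca, n), pa)
  r_on <- 100 * ca
  # a site may flip multiple times; compare occupancy with the two-state
  # analytic propagator
  p_eq <- r_on / (r_on + 25)
  p_t <- p_eq * (1 - exp(-(r_on + 25) * dt))
  frac <- mean(res$channels == 2L)
  expect_lt(abs(frac - p_t), 3 * sqrt(p_t * (1 - p_t) / (4 * n)))

  # an ensemble started in the rest state relaxes to the stationary
  # distribution (the IP3 site needs a ~50-s horizon at high Ca)
  set.seed(8)
  n <- 250
  ch <- matrix(0L, n, 4)
  res <- advance_channels(ch, 200, rep(10, n), p)
  occ <- tabulate(as.vector(res$channels) + 1L, 8) / (4 * n)
  pi <- stationary_subunit_distribution(10, p)
  se <- sqrt(pi * (1 - pi) / (4 * n))
  expect_true(all(abs(occ - pi) < 4 * se + 1e-3))
  # log is time ordered
  expect_true(!is.unsorted(res$log$time))
})

test_that("state labels round-trip", {
  expect_equal(state_index(state_label(0:7)), 0:7)
  expect_equal(state_label(6L), "X110")
  expect_error(state_index("X210"), "malformed")
})
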