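test_that("cluster layout places a distinct, centered 4x4 grid", {
  lay <- cluster_layout()
  expect_equal(lay$n_channels, 16)
  expect_equal(colMeans(lay$positions), c(x = 0, y = 0))
  expect_equal(nrow(unique(lay$positions)), 16)
  d <- channel_distances(lay)
  expect_equal(min(d[d > 0]), 120)
  expect_true(isSymmetric(d))
})

test_that("pore indicator uses the closed-disk convention", {
  lay <- cluster_layout()
  px <- lay$positions[3, 1]; py <- lay$positions[3, 2]
  expect_identical(chi_indicator(px, py, 3L, lay), 1L)
  # boundary point at distance exactly r belongs to the disk
  expect_identical(chi_indicator(px + lay$pore_radius, py, 3L, lay), 1L)
  expect_identical(chi_indicator(px + lay$pore_radius + 1e-6, py, 3L, lay), 0L)
  # all channels closed: zero everywhere
  xs <- runif(50, -300, 300); ys <- runif(50, -300, 300)
  expect_identical(chi_indicator(xs, ys, integer(0), lay),
                   integer(50))
  # brute-force distance check against the vectorized implementation
  open_set <- c(1L, 7L, 16L)
  got <- chi_indicator(xs, ys, open_set, lay)
  want <- vapply(seq_along(xs), function(i) {
    d2 <- (xs[i] - lay$positions[open_set, 1])^2 +
      (ys[i] - lay$positions[open_set, 2])^2
    as.integer(any(d2 <= lay$pore_radius^2))
  }, integer(1))
  expect_identical(got, want)
})

test_that("channel current reproduces the pore-disk approximation", {
  expect_equal(signif(channel_current(4.58e6, 6, 700), 2), 0.07)
  expect_equal(channel_current(4.58e6, 6, 1e-12), 0, tolerance = 1e-15)
  # quadratic scaling in the pore radius
  expect_equal(channel_current(4.58e6, 3, 700),
               channel_current(4.58e6, 6, 700) / 4)
})

test_that("membrane flux terms behave at the reference points", {
  fp <- flux_params()
  lay <- cluster_layout()
  # SERCA at half maximum when c = K_d
  expect_equal(serca_flux(fp$K_d, fp), fp$P_p / 2)
  # SERCA occupancy factor at rest
  expect_equal(fp$c0^2 / (fp$K_d^2 + fp$c0^2), 0.1379, tolerance = 1e-3)
  # balanced leak: flux vanishes at rest with closed channels
  expect_equal(membrane_flux(500, 500, fp$c0, integer(0), fp, lay), 0)
  # literal leak coefficient with compensating offset also rests
  fp903 <- flux_params(P_l = 903)
  expect_equal(membrane_flux(500, 500, fp$c0, integer(0), fp903, lay), 0)
  expect_equal(fp903$P_l, 903)
  # open channel dominates at its pore
  px <- lay$positions[6, 1]; py <- lay$positions[6, 2]
  expect_gt(membrane_flux(px, py, fp$c0, 6L, fp, lay), 1e8)
})

test_that("balance_leak solves the rest-state balance", {
  fp <- flux_params()
  expect_equal(fp$P_l * (fp$c_ER - fp$c0), serca_flux(fp$c0, fp))
  # no pump, no leak
  expect_equal(balance_leak(list(P_p = 0, K_d = 0.05, c0 = 0.02, c_ER = 700)), 0)
  # linear in the pump coefficient
  b1 <- balance_leak(list(P_p = 1e4, K_d = 0.05, c0 = 0.02, c_ER = 700))
  b2 <- balance_leak(list(P_p = 2e4, K_d = 0.05, c0 = 0.02, c_ER = 700))
  expect_equal(b2, 2 * b1)
  expect_error(balance_leak(list(P_p = 1, K_d = 1, c0 = 2, c_ER = 1)),
               "no root")
})
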