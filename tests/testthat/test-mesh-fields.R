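test_that("mesh resolves the pores and coarsens monotonically", {
  cfg <- sim_config()
  mesh <- build_mesh(cfg$domain, cfg$layout)
  lay <- cfg$layout
  # finest spacing at the channel sites is at most the pore radius
  for (k in seq_len(lay$n_channels)) {
    ix <- findInterval(lay$positions[k, 1], mesh$x$faces)
    expect_lte(mesh$x$widths[ix], lay$pore_radius + 1e-9)
  }
  expect_lte(mesh$z$widths[1], lay$pore_radius + 1e-9)
  # spacing grows monotonically away from the cluster beyond the pores
  # (the outermost cell may be trimmed to fit the domain exactly)
  out_x <- which(mesh$x$centers > max(lay$positions[, 1]) +
                   2 * lay$pore_radius)
  out_x <- out_x[-length(out_x)]
  expect_true(all(diff(mesh$x$widths[out_x]) >= -1e-9))
  nz <- length(mesh$z$widths)
  expect_true(all(diff(mesh$z$widths[-nz]) >= -1e-9))
  # the mesh tiles the domain exactly
  expect_equal(sum(mesh$x$widths), cfg$domain$Lx)
  expect_equal(sum(mesh$z$widths), cfg$domain$Lz)
  # pore coverage sums to the disk area
  for (k in c(1, 6, 16)) {
    a <- sum(mesh$pore_cover[mesh$pore_cover[, "channel"] == k, "area"])
    expect_equal(a, pi * lay$pore_radius^2, tolerance = 0.02)
  }
})

test_that("box average and domain minimum match quadrature oracles", {
  cfg <- sim_config()
  mesh <- build_mesh(cfg$domain, cfg$layout)
  # uniform field
  st <- field_state(mesh, c = 0.7)
  expect_equal(box_average(st), 0.7)
  expect_equal(domain_minimum(st), 0.7)
  # field nonzero only outside the box averages to zero
  r_out <- with(mesh, as.vector(outer(outer(abs(x$centers) > 260,
                                            abs(y$centers) > 260),
                                      z$centers > 520, "|")))
  st$c <- as.numeric(r_out)
  expect_equal(box_average(st), 0)
  # graded synthetic field against a dense Riemann sum
  f <- function(x, y, z) 0.02 + exp(-(x^2 + y^2 + z^2) / (2 * 300^2))
  st$c <- as.vector(outer(outer(exp(-mesh$x$centers^2 / (2 * 300^2)),
                                exp(-mesh$y$centers^2 / (2 * 300^2))),
                          exp(-mesh$z$centers^2 / (2 * 300^2)))) + 0.02
  gs <- seq(-250 + 2.5, 250 - 2.5, by = 5)
  zs <- seq(2.5, 500 - 2.5, by = 5)
  oracle <- mean(outer(outer(exp(-gs^2 / (2 * 300^2)),
                             exp(-gs^2 / (2 * 300^2))),
                       exp(-zs^2 / (2 * 300^2)))) + 0.02
  expect_equal(box_average(st), oracle, tolerance = 0.02)
  expect_equal(domain_minimum(st), min(st$c))
  expect_error(box_average(st, box_edge = 10000), "exceeds")
})

test_that("mass is conserved with boundary fluxes disabled", {
  cfg <- sim_config(flux = flux_params(P_p = 1e-12, P_l = 0),
                    grid_control = list(dt_max = 0.2))
  mesh <- build_mesh(cfg$domain, cfg$layout)
  blob <- as.vector(outer(outer(exp(-mesh$x$centers^2 / (2 * 200^2)),
                                exp(-mesh$y$centers^2 / (2 * 200^2))),
                          exp(-mesh$z$centers^2 / (2 * 200^2))))
  st <- field_state(mesh, c = 0.02 + 5 * blob, b = 1.98, bp = cfg$buffer)
  m0 <- total_calcium(st)
  st2 <- step_fields(st, 10, integer(0), cfg)
  expect_equal(total_calcium(st2), m0, tolerance = 1e-8)
  # positivity and buffer bounds after the step
  expect_gte(min(st2$c), 0)
  expect_gte(min(st2$b), 0)
  expect_lte(max(st2$b), cfg$buffer$B_total)
  # reaction redistributed mass between the species
  expect_gt(max(abs(st2$b - st$b)), 0.01)
})

test_that("the balanced rest state is a fixed point over 100 s", {
  cfg <- sim_config(grid_control = list(dt_max = 1))
  mesh <- build_mesh(cfg$domain, cfg$layout)
  st <- field_state(mesh, c = cfg$flux$c0, bp = cfg$buffer)
  st2 <- step_fields(st, 100, integer(0), cfg)
  expect_lt(max(abs(st2$c - cfg$flux$c0)), 1e-3 * cfg$flux$c0)
})

test_that("a single central open channel produces a mirror-symmetric field", {
  lay1 <- cluster_layout(n_side = 1L)
  cfg <- sim_config(layout = lay1, domain = domain_spec(1000, 1000, 1000))
  mesh <- build_mesh(cfg$domain, lay1)
  st <- field_state(mesh, c = cfg$flux$c0, bp = cfg$buffer)
  st2 <- step_fields(st, 0.02, 1L, cfg)
  nx <- mesh$dims[1]; ny <- mesh$dims[2]; nz <- mesh$dims[3]
  arr <- array(st2$c, c(nx, ny, nz))
  # mirror in x and in y about the pore axis (mesh is mirror symmetric)
  expect_equal(arr, arr[nx:1, , ], tolerance = 1e-6)
  expect_equal(arr, arr[, ny:1, ], tolerance = 1e-6)
  # and x-y exchange symmetry for the square layout
  expect_equal(arr, aperm(arr, c(2, 1, 3)), tolerance = 1e-6)
  expect_gt(max(st2$c), 1)  # the pore region actually charged
})
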