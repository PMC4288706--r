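# Graded Cartesian finite-volume mesh for the cuboidal cytosolic domain.
# The ER membrane is the z = 0 face; the cluster sits at the center of the
# membrane plane. Cell spacing is finest (<= pore radius) at the channel
# pores and grows linearly with distance up to a cap.

#' Cuboidal domain specification
#'
#' Default 3.25 x 3.25 x 2 um: the height above the membrane (Lz = 2 um) is
#' pinned by the conversion of the volumetric SERCA capacity (10 uM/s)
#' into the boundary flux coefficient (20,000 nm/s); the lateral extents
#' are set so that sustained release does not saturate the pump capacity
#' of the membrane, which would merge distinct release events into one
#' (see the methods vignette).
#'
#' @param Lx,Ly,Lz domain extents, nm.
#' @return object of class `domain_spec`.
#' @export
domain_spec <- function(Lx = 3250, Ly = 3250, Lz = 2000) {
  stopifnot(Lx > 0, Ly > 0, Lz > 0)
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz), class = "domain_spec")
}

# one-dimensional graded cell widths on [0, L2] with refinement centers;
# desired spacing h(x) = h_min within 2*h_min of a center (so the pore
# disks are resolved at h_min), then h_min + slope * distance, capped at
# h_max
.graded_half_axis <- function(L2, centers, h_min, slope, h_max) {
  hfun <- function(x) {
    d <- if (!length(centers)) abs(x) else min(abs(x - centers))
    min(h_max, h_min + slope * max(0, d - 2 * h_min))
  }
  w <- numeric(0)
  x <- 0
  while (x < L2 - 1e-9) {
    h <- hfun(x + hfun(x) / 2)
    h <- min(h, L2 - x)
    # avoid a trailing sliver: merge into the previous cell if tiny
    if (L2 - (x + h) < 0.25 * h && L2 - (x + h) > 0) h <- L2 - x
    w <- c(w, h)
    x <- x + h
  }
  w
}

#' Build the graded finite-volume mesh
#'
#' Tensor-product cell-centered mesh, mirror-symmetric in x and y about the
#' cluster center, with spacing `h_min` at the channel pores (and at the
#' membrane in z) growing linearly with distance (rate `slope`) up to
#' `h_max`. The default `h_min` equals the pore radius so the mesh resolves
#' the pore disks.
#'
#' @param domain a [domain_spec()].
#' @param layout a [cluster_layout()].
#' @param h_min finest spacing, nm (default the pore radius).
#' @param slope linear growth rate of spacing with distance (dimensionless).
#' @param h_max coarsest spacing, nm.
#' @return object of class `fv_mesh` with per-axis centers and widths,
#'   `dims`, cell `volumes` implicit as the width outer product, and the
#'   membrane-cell pore coverage table `pore_cover` (columns `cell2d`
#'   0-based membrane cell index, `channel`, `area` covered, nm^2).
#' @export
build_mesh <- function(domain, layout, h_min = layout$pore_radius,
                       slope = 0.5, h_max = 150) {
  stopifnot(h_min > 0, slope > 0, h_max >= h_min)
  half_x <- .graded_half_axis(domain$Lx / 2, abs(unique(layout$positions[, 1])),
                              h_min, slope, h_max)
  half_y <- .graded_half_axis(domain$Ly / 2, abs(unique(layout$positions[, 2])),
                              h_min, slope, h_max)
  wx <- c(rev(half_x), half_x)
  wy <- c(rev(half_y), half_y)
  wz <- .graded_half_axis(domain$Lz, 0, h_min, slope, h_max)
  ax <- function(w, x0) {
    f <- x0 + cumsum(c(0, w))
    list(widths = w, faces = f, centers = (f[-1] + f[-length(f)]) / 2)
  }
  m <- structure(list(x = ax(wx, -domain$Lx / 2),
                      y = ax(wy, -domain$Ly / 2),
                      z = ax(wz, 0),
                      dims = c(length(wx), length(wy), length(wz)),
                      domain = domain, layout = layout,
                      h_min = h_min, slope = slope, h_max = h_max),
                 class = "fv_mesh")
  m$pore_cover <- .pore_coverage(m, layout)
  m$ctrl_mask <- .pore_mask(m, layout)
  m
}

# cells within mask_radius of a pore center (3D, z from the membrane):
# excluded from the step-size error metric of the integrator
.pore_mask <- function(mesh, layout, mask_radius = 4 * layout$pore_radius) {
  near2 <- function(axis, p) {
    d <- outer(axis, p, "-")
    apply(d^2, 1, min)
  }
  dx2 <- near2(mesh$x$centers, layout$positions[, 1])
  dy2 <- near2(mesh$y$centers, layout$positions[, 2])
  # lateral distance to the nearest pore is approximated per axis; exact
  # enough for a control mask
  lat2 <- outer(dx2, dy2, "+")
  r2 <- outer(as.vector(lat2), mesh$z$centers^2, "+")
  as.integer(as.vector(r2) <= mask_radius^2)
}

# area of each membrane cell face covered by each pore disk (16x16
# subsampling of candidate faces; deterministic)
.pore_coverage <- function(mesh, layout) {
  nx <- mesh$dims[1]
  fx <- mesh$x$faces; fy <- mesh$y$faces
  r <- layout$pore_radius
  rows <- list()
  ss <- (seq_len(16) - 0.5) / 16
  for (k in seq_len(layout$n_channels)) {
    px <- layout$positions[k, 1]; py <- layout$positions[k, 2]
    ix <- which(fx[-length(fx)] < px + r & fx[-1] > px - r)
    iy <- which(fy[-length(fy)] < py + r & fy[-1] > py - r)
    for (i in ix) for (j in iy) {
      xs <- fx[i] + ss * mesh$x$widths[i]
      ys <- fy[j] + ss * mesh$y$widths[j]
      g <- expand.grid(x = xs, y = ys)
      frac <- mean((g$x - px)^2 + (g$y - py)^2 <= r^2)
      if (frac > 0)
        rows[[length(rows) + 1]] <-
          c(cell2d = (i - 1) + nx * (j - 1), channel = k,
            area = frac * mesh$x$widths[i] * mesh$y$widths[j])
    }
  }
  if (!length(rows)) return(matrix(numeric(0), 0, 3,
                                   dimnames = list(NULL, c("cell2d", "channel", "area"))))
  do.call(rbind, rows)
}

#' @export
print.fv_mesh <- function(x, ...) {
  cat("finite-volume mesh:", paste(x$dims, collapse = " x "),
      "cells (", prod(x$dims), ")\n")
  cat("  spacing", x$h_min, "-", x$h_max, "nm, domain",
      x$domain$Lx, "x", x$domain$Ly, "x", x$domain$Lz, "nm\n")
  invisible(x)
}

#' Concentration field state on a mesh
#'
#' Free Ca2+ field `c` and bound-buffer field `b` (uM) as vectors in cell
#' order (x fastest), plus the current time.
#'
#' @param mesh an [fv_mesh()].
#' @param c initial free Ca2+, scalar or full vector, uM.
#' @param b initial bound buffer, scalar or full vector, uM; default the
#'   reaction equilibrium B_total c / (K + c) for scalar `c`.
#' @param bp a [buffer_params()] (used for the default `b`).
#' @param t initial time, s.
#' @return object of class `field_state`.
#' @export
field_state <- function(mesh, c = 0.02, b = NULL, bp = buffer_params(), t = 0) {
  n <- prod(mesh$dims)
  cv <- rep_len(c, n)
  if (is.null(b)) b <- bp$B_total * cv / (bp$K + cv)
  bv <- rep_len(b, n)
  if (any(cv < 0) || any(bv < 0) || any(bv > bp$B_total + 1e-9))
    stop("initial fields violate bounds")
  structure(list(c = cv, b = bv, t = t, mesh = mesh), class = "field_state")
}

#' Volume-weighted average of the Ca2+ field over the cluster box
#'
#' Mean free Ca2+ over a cube of edge `box_edge` centered laterally on the
#' cluster center and sitting on the membrane (z from 0 to `box_edge`),
#' weighting each cell by its overlap volume with the box.
#'
#' @param state a [field_state()].
#' @param box_edge box edge length, nm (default 500).
#' @return mean concentration, uM.
#' @export
box_average <- function(state, box_edge = 500) {
  m <- state$mesh
  h <- box_edge / 2
  if (h > m$domain$Lx / 2 || h > m$domain$Ly / 2 || box_edge > m$domain$Lz)
    stop("box exceeds domain")
  ov <- function(f, lo, hi) pmax(0, pmin(f[-1], hi) - pmax(f[-length(f)], lo))
  wx <- ov(m$x$faces, -h, h); wy <- ov(m$y$faces, -h, h)
  wz <- ov(m$z$faces, 0, box_edge)
  w <- as.vector(outer(outer(wx, wy), wz))
  sum(w * state$c) / sum(w)
}

#' Minimum of the Ca2+ field over the domain
#'
#' @param state a [field_state()].
#' @return minimum free Ca2+ over all mesh cells, uM.
#' @export
domain_minimum <- function(state) min(state$c)

#' Total dissolved calcium in the domain
#'
#' Volume integral of c + b, for conservation checks. Units uM nm^3.
#' @param state a [field_state()].
#' @return total amount, uM nm^3.
#' @export
total_calcium <- function(state) {
  m <- state$mesh
  v <- as.vector(outer(outer(m$x$widths, m$y$widths), m$z$widths))
  sum(v * (state$c + state$b))
}

#' Ca2+ along the membrane line through the cluster center
#'
#' Samples the first cell layer at the membrane along x at the y-row
#' nearest the cluster center (the sampling line of a line-scan record).
#'
#' @param state a [field_state()].
#' @return data frame with `x` (nm) and `c` (uM).
#' @export
line_scan <- function(state) {
  m <- state$mesh
  iy <- which.min(abs(m$y$centers))
  nx <- m$dims[1]
  idx <- seq_len(nx) + nx * (iy - 1)   # iz = 0 layer
  data.frame(x = m$x$centers, c = state$c[idx])
}
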