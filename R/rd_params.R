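# Reaction-diffusion domain: geometry, buffer and membrane-flux parameters,
# and the closed-form flux relations. Units are fixed at uM, nm, s, pA
# throughout the package interface.

#' Faraday constant, C/mol
#' @keywords internal
.faraday <- 96485.33212

#' Geometry of the channel cluster on the ER membrane
#'
#' A single cluster of `n_side^2` IP3R channels in a regular grid centered
#' in the membrane plane (z = 0 face of the cuboid), default 4x4 channels
#' 120 nm apart with 6 nm pore radius.
#'
#' @param n_side channels per grid side (default 4, i.e. 16 channels).
#' @param spacing inter-channel distance, nm.
#' @param pore_radius channel pore radius, nm.
#' @return object of class `cluster_layout` with `positions` (n x 2 matrix
#'   of x, y pore-center coordinates, nm, cluster centered at the origin),
#'   `n_channels`, `spacing`, `pore_radius`.
#' @export
cluster_layout <- function(n_side = 4L, spacing = 120, pore_radius = 6) {
  stopifnot(n_side >= 1, spacing > 0, pore_radius > 0)
  g <- (seq_len(n_side) - (n_side + 1) / 2) * spacing
  pos <- as.matrix(expand.grid(x = g, y = g))
  if (anyDuplicated(pos)) stop("channel positions must be pairwise distinct")
  structure(list(n_channels = n_side^2, n_side = as.integer(n_side),
                 spacing = spacing, pore_radius = pore_radius,
                 positions = pos),
            class = "cluster_layout")
}

#' Pairwise inter-channel distances
#' @param layout a [cluster_layout()].
#' @return n x n matrix of center distances, nm.
#' @export
channel_distances <- function(layout) {
  as.matrix(stats::dist(layout$positions))
}

#' Mobile buffer parameters
#'
#' One mobile Ca2+ buffer species with simple bimolecular kinetics.
#' Defaults: total concentration 200 uM, on-rate 150 1/(uM s), off-rate
#' 300 1/s (equilibrium dissociation 2 uM), diffusion 5 um^2/s (a mobile
#' protein/dextran-scale buffer; together with the lateral domain extent
#' this sets the lifetime of the residual calcium domain - see the methods
#' vignette).
#'
#' @param D_b buffer diffusion coefficient, nm^2/s.
#' @param B_total total buffer concentration, uM.
#' @param k_on binding rate, 1/(uM s).
#' @param k_off unbinding rate, 1/s.
#' @return object of class `buffer_params`.
#' @export
buffer_params <- function(D_b = 5e6, B_total = 200, k_on = 150, k_off = 300) {
  stopifnot(D_b > 0, B_total > 0, k_on > 0, k_off > 0)
  structure(list(D_b = D_b, B_total = B_total, k_on = k_on, k_off = k_off,
                 K = k_off / k_on),
            class = "buffer_params")
}

#' Membrane flux parameters
#'
#' Channel, SERCA-pump and leak flux coefficients of the ER membrane
#' boundary condition, plus luminal and resting cytosolic Ca2+.
#' The SERCA Hill coefficient is fixed at 2. If `P_l` is `NULL` the leak
#' coefficient is computed by [balance_leak()] so that the closed-channel
#' rest state is an exact fixed point; if a literal `P_l` is given, a
#' constant compensating offset is added so that the rest state is still a
#' fixed point (the leak's stated purpose).
#'
#' @param P_ch channel flux coefficient, nm/s.
#' @param P_p SERCA pump coefficient, nm/s (volume pump rate times domain
#'   height).
#' @param K_d SERCA dissociation constant, uM.
#' @param P_l leak coefficient, nm/s, or `NULL` to balance at rest.
#' @param c_ER luminal ER Ca2+ (constant), uM.
#' @param c0 resting cytosolic Ca2+, uM.
#' @param D_c free Ca2+ diffusion coefficient, nm^2/s.
#' @return object of class `flux_params`; `$P_l` the leak coefficient used,
#'   `$leak_offset` the constant offset (uM nm/s, zero in balanced mode).
#' @export
flux_params <- function(P_ch = 4.58e6, P_p = 20000, K_d = 0.05,
                        P_l = NULL, c_ER = 700, c0 = 0.02, D_c = 223e6) {
  stopifnot(P_ch > 0, P_p >= 0, K_d > 0, c_ER > 0, c0 >= 0, D_c > 0)
  fp <- structure(list(P_ch = P_ch, P_p = P_p, K_d = K_d,
                       P_l = NA_real_, leak_offset = 0,
                       c_ER = c_ER, c0 = c0, D_c = D_c,
                       faraday_constant = .faraday),
                  class = "flux_params")
  if (is.null(P_l)) {
    fp$P_l <- balance_leak(fp)
  } else {
    stopifnot(P_l >= 0)
    fp$P_l <- P_l
    # constant offset making J(c0, closed) = 0 with the literal coefficient
    fp$leak_offset <- P_l * (c_ER - c0) - serca_flux(c0, fp)
  }
  fp
}

#' Pore indicator function on the membrane
#'
#' 1 iff the membrane point lies within (closed-disk convention, distance
#' <= pore radius) the pore of an open channel, else 0. Controls the
#' channel term of the membrane flux.
#'
#' @param x,y membrane-plane coordinates, nm (vectorized).
#' @param open_set integer indices (1-based) of open channels.
#' @param layout a [cluster_layout()].
#' @return integer vector of 0/1.
#' @export
chi_indicator <- function(x, y, open_set, layout) {
  out <- integer(length(x))
  r2 <- layout$pore_radius^2
  for (k in open_set) {
    d2 <- (x - layout$positions[k, 1])^2 + (y - layout$positions[k, 2])^2
    out[d2 <= r2] <- 1L
  }
  out
}

#' Single-channel current from the pore-disk flux approximation
#'
#' The Ca2+ current through one open pore, approximating the pore-disk
#' integral of the channel flux with c << c_ER:
#' I = 2 F P_ch pi r^2 c_ER, returned in pA.
#'
#' @param P_ch channel flux coefficient, nm/s.
#' @param r pore radius, nm.
#' @param c_ER luminal Ca2+, uM.
#' @return current in pA.
#' @export
channel_current <- function(P_ch, r, c_ER) {
  stopifnot(P_ch > 0, r > 0, c_ER >= 0)
  # uM * nm^3/s = 1e-30 mol/s; 2F C/mol; 1 A = 1e12 pA
  q <- P_ch * pi * r^2 * c_ER            # uM nm^3 / s
  2 * .faraday * q * 1e-30 * 1e12        # pA
}

#' SERCA pump flux density
#'
#' Hill-type (coefficient 2) pump term P_p c^2 / (K_d^2 + c^2), uM nm/s,
#' directed out of the cytosol.
#'
#' @param c cytosolic Ca2+, uM (vectorized).
#' @param fp a [flux_params()] object.
#' @return flux density, uM nm/s.
#' @export
serca_flux <- function(c, fp) fp$P_p * c^2 / (fp$K_d^2 + c^2)

#' Membrane flux density at a membrane point
#'
#' The ER-membrane boundary flux for free Ca2+ (uM nm/s, positive into the
#' cytosol): channel flux P_ch chi (c_ER - c) plus leak P_l (c_ER - c)
#' (minus the compensating offset in literal-leak mode), minus the SERCA
#' Hill-2 term. The bound-buffer field has a zero-flux membrane condition.
#'
#' @param x,y membrane coordinates, nm.
#' @param c local free Ca2+ at the membrane, uM.
#' @param open_set open channel indices (1-based).
#' @param fp a [flux_params()] object.
#' @param layout a [cluster_layout()].
#' @return flux density, uM nm/s (amount per area per time, positive into
#'   the cytosol).
#' @export
membrane_flux <- function(x, y, c, open_set, fp, layout) {
  chi <- chi_indicator(x, y, open_set, layout)
  fp$P_ch * chi * (fp$c_ER - c) + fp$P_l * (fp$c_ER - c) - fp$leak_offset -
    serca_flux(c, fp)
}

#' Leak coefficient balancing SERCA at rest
#'
#' Solves P_l (c_ER - c0) = P_p c0^2 / (K_d^2 + c0^2) so that the membrane
#' flux with all channels closed vanishes exactly at the resting
#' concentration; with this coefficient a simulation started at rest with
#' closed channels stays at rest.
#'
#' @param fp a [flux_params()]-like list with `P_p`, `K_d`, `c0`, `c_ER`.
#' @return leak coefficient P_l, nm/s.
#' @export
balance_leak <- function(fp) {
  if (fp$c_ER <= fp$c0) stop("no root: c_ER must exceed c0")
  fp$P_p * fp$c0^2 / (fp$K_d^2 + fp$c0^2) / (fp$c_ER - fp$c0)
}
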