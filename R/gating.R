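# Modified DeYoung-Keizer (DYK) subunit/channel gating model.
#
# Each IP3R channel has 4 identical subunits; each subunit carries an IP3
# binding site, an activating Ca2+ site and an inhibiting Ca2+ site, giving
# 8 subunit states X_ijk (i = IP3 site, j = activating site, k = inhibiting
# site; 1 = bound). Encoded as the 3-bit integer s = 4i + 2j + k (0..7).
#
# Rate-index convention (all rates per site):
#   1  IP3 binding/unbinding while not inhibited (k = 0)
#   2  inhibition binding/unbinding with IP3 bound (i = 1)
#   3  IP3 binding/unbinding while inhibited (k = 1)
#   4  inhibition binding/unbinding without IP3 (i = 0)
#   5  activation binding/unbinding (always)
# Binding propensity a_i * [ligand] (ligand = Ca2+ for the two Ca2+ sites,
# IP3 for the IP3 site), unbinding propensity b_i = a_i * d_i.

#' Default DYK rate constants
#'
#' On-rates `a` (1/(uM s)) and dissociation constants `d` (uM) of the
#' modified DYK scheme for type-1 IP3R channels. Off-rates `b` (1/s) follow
#' from b_i = a_i d_i; the two cells not derivable independently (b1, b4)
#' are filled by [derive_missing_offrates()].
#'
#' @name dyk-defaults
#' @keywords internal
NULL

.dyk_default_a <- c(0.20, 0.02, 0.40, 0.10, 100)
.dyk_default_d <- c(0.001, 78, 2, 0.039, 0.25)
.dyk_default_b <- c(NA, 1.56, 0.80, NA, 25)

#' Construct and validate DYK gating parameters
#'
#' @param ip3 ambient IP3 concentration (uM). Constant over a run.
#' @param a on-rate constants a_1..a_5, 1/(uM s).
#' @param b off-rate constants b_1..b_5, 1/s. `NA` entries are filled from
#'   b_i = a_i d_i via [derive_missing_offrates()].
#' @param d dissociation constants d_1..d_5, uM.
#' @param check_balance if `TRUE` (default) the detailed-balance constraint
#'   d1 d2 = d3 d4 is enforced; it guarantees that the stationary subunit
#'   distribution satisfies pairwise detailed balance on every edge of the
#'   DYK cube. Set `FALSE` only for deliberately degenerate configurations
#'   (e.g. sites switched off in analytic checks).
#' @param tol relative tolerance for the balance residual and for
#'   consistency of supplied b with a*d.
#' @return an object of class `gating_params`.
#' @export
gating_params <- function(ip3 = 0.05,
                          a = .dyk_default_a,
                          b = .dyk_default_b,
                          d = .dyk_default_d,
                          check_balance = TRUE,
                          tol = 1e-9) {
  stopifnot(length(a) == 5, length(b) == 5, length(d) == 5, length(ip3) == 1)
  if (ip3 < 0) stop("ip3 must be nonnegative")
  if (any(a < 0) || any(d < 0)) stop("rate constants must be nonnegative")
  p <- structure(list(a = as.numeric(a), b = as.numeric(b),
                      d = as.numeric(d), ip3 = as.numeric(ip3)),
                 class = "gating_params")
  p <- derive_missing_offrates(p)
  known <- !is.na(b)
  bad <- known & abs(p$b - a * d) > tol * pmax(1, abs(a * d))
  if (any(bad))
    stop("off-rates inconsistent with b_i = a_i * d_i at index ",
         paste(which(bad), collapse = ", "))
  if (check_balance) {
    if (any(c(p$a, p$b, p$d) <= 0))
      stop("all gating rate constants must be strictly positive")
    resid <- abs(p$d[1] * p$d[2] - p$d[3] * p$d[4])
    if (resid > tol * max(1, p$d[1] * p$d[2]))
      stop("detailed balance violated: d1*d2 != d3*d4 (residual ",
           format(resid), " uM^2)")
  }
  p
}

#' Fill off-rates from the dissociation-constant identity
#'
#' Off-rate table cells that are not specified are recovered from
#' b_i = a_i d_i, the definition of the dissociation constant.
#'
#' @param p a `gating_params` object (possibly with `NA` off-rates).
#' @return `p` with all off-rates set.
#' @export
derive_missing_offrates <- function(p) {
  miss <- is.na(p$b)
  p$b[miss] <- p$a[miss] * p$d[miss]
  p
}

#' @export
print.gating_params <- function(x, ...) {
  cat("DYK gating parameters ([IP3] =", x$ip3, "uM)\n")
  tab <- data.frame(i = 1:5,
                    a = x$a, b = x$b, d = x$d,
                    row.names = c("IP3 (not inhibited)", "inhibition (IP3 bound)",
                                  "IP3 (inhibited)", "inhibition (no IP3)",
                                  "activation"))
  names(tab) <- c("i", "a [1/(uM s)]", "b [1/s]", "d [uM]")
  print(tab, ...)
  invisible(x)
}

# -- subunit state helpers ----------------------------------------------------

#' Subunit state encoding
#'
#' Subunit states are 3-bit integers s = 4i + 2j + k with i the IP3 site,
#' j the activating Ca2+ site and k the inhibiting Ca2+ site (1 = bound).
#' `state_label(6)` is `"X110"`; `state_index("X110")` is `6`.
#'
#' @param s integer vector of states in 0..7.
#' @param label character vector like `"X110"`.
#' @return labels, indices, or logical site occupancies.
#' @export
state_label <- function(s) {
  stopifnot(all(s %in% 0:7))
  paste0("X", s %/% 4L, (s %/% 2L) %% 2L, s %% 2L)
}

#' @rdname state_label
#' @export
state_index <- function(label) {
  m <- regmatches(label, regexec("^X([01])([01])([01])$", label))
  if (any(lengths(m) != 4)) stop("malformed state label")
  vapply(m, function(g) 4L * as.integer(g[2]) + 2L * as.integer(g[3]) +
           as.integer(g[4]), integer(1))
}

#' @rdname state_label
#' @export
state_ip3_bound <- function(s) (s %/% 4L) == 1L

#' @rdname state_label
#' @export
state_activated <- function(s) ((s %/% 2L) %% 2L) == 1L

#' @rdname state_label
#' @export
state_inhibited <- function(s) (s %% 2L) == 1L

#' Channel-level predicates
#'
#' A channel (4 subunits) is open iff at least 3 subunits are in X110
#' (IP3 and activating Ca2+ bound, not inhibited); it is activatable iff at
#' least 3 subunits have IP3 bound. Open implies activatable.
#'
#' @param subunits integer vector of length 4 (one channel) or a matrix
#'   with 4 columns (one row per channel), states in 0..7.
#' @return logical scalar or vector.
#' @export
channel_open <- function(subunits) {
  if (is.matrix(subunits)) return(rowSums(subunits == 6L) >= 3L)
  sum(subunits == 6L) >= 3L
}

#' @rdname channel_open
#' @export
channel_activatable <- function(subunits) {
  if (is.matrix(subunits)) return(rowSums(subunits >= 4L) >= 3L)
  sum(subunits >= 4L) >= 3L
}

# -- propensities -------------------------------------------------------------

#' Transition propensities of one subunit
#'
#' Returns the (at most three) transitions leaving subunit state `s`, one
#' per binding site, with propensities from the DYK cube: binding at
#' a_i * [ligand], unbinding at b_i. The rate index is selected by the
#' occupancy of the other sites: the IP3 site uses i = 1 when not inhibited
#' and i = 3 when inhibited; the inhibiting site uses i = 2 when IP3 is
#' bound and i = 4 when not; the activating site always uses i = 5.
#'
#' @param s subunit state, integer 0..7.
#' @param ca local Ca2+ concentration (uM) driving the two Ca2+ sites.
#' @param p a [gating_params()] object; `p$ip3` drives the IP3 site.
#' @return data frame with columns `target` (state 0..7), `site`
#'   (`"ip3"`, `"act"`, `"inh"`) and `rate` (1/s).
#' @export
subunit_propensities <- function(s, ca, p) {
  stopifnot(length(s) == 1, s %in% 0:7, length(ca) == 1)
  if (ca < 0) stop("negative Ca2+ concentration")
  i <- s %/% 4L; j <- (s %/% 2L) %% 2L; k <- s %% 2L
  idx_ip3 <- if (k == 1L) 3L else 1L
  idx_inh <- if (i == 1L) 2L else 4L
  rate_ip3 <- if (i == 1L) p$b[idx_ip3] else p$a[idx_ip3] * p$ip3
  rate_act <- if (j == 1L) p$b[5] else p$a[5] * ca
  rate_inh <- if (k == 1L) p$b[idx_inh] else p$a[idx_inh] * ca
  data.frame(target = c(bitwXor(s, 4L), bitwXor(s, 2L), bitwXor(s, 1L)),
             site = c("ip3", "act", "inh"),
             rate = c(rate_ip3, rate_act, rate_inh),
             stringsAsFactors = FALSE)
}

#' Generator matrix of the 8-state subunit chain
#'
#' @inheritParams subunit_propensities
#' @return 8x8 rate matrix Q with Q[s+1, t+1] the rate s -> t and
#'   rows summing to zero.
#' @export
subunit_generator <- function(ca, p) {
  Q <- matrix(0, 8, 8, dimnames = list(state_label(0:7), state_label(0:7)))
  for (s in 0:7) {
    tr <- subunit_propensities(s, ca, p)
    Q[s + 1L, tr$target + 1L] <- tr$rate
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of a subunit at fixed concentrations
#'
#' Solves the stationary condition pi^T Q = 0, sum(pi) = 1 of the 8-state
#' generator by a direct linear solve. Because the detailed-balance
#' constraint d1 d2 = d3 d4 holds, the solution also satisfies pairwise
#' detailed balance on every edge of the DYK cube and factorizes over an
#' independent activation site and a joint (IP3, inhibition) pair; that
#' closed form is used as an independent oracle in the tests, not here.
#'
#' @inheritParams subunit_propensities
#' @return named probability vector of length 8 (states X000..X111 in
#'   integer order 0..7).
#' @export
stationary_subunit_distribution <- function(ca, p) {
  if (ca < 0) stop("negative Ca2+ concentration")
  Q <- subunit_generator(ca, p)
  if (all(Q == 0)) stop("singular generator: all rates zero")
  A <- rbind(t(Q), rep(1, 8))
  rhs <- c(rep(0, 8), 1)
  pi <- tryCatch(qr.solve(A, rhs), error = function(e)
    stop("stationary solve failed: ", conditionMessage(e)))
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0)) stop("stationary solve produced negative probabilities")
  pi <- pi / sum(pi)
  names(pi) <- state_label(0:7)
  pi
}

#' Steady-state open probability of a channel
#'
#' With q the stationary probability of subunit state X110, the channel
#' (>= 3 of 4 subunits in X110) open probability is 4 q^3 (1-q) + q^4.
#' For fixed Ca2+ it is nondecreasing in IP3, and the Ca2+ value maximizing
#' it shifts to higher Ca2+ as IP3 increases.
#'
#' @param ca Ca2+ concentration(s), uM; vectorized.
#' @param p a [gating_params()] object.
#' @return open probability, same length as `ca`.
#' @export
open_probability <- function(ca, p) {
  vapply(ca, function(cc) {
    q <- stationary_subunit_distribution(cc, p)[["X110"]]
    4 * q^3 * (1 - q) + q^4
  }, numeric(1))
}

# -- stochastic advance -------------------------------------------------------

#' Advance a set of channels by exact CTMC sampling
#'
#' Advances every subunit of every channel over `[t, t + dt)` with rates
#' held constant (the hybrid scheme freezes concentrations over macro
#' steps). Sampling is statistically exact for constant rates: per subunit,
#' competing exponential waiting times are drawn from the current
#' propensities, the earliest transition below `dt` is applied, propensities
#' are recomputed, and the procedure repeats. Uses R's RNG stream.
#'
#' @param channels integer matrix, one row per channel, 4 columns of
#'   subunit states 0..7.
#' @param dt time step, s (> 0).
#' @param ca_per_channel Ca2+ concentration (uM) driving each channel; one
#'   value per row of `channels`.
#' @param p a [gating_params()] object.
#' @param t0 absolute start time attached to the transition log.
#' @return list with `channels` (advanced matrix) and `log`, a data frame
#'   (time, channel 1-based, subunit, from, to) of applied transitions in
#'   time order.
#' @export
advance_channels <- function(channels, dt, ca_per_channel, p, t0 = 0) {
  if (!is.matrix(channels) || ncol(channels) != 4)
    stop("channels must be a matrix with 4 columns")
  if (dt <= 0) stop("dt must be positive")
  if (length(ca_per_channel) != nrow(channels))
    stop("one driving concentration per channel required")
  if (any(ca_per_channel < 0)) stop("negative Ca2+ concentration")
  res <- advance_channels_cpp(channels, dt, ca_per_channel,
                              p$a, p$b, p$ip3)
  log <- as.data.frame(res$log)
  names(log) <- c("time", "channel", "subunit", "from", "to")
  if (nrow(log)) log$time <- log$time + t0
  list(channels = res$channels, log = log)
}

#' Draw initial subunit states from the stationary regime
#'
#' Initial channel states are drawn independently per subunit from the
#' stationary distribution at a given (typically high) Ca2+ concentration,
#' emulating a cluster with low excitability after strong prior activity.
#'
#' @param n_channels number of channels.
#' @param ca Ca2+ concentration (uM) of the initializing regime.
#' @param p a [gating_params()] object.
#' @return integer matrix `n_channels` x 4 of subunit states.
#' @export
draw_initial_channels <- function(n_channels, ca, p) {
  pi <- stationary_subunit_distribution(ca, p)
  matrix(sample(0:7, n_channels * 4L, replace = TRUE, prob = pi),
         nrow = n_channels, ncol = 4L)
}
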