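# Hybrid simulation: couples the stochastic DYK gating to the
# deterministic concentration model. Three modes:
#   grid    - full reaction-diffusion on the finite-volume mesh
#   reduced - calibrated two-compartment + kernel model for long traces
#   replay  - prescribed gating schedule driving the fields (no stochastic
#             gating); used for domain-size and mesh sensitivity checks
#             and for calibrating the reduced mode against the grid.

#' Reduced-domain model parameters
#'
#' The reduced mode represents the concentration field by two well-mixed
#' compartments (the 500-nm cluster box and the remaining bulk, the latter
#' standing in for the domain minimum) plus, per channel, a nanodomain
#' kernel K(d) = amp * exp(-d/lambda) / d giving the concentration a closed
#' channel sees per open channel at center distance d, and a residual term
#' that memorizes the kernel superposition at each open-set change and
#' decays with `tau_domain`. Defaults are calibrated against the package's
#' grid solver with [calibrate_reduced()] (single-channel replay on the
#' default mesh; see the methods vignette).
#'
#' @param kern_amp kernel amplitude, uM nm.
#' @param kern_lambda kernel decay length, nm.
#' @param tau_domain residual decay time, s.
#' @param g_box box-bulk exchange conductance for total calcium, um^3/s.
#' @param box_excess nanodomain inflation of the box average per open
#'   channel, uM: closed channels are driven from the baseline
#'   c_box - n_open * box_excess (floored at the bulk value) plus kernel
#'   and residual terms.
#' @param Q release rate of total calcium per open channel, uM um^3/s
#'   (default the pore-disk flux at the fixed 150 uM pore concentration).
#' @param ca_open fixed Ca2+ concentration driving open channels, uM.
#' @param dt_open,dt_closed,dt_elevated macro-step caps (s) while any
#'   channel is open / at rest / while the box is still elevated above
#'   `c_elevated`.
#' @param c_elevated box concentration (uM) above which the shorter
#'   `dt_elevated` cap applies.
#' @param sub_h compartment-ODE substep, s.
#' @return object of class `reduced_params`.
#' @export
reduced_params <- function(kern_amp = 465.4, kern_lambda = 101.2,
                           tau_domain = 1.276e-3, g_box = 937.7,
                           Q = 342.5, box_excess = 0.2465, ca_open = 150,
                           dt_open = 1e-3, dt_closed = 1e-2,
                           dt_elevated = 2e-3, c_elevated = 0.05,
                           sub_h = 2e-4) {
  structure(list(kern_amp = kern_amp, kern_lambda = kern_lambda,
                 tau_domain = tau_domain, g_box = g_box, Q = Q,
                 box_excess = box_excess, ca_open = ca_open,
                 dt_open = dt_open,
                 dt_closed = dt_closed, dt_elevated = dt_elevated,
                 c_elevated = c_elevated, sub_h = sub_h),
            class = "reduced_params")
}

#' Simulation configuration
#'
#' Collects every parameter block of a run. Defaults reproduce the
#' reference parameter tables (gating constants, buffer, fluxes, 16-channel
#' cluster).
#'
#' @param ip3 ambient IP3 concentration, uM.
#' @param duration simulated time, s.
#' @param transient_discard initial interval excluded from statistics, s.
#' @param seed RNG seed of the run.
#' @param mode one of `"reduced"`, `"grid"`, `"replay"`.
#' @param cadence output sampling interval, s.
#' @param ca_init Ca2+ concentration (uM) of the stationary regime from
#'   which initial channel states are drawn (high Ca2+ = low excitability).
#' @param box_edge edge of the cluster-vicinity averaging box, nm.
#' @param log_subunits record the full subunit transition log (memory-heavy
#'   for long runs; channel open/close events are always logged).
#' @param gating,layout,domain,buffer,flux,reduced parameter blocks; see
#'   [gating_params()], [cluster_layout()], [domain_spec()],
#'   [buffer_params()], [flux_params()], [reduced_params()].
#' @param grid_control list of grid-solver controls: `h_min`, `slope`,
#'   `h_max` (mesh grading, nm), `dt0`, `dt_max` (s), `max_change`
#'   (relative-change bound per accepted step).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(ip3 = 0.05, duration = 10, transient_discard = 100,
                       seed = 1L, mode = c("reduced", "grid", "replay"),
                       cadence = 0.01, ca_init = 10, box_edge = 500,
                       log_subunits = FALSE,
                       gating = gating_params(ip3 = ip3),
                       layout = cluster_layout(),
                       domain = domain_spec(),
                       buffer = buffer_params(),
                       flux = flux_params(),
                       reduced = reduced_params(),
                       grid_control = list()) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be positive")
  if (transient_discard < 0) stop("transient_discard must be nonnegative")
  if (cadence <= 0) stop("cadence must be positive")
  gating$ip3 <- ip3
  gc0 <- list(h_min = layout$pore_radius, slope = 0.5, h_max = 150,
              dt0 = 1e-6, dt_max = 0.05, max_change = 0.2, theta = 0.55)
  gc0[names(grid_control)] <- grid_control
  structure(list(ip3 = ip3, duration = duration,
                 transient_discard = transient_discard,
                 seed = as.integer(seed), mode = mode, cadence = cadence,
                 ca_init = ca_init, box_edge = box_edge,
                 log_subunits = log_subunits, gating = gating,
                 layout = layout, domain = domain, buffer = buffer,
                 flux = flux, reduced = reduced, grid_control = gc0),
            class = "sim_config")
}

.reduced_filled <- function(cfg) {
  rp <- cfg$reduced
  if (is.null(rp$Q)) {
    fp <- cfg$flux
    rp$Q <- fp$P_ch * pi * cfg$layout$pore_radius^2 *
      (fp$c_ER - rp$ca_open) * 1e-9  # uM nm^3/s -> uM um^3/s
  }
  rp
}

.new_trace <- function(time, n_open, n_activatable, box_avg_ca,
                       domain_min_ca, open_log, config, mode,
                       transitions = NULL, extra = list()) {
  open_log <- as.data.frame(open_log)
  names(open_log) <- c("time", "channel", "open")
  tr <- c(list(time = time, n_open = n_open, n_activatable = n_activatable,
               box_avg_ca = box_avg_ca, domain_min_ca = domain_min_ca,
               open_log = open_log, transitions = transitions,
               config = config, seed = config$seed, mode = mode),
          extra)
  class(tr) <- "ca_trace"
  tr
}

#' Run a hybrid simulation
#'
#' Macro-step loop coupling gating and concentrations: concentrations are
#' advanced with the open set frozen; gating is advanced by exact CTMC with
#' per-channel driving concentrations frozen over each macro step (fixed
#' `ca_open` = 150 uM for open channels; the local concentration at the
#' channel pore center for closed ones); any channel open/close transition
#' splits the macro step so the fields never see a stale open set. Initial
#' channel states are drawn from the stationary regime at `ca_init`. The
#' trace is a pure function of (config, seed).
#'
#' @param cfg a [sim_config()] (mode `"reduced"` or `"grid"`).
#' @return a `ca_trace` object.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mode == "replay")
    stop("use run_replay() for replay mode")
  set.seed(cfg$seed)
  channels0 <- draw_initial_channels(cfg$layout$n_channels, cfg$ca_init,
                                     cfg$gating)
  if (cfg$mode == "reduced") {
    .run_reduced(cfg, channels0, schedule = NULL)
  } else {
    .run_grid(cfg, channels0, schedule = NULL)
  }
}

#' Replay a prescribed gating schedule
#'
#' Drives the concentration model with scripted channel open/close times
#' and no stochastic gating, as used for mesh- and domain-size sensitivity
#' checks (the same openings and closings can be replayed on a refined mesh
#' or in a larger domain).
#'
#' @param schedule data frame with columns `channel` (1-based),
#'   `t_open`, `t_close` (s).
#' @param cfg a [sim_config()]; `cfg$mode` selects the field model
#'   (`"grid"` or `"reduced"`).
#' @param record optional extra records for grid mode: `"line_scan"`
#'   and/or `"pore"` (per-channel pore-center concentrations).
#' @return a `ca_trace` (with `n_activatable` = NA: no gating model runs).
#' @export
run_replay <- function(schedule, cfg, record = character()) {
  stopifnot(inherits(cfg, "sim_config"))
  schedule <- .check_schedule(schedule, cfg)
  set.seed(cfg$seed)
  if (cfg$mode == "grid") .run_grid(cfg, NULL, schedule, record)
  else .run_reduced(cfg, NULL, schedule)
}

.check_schedule <- function(schedule, cfg) {
  schedule <- as.data.frame(schedule)
  need <- c("channel", "t_open", "t_close")
  if (!all(need %in% names(schedule))) stop("schedule needs columns ",
                                            paste(need, collapse = ", "))
  if (nrow(schedule)) {
    with(schedule, {
      if (any(t_open < 0) || any(t_close <= t_open))
        stop("malformed schedule intervals")
      if (any(t_close > cfg$duration)) stop("schedule exceeds duration")
      if (any(channel < 1 | channel > cfg$layout$n_channels))
        stop("schedule channel index out of range")
    })
    by_ch <- split(schedule, schedule$channel)
    for (s in by_ch) {
      s <- s[order(s$t_open), ]
      if (nrow(s) > 1 && any(s$t_open[-1] < s$t_close[-nrow(s)]))
        stop("overlapping intervals for one channel")
    }
  }
  schedule[order(schedule$t_open), , drop = FALSE]
}

.run_reduced <- function(cfg, channels0, schedule) {
  rp <- .reduced_filled(cfg)
  gp <- cfg$gating
  fp <- cfg$flux
  bp <- cfg$buffer
  dom <- cfg$domain
  Vbox <- (cfg$box_edge * 1e-3)^3
  Vdom <- dom$Lx * dom$Ly * dom$Lz * 1e-9
  Abox <- (cfg$box_edge * 1e-3)^2
  Amem <- dom$Lx * dom$Ly * 1e-6
  sched_mat <- if (is.null(schedule) || !nrow(schedule))
    matrix(numeric(0), 0, 3)
  else as.matrix(schedule[, c("channel", "t_open", "t_close")])
  sub0 <- if (is.null(channels0))
    matrix(0L, cfg$layout$n_channels, 4) else channels0
  res <- reduced_run_cpp(sub0, gp$ip3, gp$a, gp$b,
                         cfg$duration, cfg$cadence, rp$ca_open,
                         channel_distances(cfg$layout),
                         rp$kern_amp, rp$kern_lambda, rp$tau_domain,
                         rp$g_box, rp$Q, rp$box_excess,
                         Vbox, Vdom - Vbox, Abox,
                         Amem - Abox, fp$P_p, fp$K_d, fp$P_l,
                         fp$leak_offset, fp$c_ER, bp$B_total, bp$K,
                         fp$c0, rp$dt_open, rp$dt_closed, rp$dt_elevated,
                         rp$c_elevated, rp$sub_h,
                         isTRUE(cfg$log_subunits) && is.null(schedule),
                         !is.null(schedule), sched_mat)
  transitions <- NULL
  if (isTRUE(cfg$log_subunits) && is.null(schedule)) {
    transitions <- as.data.frame(res$sub_log)
    names(transitions) <- c("time", "channel", "subunit", "from", "to")
  }
  .new_trace(res$time, res$n_open, res$n_activatable, res$box_avg_ca,
             res$domain_min_ca, res$open_log, cfg, "reduced",
             transitions = transitions,
             extra = list(final_subunits = res$subunits,
                          n_ssa = res$n_ssa, n_segments = res$n_segments))
}

# ---- grid mode --------------------------------------------------------------

.grid_setup <- function(cfg) {
  gc <- cfg$grid_control
  mesh <- build_mesh(cfg$domain, cfg$layout, h_min = gc$h_min,
                     slope = gc$slope, h_max = gc$h_max)
  state <- field_state(mesh, c = cfg$flux$c0, bp = cfg$buffer)
  list(mesh = mesh, state = state)
}

# P_ch * covered-area fraction per membrane cell for the current open set
.pch_frac <- function(mesh, open_set, fp) {
  nx <- mesh$dims[1]
  out <- numeric(nx * mesh$dims[2])
  pc <- mesh$pore_cover
  keep <- pc[, "channel"] %in% open_set
  if (any(keep)) {
    pc <- pc[keep, , drop = FALSE]
    ix <- pc[, "cell2d"] %% nx + 1
    iy <- pc[, "cell2d"] %/% nx + 1
    aface <- mesh$x$widths[ix] * mesh$y$widths[iy]
    for (r in seq_len(nrow(pc)))
      out[pc[r, "cell2d"] + 1] <- out[pc[r, "cell2d"] + 1] +
        fp$P_ch * pc[r, "area"] / aface[r]
  }
  out
}

#' Advance the concentration fields over one step
#'
#' Advances the reaction-diffusion system with the given open set frozen,
#' using the ADI integrator with adaptive substeps.
#'
#' @param state a [field_state()].
#' @param dt interval to advance, s (> 0).
#' @param open_set open channel indices (1-based), frozen over the step.
#' @param cfg a [sim_config()] providing parameters and solver controls.
#' @param dt0 initial substep, s (default the configured `dt0`; callers
#'   advancing repeatedly pass the previous step's final substep).
#' @return the advanced `field_state` (attribute `steps` holds substep
#'   diagnostics).
#' @export
step_fields <- function(state, dt, open_set, cfg, dt0 = NULL) {
  if (dt <= 0) stop("dt must be positive")
  m <- state$mesh
  gc <- cfg$grid_control
  bp <- cfg$buffer
  fp <- cfg$flux
  res <- grid_advance_cpp(state$c, state$b,
                          m$x$widths, m$y$widths, m$z$widths,
                          fp$D_c, bp$D_b, bp$k_on, bp$k_off, bp$B_total,
                          .pch_frac(m, open_set, fp),
                          fp$P_l, fp$leak_offset, fp$P_p, fp$K_d, fp$c_ER,
                          dt, if (is.null(dt0)) gc$dt0 else dt0,
                          gc$dt_max, gc$max_change, gc$theta,
                          m$ctrl_mask)
  out <- state
  out$c <- res$c
  out$b <- res$b
  out$t <- state$t + dt
  attr(out, "steps") <- c(steps = res$steps, rejects = res$rejects,
                          dt_last = res$dt_last)
  out
}

# cell index (1-based) of the membrane cell containing each pore center
.pore_cells <- function(mesh, layout) {
  nx <- mesh$dims[1]
  vapply(seq_len(layout$n_channels), function(k) {
    ix <- findInterval(layout$positions[k, 1], mesh$x$faces,
                       rightmost.closed = TRUE)
    iy <- findInterval(layout$positions[k, 2], mesh$y$faces,
                       rightmost.closed = TRUE)
    ix + nx * (iy - 1)
  }, numeric(1))
}

.run_grid <- function(cfg, channels0, schedule, record = character()) {
  gs <- .grid_setup(cfg)
  state <- gs$state
  mesh <- gs$mesh
  gp <- cfg$gating
  nch <- cfg$layout$n_channels
  pore_cells <- .pore_cells(mesh, cfg$layout)
  replay <- !is.null(schedule)
  open_flag <- rep(FALSE, nch)
  channels <- channels0
  if (!replay) open_flag <- channel_open(channels)

  nsamp <- floor(cfg$duration / cfg$cadence + 1e-9) + 1
  samp <- data.frame(time = numeric(nsamp), n_open = numeric(nsamp),
                     n_activatable = numeric(nsamp),
                     box_avg_ca = numeric(nsamp),
                     domain_min_ca = numeric(nsamp))
  want_ls <- "line_scan" %in% record
  want_pore <- "pore" %in% record
  ls_mat <- if (want_ls) matrix(NA_real_, nsamp, mesh$dims[1]) else NULL
  pore_mat <- if (want_pore) matrix(NA_real_, nsamp, nch) else NULL
  olog <- list()
  tlog <- list()
  isamp <- 0
  rec <- function(t) {
    isamp <<- isamp + 1
    samp[isamp, ] <<- list(t, sum(open_flag),
                           if (replay) NA_real_
                           else sum(channel_activatable(channels)),
                           box_average(state, cfg$box_edge),
                           domain_minimum(state))
    if (want_ls) ls_mat[isamp, ] <<- line_scan(state)$c
    if (want_pore) pore_mat[isamp, ] <<- state$c[pore_cells]
  }
  rec(0)

  togs <- if (replay && nrow(schedule))
    data.frame(t = c(schedule$t_open, schedule$t_close),
               ch = rep(schedule$channel, 2),
               on = rep(c(TRUE, FALSE), each = nrow(schedule)))
  else data.frame(t = numeric(0), ch = integer(0), on = logical(0))
  togs <- togs[order(togs$t), ]
  itog <- 1

  t <- 0
  eps <- 1e-9
  cur_dt0 <- cfg$grid_control$dt0
  dt_open_cap <- cfg$reduced$dt_open
  dt_closed_cap <- cfg$reduced$dt_closed
  while (t < cfg$duration - eps) {
    next_samp <- cfg$cadence * isamp
    t_end <- min(cfg$duration, next_samp)
    if (!replay)
      t_end <- min(t_end, t + if (any(open_flag)) dt_open_cap else dt_closed_cap)
    if (replay && itog <= nrow(togs)) t_end <- min(t_end, togs$t[itog])
    seg <- t_end - t
    if (seg > eps) {
      if (!replay) {
        ca_drive <- ifelse(open_flag, cfg$reduced$ca_open,
                           pmax(state$c[pore_cells], 0))
        adv <- advance_channels(channels, seg, ca_drive, gp, t0 = t)
        # split the macro step at the first open/close transition
        cut <- seg
        newch <- adv$channels
        log <- adv$log
        if (nrow(log)) {
          tmp <- channels
          for (r in seq_len(nrow(log))) {
            ch <- log$channel[r]
            tmp[ch, log$subunit[r]] <- log$to[r]
            if (channel_open(tmp[ch, ]) != open_flag[ch]) {
              cut <- log$time[r] - t
              newch <- tmp
              log <- log[seq_len(r), , drop = FALSE]
              olog[[length(olog) + 1]] <- c(log$time[r], ch,
                                            as.numeric(!open_flag[ch]))
              break
            }
          }
        }
        state <- step_fields(state, cut, which(open_flag), cfg, dt0 = cur_dt0)
        cur_dt0 <- attr(state, "steps")["dt_last"]
        prev_open <- open_flag
        channels <- newch
        open_flag <- channel_open(channels)
        if (any(prev_open != open_flag)) cur_dt0 <- cfg$grid_control$dt0
        if (nrow(log) && isTRUE(cfg$log_subunits))
          tlog[[length(tlog) + 1]] <- log
        t <- t + cut
      } else {
        state <- step_fields(state, seg, which(open_flag), cfg, dt0 = cur_dt0)
        cur_dt0 <- attr(state, "steps")["dt_last"]
        t <- t_end
      }
    } else t <- t_end
    while (replay && itog <= nrow(togs) && togs$t[itog] <= t + eps) {
      ch <- togs$ch[itog]
      if (open_flag[ch] != togs$on[itog]) {
        open_flag[ch] <- togs$on[itog]
        olog[[length(olog) + 1]] <- c(t, ch, as.numeric(togs$on[itog]))
        cur_dt0 <- cfg$grid_control$dt0
      }
      itog <- itog + 1
    }
    if (isamp < nsamp && t >= cfg$cadence * isamp - eps)
      rec(cfg$cadence * isamp)
  }
  while (isamp < nsamp) rec(cfg$duration)

  olog <- if (length(olog)) do.call(rbind, olog) else matrix(numeric(0), 0, 3)
  transitions <- if (length(tlog)) do.call(rbind, tlog) else NULL
  .new_trace(samp$time, samp$n_open, samp$n_activatable, samp$box_avg_ca,
             samp$domain_min_ca, olog, cfg, if (replay) "replay" else "grid",
             transitions = transitions,
             extra = list(final_state = state, line_scan = ls_mat,
                          pore_ca = pore_mat,
                          line_scan_x = if (want_ls) mesh$x$centers else NULL))
}

# ---- trace methods ----------------------------------------------------------

#' @export
print.ca_trace <- function(x, ...) {
  cat("ca_trace:", x$mode, "mode,", round(max(x$time), 3), "s, [IP3] =",
      x$config$ip3, "uM, seed", x$seed, "\n")
  cat("  samples:", length(x$time), " open/close events:",
      nrow(x$open_log), "\n")
  cat("  box_avg_ca range:", signif(min(x$box_avg_ca), 3), "-",
      signif(max(x$box_avg_ca), 3), "uM\n")
  invisible(x)
}

#' @export
summary.ca_trace <- function(object, ...) {
  on <- object$n_open
  cat("trace of", round(max(object$time), 2), "s (", object$mode, ")\n")
  cat("  fraction of time with open channels:",
      signif(mean(on > 0), 3), "\n")
  cat("  max open channels:", max(on), "\n")
  if (!all(is.na(object$n_activatable)))
    cat("  mean activatable channels:",
        signif(mean(object$n_activatable), 3), "\n")
  invisible(object)
}

#' @export
plot.ca_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$n_open, type = "s", ylab = "open channels",
                 xlab = "", ...)
  graphics::plot(x$time, x$box_avg_ca, type = "l",
                 ylab = "box avg [Ca2+] (uM)", xlab = "")
  graphics::plot(x$time, x$domain_min_ca, type = "l",
                 ylab = "domain min [Ca2+] (uM)", xlab = "time (s)")
  invisible(x)
}
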