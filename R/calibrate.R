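# Calibration of the reduced-domain model against the grid solver.

#' Calibrate the reduced-domain model against grid-mode replays
#'
#' Replays scripted gating on the full grid solver and fits the reduced
#' model so that (a) the concentrations closed channels see during openings
#' and (b) the post-closure box-average decay match the grid:
#' a single-channel replay yields the nanodomain kernel (amplitude and
#' decay length of K(d) = A exp(-d/lambda)/d from the steady excess at the
#' other channel sites), the residual decay time (exponential fit of the
#' nearest-neighbour excess after closure), the effective per-channel
#' release rate (pore-disk flux at the measured open-pore concentration)
#' and the box-bulk exchange conductance (steady box/bulk balance); a
#' multi-channel replay then validates the box-average time course
#' (relative RMS reported in the diagnostics).
#'
#' @param cfg a [sim_config()]; grid-solver controls and physical
#'   parameters are taken from it.
#' @param open_channel channel used for the single-channel replay; a
#'   corner channel, so that sites at least three grid spacings away exist
#'   for the far-field baseline fit.
#' @param open_time single-channel open duration, s.
#' @param check_schedule optional multi-channel validation schedule
#'   (data frame channel/t_open/t_close); `NULL` skips validation.
#' @param rms_tol relative RMS tolerance of the validation, reported in
#'   the diagnostics and checked with a warning.
#' @return a [reduced_params()] object with attribute `diagnostics`
#'   (fit details and validation RMS).
#' @export
calibrate_reduced <- function(cfg, open_channel = 1, open_time = 0.05,
                              check_schedule = NULL, rms_tol = 0.15) {
  lay <- cfg$layout
  fp <- cfg$flux
  t_on <- 0.005
  t_off <- t_on + open_time
  cfg1 <- cfg
  cfg1$mode <- "grid"
  cfg1$duration <- t_off + 0.05
  cfg1$cadence <- 1e-3
  # strict step control: the near-field values being fitted converge to a
  # few percent at this bound (looser bounds bias the nearest-neighbour
  # site upward)
  cfg1$grid_control$max_change <- min(cfg1$grid_control$max_change, 0.05)
  sched <- data.frame(channel = open_channel, t_open = t_on, t_close = t_off)
  tr <- run_replay(sched, cfg1, record = "pore")
  t <- tr$time
  pore <- tr$pore_ca

  steady <- which(t >= t_off - 0.01 & t < t_off - 1e-9)
  c_pore_open <- mean(pore[steady, open_channel])
  c_box_ss <- mean(tr$box_avg_ca[steady])
  c_blk_ss <- mean(tr$domain_min_ca[steady])

  # baseline a closed channel sees while others are open: the far channel
  # sites (beyond the kernel range) sit below the box average because the
  # open-channel nanodomain inflates the box mean; box_excess is that
  # inflation per open channel
  d <- channel_distances(lay)[, open_channel]
  pore_ss <- colMeans(pore[steady, , drop = FALSE])
  far <- which(d >= 3 * lay$spacing)
  base_ss <- mean(pore_ss[far])

  # kernel: steady excess over the corrected baseline at the other sites
  exc <- pore_ss - base_ss
  use <- which(d > 0 & d <= 3.1 * lay$spacing & exc > 0)
  if (length(use) < 3) stop("kernel fit not converged: too few usable sites")
  fit <- stats::lm(log(exc[use] * d[use]) ~ d[use])
  kern_amp <- exp(unname(stats::coef(fit)[1]))
  kern_lambda <- -1 / unname(stats::coef(fit)[2])
  if (kern_lambda <= 0) stop("kernel fit not converged: nonpositive decay length")

  # residual decay: nearest-neighbour excess over the first few ms after
  # closure (the nanodomain collapses fast; the slow box/bulk clearance is
  # carried by the compartments, not the residual)
  nb <- which(abs(d - lay$spacing) < 1e-6)[1]
  e0 <- mean(pore[steady, nb]) - c_box_ss
  post <- which(t > t_off & t <= t_off + 0.004)
  e_post <- pore[post, nb] - tr$box_avg_ca[post]
  pos <- which(e_post > 0)
  if (length(pos) < 2) stop("residual fit not converged")
  dfit <- stats::lm(log(c(e0, e_post[pos])) ~ c(t_off, t[post][pos]))
  tau_domain <- -1 / unname(stats::coef(dfit)[2])
  if (tau_domain <= 0) stop("residual fit not converged: nonpositive tau")

  # effective release; box-bulk exchange fitted to the post-closure
  # box-average decay (the residual-domain clearance the reduced
  # compartments must reproduce)
  Q_eff <- fp$P_ch * pi * lay$pore_radius^2 * (fp$c_ER - c_pore_open) * 1e-9
  dom <- cfg$domain
  Vbox <- (cfg$box_edge * 1e-3)^3
  Vdom <- dom$Lx * dom$Ly * dom$Lz * 1e-9
  Abox <- (cfg$box_edge * 1e-3)^2
  Amem <- dom$Lx * dom$Ly * 1e-6
  bpar <- cfg$buffer
  beta <- function(c) 1 + bpar$B_total * bpar$K / (bpar$K + c)^2
  phi <- function(c) fp$P_l * (fp$c_ER - c) - fp$leak_offset -
    fp$P_p * c^2 / (fp$K_d^2 + c^2)
  post <- which(t > t_off & t <= t_off + 0.04)
  decay_sse <- function(g) {
    cb <- tr$box_avg_ca[max(which(t <= t_off))]
    ck <- tr$domain_min_ca[max(which(t <= t_off))]
    sse <- 0
    tt <- t_off
    for (i in post) {
      while (tt < t[i] - 1e-12) {
        h <- min(2e-4, t[i] - tt)
        ex <- g * (cb - ck)
        cb <- max(cb + h * (-ex + Abox * phi(cb) * 1e-3) / (Vbox * beta(cb)), 0)
        ck <- max(ck + h * (ex + (Amem - Abox) * phi(ck) * 1e-3) /
                    ((Vdom - Vbox) * beta(ck)), 0)
        tt <- tt + h
      }
      sse <- sse + (cb - tr$box_avg_ca[i])^2
    }
    sse
  }
  g_box <- stats::optimize(decay_sse, c(50, 20000))$minimum

  # nanodomain inflation of the (reduced-model) box average per open
  # channel, chosen so the closed-channel drive baseline during openings
  # reproduces the grid's far-site pore concentration
  box_excess <- max(Q_eff / g_box + c_blk_ss - base_ss, 0)

  # multi-channel replay: buffer saturation makes simultaneous nanodomains
  # superlinear, so the kernel amplitude is rescaled by a joint log-least-
  # squares fit over the single- and multi-channel closed-site excesses
  inner <- order(rowSums(abs(lay$positions)))[1:4]
  sched4 <- data.frame(channel = inner, t_open = t_on, t_close = t_off)
  tr4 <- run_replay(sched4, cfg1, record = "pore")
  steady4 <- which(tr4$time >= t_off - 0.01 & tr4$time < t_off - 1e-9)
  pore4 <- colMeans(tr4$pore_ca[steady4, , drop = FALSE])
  Dm <- channel_distances(lay)
  Km <- kern_amp * exp(-Dm / kern_lambda) / pmax(Dm, 1e-9)
  diag(Km) <- 0
  S4 <- rowSums(Km[, inner])
  base4 <- max(4 * Q_eff / g_box + c_blk_ss - 4 * box_excess, c_blk_ss)
  closed4 <- setdiff(seq_len(lay$n_channels), inner)
  exc4 <- pore4[closed4] - base4
  ok4 <- exc4 > 0 & S4[closed4] > 0
  lr <- c(rep(0, length(use)),            # single-channel sites fit exactly
          log(exc4[ok4] / S4[closed4][ok4]))
  amp_scale <- exp(mean(lr))
  kern_amp <- kern_amp * amp_scale
  drive_rms <- sqrt(mean((lr - log(amp_scale))^2))

  rp <- reduced_params(kern_amp = kern_amp, kern_lambda = kern_lambda,
                       tau_domain = tau_domain, g_box = g_box, Q = Q_eff,
                       box_excess = box_excess,
                       ca_open = cfg$reduced$ca_open,
                       dt_open = cfg$reduced$dt_open,
                       dt_closed = cfg$reduced$dt_closed,
                       dt_elevated = cfg$reduced$dt_elevated,
                       c_elevated = cfg$reduced$c_elevated,
                       sub_h = cfg$reduced$sub_h)
  diag <- list(c_pore_open = c_pore_open, c_box_ss = c_box_ss,
               c_blk_ss = c_blk_ss, base_ss = base_ss,
               amp_scale = amp_scale,
               drive_rms = drive_rms,
               kernel_distances = d[use],
               kernel_excess = exc[use], rms = NA_real_)

  if (!is.null(check_schedule)) {
    cfg2 <- cfg
    cfg2$mode <- "grid"
    cfg2$duration <- max(check_schedule$t_close) + 0.05
    cfg2$cadence <- 1e-3
    g <- run_replay(check_schedule, cfg2)
    cfg2$mode <- "reduced"
    cfg2$reduced <- rp
    r <- run_replay(check_schedule, cfg2)
    sel <- g$box_avg_ca > 2 * fp$c0
    rms <- sqrt(mean(((r$box_avg_ca[sel] - g$box_avg_ca[sel]) /
                        g$box_avg_ca[sel])^2))
    diag$rms <- rms
    if (!is.finite(rms) || rms > rms_tol)
      warning("reduced-mode validation RMS ", signif(rms, 3),
              " exceeds tolerance ", rms_tol)
  }
  attr(rp, "diagnostics") <- diag
  rp
}

#' Single step of the reduced concentration model
#'
#' Advances the two compartments and the per-channel residuals over `dt`
#' with a fixed open set: the box and bulk exchange total calcium and feel
#' the membrane SERCA/leak terms scaled by their membrane-area share
#' (rapid-buffer factor converting to free concentration); residuals decay
#' exponentially with `tau_domain` and are floored at the current kernel
#' superposition. The driving concentration a closed channel `m` sees is
#' `c_box + max(R_m, S_m)`; open channels see the fixed `ca_open`.
#'
#' @param state list with `c_box`, `c_blk` (uM) and `R` (per-channel
#'   residual, uM).
#' @param dt step, s.
#' @param open_set open channel indices (1-based).
#' @param cfg a [sim_config()] (reduced/flux/buffer/layout blocks used).
#' @return the advanced state, with `drive` (per-channel driving
#'   concentrations) attached.
#' @export
reduced_step <- function(state, dt, open_set, cfg) {
  if (dt <= 0) stop("dt must be positive")
  rp <- .reduced_filled(cfg)
  fp <- cfg$flux
  bp <- cfg$buffer
  lay <- cfg$layout
  dom <- cfg$domain
  Vbox <- (cfg$box_edge * 1e-3)^3
  Vdom <- dom$Lx * dom$Ly * dom$Lz * 1e-9
  Vblk <- Vdom - Vbox
  Abox <- (cfg$box_edge * 1e-3)^2
  Ablk <- dom$Lx * dom$Ly * 1e-6 - Abox
  beta <- function(c) 1 + bp$B_total * bp$K / (bp$K + c)^2
  phi <- function(c) fp$P_l * (fp$c_ER - c) - fp$leak_offset -
    fp$P_p * c^2 / (fp$K_d^2 + c^2)
  n_open <- length(open_set)
  deriv <- function(cb, ck) {
    ex <- rp$g_box * (cb - ck)
    c((n_open * rp$Q - ex + Abox * phi(cb) * 1e-3) / (Vbox * beta(cb)),
      (ex + Ablk * phi(ck) * 1e-3) / (Vblk * beta(ck)))
  }
  cb <- state$c_box; ck <- state$c_blk
  remaining <- dt
  while (remaining > 1e-15) {
    h <- min(rp$sub_h, 0.2 / (rp$g_box / (Vbox * beta(cb)) + 1), remaining)
    d0 <- deriv(cb, ck)
    d1 <- deriv(max(cb + h * d0[1], 0), max(ck + h * d0[2], 0))
    cb <- max(cb + h * (d0[1] + d1[1]) / 2, 0)
    ck <- max(ck + h * (d0[2] + d1[2]) / 2, 0)
    remaining <- remaining - h
  }
  D <- channel_distances(lay)
  K <- rp$kern_amp * exp(-D / rp$kern_lambda) / pmax(D, 1e-9)
  diag(K) <- 0
  S <- if (n_open) rowSums(K[, open_set, drop = FALSE]) else
    numeric(lay$n_channels)
  R <- pmax(state$R * exp(-dt / rp$tau_domain), S)
  out <- list(c_box = cb, c_blk = ck, R = R)
  drive <- max(cb - n_open * rp$box_excess, min(ck, cb)) + pmax(R, S)
  drive[open_set] <- rp$ca_open
  out$drive <- drive
  out
}

#' IP3-sweep event statistics report
#'
#' Runs reduced-mode simulations over a set of IP3 conditions (several
#' seeds each), detects and classifies events, and assembles the
#' per-condition statistics: event counts, duration mean/SD, duration-tail
#' fractions, activatable-channel statistics, wave counts and IWI/IPI
#' statistics, plus the SD-versus-mean IWI regression when at least two
#' conditions have two or more waves.
#'
#' @param ip3_values IP3 conditions, uM.
#' @param seeds seeds pooled per condition.
#' @param duration run length, s (statistics start after the configured
#'   transient discard).
#' @param cfg_base template [sim_config()]; ip3/seed/duration are
#'   overridden per run.
#' @param keep_catalogs also return the pooled per-condition catalogs.
#' @return list with `table` (per-condition data frame), `regression`
#'   (from [iwi_regression()], or NULL), and optionally `catalogs`.
#' @export
sweep_report <- function(ip3_values, seeds = 1:3, duration = 2100,
                         cfg_base = sim_config(), keep_catalogs = FALSE) {
  rows <- list()
  cats_all <- list()
  for (ip3 in ip3_values) {
    cats <- lapply(seeds, function(s) {
      cfg <- cfg_base
      cfg$ip3 <- ip3
      cfg$gating$ip3 <- ip3
      cfg$seed <- as.integer(s)
      cfg$duration <- duration
      cfg$mode <- "reduced"
      tr <- run_simulation(cfg)
      classify_events(detect_events(tr), tr)
    })
    pooled <- pool_catalogs(cats)
    ints <- iwi_ipi(cats)
    rows[[length(rows) + 1]] <- data.frame(
      ip3 = ip3, n_events = nrow(pooled),
      n_waves = sum(pooled$label == "wave"),
      mean_duration = mean(pooled$duration),
      sd_duration = stats::sd(pooled$duration),
      frac_gt2s = mean(pooled$duration > 2),
      frac_gt3s = mean(pooled$duration > 3),
      frac_lt1s = mean(pooled$duration < 1),
      mean_activatable = mean(pooled$n_activatable_start),
      sd_activatable = stats::sd(pooled$n_activatable_start),
      n_iwi = length(ints$iwi), iwi_mean = ints$iwi_mean,
      iwi_sd = ints$iwi_sd, ipi_mean = ints$ipi_mean)
    cats_all[[as.character(ip3)]] <- pooled
  }
  tab <- do.call(rbind, rows)
  reg <- NULL
  ok <- !is.na(tab$iwi_mean) & !is.na(tab$iwi_sd) & tab$n_iwi >= 2
  if (sum(ok) >= 2)
    reg <- iwi_regression(data.frame(ip3 = tab$ip3[ok],
                                     mean = tab$iwi_mean[ok],
                                     sd = tab$iwi_sd[ok]))
  out <- list(table = tab, regression = reg)
  if (keep_catalogs) out$catalogs <- cats_all
  out
}
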