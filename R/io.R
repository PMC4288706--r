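# Configuration persistence (YAML), trace/catalog export (delimited text),
# and the planted-event fixture generator for testing the analysis stage.

.config_blocks <- list(
  simulation = c("ip3", "duration", "transient_discard", "seed", "mode",
                 "cadence", "ca_init", "box_edge", "log_subunits"),
  gating = c("a", "b", "d"),
  layout = c("n_side", "spacing", "pore_radius"),
  domain = c("Lx", "Ly", "Lz"),
  buffer = c("D_b", "B_total", "k_on", "k_off"),
  flux = c("P_ch", "P_p", "K_d", "P_l", "c_ER", "c0", "D_c"),
  reduced = c("kern_amp", "kern_lambda", "tau_domain", "g_box", "Q", "box_excess",
              "ca_open", "dt_open", "dt_closed", "dt_elevated",
              "c_elevated", "sub_h"),
  grid_control = c("h_min", "slope", "h_max", "dt0", "dt_max", "max_change", "theta"))

#' Serialize a simulation configuration to YAML
#'
#' @param cfg a [sim_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- list(
    schema = 1L,
    simulation = cfg[.config_blocks$simulation],
    gating = cfg$gating[.config_blocks$gating],
    layout = cfg$layout[c("n_side", "spacing", "pore_radius")],
    domain = cfg$domain[.config_blocks$domain],
    buffer = cfg$buffer[.config_blocks$buffer],
    flux = cfg$flux[c("P_ch", "P_p", "K_d", "c_ER", "c0", "D_c")],
    reduced = cfg$reduced[.config_blocks$reduced],
    grid_control = cfg$grid_control[.config_blocks$grid_control])
  # leak: balanced mode round-trips as the keyword, literal mode as a number
  out$flux$P_l <- if (cfg$flux$leak_offset == 0 &&
                        isTRUE(all.equal(cfg$flux$P_l, balance_leak(cfg$flux))))
    "balanced" else cfg$flux$P_l
  out$reduced$Q <- if (is.null(cfg$reduced$Q)) "default" else cfg$reduced$Q
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration; unknown keys are rejected with their key
#' path, missing keys are defaulted from the reference parameter tables.
#' Gating parameters are re-validated (including the detailed-balance
#' constraint d1 d2 = d3 d4).
#'
#' @param path YAML file; an empty file yields the full default config.
#' @return a [sim_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw$schema <- NULL
  known_blocks <- names(.config_blocks)
  for (bl in names(raw)) {
    if (!bl %in% known_blocks) stop("unknown config block: ", bl)
    unknown <- setdiff(names(raw[[bl]]), .config_blocks[[bl]])
    if (length(unknown))
      stop("unknown config key: ", bl, ".", unknown[1])
  }
  sim <- raw$simulation
  g <- raw$gating
  gating <- tryCatch(
    gating_params(ip3 = if (is.null(sim$ip3)) 0.05 else sim$ip3,
                  a = if (is.null(g$a)) .dyk_default_a else unlist(g$a),
                  b = if (is.null(g$b)) .dyk_default_b else unlist(g$b),
                  d = if (is.null(g$d)) .dyk_default_d else unlist(g$d)),
    error = function(e) stop("gating-parameter error: ", conditionMessage(e)))
  lay <- raw$layout
  layout <- cluster_layout(
    n_side = if (is.null(lay$n_side)) 4L else lay$n_side,
    spacing = if (is.null(lay$spacing)) 120 else lay$spacing,
    pore_radius = if (is.null(lay$pore_radius)) 6 else lay$pore_radius)
  dm <- raw$domain
  domain <- domain_spec(Lx = if (is.null(dm$Lx)) 3250 else dm$Lx,
                        Ly = if (is.null(dm$Ly)) 3250 else dm$Ly,
                        Lz = if (is.null(dm$Lz)) 2000 else dm$Lz)
  drop_null <- function(x) {
    if (is.null(x)) list() else x[!vapply(x, is.null, TRUE)]
  }
  buffer <- do.call(buffer_params, drop_null(raw$buffer))
  fl <- raw$flux
  if (identical(fl$P_l, "balanced")) fl$P_l <- NULL
  flux <- do.call(flux_params, drop_null(fl))
  rd <- raw$reduced
  if (identical(rd$Q, "default")) rd$Q <- NULL
  reduced <- do.call(reduced_params, drop_null(rd))
  args <- list(gating = gating, layout = layout, domain = domain,
               buffer = buffer, flux = flux, reduced = reduced,
               grid_control = if (is.null(raw$grid_control)) list()
               else raw$grid_control)
  for (k in .config_blocks$simulation)
    if (!is.null(sim[[k]])) args[[k]] <- sim[[k]]
  do.call(sim_config, args)
}

# ---- fixtures ---------------------------------------------------------------

#' Specification of a planted-event fixture
#'
#' @param events data frame with one planted event per row: `t_start`,
#'   `duration` (s), `amplitude` (peak open channels), `label`
#'   (`"puff"`/`"wave"`), optional `n_openings` (default 3),
#'   `n_act_start`, `n_act_end`.
#' @param duration trace length, s.
#' @param cadence sampling interval, s.
#' @param noise_sd Gaussian noise on the concentration series, uM.
#' @param baseline resting box concentration, uM.
#' @param level in-event box concentration, uM.
#' @param wave_level in-event domain-minimum concentration for waves, uM.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(events, duration = 100, cadence = 0.01,
                         noise_sd = 0, baseline = 0.02, level = 0.3,
                         wave_level = 0.3) {
  events <- as.data.frame(events)
  stopifnot(all(c("t_start", "duration", "amplitude", "label")
                %in% names(events)))
  if (is.null(events$n_openings)) events$n_openings <- rep(3, nrow(events))
  if (is.null(events$n_act_start)) events$n_act_start <- rep(8, nrow(events))
  if (is.null(events$n_act_end)) events$n_act_end <- rep(6, nrow(events))
  events <- events[order(events$t_start), ]
  ends <- events$t_start + events$duration
  if (nrow(events) > 1 && any(events$t_start[-1] <= ends[-nrow(events)]))
    stop("planted events overlap")
  if (any(ends > duration)) stop("planted event exceeds duration")
  structure(list(events = events, duration = duration, cadence = cadence,
                 noise_sd = noise_sd, baseline = baseline, level = level,
                 wave_level = wave_level),
            class = "fixture_spec")
}

#' Synthesize a trace with planted events
#'
#' Builds a `ca_trace` whose box-average series carries rectangular
#' super-threshold pulses at the planted events, whose open/close log holds
#' the planted number of channel openings per event, and whose
#' domain-minimum series is elevated during wave-labelled events. The
#' ground truth (including the exact detection times implied by linear
#' crossing interpolation at zero noise) is stored in attribute
#' `ground_truth`; [detect_events()] recovers it exactly at zero noise.
#'
#' @param spec a [fixture_spec()].
#' @param seed RNG seed for the noise.
#' @param threshold detection threshold the ground-truth times refer
#'   to, uM.
#' @return a `ca_trace`.
#' @export
make_fixture <- function(spec, seed = 1L, threshold = 0.1) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(seed)
  tgrid <- seq(0, spec$duration, by = spec$cadence)
  n <- length(tgrid)
  box <- rep(spec$baseline, n)
  dmin <- rep(spec$baseline, n)
  nopen <- rep(0, n)
  nact <- rep(if (nrow(spec$events)) max(spec$events$n_act_start) else 8, n)
  ev <- spec$events
  olog <- list()
  gt <- list()
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$t_start[i]; t1 <- t0 + ev$duration[i]
    idx <- which(tgrid >= t0 - 1e-12 & tgrid <= t1 + 1e-12)
    box[idx] <- spec$level
    nopen[idx] <- ev$amplitude[i]
    nact[idx] <- round(seq(ev$n_act_start[i], ev$n_act_end[i],
                           length.out = length(idx)))
    if (ev$label[i] == "wave") dmin[idx] <- spec$wave_level
    topen <- seq(t0, t1, length.out = ev$n_openings[i] + 1)[-(ev$n_openings[i] + 1)]
    for (to in topen)
      olog[[length(olog) + 1]] <- c(to, 1, 1)
    olog[[length(olog) + 1]] <- c(t1, 1, 0)
    # detection times implied by linear interpolation of the pulse edges
    i0 <- max(idx[1] - 1, 1)
    i1 <- min(idx[length(idx)] + 1, n)
    det0 <- if (i0 == idx[1]) tgrid[1] else
      tgrid[i0] + (threshold - spec$baseline) /
        (spec$level - spec$baseline) * spec$cadence
    det1 <- if (i1 == idx[length(idx)]) tgrid[n] else
      tgrid[idx[length(idx)]] + (spec$level - threshold) /
        (spec$level - spec$baseline) * spec$cadence
    gt[[i]] <- data.frame(t_start_nominal = t0, t_end_nominal = t1,
                          t_start_detect = det0, t_end_detect = det1,
                          amplitude = ev$amplitude[i],
                          n_openings = ev$n_openings[i],
                          label = ev$label[i])
  }
  if (spec$noise_sd > 0) {
    box <- pmax(box + stats::rnorm(n, 0, spec$noise_sd), 0)
    dmin <- pmax(dmin + stats::rnorm(n, 0, spec$noise_sd), 0)
  }
  olog <- if (length(olog)) do.call(rbind, olog) else matrix(numeric(0), 0, 3)
  cfg <- sim_config(duration = spec$duration, transient_discard = 0,
                    cadence = spec$cadence, seed = seed)
  tr <- .new_trace(tgrid, nopen, nact, box, dmin, olog, cfg, "fixture")
  attr(tr, "ground_truth") <- if (length(gt)) do.call(rbind, gt) else
    data.frame()
  tr
}

# ---- tabular export ---------------------------------------------------------

#' Export traces, catalogs and statistics tables as delimited text
#'
#' Writes tab-separated text with a commented unit header. A `ca_trace`
#' becomes a directory with `series.tsv`, `open_log.tsv` and `config.yaml`;
#' an `event_catalog` or plain data frame becomes a single TSV file.
#' Outputs are bit-stable given fixed inputs.
#'
#' @param x object to export.
#' @param path output file (or directory for traces).
#' @return `path`, invisibly.
#' @export
export_tables <- function(x, path) UseMethod("export_tables")

.write_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE,
                            justify = "none"),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
export_tables.event_catalog <- function(x, path) {
  .write_tsv(as.data.frame(x), path,
             "release events: times/durations in s, amplitude = peak open channels")
}

#' @export
export_tables.data.frame <- function(x, path) {
  .write_tsv(x, path, "statistics table (units: uM, nm, s)")
}

#' @export
export_tables.ca_trace <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ser <- data.frame(time = x$time, n_open = x$n_open,
                    n_activatable = x$n_activatable,
                    box_avg_ca = x$box_avg_ca,
                    domain_min_ca = x$domain_min_ca)
  .write_tsv(ser, file.path(path, "series.tsv"),
             "time s | counts | concentrations uM")
  .write_tsv(x$open_log, file.path(path, "open_log.tsv"),
             "channel open/close events: time s, channel 1-based, open 1/0")
  if (!is.null(x$transitions))
    .write_tsv(x$transitions, file.path(path, "transitions.tsv"),
               "subunit transitions: time s, channel, subunit, from, to (state 0-7)")
  save_config(x$config, file.path(path, "config.yaml"))
  invisible(path)
}

#' Read back an exported trace
#'
#' @param path directory written by [export_tables()] for a trace.
#' @return a `ca_trace` (series, open/close log and config; solver
#'   diagnostics are not round-tripped).
#' @export
read_trace <- function(path) {
  ser <- utils::read.delim(file.path(path, "series.tsv"), comment.char = "#")
  ol <- utils::read.delim(file.path(path, "open_log.tsv"), comment.char = "#")
  cfg <- load_config(file.path(path, "config.yaml"))
  tfile <- file.path(path, "transitions.tsv")
  transitions <- if (file.exists(tfile))
    utils::read.delim(tfile, comment.char = "#") else NULL
  .new_trace(ser$time, ser$n_open, ser$n_activatable, ser$box_avg_ca,
             ser$domain_min_ca, as.matrix(ol), cfg, cfg$mode,
             transitions = transitions)
}
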