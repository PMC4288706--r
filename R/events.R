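# Event analysis: detection of collective release events from the
# box-averaged Ca2+ series, classification into puffs and waves, and the
# duration / activatable-channel / event-shape / interval / phase
# statistics.

#' Detect collective release events in a trace
#'
#' A collective event is a maximal interval during which the box-averaged
#' Ca2+ concentration exceeds `threshold`; its lifetime (duration) is the
#' threshold-exceedance interval, with crossing times interpolated linearly
#' between samples. Events separated by less than `debounce` of
#' sub-threshold time are merged, and events whose window contains fewer
#' than `min_openings` channel openings are filtered out (this removes all
#' single-opening blips). The initial transient of the run
#' (`trace$config$transient_discard`) is excluded.
#'
#' @param trace a `ca_trace` with `box_avg_ca` and the open/close log.
#' @param threshold detection threshold on the box average, uM.
#' @param min_openings minimum number of channel openings per event.
#' @param debounce merge gap, s.
#' @param discard start of the analysis window, s (default the config's
#'   transient discard, capped at the trace end).
#' @return an `event_catalog`: data frame with one row per event
#'   (`t_start`, `t_end`, `duration`, `peak_n_open`, `amplitude`,
#'   `n_activatable_start`, `n_activatable_end`, `n_openings`, `label`),
#'   time-ordered and non-overlapping, with the analysis window and
#'   thresholds in attributes.
#' @export
detect_events <- function(trace, threshold = 0.1, min_openings = 2,
                          debounce = 0.02, discard = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  if (is.null(trace$box_avg_ca)) stop("trace lacks box_avg_ca series")
  if (is.null(discard)) discard <- min(trace$config$transient_discard,
                                       max(trace$time))
  t <- trace$time
  v <- trace$box_avg_ca
  above <- v > threshold
  n <- length(t)
  starts <- which(above & !c(FALSE, above[-n]))
  ends <- which(above & !c(above[-1], FALSE))
  cross <- function(i0, i1, thr) {
    # linear interpolation of the crossing time between samples i0, i1
    t[i0] + (thr - v[i0]) / (v[i1] - v[i0]) * (t[i1] - t[i0])
  }
  t_start <- vapply(starts, function(i)
    if (i == 1) t[1] else cross(i - 1, i, threshold), numeric(1))
  t_end <- vapply(ends, function(i)
    if (i == n) t[n] else cross(i + 1, i, threshold), numeric(1))
  keep <- t_start >= discard
  t_start <- t_start[keep]; t_end <- t_end[keep]
  # merge events separated by < debounce of sub-threshold time
  if (length(t_start) > 1) {
    merged_s <- t_start[1]; merged_e <- t_end[1]
    for (i in 2:length(t_start)) {
      if (t_start[i] - merged_e[length(merged_e)] < debounce) {
        merged_e[length(merged_e)] <- t_end[i]
      } else {
        merged_s <- c(merged_s, t_start[i]); merged_e <- c(merged_e, t_end[i])
      }
    }
    t_start <- merged_s; t_end <- merged_e
  }
  ol <- trace$open_log
  openings <- ol$time[ol$open == 1]
  n_openings <- vapply(seq_along(t_start), function(i)
    sum(openings >= t_start[i] - 1e-9 & openings <= t_end[i] + 1e-9),
    numeric(1))
  keep <- n_openings >= min_openings
  t_start <- t_start[keep]; t_end <- t_end[keep]
  n_openings <- n_openings[keep]
  nact <- function(times) {
    if (all(is.na(trace$n_activatable))) return(rep(NA_real_, length(times)))
    if (!length(times)) return(numeric(0))
    stats::approx(t, trace$n_activatable, times, method = "constant",
                  rule = 2)$y
  }
  peak <- vapply(seq_along(t_start), function(i) {
    idx <- which(t >= t_start[i] & t <= t_end[i])
    if (!length(idx)) idx <- which.min(abs(t - (t_start[i] + t_end[i]) / 2))
    max(trace$n_open[idx])
  }, numeric(1))
  cat_df <- data.frame(t_start = t_start, t_end = t_end,
                       duration = t_end - t_start,
                       peak_n_open = peak, amplitude = peak,
                       n_activatable_start = nact(t_start),
                       n_activatable_end = nact(t_end),
                       n_openings = n_openings,
                       label = rep(NA_character_, length(t_start)),
                       stringsAsFactors = FALSE)
  structure(cat_df,
            class = c("event_catalog", "data.frame"),
            threshold = threshold, min_openings = min_openings,
            debounce = debounce,
            window = c(discard, max(t)),
            source = list(seed = trace$seed, mode = trace$mode,
                          ip3 = trace$config$ip3))
}

#' Classify detected events into puffs and waves
#'
#' An event is a wave if it elevates the local Ca2+ concentration to at
#' least `wave_threshold` everywhere in the domain at some instant, i.e. if
#' the domain-wide minimum (or its reduced-mode bulk proxy) reaches the
#' threshold during the event window; otherwise it is a puff. The default
#' threshold equals the dissociation constant of activation (d5 = 0.25 uM):
#' a wave-classified event could trigger a nearby cluster anywhere.
#'
#' @param catalog an [detect_events()] catalog.
#' @param trace the source `ca_trace` (provides `domain_min_ca`).
#' @param wave_threshold classification threshold, uM.
#' @return the catalog with `label` filled (`"puff"` or `"wave"`).
#' @export
classify_events <- function(catalog, trace, wave_threshold = 0.25) {
  stopifnot(inherits(catalog, "event_catalog"))
  t <- trace$time
  v <- trace$domain_min_ca
  lab <- vapply(seq_len(nrow(catalog)), function(i) {
    idx <- which(t >= catalog$t_start[i] & t <= catalog$t_end[i])
    if (!length(idx))
      idx <- which.min(abs(t - (catalog$t_start[i] + catalog$t_end[i]) / 2))
    if (max(v[idx]) >= wave_threshold) "wave" else "puff"
  }, character(1))
  catalog$label <- lab
  attr(catalog, "wave_threshold") <- wave_threshold
  catalog
}

#' Pool event catalogs from several runs
#'
#' Concatenates catalogs (e.g. several seeds of one condition) into one
#' data frame; interval statistics ([iwi_ipi()]) must be computed per run
#' and pooled at the interval level, so the per-run identity is kept in a
#' `run` column.
#'
#' @param ... event catalogs, or a single list of them.
#' @return a pooled `event_catalog` (attribute `windows` lists the per-run
#'   analysis windows).
#' @export
pool_catalogs <- function(...) {
  cats <- list(...)
  if (length(cats) == 1 && !inherits(cats[[1]], "event_catalog"))
    cats <- cats[[1]]
  dfs <- lapply(seq_along(cats), function(i)
    cbind(as.data.frame(cats[[i]]), run = i))
  out <- do.call(rbind, dfs)
  structure(out, class = c("event_catalog", "data.frame"),
            windows = lapply(cats, attr, "window"),
            threshold = attr(cats[[1]], "threshold"))
}

#' Event-duration distribution and summary per condition
#'
#' Histogram of event durations with multinomial sampling errors, plus
#' mean and standard deviation, per IP3 condition.
#'
#' @param catalogs a single catalog or named list of catalogs (names =
#'   IP3 labels).
#' @param breaks histogram breaks, s.
#' @return data frame of per-condition summaries with the binned counts in
#'   attribute `histograms` (per condition: mids, counts, se).
#' @export
duration_histogram <- function(catalogs, breaks = seq(0, 12, 0.25)) {
  if (inherits(catalogs, "event_catalog")) catalogs <- list(catalogs)
  hists <- lapply(catalogs, function(cat) {
    d <- pmin(cat$duration, max(breaks))
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    ntot <- length(d)
    p <- if (ntot) h$counts / ntot else 0
    list(mids = h$mids, counts = h$counts,
         se = sqrt(ntot * p * (1 - p)))
  })
  summ <- data.frame(
    condition = if (is.null(names(catalogs)))
      as.character(seq_along(catalogs)) else names(catalogs),
    n_events = vapply(catalogs, nrow, numeric(1)),
    mean_duration = vapply(catalogs, function(x) mean(x$duration), numeric(1)),
    sd_duration = vapply(catalogs, function(x) stats::sd(x$duration),
                         numeric(1)))
  attr(summ, "histograms") <- hists
  summ
}

#' Distribution of activatable channels at event start
#'
#' @param catalogs a single catalog or named list by IP3 condition.
#' @return data frame with per-condition mean/SD of the number of
#'   activatable channels at event start; per-condition counts over 0..16
#'   in attribute `histograms`.
#' @export
activatable_histogram <- function(catalogs) {
  if (inherits(catalogs, "event_catalog")) catalogs <- list(catalogs)
  hists <- lapply(catalogs, function(cat)
    table(factor(cat$n_activatable_start, levels = 0:16)))
  summ <- data.frame(
    condition = if (is.null(names(catalogs)))
      as.character(seq_along(catalogs)) else names(catalogs),
    n_events = vapply(catalogs, nrow, numeric(1)),
    mean_activatable = vapply(catalogs, function(x)
      mean(x$n_activatable_start), numeric(1)),
    sd_activatable = vapply(catalogs, function(x)
      stats::sd(x$n_activatable_start), numeric(1)))
  attr(summ, "histograms") <- hists
  summ
}

#' Event duration versus activatable channels
#'
#' Conditional statistics relating event duration to the number of
#' activatable channels: mean/SD duration grouped by the count at event
#' start, and mean/SD of the count at event end grouped by duration bins.
#'
#' @param catalog an event catalog (possibly pooled).
#' @param duration_breaks bin edges for the duration grouping, s.
#' @return list with `by_start` (per start-count duration statistics),
#'   `by_duration` (per duration-bin end-count statistics) and the raw
#'   `scatter` columns.
#' @export
duration_vs_activatable <- function(catalog,
                                    duration_breaks = c(0, 0.5, 1, 2, 3, 5, Inf)) {
  by_start <- do.call(rbind, lapply(split(catalog$duration,
                                          catalog$n_activatable_start),
                                    function(d) data.frame(
                                      n = length(d), mean_duration = mean(d),
                                      sd_duration = stats::sd(d))))
  by_start <- cbind(n_activatable_start =
                      as.numeric(rownames(by_start)), by_start)
  bin <- cut(catalog$duration, duration_breaks, right = FALSE)
  by_dur <- do.call(rbind, lapply(split(catalog$n_activatable_end, bin),
                                  function(v) data.frame(
                                    n = length(v),
                                    mean_end = if (length(v)) mean(v) else NA,
                                    sd_end = if (length(v)) stats::sd(v) else NA)))
  by_dur <- cbind(duration_bin = rownames(by_dur), by_dur)
  rownames(by_start) <- rownames(by_dur) <- NULL
  list(by_start = by_start, by_duration = by_dur,
       scatter = catalog[, c("duration", "n_activatable_start",
                             "n_activatable_end")])
}

#' Average event shape
#'
#' Mean time course of the number of open channels over events aligned at
#' event start, normalized to a peak of 1. Group events beforehand (e.g.
#' by IP3 or by puff/wave label) to compare termination mechanisms.
#'
#' @param catalog event catalog (a subset selects the group).
#' @param trace the source trace, or a list of traces indexed by the
#'   catalog's `run` column for pooled catalogs.
#' @param t_max shape window after event start, s.
#' @param dt shape time resolution, s.
#' @return data frame with `tau` (time since event start, s) and `n_open`
#'   (peak-normalized mean open-channel count).
#' @export
average_event_shape <- function(catalog, trace, t_max = 3, dt = 0.01) {
  if (!nrow(catalog)) stop("empty catalog")
  traces <- if (inherits(trace, "ca_trace")) list(trace) else trace
  run <- if ("run" %in% names(catalog)) catalog$run else rep(1, nrow(catalog))
  tau <- seq(0, t_max, by = dt)
  acc <- matrix(0, nrow(catalog), length(tau))
  for (i in seq_len(nrow(catalog))) {
    tr <- traces[[run[i]]]
    acc[i, ] <- stats::approx(tr$time, tr$n_open, catalog$t_start[i] + tau,
                              method = "constant", rule = 2)$y
  }
  m <- colMeans(acc)
  data.frame(tau = tau, n_open = m / max(m))
}

#' Inter-wave and inter-puff intervals
#'
#' IWI: start-to-start interval between consecutive waves. IPI: interval
#' from the end of a puff to the start of the next puff, excluded if a wave
#' lies between the two puffs. For pooled input (list of catalogs or a
#' [pool_catalogs()] result) the intervals are computed per run and then
#' concatenated, never across runs.
#'
#' @param catalog a classified catalog, list of catalogs, or pooled
#'   catalog with a `run` column.
#' @param anchor `"start"` (default) anchors the IWI at wave starts,
#'   `"end_to_start"` at preceding wave end.
#' @return list with `iwi`, `ipi` (s) and their means and SDs.
#' @export
iwi_ipi <- function(catalog, anchor = c("start", "end_to_start")) {
  anchor <- match.arg(anchor)
  cats <- if (inherits(catalog, "event_catalog")) {
    if ("run" %in% names(catalog)) split(catalog, catalog$run)
    else list(catalog)
  } else catalog
  iwi <- numeric(0); ipi <- numeric(0)
  for (cat in cats) {
    if (anyNA(cat$label)) stop("classify events before interval analysis")
    w <- cat[cat$label == "wave", ]
    p <- cat[cat$label == "puff", ]
    if (nrow(w) >= 2) {
      iwi <- c(iwi, if (anchor == "start") diff(w$t_start)
               else w$t_start[-1] - w$t_end[-nrow(w)])
    }
    if (nrow(p) >= 2) {
      for (i in seq_len(nrow(p) - 1)) {
        split_by_wave <- any(w$t_start > p$t_end[i] &
                               w$t_start < p$t_start[i + 1])
        if (!split_by_wave) ipi <- c(ipi, p$t_start[i + 1] - p$t_end[i])
      }
    }
  }
  list(iwi = iwi, ipi = ipi,
       iwi_mean = mean(iwi), iwi_sd = stats::sd(iwi),
       ipi_mean = mean(ipi), ipi_sd = stats::sd(ipi))
}

#' Regression of IWI standard deviation on IWI mean
#'
#' Ordinary least squares of the per-condition IWI SD on the IWI mean
#' across IP3 conditions; the mean-axis (x) intercept is the minimal
#' average IWI as the SD extrapolates to zero.
#'
#' @param iwi_stats data frame with columns `mean` and `sd` (one row per
#'   IP3 condition) and optionally `ip3`.
#' @return list with `slope`, `x_intercept` (s), `intercept` (the SD-axis
#'   intercept), `cv` (per-condition coefficients of variation) and the
#'   `fit` object.
#' @export
iwi_regression <- function(iwi_stats) {
  if (nrow(iwi_stats) < 2) stop("need at least two conditions for regression")
  fit <- stats::lm(sd ~ mean, data = iwi_stats)
  slope <- unname(stats::coef(fit)[2])
  icpt <- unname(stats::coef(fit)[1])
  list(slope = slope, intercept = icpt, x_intercept = -icpt / slope,
       cv = iwi_stats$sd / iwi_stats$mean, fit = fit)
}

#' Inter-wave phase statistics of puffs
#'
#' For every puff lying strictly between two consecutive waves, the phase
#' is the elapsed fraction of the inter-wave interval,
#' (t_puff - t_prev_wave) / (t_next_wave - t_prev_wave) with wave times
#' anchored at wave starts. Amplitudes are rescaled by the mean amplitude
#' of the pooled dataset before binning. Puff counts per phase bin are
#' reported both raw and as a rate per total inter-wave time; the
#' refractory fraction is the largest initial contiguous span of bins whose
#' pooled count stays below `empty_frac` of the total.
#'
#' @param catalog classified catalog, list, or pooled catalog with `run`.
#' @param n_bins number of phase bins.
#' @param empty_frac bin-count fraction under which a leading bin counts
#'   as part of the refractory span.
#' @return list with `records` (one row per inter-wave puff: phase,
#'   amplitude, rescaled amplitude), `bins` (per-bin counts, rate,
#'   amplitude mean/SD) and `refractory_fraction` (of the IWI). Empty with
#'   a warning if fewer than two waves exist.
#' @export
phase_statistics <- function(catalog, n_bins = 10, empty_frac = 0.05) {
  cats <- if (inherits(catalog, "event_catalog")) {
    if ("run" %in% names(catalog)) split(catalog, catalog$run)
    else list(catalog)
  } else catalog
  recs <- list()
  total_iwi <- 0
  for (cat in cats) {
    if (anyNA(cat$label)) stop("classify events before phase analysis")
    w <- cat[cat$label == "wave", ]
    if (nrow(w) < 2) next
    total_iwi <- total_iwi + sum(diff(w$t_start))
    p <- cat[cat$label == "puff", ]
    for (i in seq_len(nrow(p))) {
      prev <- max(c(-Inf, w$t_start[w$t_start < p$t_start[i]]))
      nxt <- min(c(Inf, w$t_start[w$t_start > p$t_start[i]]))
      if (is.finite(prev) && is.finite(nxt)) {
        recs[[length(recs) + 1]] <- data.frame(
          phase = (p$t_start[i] - prev) / (nxt - prev),
          amplitude = p$amplitude[i])
      }
    }
  }
  if (!length(recs)) {
    warning("fewer than two waves: no phase statistics")
    return(list(records = data.frame(phase = numeric(0),
                                     amplitude = numeric(0),
                                     rescaled = numeric(0)),
                bins = NULL, refractory_fraction = NA_real_))
  }
  records <- do.call(rbind, recs)
  records$rescaled <- records$amplitude / mean(records$amplitude)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(records$phase, edges, include.lowest = TRUE)
  counts <- as.vector(table(bin))
  amp_mean <- vapply(split(records$rescaled, bin),
                     function(v) if (length(v)) mean(v) else NA_real_,
                     numeric(1))
  amp_sd <- vapply(split(records$rescaled, bin),
                   function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                   numeric(1))
  bins <- data.frame(phase_lo = edges[-length(edges)], phase_hi = edges[-1],
                     count = counts,
                     rate = counts / total_iwi,
                     amplitude_mean = amp_mean, amplitude_sd = amp_sd)
  thresh <- empty_frac * sum(counts)
  lead <- 0
  for (i in seq_len(n_bins)) {
    if (counts[i] < thresh) lead <- i else break
  }
  list(records = records, bins = bins,
       refractory_fraction = lead / n_bins,
       total_interwave_time = total_iwi)
}

#' @export
print.event_catalog <- function(x, ...) {
  cat("event catalog:", nrow(x), "events")
  if (!anyNA(x$label) && nrow(x))
    cat(" (", sum(x$label == "puff"), "puffs,",
        sum(x$label == "wave"), "waves )")
  cat("\n  detection threshold", attr(x, "threshold"), "uM, window",
      paste(signif(attr(x, "window"), 4), collapse = " - "), "s\n")
  if (nrow(x)) {
    cat("  durations:", signif(mean(x$duration), 3), "+/-",
        signif(stats::sd(x$duration), 3), "s\n")
  }
  invisible(x)
}

#' @export
summary.event_catalog <- function(object, ...) {
  print(object)
  if (nrow(object)) print(utils::head(as.data.frame(object), 10))
  invisible(object)
}

#' @export
plot.event_catalog <- function(x, ...) {
  graphics::hist(x$duration, breaks = seq(0, max(c(1, x$duration)) + 0.25,
                                          0.25),
                 main = "event durations", xlab = "duration (s)", ...)
  invisible(x)
}
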