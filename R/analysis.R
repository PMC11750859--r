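# trace_analysis: spike detection, half-duration, afterdischarge statistics,
# dV/dt features and multi-site latency ordering on membrane-potential traces.

as_trace_matrix <- function(trace, site = NULL) {
  if (inherits(trace, "trace_set")) {
    if (is.null(site)) site <- trace$sites[1]
    list(v = trace$v[, site], time = trace$time)
  } else stop("expected a trace_set; pass v and time explicitly instead")
}

#' Detect spikes by upward threshold crossing
#'
#' Events are upward crossings of `threshold` separated by at least
#' `refractory` ms. The peak is the maximum between the crossing and the
#' subsequent downward crossing (or the end of the trace); the baseline is
#' the minimum over the `baseline_window` ms preceding the crossing. The
#' half-duration of each event (width at baseline + half amplitude, linearly
#' interpolated on both flanks) is filled in via [half_duration()].
#'
#' @param v membrane potential, mV (numeric vector), or a `trace_set`.
#' @param time time grid, ms (uniform); taken from the trace set when `v`
#'   is one.
#' @param threshold detection threshold, mV.
#' @param refractory minimum separation of crossings, ms.
#' @param baseline_window pre-crossing window for the baseline, ms.
#' @param site site label when `v` is a `trace_set`.
#' @return data frame with one row per spike: `t_cross`, `t_peak`,
#'   `v_peak`, `v_base`, `half_duration` (ms; `NA` if a flank never returns
#'   to the half level before the next event).
#' @export
detect_spikes <- function(v, time = NULL, threshold = -20, refractory = 2,
                          baseline_window = 5, site = NULL) {
  if (inherits(v, "trace_set")) {
    tm <- as_trace_matrix(v, site); v <- tm$v; time <- tm$time
  }
  stopifnot(length(v) == length(time), length(v) >= 2)
  empty <- data.frame(t_cross = numeric(0), t_peak = numeric(0),
                      v_peak = numeric(0), v_base = numeric(0),
                      half_duration = numeric(0))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) == 0) return(empty)
  keep <- integer(0)
  last_t <- -Inf
  for (i in up) {
    if (time[i] - last_t >= refractory) {
      keep <- c(keep, i)
      last_t <- time[i]
    }
  }
  n <- length(v)
  rows <- lapply(seq_along(keep), function(j) {
    i <- keep[j]
    down <- which(v[i:n] < threshold)
    j_end <- if (length(down) > 0) i + down[1] - 2L else n
    pk <- i - 1L + which.max(v[i:j_end])
    base_idx <- which(time >= time[i] - baseline_window & time < time[i])
    v_base <- if (length(base_idx) > 0) min(v[base_idx]) else v[max(i - 1L, 1L)]
    data.frame(t_cross = time[i], t_peak = time[pk], v_peak = v[pk],
               v_base = v_base, half_duration = NA_real_)
  })
  ev <- do.call(rbind, rows)
  for (j in seq_len(nrow(ev))) {
    limit <- if (j < nrow(ev)) ev$t_cross[j + 1] else Inf
    ev$half_duration[j] <- half_duration(v, time, ev[j, ], next_event = limit)
  }
  ev
}

#' Width of a spike at half amplitude
#'
#' The half level is `v_base + 0.5 * (v_peak - v_base)`; the width is the
#' distance between the linearly interpolated crossings of that level on the
#' rising and the falling flank. Invariant under affine transforms
#' `v -> a*v + b` (a > 0).
#'
#' @param v membrane potential, mV.
#' @param time time grid, ms.
#' @param event one spike event (row of [detect_spikes()] output, or a list
#'   with `t_peak`, `v_peak`, `v_base`).
#' @param next_event time limit for the falling flank, ms (crossing of the
#'   next event).
#' @return half-duration in ms, or `NA` if the falling flank never returns
#'   to the half level before `next_event`.
#' @export
half_duration <- function(v, time, event, next_event = Inf) {
  level <- event$v_base + 0.5 * (event$v_peak - event$v_base)
  ipk <- which.min(abs(time - event$t_peak))
  cross_at <- function(i0, i1) {
    # linear interpolation of the level crossing between samples i0, i1
    time[i0] + (level - v[i0]) / (v[i1] - v[i0]) * (time[i1] - time[i0])
  }
  # rising flank: last sample below the level before the peak
  below <- which(v[seq_len(ipk)] < level)
  if (length(below) == 0) return(NA_real_)
  i0 <- max(below)
  if (i0 == ipk) return(NA_real_)
  t_rise <- cross_at(i0, i0 + 1L)
  # falling flank: first sample below the level after the peak
  n <- length(v)
  after <- seq.int(ipk, n)
  after <- after[time[after] <= next_event]
  below_f <- after[v[after] < level]
  if (length(below_f) == 0) return(NA_real_)
  i1 <- below_f[1]
  t_fall <- cross_at(i1 - 1L, i1)
  t_fall - t_rise
}

#' Post-stimulus afterdischarge summary
#'
#' Counts spikes later than `stim_end + guard` and within `stim_end +
#' window`; afterdischarge is present when the count reaches
#' `presence_min`. Frequency is `(n - 1) / (t_last - t_first)` (Hz),
#' defined for `n >= 2`.
#'
#' @param events spike events ([detect_spikes()] output), sorted by time.
#' @param stim_end end of the stimulus train, ms.
#' @param window observation window after `stim_end`, ms.
#' @param guard dead time after `stim_end` ignored by the count, ms
#'   (excludes the immediate rebound spike of a train).
#' @param presence_min minimum spike count for presence.
#' @return list of class `afterdischarge_summary`: `present`, `n_spikes`,
#'   `t_first`, `t_last` (ms), `frequency_hz`.
#' @export
afterdischarge_summary <- function(events, stim_end, window = 2000,
                                   guard = 50, presence_min = 3) {
  t <- events$t_peak
  post <- t > stim_end + guard & t <= stim_end + window
  tp <- sort(t[post])
  n <- length(tp)
  freq <- if (n >= 2) (n - 1) / (tp[n] - tp[1]) * 1000 else NA_real_
  structure(list(present = n >= presence_min, n_spikes = n,
                 t_first = if (n > 0) tp[1] else NA_real_,
                 t_last = if (n > 0) tp[n] else NA_real_,
                 frequency_hz = freq),
            class = "afterdischarge_summary")
}

#' @export
print.afterdischarge_summary <- function(x, ...) {
  cat("afterdischarge:", if (x$present) "present" else "absent",
      "|", x$n_spikes, "post-stimulus spikes")
  if (is.finite(x$frequency_hz))
    cat(" |", format(x$frequency_hz, digits = 4), "Hz")
  cat("\n")
  invisible(x)
}

#' Time derivative of a trace (mV/ms)
#'
#' Central differences in the interior, one-sided at the ends.
#'
#' @param v membrane potential, mV.
#' @param dt sampling step, ms.
#' @return numeric vector of `dV/dt`, same length as `v`.
#' @export
derivative_trace <- function(v, dt) {
  n <- length(v)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d
}

#' Count dV/dt peaks in the rising phase of a spike
#'
#' Counts local maxima of `dV/dt` reaching `prominence` between the
#' threshold crossing and the peak of the event. Two or more peaks indicate
#' an inflection in the rising phase (an IS-SD break, the signature of an
#' antidromically invading spike).
#'
#' @param v membrane potential, mV (finely sampled, e.g. dt = 0.01 ms).
#' @param time time grid, ms.
#' @param event one spike event.
#' @param prominence minimum `dV/dt` of a counted peak, mV/ms.
#' @return integer number of rising-phase dV/dt peaks.
#' @export
rising_phase_dvdt_peaks <- function(v, time, event, prominence = 10) {
  dt <- time[2] - time[1]
  d <- derivative_trace(v, dt)
  idx <- which(time >= event$t_cross & time <= event$t_peak)
  idx <- idx[idx > 1 & idx < length(v)]
  if (length(idx) == 0) return(0L)
  is_max <- d[idx] > d[idx - 1L] & d[idx] >= d[idx + 1L] & d[idx] >= prominence
  sum(is_max)
}

#' Per-spike site ordering across recording sites
#'
#' Spikes are detected per site; events of the non-reference sites are
#' matched to each spike of the first listed site by nearest peak time
#' within `window` ms (ties break toward the earlier event and are
#' flagged). Each matched group is ordered by peak time; groups with exactly
#' equal times fall back to the input site order and are flagged as ties.
#'
#' @param traces a `trace_set`.
#' @param sites site labels to order (default: all sites of the trace set).
#' @param window matching window, ms.
#' @param threshold,refractory passed to [detect_spikes()].
#' @return list with `groups` (data frame: one row per reference spike,
#'   peak time per site as `t_<site>`, `order` string of site labels from
#'   earliest to latest, `tie` flag) and `unmatched` (named list of peak
#'   times per site that joined no group).
#' @export
latency_order <- function(traces, sites = NULL, window = 5,
                          threshold = -20, refractory = 2) {
  if (is.null(sites)) sites <- traces$sites
  ev <- lapply(sites, function(s)
    detect_spikes(traces, site = s, threshold = threshold,
                  refractory = refractory))
  names(ev) <- sites
  ref <- ev[[1]]
  used <- lapply(ev, function(e) logical(nrow(e)))
  groups <- NULL
  for (i in seq_len(nrow(ref))) {
    tp <- c(ref$t_peak[i], rep(NA_real_, length(sites) - 1))
    tie <- FALSE
    for (j in seq_along(sites)[-1]) {
      cand <- which(!used[[j]] & abs(ev[[j]]$t_peak - ref$t_peak[i]) <= window)
      if (length(cand) == 0) next
      dtv <- abs(ev[[j]]$t_peak[cand] - ref$t_peak[i])
      best <- cand[dtv == min(dtv)]
      if (length(best) > 1) { tie <- TRUE; best <- best[1] }
      used[[j]][best] <- TRUE
      tp[j] <- ev[[j]]$t_peak[best]
    }
    ok <- !is.na(tp)
    ord <- order(tp[ok], match(sites[ok], sites))
    if (any(duplicated(tp[ok]))) tie <- TRUE
    row <- as.data.frame(as.list(tp))
    names(row) <- paste0("t_", sites)
    row$order <- paste(sites[ok][ord], collapse = " < ")
    row$tie <- tie
    groups <- rbind(groups, row)
  }
  unmatched <- lapply(seq_along(sites)[-1], function(j)
    ev[[j]]$t_peak[!used[[j]]])
  names(unmatched) <- sites[-1]
  list(groups = groups, unmatched = unmatched)
}

#' Full analysis of a trace set
#'
#' Runs spike detection per site, summarizes the post-stimulus
#' afterdischarge (using the trace set's `stim_end`), and, for multi-site
#' recordings, the per-spike latency ordering.
#'
#' @param traces a `trace_set` (or a path readable by [read_trace_csv()]).
#' @param threshold,refractory spike detection parameters.
#' @param guard,presence_min,window afterdischarge parameters
#'   (see [afterdischarge_summary()]); `window` defaults to the protocol's
#'   post-stimulus window when available, else 2000 ms.
#' @return list with `spikes` (per-site event tables), `afterdischarge`
#'   (per-site summaries) and `latency` (or `NULL` for single-site sets).
#' @export
analyze_traces <- function(traces, threshold = -20, refractory = 2,
                           guard = 50, presence_min = 3, window = NULL) {
  if (is.character(traces)) traces <- read_trace_csv(traces)
  if (is.null(window))
    window <- if (!is.null(traces$protocol)) traces$protocol$t_post else 2000
  spikes <- lapply(traces$sites, function(s)
    detect_spikes(traces, site = s, threshold = threshold,
                  refractory = refractory))
  names(spikes) <- traces$sites
  ad <- NULL
  if (is.finite(traces$stim_end))
    ad <- lapply(spikes, afterdischarge_summary, stim_end = traces$stim_end,
                 window = window, guard = guard, presence_min = presence_min)
  lat <- if (length(traces$sites) >= 2)
    latency_order(traces, threshold = threshold, refractory = refractory)
  list(spikes = spikes, afterdischarge = ad, latency = lat)
}
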