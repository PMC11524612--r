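# Spike detection, firing-pattern classification, and bisection searches
# for pattern-transition thresholds.
#
# Classification vocabulary (mutually exclusive per analysis window):
# resting, subthreshold_oscillation, tonic_firing, periodic_bursting,
# bursting_with_DB, stable_DB. Decision rules:
#   * spikes: upward crossings of -20 mV with 2 ms refractory separation;
#   * depolarization block (DB): a 2 s window with mean V > -50 mV and no
#     spikes; stable_DB requires DB to hold throughout the final 20 s;
#   * bursts: spikes segmented at interspike intervals exceeding 5x the
#     within-burst median ISI;
#   * tonic firing: spikes, no DB intervals, ISI coefficient of variation
#     < 0.5; periodic bursting: >1 burst, no DB; bursting_with_DB: spikes
#     plus DB intervals that do not persist to the end;
#   * resting: no spikes and peak-to-peak V < 1 mV late in the window, V
#     hyperpolarized; subthreshold_oscillation: no spikes, no DB, but
#     peak-to-peak V oscillation > 1 mV.

#' Detect spikes in a voltage trace
#'
#' One event per upward crossing of `threshold` separated by at least
#' `refractory` ms, with the crossing time linearly interpolated. For
#' traces produced by [integrate_neuron()] with `method = "rk4"` this
#' simply returns the spike times already detected on the undecimated
#' stream.
#'
#' @param trace A `neuron_trace`, or a numeric vector of sample times (ms)
#'   if `V` is given.
#' @param V Voltage samples (mV) when `trace` is a time vector.
#' @param threshold Spike threshold (mV).
#' @param refractory Minimum separation (ms).
#' @return Spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(trace, V = NULL, threshold = -20,
                          refractory = 2) {
  if (inherits(trace, "neuron_trace")) {
    if (trace$solver$method == "rk4" &&
        threshold == trace$solver$spike_threshold &&
        refractory == trace$solver$refractory)
      return(trace$spikes)
    return(detect_spikes_v(trace$t, trace$state[, "V"], threshold,
                           refractory))
  }
  detect_spikes_v(trace, V, threshold, refractory)
}

detect_spikes_v <- function(t, V, threshold = -20, refractory = 2) {
  if (length(t) != length(V)) stop("t and V must have equal length")
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  if (!length(up)) return(numeric(0))
  frac <- (threshold - V[up]) / (V[up + 1] - V[up])
  times <- t[up] + frac * (t[up + 1] - t[up])
  keep <- c(TRUE, diff(times) > refractory)
  # enforce refractory sequentially (diff alone can chain-violate)
  out <- times[1]
  for (tt in times[-1]) if (tt - out[length(out)] > refractory)
    out <- c(out, tt)
  out
}

db_intervals_of <- function(t, V, spikes, db_window = 2000,
                            db_voltage = -50, db_flat = 5) {
  # non-overlapping 2 s windows flagged as DB plateau (depolarized mean,
  # no spikes, nearly flat -- large-amplitude subthreshold oscillation is
  # not depolarization block), then merged
  if (length(t) < 2) return(matrix(numeric(0), ncol = 2))
  breaks <- seq(t[1], t[length(t)], by = db_window)
  if (length(breaks) < 2) return(matrix(numeric(0), ncol = 2))
  idx <- findInterval(t, breaks, rightmost.closed = TRUE)
  means <- tapply(V, idx, mean)
  vpp <- tapply(V, idx, function(v) diff(range(v)))
  nwin <- length(breaks) - 1
  flag <- rep(FALSE, nwin)
  present <- as.integer(names(means))
  inw <- present[present >= 1 & present <= nwin]
  flag[inw] <- means[as.character(inw)] > db_voltage &
    vpp[as.character(inw)] < db_flat
  if (length(spikes)) {
    sp_win <- unique(findInterval(spikes, breaks, rightmost.closed = TRUE))
    sp_win <- sp_win[sp_win >= 1 & sp_win <= nwin]
    flag[sp_win] <- FALSE
  }
  if (!any(flag)) return(matrix(numeric(0), ncol = 2))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  cbind(breaks[starts[on]], breaks[ends[on] + 1])
}

segment_bursts <- function(spikes, isi_factor = 5) {
  if (length(spikes) < 2)
    return(list(boundaries = if (length(spikes))
      cbind(spikes, spikes) else matrix(numeric(0), ncol = 2),
      cv = NA_real_))
  isi <- diff(spikes)
  med <- median(isi[isi <= isi_factor * median(isi)])
  gap <- which(isi > isi_factor * med)
  starts <- c(1, gap + 1)
  ends <- c(gap, length(spikes))
  list(boundaries = cbind(spikes[starts], spikes[ends]),
       cv = sd(isi) / mean(isi))
}

#' Classify the firing pattern of a trace
#'
#' Applies the decision rules described at the top of this file to the
#' final `window` ms of the trace. Burst-class labels need windows long
#' enough to contain at least two burst cycles; windows under 60 s that
#' produce a burst-class or stable-DB label are flagged low-confidence
#' rather than rejected.
#'
#' @param trace A `neuron_trace`.
#' @param window Analysis window (ms), measured back from the end of the
#'   trace; `Inf` uses the whole trace.
#' @param settle Initial transient (ms) always excluded, even if `window`
#'   covers it.
#' @return A `firing_pattern`: list with `label`, `spike_times`,
#'   `burst_boundaries` (matrix of start/end times), `db_intervals`,
#'   `low_confidence`, and summary statistics.
#' @export
classify_firing <- function(trace, window = Inf, settle = 2000) {
  stopifnot(inherits(trace, "neuron_trace"))
  t_end <- trace$t_final
  t_from <- max(trace$t[1] + settle, t_end - window)
  keep <- trace$t >= t_from
  t <- trace$t[keep]
  V <- trace$state[keep, "V"]
  spikes <- trace$spikes[trace$spikes >= t_from]
  win_len <- t_end - t_from

  db <- db_intervals_of(t, V, spikes)
  seg <- segment_bursts(spikes)
  db_occupancy <- if (nrow(db)) sum(db[, 2] - db[, 1]) / win_len else 0
  tail20 <- max(t_from, t_end - 20000)
  db_to_end <- nrow(db) > 0 && any(db[, 2] >= t_end - 2000 &
                                     db[, 1] <= tail20) &&
    !any(spikes > tail20)

  label <- if (length(spikes) == 0) {
    late <- t >= max(t_from, t_end - min(win_len / 2, 20000))
    p2p <- diff(range(V[late]))
    if (db_to_end) "stable_DB"
    else if (p2p > 1) "subthreshold_oscillation"
    else "resting"
  } else if (db_to_end) {
    "stable_DB"
  } else if (nrow(db) > 0) {
    "bursting_with_DB"
  } else if (nrow(seg$boundaries) > 1 &&
             !(is.finite(seg$cv) && seg$cv < 0.5)) {
    "periodic_bursting"
  } else {
    "tonic_firing"
  }

  low_conf <- (label %in% c("periodic_bursting", "bursting_with_DB",
                            "stable_DB") && win_len < 60000) ||
    (label == "periodic_bursting" && nrow(seg$boundaries) < 2)

  structure(list(label = label, spike_times = spikes,
                 burst_boundaries = seg$boundaries, db_intervals = db,
                 low_confidence = low_conf,
                 stats = list(n_spikes = length(spikes),
                              n_bursts = nrow(seg$boundaries),
                              isi_cv = seg$cv,
                              db_occupancy = db_occupancy,
                              window_ms = win_len)),
            class = "firing_pattern")
}

#' @export
print.firing_pattern <- function(x, ...) {
  cat("<firing_pattern> ", x$label,
      if (x$low_confidence) " (low confidence)" else "", ": ",
      x$stats$n_spikes, " spikes, ", x$stats$n_bursts, " bursts, DB ",
      signif(100 * x$stats$db_occupancy, 3), "% of ",
      signif(x$stats$window_ms / 1000, 4), " s window\n", sep = "")
  invisible(x)
}

#' Classification report as JSON
#'
#' @param pattern A `firing_pattern`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The path (invisibly) or a JSON string.
#' @export
pattern_report_json <- function(pattern, path = NULL) {
  rep <- list(label = pattern$label,
              spike_count = pattern$stats$n_spikes,
              burst_count = pattern$stats$n_bursts,
              db_occupancy = pattern$stats$db_occupancy,
              low_confidence = pattern$low_confidence)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(rep, auto_unbox = TRUE,
                                         digits = NA)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bisection search for a pattern-transition threshold
#'
#' Locates the boundary of a scalar parameter at which a logical predicate
#' flips, by bisection. The predicate must differ at the two endpoints.
#'
#' @param range Length-2 numeric search interval.
#' @param predicate Function of one scalar returning `TRUE`/`FALSE`.
#' @param tol Stop when the bracket is narrower than this; the midpoint of
#'   the final bracket is returned.
#' @param verbose Print each probe.
#' @return The threshold estimate, with attribute `bracket`.
#' @export
#' @examples
#' find_transition(c(0, 1), function(x) x > 0.3, tol = 1e-4)
find_transition <- function(range, predicate, tol = 0.005,
                            verbose = FALSE) {
  stopifnot(length(range) == 2, diff(range) > 0, tol > 0)
  lo <- range[1]; hi <- range[2]
  p_lo <- isTRUE(predicate(lo)); p_hi <- isTRUE(predicate(hi))
  if (p_lo == p_hi)
    stop("bracket error: predicate equal at both endpoints")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    p_mid <- isTRUE(predicate(mid))
    if (verbose) message(sprintf("  probe %.6g -> %s", mid, p_mid))
    if (p_mid == p_lo) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi))
}
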