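# Signal conditioning and gait-event detection.

#' Butterworth low-pass filter specification
#'
#' Human gait dynamics sit below about 20 Hz, so raw IMU channels are
#' conditioned with a 4th-order Butterworth low-pass at 20 Hz before any
#' event detection or orientation estimation.
#'
#' @param order Filter order (default 4).
#' @param cutoff Cutoff frequency, Hz (default 20); must be below Nyquist.
#' @param sampling_rate Sampling rate, Hz.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(order = 4L, cutoff = 20, sampling_rate = 100) {
  if (cutoff >= sampling_rate / 2) {
    stop("parameter error: cutoff (", cutoff,
         " Hz) must be below the Nyquist frequency (", sampling_rate / 2, " Hz)")
  }
  if (order < 1) stop("parameter error: order must be >= 1")
  structure(list(order = as.integer(order), cutoff = cutoff,
                 sampling_rate = sampling_rate),
            class = "filter_spec")
}

.butter_cache <- new.env(parent = emptyenv())

butter_coefs <- function(spec) {
  key <- paste(spec$order, spec$cutoff, spec$sampling_rate, sep = "_")
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(spec$order, spec$cutoff / (spec$sampling_rate / 2),
                         type = "low")
    .butter_cache[[key]] <- bf
  }
  bf
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies the specified Butterworth response forward and backward
#' (zero-phase), so event timings are not biased by filter delay. Output
#' length equals input length; a constant signal passes unchanged (unit DC
#' gain).
#'
#' @param series Uniformly sampled numeric signal.
#' @param spec A [filter_spec()].
#' @return Filtered signal of equal length.
#' @export
#' @examples
#' sp <- filter_spec(4, 20, 100)
#' x <- sin(2 * pi * 2 * (0:199) / 100)
#' y <- lowpass_filter(x, sp)
lowpass_filter <- function(series, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  bad <- which(!is.finite(series))
  if (length(bad) > 0) {
    stop("data error: non-finite value in input at index ", bad[1])
  }
  if (length(series) < 3 * spec$order) {
    stop("data error: series too short to filter (need >= ", 3 * spec$order,
         " samples)")
  }
  as.numeric(lowpass_filter_mat(matrix(series, ncol = 1), spec))
}

# Zero-phase Butterworth applied column-wise to a matrix in one pass.
# Each column is extended at both ends by odd reflection (mirrored about
# the end samples) so start-up transients decay inside the padding, then
# all channels are stacked into a single vector separated by zero guards
# long enough for the filter state to die out, so one C-level recursive
# filter call covers every channel, forward and backward.
lowpass_filter_mat <- function(m, spec) {
  bf <- butter_coefs(spec)
  b <- bf$b
  a <- bf$a
  n <- nrow(m)
  k <- ncol(m)
  pad <- min(max(12L * spec$order, 24L), n - 1L)
  guard <- 150L

  head_ref <- 2 * m[rep(1L, pad), , drop = FALSE] - m[(pad + 1L):2L, , drop = FALSE]
  tail_ref <- 2 * m[rep(n, pad), , drop = FALSE] - m[(n - 1L):(n - pad), , drop = FALSE]
  ext <- rbind(head_ref, m, tail_ref)
  ne <- nrow(ext)

  one_pass <- function(mat) {
    stacked <- rbind(mat, matrix(0, guard, k))
    v <- c(rep(0, length(b) - 1), as.vector(stacked))
    z <- stats::filter(v, b, sides = 1)[-seq_len(length(b) - 1)]
    y <- stats::filter(as.numeric(z), -a[-1], method = "recursive")
    matrix(as.numeric(y), nrow(stacked), k)[seq_len(nrow(mat)), , drop = FALSE]
  }
  fwd <- one_pass(ext)
  bwd <- one_pass(fwd[rev(seq_len(ne)), , drop = FALSE])
  bwd[rev(seq_len(ne)), , drop = FALSE][pad + seq_len(n), , drop = FALSE]
}

#' Detect heel-strike and toe-off events from foot angular velocity
#'
#' Heel strikes are local maxima of the filtered foot sagittal angular
#' velocity strictly exceeding `threshold` (deg/s); toe-offs are local
#' minima below `-threshold`. Within each event type at most one peak is
#' kept per `min_separation` window (the largest); events are then forced to
#' alternate heel strike / toe-off by discarding the lower-magnitude peak of
#' any adjacent same-type pair. The threshold is strict (a 49.999 deg/s peak
#' at threshold 50 is rejected); plateaus resolve to their earliest sample;
#' edge samples cannot be peaks.
#'
#' @param foot_sagittal_gyro Filtered sagittal angular velocity, deg/s.
#' @param sampling_rate Sampling rate, Hz.
#' @param threshold Detection threshold, deg/s (default 50).
#' @param min_separation Minimum same-type event spacing, s (default 0.25,
#'   shorter than any plausible half cycle at cohort cadences).
#' @param side Optional side label ("L"/"R") copied into the result.
#' @return Data frame of class `gait_events` with columns `time`, `side`,
#'   `type` ("heel_strike"/"toe_off"), `peak_value` (deg/s), sorted by time.
#'   Empty (zero rows) when no peak crosses the threshold.
#' @export
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' x <- 120 * exp(-(t - 1)^2 / (2 * 0.04^2))
#' detect_gait_events(x, 100)
detect_gait_events <- function(foot_sagittal_gyro, sampling_rate,
                               threshold = 50, min_separation = 0.25,
                               side = NA_character_) {
  x <- foot_sagittal_gyro
  if (length(x) == 0) stop("data error: empty signal")
  if (threshold <= 0) stop("parameter error: threshold must be positive")
  n <- length(x)
  empty <- data.frame(time = numeric(0), side = character(0),
                      type = character(0), peak_value = numeric(0))
  class(empty) <- c("gait_events", "data.frame")
  if (n < 3) return(empty)

  core <- 2:(n - 1)
  is_max <- x[core] > threshold & x[core] > x[core - 1] & x[core] >= x[core + 1]
  is_min <- x[core] < -threshold & x[core] < x[core - 1] & x[core] <= x[core + 1]
  idx <- c(core[is_max], core[is_min])
  type <- rep(c("heel_strike", "toe_off"), c(sum(is_max), sum(is_min)))
  if (length(idx) == 0) return(empty)
  peak <- x[idx]

  # one event of each type per min_separation window: greedy by magnitude
  keep_window <- function(sub_idx, sub_peak) {
    o <- order(-abs(sub_peak), sub_idx)
    kept <- integer(0)
    min_gap <- min_separation * sampling_rate
    for (i in o) {
      if (all(abs(sub_idx[i] - kept) >= min_gap)) kept <- c(kept, sub_idx[i])
    }
    sub_idx %in% kept
  }
  keep <- logical(length(idx))
  for (ty in unique(type)) {
    sel <- type == ty
    keep[sel] <- keep_window(idx[sel], peak[sel])
  }
  idx <- idx[keep]; type <- type[keep]; peak <- peak[keep]
  o <- order(idx)
  idx <- idx[o]; type <- type[o]; peak <- peak[o]

  # enforce alternation: drop the weaker of adjacent same-type events
  repeat {
    if (length(idx) < 2) break
    same <- which(type[-1] == type[-length(type)])
    if (length(same) == 0) break
    i <- same[1]
    drop <- if (abs(peak[i]) >= abs(peak[i + 1])) i + 1L else i
    idx <- idx[-drop]; type <- type[-drop]; peak <- peak[-drop]
  }

  # sub-sample peak time by parabolic interpolation through the peak and
  # its neighbours (plateaus keep the sample time)
  xm <- x[idx - 1]
  xp <- x[idx + 1]
  den <- xm - 2 * x[idx] + xp
  delta <- ifelse(abs(den) > 0, 0.5 * (xm - xp) / den, 0)
  delta[!is.finite(delta) | abs(delta) > 0.5] <- 0

  out <- data.frame(
    time = (idx - 1 + delta) / sampling_rate,
    side = side,
    type = type,
    peak_value = peak,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("gait_events", "data.frame")
  out
}

#' Segment gait cycles from detected events
#'
#' A cycle runs between consecutive same-side heel strikes containing
#' exactly one intervening same-side toe-off; incomplete leading/trailing
#' fragments are discarded. Contralateral toe-off and heel-strike times
#' falling inside the cycle are attached when present (they define the
#' double-support sub-phases).
#'
#' @param events_left,events_right `gait_events` tables for the left and
#'   right foot (as returned by [detect_gait_events()]).
#' @return Data frame of class `gait_cycles`: `side`, `start_hs`, `toe_off`,
#'   `end_hs`, `contra_to`, `contra_hs` (NA when absent), `duration`.
#' @export
segment_cycles <- function(events_left, events_right) {
  one_side <- function(ev, contra, side) {
    hs <- ev$time[ev$type == "heel_strike"]
    to <- ev$time[ev$type == "toe_off"]
    if (length(hs) < 2) {
      return(data.frame(side = character(0), start_hs = numeric(0),
                        toe_off = numeric(0), end_hs = numeric(0),
                        contra_to = numeric(0), contra_hs = numeric(0),
                        duration = numeric(0)))
    }
    c_to <- contra$time[contra$type == "toe_off"]
    c_hs <- contra$time[contra$type == "heel_strike"]
    a <- hs[-length(hs)]
    b <- hs[-1]
    # first same-side toe-off / contralateral event strictly inside (a, b)
    first_inside <- function(ev, a, b) {
      if (length(ev) == 0) return(list(t = rep(NA_real_, length(a)), n = integer(length(a))))
      pos <- findInterval(a, ev) + 1L  # index of first ev > a
      t <- ifelse(pos <= length(ev) & ev[pmin(pos, length(ev))] < b,
                  ev[pmin(pos, length(ev))], NA_real_)
      n <- findInterval(b - 1e-12, ev) - findInterval(a, ev)
      list(t = t, n = n)
    }
    tos <- first_inside(to, a, b)
    cto <- first_inside(c_to, a, b)
    chs <- first_inside(c_hs, a, b)
    ok <- tos$n == 1L
    data.frame(side = rep(side, sum(ok)), start_hs = a[ok],
               toe_off = tos$t[ok], end_hs = b[ok],
               contra_to = cto$t[ok], contra_hs = chs$t[ok],
               duration = (b - a)[ok])
  }
  out <- rbind(one_side(events_left, events_right, "L"),
               one_side(events_right, events_left, "R"))
  if (is.null(out)) {
    out <- data.frame(side = character(0), start_hs = numeric(0),
                      toe_off = numeric(0), end_hs = numeric(0),
                      contra_to = numeric(0), contra_hs = numeric(0),
                      duration = numeric(0))
  }
  rownames(out) <- NULL
  class(out) <- c("gait_cycles", "data.frame")
  out
}

#' Write detected events as CSV
#'
#' @param events A `gait_events` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(time_s = events$time, side = events$side,
                   type = events$type, peak_dps = events$peak_value)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
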