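#' Detect stationary footfalls in a foot trace
#'
#' Each foot comes briefly to rest around each footfall (mid-stance with the
#' foot flat). Footfalls are detected as runs where the foot's speed stays
#' below `speed_threshold` for at least `min_dwell` seconds; the event time
#' is the run midpoint. Events closer than `refractory` seconds are merged.
#'
#' @param trace a `foot_trace` (uniformly sampled `time_s`, `x_m`).
#' @param speed_threshold stationarity threshold, m/s.
#' @param min_dwell minimum stationary duration, s.
#' @param refractory minimum separation between footfalls, s.
#' @return data frame with `time_s`, `index` (sample index of the event)
#'   and `x_m` (trace position at the event).
#' @export
detect_footfalls <- function(trace, speed_threshold = 0.05,
                             min_dwell = 0.08, refractory = 0.4) {
  dt <- diff(trace$time_s)
  if (length(dt) < 2 || max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop_curbwalk("format", "foot trace must be uniformly sampled")
  dt <- dt[1]
  v <- trace_velocity(trace$x_m, dt)
  still <- abs(v) < speed_threshold
  if (all(still))
    stop_curbwalk("detection",
                  "entire trace below the stationarity threshold: no strides to detect")
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * dt >= min_dwell
  if (!any(keep))
    stop_curbwalk("detection", "no stationary dwell of sufficient duration found")
  # event time = midpoint of the stationary run, with the run edges located
  # by linear interpolation of the threshold crossings (sub-sample accuracy;
  # the position is read at a sample inside the dwell, where it is constant)
  ks <- starts[keep]; ke <- ends[keep]
  va <- abs(v)
  im1 <- pmax(ks - 1, 1)
  ip1 <- pmin(ke + 1, length(va))
  t_in <- ifelse(ks > 1,
                 trace$time_s[im1] + dt * (va[im1] - speed_threshold) /
                   pmax(va[im1] - va[ks], 1e-12),
                 trace$time_s[ks])
  t_out <- ifelse(ke < length(va),
                  trace$time_s[ke] + dt * (speed_threshold - va[ke]) /
                    pmax(va[ip1] - va[ke], 1e-12),
                  trace$time_s[ke])
  tt <- (t_in + t_out) / 2
  mids <- floor((ks + ke) / 2)
  sep <- c(Inf, diff(tt))
  ok <- sep >= refractory | sep == Inf
  data.frame(time_s = tt[ok], index = mids[ok],
             x_m = trace$x_m[mids[ok]])
}

# central-difference velocity with one-sided ends
trace_velocity <- function(x, dt) {
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v
}

#' Zero-velocity-update integration of a foot trace
#'
#' Inertial integration drifts; the foot's known rest at each footfall is
#' used to correct it. Between consecutive footfall events the foot
#' velocity receives a correction linear in time that forces it to zero at
#' both bounding events (a constant offset before the first and after the
#' last event), and position is re-integrated continuously from the first
#' event's position.
#'
#' @param trace a `foot_trace`.
#' @param events footfall events from [detect_footfalls()].
#' @return a data frame (`time_s`, `x_m`, `z_m` if present) with the
#'   drift-corrected forward position, carrying the trace attributes.
#' @export
zupt_integrate <- function(trace, events) {
  if (nrow(events) < 2)
    stop_curbwalk("detection", "need at least two footfall events to correct drift")
  if (any(events$index < 1 | events$index > nrow(trace)))
    stop("footfall events outside the trace", call. = FALSE)
  dt <- trace$time_s[2] - trace$time_s[1]
  v <- trace_velocity(trace$x_m, dt)
  corr <- numeric(length(v))
  ei <- events$index
  corr[seq_len(ei[1])] <- v[ei[1]]
  for (k in seq_len(length(ei) - 1)) {
    seg <- seq(ei[k], ei[k + 1])
    corr[seg] <- v[ei[k]] +
      (v[ei[k + 1]] - v[ei[k]]) * (seg - ei[k]) / (ei[k + 1] - ei[k])
  }
  corr[seq(ei[length(ei)], length(v))] <- v[ei[length(ei)]]
  vc <- v - corr
  x <- cumsum(c(0, (vc[-1] + vc[-length(vc)]) / 2 * dt))
  x <- x - x[ei[1]] + trace$x_m[ei[1]]
  out <- trace
  out$x_m <- x
  out
}

#' Build a stride table from corrected positions
#'
#' A stride runs between two consecutive footfalls of the same foot; its
#' average speed is the stride length divided by the stride time. The
#' stride is assigned to the footfall at which it begins.
#'
#' @param positions drift-corrected trace from [zupt_integrate()].
#' @param events footfall events from [detect_footfalls()].
#' @return a `stride_table` data frame: `footfall_time`,
#'   `footfall_position`, `stride_length`, `stride_time`, `stride_speed`
#'   (NA on the final footfall, which starts no stride), with attribute
#'   `foot`.
#' @export
build_stride_table <- function(positions, events) {
  if (nrow(events) < 2)
    stop_curbwalk("detection", "need at least two footfalls to form a stride")
  x <- positions$x_m[events$index]
  t <- events$time_s
  n <- length(x)
  len <- c(diff(x), NA_real_)
  dur <- c(diff(t), NA_real_)
  structure(data.frame(footfall_time = t, footfall_position = x,
                       stride_length = len, stride_time = dur,
                       stride_speed = len / dur),
            class = c("stride_table", "data.frame"),
            foot = attr(positions, "foot"))
}

#' Reconcile the two feet's total distances
#'
#' Residual integration drift makes the two feet disagree slightly on the
#' distance travelled. Each foot's positions receive a correction linear in
#' time so both report the same total distance (their mean), and stride
#' lengths are recomputed.
#'
#' @param left,right `stride_table`s spanning the same traversal.
#' @param max_discrepancy largest tolerated relative disagreement before
#'   the trial is rejected as a quality-control failure.
#' @return list with corrected `left` and `right` stride tables.
#' @export
detrend_feet <- function(left, right, max_discrepancy = 0.10) {
  tot <- function(s) s$footfall_position[nrow(s)] - s$footfall_position[1]
  tl <- tot(left); tr <- tot(right)
  if (abs(tl - tr) > max_discrepancy * max(abs(tl), abs(tr)))
    stop_curbwalk("quality",
      sprintf("feet disagree on total distance by %.1f%%: trial rejected",
              100 * abs(tl - tr) / max(abs(tl), abs(tr))))
  target <- (tl + tr) / 2
  fix <- function(s, total) {
    t0 <- s$footfall_time[1]
    span <- s$footfall_time[nrow(s)] - t0
    s$footfall_position <- s$footfall_position +
      (target - total) * (s$footfall_time - t0) / span
    n <- nrow(s)
    s$stride_length <- c(diff(s$footfall_position), NA_real_)
    s$stride_speed <- s$stride_length / s$stride_time
    s
  }
  list(left = fix(left, tl), right = fix(right, tr))
}

#' Per-step body-speed sequence from the two feet
#'
#' Interleaves the two feet's stride speeds into one discrete sequence,
#' one sample per step: the body's speed at step `i` is the stride speed of
#' the foot whose footfall begins that step (the body travels the same
#' distance per stride as the feet). Step `i = 0` is the footfall onto the
#' height change; times are relative to it; the sequence is cropped to a
#' central window of `window_m` metres centred on that footfall.
#'
#' @param left,right (detrended) `stride_table`s.
#' @param perturbation_time time of the footfall onto the height change
#'   (from trial metadata; for Control the equivalent position).
#' @param window_m length of the retained central segment, m.
#' @param condition label carried onto the result.
#' @return a [speed_trajectory()].
#' @export
body_speed_sequence <- function(left, right, perturbation_time,
                                window_m = 8.5, condition = NA_character_) {
  ff <- rbind(
    data.frame(time_s = left$footfall_time, x_m = left$footfall_position,
               speed = left$stride_speed),
    data.frame(time_s = right$footfall_time, x_m = right$footfall_position,
               speed = right$stride_speed))
  ff <- ff[order(ff$time_s), ]
  ff <- ff[!is.na(ff$speed), ]
  i0 <- which.min(abs(ff$time_s - perturbation_time))
  step_dt <- stats::median(diff(sort(ff$time_s)))
  if (abs(ff$time_s[i0] - perturbation_time) > 1.5 * step_dt)
    stop_curbwalk("alignment",
                  "no footfall near the stated perturbation time: cannot align the segment")
  x0 <- ff$x_m[i0]
  keep <- abs(ff$x_m - x0) <= window_m / 2
  # retain the maximal contiguous run of in-window footfalls around i = 0
  lo <- i0; while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(keep) && keep[hi + 1]) hi <- hi + 1
  kept <- seq(lo, hi)
  speed_trajectory(step_index = kept - i0,
                   time_s = ff$time_s[kept] - ff$time_s[i0],
                   speed_mps = ff$speed[kept],
                   condition = condition)
}

#' Reconstruct one trial end to end
#'
#' Convenience wrapper running the full measurement pipeline on a pair of
#' synthesized (or identically formatted) foot traces: footfall detection,
#' zero-velocity-update integration, stride tables, inter-foot detrending,
#' and the interleaved, cropped per-step body-speed sequence.
#'
#' @param traces list with `left` and `right` foot traces.
#' @param perturbation_time time of the footfall onto the height change.
#' @param window_m central analysis window, m.
#' @param condition label carried onto the result.
#' @param ... passed to [detect_footfalls()].
#' @return a [speed_trajectory()].
#' @export
reconstruct_trial <- function(traces, perturbation_time, window_m = 8.5,
                              condition = NA_character_, ...) {
  tabs <- lapply(traces[c("left", "right")], function(tr) {
    ev <- detect_footfalls(tr, ...)
    pos <- zupt_integrate(tr, ev)
    build_stride_table(pos, ev)
  })
  tabs <- detrend_feet(tabs$left, tabs$right)
  body_speed_sequence(tabs$left, tabs$right, perturbation_time,
                      window_m = window_m, condition = condition)
}
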