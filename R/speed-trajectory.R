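#' Discrete per-step speed trajectories
#'
#' The common container for walking-speed sequences, used both for model
#' predictions ([body_speed_trajectory()]) and for reconstructed
#' experimental sequences ([body_speed_sequence()]). Step index 0 is the
#' step landing on the height change (or the equivalent position for level
#' walking) and times are relative to that footfall.
#'
#' @param step_index consecutive integer step indices (0 at the
#'   perturbation step).
#' @param time_s per-step times in seconds, relative to `t = 0`.
#' @param speed_mps per-step body speeds in m/s.
#' @param condition label (`"up"`, `"down"`, `"control"`, or a strategy).
#' @param ... further per-step columns (e.g. `sd_mps` for averages).
#' @return a data frame of class `speed_trajectory` with attributes
#'   `condition` and `mean_speed`.
#' @export
speed_trajectory <- function(step_index, time_s, speed_mps,
                             condition = NA_character_, ...) {
  stopifnot(length(step_index) == length(time_s),
            length(time_s) == length(speed_mps))
  if (length(step_index) > 1 && any(diff(step_index) != 1))
    stop("step_index must be consecutive integers", call. = FALSE)
  df <- data.frame(step_index = as.integer(step_index), time_s = time_s,
                   speed_mps = speed_mps, ...)
  structure(df, class = c("speed_trajectory", "data.frame"),
            condition = condition, mean_speed = mean(speed_mps))
}

#' @rdname speed_trajectory
#' @param trajectory a `speed_trajectory`.
#' @return `fluctuations()`: the speed sequence with the trajectory's own
#'   mean removed (the "delta-v" series used throughout the analyses).
#' @export
fluctuations <- function(trajectory) {
  trajectory$speed_mps - mean(trajectory$speed_mps)
}

#' @rdname speed_trajectory
#' @export
condition_label <- function(trajectory) attr(trajectory, "condition")

#' @export
print.speed_trajectory <- function(x, ...) {
  cat(sprintf("<speed_trajectory: %d steps, condition %s, mean %.3f m/s>\n",
              nrow(x), attr(x, "condition"), attr(x, "mean_speed")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Average speed trajectories across trials at discrete step numbers
#'
#' Per-index mean of speeds and times over the common index range
#' (intersection); used to form a subject's average trajectory per
#' condition, and the grand average across subjects.
#'
#' @param trajectories a non-empty list of `speed_trajectory` objects.
#' @return a `speed_trajectory` with columns `step_index`, `time_s`,
#'   `speed_mps`, `sd_mps` (NA when a single trajectory is supplied).
#' @export
average_condition <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  idx <- Reduce(intersect, lapply(trajectories, function(tr) tr$step_index))
  if (length(idx) == 0)
    stop_curbwalk("alignment", "trajectories share no common step indices")
  idx <- sort(idx)
  sp <- sapply(trajectories, function(tr)
    tr$speed_mps[match(idx, tr$step_index)])
  tm <- sapply(trajectories, function(tr)
    tr$time_s[match(idx, tr$step_index)])
  sp <- matrix(sp, nrow = length(idx))
  tm <- matrix(tm, nrow = length(idx))
  speed_trajectory(step_index = idx,
                   time_s = rowMeans(tm),
                   speed_mps = rowMeans(sp),
                   condition = attr(trajectories[[1]], "condition"),
                   sd_mps = if (ncol(sp) > 1) apply(sp, 1, stats::sd)
                            else rep(NA_real_, length(idx)))
}
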