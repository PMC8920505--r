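#' Synthetic walkway cohort configuration
#'
#' Describes the emulated experiment: subjects walk a level walkway with a
#' single raised step at its midpoint, in Up-step, Down-step and level
#' Control conditions, at self-selected speeds. Defaults follow the study
#' conditions: 12 subjects, 30 m walkway, 7.5 cm curb, overall speeds
#' 1.38 +/- 0.10 m/s across subjects, ~5% coefficient of variation between
#' a subject's trials, and ~2.2% within-trial step-speed noise.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param walkway_length walkway length, m.
#' @param step_height curb height, m (magnitude; the condition sets the sign).
#' @param mean_speed population mean self-selected speed, m/s.
#' @param sd_speed_between_subjects SD of subject mean speeds, m/s.
#' @param cv_speed_between_trials c.v. of a subject's trial speeds.
#' @param cv_step_noise c.v. of i.i.d. per-step speed noise within a trial.
#' @param trials_per_condition trials per subject and condition.
#' @param sample_rate foot-trace sampling rate, Hz (>= 20).
#' @param base_step_length step length at `mean_speed`, m.
#' @param step_length_exponent exponent `q` of the preferred step-length
#'   relation `S(v) = base * (v / mean_speed)^q`.
#' @param drift_rms RMS of the white accelerometer error integrated into
#'   the synthesized traces, m/s^2 (0 disables drift).
#' @param dwell_duration stationary footfall dwell, s (>= 0.08).
#' @param swing_peak_height peak foot height during swing, m.
#' @param rng_seed integer seed governing the whole cohort.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12, walkway_length = 30,
                          step_height = 0.075, mean_speed = 1.38,
                          sd_speed_between_subjects = 0.10,
                          cv_speed_between_trials = 0.05,
                          cv_step_noise = 0.022,
                          trials_per_condition = 4,
                          sample_rate = 100,
                          base_step_length = 0.72,
                          step_length_exponent = 0.42,
                          drift_rms = 0.02,
                          dwell_duration = 0.12,
                          swing_peak_height = 0.05,
                          rng_seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_subjects >= 2, walkway_length > 0, step_height > 0,
              mean_speed > 0, sd_speed_between_subjects >= 0,
              cv_speed_between_trials >= 0, cv_speed_between_trials < 0.2,
              cv_step_noise >= 0, cv_step_noise < 0.2,
              trials_per_condition >= 1, sample_rate >= 20,
              base_step_length > 0, drift_rms >= 0,
              dwell_duration >= 0.08)
  })
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @param path file ending in `.yaml`, `.yml` or `.json`; a bundled
#'   `cohort.yaml` with the default study conditions ships under
#'   `system.file("extdata", package = "curbwalk")`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("cohort config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported cohort config format: .", ext, call. = FALSE))
  do.call(cohort_config, vals[names(vals) %in% names(formals(cohort_config))])
}

#' @rdname cohort_config
#' @param config a `cohort_config` object.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(unclass(config), path),
    json = jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                                digits = NA),
    stop("unsupported cohort config format: .", ext, call. = FALSE))
  invisible(path)
}

# evaluate fn under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Draw a synthetic cohort
#'
#' Samples subject mean speeds from
#' `Normal(mean_speed, sd_speed_between_subjects^2)` and per-trial speeds
#' from `Normal(subject mean, (cv_speed_between_trials * subject mean)^2)`,
#' for every subject, condition (`up`, `down`, `control`) and trial. Fully
#' reproducible from `rng_seed`.
#'
#' @param config a [cohort_config()].
#' @return a data frame with one row per trial: `subject`, `condition`,
#'   `trial`, `subject_mean_speed`, `trial_speed`, `step_height` (signed,
#'   m), and a derived `trial_seed`.
#' @export
draw_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$rng_seed, {
    subj_speed <- stats::rnorm(config$n_subjects, config$mean_speed,
                               config$sd_speed_between_subjects)
    subj_speed <- pmax(subj_speed, 0.4)   # physical floor, effectively never hit
    grid <- expand.grid(trial = seq_len(config$trials_per_condition),
                        condition = c("up", "down", "control"),
                        subject = seq_len(config$n_subjects),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("subject", "condition", "trial")]
    grid$subject_mean_speed <- subj_speed[grid$subject]
    grid$trial_speed <- stats::rnorm(nrow(grid), grid$subject_mean_speed,
                                     config$cv_speed_between_trials *
                                       grid$subject_mean_speed)
    grid$step_height <- config$step_height *
      (grid$condition == "up") - config$step_height * (grid$condition == "down")
    grid$trial_seed <- config$rng_seed * 10000L + seq_len(nrow(grid))
    grid
  })
}

#' Model-predicted reference compensation pattern
#'
#' Solves the minimum-work Up-step compensation at the nominal walker
#' condition and converts it to a body-speed fluctuation pattern in m/s.
#' The generator treats this pattern as the true response at the reference
#' condition (curb height `config$step_height`, overall speed
#' `config$mean_speed`); its absolute amplitude is the model's, configurable
#' through `params` rather than fitted to any recording.
#'
#' @param config a [cohort_config()].
#' @param params walker parameters for the reference solve.
#' @param measure `"step"` (the injected per-step truth) or `"stride"` (the
#'   measurement-equivalent; see [body_speed_trajectory()]).
#' @param solution an already-solved optimal `control_solution`, to avoid
#'   re-solving.
#' @return a `speed_trajectory` of the optimal Up-step compensation with
#'   attribute `reference` (list with `b_up` in m and `v_up` in m/s).
#' @export
reference_pattern <- function(config = cohort_config(),
                              params = walker_params(),
                              measure = c("step", "stride"),
                              solution = NULL) {
  measure <- match.arg(measure)
  sol <- if (is.null(solution)) solve_min_work(params) else solution
  traj <- body_speed_trajectory(sol, condition = "up", measure = measure)
  attr(traj, "reference") <- list(b_up = config$step_height,
                                  v_up = config$mean_speed)
  traj
}

#' Generate one synthetic trial with full ground truth
#'
#' Lays out footfalls over the walkway with the curb at its midpoint and
#' injects the scaled compensation pattern into the per-step speeds:
#' `delta_v_i = (b / b_up) * (v_up / v_trial) * delta_v_i^up`, plus i.i.d.
#' noise with c.v. `cv_step_noise`. Step length follows the preferred-step
#' relation at the trial speed and is held fixed within the trial, so the
#' per-step speed, length and duration are mutually consistent exactly.
#'
#' @param trial_speed the trial's overall walking speed, m/s.
#' @param condition `"up"`, `"down"` or `"control"`.
#' @param pattern a [reference_pattern()] (or compatible `speed_trajectory`).
#' @param config a [cohort_config()].
#' @param seed integer seed for the per-step noise.
#' @return a `trial_ground_truth` list: `footfalls` (data frame: `index`,
#'   `foot`, `time_s`, `x_m`, `z_m`), `steps` (data frame: per-step `length`,
#'   `duration`, `speed`, `injected_dv`), `perturbation_step` (index of the
#'   footfall onto the height change), `condition`, `trial_speed`.
#' @export
generate_trial <- function(trial_speed, condition = c("up", "down", "control"),
                           pattern = NULL, config = cohort_config(),
                           seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(pattern)) pattern <- reference_pattern(config)
  ref <- attr(pattern, "reference")
  if (is.null(ref)) ref <- list(b_up = config$step_height,
                                v_up = config$mean_speed)
  step_len <- config$base_step_length *
    (trial_speed / config$mean_speed)^config$step_length_exponent
  n_steps <- floor(config$walkway_length / step_len)
  # odd step count: both feet then cover the same total distance, so the
  # inter-foot detrending reconciles drift rather than a layout artefact
  if (n_steps %% 2 == 0) n_steps <- n_steps - 1L
  if (length(pattern$step_index) > n_steps)
    stop_curbwalk("configuration",
                  "compensation pattern longer than the trial's step count")
  curb_x <- config$walkway_length / 2
  x <- step_len * seq(0, n_steps)           # footfall positions incl. start
  perturb <- which(x >= curb_x)[1] - 1L     # step index landing on the curb
  b_signed <- switch(condition, up = config$step_height,
                     down = -config$step_height, control = 0)
  dv <- numeric(n_steps)
  pat_rows <- perturb + pattern$step_index
  ok <- pat_rows >= 1 & pat_rows <= n_steps
  dv[pat_rows[ok]] <- (b_signed / ref$b_up) * (ref$v_up / trial_speed) *
    fluctuations(pattern)[ok]
  noise <- with_seed(seed,
    stats::rnorm(n_steps, 0, config$cv_step_noise * trial_speed))
  speeds <- trial_speed + dv + noise
  durations <- step_len / speeds
  times <- c(0, cumsum(durations))
  z <- if (b_signed >= 0) ifelse(x >= curb_x, b_signed, 0)
       else ifelse(x >= curb_x, 0, -b_signed)  # Down-step: walk off a platform
  footfalls <- data.frame(index = seq(0, n_steps),
                          foot = rep(c("left", "right"),
                                     length.out = n_steps + 1),
                          time_s = times, x_m = x, z_m = z)
  steps <- data.frame(step = seq_len(n_steps),
                      length = rep(step_len, n_steps),
                      duration = durations,
                      speed = speeds,
                      injected_dv = dv)
  structure(list(footfalls = footfalls, steps = steps,
                 perturbation_step = perturb, condition = condition,
                 trial_speed = trial_speed, step_length = step_len,
                 curb_position = curb_x),
            class = "trial_ground_truth")
}

#' Ground-truth body-speed trajectory of a synthetic trial
#'
#' Expresses a trial's true speeds as a [speed_trajectory()] aligned to the
#' perturbation (step index 0 at the footfall onto the height change),
#' either per step (`measure = "step"`: each step's length over its
#' duration) or in the stride-based convention of the inertial measurement
#' (`measure = "stride"`: the two steps following each midstance, assigned
#' to that midstance). The stride measure is what [reconstruct_trial()]
#' estimates; use it as the oracle when validating the pipeline.
#'
#' @param trial a [generate_trial()] result.
#' @param measure `"step"` or `"stride"`.
#' @param window_m central window retained, m (NULL keeps everything).
#' @return a [speed_trajectory()].
#' @export
true_body_speed <- function(trial, measure = c("step", "stride"),
                            window_m = 8.5) {
  measure <- match.arg(measure)
  st <- trial$steps
  tmid <- cumsum(st$duration)
  p <- trial$perturbation_step
  if (measure == "step") {
    idx <- st$step
    speed <- st$speed
    times <- tmid - tmid[p]
    pos <- st$length * st$step
  } else {
    idx <- seq_len(nrow(st) - 2)
    speed <- (st$length[idx + 1] + st$length[idx + 2]) /
      (st$duration[idx + 1] + st$duration[idx + 2])
    times <- tmid[idx] - tmid[p]
    pos <- st$length[idx] * idx
  }
  if (!is.null(window_m)) {
    keep <- abs(pos - st$length[1] * p) <= window_m / 2
    idx <- idx[keep]; speed <- speed[keep]; times <- times[keep]
  }
  speed_trajectory(step_index = idx - p, time_s = times, speed_mps = speed,
                   condition = trial$condition)
}

# quintic smoothstep: zero velocity and acceleration at both ends
smoothstep5 <- function(s) s^3 * (10 - 15 * s + 6 * s^2)

#' Synthesize continuous foot traces for a trial
#'
#' Builds each foot's continuous forward position as smooth swing arcs
#' between stationary dwells centred on its footfalls (the brief rest of the
#' foot in mid-stance that zero-velocity correction relies on), then
#' corrupts the forward position with the double integral of white
#' accelerometer noise (`drift_rms`), emulating inertial integration drift.
#'
#' @param trial a [generate_trial()] result.
#' @param config a [cohort_config()].
#' @param seed integer seed for the drift noise.
#' @return list with elements `left` and `right`, each a `foot_trace` data
#'   frame (`time_s`, `x_m`, `z_m`) with attributes `foot`, `sample_rate`,
#'   and `true_dwell_times`.
#' @export
synthesize_foot_traces <- function(trial, config = cohort_config(),
                                   seed = 1L) {
  stopifnot(inherits(trial, "trial_ground_truth"))
  if (config$sample_rate < 20)
    stop_curbwalk("configuration", "sample_rate below 20 Hz cannot represent swing")
  fs <- config$sample_rate
  d2 <- config$dwell_duration / 2
  tg <- seq(min(trial$footfalls$time_s) - 0.5,
            max(trial$footfalls$time_s) + 0.5, by = 1 / fs)
  one_foot <- function(foot, drift_seed) {
    ff <- trial$footfalls[trial$footfalls$foot == foot, ]
    x <- numeric(length(tg)); z <- numeric(length(tg))
    x[] <- ff$x_m[1]; z[] <- ff$z_m[1]
    for (j in seq_len(nrow(ff))) {
      in_dwell <- tg >= ff$time_s[j] - d2 & tg <= ff$time_s[j] + d2
      x[in_dwell] <- ff$x_m[j]; z[in_dwell] <- ff$z_m[j]
      if (j < nrow(ff)) {
        t0 <- ff$time_s[j] + d2; t1 <- ff$time_s[j + 1] - d2
        sw <- tg > t0 & tg < t1
        s <- (tg[sw] - t0) / (t1 - t0)
        x[sw] <- ff$x_m[j] + (ff$x_m[j + 1] - ff$x_m[j]) * smoothstep5(s)
        z[sw] <- ff$z_m[j] + (ff$z_m[j + 1] - ff$z_m[j]) * s +
          config$swing_peak_height * sin(pi * s)
      }
    }
    tail_idx <- tg > ff$time_s[nrow(ff)] + d2
    x[tail_idx] <- ff$x_m[nrow(ff)]; z[tail_idx] <- ff$z_m[nrow(ff)]
    if (config$drift_rms > 0) {
      dt <- 1 / fs
      acc_err <- with_seed(drift_seed,
                           stats::rnorm(length(tg), 0, config$drift_rms))
      x <- x + cumsum(cumsum(acc_err) * dt) * dt
    }
    structure(data.frame(time_s = tg, x_m = x, z_m = z),
              class = c("foot_trace", "data.frame"),
              foot = foot, sample_rate = fs,
              true_dwell_times = ff$time_s)
  }
  list(left = one_foot("left", seed * 2L),
       right = one_foot("right", seed * 2L + 1L))
}
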