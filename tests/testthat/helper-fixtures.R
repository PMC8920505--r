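# Heavy fixtures computed once per session and shared across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

nominal_params <- function() walker_params()

# optimal Up-step solution at nominal conditions
fx_opt_up <- function() fixture("opt_up", solve_min_work(walker_params()))
fx_opt_down <- function() fixture("opt_down",
  solve_min_work(walker_params(), terrain_profile(step_height = -0.075)))

# small, quick cohort configurations
quiet_config <- function(...) cohort_config(n_subjects = 3,
                                            trials_per_condition = 2, ...)

# per-step reference pattern reused by generator/reconstruction/stats tests
fx_pattern <- function() fixture("pattern",
  reference_pattern(cohort_config(), solution = fx_opt_up()))
fx_pattern_stride <- function() fixture("pattern_stride",
  reference_pattern(cohort_config(), measure = "stride",
                    solution = fx_opt_up()))

# a synthetic trajectory with a given fluctuation series laid on top of a
# constant speed (index centred on 0)
toy_trajectory <- function(dv, speed = 1.4, condition = "up") {
  n <- length(dv)
  half <- (n - 1) / 2
  speed_trajectory(step_index = seq(-half, half),
                   time_s = seq(-half, half) * 0.52,
                   speed_mps = speed + dv, condition = condition)
}
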