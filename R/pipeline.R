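#' Write a control solution to JSON / CSV
#'
#' @param solution a `control_solution`.
#' @param path output file; `.json` stores the full solution with metadata,
#'   `.csv` the discrete speed trajectory (columns `step_index`, `time_s`,
#'   `body_speed_mps`, `midstance_speed_mps`, `pushoff_work_MgL`).
#' @return the path, invisibly.
#' @export
write_solution <- function(solution, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    payload <- list(strategy = strategy(solution),
                    total_work_MgL = total_work(solution),
                    total_time = total_time(solution),
                    time_residual = time_residual(solution),
                    params = unclass(attr(solution, "params")),
                    terrain = as.numeric(attr(solution, "terrain")),
                    steps = as.data.frame(solution))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    traj <- body_speed_trajectory(solution)
    utils::write.csv(data.frame(step_index = traj$step_index,
                                time_s = traj$time_s,
                                body_speed_mps = traj$speed_mps,
                                midstance_speed_mps = traj$midstance_speed_mps,
                                pushoff_work_MgL = solution$pushoff_work),
                     path, row.names = FALSE)
  } else stop("unsupported solution format: .", ext, call. = FALSE)
  invisible(path)
}

#' Simulate a cohort and write per-trial traces
#'
#' Generates the full synthetic cohort (ground truth and continuous foot
#' traces) and, optionally, writes each trial's traces as CSV
#' (`time_s, x_m, z_m` per foot), a ground-truth JSON, and a cohort
#' manifest CSV.
#'
#' @param config a [cohort_config()].
#' @param out_dir directory for the CSV/JSON outputs (NULL keeps everything
#'   in memory).
#' @param pattern injected reference pattern; computed from the nominal
#'   walker when NULL.
#' @return invisibly, a list with `manifest` (the [draw_cohort()] frame)
#'   and `trials` (list of `list(truth, traces)`).
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL,
                            pattern = NULL) {
  if (is.null(pattern)) pattern <- reference_pattern(config)
  manifest <- draw_cohort(config)
  trials <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    truth <- generate_trial(row$trial_speed, row$condition, pattern,
                            config, seed = row$trial_seed)
    traces <- synthesize_foot_traces(truth, config, seed = row$trial_seed)
    trials[[r]] <- list(truth = truth, traces = traces)
    if (!is.null(out_dir)) {
      stem <- sprintf("s%02d_%s_t%02d", row$subject, row$condition, row$trial)
      for (ft in c("left", "right"))
        utils::write.csv(traces[[ft]],
                         file.path(out_dir, paste0(stem, "_", ft, ".csv")),
                         row.names = FALSE)
      jsonlite::write_json(
        list(condition = truth$condition, trial_speed = truth$trial_speed,
             perturbation_step = truth$perturbation_step,
             perturbation_time = truth$footfalls$time_s[truth$perturbation_step + 1],
             steps = truth$steps, footfalls = truth$footfalls),
        file.path(out_dir, paste0(stem, "_truth.json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  invisible(list(manifest = manifest, trials = trials))
}

# reconstruct every trial of a simulated cohort -> list of speed_trajectory
process_cohort <- function(sim, window_m = 8.5) {
  lapply(sim$trials, function(tr) {
    pt <- tr$truth$footfalls$time_s[tr$truth$perturbation_step + 1]
    reconstruct_trial(tr$traces, pt, window_m = window_m,
                      condition = tr$truth$condition)
  })
}

#' Run the full prediction / simulation / reconstruction / analysis pipeline
#'
#' Executes the four stages end to end: (1) solve the model strategies for
#' Up- and Down-steps; (2) generate the synthetic cohort and its foot
#' traces; (3) reconstruct per-step body-speed sequences and per-subject
#' condition averages; (4) run the pattern-correlation and scaling
#' analyses. Writes a JSON report carrying the seed and a parameter hash,
#' plus solution and summary files, into `out_dir`.
#'
#' @param params a [walker_params()].
#' @param config a [cohort_config()]; its `rng_seed` is overridden by
#'   `seed`.
#' @param out_dir output directory (created if missing; NULL skips file
#'   output).
#' @param seed integer seed governing all randomness.
#' @param strategies model strategies to solve.
#' @return (invisibly) a list with `solutions`, `cohort` manifest,
#'   `trajectories`, `subject_averages`, `analysis`, and `report`.
#' @export
run_pipeline <- function(params = walker_params(), config = cohort_config(),
                         out_dir = NULL, seed = 1L,
                         strategies = c("optimal", "none", "reactive",
                                        "tight")) {
  config$rng_seed <- as.integer(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ## 1. predict
  solvers <- list(optimal = solve_min_work, none = simulate_no_compensation,
                  reactive = solve_reactive, tight = solve_tight_regulation)
  unknown <- setdiff(strategies, names(solvers))
  if (length(unknown))
    stop("unknown strategy: ", paste(unknown, collapse = ", "), call. = FALSE)
  up_terrain <- terrain_profile(step_height = params$step_height)
  dn_terrain <- terrain_profile(step_height = -params$step_height)
  solutions <- lapply(solvers[strategies], function(f) f(params, up_terrain))
  solutions$optimal_down <- solve_min_work(params, dn_terrain)
  ng <- nominal_gait(params)
  pers <- persistence_steps(params)

  ## 2. simulate
  sol_up <- if ("optimal" %in% strategies) solutions$optimal
            else solve_min_work(params, up_terrain)
  pattern <- reference_pattern(config, params, solution = sol_up)
  pattern_stride <- reference_pattern(config, params, measure = "stride",
                                      solution = sol_up)
  sim <- simulate_cohort(config, out_dir = NULL, pattern = pattern)

  ## 3. process
  trajs <- process_cohort(sim)
  man <- sim$manifest
  subj_avg <- lapply(c(up = "up", down = "down", control = "control"),
    function(cc) {
      lapply(split(which(man$condition == cc), man$subject[man$condition == cc]),
             function(ii) average_condition(trajs[ii]))
    })

  ## 4. analyze
  grand_up <- average_condition(subj_avg$up)
  corr_up <- pattern_correlation(subj_avg$up, grand_up)
  corr_model <- pattern_correlation(subj_avg$up, pattern_stride)
  height_fit <- fit_height_scaling(trajs, man$step_height, grand_up,
                                   b_up = config$step_height)
  up_sel <- man$condition == "up"
  speed_fit <- fit_speed_scaling(trajs[up_sel], man$trial_speed[up_sel],
                                 grand_up)
  variab <- variability_summary(trajs, man$subject, man$condition)
  analysis <- list(correlation_vs_average = corr_up,
                   correlation_vs_model = corr_model,
                   height_scaling = height_fit,
                   speed_scaling = speed_fit,
                   variability = variab)

  report <- list(
    seed = as.integer(seed),
    params_hash = params_hash(params, config),
    nominal = list(pushoff_work = ng$pushoff_work, step_time = ng$step_time,
                   bout_work = ng$bout_work),
    strategy_works = lapply(solutions, total_work),
    persistence_steps = pers$steps,
    no_compensation_time_loss_s =
      if ("none" %in% strategies)
        -rev(solutions$none$cumulative_time_gain)[1] * time_scale()
      else NA_real_,
    correlation_vs_average = corr_up$mean_rho,
    correlation_vs_average_p = corr_up$p_value,
    correlation_vs_model = corr_model$mean_rho,
    height_scaling_cb = height_fit$coefficient,
    speed_scaling_cv = speed_fit$coefficient,
    control_within_trial_cv =
      variab$within_trial_cv[variab$condition == "control"])

  if (!is.null(out_dir)) {
    for (nm in names(solutions))
      write_solution(solutions[[nm]], file.path(out_dir, paste0(nm, ".json")))
    utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(variab, file.path(out_dir, "variability.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(solutions = solutions, cohort = man, trajectories = trajs,
                 subject_averages = subj_avg, analysis = analysis,
                 report = report))
}

# stable fingerprint of the run configuration, recorded in every report
params_hash <- function(params, config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(list(unclass(params), unclass(config)),
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
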