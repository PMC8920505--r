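#' Terrain profile for a walking bout
#'
#' Per-step surface height changes `b_i` for a bout of `n_steps` steps
#' indexed `i = -(N-1)/2 ... (N-1)/2`. For the single-curb task exactly one
#' entry (at `i = 0`, the step onto the curb) is nonzero.
#'
#' @param n_steps odd number of steps in the bout (default 15).
#' @param step_height signed height of the single uneven step (length
#'   units; positive for an Up-step). Zero gives level terrain.
#' @param perturbation_index step index carrying the height change
#'   (default 0, the bout midpoint).
#' @return a named numeric vector of class `terrain_profile`; names are the
#'   step indices.
#' @examples
#' terrain_profile(15, 0.075)    # Up-step at i = 0
#' terrain_profile(15, -0.075)   # Down-step
#' @export
terrain_profile <- function(n_steps = 15, step_height = 0.075,
                            perturbation_index = 0) {
  stopifnot(n_steps >= 3, n_steps %% 2 == 1)
  half <- (n_steps - 1) / 2
  idx <- seq(-half, half)
  if (!perturbation_index %in% idx)
    stop("perturbation_index must be one of the bout's step indices",
         call. = FALSE)
  b <- stats::setNames(rep(0, n_steps), idx)
  b[as.character(perturbation_index)] <- step_height
  structure(b, class = "terrain_profile",
            perturbation_index = perturbation_index)
}

## ---- internal single-shooting machinery --------------------------------
##
## The bout is parameterized by its midstance speeds rather than its
## push-offs: given consecutive midstance speeds and the terrain, the
## push-off that joins them is unique and closed-form, and the two equality
## constraints of the optimal-control problem (terminal speed; total time)
## reduce to one fixed endpoint and one scalar constraint handled by a
## Lagrange multiplier. This keeps the solve smooth, deterministic, and
## free of a general NLP solver.

bout_geometry <- function(params, terrain) {
  lapply(as.numeric(terrain), function(b)
    transition_geometry(inter_foot_chord(params), b, params$leg_length))
}

# work and time of one step given entry/exit midstance speeds
step_work_time <- function(v_in, v_out, geo, params, penalty = 1e3) {
  g <- params$gravity; L <- params$leg_length
  Phi <- geo$inter_leg_angle
  v_pre <- sqrt(v_in^2 + 2 * g * L * (1 - cos(geo$phi1)))
  v_post <- sqrt(v_out^2 + 2 * g * L * (1 - cos(geo$phi2)))
  P <- (v_post - v_pre * cos(Phi)) / sin(Phi)
  u <- 0.5 * params$body_mass * max(P, 0)^2 +
    if (P < 0) penalty * P^2 else 0     # pushing cannot pull
  tau <- pendulum_half_time(v_in, geo$phi1, g, L) +
    pendulum_half_time(v_out, geo$phi2, g, L)
  c(work = u, time = tau, impulse = P)
}

bout_work_time <- function(speeds, geos, params) {
  # speeds: length N + 1 (entry midstance, then the N per-step midstances)
  if (any(!is.finite(speeds)) || any(speeds < 0.02))
    return(c(1e6, 1e6))
  W <- 0; Tt <- 0
  for (i in seq_along(geos)) {
    wt <- step_work_time(speeds[i], speeds[i + 1], geos[[i]], params)
    W <- W + wt[["work"]]; Tt <- Tt + wt[["time"]]
  }
  c(W, Tt)
}

# Minimize total work over the free midstance speeds subject to the total
# bout time hitting time_target: BFGS on W + lambda * (T - T0), with a
# secant iteration driving the scalar multiplier to feasibility.
solve_speed_program <- function(params, terrain, free, fixed_speeds,
                                time_target, time_tol = 1e-10) {
  geos <- bout_geometry(params, terrain)
  start <- fixed_speeds[free]   # cold start at nominal: empirically unimodal
  inner <- function(lambda) {
    f <- function(vf) {
      z <- fixed_speeds; z[free] <- vf
      wt <- bout_work_time(z, geos, params)
      if (!is.finite(wt[1]) || wt[1] >= 1e6) return(1e6)
      wt[1] + lambda * (wt[2] - time_target)
    }
    op <- stats::optim(start, f, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-16))
    op <- stats::optim(op$par, f, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-16))
    z <- fixed_speeds; z[free] <- op$par
    list(speeds = z, par = op$par, wt = bout_work_time(z, geos, params))
  }
  l1 <- 0
  r1 <- inner(l1); g1 <- r1$wt[2] - time_target
  l2 <- 0.05
  r2 <- inner(l2); g2 <- r2$wt[2] - time_target
  for (k in seq_len(80)) {
    if (!is.finite(g2) || abs(g2) < time_tol) break
    if (g2 == g1) break
    l3 <- l2 - g2 * (l2 - l1) / (g2 - g1)
    l1 <- l2; g1 <- g2; l2 <- l3
    r2 <- inner(l2); g2 <- r2$wt[2] - time_target
  }
  if (!is.finite(g2) || abs(g2) > 1e-6)
    stop_curbwalk("optimization",
      sprintf("constrained solve did not converge: time residual %.3e", g2))
  list(speeds = r2$speeds, total_work = r2$wt[1], total_time = r2$wt[2],
       time_residual = g2, multiplier = l2, geos = geos)
}

# assemble a control_solution from a midstance-speed sequence
build_solution <- function(speeds, geos, params, terrain, strategy,
                           time_residual = NA_real_, multiplier = NA_real_) {
  N <- length(geos)
  tau_nom <- nominal_gait(params)$step_time
  u <- tau <- loss <- adv <- imp <- numeric(N)
  for (i in seq_len(N)) {
    wt <- step_work_time(speeds[i], speeds[i + 1], geos[[i]], params,
                         penalty = 0)
    u[i] <- wt[["work"]]; tau[i] <- wt[["time"]]; imp[i] <- wt[["impulse"]]
    Phi <- geos[[i]]$inter_leg_angle
    v_pre <- sqrt(speeds[i]^2 +
                    2 * params$gravity * params$leg_length * (1 - cos(geos[[i]]$phi1)))
    along <- v_pre * sin(Phi) - max(imp[i], 0) * cos(Phi)
    loss[i] <- if (along > 0) 0.5 * params$body_mass * along^2 else 0
    adv[i] <- geos[[i]]$advance
  }
  half <- (N - 1) / 2
  sol <- data.frame(step_index = seq(-half, half),
                    pushoff_work = u,
                    midstance_speed = speeds[-1],
                    step_time = tau,
                    collision_loss = loss,
                    advance = adv,
                    cumulative_time_gain = cumsum(tau_nom - tau))
  structure(sol, class = c("control_solution", "data.frame"),
            strategy = strategy,
            total_work = sum(u),
            total_time = sum(tau),
            time_residual = time_residual,
            multiplier = multiplier,
            entry_speed = speeds[1],
            params = params, terrain = terrain)
}

#' Control strategies for negotiating a single uneven step
#'
#' All four strategies walk the same `n_steps`-step bout whose terrain holds
#' a single height change at step `i = 0`, starting from steady nominal gait
#' (entry midstance speed `V`).
#'
#' * `solve_min_work()` — the optimal strategy: minimizes total push-off
#'   work subject to (i) ending the bout at nominal speed and (ii) matching
#'   the total time of nominal level walking over the same number of steps.
#'   The solution is the anticipatory triphasic pattern: speed up before the
#'   Up-step, lose momentum atop it, regain speed after.
#' * `solve_reactive()` — nonanticipatory: push-offs are held at nominal
#'   through the push-off onto the uneven step (`i <= 0`, before the
#'   perturbation has affected the body); the remaining steps are optimized
#'   under the same time and terminal-speed constraints.
#' * `solve_tight_regulation()` — each step's push-off is chosen (by root
#'   finding, sequentially through the terrain) so that every step time
#'   equals the nominal step time.
#' * `simulate_no_compensation()` — nominal push-off on every step, no
#'   constraints; the walker recovers speed passively but accumulates a time
#'   loss on an Up-step.
#'
#' @param params a [walker_params()] object.
#' @param terrain a [terrain_profile()]; defaults to the params' step height
#'   at the midpoint of a 15-step bout.
#' @param time_tol convergence tolerance on the total-time constraint.
#' @return A `control_solution`: a data frame with one row per step
#'   (`step_index`, `pushoff_work`, `midstance_speed`, `step_time`,
#'   `collision_loss`, `advance`, `cumulative_time_gain`) and attributes
#'   `strategy`, `total_work`, `total_time`, `time_residual` (see
#'   [total_work()]).
#' @examples
#' \donttest{
#' p <- walker_params()
#' opt <- solve_min_work(p)
#' total_work(opt)          # about 0.495 MgL
#' }
#' @export
solve_min_work <- function(params = walker_params(),
                           terrain = terrain_profile(step_height = params$step_height),
                           time_tol = 1e-10) {
  N <- length(terrain)
  ng <- nominal_gait(params, n_steps = N)
  V <- params$midstance_speed
  fixed <- rep(V, N + 1)                   # entry and terminal pinned at V
  free <- seq(2, N)                        # interior midstance speeds
  r <- solve_speed_program(params, terrain, free, fixed,
                           time_target = N * ng$step_time, time_tol = time_tol)
  build_solution(r$speeds, r$geos, params, terrain, "optimal",
                 r$time_residual, r$multiplier)
}

#' @rdname solve_min_work
#' @export
solve_reactive <- function(params = walker_params(),
                           terrain = terrain_profile(step_height = params$step_height),
                           time_tol = 1e-10) {
  N <- length(terrain)
  ng <- nominal_gait(params, n_steps = N)
  V <- params$midstance_speed
  pidx <- which(as.integer(names(terrain)) == attr(terrain, "perturbation_index"))
  # nominal push-offs through the step onto the perturbation
  v <- V; pre <- V
  for (i in seq_len(pidx)) {
    s <- step_map(v, ng$pushoff_work, terrain[i], params)
    v <- s$v_next; pre <- c(pre, v)
  }
  fixed <- rep(V, N + 1)
  fixed[seq_along(pre)] <- pre
  free <- seq(pidx + 2, N)                 # speeds after the perturbed step
  r <- solve_speed_program(params, terrain, free, fixed,
                           time_target = N * ng$step_time, time_tol = time_tol)
  build_solution(r$speeds, r$geos, params, terrain, "reactive",
                 r$time_residual, r$multiplier)
}

#' @rdname solve_min_work
#' @export
solve_tight_regulation <- function(params = walker_params(),
                                   terrain = terrain_profile(step_height = params$step_height)) {
  N <- length(terrain)
  ng <- nominal_gait(params, n_steps = N)
  geos <- bout_geometry(params, terrain)
  speeds <- numeric(N + 1)
  speeds[1] <- params$midstance_speed
  for (i in seq_len(N)) {
    fr <- function(vn) step_work_time(speeds[i], vn, geos[[i]], params)[["time"]] -
      ng$step_time
    root <- tryCatch(
      stats::uniroot(fr, c(0.05, 3 * params$midstance_speed), tol = 1e-14),
      error = function(e) stop_curbwalk("regulation",
        sprintf("no admissible push-off keeps step %d at the nominal step time", i)))
    speeds[i + 1] <- root$root
  }
  build_solution(speeds, geos, params, terrain, "tight_time")
}

#' @rdname solve_min_work
#' @export
simulate_no_compensation <- function(params = walker_params(),
                                     terrain = terrain_profile(step_height = params$step_height)) {
  N <- length(terrain)
  ng <- nominal_gait(params, n_steps = N)
  geos <- bout_geometry(params, terrain)
  speeds <- numeric(N + 1)
  speeds[1] <- params$midstance_speed
  for (i in seq_len(N)) {
    s <- step_map(speeds[i], ng$pushoff_work, terrain[i], params)
    speeds[i + 1] <- s$v_next
  }
  build_solution(speeds, geos, params, terrain, "none")
}

#' Accessors for control solutions
#'
#' @param solution a `control_solution` from [solve_min_work()] and friends.
#' @return `total_work()` the bout push-off work (MgL units);
#'   `total_time()` the bout duration; `time_residual()` the constraint
#'   residual (NA for unconstrained strategies); `strategy()` the label.
#' @export
total_work <- function(solution) attr(solution, "total_work")

#' @rdname total_work
#' @export
total_time <- function(solution) attr(solution, "total_time")

#' @rdname total_work
#' @export
time_residual <- function(solution) attr(solution, "time_residual")

#' @rdname total_work
#' @export
strategy <- function(solution) attr(solution, "strategy")

#' @export
print.control_solution <- function(x, ...) {
  cat(sprintf("<control_solution: %s strategy, %d steps>\n",
              attr(x, "strategy"), nrow(x)))
  cat(sprintf("  total push-off work %.4f MgL over time %.4f (residual %s)\n",
              attr(x, "total_work"), attr(x, "total_time"),
              format(attr(x, "time_residual"), digits = 3)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Convert a control solution to a per-step body-speed trajectory
#'
#' The experimental measure of walking speed is each step's horizontal
#' advance divided by its duration, assigned to the midstance instant.
#' This converts a model solution to that measure, in dimensional units
#' (speed unit `sqrt(gL)`, time unit `sqrt(L/g)`), with `t = 0` at the
#' midstance after landing on the uneven step.
#'
#' @param solution a `control_solution`.
#' @param gravity_mps2,leg_length_m dimensional scales (human defaults).
#' @param condition label stored on the trajectory (defaults to the
#'   solution's strategy).
#' @param measure `"step"` (default): each step's advance over its
#'   duration. `"stride"`: the equivalent of the inertial measurement —
#'   the advance and duration of the two steps following each midstance,
#'   i.e. one stride of the foot planted there, assigned to that midstance
#'   (the last two indices are dropped). Use `"stride"` when comparing
#'   against reconstructed sequences.
#' @return A `speed_trajectory`: data frame with `step_index`, `time_s`,
#'   `speed_mps` and (for `measure = "step"`) `midstance_speed_mps`, plus
#'   attributes `condition` and `mean_speed`.
#' @export
body_speed_trajectory <- function(solution, gravity_mps2 = 9.81,
                                  leg_length_m = 1,
                                  condition = strategy(solution),
                                  measure = c("step", "stride")) {
  measure <- match.arg(measure)
  vs <- speed_scale(gravity_mps2, leg_length_m)
  ts <- time_scale(gravity_mps2, leg_length_m)
  i0 <- which(solution$step_index == 0)
  tmid <- cumsum(solution$step_time)
  times <- (tmid - tmid[i0]) * ts
  if (measure == "step") {
    speed_trajectory(step_index = solution$step_index,
                     time_s = times,
                     speed_mps = solution$advance / solution$step_time * vs,
                     midstance_speed_mps = solution$midstance_speed * vs,
                     condition = condition)
  } else {
    n <- nrow(solution)
    keep <- seq_len(n - 2)
    stride_speed <- (solution$advance[keep + 1] + solution$advance[keep + 2]) /
      (solution$step_time[keep + 1] + solution$step_time[keep + 2]) * vs
    speed_trajectory(step_index = solution$step_index[keep],
                     time_s = times[keep],
                     speed_mps = stride_speed,
                     condition = condition)
  }
}

#' Self-similarity of optimal compensation patterns
#'
#' Solves the minimum-work compensation for each parameter set and compares
#' the normalized discrete speed-fluctuation patterns: a single basic
#' pattern, rescaled in amplitude, describes different walking conditions.
#' Amplitudes scale inversely with speed (a fixed curb perturbs the larger
#' kinetic energy of faster walking relatively less).
#'
#' @param params_list list of two or more [walker_params()] objects.
#' @param terrain common [terrain_profile()].
#' @return list with `correlations` (pairwise Pearson matrix of the
#'   mean-removed patterns), `amplitudes` (SD of each fluctuation pattern),
#'   and `solutions`.
#' @export
self_similarity_report <- function(params_list,
                                   terrain = terrain_profile()) {
  stopifnot(length(params_list) >= 2)
  sols <- lapply(params_list, solve_min_work, terrain = terrain)
  pats <- lapply(sols, function(s) s$midstance_speed - mean(s$midstance_speed))
  M <- sapply(pats, identity)
  corr <- stats::cor(M)
  dimnames(corr) <- list(names(params_list), names(params_list))
  list(correlations = corr,
       amplitudes = apply(M, 2, stats::sd),
       solutions = sols)
}
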