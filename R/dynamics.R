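## Stance-phase pendulum mechanics and the impulsive step-to-step transition.
## Everything here is deterministic point-mass mechanics; the only numerics
## are a fixed-order Gauss-Legendre quadrature for pendulum arc times.

# 40-node Gauss-Legendre rule on [0, 1], cached at first use. The pendulum
# time integrand is analytic for v_mid > 0, so the fixed rule converges far
# below the 1e-10 tolerance the solvers assume (checked against
# stats::integrate and an ODE oracle in the tests).
.curbwalk <- new.env(parent = emptyenv())

gl_rule <- function() {
  if (is.null(.curbwalk$gl)) {
    g <- pracma::gaussLegendre(40, 0, 1)
    .curbwalk$gl <- list(x = g$x, w = g$w)
  }
  .curbwalk$gl
}

# Time for the pendulum to swing between the vertical and angle phi, given
# midstance speed v_mid: dt = d(theta) / thetadot with
# thetadot^2 = v_mid^2/L^2 + (2 g / L)(1 - cos theta).
pendulum_half_time <- function(v_mid, phi, gravity = 1, leg_length = 1) {
  if (phi <= 0) return(0)
  gl <- gl_rule()
  th <- phi * gl$x
  om <- sqrt(v_mid^2 / leg_length^2 +
               (2 * gravity / leg_length) * (1 - cos(th)))
  phi * sum(gl$w / om)
}

#' Double-support geometry of an uneven step
#'
#' At the step-to-step transition the pelvis sits at the intersection of two
#' circles of radius `L`: one about the trailing foot (surface height 0) and
#' one about the leading foot (surface height `b`), the feet separated by a
#' chord of length `S_chord`. Returns the trailing-leg angle `phi1` (forward
#' of vertical) and leading-leg angle `phi2` (behind vertical); their sum is
#' the inter-leg angle, which depends only on the chord, so it is unchanged
#' by terrain height.
#'
#' @param chord distance between the two footfall points (length units).
#' @param step_height signed surface height change `b` at the leading foot.
#' @param leg_length leg length `L`.
#' @return list with `phi1`, `phi2`, `inter_leg_angle` (= `phi1 + phi2`), and
#'   `advance` (horizontal distance between the feet).
#' @examples
#' transition_geometry(0.79, 0)        # level: phi1 = phi2 = asin(0.395)
#' transition_geometry(0.79, 0.075)    # Up-step: phi1 > phi2
#' @export
transition_geometry <- function(chord, step_height, leg_length = 1) {
  if (abs(step_height) >= chord)
    stop_curbwalk("terrain", "|step_height| must be smaller than the chord")
  if (chord <= 0 || chord >= 2 * leg_length)
    stop_curbwalk("geometry", "chord must lie in (0, 2L): legs cannot span it")
  adv <- sqrt(chord^2 - step_height^2)
  h <- sqrt(leg_length^2 - (chord / 2)^2)   # pelvis offset from the mid-chord
  px <- adv / 2 - h * step_height / chord
  py <- step_height / 2 + h * adv / chord
  phi1 <- atan2(px, py)
  phi2 <- atan2(adv - px, py - step_height)
  list(phi1 = phi1, phi2 = phi2, inter_leg_angle = phi1 + phi2, advance = adv)
}

#' Stance-phase half arcs
#'
#' The single stance phase is an energy-conserving inverted pendulum.
#' `stance_descend()` takes the walker from midstance (leg vertical, speed
#' `v_mid`) down the arc to leg angle `phi_exit`, returning the exit speed
#' and the elapsed time. `stance_ascend()` is the rising half: from leg angle
#' `phi_entry` just after contact (speed `v_entry`) up to the next midstance.
#' If the entry speed cannot carry the pelvis over the top, the walker fails
#' to vault and an error of class `curbwalk_vault_error` is thrown.
#'
#' @param v_mid,v_entry speed at midstance / just after the transition.
#' @param phi_exit,phi_entry stance-leg angle from vertical (rad, in
#'   `[0, pi/2)`).
#' @param params a [walker_params()] object (supplies `g` and `L`).
#' @return list with the exit/midstance speed and the half-arc time.
#' @export
stance_descend <- function(v_mid, phi_exit, params = walker_params()) {
  stopifnot(v_mid > 0, phi_exit >= 0, phi_exit < pi / 2)
  g <- params$gravity; L <- params$leg_length
  v_exit <- sqrt(v_mid^2 + 2 * g * L * (1 - cos(phi_exit)))
  list(v_exit = v_exit,
       half_time = pendulum_half_time(v_mid, phi_exit, g, L))
}

#' @rdname stance_descend
#' @export
stance_ascend <- function(v_entry, phi_entry, params = walker_params()) {
  stopifnot(v_entry > 0, phi_entry >= 0, phi_entry < pi / 2)
  g <- params$gravity; L <- params$leg_length
  vm2 <- v_entry^2 - 2 * g * L * (1 - cos(phi_entry))
  if (vm2 <= 0)
    stop_curbwalk("vault",
      sprintf("failure to vault: entry speed %.4f below the %.4f needed to reach midstance",
              v_entry, sqrt(2 * g * L * (1 - cos(phi_entry)))))
  v_mid <- sqrt(vm2)
  list(v_mid = v_mid,
       half_time = pendulum_half_time(v_mid, phi_entry, g, L))
}

#' Impulsive push-off and collision
#'
#' The step-to-step transition redirects the centre-of-mass velocity from
#' one pendular arc to the next. The pre-transition velocity (magnitude
#' `v_pre`, perpendicular to the trailing leg) is first augmented by an
#' impulsive push-off of magnitude `impulse` (per unit mass) directed along
#' the trailing leg, then the component directed along the leading leg is
#' removed by a perfectly inelastic collision. With inter-leg angle
#' `Phi = phi1 + phi2`:
#' `v_post = v_pre * cos(Phi) + P * sin(Phi)`;
#' push-off work `u = M P^2 / 2`; collision loss
#' `M (v_pre sin(Phi) - P cos(Phi))^2 / 2` when that component points into
#' the leading leg (a push-off so large that the bracket goes negative
#' cannot be absorbed by a point-foot contact, so the loss is clamped at 0
#' and flagged).
#'
#' @param v_pre pre-transition speed (perpendicular to the trailing leg).
#' @param impulse push-off impulse per unit mass, `>= 0`.
#' @param phi1,phi2 trailing/leading leg angles from [transition_geometry()].
#' @param body_mass pelvis mass `M`.
#' @return list with `v_post`, `pushoff_work`, `collision_loss`, and logical
#'   `loss_clamped`.
#' @export
impulsive_transition <- function(v_pre, impulse, phi1, phi2, body_mass = 1) {
  if (impulse < 0)
    stop_curbwalk("actuation", "push-off impulse cannot be negative (it cannot pull)")
  stopifnot(v_pre > 0)
  Phi <- phi1 + phi2
  v_post <- v_pre * cos(Phi) + impulse * sin(Phi)
  along_lead <- v_pre * sin(Phi) - impulse * cos(Phi)
  clamped <- along_lead < 0
  loss <- if (clamped) 0 else 0.5 * body_mass * along_lead^2
  list(v_post = v_post,
       pushoff_work = 0.5 * body_mass * impulse^2,
       collision_loss = loss,
       loss_clamped = clamped)
}

#' One-step map of the walker
#'
#' Composes a full step: descend the pendular arc from midstance, perform
#' the push-off/collision transition onto terrain raised by `step_height`,
#' and rise to the next midstance. Midstance speeds are the per-step state:
#' `step_map` advances `v_mid` to the next midstance under push-off work `u`.
#'
#' The energy audit holds to solver tolerance:
#' `M/2 (v_next^2 - v_mid^2) = u - collision_loss - M g b`.
#'
#' @param v_mid midstance speed entering the step.
#' @param pushoff_work push-off work `u >= 0` for the transition.
#' @param step_height signed terrain height change at this step's contact.
#' @param params a [walker_params()] object.
#' @return A `step_outcome` list: `v_next`, `step_time`, `pushoff_work`,
#'   `collision_loss`, `advance` (horizontal), `loss_clamped`.
#' @examples
#' p <- walker_params()
#' ng <- nominal_gait(p)
#' step_map(p$midstance_speed, ng$pushoff_work, 0, p)$v_next  # fixed point
#' @export
step_map <- function(v_mid, pushoff_work, step_height, params = walker_params()) {
  if (pushoff_work < 0)
    stop_curbwalk("actuation", "push-off work must be non-negative")
  geo <- transition_geometry(inter_foot_chord(params), step_height,
                             params$leg_length)
  down <- stance_descend(v_mid, geo$phi1, params)
  tr <- impulsive_transition(down$v_exit,
                             sqrt(2 * pushoff_work / params$body_mass),
                             geo$phi1, geo$phi2, params$body_mass)
  up <- stance_ascend(tr$v_post, geo$phi2, params)
  structure(list(v_next = up$v_mid,
                 step_time = down$half_time + up$half_time,
                 pushoff_work = tr$pushoff_work,
                 collision_loss = tr$collision_loss,
                 advance = geo$advance,
                 loss_clamped = tr$loss_clamped),
            class = "step_outcome")
}

#' Nominal steady gait
#'
#' Solves (in closed form) for the push-off that makes the nominal midstance
#' speed `V` a fixed point of the level-ground step map: the transition must
#' leave the speed unchanged, which requires an impulse
#' `P = v_pre * tan(Phi / 2)`. Returns the per-step push-off work, step
#' time, and the work of an `n_steps` bout of steady walking.
#'
#' @param params a [walker_params()] object.
#' @param n_steps bout length used for `bout_work` (default 15).
#' @return list with `pushoff_work` (`u_nom`), `impulse`, `step_time`
#'   (`tau_nom`), `v_pre` (pre-transition speed), and `bout_work`.
#' @export
nominal_gait <- function(params = walker_params(), n_steps = 15) {
  alpha <- leg_splay(params)
  g <- params$gravity; L <- params$leg_length; V <- params$midstance_speed
  v_pre <- sqrt(V^2 + 2 * g * L * (1 - cos(alpha)))
  impulse <- v_pre * tan(alpha)          # Phi/2 = alpha on level ground
  u_nom <- 0.5 * params$body_mass * impulse^2
  tau_nom <- 2 * pendulum_half_time(V, alpha, g, L)
  list(pushoff_work = u_nom, impulse = impulse, step_time = tau_nom,
       v_pre = v_pre, bout_work = n_steps * u_nom, n_steps = n_steps)
}

#' Perturbation persistence of the step map
#'
#' Linearizes the level-ground step map in midstance speed about the nominal
#' fixed point, holding the push-off at nominal. The eigenvalue
#' `lambda` in (0, 1) gives the geometric decay of a speed perturbation; the
#' function returns the number of steps for the perturbation to decay by
#' `decay_fraction`, `log(1 - decay_fraction) / log(lambda)`.
#'
#' @param params a [walker_params()] object.
#' @param decay_fraction fraction of the perturbation to shed (in (0, 1));
#'   0.9 gives the conventional 90%-decay persistence.
#' @param h finite-difference step for the linearization.
#' @return list with `steps`, `eigenvalue`, and `decay_fraction`.
#' @export
persistence_steps <- function(params = walker_params(), decay_fraction = 0.9,
                              h = 1e-6) {
  if (decay_fraction < 0 || decay_fraction >= 1)
    stop("decay_fraction must lie in [0, 1)", call. = FALSE)
  u_nom <- nominal_gait(params)$pushoff_work
  V <- params$midstance_speed
  lam <- (step_map(V + h, u_nom, 0, params)$v_next -
            step_map(V - h, u_nom, 0, params)$v_next) / (2 * h)
  if (lam >= 1 || lam <= 0)
    stop_curbwalk("stability",
      sprintf("step map eigenvalue %.4f outside (0,1): no passive stability here", lam))
  steps <- if (decay_fraction == 0) 0 else log(1 - decay_fraction) / log(lam)
  list(steps = steps, eigenvalue = lam, decay_fraction = decay_fraction)
}

# classed conditions so callers (and tests) can distinguish failure modes
stop_curbwalk <- function(kind, msg) {
  stop(structure(class = c(paste0("curbwalk_", kind, "_error"),
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
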