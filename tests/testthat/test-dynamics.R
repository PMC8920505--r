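test_that("transition geometry matches the independent two-circle oracle", {
  # level ground: symmetry forces sin(phi) = chord / 2L
  g0 <- transition_geometry(0.79, 0, 1)
  expect_equal(g0$phi1, asin(0.395), tolerance = 1e-12)
  expect_equal(g0$phi2, asin(0.395), tolerance = 1e-12)

  # uneven steps: independent oracle solves the circle intersection by
  # root-finding on the trailing-leg angle
  oracle <- function(chord, b, L = 1) {
    ax <- sqrt(chord^2 - b^2)
    t1 <- stats::uniroot(function(t)
      (L * sin(t) - ax)^2 + (L * cos(t) - b)^2 - L^2,
      c(-pi / 4, pi / 2), tol = 1e-15)$root
    px <- L * sin(t1); py <- L * cos(t1)
    c(phi1 = t1, phi2 = atan2(ax - px, py - b))
  }
  for (b in c(0.075, -0.075, 0.03, -0.2)) {
    g <- transition_geometry(0.79, b, 1)
    o <- oracle(0.79, b)
    expect_equal(g$phi1, unname(o["phi1"]), tolerance = 1e-10)
    expect_equal(g$phi2, unname(o["phi2"]), tolerance = 1e-10)
    # pelvis height agrees from both legs; inter-leg angle set by the chord
    expect_equal(cos(g$phi1), b + cos(g$phi2), tolerance = 1e-12)
    expect_equal(g$inter_leg_angle, 2 * asin(0.395), tolerance = 1e-12)
  }
  # raised leading foot pulls the pelvis toward the trailing foot
  gup <- transition_geometry(0.79, 0.075, 1)
  expect_lt(gup$phi1, gup$phi2)
  expect_equal(gup$phi1, 0.3109879502, tolerance = 1e-9)
  expect_equal(gup$phi2, 0.5011477519, tolerance = 1e-9)

  expect_error(transition_geometry(0.79, 0.80, 1), class = "curbwalk_terrain_error")
  expect_error(transition_geometry(2.2, 0, 1), class = "curbwalk_geometry_error")
})

test_that("stance arcs conserve energy and their times match an ODE oracle", {
  p <- walker_params()
  d <- stance_descend(0.44, 0.4063, p)
  expect_equal(d$v_exit, sqrt(0.44^2 + 2 * (1 - cos(0.4063))),
               tolerance = 1e-12)
  expect_equal(d$v_exit, 0.5970102239, tolerance = 1e-9)

  # degenerate arc
  d0 <- stance_descend(0.44, 1e-12, p)
  expect_equal(d0$v_exit, 0.44, tolerance = 1e-10)
  expect_lt(d0$half_time, 1e-10)
  expect_equal(stance_ascend(0.6, 0, p)$v_mid, 0.6)

  # mechanical energy constant along the arc (descend then ascend closure)
  a <- stance_ascend(d$v_exit, 0.4063, p)
  expect_equal(a$v_mid, 0.44, tolerance = 1e-12)
  expect_equal(a$half_time, d$half_time, tolerance = 1e-12)

  # brute-force time oracle: integrate theta'' = (g/L) sin(theta) with
  # deSolve and find the crossing of the exit angle by root-finding
  skip_if_not_installed("deSolve")
  ode_time <- function(v_mid, phi) {
    out <- deSolve::lsodar(
      y = c(th = 0, om = v_mid),
      times = seq(0, 5, by = 0.001),
      func = function(t, y, parms) list(c(y["om"], sin(y["th"]))),
      rootfunc = function(t, y, parms) y["th"] - phi,
      rtol = 1e-12, atol = 1e-12)
    unname(out[nrow(out), "time"])
  }
  for (cs in list(c(0.44, 0.4063), c(0.30, 0.25), c(0.60, 0.50))) {
    got <- stance_descend(cs[1], cs[2], p)$half_time
    expect_equal(got, ode_time(cs[1], cs[2]), tolerance = 1e-6)
  }

  # failure to vault just below the energy barrier
  vbar <- sqrt(2 * (1 - cos(0.4063)))
  expect_error(stance_ascend(vbar * 0.999, 0.4063, p),
               class = "curbwalk_vault_error")
})

test_that("impulsive transition agrees with explicit 2-D vector mechanics", {
  # no transition at all
  tr0 <- impulsive_transition(0.6, 0, 0, 0)
  expect_equal(tr0$v_post, 0.6)
  expect_equal(tr0$pushoff_work, 0)
  expect_equal(tr0$collision_loss, 0)

  # steady-gait trig identity: P = v tan(Phi/2) leaves speed unchanged
  for (Phi in c(0.4, 0.8121, 1.0)) {
    tr <- impulsive_transition(0.6, 0.6 * tan(Phi / 2), Phi / 2, Phi / 2)
    expect_equal(tr$v_post, 0.6, tolerance = 1e-12)
  }

  # vector oracle: rotate explicit velocity/impulse vectors
  vec_oracle <- function(v, P, phi1, phi2) {
    vv <- v * c(cos(phi1), -sin(phi1)) + P * c(sin(phi1), cos(phi1))
    e2 <- c(-sin(phi2), cos(phi2))            # leading leg, foot to pelvis
    along <- sum(vv * e2)
    if (along < 0) {                          # compressive: absorbed
      vv <- vv - along * e2
      loss <- 0.5 * along^2
    } else loss <- 0
    c(v_post = sqrt(sum(vv^2)), loss = loss)
  }
  set.seed(42)
  for (k in 1:25) {
    v <- runif(1, 0.3, 0.8)
    phi1 <- runif(1, 0.1, 0.6); phi2 <- runif(1, 0.1, 0.6)
    # stay in the physical regime where the leading-leg collision is
    # compressive (the clamped branch is exercised separately below)
    P <- runif(1, 0, 0.9 * v * tan(phi1 + phi2))
    got <- impulsive_transition(v, P, phi1, phi2)
    o <- vec_oracle(v, P, phi1, phi2)
    expect_equal(got$v_post, unname(o["v_post"]), tolerance = 1e-10)
    expect_equal(got$collision_loss, unname(o["loss"]), tolerance = 1e-10)
    expect_gte(got$pushoff_work, 0)
    expect_gte(got$collision_loss, 0)
  }

  # a push-off so large the leading leg would be pulled: loss clamped
  big <- impulsive_transition(0.3, 2, 0.4, 0.4)
  expect_true(big$loss_clamped)
  expect_equal(big$collision_loss, 0)

  expect_error(impulsive_transition(0.6, -0.1, 0.4, 0.4),
               class = "curbwalk_actuation_error")
})

test_that("step map has the nominal fixed point and closes its energy audit", {
  p <- walker_params()
  ng <- nominal_gait(p)
  s <- step_map(p$midstance_speed, ng$pushoff_work, 0, p)
  expect_equal(s$v_next, p$midstance_speed, tolerance = 1e-10)
  expect_equal(s$step_time, ng$step_time, tolerance = 1e-10)

  # an Up-step under nominal push-off costs speed
  sup <- step_map(p$midstance_speed, ng$pushoff_work, 0.075, p)
  expect_lt(sup$v_next, p$midstance_speed)

  # energy audit over randomized inputs:
  # dKE = u - collision_loss - M g b
  set.seed(7)
  for (k in 1:100) {
    v <- runif(1, 0.35, 0.65); u <- runif(1, 0, 0.08)
    b <- runif(1, -0.15, 0.15)
    out <- tryCatch(step_map(v, u, b, p), error = function(e) NULL)
    if (is.null(out)) next                     # failure to vault is legal
    dKE <- 0.5 * (out$v_next^2 - v^2)
    expect_equal(dKE, out$pushoff_work - out$collision_loss - b,
                 tolerance = 1e-8)
    expect_gt(out$step_time, 0)
  }

  expect_error(step_map(0.44, -0.01, 0, p), class = "curbwalk_actuation_error")
  expect_error(step_map(0.2, 0, 0.075, p), class = "curbwalk_vault_error")
})

test_that("nominal push-off grows with step length at fixed speed", {
  u <- vapply(c(0.6, 0.7, 0.79),
              function(S) nominal_gait(walker_params(step_length = S))$pushoff_work,
              numeric(1))
  expect_true(all(diff(u) > 0))
  ng <- nominal_gait(walker_params(), n_steps = 15)
  expect_equal(ng$bout_work, 15 * ng$pushoff_work)
})

test_that("perturbation persistence comes from a contracting linearization", {
  p <- walker_params()
  pers <- persistence_steps(p)
  expect_gt(pers$eigenvalue, 0)
  expect_lt(pers$eigenvalue, 1)

  # linearization slope matches the nonlinear map under +/-1% perturbations
  ng <- nominal_gait(p)
  V <- p$midstance_speed
  fd <- (step_map(V * 1.01, ng$pushoff_work, 0, p)$v_next -
           step_map(V * 0.99, ng$pushoff_work, 0, p)$v_next) / (0.02 * V)
  expect_equal(pers$eigenvalue, fd, tolerance = 1e-3)

  # the eigenvalue is the cosine of the inter-leg angle (analytic form)
  expect_equal(pers$eigenvalue, cos(2 * leg_splay(p)), tolerance = 1e-6)

  expect_equal(persistence_steps(p, decay_fraction = 0)$steps, 0)
  expect_error(persistence_steps(p, decay_fraction = 1.2))
})

test_that("walker parameters validate, serialize, and carry the units", {
  expect_error(walker_params(step_length = -1), "step_length")
  expect_error(walker_params(step_height = 0.8), "step_height")
  expect_error(walker_params(gravity = 0), "positive")

  p <- walker_params(midstance_speed = 0.5, step_height = -0.075)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_walker_params(p, f)
    q <- read_walker_params(f)
    expect_equal(unclass(q), unclass(p))
  }
  expect_error(read_walker_params(tempfile(fileext = ".yaml")), "not found")

  # bundled nominal condition equals the package defaults
  nom <- read_walker_params(system.file("extdata", "nominal.yaml",
                                        package = "curbwalk"))
  expect_equal(unclass(nom), unclass(walker_params()))
})
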