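#' Walker model parameters
#'
#' Describes the point-mass inverted-pendulum walker: a pelvis of mass `M`
#' atop rigid, massless legs of length `L`, taking steps of fixed length `S`
#' at a nominal midstance speed `V`, over terrain with an optional single
#' height change `b`. All quantities are dimensionless by default
#' (`M = L = g = 1`); conversion to human scale uses the speed unit
#' `sqrt(g*L)` and time unit `sqrt(L/g)` (see [speed_scale()]).
#'
#' The step length is interpreted through the inter-leg angle: the two legs
#' splay by `2*alpha` about vertical with `alpha = S / (2*L)` radians, so the
#' chord between footfall points is `2*L*sin(alpha)`. This convention,
#' together with the impulsive push-off/collision transition, reproduces the
#' published bout works for the curb-compensation task.
#'
#' @param body_mass pelvis point mass `M` (mass units, > 0).
#' @param leg_length leg length `L` (length units, > 0).
#' @param gravity gravitational acceleration `g` (> 0).
#' @param step_length step length `S` (length units); the legs splay by
#'   `alpha = S/(2*leg_length)` each side of vertical.
#' @param midstance_speed nominal forward speed `V` at midstance, when the
#'   stance leg is vertical (speed units, > 0).
#' @param step_height terrain height change `b` (length units, signed;
#'   positive for an Up-step). Must satisfy `|b| <` inter-foot chord.
#'
#' @return An object of class `walker_params` (a validated named list).
#' @examples
#' p <- walker_params()
#' leg_splay(p)                # alpha, rad
#' inter_foot_chord(p)         # 2 L sin(alpha)
#' @seealso [nominal_gait()], [step_map()], [read_walker_params()]
#' @export
walker_params <- function(body_mass = 1, leg_length = 1, gravity = 1,
                          step_length = 0.79, midstance_speed = 0.44,
                          step_height = 0.075) {
  p <- list(body_mass = body_mass, leg_length = leg_length, gravity = gravity,
            step_length = step_length, midstance_speed = midstance_speed,
            step_height = step_height)
  validate_walker_params(p)
  structure(p, class = "walker_params")
}

validate_walker_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("body_mass", "leg_length", "gravity", "step_length",
              "midstance_speed", "step_height")) {
    if (!num1(p[[f]])) stop("walker_params: '", f, "' must be a finite number",
                            call. = FALSE)
  }
  if (p$body_mass <= 0 || p$leg_length <= 0 || p$gravity <= 0)
    stop("walker_params: mass, leg length and gravity must be positive",
         call. = FALSE)
  if (p$step_length <= 0 || p$step_length >= pi * p$leg_length)
    stop("walker_params: step_length must lie in (0, pi*L)", call. = FALSE)
  if (p$midstance_speed <= 0)
    stop("walker_params: midstance_speed must be positive", call. = FALSE)
  chord <- 2 * p$leg_length * sin(p$step_length / (2 * p$leg_length))
  if (abs(p$step_height) >= chord)
    stop("walker_params: |step_height| must be smaller than the inter-foot chord",
         call. = FALSE)
  invisible(p)
}

#' @rdname walker_params
#' @param params a `walker_params` object.
#' @export
leg_splay <- function(params) params$step_length / (2 * params$leg_length)

#' @rdname walker_params
#' @export
inter_foot_chord <- function(params)
  2 * params$leg_length * sin(leg_splay(params))

#' @export
print.walker_params <- function(x, ...) {
  cat("Inverted-pendulum walker parameters (dimensionless unless scaled):\n")
  cat(sprintf("  mass M = %g, leg length L = %g, gravity g = %g\n",
              x$body_mass, x$leg_length, x$gravity))
  cat(sprintf("  step length S = %g (leg splay alpha = %.4f rad, chord = %.4f)\n",
              x$step_length, leg_splay(x), inter_foot_chord(x)))
  cat(sprintf("  midstance speed V = %g, step height b = %g\n",
              x$midstance_speed, x$step_height))
  invisible(x)
}

#' Dimensional scales of the walker
#'
#' Speeds in the model are naturally measured in units of `sqrt(g*L)` and
#' times in units of `sqrt(L/g)`. For human scale (`g = 9.81` m/s^2,
#' `L = 1` m) these are 3.13 m/s and 0.32 s.
#'
#' @param gravity_mps2 gravitational acceleration in m/s^2.
#' @param leg_length_m leg length in metres.
#' @return `speed_scale()` the speed unit in m/s; `time_scale()` the time
#'   unit in seconds.
#' @examples
#' speed_scale()  # 3.13 m/s
#' time_scale()   # 0.32 s
#' @export
speed_scale <- function(gravity_mps2 = 9.81, leg_length_m = 1)
  sqrt(gravity_mps2 * leg_length_m)

#' @rdname speed_scale
#' @export
time_scale <- function(gravity_mps2 = 9.81, leg_length_m = 1)
  sqrt(leg_length_m / gravity_mps2)

#' Read or write walker parameters (YAML or JSON)
#'
#' Serializes a [walker_params()] object. The format is chosen from the file
#' extension (`.yaml`/`.yml` or `.json`). A bundled `nominal.yaml`
#' (see `system.file("extdata", "nominal.yaml", package = "curbwalk")`)
#' encodes the nominal condition `V = 0.44 sqrt(gL)`, `S = 0.79 L`,
#' `b = 0.075 L`.
#'
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @return `read_walker_params()` a `walker_params` object;
#'   `write_walker_params()` the path, invisibly.
#' @export
read_walker_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter format: .", ext, call. = FALSE))
  do.call(walker_params, vals[names(vals) %in% names(formals(walker_params))])
}

#' @rdname read_walker_params
#' @param params a `walker_params` object.
#' @export
write_walker_params <- function(params, path) {
  stopifnot(inherits(params, "walker_params"))
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(params)
  switch(ext,
    yaml = , yml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported parameter format: .", ext, call. = FALSE))
  invisible(path)
}
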