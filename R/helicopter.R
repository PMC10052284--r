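#' Helicopter lift specification
#'
#' Mass, gravity and the lift values that define the simplified vertical
#' dynamics: a constant lift L yields the constant vertical acceleration
#' `a = L/m - g` (up-positive). The initial-descent lift is 99% of the
#' hover lift `m*g`, producing the slow pre-decision sink rate; the attempt
#' lift is the single pre-programmed value applied when the landing is
#' committed (80,000 N for the low-lifter group, 90,000 N for the
#' heavy-lifter group).
#'
#' @param mass Helicopter mass in kg (> 0). Default 10,000 kg.
#' @param gravity Gravitational acceleration in m/s^2. Default 9.81.
#' @param lift_attempt Attempt lift L_attempt in newtons.
#' @param lift_initial Initial-descent lift in newtons. Default 97,119 N
#'   (99% of m*g).
#' @param lift_min,lift_max Bounds of the helicopter's lift envelope in
#'   newtons (used for landscape grids; the exact envelope of the simulated
#'   helicopters is not otherwise constrained).
#' @return An object of class `helicopter_spec`.
#' @examples
#' helicopter_spec(lift_attempt = 80000) # the low-lifter
#' @export
helicopter_spec <- function(mass = 10000, gravity = 9.81,
                            lift_attempt = 80000, lift_initial = 97119,
                            lift_min = 70000, lift_max = 110000) {
  stopifnot(is.numeric(mass), mass > 0, is.numeric(gravity), gravity > 0,
            is.numeric(lift_attempt), is.numeric(lift_initial),
            is.numeric(lift_min), is.numeric(lift_max))
  if (!(lift_min <= lift_attempt && lift_attempt <= lift_max))
    stop("lift_attempt must lie within [lift_min, lift_max]")
  structure(
    list(mass = mass, gravity = gravity, lift_attempt = lift_attempt,
         lift_initial = lift_initial, lift_min = lift_min,
         lift_max = lift_max),
    class = "helicopter_spec"
  )
}

#' @export
print.helicopter_spec <- function(x, ...) {
  cat(sprintf(paste0("<helicopter_spec> m = %g kg, g = %g m/s^2, ",
                     "L_attempt = %g N, L_initial = %g N\n"),
              x$mass, x$gravity, x$lift_attempt, x$lift_initial))
  invisible(x)
}

#' Kinematic state of the helicopter
#'
#' @param time Seconds from descent onset.
#' @param altitude Height above the deck's mean plane, metres, up-positive.
#' @param velocity Vertical velocity, m/s, up-positive.
#' @return An object of class `kinematic_state`.
#' @export
kinematic_state <- function(time = 0, altitude, velocity = 0) {
  stopifnot(is.numeric(time), is.numeric(altitude), is.numeric(velocity),
            is.finite(time), is.finite(altitude), is.finite(velocity))
  structure(list(time = time, altitude = altitude, velocity = velocity),
            class = "kinematic_state")
}

#' Constant-lift ballistic propagation
#'
#' Under a constant lift the helicopter undergoes constant vertical
#' acceleration `a = lift/m - g`, so position and velocity follow the
#' uniform-acceleration closed forms.
#'
#' @param heli A [helicopter_spec()].
#' @param lift Applied lift in newtons.
#' @param z0,v0 Altitude (m) and velocity (m/s) at the start of propagation.
#' @param tau Elapsed time(s) in seconds (>= 0, vectorised).
#' @return A list with numeric vectors `z` and `v`.
#' @examples
#' h <- helicopter_spec()
#' constant_lift_state(h, 97119, z0 = 9, v0 = 0, tau = 1)$v # -0.0981 m/s
#' @export
constant_lift_state <- function(heli, lift, z0, v0, tau) {
  stopifnot(inherits(heli, "helicopter_spec"), is.numeric(lift),
            is.numeric(tau))
  if (any(tau < 0)) stop("tau must be >= 0")
  a <- lift / heli$mass - heli$gravity
  list(z = z0 + v0 * tau + 0.5 * a * tau^2, v = v0 + a * tau)
}
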