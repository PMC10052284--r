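# Contact-time solver and touchdown-velocity computation.
#
# The gap between helicopter and deck under a constant lift is
#   gap(tau) = z0 + v0*tau + a*tau^2/2 - A*sin(phase + w*(t0 + tau)),
# a quadratic minus a sinusoid. Touchdown is the first tau > 0 with
# gap(tau) = 0, located by a fine-grid sign-change scan followed by
# bracketed root polishing (stats::uniroot, tolerance `tol` seconds).

# Conservative search horizon: time for the quadratic to fall below the
# lowest deck position (when descending), or the time to stop sinking
# (when climbing), plus two heave periods so a rising deck can still catch
# the helicopter.
contact_horizon <- function(heli, lift, z0, v0, heave) {
  a <- lift / heli$mass - heli$gravity
  period <- 1 / heave$frequency
  depth <- z0 + heave$amplitude + 1
  if (a < 0) {
    t_fall <- (v0 + sqrt(v0^2 + 2 * abs(a) * depth)) / abs(a)
    t_fall + 2 * period
  } else {
    t_stop <- if (v0 < 0) -v0 / a else 0
    t_stop + 2 * period
  }
}

#' Time remaining before touchdown under a constant lift
#'
#' Solves for the first time at which the helicopter, propagated ballistically
#' from `state0` under the given constant lift, meets the heaving deck
#' (`z_heli = z_ship`). The deck plane is the heave sinusoid about the deck's
#' mean plane; altitude in `state0` is measured from that mean plane.
#'
#' @param heli A [helicopter_spec()].
#' @param lift Applied lift in newtons.
#' @param state0 A [kinematic_state()] at the moment the lift is applied.
#' @param heave A [heave_spec()] (phase referenced to `t = 0` of the descent).
#' @param scan_dt Step of the sign-change scan in seconds.
#' @param tol Root tolerance in seconds.
#' @return The time-to-contact `delta_t` in seconds, or `NA_real_` when the
#'   gap stays positive over the search horizon (no contact: the helicopter
#'   climbs away). A gap that only grazes zero (within 1e-9 m) counts as
#'   contact at the graze time.
#' @examples
#' # flat sea: fall from 5 m under the low-lifter attempt lift
#' h <- helicopter_spec(lift_attempt = 80000)
#' contact_time(h, 80000, kinematic_state(0, 5, 0), heave_spec(amplitude = 0))
#' @export
contact_time <- function(heli, lift, state0, heave,
                         scan_dt = 0.002, tol = 1e-6) {
  stopifnot(inherits(heli, "helicopter_spec"),
            inherits(state0, "kinematic_state"),
            inherits(heave, "heave_spec"))
  a <- lift / heli$mass - heli$gravity
  z0 <- state0$altitude
  v0 <- state0$velocity
  t0 <- state0$time
  gap <- function(tau) {
    z0 + v0 * tau + 0.5 * a * tau^2 - heave_position(heave, t0 + tau)
  }
  g0 <- gap(0)
  # tolerate rounding at the window edge (root tolerance of the caller)
  if (g0 < -1e-5) stop("already below deck")
  if (g0 <= 1e-9) return(0)
  horizon <- contact_horizon(heli, lift, z0, v0, heave)
  taus <- seq(0, horizon, by = scan_dt)
  gv <- gap(taus)
  below <- which(gv <= 0)
  if (length(below) == 0) {
    # degenerate grazing contact: gap touches zero without a sign change
    j <- which.min(gv)
    if (gv[j] <= 1e-9 && j > 1) {
      gr <- optimize(gap, c(taus[max(1, j - 1)], taus[min(length(taus), j + 1)]),
                     tol = tol)
      if (gr$objective <= 1e-9) return(gr$minimum)
    }
    return(NA_real_)
  }
  i <- below[1]
  if (i == 1) return(0)
  root <- uniroot(gap, c(taus[i - 1], taus[i]), tol = tol)$root
  # Newton polish with the analytic gap derivative (relative closing
  # velocity); quadratic convergence to machine precision from the
  # bracketed root
  dgap <- function(tau) {
    v0 + a * tau - heave_velocity(heave, t0 + tau)
  }
  for (k in 1:3) {
    d <- dgap(root)
    if (abs(d) < 1e-12) break
    step <- gap(root) / d
    cand <- root - step
    if (cand < taus[i - 1] - scan_dt || cand > taus[i] + scan_dt) break
    root <- cand
    if (abs(step) < 1e-13) break
  }
  max(root, 0)
}

classify_touchdown <- function(v_td_mag, v_crt) {
  if (is.na(v_td_mag)) "no_contact" else if (v_td_mag <= v_crt) "safe" else "unsafe"
}

#' Touchdown outcome under a constant lift
#'
#' Computes the touchdown velocity reached when a constant lift is applied
#' from `state0`:
#' `V_td = V_current + (L/m - g) * delta_t - A*2*pi*f * cos(phi_current + 2*pi*f*delta_t)`,
#' the relative vertical velocity between helicopter and deck at the contact
#' time `delta_t` returned by [contact_time()]. The outcome is classified
#' `safe` when `|V_td| <= v_crt`, `unsafe` when above, and `no_contact` when
#' the helicopter never reaches the deck.
#'
#' @inheritParams contact_time
#' @param v_crt Critical touchdown velocity in m/s (default 3).
#' @return An object of class `touchdown_outcome`: a list with `contact`,
#'   `delta_t`, `v_td_rel` (signed, up-positive; at a closing first contact
#'   `v_td_rel <= 0`), `v_td_mag`, `pi` (`v_td_mag / v_crt`) and
#'   `classification`.
#' @examples
#' h <- helicopter_spec(lift_attempt = 80000)
#' touchdown_velocity(h, 80000, kinematic_state(0, 5, 0),
#'                    heave_spec(amplitude = 0))
#' @export
touchdown_velocity <- function(heli, lift, state0, heave, v_crt = 3,
                               scan_dt = 0.002, tol = 1e-6) {
  dt <- contact_time(heli, lift, state0, heave, scan_dt = scan_dt, tol = tol)
  if (is.na(dt)) {
    return(structure(list(contact = FALSE, delta_t = NA_real_,
                          v_td_rel = NA_real_, v_td_mag = NA_real_,
                          pi = Inf, classification = "no_contact"),
                     class = "touchdown_outcome"))
  }
  a <- lift / heli$mass - heli$gravity
  v_rel <- state0$velocity + a * dt -
    heave_velocity(heave, state0$time + dt)
  structure(list(contact = TRUE, delta_t = dt, v_td_rel = v_rel,
                 v_td_mag = abs(v_rel), pi = abs(v_rel) / v_crt,
                 classification = classify_touchdown(abs(v_rel), v_crt)),
            class = "touchdown_outcome")
}

#' @export
print.touchdown_outcome <- function(x, ...) {
  if (!x$contact) {
    cat("<touchdown_outcome> no contact\n")
  } else {
    cat(sprintf(
      "<touchdown_outcome> delta_t = %.4f s, V_td = %.4f m/s (pi = %.4f, %s)\n",
      x$delta_t, x$v_td_mag, x$pi, x$classification))
  }
  invisible(x)
}
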