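#' The experimental condition grid
#'
#' Deck-landing-ability was manipulated by crossing the initial hover
#' altitude `Z_init` (5, 7, 9 m above the deck's mean plane) with the heave
#' phase at descent onset `phi_init` (0, pi/2, pi rad). The pair
#' (5 m, 0 rad) is excluded: its descent phase is too short to leave a
#' usable response window. Eight conditions remain.
#'
#' @param z_init Altitudes of the grid (m).
#' @param phi_init Phases of the grid (rad).
#' @param exclude Two-column data frame of pairs to drop; defaults to the
#'   single excluded pair.
#' @return A tibble with columns `z_init` and `phi_init`, ordered by
#'   ascending `z_init` then ascending `phi_init`.
#' @examples
#' build_condition_grid() # 8 rows
#' @export
build_condition_grid <- function(z_init = c(5, 7, 9),
                                 phi_init = c(0, pi / 2, pi),
                                 exclude = data.frame(z_init = 5, phi_init = 0)) {
  g <- expand.grid(phi_init = phi_init, z_init = z_init,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$z_init, g$phi_init), c("z_init", "phi_init")]
  if (!is.null(exclude) && nrow(exclude)) {
    keep <- !mapply(function(z, p) any(abs(exclude$z_init - z) < 1e-9 &
                                         abs(exclude$phi_init - p) < 1e-9),
                    g$z_init, g$phi_init)
    g <- g[keep, ]
  }
  tibble::as_tibble(g)
}

#' No-response contact time for a condition
#'
#' Time from descent onset at which the helicopter, sinking under the
#' initial-descent lift from `z_init` with zero velocity, meets the deck.
#' This is the end of the trial when no key is pressed, and the upper edge
#' of the response window.
#'
#' @param z_init Initial hover altitude (m above the deck's mean plane).
#' @param phi_init Heave phase at descent onset (rad).
#' @param config A configuration list (see [default_config()]).
#' @return Contact time in seconds.
#' @examples
#' no_response_contact_time(9, 0)
#' @export
no_response_contact_time <- function(z_init, phi_init, config = default_config()) {
  cfg <- validate_config(config)
  heli <- cfg_heli(cfg, "LL") # initial-descent lift is group-independent
  contact_time(heli, heli$lift_initial, kinematic_state(0, z_init, 0),
               cfg_heave(cfg, phi_init),
               scan_dt = cfg$grids$contact_scan_dt_s,
               tol = cfg$grids$solver_tol_s)
}

# Helicopter state after sinking under the initial-descent lift for t seconds
descent_state <- function(t, z_init, cfg) {
  a0 <- cfg$physics$lift_initial_descent_N / cfg$physics$mass_kg - cfg$physics$g
  kinematic_state(time = t, altitude = z_init + 0.5 * a0 * t^2,
                  velocity = a0 * t)
}
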