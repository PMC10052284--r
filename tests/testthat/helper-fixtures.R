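# Shared fixtures and independent oracles, built in code at test time.

# Brute-force forward integration of the constant-lift descent against the
# heave, on a 1 ms grid (velocity-Verlet step, exact for constant
# acceleration), with linear interpolation of the first crossing.
# Independent of the analytic contact solver.
oracle_first_crossing <- function(a, z0, v0, t0, heave, dt = 1e-3,
                                  t_max = 60) {
  n <- ceiling(t_max / dt)
  z <- z0
  v <- v0
  tau_prev <- 0
  gap_prev <- z0 - heave_state(heave, t0)$position
  if (gap_prev < 0) stop("oracle: starts below deck")
  for (i in seq_len(n)) {
    z <- z + v * dt + 0.5 * a * dt^2
    v <- v + a * dt
    tau <- i * dt
    hs <- heave_state(heave, t0 + tau)
    gap <- z - hs$position
    if (gap <= 0) {
      frac <- gap_prev / (gap_prev - gap)
      tau_c <- tau_prev + frac * dt
      v_heli <- v - a * dt * (1 - frac)
      v_ship <- heave_state(heave, t0 + tau_c)$velocity
      return(list(tau = tau_c, v_rel = v_heli - v_ship))
    }
    gap_prev <- gap
    tau_prev <- tau
  }
  list(tau = NA_real_, v_rel = NA_real_)
}

# pi_table is expensive enough to share across test files
cached_pi_table <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- pi_table()
    val
  }
})

# small helper to fetch one row of the cached table
pt_row <- function(group, z, phi) {
  pt <- cached_pi_table()
  pt[pt$group == group & abs(pt$z_init - z) < 1e-9 &
       abs(pt$phi_init - phi) < 1e-9, ]
}

# a minimal hand-built trial log for the analysis unit tests
toy_log <- function() {
  tibble::tibble(
    participant_id = c("a", "a", "a", "a", "a", "b", "b"),
    group = "LL",
    z_init_m = 9, phi_init_rad = 0, augmented = FALSE,
    pi_optimal = 0.7, t_optimal_s = 8.5,
    decision = c("attempt", "attempt", "attempt", "abort", "attempt",
                 "attempt", "none"),
    decision_time_s = c(8.5, 9.0, 8.0, 7.0, 8.6, 8.4, NA),
    v_td_attempt_mps = c(2.1, 3.5, 2.9, NA, 3.2, 2.5, NA),
    v_td_abort_mps = c(NA, NA, NA, 4.1, NA, NA, NA),
    timing_error_s = c(0, 0.5, -0.5, NA, 0.1, -0.1, NA),
    timing_category = c("on_time", "on_time", "on_time", NA, "on_time",
                        "on_time", NA),
    safe_outcome = c(TRUE, FALSE, TRUE, NA, FALSE, TRUE, NA),
    no_response = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}
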