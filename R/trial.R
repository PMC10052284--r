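# Trial engine: decision application and outcome computation.

#' A yes/no/none decision
#'
#' @param kind `"attempt"` (Yes key), `"abort"` (No key) or `"none"`.
#' @param time Seconds from descent onset; required unless `kind = "none"`.
#' @return A list of class `dl_decision`.
#' @export
decision <- function(kind = c("attempt", "abort", "none"), time = NA_real_) {
  kind <- match.arg(kind)
  if (kind != "none" && !is.finite(time))
    stop("a time is required for an attempt or abort decision")
  structure(list(kind = kind, time = time), class = "dl_decision")
}

#' Run a single trial
#'
#' Applies a decision to one condition and computes the outcome. On an
#' attempt, the helicopter state is propagated under the initial-descent
#' lift to the decision time and the attempt lift takes over; the touchdown
#' velocity `v_td_attempt` and the timing error relative to the optimal
#' time are recorded. On an abort, the counterfactual `v_td_abort` — the
#' touchdown velocity had the manoeuvre been pursued with the attempt lift
#' from the abort moment — is computed by the identical kinematics. With no
#' response, the helicopter reaches the deck under the initial-descent lift
#' and the trial is flagged `no_response`.
#'
#' Decisions during the lockout are rejected (they were not taken into
#' account in the protocol), as are decisions after the no-response
#' contact.
#'
#' @inheritParams no_response_contact_time
#' @param group `"LL"` or `"HL"`: selects the attempt lift.
#' @param dec A [decision()].
#' @param augmented Logical flag recorded on the trial.
#' @param participant_id Identifier recorded on the trial.
#' @param pi_info Optional precomputed [pi_optimal()] result for this
#'   condition/group (avoids recomputation in cohort loops).
#' @return A one-row tibble (a trial record): `participant_id`, `group`,
#'   `z_init_m`, `phi_init_rad`, `augmented`, `pi_optimal`, `t_optimal_s`,
#'   `decision`, `decision_time_s`, `v_td_attempt_mps`, `v_td_abort_mps`,
#'   `timing_error_s`, `timing_category`, `safe_outcome`, `no_response`.
#' @examples
#' po <- pi_optimal(9, 0, "LL")
#' run_trial(9, 0, "LL", decision("attempt", po$t_optimal))
#' @export
run_trial <- function(z_init, phi_init, group, dec,
                      augmented = FALSE, participant_id = "p1",
                      config = default_config(), pi_info = NULL) {
  cfg <- validate_config(config)
  stopifnot(inherits(dec, "dl_decision"), group %in% c("LL", "HL"))
  if (is.null(pi_info)) pi_info <- pi_optimal(z_init, phi_init, group, cfg)
  lockout <- cfg$timeline$response_lockout_s
  heli <- cfg_heli(cfg, group)
  heave <- cfg_heave(cfg, phi_init)
  v_crt <- cfg$physics$v_crt_mps

  v_att <- NA_real_
  v_abo <- NA_real_
  terr <- NA_real_
  tcat <- NA_character_
  safe <- NA
  if (dec$kind != "none") {
    if (dec$time < lockout) stop("response during lockout")
    if (dec$time >= pi_info$t_end)
      stop("response after the no-response contact time")
    st <- descent_state(dec$time, z_init, cfg)
    out <- touchdown_velocity(heli, heli$lift_attempt, st, heave,
                              v_crt = v_crt,
                              scan_dt = cfg$grids$contact_scan_dt_s,
                              tol = cfg$grids$solver_tol_s)
    if (dec$kind == "attempt") {
      v_att <- out$v_td_mag
      terr <- dec$time - pi_info$t_optimal
      fw <- cfg$timeline$feedback_window_s
      tcat <- if (terr < -fw) "early" else if (terr > fw) "late" else "on_time"
      safe <- out$v_td_mag <= v_crt
    } else {
      v_abo <- out$v_td_mag
    }
  }
  tibble::tibble(
    participant_id = participant_id, group = group,
    z_init_m = z_init, phi_init_rad = phi_init, augmented = augmented,
    pi_optimal = pi_info$pi_optimal, t_optimal_s = pi_info$t_optimal,
    decision = dec$kind, decision_time_s = dec$time,
    v_td_attempt_mps = v_att, v_td_abort_mps = v_abo,
    timing_error_s = terr, timing_category = tcat,
    safe_outcome = safe, no_response = dec$kind == "none"
  )
}

#' Trial specifications for one experimental block
#'
#' The 8 conditions x 4 repetitions x 2 augmentation modalities = 64 trials
#' of one participant, in an order shuffled by the seeded generator.
#'
#' @param participant_id Identifier.
#' @param group `"LL"` or `"HL"`.
#' @param seed Integer seed for the shuffle.
#' @param conditions Condition grid (default [build_condition_grid()]).
#' @param n_reps Repetitions per (condition, augmentation) cell.
#' @return A tibble with 64 rows: `participant_id`, `group`, `trial_index`,
#'   `z_init`, `phi_init`, `augmented`, `rep`.
#' @examples
#' b <- experiment_block("p1", "LL", seed = 1)
#' nrow(b)
#' @export
experiment_block <- function(participant_id, group, seed,
                             conditions = build_condition_grid(),
                             n_reps = 4) {
  stopifnot(group %in% c("LL", "HL"))
  cells <- merge(conditions,
                 expand.grid(augmented = c(FALSE, TRUE), rep = seq_len(n_reps),
                             KEEP.OUT.ATTRS = FALSE))
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  ord <- withr_seed(sample.int(nrow(cells)))
  cells <- cells[ord, ]
  tibble::tibble(participant_id = participant_id, group = group,
                 trial_index = seq_len(nrow(cells)),
                 z_init = cells$z_init, phi_init = cells$phi_init,
                 augmented = cells$augmented, rep = cells$rep)
}

#' Trial specifications for the calibration block
#'
#' The practice phase: three condition pairs, each repeated six times
#' (18 trials), shuffled by the seeded generator. Not used by the analysis
#' pipeline; provided for protocol completeness.
#'
#' @inheritParams experiment_block
#' @return A tibble with 18 rows in the [experiment_block()] layout
#'   (`augmented` is `FALSE` throughout, `rep` in 1..6).
#' @export
calibration_block <- function(participant_id, group, seed) {
  conds <- tibble::tibble(z_init = c(9, 5, 7), phi_init = c(0, pi, pi / 2))
  blk <- experiment_block(participant_id, group, seed, conditions = conds,
                          n_reps = 3)
  blk$rep <- ave(seq_len(nrow(blk)), paste(blk$z_init, blk$phi_init),
                 FUN = seq_along)
  blk$augmented <- FALSE
  blk$trial_index <- seq_len(nrow(blk))
  blk
}
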