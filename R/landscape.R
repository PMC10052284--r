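# Deck-landing-ability landscape, fixed-lift slices and pi quantities.

# pi(t): normalised touchdown velocity if the given lift were triggered at
# trigger time t of the descent. Inf where the helicopter would never reach
# the deck.
pi_at_trigger <- function(t, z_init, phi_init, lift, cfg) {
  heave <- cfg_heave(cfg, phi_init)
  heli <- cfg_heli(cfg, "LL")
  vapply(t, function(ti) {
    st <- descent_state(ti, z_init, cfg)
    out <- touchdown_velocity(heli, lift, st, heave,
                              v_crt = cfg$physics$v_crt_mps,
                              scan_dt = cfg$grids$contact_scan_dt_s,
                              tol = cfg$grids$solver_tol_s)
    out$pi
  }, numeric(1))
}

#' Fixed-lift slice of the deck-landing-ability landscape
#'
#' For one experimental condition and one attempt lift, computes
#' `pi(t) = V_td(t) / V_crt`, the normalised touchdown velocity that would
#' result from triggering the attempt lift at each trigger time `t` of the
#' descent. This is the curve the ecological display renders, and the
#' object safe windows and `pi_optimal` are extracted from. Trigger times
#' run from 0 (descent onset) to the no-response contact time.
#'
#' @inheritParams no_response_contact_time
#' @param lift Attempt lift in newtons, or a group name `"LL"`/`"HL"`.
#' @param dt Time step of the grid (s); defaults to `grids$dt_grid_s`.
#' @return A tibble of class `pi_timeline` with columns `time`, `pi`,
#'   `contact`, and attributes `z_init`, `phi_init`, `lift`, `t_end`
#'   (no-response contact time), `lockout`, `v_crt` and `pi_fun` (the
#'   continuous pi(t) evaluator used for refinement).
#' @examples
#' sl <- pi_timeline(9, 0, "LL", dt = 0.05)
#' min(sl$pi)
#' @export
pi_timeline <- function(z_init, phi_init, lift, config = default_config(),
                        dt = NULL) {
  cfg <- validate_config(config)
  lift <- resolve_lift(lift, cfg)
  if (is.null(dt)) dt <- cfg$grids$dt_grid_s
  t_end <- no_response_contact_time(z_init, phi_init, cfg)
  times <- unique(c(seq(0, t_end, by = dt), t_end))
  pis <- pi_at_trigger(times, z_init, phi_init, lift, cfg)
  out <- tibble::tibble(time = times, pi = pis, contact = is.finite(pis))
  structure(out,
            class = c("pi_timeline", class(out)),
            z_init = z_init, phi_init = phi_init, lift = lift,
            t_end = t_end, lockout = cfg$timeline$response_lockout_s,
            v_crt = cfg$physics$v_crt_mps,
            pi_fun = function(t) pi_at_trigger(t, z_init, phi_init, lift, cfg))
}

#' @describeIn pi_timeline Base-graphics view of a slice: the pi(t) curve
#'   with the safe region coloured by the display ramp and the critical
#'   line at pi = 1.
#' @param x A `pi_timeline`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pi_timeline <- function(x, ...) {
  col <- ramp_color(x$pi)
  cols <- ifelse(is.na(col[, 1]), "grey60",
                 grDevices::rgb(col[, 1], col[, 2], col[, 3],
                                maxColorValue = 255))
  finite <- is.finite(x$pi)
  graphics::plot(x$time[finite], x$pi[finite], type = "n",
                 xlab = "trigger time (s)",
                 ylab = expression(pi == V[td] / V[crt]), ...)
  graphics::points(x$time[finite], x$pi[finite], col = cols[finite],
                   pch = 16, cex = 0.5)
  graphics::abline(h = 1, col = "red3", lwd = 2)
  lock <- attr(x, "lockout")
  if (is.finite(lock)) graphics::abline(v = lock, lty = 3)
  invisible(x)
}

resolve_lift <- function(lift, cfg) {
  if (is.character(lift)) {
    if (!lift %in% c("LL", "HL")) stop("lift group must be 'LL' or 'HL'")
    cfg$physics$lift_attempt_N[[lift]]
  } else {
    stopifnot(is.numeric(lift), length(lift) == 1)
    lift
  }
}

#' Build the deck-landing-ability landscape
#'
#' Evaluates the touchdown outcome over a grid of (trigger time, lift)
#' cells: the 3-D landscape whose colored valleys are safe deck-landings
#' (`|V_td| <= V_crt`), gray peaks unsafe ones, and white cells lifts that
#' make the helicopter climb away without contact. The helicopter state at
#' each trigger time comes from propagating the initial-descent law.
#'
#' @inheritParams no_response_contact_time
#' @param lift_grid Strictly increasing vector of lifts (N).
#' @param time_grid Strictly increasing vector of trigger times (s) within
#'   the descent phase; defaults to the full descent sampled at
#'   `grids$dt_grid_s * 10`.
#' @return A tibble of class `dl_landscape` with one row per cell:
#'   `trigger_time_s`, `lift_N`, `contact`, `delta_t_s`, `v_td_mag_mps`,
#'   `pi`, `class`.
#' @examples
#' ls <- build_landscape(9, 0, lift_grid = seq(80000, 95000, 5000),
#'                       time_grid = seq(0, 10, 1))
#' table(ls$class)
#' @export
build_landscape <- function(z_init, phi_init, lift_grid, time_grid = NULL,
                            config = default_config()) {
  cfg <- validate_config(config)
  stopifnot(is.numeric(lift_grid), length(lift_grid) >= 1,
            all(diff(lift_grid) > 0))
  t_end <- no_response_contact_time(z_init, phi_init, cfg)
  if (is.null(time_grid))
    time_grid <- seq(0, t_end, by = cfg$grids$dt_grid_s * 10)
  stopifnot(is.numeric(time_grid), all(diff(time_grid) > 0))
  if (any(time_grid < 0) || any(time_grid > t_end + 1e-9))
    stop("time_grid must lie within the descent phase [0, t_end]")
  heave <- cfg_heave(cfg, phi_init)
  heli <- cfg_heli(cfg, "LL")
  cells <- expand.grid(lift_N = lift_grid, trigger_time_s = time_grid,
                       KEEP.OUT.ATTRS = FALSE)[, c("trigger_time_s", "lift_N")]
  res <- mapply(function(t, L) {
    out <- touchdown_velocity(heli, L, descent_state(t, z_init, cfg), heave,
                              v_crt = cfg$physics$v_crt_mps,
                              scan_dt = cfg$grids$contact_scan_dt_s,
                              tol = cfg$grids$solver_tol_s)
    c(contact = out$contact, delta_t = out$delta_t, v_td = out$v_td_mag,
      pi = out$pi)
  }, cells$trigger_time_s, cells$lift_N)
  out <- tibble::tibble(
    trigger_time_s = cells$trigger_time_s,
    lift_N = cells$lift_N,
    contact = as.logical(res["contact", ]),
    delta_t_s = res["delta_t", ],
    v_td_mag_mps = res["v_td", ],
    pi = res["pi", ],
    class = ifelse(!as.logical(res["contact", ]), "no_contact",
                   ifelse(res["pi", ] <= 1, "safe", "unsafe"))
  )
  structure(out, class = c("dl_landscape", class(out)),
            z_init = z_init, phi_init = phi_init, t_end = t_end,
            v_crt = cfg$physics$v_crt_mps)
}

#' Extract a fixed-lift slice from a built landscape
#'
#' Selects the cells of a [build_landscape()] result at one lift value,
#' returning them in `pi_timeline` form. For a slice at arbitrary
#' resolution compute it directly with [pi_timeline()].
#'
#' @param landscape A `dl_landscape` tibble.
#' @param lift Lift value (N); must be one of the landscape's grid lifts.
#' @return A `pi_timeline` tibble (without the continuous evaluator).
#' @export
slice_at_lift <- function(landscape, lift) {
  stopifnot(inherits(landscape, "dl_landscape"))
  sel <- abs(landscape$lift_N - lift) < 1e-6
  if (!any(sel)) stop("lift ", lift, " is not on the landscape's lift grid")
  rows <- landscape[sel, ]
  out <- tibble::tibble(time = rows$trigger_time_s, pi = rows$pi,
                        contact = rows$contact)
  structure(out, class = c("pi_timeline", class(out)),
            z_init = attr(landscape, "z_init"),
            phi_init = attr(landscape, "phi_init"),
            lift = lift, t_end = attr(landscape, "t_end"),
            lockout = NA_real_, v_crt = attr(landscape, "v_crt"),
            pi_fun = NULL)
}

#' Safe deck-landing windows of a slice
#'
#' Maximal contiguous intervals with `pi(t) <= 1`: the colored valleys of
#' the display. Edges interior to the slice are refined by bisection on
#' `pi(t) - 1` when the slice carries its continuous evaluator; windows may
#' also open at the slice start or close at the no-response contact time.
#' Each window carries its depth (minimum pi) and the optimal time (argmin).
#'
#' @param slice A [pi_timeline()].
#' @param edge_tol Edge refinement tolerance in seconds.
#' @return A tibble with columns `onset`, `offset`, `depth_pi`,
#'   `t_optimal`; zero rows when the slice never dips to pi <= 1.
#' @examples
#' extract_safe_windows(pi_timeline(9, 0, "HL", dt = 0.02))
#' @export
extract_safe_windows <- function(slice, edge_tol = 1e-4) {
  stopifnot(inherits(slice, "pi_timeline"), nrow(slice) > 0)
  pf <- attr(slice, "pi_fun")
  below <- slice$pi <= 1
  if (!any(below))
    return(tibble::tibble(onset = numeric(0), offset = numeric(0),
                          depth_pi = numeric(0), t_optimal = numeric(0)))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  runs <- which(r$values)
  refine <- function(lo, hi) {
    # root of pi(t) - 1 in [lo, hi]; falls back to the grid edge
    if (is.null(pf)) return(NA_real_)
    f <- function(t) pf(t) - 1
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    uniroot(f, c(lo, hi), tol = edge_tol)$root
  }
  out <- lapply(runs, function(k) {
    i <- starts[k]; j <- ends[k]
    onset <- slice$time[i]
    offset <- slice$time[j]
    if (i > 1) {
      r0 <- refine(slice$time[i - 1], slice$time[i])
      if (!is.na(r0)) onset <- r0
    }
    if (j < nrow(slice)) {
      r1 <- refine(slice$time[j], slice$time[j + 1])
      if (!is.na(r1)) offset <- r1
    }
    idx <- which.min(slice$pi[i:j]) + i - 1
    t_opt <- slice$time[idx]
    depth <- slice$pi[idx]
    if (!is.null(pf)) {
      lo <- slice$time[max(i, idx - 1)]
      hi <- slice$time[min(j, idx + 1)]
      if (hi > lo) {
        op <- optimize(pf, c(lo, hi), tol = 1e-7)
        if (op$objective < depth) {
          depth <- op$objective
          t_opt <- op$minimum
        }
      }
    }
    tibble::tibble(onset = onset, offset = offset, depth_pi = depth,
                   t_optimal = t_opt)
  })
  dplyr::bind_rows(out)
}

#' Per-condition optimum of the affordance ratio
#'
#' `pi_optimal` is the minimum of `pi(t)` over the response window
#' `[response_lockout_s, t_end]`, where `t_end` is the no-response contact
#' time; `t_optimal` is its argmin. Attempting at `t_optimal` yields the
#' minimal touchdown velocity attainable in the trial
#' (`V_optimal = pi_optimal * V_crt`). A condition with `pi_optimal > 1`
#' never affords a safe deck-landing.
#'
#' The minimisation scans a grid (`grids$pi_opt_dt_s`) and refines the best
#' bracket with golden-section search; the window's upper edge (where an
#' attempt degenerates into the no-response impact) is evaluated exactly.
#'
#' @inheritParams pi_timeline
#' @return A list with `pi_optimal`, `t_optimal`, `t_end` and `lockout`.
#' @examples
#' pi_optimal(9, 0, "LL")$pi_optimal # about 0.70
#' @export
pi_optimal <- function(z_init, phi_init, lift, config = default_config()) {
  cfg <- validate_config(config)
  lift <- resolve_lift(lift, cfg)
  lockout <- cfg$timeline$response_lockout_s
  t_end <- no_response_contact_time(z_init, phi_init, cfg)
  if (lockout >= t_end)
    stop("response lockout exceeds the no-response contact time")
  f <- function(t) pi_at_trigger(t, z_init, phi_init, lift, cfg)
  ts <- unique(c(seq(lockout, t_end, by = cfg$grids$pi_opt_dt_s), t_end))
  pis <- f(ts)
  j <- which.min(pis)
  best_pi <- pis[j]
  best_t <- ts[j]
  lo <- ts[max(1, j - 1)]
  hi <- ts[min(length(ts), j + 1)]
  if (hi > lo) {
    op <- optimize(f, c(lo, hi), tol = 1e-8)
    if (op$objective < best_pi) {
      best_pi <- op$objective
      best_t <- op$minimum
    }
  }
  list(pi_optimal = best_pi, t_optimal = best_t, t_end = t_end,
       lockout = lockout)
}

#' Table of pi_optimal over all conditions and both groups
#'
#' @param config A configuration list.
#' @param conditions Condition grid; defaults to [build_condition_grid()].
#' @return A tibble with one row per (group, condition): `group`, `z_init`,
#'   `phi_init`, `pi_optimal`, `t_optimal`, `t_end`, `lockout`, `safe`
#'   (`pi_optimal <= 1`).
#' @examples
#' \donttest{pi_table()}
#' @export
pi_table <- function(config = default_config(),
                     conditions = build_condition_grid()) {
  cfg <- validate_config(config)
  rows <- lapply(c("LL", "HL"), function(grp) {
    res <- mapply(function(z, p) {
      po <- pi_optimal(z, p, grp, cfg)
      c(po$pi_optimal, po$t_optimal, po$t_end, po$lockout)
    }, conditions$z_init, conditions$phi_init)
    tibble::tibble(group = grp, z_init = conditions$z_init,
                   phi_init = conditions$phi_init,
                   pi_optimal = res[1, ], t_optimal = res[2, ],
                   t_end = res[3, ], lockout = res[4, ],
                   safe = res[1, ] <= 1)
  })
  dplyr::bind_rows(rows)
}
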