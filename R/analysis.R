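# Decision-analysis pipeline on trial logs.

drop_no_response <- function(logs) {
  logs[!isTRUE_vec(logs$no_response), , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Attempt-frequency table
#'
#' Frequency of attempted deck-landings per (group, condition,
#' augmentation) cell: computed per participant first, then averaged
#' across participants, mirroring the inter-individual means the study's
#' ANOVAs consumed. Trials in which no key was pressed are excluded.
#' Cells with no usable trials are kept with `attempt_freq = NA` and
#' `empty = TRUE` rather than silently zeroed.
#'
#' @param logs A trial-log tibble (from [generate_cohort()],
#'   [run_trial()] rows, or [read_trial_log()]).
#' @return A tibble of class `frequency_table`: `group`, `z_init_m`,
#'   `phi_init_rad`, `pi_optimal`, `augmented`, `attempt_freq`, `freq_sd`,
#'   `n_participants`, `n_trials`, `empty`.
#' @export
attempt_frequency <- function(logs) {
  stopifnot(nrow(logs) > 0)
  cells <- unique(logs[, c("group", "z_init_m", "phi_init_rad", "augmented",
                           "pi_optimal")])
  d <- drop_no_response(logs)
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$z_init_m, .data$phi_init_rad,
                    .data$augmented, .data$pi_optimal, .data$participant_id),
    freq = mean(.data$decision == "attempt"), n = dplyr::n(),
    .groups = "drop")
  agg <- dplyr::summarise(
    dplyr::group_by(per, .data$group, .data$z_init_m, .data$phi_init_rad,
                    .data$augmented, .data$pi_optimal),
    attempt_freq = mean(.data$freq), freq_sd = sd(.data$freq),
    n_participants = dplyr::n(), n_trials = sum(.data$n),
    .groups = "drop")
  out <- dplyr::left_join(
    cells, agg,
    by = c("group", "z_init_m", "phi_init_rad", "augmented", "pi_optimal"))
  out$empty <- is.na(out$attempt_freq)
  out$n_participants[out$empty] <- 0L
  out$n_trials[out$empty] <- 0L
  out <- out[order(out$group, out$augmented, out$pi_optimal), ]
  out <- tibble::as_tibble(out)
  class(out) <- c("frequency_table", class(out))
  out
}

#' Sigmoid fit of attempt frequency against pi_optimal
#'
#' Least-squares fit of the decreasing logistic
#' `p(pi) = 1 / (1 + exp((pi - midpoint) / slope))` to the cell mean
#' attempt frequencies of one (group, augmentation) stratum: the customary
#' psychometric description of affordance perception, whose midpoint
#' estimates the perceived critical point. The fit uses
#' Levenberg-Marquardt least squares with a deterministic multi-start
#' fallback.
#'
#' @param freq_table An [attempt_frequency()] table.
#' @param group `"LL"` or `"HL"`.
#' @param augmented Logical stratum selector.
#' @return A list of class `sigmoid_fit`: `midpoint_pi`, `slope`,
#'   `residual_sse`, `unidentifiable` (TRUE when the responses are all 0 or
#'   all 1, where the midpoint is unconstrained), `fitted` (tibble of
#'   `pi_optimal`, `observed`, `fitted`).
#' @export
fit_sigmoid <- function(freq_table, group, augmented = FALSE) {
  d <- freq_table[freq_table$group == group &
                    freq_table$augmented == augmented &
                    !freq_table$empty, ]
  if (length(unique(d$pi_optimal)) < 4)
    stop("need >= 4 distinct pi_optimal values to fit a sigmoid")
  x <- d$pi_optimal
  y <- d$attempt_freq
  unident <- all(y >= 1 - 1e-9) || all(y <= 1e-9)
  sse <- function(par) {
    p <- 1 / (1 + exp((x - par[1]) / exp(par[2])))
    sum((y - p)^2)
  }
  # deterministic multi-start on (midpoint, log slope)
  starts <- expand.grid(m = seq(min(x), max(x), length.out = 7),
                        ls = log(c(0.02, 0.05, 0.1, 0.3)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- optim(c(starts$m[i], starts$ls[i]), sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || f$value < best$value) best <- f
  }
  midpoint <- best$par[1]
  slope <- exp(best$par[2])
  # polish with analytic least squares when possible
  pol <- tryCatch({
    df <- data.frame(x = x, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ 1 / (1 + exp((x - m) / k)), data = df,
      start = list(m = midpoint, k = slope),
      lower = c(-Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(m = unname(cf["m"]), k = unname(cf["k"]),
         sse = sum(stats::resid(fit)^2))
  }, error = function(e) NULL)
  if (!is.null(pol) && pol$sse <= best$value + 1e-12) {
    midpoint <- pol$m
    slope <- pol$k
    res <- pol$sse
  } else res <- best$value
  fitted <- 1 / (1 + exp((x - midpoint) / slope))
  structure(list(midpoint_pi = midpoint, slope = slope, residual_sse = res,
                 unidentifiable = unident,
                 fitted = tibble::tibble(pi_optimal = x, observed = y,
                                         fitted = fitted)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> midpoint pi = %.4f, slope = %.4f, SSE = %.3g%s\n",
              x$midpoint_pi, x$slope, x$residual_sse,
              if (x$unidentifiable) " (unidentifiable)" else ""))
  invisible(x)
}

#' Touchdown-velocity distributions and unsafe rates
#'
#' Histograms of the attempted (`v_td_attempt`) and counterfactual aborted
#' (`v_td_abort`) touchdown velocities per (group, augmentation), plus the
#' two headline rates, computed per participant and then averaged with an
#' across-participant SD (the study's mean +/- sd reporting):
#' `unsafe_attempt_rate`, the fraction of attempts with `v_td > V_crt`,
#' and `abort_miss_rate`, the fraction of aborts whose counterfactual
#' touchdown would have been safe (`v_td_abort <= V_crt`).
#'
#' @param logs A trial-log tibble.
#' @param v_crt Critical velocity (m/s); taken from the log attribute when
#'   present.
#' @param bin_width Histogram bin width in m/s.
#' @return A list with `rates` (tibble: `group`, `augmented`, `rate`,
#'   `mean`, `sd`, `n_participants`, `undefined` flag for cells with no
#'   attempts/aborts) and `histograms` (tibble: `group`, `augmented`,
#'   `kind`, `bin_lo`, `bin_hi`, `count`).
#' @export
velocity_distributions <- function(logs, v_crt = NULL, bin_width = 0.5) {
  if (is.null(v_crt)) v_crt <- attr(logs, "v_crt") %||% 3
  d <- drop_no_response(logs)
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$augmented, .data$participant_id),
    unsafe_attempt = if (any(!is.na(.data$v_td_attempt_mps)))
      mean(.data$v_td_attempt_mps[!is.na(.data$v_td_attempt_mps)] > v_crt)
    else NA_real_,
    abort_miss = if (any(!is.na(.data$v_td_abort_mps)))
      mean(.data$v_td_abort_mps[!is.na(.data$v_td_abort_mps)] <= v_crt)
    else NA_real_,
    .groups = "drop")
  agg1 <- dplyr::summarise(
    dplyr::group_by(per, .data$group, .data$augmented),
    rate = "unsafe_attempt_rate",
    mean = mean(.data$unsafe_attempt, na.rm = TRUE),
    sd = sd(.data$unsafe_attempt, na.rm = TRUE),
    n_participants = sum(!is.na(.data$unsafe_attempt)), .groups = "drop")
  agg2 <- dplyr::summarise(
    dplyr::group_by(per, .data$group, .data$augmented),
    rate = "abort_miss_rate",
    mean = mean(.data$abort_miss, na.rm = TRUE),
    sd = sd(.data$abort_miss, na.rm = TRUE),
    n_participants = sum(!is.na(.data$abort_miss)), .groups = "drop")
  rates <- dplyr::bind_rows(agg1, agg2)
  rates$undefined <- rates$n_participants == 0
  rates$mean[rates$undefined] <- NA_real_
  hist_of <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    lo <- floor(min(v) / bin_width) * bin_width
    hi <- ceiling(max(v) / bin_width + 1e-9) * bin_width
    br <- seq(lo, hi, by = bin_width)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    tibble::tibble(bin_lo = head(h$breaks, -1), bin_hi = tail(h$breaks, -1),
                   count = h$counts)
  }
  histos <- dplyr::bind_rows(lapply(split(d, list(d$group, d$augmented),
                                          drop = TRUE), function(s) {
    dplyr::bind_rows(
      attempt = hist_of(s$v_td_attempt_mps),
      abort = hist_of(s$v_td_abort_mps), .id = "kind") |>
      dplyr::mutate(group = s$group[1], augmented = s$augmented[1],
                    .before = 1)
  }))
  list(rates = tibble::as_tibble(rates), histograms = histos, v_crt = v_crt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Timing-error analysis
#'
#' Error between the moment of each attempted deck-landing and the
#' condition's optimal time, restricted to the conditions that afford a
#' safe window. Aborts and no-responses are excluded; per-participant
#' means are aggregated across participants.
#'
#' @param logs A trial-log tibble.
#' @param safe_conditions Optional tibble (`z_init_m`, `phi_init_rad`) of
#'   conditions to keep. By default, conditions whose across-group mean
#'   `pi_optimal` is <= 1 in the log (the study's five safe-window
#'   conditions).
#' @return A tibble: `group`, `z_init_m`, `phi_init_rad`, `pi_optimal`,
#'   `augmented`, `mean_error_s`, `sd_error_s`, `mean_abs_error_s`,
#'   `n_participants`.
#' @export
timing_errors <- function(logs, safe_conditions = NULL) {
  d <- logs[logs$decision == "attempt" & !is.na(logs$timing_error_s), ]
  if (is.null(safe_conditions)) {
    cond <- dplyr::summarise(
      dplyr::group_by(unique(logs[, c("group", "z_init_m", "phi_init_rad",
                                      "pi_optimal")]),
                      .data$z_init_m, .data$phi_init_rad),
      mean_pi = mean(.data$pi_optimal), .groups = "drop")
    safe_conditions <- cond[cond$mean_pi <= 1, c("z_init_m", "phi_init_rad")]
  }
  d <- dplyr::semi_join(d, safe_conditions,
                        by = c("z_init_m", "phi_init_rad"))
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$z_init_m, .data$phi_init_rad,
                    .data$pi_optimal, .data$augmented, .data$participant_id),
    err = mean(.data$timing_error_s), aerr = mean(abs(.data$timing_error_s)),
    .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per, .data$group, .data$z_init_m, .data$phi_init_rad,
                    .data$pi_optimal, .data$augmented),
    mean_error_s = mean(.data$err), sd_error_s = sd(.data$err),
    mean_abs_error_s = mean(.data$aerr), n_participants = dplyr::n(),
    .groups = "drop")
}

#' Decision frequencies positioned on the affordance landscape
#'
#' Bins the decision times of one condition/group on the slice's time axis
#' and attaches outcome classes, for plotting decisions over the
#' deck-landing-ability valley (attempted and aborted manoeuvres, symbol
#' size by frequency, colour by touchdown velocity relative to V_crt).
#'
#' @param logs A trial-log tibble.
#' @param z_init,phi_init The condition.
#' @param group `"LL"` or `"HL"`.
#' @param bin_width Time-bin width in seconds.
#' @param v_crt Critical velocity (m/s).
#' @return A tibble: `t_bin` (bin centre), `decision`, `augmented`, `freq`
#'   (fraction of that stratum's decisions in the bin), `n`,
#'   `mean_v_td_mps`, `class` (`safe`/`unsafe` by the bin's mean velocity).
#' @export
landscape_overlay <- function(logs, z_init, phi_init, group,
                              bin_width = 0.5, v_crt = NULL) {
  if (is.null(v_crt)) v_crt <- attr(logs, "v_crt") %||% 3
  d <- logs[logs$group == group &
              abs(logs$z_init_m - z_init) < 1e-9 &
              abs(logs$phi_init_rad - phi_init) < 1e-9 &
              logs$decision != "none", ]
  if (nrow(d) == 0)
    return(tibble::tibble(t_bin = numeric(0), decision = character(0),
                          augmented = logical(0), freq = numeric(0),
                          n = integer(0), mean_v_td_mps = numeric(0),
                          class = character(0)))
  d$v_td <- ifelse(d$decision == "attempt", d$v_td_attempt_mps,
                   d$v_td_abort_mps)
  d$t_bin <- (floor(d$decision_time_s / bin_width) + 0.5) * bin_width
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$decision, .data$augmented, .data$t_bin),
    n = dplyr::n(), mean_v_td_mps = mean(.data$v_td), .groups = "drop_last")
  per <- dplyr::mutate(per, freq = .data$n / sum(.data$n))
  per <- dplyr::ungroup(per)
  per$class <- ifelse(per$mean_v_td_mps <= v_crt, "safe", "unsafe")
  per[order(per$decision, per$augmented, per$t_bin),
      c("t_bin", "decision", "augmented", "freq", "n", "mean_v_td_mps",
        "class")]
}
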