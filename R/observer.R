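# Synthetic noisy-threshold observers standing in for the human cohort.

#' Observer parameters
#'
#' The synthetic observer perceives the trial's affordance through
#' multiplicative log-normal noise: `pi_hat = pi_optimal * exp(eps)`,
#' `eps ~ N(0, pi_noise_sd)`. It attempts the landing iff
#' `pi_hat <= threshold_theta`, at the perceived optimal time
#' `t_optimal + jitter` (`jitter ~ N(0, timing_jitter_sd)`, clamped into
#' the response window); otherwise it aborts `abort_latency_s` after the
#' lockout. When the visual augmentation is available the perceptual noise
#' and the timing jitter shrink by the two augmentation factors (in (0, 1]:
#' augmentation never worsens perception).
#'
#' Defaults are calibration choices, not measurements: they were selected
#' (see the methods vignette) so that a default cohort reproduces the
#' aggregate structure of the behavioural findings — attempt rates falling
#' sigmoidally in pi_optimal, roughly 40% unsafe attempts without
#' augmentation versus under 10% with it, and smaller timing errors when
#' augmented.
#'
#' @param pi_noise_sd SD of the log-scale perceptual noise (control).
#' @param threshold_theta Attempt threshold on perceived pi.
#' @param timing_jitter_sd SD of the attempt-timing jitter in seconds
#'   (control).
#' @param abort_latency_s Delay after lockout at which an abort is pressed.
#' @param augmentation_noise_factor,augmentation_jitter_factor
#'   Multipliers in (0, 1] applied to `pi_noise_sd` / `timing_jitter_sd`
#'   under augmentation.
#' @param forgotten_rate,double_press_rate Optional label-noise rates:
#'   probability that a trial is a forgotten response (no key) or a
#'   double press (both keys; the last key pressed is the recorded one).
#'   Default 0 (off); the study observed 2.3% and 4.2%.
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(pi_noise_sd = 0.5, threshold_theta = 0.95,
                            timing_jitter_sd = 1.1, abort_latency_s = 1,
                            augmentation_noise_factor = 0.25,
                            augmentation_jitter_factor = 0.3,
                            forgotten_rate = 0, double_press_rate = 0) {
  p <- list(pi_noise_sd = pi_noise_sd, threshold_theta = threshold_theta,
            timing_jitter_sd = timing_jitter_sd,
            abort_latency_s = abort_latency_s,
            augmentation_noise_factor = augmentation_noise_factor,
            augmentation_jitter_factor = augmentation_jitter_factor,
            forgotten_rate = forgotten_rate,
            double_press_rate = double_press_rate)
  stopifnot(pi_noise_sd >= 0, timing_jitter_sd >= 0, abort_latency_s >= 0,
            threshold_theta > 0,
            augmentation_noise_factor > 0, augmentation_noise_factor <= 1,
            augmentation_jitter_factor > 0, augmentation_jitter_factor <= 1,
            forgotten_rate >= 0, forgotten_rate <= 1,
            double_press_rate >= 0, double_press_rate <= 1)
  structure(p, class = "observer_params")
}

slice_summary <- function(slice) {
  if (inherits(slice, "pi_timeline")) {
    w <- extract_safe_windows(slice)
    lock <- attr(slice, "lockout")
    ok <- slice$time >= ifelse(is.na(lock), 0, lock)
    j <- which.min(replace(slice$pi, !ok, Inf))
    list(pi_optimal = slice$pi[j], t_optimal = slice$time[j],
         t_end = attr(slice, "t_end"),
         lockout = ifelse(is.na(lock), 0, lock))
  } else {
    stopifnot(all(c("pi_optimal", "t_optimal", "t_end", "lockout") %in%
                    names(slice)))
    slice
  }
}

#' Simulate one attempt/abort decision
#'
#' Draws the observer's perceived affordance and returns the resulting
#' decision. Uses R's RNG stream: seed it (`set.seed`) for reproducibility.
#'
#' @param slice A [pi_timeline()] or a list with `pi_optimal`, `t_optimal`,
#'   `t_end`, `lockout` (e.g. a row of [pi_table()] plus lockout).
#' @param params An [observer_params()].
#' @param augmented Logical; applies the augmentation factors.
#' @return A [decision()].
#' @examples
#' set.seed(1)
#' decide(list(pi_optimal = 0.7, t_optimal = 8.5, t_end = 14, lockout = 6.5),
#'        observer_params(), augmented = FALSE)
#' @export
decide <- function(slice, params = observer_params(), augmented = FALSE) {
  stopifnot(inherits(params, "observer_params"))
  s <- slice_summary(slice)
  sigma <- params$pi_noise_sd *
    if (augmented) params$augmentation_noise_factor else 1
  jsd <- params$timing_jitter_sd *
    if (augmented) params$augmentation_jitter_factor else 1
  pi_hat <- s$pi_optimal * exp(rnorm(1, 0, sigma))
  eps <- 1e-3
  if (pi_hat <= params$threshold_theta) {
    t_att <- s$t_optimal + rnorm(1, 0, jsd)
    t_att <- min(max(t_att, s$lockout), s$t_end - eps)
    decision("attempt", t_att)
  } else {
    t_abo <- min(max(s$lockout + params$abort_latency_s, s$lockout),
                 s$t_end - eps)
    decision("abort", t_abo)
  }
}

#' Simulate a full synthetic cohort
#'
#' Generates the trial log of a two-group experiment: `n_ll` low-lifter and
#' `n_hl` heavy-lifter participants, each running one 64-trial
#' [experiment_block()] scored by [decide()] and [run_trial()]. Each
#' participant's RNG stream derives deterministically from `master_seed`,
#' so the same seed reproduces the table byte for byte.
#'
#' With `params$forgotten_rate`/`double_press_rate` positive, trials are
#' relabelled with those probabilities: forgotten trials become
#' no-responses; double-press trials keep the last key pressed (the
#' recorded decision flips) and are marked in `n_presses`.
#'
#' @param n_ll,n_hl Participants per group (study cohort: 15 and 14).
#' @param params An [observer_params()].
#' @param master_seed Integer master seed.
#' @param config A configuration list.
#' @param pit Optional precomputed [pi_table()] for this config.
#' @return A trial-log tibble: one row per trial in the [run_trial()]
#'   layout plus `trial_index` and `n_presses`.
#' @examples
#' \donttest{log1 <- generate_cohort(n_ll = 2, n_hl = 2, master_seed = 1)}
#' @export
generate_cohort <- function(n_ll = 15, n_hl = 14,
                            params = observer_params(), master_seed = 1,
                            config = default_config(), pit = NULL) {
  stopifnot(n_ll >= 0, n_hl >= 0, n_ll + n_hl >= 1)
  cfg <- validate_config(config)
  if (is.null(pit)) pit <- pi_table(cfg)
  lockout <- cfg$timeline$response_lockout_s
  groups <- c(rep("LL", n_ll), rep("HL", n_hl))
  ids <- sprintf("%s%02d", tolower(groups),
                 c(seq_len(n_ll), seq_len(n_hl)))
  logs <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    pseed <- (as.integer(master_seed) %% 100000L) * 1000L + k
    blk <- experiment_block(ids[k], groups[k], seed = pseed)
    set.seed(pseed + 500L)
    rows <- vector("list", nrow(blk))
    for (i in seq_len(nrow(blk))) {
      key <- pit$group == groups[k] &
        abs(pit$z_init - blk$z_init[i]) < 1e-9 &
        abs(pit$phi_init - blk$phi_init[i]) < 1e-9
      info <- list(pi_optimal = pit$pi_optimal[key][1],
                   t_optimal = pit$t_optimal[key][1],
                   t_end = pit$t_end[key][1], lockout = lockout)
      dec <- decide(info, params, augmented = blk$augmented[i])
      n_presses <- 1L
      if (params$double_press_rate > 0 &&
          runif(1) < params$double_press_rate) {
        # both keys pressed; the recorded decision is the last key
        flip <- if (dec$kind == "attempt") "abort" else "attempt"
        dec <- decision(flip, dec$time)
        n_presses <- 2L
      }
      if (params$forgotten_rate > 0 && runif(1) < params$forgotten_rate)
        dec <- decision("none")
      rec <- run_trial(blk$z_init[i], blk$phi_init[i], groups[k], dec,
                       augmented = blk$augmented[i],
                       participant_id = ids[k], config = cfg,
                       pi_info = info)
      rec$trial_index <- blk$trial_index[i]
      rec$n_presses <- n_presses
      rows[[i]] <- rec
    }
    logs[[k]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(logs)
  attr(out, "v_crt") <- cfg$physics$v_crt_mps
  out
}

#' Maximum-likelihood refit of the observer decision model
#'
#' Recovers the attempt threshold `theta` and the perceptual noise `sigma`
#' from a trial log by maximising the Bernoulli likelihood of the
#' attempt/abort outcomes: each trial is an attempt with probability
#' `P(pi_optimal * exp(eps) <= theta) = Phi((log theta - log pi_optimal) / sigma)`.
#' Fit on control (non-augmented) trials of one group at a time, or on all
#' trials of one modality if the noise is shared.
#'
#' The threshold is shared between the two augmentation modalities while
#' each modality has its own noise, so by default both halves of the log
#' inform the fit: the sharp psychometric step of the low-noise augmented
#' trials pins the threshold, which in turn identifies the control noise.
#' Set `augmented` to fit a single modality alone.
#'
#' @param logs A trial-log tibble (no-response trials are dropped).
#' @param augmented `NULL` (default) for the joint shared-threshold fit,
#'   or `TRUE`/`FALSE` to restrict to one modality.
#' @return A list with `theta`, `sigma` (control noise, or the modality's
#'   noise for a single-modality fit), `sigma_augmented` (joint fit only),
#'   `logLik` and `convergence`.
#' @export
fit_observer <- function(logs, augmented = NULL) {
  d <- logs[!logs$no_response, ]
  if (!is.null(augmented)) d <- d[d$augmented == augmented, ]
  if (nrow(d) == 0) stop("no usable trials")
  y <- as.integer(d$decision == "attempt")
  lp <- log(d$pi_optimal)
  aug <- d$augmented
  joint <- is.null(augmented) && any(aug) && any(!aug)
  bern_nll <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  if (joint) {
    nll <- function(par) {
      sig <- ifelse(aug, exp(par[3]), exp(par[2]))
      bern_nll(stats::pnorm((par[1] - lp) / sig))
    }
    fit <- optim(c(0, log(0.3), log(0.1)), nll, method = "L-BFGS-B",
                 lower = c(log(0.2), log(1e-3), log(1e-3)),
                 upper = c(log(5), log(5), log(5)))
    list(theta = exp(fit$par[1]), sigma = exp(fit$par[2]),
         sigma_augmented = exp(fit$par[3]),
         logLik = -fit$value, convergence = fit$convergence)
  } else {
    nll <- function(par) {
      bern_nll(stats::pnorm((par[1] - lp) / exp(par[2])))
    }
    fit <- optim(c(0, log(0.3)), nll, method = "L-BFGS-B",
                 lower = c(log(0.2), log(1e-3)),
                 upper = c(log(5), log(5)))
    list(theta = exp(fit$par[1]), sigma = exp(fit$par[2]),
         sigma_augmented = NA_real_,
         logLik = -fit$value, convergence = fit$convergence)
  }
}
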