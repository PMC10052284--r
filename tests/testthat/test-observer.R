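test_that("the noiseless ideal observer attempts iff a safe window exists", {
  ideal <- observer_params(pi_noise_sd = 0, threshold_theta = 1,
                           timing_jitter_sd = 0)
  pt <- cached_pi_table()
  for (i in seq_len(nrow(pt))) {
    info <- list(pi_optimal = pt$pi_optimal[i], t_optimal = pt$t_optimal[i],
                 t_end = pt$t_end[i], lockout = pt$lockout[i])
    set.seed(1)
    d <- decide(info, ideal, augmented = FALSE)
    if (pt$pi_optimal[i] <= 1) {
      expect_identical(d$kind, "attempt")
      expect_equal(d$time, pt$t_optimal[i], tolerance = 2e-3)
    } else {
      expect_identical(d$kind, "abort")
    }
  }
})

test_that("abort probability approaches one as noise vanishes when no window exists", {
  info <- list(pi_optimal = 1.5, t_optimal = 10, t_end = 12, lockout = 6.5)
  for (sd in c(0.3, 0.1, 0.02)) {
    p <- observer_params(pi_noise_sd = sd, threshold_theta = 1)
    set.seed(2)
    kinds <- replicate(300, decide(info, p)$kind)
    frac_abort <- mean(kinds == "abort")
    if (sd == 0.3) expect_gt(frac_abort, 0.8)
    if (sd == 0.02) expect_equal(frac_abort, 1)
  }
})

test_that("attempt fraction matches a large Monte-Carlo oracle near threshold", {
  # condition just above the critical point, moderate noise
  info <- list(pi_optimal = 1.05, t_optimal = 10, t_end = 12, lockout = 6.5)
  p <- observer_params(pi_noise_sd = 0.4, threshold_theta = 1,
                       timing_jitter_sd = 0)
  set.seed(11)
  frac <- mean(replicate(1000, decide(info, p)$kind == "attempt"))
  # independent oracle: direct simulation of the perceived-ratio rule
  set.seed(99)
  oracle <- mean(1.05 * exp(rnorm(1e5, 0, 0.4)) <= 1)
  expect_equal(frac, oracle, tolerance = 0.03 / oracle)
})

test_that("decisions respect the response window", {
  info <- list(pi_optimal = 0.3, t_optimal = 6.6, t_end = 8, lockout = 6.5)
  p <- observer_params(timing_jitter_sd = 5) # huge jitter forces clamping
  set.seed(5)
  for (i in 1:50) {
    d <- decide(info, p)
    expect_gte(d$time, 6.5)
    expect_lt(d$time, 8)
  }
})

test_that("cohort generation is reproducible and correctly sized", {
  pt <- cached_pi_table()
  l1 <- generate_cohort(n_ll = 2, n_hl = 1, master_seed = 7, pit = pt)
  expect_equal(nrow(l1), 3 * 64)
  expect_equal(length(unique(l1$participant_id)), 3)
  expect_equal(sum(l1$group == "LL"), 2 * 64)
  l2 <- generate_cohort(n_ll = 2, n_hl = 1, master_seed = 7, pit = pt)
  expect_identical(l1, l2)
  l3 <- generate_cohort(n_ll = 2, n_hl = 1, master_seed = 8, pit = pt)
  expect_false(identical(l1$decision, l3$decision))
  # per-trial pi_optimal agrees with the core model's table
  m <- merge(l1, pt, by.x = c("group", "z_init_m", "phi_init_rad"),
             by.y = c("group", "z_init", "phi_init"))
  expect_equal(m$pi_optimal.x, m$pi_optimal.y, tolerance = 1e-12)
})

test_that("attempt frequency is non-increasing in pi_optimal in expectation", {
  # many observers on each condition's summary, control modality
  pt <- cached_pi_table()
  pt <- pt[order(pt$pi_optimal), ]
  p <- observer_params()
  set.seed(31)
  frac <- vapply(seq_len(nrow(pt)), function(i) {
    info <- list(pi_optimal = pt$pi_optimal[i], t_optimal = pt$t_optimal[i],
                 t_end = pt$t_end[i], lockout = pt$lockout[i])
    mean(replicate(1000, decide(info, p)$kind == "attempt"))
  }, numeric(1))
  # allow small Monte-Carlo wiggle on what must be a decreasing trend
  expect_true(all(diff(frac) < 0.05))
  expect_lt(frac[length(frac)], frac[1])
})

test_that("label noise injects forgotten and double-press trials at the set rates", {
  pt <- cached_pi_table()
  p <- observer_params(forgotten_rate = 0.2, double_press_rate = 0.3)
  l <- generate_cohort(n_ll = 3, n_hl = 3, params = p, master_seed = 9,
                       pit = pt)
  expect_gt(mean(l$no_response), 0.1)
  expect_gt(mean(l$n_presses == 2), 0.2)
  clean <- generate_cohort(n_ll = 1, n_hl = 1, master_seed = 9, pit = pt)
  expect_equal(mean(clean$no_response), 0)
})
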