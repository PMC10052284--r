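test_that("attempt frequencies are per-participant means, excluding no-responses", {
  log <- toy_log()
  ft <- attempt_frequency(log)
  # participant a: 4/5 attempts; participant b: 1/1 (the none trial drops)
  expect_equal(nrow(ft), 1)
  expect_equal(ft$attempt_freq, mean(c(0.8, 1)))
  expect_equal(ft$n_trials, 6)
  expect_false(ft$empty)
  # invariant to row order
  ft2 <- attempt_frequency(log[sample(nrow(log)), ])
  expect_equal(ft2$attempt_freq, ft$attempt_freq)
})

test_that("all-attempt cells give frequency one", {
  log <- toy_log()[c(1, 2, 3, 5), ]
  expect_equal(attempt_frequency(log)$attempt_freq, 1)
})

test_that("sigmoid fit recovers exact logistic data", {
  x <- sort(cached_pi_table()$pi_optimal[cached_pi_table()$group == "LL"])
  y <- 1 / (1 + exp((x - 0.9) / 0.05))
  ft <- tibble::tibble(group = "LL", z_init_m = NA, phi_init_rad = NA,
                       pi_optimal = x, augmented = FALSE,
                       attempt_freq = y, freq_sd = 0,
                       n_participants = 10, n_trials = 40, empty = FALSE)
  f <- fit_sigmoid(ft, "LL", augmented = FALSE)
  expect_equal(f$midpoint_pi, 0.9, tolerance = 1e-6)
  expect_equal(f$slope, 0.05, tolerance = 1e-4)
  expect_lt(f$residual_sse, 1e-12)
  expect_false(f$unidentifiable)
})

test_that("step data from ideal observers brackets the midpoint at the critical point", {
  pt <- cached_pi_table()
  x <- sort(pt$pi_optimal[pt$group == "HL"])
  y <- as.numeric(x <= 1)
  ft <- tibble::tibble(group = "HL", z_init_m = NA, phi_init_rad = NA,
                       pi_optimal = x, augmented = FALSE,
                       attempt_freq = y, freq_sd = 0,
                       n_participants = 10, n_trials = 40, empty = FALSE)
  f <- fit_sigmoid(ft, "HL", augmented = FALSE)
  lo <- max(x[x <= 1])
  hi <- min(x[x > 1])
  expect_gte(f$midpoint_pi, lo - 1e-6)
  expect_lte(f$midpoint_pi, hi + 1e-6)
  # the fit is at least as good as the best constant
  expect_lte(f$residual_sse, sum((y - mean(y))^2) + 1e-12)
})

test_that("degenerate all-one data is flagged unidentifiable", {
  x <- seq(0.1, 0.8, length.out = 6)
  ft <- tibble::tibble(group = "LL", z_init_m = NA, phi_init_rad = NA,
                       pi_optimal = x, augmented = FALSE,
                       attempt_freq = 1, freq_sd = 0,
                       n_participants = 5, n_trials = 20, empty = FALSE)
  expect_true(fit_sigmoid(ft, "LL")$unidentifiable)
})

test_that("unsafe-attempt and abort-miss rates match hand counts", {
  log <- toy_log()
  vd <- velocity_distributions(log, v_crt = 3)
  ua <- vd$rates[vd$rates$rate == "unsafe_attempt_rate", ]
  # participant a: 2 of 4 attempts above 3; participant b: 0 of 1
  expect_equal(ua$mean, mean(c(0.5, 0)))
  am <- vd$rates[vd$rates$rate == "abort_miss_rate", ]
  # the single abort would have been unsafe: miss rate 0
  expect_equal(am$mean, 0)
  expect_true(all(vd$rates$mean[!vd$rates$undefined] >= 0 &
                    vd$rates$mean[!vd$rates$undefined] <= 1))
  expect_true(sum(vd$histograms$count[vd$histograms$kind == "attempt"]) == 5)
})

test_that("timing errors aggregate per participant over safe conditions", {
  log <- toy_log() # pi_optimal 0.7 <= 1, condition retained
  te <- timing_errors(log)
  # participant a attempts: errors 0, .5, -.5, .1 -> mean .025, mae .275
  # participant b: error -.1
  expect_equal(te$mean_error_s, mean(c(0.025, -0.1)))
  expect_equal(te$mean_abs_error_s, mean(c(0.275, 0.1)))
  expect_equal(te$n_participants, 2)
  # a uniform +0.5 s shift moves the mean error by +0.5 s
  shifted <- log
  shifted$timing_error_s <- shifted$timing_error_s + 0.5
  expect_equal(timing_errors(shifted)$mean_error_s,
               te$mean_error_s + 0.5)
  # unsafe conditions are dropped
  unsafe <- log
  unsafe$pi_optimal <- 1.2
  expect_equal(nrow(timing_errors(unsafe)), 0)
})

test_that("landscape overlay bins decisions and classes outcomes", {
  log <- toy_log()
  ov <- landscape_overlay(log, 9, 0, "LL")
  expect_true(all(ov$class[ov$mean_v_td_mps > 3] == "unsafe"))
  # frequencies sum to one within each decision stratum
  sums <- tapply(ov$freq, paste(ov$decision, ov$augmented), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # single marker for a single-attempt log
  single <- log[1, ]
  ov1 <- landscape_overlay(single, 9, 0, "LL")
  expect_equal(nrow(ov1), 1)
  expect_equal(ov1$freq, 1)
  expect_identical(ov1$class, "safe")
  # empty selection gives an empty overlay
  expect_equal(nrow(landscape_overlay(log, 5, pi, "LL")), 0)
})
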