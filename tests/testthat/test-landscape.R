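test_that("slice values equal pointwise touchdown computations", {
  cfg <- default_config()
  sl <- pi_timeline(9, 0, "LL", dt = 0.25)
  h <- helicopter_spec(lift_attempt = 80000)
  heave <- heave_spec(2.5, 0.14, 0)
  a0 <- 97119 / 10000 - 9.81
  for (i in seq(1, nrow(sl), by = 7)) {
    t <- sl$time[i]
    st <- kinematic_state(t, 9 + 0.5 * a0 * t^2, a0 * t)
    td <- touchdown_velocity(h, 80000, st, heave)
    expect_equal(sl$pi[i], td$pi, tolerance = 1e-9)
  }
})

test_that("flat sea slice is smooth and lift-monotone", {
  cfg <- validate_config(list(physics = list(A_m = 0)))
  sl <- pi_timeline(9, 0, "LL", config = cfg, dt = 0.1)
  # no oscillation: strictly decreasing toward the boundary optimum
  expect_true(all(diff(sl$pi) < 1e-9))
  # the heavier lift lands softer everywhere except at the very boundary,
  # where an immediate-contact attempt degenerates to the same impact
  sh <- pi_timeline(9, 0, "HL", config = cfg, dt = 0.1)
  interior <- seq_len(nrow(sl) - 1)
  expect_true(all(sh$pi[interior] < sl$pi[interior]))
})

test_that("the two groups carve different valleys from the same condition", {
  ll <- pi_timeline(9, 0, "LL", dt = 0.05)
  hl <- pi_timeline(9, 0, "HL", dt = 0.05)
  wll <- extract_safe_windows(ll)
  whl <- extract_safe_windows(hl)
  expect_gt(nrow(wll), 0)
  expect_gt(nrow(whl), 0)
  # heavier lift digs a deeper and wider valley
  expect_lt(min(whl$depth_pi), min(wll$depth_pi))
  expect_gt(max(whl$offset - whl$onset), max(wll$offset - wll$onset))
})

test_that("landscape cells partition into the three outcome classes", {
  ls <- build_landscape(9, 0, lift_grid = seq(75000, 105000, length.out = 10),
                        time_grid = seq(0, 12, length.out = 10))
  expect_equal(nrow(ls), 100)
  expect_setequal(unique(ls$class), c("safe", "unsafe", "no_contact"))
  # cells equal pointwise touchdown_velocity calls
  h <- helicopter_spec()
  heave <- heave_spec(2.5, 0.14, 0)
  a0 <- 97119 / 10000 - 9.81
  idx <- c(1, 25, 50, 87)
  for (i in idx) {
    t <- ls$trigger_time_s[i]
    st <- kinematic_state(t, 9 + 0.5 * a0 * t^2, a0 * t)
    td <- touchdown_velocity(h, ls$lift_N[i], st, heave)
    expect_equal(ls$pi[i], td$pi, tolerance = 1e-9)
  }
  # from the hover state, lifts above m*g climb away without contact,
  # and conversely every no-contact cell needs more lift than hover
  at0 <- ls$trigger_time_s == 0
  expect_true(all(ls$class[at0 & ls$lift_N > 98100] == "no_contact"))
  expect_true(all(ls$lift_N[ls$class == "no_contact"] > 98100))
})

test_that("landscape classification counts match the integration oracle", {
  h <- helicopter_spec()
  heave <- heave_spec(2.5, 0.14, 0)
  a0 <- 97119 / 10000 - 9.81
  ls <- build_landscape(7, 0, lift_grid = seq(76000, 104000, length.out = 20),
                        time_grid = seq(0, 12, length.out = 20))
  oracle_class <- mapply(function(t, L) {
    a <- L / h$mass - h$gravity
    orc <- oracle_first_crossing(a, 7 + 0.5 * a0 * t^2, a0 * t, t, heave)
    if (is.na(orc$tau)) "no_contact"
    else if (abs(orc$v_rel) <= 3) "safe" else "unsafe"
  }, ls$trigger_time_s, ls$lift_N)
  # borderline cells may flip by solver-vs-oracle rounding; classes must
  # agree in overwhelming majority and in total counts
  expect_gte(mean(oracle_class == ls$class), 0.98)
  expect_equal(as.vector(table(factor(oracle_class, c("safe", "unsafe", "no_contact")))),
               as.vector(table(factor(ls$class, c("safe", "unsafe", "no_contact")))),
               tolerance = 2)
})

test_that("slice_at_lift extracts landscape columns as a pi timeline", {
  ls <- build_landscape(9, 0, lift_grid = c(80000, 90000),
                        time_grid = seq(0, 12, 0.5))
  sl <- slice_at_lift(ls, 80000)
  expect_s3_class(sl, "pi_timeline")
  ref <- pi_timeline(9, 0, "LL", dt = 0.5)
  common <- seq_len(nrow(sl))
  expect_equal(sl$pi, ref$pi[seq_along(sl$pi)], tolerance = 1e-9)
  expect_error(slice_at_lift(ls, 85000), "lift grid")
})

test_that("safe windows are consistent with the pi <= 1 region", {
  for (spec in list(c(9, 0, "LL"), c(7, pi / 2, "HL"))) {
    sl <- pi_timeline(as.numeric(spec[1]), as.numeric(spec[2]), spec[3],
                      dt = 0.02)
    w <- extract_safe_windows(sl)
    expect_gt(nrow(w), 0)
    expect_true(all(w$onset < w$offset))
    expect_true(all(w$depth_pi >= 0 & w$depth_pi <= 1))
    expect_true(all(w$t_optimal >= w$onset & w$t_optimal <= w$offset))
    inside <- rep(FALSE, nrow(sl))
    for (k in seq_len(nrow(w)))
      inside <- inside | (sl$time >= w$onset[k] & sl$time <= w$offset[k])
    expect_true(all(sl$pi[inside] <= 1 + 1e-6))
    outside_ok <- sl$pi[!inside] > 1 - 1e-6 | !sl$contact[!inside]
    expect_true(all(outside_ok))
  }
})

test_that("a slice that never dips below one has no safe windows", {
  # heavy-lifter condition (9 m, pi/2) within the response window only
  sl <- pi_timeline(9, pi / 2, "HL", dt = 0.02)
  lock <- attr(sl, "lockout")
  sub <- sl[sl$time >= lock, ]
  attr_copy <- attributes(sl)
  for (a in setdiff(names(attr_copy), c("row.names", "names")))
    attr(sub, a) <- attr_copy[[a]]
  expect_equal(nrow(extract_safe_windows(sub)), 0)
})

test_that("window edges are stable under grid refinement", {
  coarse <- extract_safe_windows(pi_timeline(9, 0, "HL", dt = 0.1))
  fine <- extract_safe_windows(pi_timeline(9, 0, "HL", dt = 0.01))
  expect_equal(nrow(coarse), nrow(fine))
  expect_equal(coarse$onset, fine$onset, tolerance = 1e-3)
  expect_equal(coarse$offset, fine$offset, tolerance = 1e-3)
})

test_that("flat-sea pi_optimal equals the analytic boundary optimum", {
  cfg <- validate_config(list(physics = list(A_m = 0)))
  a0 <- abs(97119 / 10000 - 9.81)
  for (z0 in c(7, 9)) {
    po <- pi_optimal(z0, 0, "LL", cfg)
    # the slice decreases toward the no-response impact: optimum at the
    # boundary with speed sqrt(2 * z0 * |a0|)
    expect_equal(po$pi_optimal, sqrt(2 * z0 * a0) / 3, tolerance = 1e-4)
    expect_equal(po$t_optimal, sqrt(2 * z0 / a0), tolerance = 1e-3)
  }
})

test_that("pi_table covers both groups over the eight conditions", {
  pt <- cached_pi_table()
  expect_equal(nrow(pt), 16)
  expect_equal(sum(pt$group == "LL"), 8)
  expect_true(all(pt$pi_optimal > 0))
  expect_true(all(pt$t_optimal >= pt$lockout - 1e-9))
  expect_true(all(pt$t_optimal <= pt$t_end + 1e-9))
  # no-response contact exceeds the lockout in every retained condition
  expect_true(all(pt$t_end > pt$lockout))
})
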