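test_that("CV/SD conversions reproduce the regulatory constants and invert", {
  # printed switch-point constants of the rule
  expect_within(cv2sd(0.30), 0.29356, 5e-6)
  expect_within(cv2sd(0.1393), 0.1386, 5e-5)
  expect_within(sd2cv(0.29356), 0.3000, 1e-4)
  expect_identical(cv2sd(0), 0)
  expect_identical(sd2cv(0), 0)
  # inverse-function property on a CV grid
  cv <- seq(0.05, 0.40, by = 0.01)
  expect_true(all(abs(sd2cv(cv2sd(cv)) - cv) < 1e-12))
  # strictly increasing
  expect_true(all(diff(cv2sd(cv)) > 0))
  expect_error(cv2sd(-0.1), "non-negative")
  expect_error(sd2cv(c(0.1, -1)), "non-negative")
})

test_that("acceptance limits take the right branch and stay log-symmetric", {
  lim <- acceptance_limits(0.10, crit_nlivr)
  expect_equal(lim$regime, "floor")
  expect_within(lim$lower, 0.9000, 1e-12)
  expect_within(lim$upper, 1 / 0.9, 1e-12)

  # at s_WR = 0.29356 the scaled branch is continuous with the cap
  lim <- acceptance_limits(0.29356, crit_nlivr)
  expect_equal(lim$regime, "scaled")
  expect_within(lim$lower, 0.8000, 1e-4)
  expect_within(lim$upper, 1.2500, 1e-4)
  expect_within(lim$lower, exp(-0.76 * 0.29356), 1e-12)

  lim <- acceptance_limits(0.35, crit_nlivr)
  expect_equal(lim$regime, "cap")
  expect_equal(lim$lower, 0.80)
  expect_equal(lim$upper, 1.25)

  # mid-range: exp(+/- 0.76 * 0.19804), evaluated independently
  s <- cv2sd(0.20)
  expect_within(s, 0.19804, 5e-6)
  lim <- acceptance_limits(s, crit_nlivr)
  expect_within(lim$lower, 0.8603, 1e-4)
  expect_within(lim$upper, 1.1624, 1e-4)

  # exact log-symmetry and monotone width over a dense grid
  grid <- acceptance_limits(seq(0, 0.6, by = 0.002), crit_nlivr)
  expect_true(all(abs(log(grid$upper) + log(grid$lower)) < 1e-12))
  expect_true(all(diff(grid$upper) >= 0))
  # constant on the floor and cap plateaus
  expect_equal(length(unique(grid$upper[grid$regime == "floor"])), 1L)
  expect_equal(length(unique(grid$upper[grid$regime == "cap"])), 1L)

  # near-continuity at both switch points
  expect_within(acceptance_limits(cv2sd(0.1393), crit_nlivr)$upper, 1 / 0.9,
                1e-3)
  expect_within(acceptance_limits(cv2sd(0.30), crit_nlivr)$upper, 1.25, 1e-4)

  # boundary membership: the switch values themselves are not scaled
  expect_equal(acceptance_limits(crit_nlivr$sd_lower, crit_nlivr)$regime,
               "floor")
  expect_equal(acceptance_limits(crit_nlivr$sd_upper, crit_nlivr)$regime,
               "cap")

  expect_error(acceptance_limits(-0.1, crit_nlivr), "non-negative")
})

test_that("null-boundary GMR schedule follows the three branches", {
  expect_equal(t1e_true_gmr(0.10, crit_nlivr), 0.90)
  expect_equal(t1e_true_gmr(0.35, crit_nlivr), 0.80)
  expect_within(t1e_true_gmr(0.20, crit_nlivr), 0.8603, 1e-4)
  # equals the lower acceptance limit at the true s_WR, across the mid-range
  cv <- seq(0.145, 0.295, by = 0.005)
  expect_equal(t1e_true_gmr(cv, crit_nlivr),
               acceptance_limits(cv2sd(cv), crit_nlivr)$lower)
  expect_error(t1e_true_gmr(0), "positive")
})

test_that("criterion construction validates its invariants", {
  expect_error(nlivr_criterion(floor_limits = c(0.9, 1.12)), "log-symmetric")
  expect_error(nlivr_criterion(alpha = 0.6), "alpha")
  expect_error(nlivr_criterion(k = -1))
  expect_error(nlivr_criterion(cv_switch_lower = 0.35,
                               cv_switch_upper = 0.30))
  # fixed criterion never scales, reproducing plain ABE with tighter limits
  grid <- acceptance_limits(seq(0, 0.6, by = 0.05), crit_tighter)
  expect_true(all(grid$regime == "floor"))
  expect_equal(grid$lower, rep(0.9, nrow(grid)))
  expect_output(print(crit_nlivr_pec), "point-estimate constraint")
  expect_output(print(crit_tighter), "fixed limits 90.00-111.11%")
})
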