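test_that("trial generation is reproducible and validated", {
  a <- simulate_trial(12, 0.9, 0.2, seed = 5)
  b <- simulate_trial(12, 0.9, 0.2, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 36L)
  expect_equal(as.integer(table(a$sequence[a$period == 1])), rep(4L, 3))
  # two R and one T per subject
  counts <- table(a$subject, a$treatment)
  expect_true(all(counts[, "R"] == 2 & counts[, "T"] == 1))
  expect_error(simulate_trial(10, 0.9, 0.2), "divisible by 3")
  expect_error(simulate_trial(3, 0.9, 0.2))
})

test_that("noise-free data recover the generative parameters exactly", {
  tr <- simulate_trial(12, 0.85, cv_wr = 0, cv_wt = 0, cv_between = 0.3,
                       seed = 1)
  for (rule in c("pooled", "contrast")) {
    st <- analyze_trial(tr, df_rule = rule)
    expect_within(st$pe, log(0.85), 1e-12)
    expect_within(st$se_pe, 0, 1e-10)
    expect_within(st$s2_wr, 0, 1e-20)
  }
})

test_that("pooled analysis equals the all-data ANOVA fitted by lm()", {
  # independent oracle: lm(y ~ treatment + period + subject), including
  # nonzero nuisance effects, heteroscedasticity, and an unbalanced trial
  tr <- simulate_trial(15, 0.92, 0.25, cv_wt = 0.18, seed = 7,
                       sequence_effects = c(0.1, -0.2, 0.05),
                       period_effects = c(0, 0.3, -0.1))
  for (data in list(tr, dplyr::filter(tr, subject != 15))) {
    st <- analyze_trial(data, df_rule = "pooled")
    fit <- stats::lm(log_value ~ treatment + factor(period) + factor(subject),
                     data = data)
    co <- summary(fit)$coefficients["treatmentT", ]
    expect_within(st$pe, co[["Estimate"]], 1e-10)
    expect_within(st$se_pe, co[["Std. Error"]], 1e-10)
    expect_equal(st$df_pe, fit$df.residual)
  }
})

test_that("contrast analysis matches a hand computation on a toy dataset", {
  # 6 subjects, hand-chosen log values
  vals <- c(
    # subject 1..2 TRR: periods 1,2,3
    0.10, 0.02, -0.04,
    0.20, 0.12, 0.16,
    # subject 3..4 RTR
    0.00, -0.08, 0.06,
    0.30, 0.18, 0.22,
    # subject 5..6 RRT
    -0.10, -0.02, -0.12,
    0.08, 0.14, 0.04
  )
  tr <- tibble::tibble(
    subject = rep(1:6, each = 3),
    sequence = rep(c("TRR", "RTR", "RRT"), each = 6),
    period = rep(1:3, 6),
    treatment = unlist(strsplit(rep(c("TRR", "RTR", "RRT"), each = 2), "")),
    log_value = vals
  )
  # brute-force oracle computed directly from the definitions
  cvals <- c(0.10 - (0.02 - 0.04) / 2, 0.20 - (0.12 + 0.16) / 2,
             -0.08 - (0.00 + 0.06) / 2, 0.18 - (0.30 + 0.22) / 2,
             -0.12 - (-0.10 - 0.02) / 2, 0.04 - (0.08 + 0.14) / 2)
  dvals <- c(0.02 - (-0.04), 0.12 - 0.16, 0.00 - 0.06, 0.30 - 0.22,
             -0.10 - (-0.02), 0.08 - 0.14)
  seq_means <- colMeans(matrix(cvals, nrow = 2))
  pe_hand <- mean(seq_means)
  ss_c <- sum((matrix(cvals, 2) - rep(seq_means, each = 2))^2)
  dmeans <- colMeans(matrix(dvals, nrow = 2))
  ss_d <- sum((matrix(dvals, 2) - rep(dmeans, each = 2))^2)

  st <- analyze_trial(tr, df_rule = "contrast")
  expect_within(st$pe, pe_hand, 1e-12)
  expect_within(st$s2_wr, ss_d / (2 * 3), 1e-12)
  expect_within(st$se_pe, sqrt(ss_c / 3 / 6), 1e-12)
  expect_equal(st$df_pe, 3)
  expect_equal(st$df_wr, 3)
})

test_that("estimates are invariant to sequence and period effect sizes", {
  base <- analyze_trial(simulate_trial(15, 0.92, 0.25, seed = 7), "contrast")
  shifted <- analyze_trial(
    simulate_trial(15, 0.92, 0.25, seed = 7,
                   sequence_effects = c(1, -2, 3),
                   period_effects = c(0, 5, -4)),
    "contrast"
  )
  expect_within(shifted$pe, base$pe, 1e-10)
  expect_within(shifted$s2_wr, base$s2_wr, 1e-10)
  expect_within(shifted$se_pe, base$se_pe, 1e-10)
})

test_that("analysis rejects incomplete or degenerate trials", {
  tr <- toy_trial()
  expect_error(analyze_trial(tr[-1, ]), "periods 1, 2, 3")
  small <- dplyr::filter(tr, subject %in% c(1, 5, 9))
  expect_error(analyze_trial(small), "2 subjects per sequence")
  bad <- tr
  bad$treatment[1] <- "R"
  expect_error(analyze_trial(bad))
})

test_that("the generative model is unbiased for pe and s2_wr", {
  # law-of-large-numbers check against the generative parameters, using the
  # vectorised subject-level engine
  set.seed(31)
  raw <- nlivr:::draw_stats_subject_raw(30, 0.9, 0.2, 0.2, 4000, "pooled")
  sigma2 <- log(1.04)
  expect_within(mean(raw$pe), log(0.9), 3 * sd(raw$pe) / sqrt(4000))
  expect_within(mean(raw$s2_wr), sigma2, 3 * sd(raw$s2_wr) / sqrt(4000))
  expect_within(sd(raw$pe), sqrt(1.5 * sigma2 / 30), 0.05 * sd(raw$pe))
  # and through the full single-trial path on a smaller scale
  pes <- vapply(1:200, function(i) {
    analyze_trial(simulate_trial(30, 0.9, 0.2, seed = 5000 + i))$pe
  }, 0)
  expect_within(mean(pes), log(0.9), 3 * sd(pes) / sqrt(200))
})
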