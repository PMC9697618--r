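# Fast summary-statistic simulation engine: draws the sufficient statistics
# of an analysed 2x3x3 trial directly from their sampling laws instead of
# generating subject data. This is the engine used for large (n, CV) grids;
# the subject-level engine is the gold standard it is validated against.

#' Draw trial summary statistics directly from their sampling distributions
#'
#' For a homoscedastic 2x3x3 partial replicate trial with within-subject
#' log-scale variance `sigma^2 = log(1 + cv^2)`, the analysed statistics have
#' (exactly, under the additive normal model) the joint law
#'
#' * `pe ~ Normal(log(gmr), 1.5 * sigma^2 / n)` -- the 1.5 is the
#'   least-squares variance factor of the contrast `T - (R1 + R2)/2`;
#' * `s2_wr ~ sigma^2 * chisq(n - 3) / (n - 3)`, independent of `pe` (the
#'   reference differences `d_i` are uncorrelated with the treatment
#'   contrasts `c_i`);
#' * `se_pe^2 = 1.5 * mse / n`, where under the contrast analysis
#'   (`df_rule = "contrast"`) `mse ~ sigma^2 * chisq(n - 3) / (n - 3)`
#'   independent of the other two, and under the all-data ANOVA
#'   (`df_rule = "pooled"`) `mse = ((n - 3) * s2_wr +
#'   sigma^2 * chisq(n)) / (2n - 3)`, sharing the reference-difference
#'   channel with `s2_wr` exactly as the real ANOVA does.
#'
#' With these laws the engine reproduces the joint distribution of the
#' analysed subject-level trial exactly (balanced, homoscedastic case); the
#' engine-equivalence tests against the subject-level simulator check this
#' mechanically.
#'
#' Heteroscedastic scenarios (`cv_wt != cv_wr`) are not representable in this
#' engine; use the subject-level engine for those.
#'
#' @param n Total subjects (>= 6, divisible by 3).
#' @param gmr True geometric mean ratio.
#' @param cv Common within-subject CV (fraction) of test and reference.
#' @param nsims Number of replicate trials to draw.
#' @param seed Optional seed (caller's RNG state is restored).
#' @param df_rule `"pooled"` (default) or `"contrast"`, as in
#'   [analyze_trial()].
#' @return A tibble with `nsims` rows: `pe`, `se_pe`, `df_pe`, `s2_wr`,
#'   `df_wr`, `n`.
#' @seealso [simulate_trial()], [decide_be()], [estimate_power()].
#' @examples
#' draw_summary_stats(n = 24, gmr = 0.95, cv = 0.2, nsims = 5, seed = 1)
#' @export
draw_summary_stats <- function(n, gmr, cv, nsims, seed = NULL,
                               df_rule = c("pooled", "contrast")) {
  df_rule <- match.arg(df_rule)
  stopifnot(nsims >= 1)
  raw <- with_seed(seed, draw_stats_raw(n, gmr, cv, nsims, df_rule))
  tibble::tibble(
    pe = raw$pe, se_pe = raw$se, df_pe = raw$df,
    s2_wr = raw$s2_wr, df_wr = n - 3, n = n
  )
}

# raw vector version used in the hot loops (no tibble construction);
# assumes the caller has already arranged the RNG state.
#
# In the pooled rule the ANOVA mean square shares the reference-difference
# channel with s2_wr: mse = ((n-3) * s2_wr + sigma^2 * chisq(n)) / (2n - 3),
# which reproduces the exact joint law of the analysed subject-level trial
# (the chisq(n) part collects the treatment-contrast channel, n - 3 df, and
# the three mean-channel residual df). In the contrast rule s_c^2 really is
# independent of s2_wr (the c and d contrasts are uncorrelated), so the
# draws are independent there.
draw_stats_raw <- function(n, gmr, cv, nsims, df_rule) {
  stopifnot(length(n) == 1L, n >= 6, n %% 3 == 0, gmr > 0, cv >= 0)
  sigma2 <- log1p(cv^2)
  pe <- stats::rnorm(nsims, log(gmr), sqrt(1.5 * sigma2 / n))
  s2_wr <- sigma2 * stats::rchisq(nsims, n - 3) / (n - 3)
  if (df_rule == "pooled") {
    df <- 2 * n - 3
    mse <- ((n - 3) * s2_wr + sigma2 * stats::rchisq(nsims, n)) / df
  } else {
    df <- n - 3
    mse <- sigma2 * stats::rchisq(nsims, df) / df
  }
  list(pe = pe, se = sqrt(1.5 * mse / n), df = df, s2_wr = s2_wr)
}

# Subject-level batch engine: generates period-level within-subject errors
# for `nsims` balanced trials at once and runs the same estimators as
# analyze_trial() in vectorised form. Fixed sequence/period effects and the
# subject random effect are omitted because every statistic returned is
# exactly invariant to them (they cancel in the c and d channels); that
# invariance is asserted by tests on the single-trial path.
draw_stats_subject_raw <- function(n, gmr, cv_wr, cv_wt, nsims, df_rule) {
  stopifnot(n >= 6, n %% 3 == 0)
  m <- n / 3
  st <- cv2sd(cv_wt)
  sr <- cv2sd(cv_wr)
  eps_t <- matrix(stats::rnorm(n * nsims, 0, st), n, nsims)
  eps_r1 <- matrix(stats::rnorm(n * nsims, 0, sr), n, nsims)
  eps_r2 <- matrix(stats::rnorm(n * nsims, 0, sr), n, nsims)
  C <- log(gmr) + eps_t - (eps_r1 + eps_r2) / 2
  D <- eps_r1 - eps_r2
  g <- rep(1:3, each = m)
  cbar <- rowsum(C, g) / m                      # 3 x nsims sequence means
  dbar <- rowsum(D, g) / m
  ss_c <- colSums(C^2) - m * colSums(cbar^2)    # pooled within-sequence SS
  ss_d <- colSums(D^2) - m * colSums(dbar^2)
  pe <- colMeans(cbar)
  s2_wr <- ss_d / (2 * (n - 3))
  if (df_rule == "contrast") {
    se <- sqrt(ss_c / (n - 3) / n)
    df <- n - 3
  } else {
    w <- c(rep(m / 1.5, 3), rep(m / 2, 3))
    A <- METHOD_A_DESIGN
    W_A <- w * A
    M <- diag(w) - W_A %*% solve(crossprod(A, W_A), t(W_A))
    z <- rbind(cbar, dbar)
    q_extra <- colSums(z * (M %*% z))
    df <- 2 * n - 3
    mse <- (ss_c / 1.5 + ss_d / 2 + q_extra) / df
    se <- sqrt(1.5 * mse / n)
  }
  list(pe = pe, se = se, df = df, s2_wr = s2_wr)
}
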