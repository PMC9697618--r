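# Subject-level 2x3x3 partial replicate trials: simulation, analysis, CSV I/O.
#
# The design has three sequences TRR / RTR / RRT over three periods; every
# subject receives the reference twice, which is what makes s_WR estimable
# within the trial itself.

SEQUENCES <- c("TRR", "RTR", "RRT")

# run `expr` under `seed` without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit(
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  )
  set.seed(seed)
  expr
}

#' Simulate one 2x3x3 partial replicate bioequivalence trial
#'
#' Generates subject-level log-scale observations under the standard additive
#' crossover model: fixed sequence and period effects, a normal between-
#' subject random effect, a treatment effect of `log(gmr)` for the test
#' product, and normal within-subject error whose standard deviation is
#' `cv2sd(cv_wr)` for reference administrations and `cv2sd(cv_wt)` for the
#' test administration.
#'
#' Sequences are filled in balanced blocks of `n/3` subjects. All estimators
#' in [analyze_trial()] are invariant to the sequence and period effect
#' magnitudes (they cancel in the within-subject contrasts), so the defaults
#' of zero are harmless; nonzero values are accepted to exercise that
#' invariance.
#'
#' @param n Total number of subjects; at least 6 and divisible by 3.
#' @param gmr True test/reference ratio of geometric means.
#' @param cv_wr Within-subject CV of the reference product (fraction).
#' @param cv_wt Within-subject CV of the test product; defaults to `cv_wr`
#'   (homoscedasticity).
#' @param cv_between Between-subject CV (fraction) generating the subject
#'   random effect.
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards. Identical seeds give identical trials.
#' @param sequence_effects,period_effects Optional length-3 fixed effects on
#'   the log scale.
#' @return A tibble with one row per subject-period: columns `subject`
#'   (integer), `sequence` (`"TRR"`, `"RTR"`, `"RRT"`), `period` (1--3),
#'   `treatment` (`"T"` or `"R"`) and `log_value`.
#' @seealso [analyze_trial()], [draw_summary_stats()] for the fast
#'   summary-statistic engine.
#' @examples
#' trial <- simulate_trial(n = 12, gmr = 0.95, cv_wr = 0.2, seed = 1)
#' analyze_trial(trial)
#' @export
simulate_trial <- function(n, gmr, cv_wr, cv_wt = cv_wr, cv_between = 0.30,
                           seed = NULL,
                           sequence_effects = c(0, 0, 0),
                           period_effects = c(0, 0, 0)) {
  stopifnot(length(n) == 1L, n >= 6, gmr > 0, cv_wr >= 0, cv_wt >= 0,
            cv_between >= 0, length(sequence_effects) == 3L,
            length(period_effects) == 3L)
  if (n %% 3 != 0) {
    stop("balanced generation requires `n` divisible by 3", call. = FALSE)
  }
  with_seed(seed, {
    m <- n / 3
    seq_lab <- rep(SEQUENCES, each = m)
    subj_eff <- stats::rnorm(n, 0, cv2sd(cv_between))
    grid <- tidyr::expand_grid(subject = seq_len(n), period = 1:3)
    grid$sequence <- seq_lab[grid$subject]
    grid$treatment <- substr(grid$sequence, grid$period, grid$period)
    sd_w <- ifelse(grid$treatment == "T", cv2sd(cv_wt), cv2sd(cv_wr))
    grid$log_value <-
      sequence_effects[match(grid$sequence, SEQUENCES)] +
      period_effects[grid$period] +
      subj_eff[grid$subject] +
      ifelse(grid$treatment == "T", log(gmr), 0) +
      stats::rnorm(nrow(grid), 0, sd_w)
    dplyr::select(grid, "subject", "sequence", "period", "treatment",
                  "log_value")
  })
}

#' Analyse a 2x3x3 trial into the sufficient statistics of the BE decision
#'
#' Reduces subject-level data to the quantities the TOST decision needs: the
#' log-scale point estimate of the test-reference difference with its
#' standard error and degrees of freedom, and the within-subject reference
#' variance `s2_wr` with its degrees of freedom.
#'
#' Each subject contributes two within-subject contrasts: the
#' treatment contrast `c_i = logT - (logR1 + logR2)/2` and the reference
#' difference `d_i = logR1 - logR2` (period order). Both are free of subject
#' and sequence effects; period effects cancel within sequence. Always,
#' `s2_wr` is the pooled within-sequence variance of `d_i` divided by 2, with
#' `n - 3` degrees of freedom, and the point estimate is the unweighted mean
#' of the per-sequence means of `c_i` (for a balanced trial this attains the
#' least-squares variance `1.5 * sigma^2 / n`).
#'
#' Two conventions are offered for the standard error of the point estimate:
#'
#' * `df_rule = "pooled"` (default): the all-data fixed-effects ANOVA
#'   (treatment + period + subject), whose residual mean square pools the
#'   `c` and `d` channels and carries `2n - 3` degrees of freedom. This is
#'   the convention under which published sample-size tables for this design
#'   were generated, and it is reproduced here exactly (it equals `lm()` on
#'   the full data) via the orthogonal channel decomposition.
#' * `df_rule = "contrast"`: the pooled within-sequence variance of `c_i`
#'   alone, with `n - 3` degrees of freedom -- a self-contained analysis of
#'   the treatment contrasts.
#'
#' @param data A tibble in the [simulate_trial()] layout. Unbalanced
#'   sequences are accepted (at least 2 subjects per sequence); incomplete
#'   subjects are an error -- there is no imputation.
#' @param df_rule `"pooled"` or `"contrast"` (see Details).
#' @return A one-row tibble: `pe` (log scale), `se_pe`, `df_pe`, `s2_wr`,
#'   `df_wr`, `n`.
#' @examples
#' analyze_trial(simulate_trial(12, 0.95, 0.2, seed = 1))
#' @export
analyze_trial <- function(data, df_rule = c("pooled", "contrast")) {
  df_rule <- match.arg(df_rule)
  ch <- trial_channels(data)
  n <- ch$n
  ns <- ch$ns
  # pooled within-sequence sums of squares of the two channels
  ss_c <- sum((ch$c - ch$cbar[ch$seq_idx])^2)
  ss_d <- sum((ch$d - ch$dbar[ch$seq_idx])^2)
  s2_wr <- ss_d / (2 * (n - 3))
  pe <- mean(ch$cbar)
  if (df_rule == "contrast") {
    s_c2 <- ss_c / (n - 3)
    se_pe <- sqrt(s_c2 * sum(1 / ns)) / 3
    df_pe <- n - 3
  } else {
    fit <- method_a_fit(ch$cbar, ch$dbar, ns, ss_c, ss_d)
    pe <- fit$pe
    se_pe <- fit$se_pe
    df_pe <- fit$df_pe
  }
  tibble::tibble(pe = pe, se_pe = se_pe, df_pe = df_pe,
                 s2_wr = s2_wr, df_wr = n - 3, n = n)
}

# Validate a trial tibble and reduce it to per-subject channels
# c = T - (R1+R2)/2 and d = R1 - R2 (period order), with sequence bookkeeping.
trial_channels <- function(data) {
  req <- c("subject", "sequence", "period", "treatment", "log_value")
  if (!all(req %in% names(data))) {
    stop("trial data must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(data$sequence %in% SEQUENCES)) {
    stop("`sequence` must be one of TRR, RTR, RRT", call. = FALSE)
  }
  wide <- data |>
    dplyr::arrange(.data$subject, .data$period) |>
    dplyr::group_by(.data$subject)
  counts <- dplyr::summarise(
    wide,
    k = dplyr::n(),
    n_t = sum(.data$treatment == "T"),
    seqs = dplyr::n_distinct(.data$sequence),
    ok_periods = length(.data$period) == 3L &&
      isTRUE(all(sort(.data$period) == 1:3)),
    .groups = "drop"
  )
  if (any(counts$k != 3L) || !all(counts$ok_periods)) {
    stop("every subject must have exactly periods 1, 2, 3 (no imputation)",
         call. = FALSE)
  }
  if (any(counts$n_t != 1L) || any(counts$seqs != 1L)) {
    stop("every subject must have one T and two R administrations in a ",
         "single sequence", call. = FALSE)
  }
  per_subj <- dplyr::summarise(
    wide,
    sequence = .data$sequence[1],
    c = .data$log_value[.data$treatment == "T"] -
      mean(.data$log_value[.data$treatment == "R"]),
    d = diff(rev(.data$log_value[.data$treatment == "R"])),
    .groups = "drop"
  )
  # check treatment labels agree with the sequence pattern
  pat <- data |>
    dplyr::arrange(.data$subject, .data$period) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(pat = paste(.data$treatment, collapse = ""),
                     sequence = .data$sequence[1], .groups = "drop")
  if (!all(pat$pat == pat$sequence)) {
    stop("treatment labels do not match the sequence pattern", call. = FALSE)
  }
  seq_idx <- match(per_subj$sequence, SEQUENCES)
  ns <- tabulate(seq_idx, nbins = 3L)
  if (any(ns < 2L)) {
    stop("at least 2 subjects per sequence are required to estimate ",
         "variances", call. = FALSE)
  }
  cbar <- as.numeric(tapply(per_subj$c, factor(seq_idx, levels = 1:3), mean))
  dbar <- as.numeric(tapply(per_subj$d, factor(seq_idx, levels = 1:3), mean))
  list(n = nrow(per_subj), ns = ns, seq_idx = seq_idx,
       c = per_subj$c, d = per_subj$d, cbar = cbar, dbar = dbar)
}

# Expected values of the six sequence-channel means under the fixed-effects
# model, parameterised by (treatment effect tau, period effects p2, p3):
# rows are (c_TRR, c_RTR, c_RRT, d_TRR, d_RTR, d_RRT).
METHOD_A_DESIGN <- matrix(c(
  1, -0.5, -0.5,
  1,  1.0, -0.5,
  1, -0.5,  1.0,
  0,  1.0, -1.0,
  0,  0.0, -1.0,
  0, -1.0,  0.0
), nrow = 6, byrow = TRUE)

# Exact all-data ANOVA (y ~ treatment + period + subject) computed from the
# channel decomposition: the per-subject contrasts c/sqrt(1.5) and d/sqrt(2)
# are an orthonormal basis of each subject's centred 2-dim space, so the
# residual SS is the pooled within-sequence SS of both channels plus the
# weighted residual of the six channel means under the 3-parameter model.
# Agrees with lm() to machine precision (tested).
method_a_fit <- function(cbar, dbar, ns, ss_c, ss_d) {
  n <- sum(ns)
  w <- c(ns / 1.5, ns / 2)          # channel-mean weights, 1/sigma^2 units
  A <- METHOD_A_DESIGN
  z <- c(cbar, dbar)
  AtWA <- crossprod(A, w * A)
  V <- solve(AtWA)
  beta <- V %*% crossprod(A, w * z)
  resid <- z - as.numeric(A %*% beta)
  q_extra <- sum(w * resid^2)
  df_pe <- 2 * n - 3
  mse <- (ss_c / 1.5 + ss_d / 2 + q_extra) / df_pe
  list(pe = beta[1], se_pe = sqrt(mse * V[1, 1]), df_pe = df_pe, mse = mse)
}

#' Read or write subject-level trial data as CSV
#'
#' The dialect is a UTF-8 CSV with header and columns
#' `subject,sequence,period,treatment,log_value`, with `period` in 1--3,
#' `treatment` in `{T, R}` and `sequence` in `{TRR, RTR, RRT}`.
#'
#' @param path File path.
#' @return `read_trial_csv()` returns a validated trial tibble;
#'   `write_trial_csv()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trial_csv(simulate_trial(6, 1, 0.1, seed = 1), f)
#' read_trial_csv(f)
#' @export
read_trial_csv <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_integer(),
      sequence = readr::col_character(),
      period = readr::col_integer(),
      treatment = readr::col_character(),
      log_value = readr::col_double()
    )
  )
  invisible(trial_channels(data))  # validation only
  data
}

#' @rdname read_trial_csv
#' @param data A trial tibble in the [simulate_trial()] layout.
#' @export
write_trial_csv <- function(data, path) {
  invisible(trial_channels(data))  # refuse to write a malformed trial
  readr::write_csv(data, path)
  invisible(path)
}
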