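# Acceptance-limit geometry for reference-variability-narrowed bioequivalence
# limits (NLIVR) and its fixed-limit special cases.

#' Convert a within-subject CV to a log-scale standard deviation
#'
#' Pharmacokinetic metrics (AUC, Cmax) are analysed on the log scale, where a
#' within-subject coefficient of variation `cv` (as a fraction, e.g. `0.30`)
#' corresponds to the standard deviation `sqrt(log(1 + cv^2))`.
#'
#' @param cv Within-subject coefficient of variation, as a fraction (`>= 0`).
#'   Vectorised.
#' @return Log-scale standard deviation(s), same length as `cv`.
#' @seealso [sd2cv()] for the inverse.
#' @examples
#' cv2sd(0.30)    # 0.29356
#' cv2sd(0.1393)  # 0.1386
#' @export
cv2sd <- function(cv) {
  if (!is.numeric(cv) || anyNA(cv) || any(cv < 0)) {
    stop("`cv` must be a non-negative numeric vector", call. = FALSE)
  }
  sqrt(log1p(cv^2))
}

#' Convert a log-scale standard deviation to a within-subject CV
#'
#' Inverse of [cv2sd()]: `sqrt(exp(sd^2) - 1)`.
#'
#' @param sd Log-scale standard deviation (`>= 0`). Vectorised.
#' @return Coefficient(s) of variation as fractions.
#' @examples
#' sd2cv(0.29356)  # 0.30
#' @export
sd2cv <- function(sd) {
  if (!is.numeric(sd) || anyNA(sd) || any(sd < 0)) {
    stop("`sd` must be a non-negative numeric vector", call. = FALSE)
  }
  sqrt(expm1(sd^2))
}

#' Define a narrowed-limits (NLIVR) acceptance criterion
#'
#' Constructs the decision rule for average bioequivalence with acceptance
#' limits narrowed in proportion to the within-subject standard deviation of
#' the reference product, `s_WR`, estimated in the same replicate trial:
#'
#' * `s_WR <= sd_switch_lower` (default 0.1386, i.e. CV 13.93%): the fixed
#'   tighter range 90.00--111.11% applies;
#' * `s_WR >= cv2sd(cv_switch_upper)` (default CV 30%, `s_WR` 0.29356): the
#'   conventional range 80.00--125.00% applies;
#' * in between: `[L, U] = exp(-/+ k * s_WR)` with regulatory constant
#'   `k = 0.760`, which makes the rule continuous at both switch points.
#'
#' Optionally the rule also requires the GMR point estimate itself to lie
#' within `pe_constraint_limits` (default 90.00--111.11%).
#'
#' The lower switch point is stored as an exact log-scale standard deviation
#' (0.1386); the equivalent CV prints as either 13.92% or 13.93% depending on
#' rounding direction, and membership at the switch values themselves takes
#' the non-scaled regime (`<=` lower gives the floor, `>=` upper the cap).
#'
#' @param k Regulatory proportionality constant (dimensionless).
#' @param sd_switch_lower Lower switch point on the `s_WR` scale. Overridden
#'   by `cv_switch_lower` when that is supplied.
#' @param cv_switch_lower Optional lower switch point as a CV fraction.
#' @param cv_switch_upper Upper switch point as a CV fraction.
#' @param floor_limits Length-2 acceptance range applied below the lower
#'   switch; must be reciprocal (log-symmetric).
#' @param cap_limits Length-2 acceptance range applied above the upper switch.
#' @param pe_constraint Logical; additionally require the GMR point estimate
#'   inside `pe_constraint_limits`?
#' @param pe_constraint_limits Length-2 range for the point-estimate
#'   constraint.
#' @param alpha One-sided significance level of the TOST procedure (the
#'   confidence interval has level `1 - 2 * alpha`).
#' @return An object of class `be_criterion`.
#' @seealso [fixed_criterion()] for plain fixed-limit average bioequivalence,
#'   [acceptance_limits()], [decide_be()].
#' @examples
#' crit <- nlivr_criterion()
#' acceptance_limits(cv2sd(c(0.10, 0.20, 0.35)), crit)
#' @export
nlivr_criterion <- function(k = 0.760,
                            sd_switch_lower = 0.1386,
                            cv_switch_lower = NULL,
                            cv_switch_upper = 0.30,
                            floor_limits = c(0.90, 1 / 0.90),
                            cap_limits = c(0.80, 1.25),
                            pe_constraint = FALSE,
                            pe_constraint_limits = c(0.90, 1 / 0.90),
                            alpha = 0.05) {
  if (!is.null(cv_switch_lower)) sd_switch_lower <- cv2sd(cv_switch_lower)
  new_be_criterion(
    k = k,
    sd_lower = sd_switch_lower,
    sd_upper = cv2sd(cv_switch_upper),
    floor_limits = sort(floor_limits),
    cap_limits = sort(cap_limits),
    pe_constraint = isTRUE(pe_constraint),
    pe_constraint_limits = sort(pe_constraint_limits),
    alpha = alpha,
    label = if (isTRUE(pe_constraint)) "nlivr+pe" else "nlivr"
  )
}

#' Define a fixed-limit average bioequivalence criterion
#'
#' The non-scaled comparator: the acceptance range never depends on the
#' estimated `s_WR`. With the default `limits` this is the current EMA rule
#' for narrow therapeutic index drugs (tighter 90.00--111.11% range); with
#' `limits = c(0.80, 1.25)` it is conventional average bioequivalence.
#'
#' Internally this is the degenerate case of the scaled rule in which both
#' switch points coincide, so scaling never occurs.
#'
#' @inheritParams nlivr_criterion
#' @param limits Length-2 fixed acceptance range.
#' @return An object of class `be_criterion`.
#' @examples
#' fixed_criterion()                  # EMA NTI tighter limits
#' fixed_criterion(c(0.80, 1.25))     # conventional ABE
#' @export
fixed_criterion <- function(limits = c(0.90, 1 / 0.90),
                            pe_constraint = FALSE,
                            pe_constraint_limits = c(0.90, 1 / 0.90),
                            alpha = 0.05) {
  new_be_criterion(
    k = 0.760,
    sd_lower = Inf,
    sd_upper = Inf,
    floor_limits = sort(limits),
    cap_limits = sort(limits),
    pe_constraint = isTRUE(pe_constraint),
    pe_constraint_limits = sort(pe_constraint_limits),
    alpha = alpha,
    label = if (isTRUE(pe_constraint)) "fixed+pe" else "fixed"
  )
}

# low-level constructor + validation
new_be_criterion <- function(k, sd_lower, sd_upper, floor_limits, cap_limits,
                             pe_constraint, pe_constraint_limits, alpha,
                             label) {
  stopifnot(
    is.numeric(k), length(k) == 1L, k > 0,
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 0.5,
    length(floor_limits) == 2L, length(cap_limits) == 2L,
    length(pe_constraint_limits) == 2L,
    sd_lower >= 0, sd_upper >= sd_lower
  )
  check_log_symmetric <- function(lim, what) {
    if (abs(log(lim[1]) + log(lim[2])) > 1e-12) {
      stop(sprintf("`%s` must be reciprocal (log-symmetric): got (%g, %g)",
                   what, lim[1], lim[2]), call. = FALSE)
    }
  }
  check_log_symmetric(floor_limits, "floor_limits")
  check_log_symmetric(cap_limits, "cap_limits")
  check_log_symmetric(pe_constraint_limits, "pe_constraint_limits")
  if (is.finite(sd_lower) && sd_lower >= sd_upper) {
    stop("lower switch point must lie below the upper switch point",
         call. = FALSE)
  }
  structure(
    list(
      k = k, sd_lower = sd_lower, sd_upper = sd_upper,
      floor_limits = floor_limits, cap_limits = cap_limits,
      pe_constraint = pe_constraint,
      pe_constraint_limits = pe_constraint_limits,
      alpha = alpha, label = label
    ),
    class = "be_criterion"
  )
}

#' @export
print.be_criterion <- function(x, ...) {
  pct <- function(v) sprintf("%.2f-%.2f%%", 100 * trunc2(v[1]), 100 * trunc2(v[2]))
  cat("<be_criterion> ", x$label, "\n", sep = "")
  if (is.finite(x$sd_lower)) {
    cat(sprintf("  limits exp(+/- %.3f * s_WR), floored at %s (s_WR <= %.4f)\n",
                x$k, pct(x$floor_limits), x$sd_lower))
    cat(sprintf("  capped at %s (s_WR >= %.5f, CV %.2f%%)\n",
                pct(x$cap_limits), x$sd_upper, 100 * sd2cv(x$sd_upper)))
  } else {
    cat(sprintf("  fixed limits %s\n", pct(x$floor_limits)))
  }
  if (x$pe_constraint) {
    cat(sprintf("  point-estimate constraint: GMR in %s\n",
                pct(x$pe_constraint_limits)))
  }
  cat(sprintf("  one-sided alpha = %.3g (%.0f%% CI)\n",
              x$alpha, 100 * (1 - 2 * x$alpha)))
  invisible(x)
}

# truncate (not round) a ratio to 4 decimals for percent display, the
# convention that turns 1/0.9 into 111.11%
trunc2 <- function(x) trunc(x * 1e4) / 1e4

is_be_criterion <- function(x) inherits(x, "be_criterion")

assert_criterion <- function(criterion) {
  if (!is_be_criterion(criterion)) {
    stop("`criterion` must be created by nlivr_criterion() or fixed_criterion()",
         call. = FALSE)
  }
  criterion
}

#' Acceptance limits implied by a within-subject standard deviation
#'
#' Evaluates the acceptance range a criterion applies for a given (usually
#' estimated) within-subject standard deviation of the reference product.
#' The returned range is always log-symmetric, its width is non-decreasing in
#' `s_wr`, and the `regime` column records which branch applied.
#'
#' @param s_wr Log-scale within-subject standard deviation(s) of the
#'   reference product (`>= 0`). Vectorised.
#' @param criterion A [nlivr_criterion()] or [fixed_criterion()] object.
#' @return A tibble with columns `s_wr`, `lower`, `upper` (ratio scale) and
#'   `regime` (one of `"floor"`, `"scaled"`, `"cap"`).
#' @examples
#' acceptance_limits(c(0.10, 0.20, 0.35), nlivr_criterion())
#' @export
acceptance_limits <- function(s_wr, criterion = nlivr_criterion()) {
  assert_criterion(criterion)
  if (!is.numeric(s_wr) || anyNA(s_wr) || any(s_wr < 0)) {
    stop("`s_wr` must be a non-negative numeric vector", call. = FALSE)
  }
  log_u <- log_upper_limit(s_wr, criterion)
  regime <- dplyr::case_when(
    s_wr <= criterion$sd_lower ~ "floor",
    s_wr >= criterion$sd_upper ~ "cap",
    TRUE ~ "scaled"
  )
  tibble::tibble(
    s_wr = s_wr,
    lower = exp(-log_u),
    upper = exp(log_u),
    regime = regime
  )
}

# log of the upper acceptance limit; the workhorse shared with the
# vectorised decision core (lower limit is its negation by construction)
log_upper_limit <- function(s_wr, criterion) {
  ifelse(
    s_wr <= criterion$sd_lower, log(criterion$floor_limits[2]),
    ifelse(
      s_wr >= criterion$sd_upper, log(criterion$cap_limits[2]),
      criterion$k * s_wr
    )
  )
}

#' Null-boundary GMR for type-I-error estimation
#'
#' The true GMR that sits exactly on the lower acceptance limit implied by
#' the *true* within-subject variability: 0.90 below the lower switch,
#' `exp(-k * s_WR)` between the switches, 0.80 at or above the upper switch
#' (with default limits). Simulating at this GMR probes the consumer's risk
#' of the procedure.
#'
#' @param cv True within-subject CV of the reference product (fraction,
#'   `> 0`). Vectorised.
#' @inheritParams acceptance_limits
#' @return Ratio(s): the boundary GMR for each `cv`.
#' @examples
#' t1e_true_gmr(c(0.10, 0.20, 0.35))
#' @export
t1e_true_gmr <- function(cv, criterion = nlivr_criterion()) {
  assert_criterion(criterion)
  if (!is.numeric(cv) || anyNA(cv) || any(cv <= 0)) {
    stop("`cv` must be a positive numeric vector", call. = FALSE)
  }
  exp(-log_upper_limit(cv2sd(cv), criterion))
}
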