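# Exact TOST power (Owen's Q) for fixed limits and sample-size searches.

#' Owen's Q function
#'
#' The bivariate integral underlying exact TOST power,
#' \deqn{Q(\nu, t, \delta; 0, b) = \int_0^b \Phi\!\left(\frac{t x}{\sqrt\nu}
#'   - \delta\right) \frac{x^{\nu-1} e^{-x^2/2}}{\Gamma(\nu/2)\,
#'   2^{\nu/2 - 1}} \, dx,}
#' computed by adaptive quadrature to an absolute tolerance of 1e-10. With
#' `b = Inf` it equals the noncentral-t distribution function
#' `pt(t, df, ncp = delta)`.
#'
#' @param df Degrees of freedom (>= 1).
#' @param t Quantile of the t statistic.
#' @param delta Noncentrality parameter.
#' @param b Upper integration bound (>= 0, possibly `Inf`).
#' @return A probability mass in `[0, 1]`.
#' @examples
#' owens_q(10, 2, 1, Inf)
#' pt(2, 10, ncp = 1)
#' @export
owens_q <- function(df, t, delta, b) {
  stopifnot(df >= 1, b >= 0, is.finite(t) || b == 0, is.finite(delta) || b == 0)
  if (b == 0) return(0)
  lognc <- lgamma(df / 2) + (df / 2 - 1) * log(2)
  integrand <- function(x) {
    stats::pnorm(t * x / sqrt(df) - delta) *
      exp((df - 1) * log(x) - x^2 / 2 - lognc)
  }
  # the chi weight concentrates near sqrt(df - 1); integrate piecewise so
  # adaptive quadrature never misses the mass for large df or large b
  mode <- sqrt(max(df - 1, 1))
  cuts <- sort(unique(pmin(c(0, mode / 2, mode * c(1, 2, 4)), b)))
  if (is.finite(b)) cuts <- unique(c(cuts, b)) else cuts <- c(cuts, Inf)
  val <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    val <- val + stats::integrate(integrand, cuts[i], cuts[i + 1L],
                                  rel.tol = 1e-12, abs.tol = 1e-10,
                                  stop.on.error = TRUE)$value
  }
  min(max(val, 0), 1)
}

#' Exact TOST power for fixed acceptance limits
#'
#' Probability that both one-sided tests reject, i.e. that the
#' `1 - 2 * alpha` confidence interval falls inside fixed limits `(L, U)`,
#' expressed as a difference of two Owen's Q terms with noncentralities
#' `(log(gmr) - log(L)) / se` and `(log(gmr) - log(U)) / se`, where
#' `se = sqrt(design_const * log(1 + cv^2) / n)`. For the 2x3x3 partial
#' replicate design the constant is 1.5 and the default degrees of freedom
#' follow the all-data ANOVA (`2n - 3`).
#'
#' @param n Total subjects.
#' @param gmr True geometric mean ratio.
#' @param cv Within-subject CV (fraction).
#' @param limits Length-2 fixed acceptance range (ratio scale).
#' @param alpha One-sided significance level.
#' @param design_const Variance factor of the point estimate.
#' @param df_rule `"pooled"` (`df = 2n - 3`) or `"contrast"` (`df = n - 3`).
#' @return The exact power, in `[0, 1]` (a negative Owen's-Q difference,
#'   which arises when the two one-sided rejection regions are incompatible,
#'   is clipped to 0 with a warning).
#' @examples
#' exact_tost_power(n = 24, gmr = 1, cv = 0.15, limits = c(0.9, 1 / 0.9))
#' @export
exact_tost_power <- function(n, gmr, cv, limits = c(0.90, 1 / 0.90),
                             alpha = 0.05, design_const = 1.5,
                             df_rule = c("pooled", "contrast")) {
  df_rule <- match.arg(df_rule)
  limits <- sort(limits)
  if (limits[1] >= limits[2]) stop("degenerate limits", call. = FALSE)
  stopifnot(n >= 6, gmr > 0, cv > 0, alpha > 0, alpha < 0.5)
  df <- if (df_rule == "pooled") 2 * n - 3 else n - 3
  se <- sqrt(design_const * log1p(cv^2) / n)
  tval <- stats::qt(1 - alpha, df)
  d1 <- (log(gmr) - log(limits[1])) / se
  d2 <- (log(gmr) - log(limits[2])) / se
  r <- (d1 - d2) * sqrt(df) / (2 * tval)
  pw <- owens_q(df, -tval, d2, r) - owens_q(df, tval, d1, r)
  if (pw < -1e-9) {
    warning("incompatible one-sided rejection regions; power clipped to 0",
            call. = FALSE)
  }
  min(max(pw, 0), 1)
}

#' Sample size for fixed acceptance limits (exact method)
#'
#' Smallest total `n`, divisible by 3, whose [exact_tost_power()] reaches
#' `target_power`. With the default tighter limits this reproduces the
#' sample sizes of the current fixed-limit rule for NTI drugs.
#'
#' @inheritParams exact_tost_power
#' @param target_power Required power, in (0, 1).
#' @return A `be_sample_size` object; see [tidy.be_sample_size()].
#' @examples
#' sample_size_fixed(gmr = 0.95, cv = 0.1)
#' @export
sample_size_fixed <- function(gmr, cv, limits = c(0.90, 1 / 0.90),
                              alpha = 0.05, target_power = 0.80,
                              design_const = 1.5,
                              df_rule = c("pooled", "contrast")) {
  df_rule <- match.arg(df_rule)
  limits <- sort(limits)
  stopifnot(target_power > 0, target_power < 1)
  margin <- min(log(limits[2]) - log(gmr), log(gmr) - log(limits[1]))
  if (margin <= 0) {
    stop("`gmr` lies on or outside the acceptance limits: no finite sample ",
         "size achieves the target power", call. = FALSE)
  }
  pw <- function(n) exact_tost_power(n, gmr, cv, limits, alpha, design_const,
                                     df_rule)
  # large-sample starting value, then a step-3 scan to the exact minimum
  zb <- if (abs(log(gmr)) < 1e-12) {
    stats::qnorm((1 + target_power) / 2)
  } else {
    stats::qnorm(target_power)
  }
  n0 <- design_const * log1p(cv^2) * ((stats::qnorm(1 - alpha) + zb) / margin)^2
  n <- max(6L, as.integer(ceiling(n0 / 3)) * 3L)
  while (n > 6L && pw(n - 3L) >= target_power) n <- n - 3L
  while (pw(n) < target_power) n <- n + 3L
  new_be_sample_size(
    n = n, achieved_power = pw(n), target_power = target_power,
    method = "exact", gmr = gmr, cv = cv, criterion_label = "fixed",
    df_rule = df_rule, nsims = NA_real_, seed = NA_integer_
  )
}

#' Sample size for a scaled criterion (simulation-based search)
#'
#' Smallest total `n`, divisible by 3, whose Monte-Carlo power under the
#' given criterion reaches `target_power`. The search starts from the exact
#' fixed-limit sample size computed at the acceptance range implied by the
#' *true* variability, brackets the target by doubling/halving in balanced
#' steps, then refines linearly in steps of 3, so the returned `n` also
#' satisfies `power(n - 3) < target` under the same seed policy.
#'
#' Each candidate `n` is evaluated on its own RNG substream derived from
#' `seed` and `n`, making candidate evaluations independent yet fully
#' reproducible. When the accepted estimate lies within one Monte-Carlo
#' standard error of the target, that candidate is re-evaluated with four
#' times `nsims` before being accepted, which guards the minimality property
#' against simulation noise near the power boundary.
#'
#' @inheritParams estimate_power
#' @param cv Common within-subject CV (fraction) of test and reference.
#' @param target_power Required power, in (0, 1).
#' @param n_max Largest sample size tried before declaring the target
#'   unreachable.
#' @return A `be_sample_size` object.
#' @examples
#' sample_size_scaled(gmr = 1, cv = 0.15, nsims = 1e4, seed = 1)
#' @export
sample_size_scaled <- function(gmr, cv, criterion = nlivr_criterion(),
                               target_power = 0.80, nsims = 1e5, seed = 1,
                               n_max = 999L,
                               engine = c("summary", "subject"),
                               df_rule = c("pooled", "contrast")) {
  engine <- match.arg(engine)
  df_rule <- match.arg(df_rule)
  assert_criterion(criterion)
  stopifnot(target_power > 0, target_power < 1, gmr > 0, cv > 0, nsims >= 1e3)
  pw <- function(n, times = 1) {
    with_seed(derive_seed(seed, n, times),
              power_once(n, gmr, cv, cv, criterion, nsims * times, engine,
                         df_rule))
  }
  bal <- function(n) max(6L, as.integer(ceiling(n / 3)) * 3L)
  # starting guess: exact power at the range the true s_WR implies
  true_lim <- acceptance_limits(cv2sd(cv), criterion)
  n0 <- tryCatch(
    sample_size_fixed(gmr, cv, c(true_lim$lower, true_lim$upper),
                      alpha = criterion$alpha, target_power = target_power,
                      df_rule = df_rule)$n,
    error = function(e) 6L
  )
  n0 <- min(bal(n0), bal(n_max))
  # bracket by doubling/halving in balanced steps
  lo <- NULL  # largest n known below target
  hi <- NULL  # smallest n known at/above target
  n <- n0
  repeat {
    p <- pw(n)
    if (p >= target_power) {
      hi <- n
      if (n <= 6L) break
      n_dn <- bal(n / 2)
      if (!is.null(lo) || n_dn >= n) break
      n <- n_dn
    } else {
      lo <- n
      if (!is.null(hi)) break
      n_up <- bal(n * 2)
      if (n_up > n_max) {
        if (pw(bal(n_max)) >= target_power) {
          hi <- bal(n_max)
          break
        }
        stop("target power unreachable with n <= ", n_max, call. = FALSE)
      }
      n <- n_up
    }
  }
  lo <- if (is.null(lo)) 3L else lo
  # linear refinement: first balanced n above `lo` meeting the target
  n <- lo + 3L
  repeat {
    if (n > n_max) stop("target power unreachable with n <= ", n_max,
                        call. = FALSE)
    p <- pw(n)
    if (p >= target_power) {
      mc <- sqrt(p * (1 - p) / nsims)
      if (p - target_power < mc) {
        p4 <- pw(n, times = 4)       # confirmatory pass near the boundary
        if (p4 < target_power) {
          n <- n + 3L
          next
        }
        p <- p4
      }
      break
    }
    n <- n + 3L
  }
  new_be_sample_size(
    n = as.integer(n), achieved_power = p, target_power = target_power,
    method = "simulated", gmr = gmr, cv = cv,
    criterion_label = criterion$label, df_rule = df_rule, nsims = nsims,
    seed = seed
  )
}

#' Sweep sample sizes over GMR and CV values
#'
#' Maps [sample_size_scaled()] (or, for a fixed-limit criterion without
#' point-estimate constraint, the exact [sample_size_fixed()]) over the
#' cross product of `gmr` and `cv`, returning a tidy table -- the form in
#' which sample-size requirements for this design are usually published.
#'
#' @inheritParams sample_size_scaled
#' @param gmr,cv Vectors of true GMRs and CVs to cross.
#' @return A tibble with columns `gmr`, `cv`, `n`, `achieved_power`,
#'   `target_power`, `method`, `criterion`.
#' @examples
#' sample_size_table(gmr = c(1, 0.95), cv = c(0.1, 0.2),
#'                   criterion = fixed_criterion())
#' @export
sample_size_table <- function(gmr, cv, criterion = nlivr_criterion(),
                              target_power = 0.80, nsims = 1e5, seed = 1,
                              n_max = 999L,
                              df_rule = c("pooled", "contrast")) {
  df_rule <- match.arg(df_rule)
  assert_criterion(criterion)
  use_exact <- !is.finite(criterion$sd_lower) && !criterion$pe_constraint
  grid <- tidyr::expand_grid(gmr = gmr, cv = cv)
  purrr::pmap(grid, function(gmr, cv) {
    res <- if (use_exact) {
      sample_size_fixed(gmr, cv, criterion$floor_limits,
                        alpha = criterion$alpha,
                        target_power = target_power, df_rule = df_rule)
    } else {
      sample_size_scaled(gmr, cv, criterion, target_power = target_power,
                         nsims = nsims, seed = seed, n_max = n_max,
                         df_rule = df_rule)
    }
    tidy(res)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(criterion = criterion$label)
}

new_be_sample_size <- function(n, achieved_power, target_power, method, gmr,
                               cv, criterion_label, df_rule, nsims, seed) {
  structure(
    list(n = n, achieved_power = achieved_power,
         target_power = target_power, method = method, gmr = gmr, cv = cv,
         criterion_label = criterion_label, df_rule = df_rule, nsims = nsims,
         seed = seed),
    class = "be_sample_size"
  )
}

#' @export
print.be_sample_size <- function(x, ...) {
  cat(sprintf(
    "<be_sample_size> n = %d subjects (%s)\n  gmr %.4g, CV %.3g%%, target power %.0f%%, achieved %.4f\n",
    x$n, x$method, x$gmr, 100 * x$cv, 100 * x$target_power,
    x$achieved_power))
  if (x$method == "simulated") {
    cat(sprintf("  criterion %s, %g sims/candidate, seed %s\n",
                x$criterion_label, x$nsims, format(x$seed)))
  }
  invisible(x)
}

#' Tidy a sample-size result
#'
#' @param x A `be_sample_size` object.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble with the scenario and the
#'   resulting `n`; `glance()` adds the search settings.
#' @method tidy be_sample_size
#' @export
tidy.be_sample_size <- function(x, ...) {
  tibble::tibble(
    gmr = x$gmr, cv = x$cv, n = x$n, achieved_power = x$achieved_power,
    target_power = x$target_power, method = x$method
  )
}

#' @rdname tidy.be_sample_size
#' @method glance be_sample_size
#' @export
glance.be_sample_size <- function(x, ...) {
  dplyr::mutate(tidy(x), criterion = x$criterion_label, df_rule = x$df_rule,
                nsims = x$nsims, seed = x$seed)
}
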