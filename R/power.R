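# Monte-Carlo power and type-I-error estimation over (n, CV) grids.

#' Monte-Carlo power of a bioequivalence criterion for one scenario
#'
#' Simulates `nsims` trials at the given true parameters, applies the
#' decision rule to each, and returns the proportion concluding
#' bioequivalence together with its binomial Monte-Carlo standard error.
#'
#' @param n Total subjects (divisible by 3).
#' @param gmr True geometric mean ratio.
#' @param cv_wr True within-subject CV of the reference (fraction).
#' @param criterion A [nlivr_criterion()] or [fixed_criterion()] object.
#' @param nsims Number of simulated trials (>= 1000; a warning is issued
#'   below 1e5, where grid cells become visibly noisy).
#' @param seed Optional seed; identical seeds reproduce the estimate.
#' @param engine `"summary"` for the summary-statistic engine (fast,
#'   homoscedastic only) or `"subject"` for the subject-level gold standard.
#' @param df_rule Degrees-of-freedom convention, see [analyze_trial()].
#' @param cv_wt Within-subject CV of the test product; only the subject
#'   engine accepts a value different from `cv_wr`.
#' @return A one-row tibble: `criterion`, `engine`, `n`, `cv`, `gmr`,
#'   `nsims`, `prop_be`, `mc_se`.
#' @seealso [be_power()] to sweep a grid of scenarios, [estimate_t1e()].
#' @examples
#' estimate_power(n = 24, gmr = 0.95, cv_wr = 0.15, nsims = 1e4, seed = 1)
#' @export
estimate_power <- function(n, gmr, cv_wr, criterion = nlivr_criterion(),
                           nsims = 1e5, seed = NULL,
                           engine = c("summary", "subject"),
                           df_rule = c("pooled", "contrast"),
                           cv_wt = cv_wr) {
  engine <- match.arg(engine)
  df_rule <- match.arg(df_rule)
  assert_criterion(criterion)
  if (nsims < 1e3) stop("`nsims` must be at least 1000", call. = FALSE)
  if (nsims < 1e5) {
    warning("`nsims` < 1e5: Monte-Carlo error exceeds ~0.16 percentage ",
            "points at p = 0.5", call. = FALSE)
  }
  p <- with_seed(seed, power_once(n, gmr, cv_wr, cv_wt, criterion, nsims,
                                  engine, df_rule))
  tibble::tibble(
    criterion = criterion$label, engine = engine,
    n = n, cv = cv_wr, gmr = gmr, nsims = nsims,
    prop_be = p, mc_se = sqrt(p * (1 - p) / nsims)
  )
}

# one power evaluation, RNG state assumed arranged by the caller
power_once <- function(n, gmr, cv_wr, cv_wt, criterion, nsims, engine,
                       df_rule) {
  if (engine == "summary") {
    if (!isTRUE(all.equal(cv_wr, cv_wt))) {
      stop("the summary-statistic engine requires homoscedasticity ",
           "(cv_wt == cv_wr); use engine = \"subject\"", call. = FALSE)
    }
    raw <- draw_stats_raw(n, gmr, cv_wr, nsims, df_rule)
    return(mean(decide_core(raw$pe, raw$se, raw$df, raw$s2_wr, criterion)$be))
  }
  # subject engine: chunk so the period-level matrices stay modest
  chunk <- max(1L, min(nsims, as.integer(ceiling(2e6 / n))))
  done <- 0L
  hits <- 0
  while (done < nsims) {
    k <- min(chunk, nsims - done)
    raw <- draw_stats_subject_raw(n, gmr, cv_wr, cv_wt, k, df_rule)
    hits <- hits + sum(decide_core(raw$pe, raw$se, raw$df, raw$s2_wr,
                                   criterion)$be)
    done <- done + k
  }
  hits / nsims
}

#' Monte-Carlo type-I error at the null boundary
#'
#' Places the true GMR exactly on the lower acceptance limit implied by the
#' *true* variability (see [t1e_true_gmr()]) and estimates the probability of
#' (wrongly) concluding bioequivalence there, under homoscedasticity. For a
#' fixed-limit criterion this rate is the TOST size, essentially `alpha`;
#' for a scaled criterion it can be inflated because the estimated limits
#' are random.
#'
#' @inheritParams estimate_power
#' @param cv True within-subject CV (fraction) of both products.
#' @return A one-row tibble as in [estimate_power()].
#' @examples
#' estimate_t1e(n = 54, cv = 0.14, nsims = 1e4, seed = 1)
#' @export
estimate_t1e <- function(n, cv, criterion = nlivr_criterion(), nsims = 1e5,
                         seed = NULL, engine = c("summary", "subject"),
                         df_rule = c("pooled", "contrast")) {
  estimate_power(
    n = n, gmr = t1e_true_gmr(cv, criterion), cv_wr = cv,
    criterion = criterion, nsims = nsims, seed = seed,
    engine = match.arg(engine), df_rule = match.arg(df_rule)
  )
}

#' Power or type-I error over a grid of scenarios
#'
#' `be_power()` evaluates a criterion over a tibble of scenarios (columns
#' `n`, `cv`, and `gmr`), one Monte-Carlo estimate per row. `be_t1e()` does
#' the same with the GMR of each cell set to the null boundary
#' [t1e_true_gmr()] of its CV. Each row gets its own RNG substream derived
#' deterministically from `seed` and the row index
#' and its
#' `(n, cv, gmr)` values, so results do not depend on row order and criteria
#' evaluated with the same `seed` see common random numbers cell by cell.
#'
#' @param scenarios A data frame with columns `n`, `cv` and (for
#'   `be_power()`) `gmr`; see [power_surface_grid()] and [t1e_reduced_grid()]
#'   for standard grids.
#' @inheritParams estimate_power
#' @return A tibble with one row per scenario: the scenario columns plus
#'   `criterion`, `engine`, `nsims`, `seed`, `prop_be`, `mc_se`, of class
#'   `be_grid` (which has an [ggplot2::autoplot()] method).
#' @examples
#' grid <- tidyr::expand_grid(n = c(24, 48), cv = c(0.1, 0.3), gmr = 0.9)
#' be_power(grid, nlivr_criterion(), nsims = 1e3, seed = 1)
#' @export
be_power <- function(scenarios, criterion = nlivr_criterion(), nsims = 1e5,
                     seed = 1, engine = c("summary", "subject"),
                     df_rule = c("pooled", "contrast")) {
  engine <- match.arg(engine)
  df_rule <- match.arg(df_rule)
  assert_criterion(criterion)
  req <- c("n", "cv", "gmr")
  if (!is.data.frame(scenarios) || !all(req %in% names(scenarios))) {
    stop("`scenarios` must have columns n, cv, gmr", call. = FALSE)
  }
  if (nsims < 1e3) stop("`nsims` must be at least 1000", call. = FALSE)
  rows <- purrr::pmap(
    list(scenarios$n, scenarios$cv, scenarios$gmr, seq_len(nrow(scenarios))),
    function(n, cv, gmr, i) {
      p <- with_seed(derive_seed(seed, n, cv, gmr),
                     power_once(n, gmr, cv, cv, criterion, nsims, engine,
                                df_rule))
      tibble::tibble(n = n, cv = cv, gmr = gmr, prop_be = p)
    }
  )
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      criterion = criterion$label, engine = engine, nsims = nsims,
      seed = seed, mc_se = sqrt(.data$prop_be * (1 - .data$prop_be) / nsims),
      .before = "prop_be"
    )
  class(out) <- c("be_grid", class(out))
  out
}

#' @rdname be_power
#' @param cells For `be_t1e()`: a data frame with columns `n` and `cv`.
#' @export
be_t1e <- function(cells, criterion = nlivr_criterion(), nsims = 1e5,
                   seed = 1, engine = c("summary", "subject"),
                   df_rule = c("pooled", "contrast")) {
  if (!is.data.frame(cells) || !all(c("n", "cv") %in% names(cells))) {
    stop("`cells` must have columns n, cv", call. = FALSE)
  }
  scenarios <- dplyr::mutate(cells, gmr = t1e_true_gmr(.data$cv, criterion))
  be_power(scenarios, criterion, nsims = nsims, seed = seed,
           engine = match.arg(engine), df_rule = match.arg(df_rule))
}

# deterministic seed substream derivation: folds the master seed and the
# cell's defining numbers together, so grid cells are independent and the
# result does not depend on row order
derive_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (v in c(...)) x <- (x * 69069 + round(as.double(v) * 1e6)) %% 2147483647
  as.integer(x)
}

#' Standard simulation grids
#'
#' `power_surface_grid()` is the full power-surface lattice for the 2x3x3
#' design: n from 9 to 114 in steps of 3 crossed with reference CV from 5% to
#' 40% in steps of 0.125% (10116 cells per GMR -- intended for long batch
#' runs; evaluating it at 1e6 simulations per cell is a cluster-scale job).
#' `t1e_reduced_grid()` is a desk-scale grid concentrated on the region where
#' type-I-error inflation of the scaled rule occurs: CV 12--20% in steps of
#' 0.5%, n 45--114 in steps of 9.
#'
#' @param gmr True GMR(s) to cross with the lattice.
#' @param n,cv Grid vectors, overridable.
#' @return A tibble of scenario cells.
#' @examples
#' nrow(power_surface_grid(gmr = 0.9))
#' t1e_reduced_grid()
#' @export
power_surface_grid <- function(gmr = 0.90, n = seq(9L, 114L, by = 3L),
                               cv = seq(0.05, 0.40, by = 0.00125)) {
  tidyr::expand_grid(gmr = gmr, n = n, cv = cv)
}

#' @rdname power_surface_grid
#' @export
t1e_reduced_grid <- function(n = seq(45L, 114L, by = 9L),
                             cv = seq(0.12, 0.20, by = 0.005)) {
  tidyr::expand_grid(n = n, cv = cv)
}

#' Significance bound for an empirical type-I-error rate
#'
#' The one-sided 95% binomial significance bound for an empirical rejection
#' rate estimated from `nsims` simulations under a true rate `alpha`:
#' `alpha + qnorm(0.95) * sqrt(alpha * (1 - alpha) / nsims)`. An observed
#' rate above this value is statistically significantly inflated. At
#' `nsims = 1e6` and `alpha = 0.05` the bound is 0.05036.
#'
#' @param nsims Number of simulations behind the empirical rate.
#' @param alpha Nominal one-sided significance level.
#' @return The bound (fraction).
#' @examples
#' inflation_threshold(1e6)
#' @export
inflation_threshold <- function(nsims, alpha = 0.05) {
  stopifnot(nsims >= 1, alpha > 0, alpha < 1)
  alpha + stats::qnorm(0.95) * sqrt(alpha * (1 - alpha) / nsims)
}
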