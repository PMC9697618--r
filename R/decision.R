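# TOST confidence interval and the bioequivalence decision.

#' Two one-sided tests (TOST) confidence interval
#'
#' The classical `1 - 2 * alpha` confidence interval for the geometric mean
#' ratio, `exp(pe -/+ t(1 - alpha, df) * se_pe)`, symmetric about the point
#' estimate on the log scale.
#'
#' @param stats A tibble of analysed-trial statistics with columns `pe`,
#'   `se_pe`, `df_pe` (e.g. from [analyze_trial()] or
#'   [draw_summary_stats()]). Row-wise vectorised.
#' @param alpha One-sided significance level.
#' @return `stats` with `ci_lower` and `ci_upper` columns appended (ratio
#'   scale).
#' @examples
#' stats <- analyze_trial(simulate_trial(12, 0.95, 0.2, seed = 1))
#' tost_ci(stats)
#' @export
tost_ci <- function(stats, alpha = 0.05) {
  check_stats(stats)
  stopifnot(alpha > 0, alpha < 0.5)
  tq <- stats::qt(1 - alpha, stats$df_pe)
  dplyr::mutate(
    stats,
    ci_lower = exp(.data$pe - tq * .data$se_pe),
    ci_upper = exp(.data$pe + tq * .data$se_pe)
  )
}

#' Apply a bioequivalence criterion to analysed-trial statistics
#'
#' The complete decision: the acceptance range is evaluated at the
#' *estimated* `s_WR` of the same trial (for a scaled criterion the limits
#' are therefore themselves random variables -- the source of the
#' type-I-error inflation of such rules), the TOST confidence interval must
#' be contained in that range (closed intervals: an endpoint exactly on a
#' limit passes), and, when the criterion carries a point-estimate
#' constraint, the GMR estimate must also lie within the constraint range.
#'
#' @param stats A tibble with columns `pe`, `se_pe`, `df_pe`, `s2_wr` (one
#'   row per analysed trial). Row-wise vectorised.
#' @param criterion A [nlivr_criterion()] or [fixed_criterion()] object; its
#'   `alpha` sets the confidence level.
#' @return `stats` with appended columns `ci_lower`, `ci_upper`,
#'   `point_estimate`, `range_lower`, `range_upper`, `regime`, `ci_pass`,
#'   `pe_pass`, `bioequivalent`.
#' @examples
#' simulate_trial(24, 0.95, 0.2, seed = 2) |>
#'   analyze_trial() |>
#'   decide_be(nlivr_criterion(pe_constraint = TRUE))
#' @export
decide_be <- function(stats, criterion = nlivr_criterion()) {
  assert_criterion(criterion)
  check_stats(stats, need_s2wr = TRUE)
  core <- decide_core(stats$pe, stats$se_pe, stats$df_pe, stats$s2_wr,
                      criterion)
  swr <- sqrt(stats$s2_wr)
  dplyr::mutate(
    stats,
    ci_lower = exp(core$log_lo),
    ci_upper = exp(core$log_hi),
    point_estimate = exp(.data$pe),
    range_lower = exp(-core$log_u),
    range_upper = exp(core$log_u),
    regime = dplyr::case_when(
      swr <= criterion$sd_lower ~ "floor",
      swr >= criterion$sd_upper ~ "cap",
      TRUE ~ "scaled"
    ),
    ci_pass = core$ci_pass,
    pe_pass = core$pe_pass,
    bioequivalent = core$be
  )
}

# vectorised decision core shared by decide_be() and the power engines;
# works on raw vectors for speed
decide_core <- function(pe, se, df, s2_wr, criterion) {
  log_u <- log_upper_limit(sqrt(s2_wr), criterion)
  tq <- stats::qt(1 - criterion$alpha, df)
  log_lo <- pe - tq * se
  log_hi <- pe + tq * se
  ci_pass <- (log_lo >= -log_u) & (log_hi <= log_u)
  pe_pass <- if (criterion$pe_constraint) {
    pe >= log(criterion$pe_constraint_limits[1]) &
      pe <= log(criterion$pe_constraint_limits[2])
  } else {
    rep(TRUE, length(pe))
  }
  list(log_lo = log_lo, log_hi = log_hi, log_u = log_u,
       ci_pass = ci_pass, pe_pass = pe_pass, be = ci_pass & pe_pass)
}

check_stats <- function(stats, need_s2wr = FALSE) {
  req <- c("pe", "se_pe", "df_pe", if (need_s2wr) "s2_wr")
  if (!is.data.frame(stats) || !all(req %in% names(stats))) {
    stop("`stats` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(stats$df_pe < 1)) stop("`df_pe` must be >= 1", call. = FALSE)
  if (any(stats$se_pe < 0)) stop("`se_pe` must be >= 0", call. = FALSE)
  if (need_s2wr && any(stats$s2_wr < 0)) {
    stop("`s2_wr` must be >= 0", call. = FALSE)
  }
  invisible(stats)
}
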