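# ggplot2 displays for criteria and simulation grids.

#' Plot the acceptance limits of a criterion against reference variability
#'
#' Draws the acceptance range (ratio scale) as a function of the
#' within-subject CV of the reference product: flat at the floor below the
#' lower switch, widening as `exp(+/- k * s_WR)` between the switches, flat
#' at the cap above.
#'
#' @param criterion A [nlivr_criterion()] or [fixed_criterion()] object.
#' @param cv_range CV range (fractions) to display.
#' @return A ggplot object.
#' @examples
#' plot_acceptance_limits(nlivr_criterion())
#' @export
plot_acceptance_limits <- function(criterion = nlivr_criterion(),
                                   cv_range = c(0.05, 0.40)) {
  assert_criterion(criterion)
  cv <- seq(cv_range[1], cv_range[2], length.out = 400)
  lim <- acceptance_limits(cv2sd(cv), criterion)
  dat <- tibble::tibble(cv = 100 * cv, lower = lim$lower, upper = lim$upper) |>
    tidyr::pivot_longer(c("lower", "upper"), names_to = "limit",
                        values_to = "ratio")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cv, y = 100 * .data$ratio,
                                    linetype = .data$limit)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 100, colour = "grey60",
                        linewidth = 0.3) +
    ggplot2::labs(
      x = "within-subject CV of the reference product (%)",
      y = "acceptance limit for the GMR (%)",
      title = sprintf("Acceptance limits (%s)", criterion$label)
    ) +
    ggplot2::guides(linetype = "none") +
    ggplot2::theme_minimal()
}

#' Heatmap of a simulated power or type-I-error surface
#'
#' @param object A `be_grid` tibble from [be_power()] or [be_t1e()].
#' @param ... Unused.
#' @return A ggplot object: proportion concluding BE over the (CV, n) grid.
#' @method autoplot be_grid
#' @examples
#' grid <- tidyr::expand_grid(n = seq(12, 36, 12), cv = c(0.1, 0.2, 0.3),
#'                            gmr = 0.9)
#' autoplot(be_power(grid, nsims = 1e3, seed = 1))
#' @export
autoplot.be_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 100 * .data$cv, y = .data$n,
                                       fill = .data$prop_be)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA),
                                  name = "P(conclude BE)") +
    ggplot2::labs(
      x = "within-subject CV of the reference product (%)",
      y = "total subjects",
      title = sprintf("criterion %s, GMR %s",
                      object$criterion[1],
                      paste(unique(signif(object$gmr, 4)), collapse = ", "))
    ) +
    ggplot2::theme_minimal()
}
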