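#' Plot the evidence network
#'
#' Treatments on a circle; edge width proportional to the number of
#' direct comparisons, mirroring the usual NMA network plot.
#'
#' @param object An `nma_network` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nma_network
#' @export
autoplot.nma_network <- function(object, ...) {
  k <- length(object$treatments)
  ang <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  pos <- tibble::tibble(treatment = object$treatments,
                        px = cos(ang), py = sin(ang))
  seg <- object$edges |>
    dplyr::left_join(pos, by = c(treat1 = "treatment")) |>
    dplyr::rename(x = "px", y = "py") |>
    dplyr::left_join(pos, by = c(treat2 = "treatment")) |>
    dplyr::rename(xend = "px", yend = "py")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$n_studies),
      colour = "grey60") +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(x = .data$px, y = .data$py), size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = 1.15 * .data$px, y = 1.15 * .data$py,
                                    label = .data$treatment)) +
    ggplot2::scale_linewidth(range = c(0.3, 3), name = "studies") +
    ggplot2::coord_equal(xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35)) +
    ggplot2::theme_void()
}

#' Forest plot of effects versus the reference
#'
#' Posterior medians and 95% credible intervals of each treatment's SMD
#' against the reference.
#'
#' @param object An `nma_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nma_fit
#' @export
autoplot.nma_fit <- function(object, ...) {
  td <- tidy(object) |> dplyr::filter(.data$term != "tau")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$treatment,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = paste("SMD vs", object$reference), y = NULL,
                  title = "Posterior treatment effects (95% CrI)") +
    ggplot2::theme_minimal()
}

#' Comparison-adjusted funnel plot
#'
#' Centered study effects against their standard error (inverted axis),
#' with the zero-asymmetry vertical and pseudo 95% funnel bounds.
#'
#' @param object An `nma_funnel` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nma_funnel
#' @export
autoplot.nma_funnel <- function(object, ...) {
  pts <- object$points
  smax <- max(pts$se) * 1.05
  funnel <- tibble::tibble(se = c(0, smax))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$se)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(data = funnel,
                       ggplot2::aes(x = 1.96 * .data$se, y = .data$se),
                       linetype = 3, colour = "grey50") +
    ggplot2::geom_line(data = funnel,
                       ggplot2::aes(x = -1.96 * .data$se, y = .data$se),
                       linetype = 3, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = paste(.data$treat1, "vs",
                                                    .data$treat2))) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "centered SMD", y = "standard error",
                  colour = "comparison") +
    ggplot2::theme_minimal()
}

#' SUCRA bar chart
#'
#' @param ranking Tibble from [nma_ranking()].
#' @return A ggplot object.
#' @export
plot_sucra <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$treatment,
                                                  .data$sucra),
                               y = .data$sucra)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "SUCRA") +
    ggplot2::theme_minimal()
}
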