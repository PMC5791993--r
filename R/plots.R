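#' Plot item characteristic curves
#'
#' Endorsement probability of each item as a function of the latent
#' living-conditions score. The latent level at which a curve crosses 0.5
#' is the item's difficulty; the slope there reflects its discrimination.
#'
#' @param x An `hlc_params` or `hlc_fit` object.
#' @param z_range Range of latent scores to plot over.
#' @param link Item link function.
#' @return A ggplot object.
#' @export
plot_item_curves <- function(x, z_range = c(-3, 5), link = "probit") {
  p <- if (inherits(x, "hlc_fit")) x$params else x
  stopifnot(inherits(p, "hlc_params"))
  grid <- tidyr::expand_grid(
    item = factor(p$item_names, levels = p$item_names),
    z = seq(z_range[1], z_range[2], length.out = 201)
  )
  pars <- tibble::tibble(item = factor(p$item_names, levels = p$item_names),
                         loading = p$loadings, threshold = p$thresholds)
  grid <- dplyr::left_join(grid, pars, by = "item") |>
    dplyr::mutate(prob = item_response_prob(.data$z, .data$loading,
                                            .data$threshold, link = link))
  ggplot2::ggplot(grid, ggplot2::aes(.data$z, .data$prob, colour = .data$item)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "latent living-conditions score",
                  y = "P(item endorsed)", colour = "item") +
    ggplot2::theme_minimal()
}

#' @describeIn tidy.hlc_fit Coefficient plot: estimates with robust 95%
#'   intervals, faceted by model component.
#' @param object An `hlc_fit` object (for `autoplot`).
#' @method autoplot hlc_fit
#' @export
autoplot.hlc_fit <- function(object, ...) {
  td <- tidy(object, conf.int = TRUE)
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "estimate (robust 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn external_validation Scatter plot of group mean scores against
#'   the external indicator, labelled by group.
#' @param object An `hlc_validation` object (for `autoplot`).
#' @param ... Unused.
#' @method autoplot hlc_validation
#' @export
autoplot.hlc_validation <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(.data$indicator, .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 2.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.5) +
    ggplot2::labs(
      x = object$indicator, y = object$score,
      subtitle = sprintf("Pearson r = %.3f, Spearman rho = %.3f",
                         object$pearson, object$spearman)) +
    ggplot2::theme_minimal()
}
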