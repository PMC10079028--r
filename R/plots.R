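#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' FTO histogram by group
#'
#' Bar histogram of floor-transfer FTO values with the same centred-bin
#' convention as [modal_bin()], faceted by group, with reference lines at
#' 0 ms (no-gap-no-overlap) and +200 ms (the typical short-gap mode).
#'
#' @param timing A floor-transfer tibble with `group` and `fto_ms`.
#' @param bin_width_ms Bin width (default 100).
#' @return A ggplot object.
#' @export
plot_fto_histogram <- function(timing, bin_width_ms = 100) {
  dat <- timing |>
    filter(!is.na(.data$fto_ms)) |>
    group_by(.data$group) |>
    reframe(fto_histogram(.data$fto_ms, bin_width_ms))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$centre_ms, y = .data$proportion)) +
    ggplot2::geom_col(width = bin_width_ms, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 200, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Floor Transfer Offset (ms)", y = "proportion") +
    ggplot2::theme_minimal()
}

#' Mean FTO by floor-transfer index
#'
#' Plots the per-index group means (thin lines) and their moving-average
#' smooth (thick lines), optionally with vertical marks at the average
#' detection/resolution indices.
#'
#' @param curve Output of [fto_by_index()].
#' @param marks Optional numeric vector of transfer indices to mark.
#' @return A ggplot object.
#' @export
plot_fto_by_index <- function(curve, marks = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$index, colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_fto_ms), alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_ms), linewidth = 1) +
    ggplot2::labs(x = "floor transfer index", y = "mean FTO (ms)") +
    ggplot2::theme_minimal()
  if (!is.null(marks)) {
    p <- p + ggplot2::geom_vline(xintercept = marks, linetype = "dashed")
  }
  p
}

#' Per-dyad FTO densities
#'
#' @param timing A floor-transfer tibble with `group`, `dyad_id`, `fto_ms`.
#' @return A ggplot object (one density per dyad, faceted by group).
#' @export
plot_dyad_distributions <- function(timing) {
  ggplot2::ggplot(filter(timing, !is.na(.data$fto_ms)),
                  ggplot2::aes(x = .data$fto_ms, group = .data$dyad_id)) +
    ggplot2::geom_density(alpha = 0.4, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 200, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), ncol = 1) +
    ggplot2::coord_cartesian(xlim = c(-2000, 3000)) +
    ggplot2::labs(x = "Floor Transfer Offset (ms)", y = "density") +
    ggplot2::theme_minimal()
}

#' Posterior interval plot of a fitted FTO model
#'
#' @param object An [fit_fto()] object.
#' @param ... Unused.
#' @return A ggplot object showing posterior means and 95\% credible
#'   intervals of all cell means.
#' @export
autoplot.fto_fit <- function(object, ...) {
  td <- tidy(object, pars = "cells")
  td$term <- sub("^mu\\[(.*)\\]$", "\\1", td$term)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "posterior cell mean FTO (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
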