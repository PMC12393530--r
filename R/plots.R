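# ggplot2 quick-look plots for fitted models and profiles.

#' Plot a fitted penalty model in log-log space
#'
#' Draws each component's fitted power-law line over its assigned
#' log10-distance range, with regime transitions as dashed verticals.
#'
#' @param object A [penalty_params()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.penalty_params <- function(object, ...) {
  comp <- tidy(object)
  seg <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    xr <- c(comp$x_min[i], comp$x_max[i])
    if (any(!is.finite(xr))) xr <- log10(object$fit_range_bp)
    tibble(
      component = factor(comp$component[i]),
      x = seq(xr[1], xr[2], length.out = 50),
      y = log10(comp$beta[i]) - comp$alpha[i] * seq(xr[1], xr[2], length.out = 50)
    )
  })
  p <- ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$component)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(
      x = "log10 distance (bp)", y = "log10 signal",
      title = "Fitted power-law regimes",
      subtitle = paste0(
        "alpha = ",
        paste(sprintf("%.2f", comp$alpha), collapse = ", ")
      )
    ) +
    ggplot2::theme_minimal()
  if (length(object$transitions_bp) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = log10(object$transitions_bp),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' Plot a normalized decay profile
#'
#' @param object A `normalized_profile`.
#' @param ... Unused.
#' @return A ggplot with log10 x-axis.
#' @export
autoplot.normalized_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$bin_mid_bp, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "genomic distance (bp)", y = "normalized signal (max = 1)",
      title = attr(object, "source_label") %||% "decay profile"
    ) +
    ggplot2::theme_minimal()
}

#' Overlay proxy and reference profiles
#'
#' Convenience figure for the before/after-penalty comparison: any number
#' of named `normalized_profile`s on one shared grid.
#'
#' @param ... Named `normalized_profile`s (e.g. `raw = ..., penalized =
#'   ..., reference = ...`).
#' @return A ggplot with log10 x-axis.
#' @export
plot_profile_overlay <- function(...) {
  profs <- list(...)
  if (is.null(names(profs)) || any(!nzchar(names(profs)))) {
    abort("pass named profiles, e.g. plot_profile_overlay(raw = p1, reference = p2)")
  }
  df <- purrr::imap_dfr(profs, function(p, nm) {
    tibble(profile = nm, bin_mid_bp = p$bin_mid_bp, value = p$value)
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bin_mid_bp, y = .data$value,
    colour = .data$profile
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genomic distance (bp)", y = "normalized signal (max = 1)") +
    ggplot2::theme_minimal()
}
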