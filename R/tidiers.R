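# broom-style tidiers for fitted objects.

#' Tidy a fitted penalty model
#'
#' One row per mixture component, with the decay exponent, scale, weight,
#' assigned log10-distance range and regression quality.
#'
#' @param x A [penalty_params()] object.
#' @param ... Unused.
#' @return A tibble with columns `component`, `alpha`, `beta`, `pi`,
#'   `x_min`, `x_max`, `r_squared`.
#' @export
tidy.penalty_params <- function(x, ...) {
  comp <- x$components
  comp$component <- seq_len(nrow(comp))
  dplyr::relocate(comp, "component")
}

#' One-row summary of a fitted penalty model
#'
#' @param x A [penalty_params()] object.
#' @param ... Unused.
#' @return A tibble with `n_components`, `bic`, `aic` (at the selected n,
#'   when a selection table is present), `fit_min_bp`, `fit_max_bp`,
#'   `n_transitions`, `normalization`, `seed`.
#' @export
glance.penalty_params <- function(x, ...) {
  bic <- aic <- NA_real_
  if (!is.null(x$selection)) {
    row <- x$selection[x$selection$n == x$n_components, , drop = FALSE]
    if (nrow(row) == 1) {
      bic <- row$bic
      aic <- row$aic
    }
  }
  tibble(
    n_components = x$n_components,
    bic = bic,
    aic = aic,
    fit_min_bp = x$fit_range_bp[1],
    fit_max_bp = x$fit_range_bp[2],
    n_transitions = length(x$transitions_bp),
    normalization = x$normalization,
    seed = x$seed
  )
}

#' Tidy a Gaussian-mixture fit
#'
#' @param x A `gmm_fit` from [fit_gmm()].
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `weight`,
#'   `mean_x`, `mean_y`.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble(
    component = seq_len(x$n_components),
    weight = x$weights,
    mean_x = as.numeric(x$means[1, ]),
    mean_y = as.numeric(x$means[2, ])
  )
}

#' One-row summary of a Gaussian-mixture fit
#'
#' @param x A `gmm_fit`.
#' @param ... Unused.
#' @return A tibble with `n_components`, `loglik`, `df`, `bic`, `aic`,
#'   `converged`.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    loglik = x$loglik,
    df = x$df,
    bic = x$bic,
    aic = x$aic,
    converged = x$converged
  )
}

#' Tidy a comparison report
#'
#' @param x A `comparison_report` from [compare_profiles()].
#' @param ... Unused.
#' @return A long tibble with `metric` and `value` columns.
#' @export
tidy.comparison_report <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x)[, c("spearman_rho", "wasserstein_bp", "fpr", "fnr", "f1")],
    dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
}
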