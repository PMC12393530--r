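# Penalty evaluation and application to interaction score tables.

#' Evaluate the distance penalty P(s)
#'
#' Computes \eqn{P(s) = \sum_i \pi_i \beta_i s^{-\alpha_i}} at one or more
#' genomic distances. With `normalization = "max_one_on_fit_range"` the
#' value is divided by the maximum of \eqn{P} over the fit range (attained
#' at the lower bound when all exponents are non-negative), so the penalty
#' lies in (0, 1] on the fit range and penalization only down-weights.
#'
#' @param params A [penalty_params()] object.
#' @param s Genomic distance(s) in bp; must be > 0.
#' @return Numeric vector of penalty values, same length as `s`.
#' @examples
#' p <- penalty_params(data.frame(pi = 1, beta = 1, alpha = 1),
#'   fit_range_bp = c(1, 100), normalization = "none"
#' )
#' evaluate_penalty(p, 10) # 0.1
#' @export
evaluate_penalty <- function(params, s) {
  stopifnot(inherits(params, "penalty_params"))
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("penalty distances must be finite and > 0")
  }
  v <- penalty_raw(params$components, s)
  if (identical(params$normalization, "max_one_on_fit_range")) {
    v <- v / penalty_max_on_range(params)
  }
  v
}

penalty_raw <- function(components, s) {
  out <- numeric(length(s))
  for (i in seq_len(nrow(components))) {
    out <- out + components$pi[i] * components$beta[i] * s^(-components$alpha[i])
  }
  out
}

# maximum of the unnormalized penalty over the fit range; at s_min when all
# alpha >= 0, otherwise located on a dense log grid (plus both endpoints)
penalty_max_on_range <- function(params) {
  comp <- params$components
  rng <- params$fit_range_bp
  if (all(comp$alpha >= 0)) {
    return(penalty_raw(comp, rng[1]))
  }
  grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 1024)
  max(penalty_raw(comp, grid))
}

#' Apply a distance penalty to an interaction score table
#'
#' Multiplies each row's raw score by the penalty evaluated at the row's
#' genomic distance: `penalized_score = raw_score * P(distance_bp)`. The raw
#' column is untouched. Rows whose distance lies outside the parameter fit
#' range are still penalized by the same formula (extrapolation) and flagged
#' in the logical `extrapolated` column; `clamp = TRUE` instead clamps the
#' penalty below the fit range at its value at the lower bound.
#'
#' Negative raw scores are multiplied like any other (the penalty is
#' positive, so signs are preserved); `positive_only = TRUE` first drops
#' rows with non-positive raw scores.
#'
#' @param scores A `score_table` (see [score_table()]).
#' @param params A [penalty_params()] object.
#' @param clamp Clamp the penalty at its value at the fit-range lower bound
#'   for shorter distances instead of extrapolating.
#' @param positive_only Keep only rows with `raw_score > 0` before
#'   penalizing.
#' @return The score table with `penalized_score` and `extrapolated`
#'   columns added/overwritten.
#' @export
apply_penalty <- function(scores, params, clamp = FALSE, positive_only = FALSE) {
  stopifnot(inherits(params, "penalty_params"))
  if (!inherits(scores, "score_table")) scores <- score_table(scores)
  if (positive_only) {
    scores <- scores[scores$raw_score > 0, , drop = FALSE]
  }
  s <- scores$distance_bp
  s_eval <- if (clamp) pmax(s, params$fit_range_bp[1]) else s
  pen <- evaluate_penalty(params, s_eval)
  scores$penalized_score <- scores$raw_score * pen
  scores$extrapolated <- s < params$fit_range_bp[1] | s > params$fit_range_bp[2]
  scores
}

#' Cicero-style heuristic distance term
#'
#' The comparator down-weighting term \eqn{\beta (1 - s^{-\alpha})} used by
#' the Cicero co-accessibility framework, built on a single universal
#' human-derived decay exponent (default \eqn{\alpha = 0.75}) with the scale
#' \eqn{\beta} conventionally tuned so that most interactions beyond a
#' user-defined distance (default 250 kb) are penalized. Provided for
#' side-by-side evaluation against the fitted multi-component penalty; the
#' returned value does not depend on `cutoff_bp`, which is recorded only as
#' the conventional tuning distance.
#'
#' @param s Genomic distance(s) in bp; must be > 0.
#' @param alpha Decay exponent (default 0.75).
#' @param beta Scale factor (default 1).
#' @param cutoff_bp Conventional tuning distance, recorded as an attribute.
#' @return Numeric vector `beta * (1 - s^-alpha)` with attribute
#'   `cutoff_bp`.
#' @export
cicero_baseline_penalty <- function(s, alpha = 0.75, beta = 1, cutoff_bp = 250000) {
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("distances must be finite and > 0")
  }
  structure(beta * (1 - s^(-alpha)), cutoff_bp = cutoff_bp)
}
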