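# Distance-decay model fitting: bin contacts, move to log-log space,
# decompose the point cloud with a Gaussian mixture, regress a power law per
# regime, and assemble the penalty parameters.

#' Bin a contact set by genomic distance
#'
#' @param contacts A [contact_set()].
#' @param fit_range_bp Length-2 numeric distance window in bp (default the
#'   35 kb - 500 kb loop-fitting window).
#' @param n_bins Number of bins.
#' @param spacing `"log"` (default; equalizes point density in the log-log
#'   space where the regression happens) or `"linear"`.
#' @return A [decay_profile()] whose `value` column holds the summed contact
#'   counts per half-open bin; the sum of values equals the total in-range
#'   count.
#' @export
bin_contacts <- function(contacts, fit_range_bp = c(35e3, 5e5), n_bins = 30,
                         spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(inherits(contacts, "contact_set"))
  inr <- filter_contacts(contacts, fit_range_bp[1], fit_range_bp[2])
  if (nrow(inr) == 0) {
    abort("fit infeasible: no contacts inside the fit range")
  }
  edges <- make_bin_edges(fit_range_bp[1], fit_range_bp[2], n_bins, spacing)
  b <- assign_bins(inr$distance_bp, edges)
  values <- vapply(
    seq_len(n_bins),
    function(i) sum(inr$count[which(b == i)]),
    numeric(1)
  )
  prof <- decay_profile(tibble(
    bin_start_bp = edges[-(n_bins + 1)],
    bin_end_bp = edges[-1],
    bin_mid_bp = bin_midpoints(edges, spacing),
    value = values
  ))
  attr(prof, "spacing") <- spacing
  prof
}

#' Transform a decay profile to log10-log10 points
#'
#' One point per positive-valued bin: `(log10 bin_mid_bp, log10 value)`.
#' Zero-valued bins cannot be log-transformed and are skipped (their number
#' is recorded in the `n_skipped` attribute). With `per_bp = TRUE` the bin
#' value is first divided by the bin width, turning summed counts into a
#' count density; for sampled contact data this makes the fitted slope an
#' estimate of the decay exponent regardless of the binning scheme.
#'
#' @param profile A [decay_profile()].
#' @param per_bp Divide values by bin width before the log transform.
#' @return A `log_points` tibble with columns `x`, `y`, `bin`.
#' @export
to_log_points <- function(profile, per_bp = FALSE) {
  stopifnot(inherits(profile, "decay_profile"))
  v <- profile$value
  if (per_bp) v <- v / (profile$bin_end_bp - profile$bin_start_bp)
  pos <- which(v > 0)
  if (length(pos) < 3) {
    abort("fit infeasible: fewer than 3 positive-valued bins")
  }
  pts <- tibble(
    x = log10(profile$bin_mid_bp[pos]),
    y = log10(v[pos]),
    bin = pos
  )
  structure(pts,
    class = c("log_points", class(pts)),
    n_skipped = length(v) - length(pos)
  )
}

#' Fit a 2D Gaussian mixture to log-log points
#'
#' Wraps full-covariance model-based clustering (mclust, model `VVV`) on the
#' two-dimensional `(log10 distance, log10 value)` cloud. The fit is
#' deterministic: initialization is model-based hierarchical clustering, so
#' identical inputs give identical fits; `seed` and `n_init` are recorded for
#' provenance but do not alter the result. BIC/AIC are reported in the
#' lower-is-better orientation. A singular covariance triggers a
#' regularizing conjugate prior; if the model still cannot be fit an error
#' is raised.
#'
#' @param points A `log_points` tibble from [to_log_points()].
#' @param n_components Number of mixture components (>= 1).
#' @param seed,n_init Recorded in the fit object for provenance.
#' @return A `gmm_fit` list: `n_components`, `weights`, `means`,
#'   `covariances`, `responsibilities`, `loglik`, `df`, `bic`, `aic`,
#'   `converged`, `regularized`, `seed`.
#' @export
fit_gmm <- function(points, n_components, seed = 42L, n_init = 10L) {
  stopifnot(n_components >= 1)
  m <- nrow(points)
  if (m < 3 * n_components) {
    abort(paste0(
      "fit infeasible: ", m, " points cannot support ",
      n_components, " mixture components (need >= 3 per component)"
    ))
  }
  xy <- cbind(points$x, points$y)
  quiet_mclust <- function(...) {
    suppressWarnings(suppressMessages(mclust::Mclust(...)))
  }
  regularized <- FALSE
  fit <- quiet_mclust(xy, G = n_components, modelNames = "VVV", verbose = FALSE)
  if (is.null(fit) || !is.finite(fit$loglik)) {
    regularized <- TRUE
    fit <- quiet_mclust(xy,
      G = n_components, modelNames = "VVV",
      prior = mclust::priorControl(), verbose = FALSE
    )
  }
  if (is.null(fit) || !is.finite(fit$loglik)) {
    abort(paste0(
      "GMM with ", n_components,
      " component(s) could not be fit (degenerate point configuration)"
    ))
  }
  z <- fit$z
  if (is.null(z)) z <- matrix(1, nrow = m, ncol = 1)
  structure(
    list(
      n_components = n_components,
      weights = as.numeric(fit$parameters$pro %||% 1),
      means = fit$parameters$mean,
      covariances = fit$parameters$variance$sigma,
      responsibilities = z,
      loglik = fit$loglik,
      df = fit$df,
      bic = -2 * fit$loglik + fit$df * log(m),
      aic = -2 * fit$loglik + 2 * fit$df,
      converged = TRUE,
      regularized = regularized,
      seed = seed,
      n_init = n_init
    ),
    class = "gmm_fit"
  )
}

#' Select the number of decay regimes by BIC
#'
#' Fits mixtures over a range of component counts and applies a parsimony
#' plateau rule: the selected `n` is the smallest one whose BIC lies within
#' `parsimony_delta` of the minimum over the scanned range. Candidates that
#' cannot be fit are recorded as failed and excluded.
#'
#' @param points A `log_points` tibble.
#' @param n_range Integer vector of component counts to scan.
#' @param seed Recorded for provenance.
#' @param parsimony_delta BIC plateau width (default 10).
#' @return A list with `n` (selected count), `selection` (tibble of `n`,
#'   `bic`, `aic`, `loglik`, `ok`), and `fits` (the per-n `gmm_fit`s).
#' @export
select_n_components <- function(points, n_range = 1:5, seed = 42L,
                                parsimony_delta = 10) {
  n_range <- sort(unique(as.integer(n_range)))
  stopifnot(min(n_range) >= 1)
  fits <- vector("list", length(n_range))
  rows <- vector("list", length(n_range))
  for (i in seq_along(n_range)) {
    n <- n_range[i]
    f <- tryCatch(fit_gmm(points, n, seed = seed), error = function(e) NULL)
    fits[i] <- list(f)
    rows[[i]] <- if (is.null(f)) {
      tibble(n = n, loglik = NA_real_, bic = NA_real_, aic = NA_real_, ok = FALSE)
    } else {
      tibble(n = n, loglik = f$loglik, bic = f$bic, aic = f$aic, ok = TRUE)
    }
  }
  selection <- dplyr::bind_rows(rows)
  if (!any(selection$ok)) {
    abort("fit infeasible: no candidate component count could be fit")
  }
  best <- min(selection$bic[selection$ok])
  n_sel <- selection$n[selection$ok & selection$bic <= best + parsimony_delta][1]
  list(
    n = n_sel,
    selection = selection,
    fits = setNames(fits, paste0("n", n_range))
  )
}

#' Fit one power law per mixture regime
#'
#' Each log-log point is hard-assigned to its maximum-responsibility
#' component (ties broken toward the lower-distance component) and an
#' ordinary least-squares line `y = a + b x` is fitted per component; the
#' decay exponent is `alpha = -b` and the scale `beta = 10^a`. Component
#' weights `pi` are taken from the GMM mixture weights. Components are
#' returned sorted by ascending distance.
#'
#' By default (`refine = TRUE`) the assignment is then refined: the fitted
#' lines of adjacent regimes define a crossover at their intersection;
#' points are re-partitioned at the crossovers and points within
#' `1 / |slope difference|` log10 units of a crossover (capped at
#' `exclusion_cap`) are excluded from the regression. Near a crossover the
#' observed curve is the sum of both power-law terms, which lies above
#' either line and would otherwise bias both slopes; the refinement iterates
#' to a fixed point. `refine = FALSE` gives the plain GMM hard-assignment
#' regression. `weighting = "soft"` uses responsibility-weighted least
#' squares instead of hard assignment (only with `refine = FALSE`).
#'
#' Because a decay regime is defined by a distinct exponent, adjacent
#' components whose regression slopes are statistically indistinguishable
#' (two-sided t-test on the slope difference, p above `merge_p`) are merged
#' and refitted by default. This protects the model order against mixture
#' components that capture depth-dependent noise structure rather than a
#' change in decay; disable with `merge_indistinct = FALSE`.
#'
#' @param points A `log_points` tibble.
#' @param gmm A `gmm_fit` from [fit_gmm()].
#' @param refine Apply crossover-aware iterative refinement (default TRUE).
#' @param weighting `"hard"` or `"soft"` regression weighting.
#' @param max_iter Maximum refinement iterations.
#' @param exclusion_cap Upper bound (log10 units) on the crossover exclusion
#'   half-width.
#' @param merge_indistinct Merge adjacent components with indistinguishable
#'   slopes (default TRUE).
#' @param merge_p p-value threshold above which two slopes are considered
#'   the same regime.
#' @param min_alpha_sep Practical-equivalence bound: adjacent components
#'   whose exponents differ by less than this fraction (relative to the
#'   larger exponent, floored at 0.5) are merged regardless of formal
#'   significance. Folding regimes in this framework differ by far more
#'   than 15% in their exponents.
#' @return A tibble of components: `component`, `alpha`, `beta`, `pi`,
#'   `x_min`, `x_max`, `r_squared`, `n_points`. Components with fewer than 2
#'   assigned points are dropped with a warning and weights renormalized.
#' @export
fit_component_powerlaws <- function(points, gmm, refine = TRUE,
                                    weighting = c("hard", "soft"),
                                    max_iter = 30L, exclusion_cap = 0.35,
                                    merge_indistinct = TRUE, merge_p = 0.01,
                                    min_alpha_sep = 0.15) {
  weighting <- match.arg(weighting)
  x <- points$x
  y <- points$y
  z <- gmm$responsibilities
  G <- gmm$n_components

  # argmax responsibility; ties toward the lower-distance (lower mean x) comp
  mean_x <- as.numeric(gmm$means[1, , drop = TRUE])
  ord <- order(mean_x) # ord[k] = original index of k-th comp by distance
  hard <- apply(z, 1, function(r) {
    cand <- which(r == max(r))
    if (length(cand) > 1) cand[which.min(mean_x[cand])] else cand
  })
  lab <- match(hard, ord) # 1 = lowest-distance regime

  # drop starved components up front
  counts <- tabulate(lab, nbins = G)
  if (any(counts < 2)) {
    warn(paste0(
      sum(counts < 2), " mixture component(s) had fewer than 2 assigned ",
      "points and were dropped; weights renormalized"
    ))
    keep <- which(counts >= 2)
    if (length(keep) == 0) abort("no component has enough points for regression")
    remap <- match(lab, keep)
    lab <- remap[!is.na(remap)]
    sel <- !is.na(remap)
    x <- x[sel]
    y <- y[sel]
    z <- z[sel, ord[keep], drop = FALSE]
    w_pi <- gmm$weights[ord[keep]]
    G <- length(keep)
  } else {
    z <- z[, ord, drop = FALSE]
    w_pi <- gmm$weights[ord]
  }
  w_pi <- w_pi / sum(w_pi)

  ols <- function(idx_or_w, weighted = FALSE) {
    if (weighted) {
      fit <- lm(y ~ x, weights = idx_or_w)
    } else {
      fit <- lm(y[idx_or_w] ~ x[idx_or_w])
    }
    fit
  }
  line_of <- function(fit) coef(fit) # (intercept, slope)

  refine_labels <- function(lab, G) {
    included <- rep(TRUE, length(x))
    if (G > 1 && refine && weighting == "hard") {
      for (it in seq_len(max_iter)) {
        co <- vapply(seq_len(G), function(k) {
          i <- which(lab == k & included)
          if (length(i) < 2) return(c(NA_real_, NA_real_))
          line_of(ols(i))
        }, numeric(2))
        if (any(!is.finite(co))) break
        slopes <- co[2, ]
        ints <- co[1, ]
        dslope <- slopes[-G] - slopes[-1]
        if (any(abs(dslope) < 1e-8)) break # parallel regimes: keep GMM split
        x_cross <- (ints[-1] - ints[-G]) / dslope
        if (is.unsorted(x_cross)) break # crossings out of order: keep current
        new_lab <- findInterval(x, x_cross) + 1L
        half_w <- pmin(1 / abs(dslope), exclusion_cap)
        new_incl <- rep(TRUE, length(x))
        for (k in seq_len(G - 1)) {
          new_incl <- new_incl & (abs(x - x_cross[k]) >= half_w[k])
        }
        ok <- all(vapply(
          seq_len(G),
          function(k) sum(new_lab == k & new_incl) >= 2, TRUE
        ))
        if (!ok) break
        if (identical(new_lab, lab) && identical(new_incl, included)) break
        lab <- new_lab
        included <- new_incl
      }
    }
    list(lab = lab, included = included)
  }

  # slope and its standard error on a point subset
  slope_stats <- function(idx) {
    fit <- ols(idx)
    co <- coef(fit)
    n <- length(idx)
    se <- if (n > 2) {
      sxx <- sum((x[idx] - mean(x[idx]))^2)
      sqrt(sum(stats::residuals(fit)^2) / (n - 2) / sxx)
    } else {
      Inf
    }
    c(slope = unname(co[2]), se = se, n = n)
  }

  ref <- refine_labels(lab, G)
  lab <- ref$lab
  included <- ref$included

  # merge adjacent components whose slopes are not distinguishable: regimes
  # are defined by distinct exponents, so a split with matching slopes is
  # noise structure, not a regime boundary
  if (merge_indistinct && weighting == "hard") {
    repeat {
      if (G < 2) break
      st <- vapply(seq_len(G), function(k) slope_stats(which(lab == k & included)), numeric(3))
      pvals <- vapply(seq_len(G - 1), function(k) {
        tstat <- (st["slope", k] - st["slope", k + 1]) /
          sqrt(st["se", k]^2 + st["se", k + 1]^2)
        df <- st["n", k] + st["n", k + 1] - 4
        if (!is.finite(tstat) || df < 1) 0 else 2 * stats::pt(-abs(tstat), df)
      }, numeric(1))
      # practical equivalence: exponents within `min_alpha_sep` (relative)
      # of each other are the same folding regime even if a tiny regression
      # SE makes the difference formally significant
      rel_gap <- vapply(seq_len(G - 1), function(k) {
        abs(st["slope", k] - st["slope", k + 1]) /
          max(abs(st["slope", k]), abs(st["slope", k + 1]), 0.5)
      }, numeric(1))
      mergeable <- pvals > merge_p | rel_gap < min_alpha_sep
      if (!any(mergeable)) break
      j <- which(mergeable)[which.min(rel_gap[mergeable])] # most similar pair first
      lab[lab > j] <- lab[lab > j] - 1L
      w_pi <- c(
        w_pi[seq_len(j - 1)], w_pi[j] + w_pi[j + 1],
        if (j + 1 < G) w_pi[seq(j + 2, G)] else numeric()
      )
      z <- cbind(
        z[, seq_len(j - 1), drop = FALSE],
        z[, j] + z[, j + 1],
        if (j + 1 < G) z[, seq(j + 2, G), drop = FALSE] else NULL
      )
      G <- G - 1L
      ref <- refine_labels(lab, G)
      lab <- ref$lab
      included <- ref$included
    }
  }

  comps <- purrr::map(seq_len(G), function(k) {
    if (weighting == "soft") {
      fit <- ols(z[, k], weighted = TRUE)
      idx <- which(lab == k)
    } else {
      idx <- which(lab == k & included)
      fit <- ols(idx)
    }
    co <- line_of(fit)
    res <- stats::residuals(fit)
    yy <- if (weighting == "soft") y else y[idx]
    sst <- sum((yy - mean(yy))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
    tibble(
      component = k,
      alpha = -unname(co[2]),
      beta = 10^unname(co[1]),
      pi = w_pi[k],
      x_min = min(x[lab == k]),
      x_max = max(x[lab == k]),
      r_squared = r2,
      n_points = length(idx)
    )
  })
  dplyr::bind_rows(comps)
}

#' Regime-transition distances between adjacent components
#'
#' For each adjacent pair of components (sorted by ascending distance), the
#' transition is `10^((x_max of the lower + x_min of the upper) / 2)` bp.
#' Overlapping assignment ranges fall back to the midpoint of the overlap
#' and are flagged via the `overlapping` attribute.
#'
#' @param components Component tibble from [fit_component_powerlaws()].
#' @return Numeric vector of transition distances in bp (empty for a single
#'   component), with attribute `overlapping` (logical per transition).
#' @export
transition_points <- function(components) {
  components <- dplyr::arrange(as_tibble(components), (.data$x_min + .data$x_max) / 2)
  G <- nrow(components)
  if (G < 2) {
    return(structure(numeric(), overlapping = logical()))
  }
  res <- numeric(G - 1)
  ovl <- logical(G - 1)
  for (k in seq_len(G - 1)) {
    lo_hi <- components$x_max[k]
    hi_lo <- components$x_min[k + 1]
    ovl[k] <- hi_lo < lo_hi
    res[k] <- 10^((lo_hi + hi_lo) / 2)
  }
  if (any(ovl)) warn("overlapping regimes: transition taken at the overlap midpoint")
  structure(res, overlapping = ovl)
}

#' Fit the full distance-decay model
#'
#' End-to-end pipeline: bin contacts over the fit range, transform the count
#' density to log-log points, select the number of regimes by the BIC
#' plateau rule, decompose with a Gaussian mixture, fit one power law per
#' regime, and locate the regime transitions. The result is a
#' [penalty_params()] object defining
#' \eqn{P(s) = \sum_i \pi_i \beta_i s^{-\alpha_i}}.
#'
#' @inheritParams bin_contacts
#' @inheritParams select_n_components
#' @inheritParams fit_component_powerlaws
#' @param species_label Stored in the result.
#' @param min_contacts Minimum number of in-range contacts required for a
#'   meaningful decay fit (default 100); fewer raise a fit-infeasible error.
#' @param normalization Normalization mode recorded in the result; see
#'   [evaluate_penalty()].
#' @return A [penalty_params()] object carrying the component table, the
#'   selection table, the transitions, and the seed.
#' @examples
#' cfg <- simulation_config(
#'   components = data.frame(pi = 1, beta = 1, alpha = 2.34),
#'   range_bp = c(35e3, 5e5), n_records = 2e4, seed = 7
#' )
#' fit <- fit_decay_model(simulate_contacts(cfg), n_range = 1:2)
#' tidy(fit)
#' @export
fit_decay_model <- function(contacts, fit_range_bp = c(35e3, 5e5), n_bins = 30,
                            n_range = 1:5, seed = 42L, parsimony_delta = 10,
                            spacing = c("log", "linear"),
                            refine = TRUE, weighting = c("hard", "soft"),
                            species_label = NA_character_, min_contacts = 100,
                            normalization = c("max_one_on_fit_range", "none")) {
  spacing <- match.arg(spacing)
  weighting <- match.arg(weighting)
  normalization <- match.arg(normalization)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("fit_decay_model failed at stage `", name, "`: ", conditionMessage(e)))
    })
  }
  n_in_range <- sum(contacts$distance_bp >= fit_range_bp[1] &
    contacts$distance_bp <= fit_range_bp[2])
  if (n_in_range < min_contacts) {
    abort(paste0(
      "fit infeasible: only ", n_in_range, " contact(s) in the fit range; ",
      "need at least ", min_contacts
    ))
  }
  profile <- stage("bin_contacts", bin_contacts(contacts, fit_range_bp, n_bins, spacing))
  points <- stage("to_log_points", to_log_points(profile, per_bp = TRUE))
  sel <- stage(
    "select_n_components",
    select_n_components(points, n_range, seed = seed, parsimony_delta = parsimony_delta)
  )
  gmm <- sel$fits[[paste0("n", sel$n)]]
  comps <- stage(
    "fit_component_powerlaws",
    fit_component_powerlaws(points, gmm, refine = refine, weighting = weighting)
  )
  # renormalize pi in case regression dropped a component
  comps$pi <- comps$pi / sum(comps$pi)
  trans <- stage("transition_points", transition_points(comps))
  penalty_params(
    components = comps,
    fit_range_bp = fit_range_bp,
    species_label = species_label,
    normalization = normalization,
    selection = sel$selection,
    transitions_bp = as.numeric(trans),
    seed = seed,
    generated_by = list(
      tool = "chromdecay",
      version = as.character(utils::packageVersion("chromdecay")),
      n_contacts = nrow(contacts),
      n_bins = n_bins,
      spacing = spacing
    )
  )
}
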