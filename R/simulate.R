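# Synthetic data with known ground truth: contact sets drawn from truncated
# power-law mixtures, distance-independent "raw proxy" score tables, and
# exact reference decay profiles.

#' Configuration for the synthetic-data generators
#'
#' @param components Data frame with columns `pi`, `beta`, `alpha`: the
#'   generating mixture \eqn{\sum_i \pi_i \beta_i s^{-\alpha_i}}. Weights
#'   must sum to 1.
#' @param range_bp Length-2 distance range `[s_min, s_max]` in bp.
#' @param n_records Number of records to generate.
#' @param seed Integer RNG seed; every generator is deterministic given the
#'   seed.
#' @param noise_sd Multiplicative log-normal noise scale for simulated
#'   scores (keeps scores positive).
#' @param score_level Baseline raw score for flat score tables.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(components, range_bp, n_records, seed = 42L,
                              noise_sd = 0.2, score_level = 1) {
  components <- as_tibble(components)
  stopifnot(all(c("pi", "beta", "alpha") %in% names(components)))
  if (abs(sum(components$pi) - 1) > 1e-9) {
    abort("generating component weights must sum to 1")
  }
  if (any(components$beta <= 0) || any(!is.finite(components$alpha))) {
    abort("generating beta must be > 0 and alpha finite")
  }
  stopifnot(
    length(range_bp) == 2, range_bp[1] > 0, range_bp[1] < range_bp[2],
    n_records > 0, noise_sd >= 0, score_level > 0
  )
  structure(
    list(
      components = components,
      range_bp = as.numeric(range_bp),
      n_records = as.integer(n_records),
      seed = as.integer(seed),
      noise_sd = noise_sd,
      score_level = score_level
    ),
    class = "simulation_config"
  )
}

# truncated-power-law mass int_{smin}^{smax} s^-alpha ds (log branch at
# alpha = 1)
truncated_mass <- function(alpha, smin, smax) {
  if (abs(alpha - 1) < 1e-12) {
    log(smax / smin)
  } else {
    (smax^(1 - alpha) - smin^(1 - alpha)) / (1 - alpha)
  }
}

# closed-form inverse CDF of the truncated power law s^-alpha on
# [smin, smax]; exact, so heavy tails are handled without rejection
rtruncated_powerlaw <- function(n, alpha, smin, smax) {
  if (!is.finite(smin^(1 - alpha)) || !is.finite(smax^(1 - alpha))) {
    abort(paste0(
      "alpha = ", alpha, " overflows the truncated power-law CDF at the ",
      "range bounds"
    ))
  }
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    smin * (smax / smin)^u
  } else {
    a <- smin^(1 - alpha)
    b <- smax^(1 - alpha)
    (a + u * (b - a))^(1 / (1 - alpha))
  }
}

#' Simulate a contact set from a power-law mixture
#'
#' Distances are drawn i.i.d. from the density proportional to
#' \eqn{\sum_i \pi_i \beta_i s^{-\alpha_i}} truncated to the configured
#' range: a component is chosen from the multinomial with probabilities
#' proportional to \eqn{\pi_i \beta_i Z_i} (\eqn{Z_i} the component's
#' truncated mass), then the distance by the closed-form inverse CDF of
#' that component. Fixed-width 2 kb anchors are synthesized on one
#' chromosome (`chrS`) purely so that BEDPE I/O stays exercised; anchor
#' geometry does not affect the distances.
#'
#' @param config A [simulation_config()].
#' @return A [contact_set()] with `n_records` unit-count records.
#' @export
simulate_contacts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  comp <- config$components
  smin <- config$range_bp[1]
  smax <- config$range_bp[2]
  n <- config$n_records
  withr_seed(config$seed, {
    Z <- vapply(comp$alpha, truncated_mass, 0, smin = smin, smax = smax)
    bad <- which(!is.finite(Z) | Z <= 0 |
      !is.finite(smin^(1 - comp$alpha)) | !is.finite(smax^(1 - comp$alpha)))
    if (length(bad) > 0) {
      abort(paste0(
        "component ", paste(bad, collapse = ", "),
        ": alpha causes numerical overflow/underflow of the truncated mass ",
        "at the range bounds"
      ))
    }
    pp <- comp$pi * comp$beta * Z
    pp <- pp / sum(pp)
    idx <- sample.int(nrow(comp), n, replace = TRUE, prob = pp)
    s <- numeric(n)
    for (i in seq_len(nrow(comp))) {
      sel <- idx == i
      if (any(sel)) {
        s[sel] <- rtruncated_powerlaw(sum(sel), comp$alpha[i], smin, smax)
      }
    }
    anchor_w <- 2000
    start1 <- round(stats::runif(n, 0, smax))
    df <- tibble(
      chrom1 = "chrS",
      start1 = start1,
      end1 = start1 + anchor_w,
      chrom2 = "chrS",
      start2 = start1 + round(s) - anchor_w / 2,
      end2 = start1 + round(s) + anchor_w / 2,
      distance_bp = s,
      count = 1
    )
    contact_set(df, source_label = "simulate_contacts")
  })
}

#' Simulate a distance-independent score table
#'
#' Emulates the raw-proxy failure mode the penalty corrects: pair distances
#' are uniform over the range while raw scores are
#' `score_level * exp(N(0, noise_sd))`, independent of distance, so the
#' signal does not decay with genomic separation.
#'
#' @param config A [simulation_config()] (only `range_bp`, `n_records`,
#'   `seed`, `noise_sd`, `score_level` are used).
#' @return A `score_table` with uniform distances and distance-independent
#'   scores.
#' @export
simulate_flat_scores <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_records
  withr_seed(config$seed, {
    s <- stats::runif(n, config$range_bp[1], config$range_bp[2])
    raw <- config$score_level * exp(stats::rnorm(n, 0, config$noise_sd))
    anchor_w <- 2000
    start1 <- round(stats::runif(n, 0, config$range_bp[2]))
    score_table(
      tibble(
        chrom1 = "chrS", start1 = start1, end1 = start1 + anchor_w,
        chrom2 = "chrS", start2 = start1 + round(s) - anchor_w / 2,
        end2 = start1 + round(s) + anchor_w / 2,
        distance_bp = s,
        raw_score = raw
      ),
      score_kind = "coaccessibility"
    )
  })
}

#' Exact reference decay profile for a generating mixture
#'
#' Evaluates \eqn{\sum_i \pi_i \beta_i s^{-\alpha_i}} at the bin midpoints
#' of the standard comparison grid and normalizes to a maximum of 1.0 —
#' the ground-truth curve against which proxies are scored.
#'
#' @param config A [simulation_config()].
#' @param n_bins Number of log-spaced bins.
#' @param range_bp Profile range; defaults to the configured range.
#' @return A `normalized_profile`.
#' @export
make_reference_profile <- function(config, n_bins = 30, range_bp = config$range_bp) {
  stopifnot(inherits(config, "simulation_config"))
  edges <- make_bin_edges(range_bp[1], range_bp[2], n_bins, "log")
  mids <- bin_midpoints(edges, "log")
  v <- penalty_raw(config$components, mids)
  normalized_profile(mids, v, edges = edges, label = "reference")
}

#' Preset simulation configurations
#'
#' * `"maize-like"`: a single power law with exponent 2.34 over
#'   35 kb - 500 kb, the single-regime fluid-chromatin scenario.
#' * `"two-regime"`: a steep short-range regime (alpha = 6) crossing over
#'   to a shallow long-range regime (alpha = 0.5) at about 181 kb over
#'   35 kb - 10 Mb; components are scaled as truncated densities so both
#'   regimes are sampled.
#' * `"rice-like"`: a synthetic three-regime curve in the spirit of
#'   loop/TAD/compartment organization — a steep loop-scale regime
#'   (alpha = 6.6) to ~61 kb, a near-flat domain regime (alpha = 0.31) to
#'   ~1.5 Mb, and an illustrative long-range regime (alpha = 1.3) beyond,
#'   joined continuously over 35 kb - 20 Mb. The third exponent is an
#'   invented placeholder, not an empirical value.
#' * `"flat-scores"`: configuration for [simulate_flat_scores()] over
#'   35 kb - 500 kb with 20% log-normal score noise.
#'
#' @param name Preset name.
#' @param n_records,seed Override record count and seed.
#' @return A [simulation_config()].
#' @export
sim_preset <- function(name = c("maize-like", "two-regime", "rice-like", "flat-scores"),
                       n_records = NULL, seed = 42L) {
  name <- match.arg(name)
  if (name == "maize-like") {
    simulation_config(
      components = tibble(pi = 1, beta = 1, alpha = 2.34),
      range_bp = c(35e3, 5e5),
      n_records = n_records %||% 5e4,
      seed = seed
    )
  } else if (name == "two-regime") {
    smin <- 35e3
    smax <- 1e7
    crossover <- 181e3
    z2 <- truncated_mass(0.5, smin, smax)
    beta2 <- 1 / z2
    beta1 <- beta2 * crossover^(6 - 0.5)
    simulation_config(
      components = tibble(
        pi = c(0.5, 0.5),
        beta = c(beta1, beta2),
        alpha = c(6, 0.5)
      ),
      range_bp = c(smin, smax),
      n_records = n_records %||% 1e5,
      seed = seed
    )
  } else if (name == "rice-like") {
    s1 <- 61e3
    s2 <- 1.5e6
    beta2 <- 1
    beta1 <- beta2 * s1^(6.6 - 0.31)
    beta3 <- beta2 * s2^(1.3 - 0.31)
    simulation_config(
      components = tibble(
        pi = c(1, 1, 1) / 3,
        beta = c(beta1, beta2, beta3),
        alpha = c(6.6, 0.31, 1.3)
      ),
      range_bp = c(35e3, 2e7),
      n_records = n_records %||% 1e5,
      seed = seed
    )
  } else {
    simulation_config(
      components = tibble(pi = 1, beta = 1, alpha = 2.34),
      range_bp = c(35e3, 5e5),
      n_records = n_records %||% 2e4,
      seed = seed,
      noise_sd = 0.2,
      score_level = 1
    )
  }
}

#' Generating crossover distance of a two-component mixture
#'
#' The distance at which the two weighted power-law terms of a two-component
#' [simulation_config()] are equal — the ground-truth regime transition a
#' fitted model should recover.
#'
#' @param config A two-component [simulation_config()].
#' @return Crossover distance in bp.
#' @export
generating_crossover <- function(config) {
  comp <- config$components
  stopifnot(nrow(comp) == 2)
  ((comp$pi[1] * comp$beta[1]) / (comp$pi[2] * comp$beta[2]))^(1 / (comp$alpha[1] - comp$alpha[2]))
}

# run expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
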