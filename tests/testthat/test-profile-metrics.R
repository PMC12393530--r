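test_that("standardize_profile normalizes aggregates to a maximum of 1", {
  # constant scores give an all-ones profile
  st <- score_table(tibble::tibble(
    distance_bp = seq(4e4, 4.9e5, length.out = 200),
    raw_score = 0.7
  ))
  prof <- standardize_profile(st, n_bins = 10)
  expect_equal(prof$value, rep(1, 10))

  # a single occupied bin carries the 1, the rest are 0
  cs <- contact_set(tibble::tibble(
    chrom1 = "chr1", start1 = 0, end1 = 2000,
    chrom2 = "chr1", start2 = 99000, end2 = 101000, count = 5
  ))
  prof2 <- standardize_profile(cs, n_bins = 10)
  expect_equal(sum(prof2$value == 1), 1)
  expect_equal(sum(prof2$value), 1)

  # scores proportional to 1/s at the bin mids normalize to s_min_mid / s
  edges <- chromdecay:::make_bin_edges(35e3, 5e5, 10, "log")
  mids <- chromdecay:::bin_midpoints(edges, "log")
  st3 <- score_table(tibble::tibble(distance_bp = mids, raw_score = 1 / mids))
  prof3 <- standardize_profile(st3, n_bins = 10)
  expect_equal(prof3$value, mids[1] / mids, tolerance = 1e-12)

  expect_error(
    standardize_profile(
      score_table(tibble::tibble(distance_bp = 1e5, raw_score = 0))
    ),
    "all-zero"
  )
})

test_that("spearman concordance matches a brute-force rank oracle", {
  a <- toy_profile(c(1, .8, .6, .4, .2))
  expect_equal(spearman_concordance(a, a), 1)
  rev_b <- toy_profile(c(.2, .4, .6, .8, 1))
  expect_equal(spearman_concordance(a, rev_b), -1)

  # a tie in one profile: compare against hand-computed average ranks
  tied <- toy_profile(c(1, .5, .5, .3, .1))
  other <- toy_profile(c(.9, .7, .2, .4, .05))
  expect_equal(
    spearman_concordance(tied, other),
    spearman_oracle(tied$value, other$value),
    tolerance = 1e-12
  )

  flat <- toy_profile(rep(1, 5))
  expect_warning(r <- spearman_concordance(flat, other), "zero variance")
  expect_true(is.na(r))
})

test_that("wasserstein distance equals closed-form and brute-force transport minima", {
  a <- toy_profile(c(1, .5, .2, .1))
  expect_equal(wasserstein_distance(a, a), 0)

  # point masses 100 kb apart move their whole mass across that gap
  mids <- c(5e4, 1e5, 2e5, 3e5)
  pa <- normalized_profile(mids, c(0, 1, 0, 0))
  pb <- normalized_profile(mids, c(0, 0, 1, 0))
  expect_equal(wasserstein_distance(pa, pb), 1e5)

  # frozen exact minima from a linear-programming transport solver on
  # 3-bin instances (mids 50/100/200 kb)
  m3 <- c(5e4, 1e5, 2e5)
  expect_equal(
    wasserstein_distance(
      normalized_profile(m3, c(0.5, 0.3, 0.2)),
      normalized_profile(m3, c(0.1, 0.2, 0.7))
    ),
    70000
  )
  expect_equal(
    wasserstein_distance(
      normalized_profile(m3, c(1, 0, 0)),
      normalized_profile(m3, c(0, 0, 1))
    ),
    150000
  )
  expect_equal(
    wasserstein_distance(
      normalized_profile(m3, c(0.2, 0.5, 0.3)),
      normalized_profile(m3, c(0.4, 0.4, 0.2))
    ),
    20000,
    tolerance = 1e-9
  )

  # frozen 5-bin value from an independent distributional-distance routine
  m5 <- c(40e3, 80e3, 160e3, 320e3, 480e3)
  expect_equal(
    wasserstein_distance(
      normalized_profile(m5, c(5, 4, 3, 2, 1)),
      normalized_profile(m5, c(1, 1, 1, 1, 6))
    ),
    206666.66666666666,
    tolerance = 1e-9
  )

  # quantile-integral formulation agrees on random instances
  set.seed(21)
  for (i in 1:5) {
    wa <- runif(6)
    wb <- runif(6)
    mids6 <- sort(runif(6, 1e4, 1e6))
    got <- wasserstein_distance(
      normalized_profile(mids6, wa),
      normalized_profile(mids6, wb)
    )
    expect_equal(got, wasserstein_quantile_oracle(mids6, wa, wb), tolerance = 5e-3 * got + 1)
  }
})

test_that("area error rates match a fine-grid Riemann oracle", {
  a <- toy_profile(c(1, .7, .5, .3, .2, .1))
  expect_equal(area_error_rates(a, a), c(fpr = 0, fnr = 0))

  # when the reference lies entirely under the proxy the FPR has a closed form
  prox <- toy_profile(rep(1, 6))
  ref <- toy_profile(c(1, .4, .2, .1, .05, .02))
  rates <- area_error_rates(prox, ref)
  r <- chromdecay:::refine_crossings(prox$bin_mid_bp, prox$value, ref$value)
  a_p <- chromdecay:::trapz(r$x, r$a)
  a_r <- chromdecay:::trapz(r$x, r$b)
  expect_equal(unname(rates["fpr"]), (a_p - a_r) / a_p, tolerance = 1e-12)
  expect_equal(unname(rates["fnr"]), 0)

  set.seed(33)
  for (i in 1:10) {
    pair <- random_profile_pair()
    got <- area_error_rates(pair$proxy, pair$ref)
    want <- riemann_area_rates(pair$proxy, pair$ref, n_grid = 2e5)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("F1 follows the overlap-area identity with FPR and FNR", {
  a <- toy_profile(c(1, .7, .5, .3, .2, .1))
  expect_equal(f1_from_areas(a, a), 1)

  disjoint_a <- toy_profile(c(1, .5, 0, 0, 0, 0))
  disjoint_b <- toy_profile(c(0, 0, 0, 0, .5, 1))
  expect_equal(f1_from_areas(disjoint_a, disjoint_b), 0)

  set.seed(44)
  for (i in 1:10) {
    pair <- random_profile_pair()
    rates <- area_error_rates(pair$proxy, pair$ref)
    p <- 1 - rates[["fpr"]]
    r <- 1 - rates[["fnr"]]
    expect_equal(f1_from_areas(pair$proxy, pair$ref), 2 * p * r / (p + r), tolerance = 1e-12)
  }
})

test_that("compare_profiles assembles the full report on a shared grid", {
  cfg <- simulation_config(
    components = tibble::tibble(pi = 1, beta = 1, alpha = 2),
    range_bp = c(35e3, 5e5), n_records = 100, seed = 1
  )
  ref <- make_reference_profile(cfg)
  self <- compare_profiles(ref, ref)
  expect_equal(self$spearman_rho, 1)
  expect_equal(self$wasserstein_bp, 0)
  expect_equal(self$fpr, 0)
  expect_equal(self$fnr, 0)
  expect_equal(self$f1, 1)

  # a flat proxy against a steep reference: most of the proxy area is excess
  flat <- score_table(tibble::tibble(
    distance_bp = seq(36e3, 4.99e5, length.out = 3000),
    raw_score = 1
  ))
  expect_warning(rep2 <- compare_profiles(flat, ref), "zero variance")
  expect_true(is.na(rep2$spearman_rho)) # rank of a constant is undefined
  expect_gt(rep2$fpr, 0.8)
  expect_lt(rep2$f1, 0.35)

  long <- tidy(rep2)
  expect_equal(nrow(long), 5)
})

test_that("metrics are symmetric or scale-invariant as their definitions demand", {
  set.seed(55)
  pair <- random_profile_pair()
  expect_equal(
    wasserstein_distance(pair$proxy, pair$ref),
    wasserstein_distance(pair$ref, pair$proxy)
  )
  expect_equal(
    spearman_concordance(pair$proxy, pair$ref),
    spearman_concordance(pair$ref, pair$proxy)
  )
  # swapping proxy and reference swaps the numerator areas of FPR and FNR
  fwd <- area_error_rates(pair$proxy, pair$ref)
  bwd <- area_error_rates(pair$ref, pair$proxy)
  r <- chromdecay:::refine_crossings(pair$proxy$bin_mid_bp, pair$proxy$value, pair$ref$value)
  a_p <- chromdecay:::trapz(r$x, r$a)
  a_r <- chromdecay:::trapz(r$x, r$b)
  expect_equal(unname(fwd["fpr"]) * a_p, unname(bwd["fnr"]) * a_p, tolerance = 1e-12)
  expect_equal(unname(fwd["fnr"]) * a_r, unname(bwd["fpr"]) * a_r, tolerance = 1e-12)

  # max-1 normalization absorbs any positive rescaling of a raw signal
  st <- score_table(tibble::tibble(
    distance_bp = seq(4e4, 4.8e5, length.out = 500),
    raw_score = exp(-seq(4e4, 4.8e5, length.out = 500) / 2e5)
  ))
  st_scaled <- st
  st_scaled$raw_score <- 123 * st_scaled$raw_score
  cfg <- simulation_config(
    components = tibble::tibble(pi = 1, beta = 1, alpha = 1.5),
    range_bp = c(35e3, 5e5), n_records = 10, seed = 1
  )
  ref <- make_reference_profile(cfg)
  expect_equal(
    as.data.frame(compare_profiles(st, ref)),
    as.data.frame(compare_profiles(st_scaled, ref)),
    tolerance = 1e-12
  )

  # bounds
  rates <- area_error_rates(pair$proxy, pair$ref)
  expect_true(all(rates >= 0 & rates <= 1))
  w <- wasserstein_distance(pair$proxy, pair$ref)
  expect_lte(w, diff(range(pair$proxy$bin_mid_bp)))
})
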