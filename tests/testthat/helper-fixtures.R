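# Shared fixtures and independent oracles, all built in code at test time.

# write a BEDPE file from a row list; each row is c(chrom1, s1, e1, chrom2,
# s2, e2[, count])
write_toy_bedpe <- function(rows, path = tempfile(fileext = ".bedpe")) {
  lines <- vapply(rows, function(r) paste(r, collapse = "\t"), "")
  writeLines(lines, path)
  path
}

write_toy_scores <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

# exactly collinear log-log points y = intercept + slope * x
collinear_points <- function(slope, intercept, n = 20, x_range = c(4.2, 5.8)) {
  x <- seq(x_range[1], x_range[2], length.out = n)
  pts <- tibble::tibble(x = x, y = intercept + slope * x, bin = seq_len(n))
  structure(pts, class = c("log_points", class(pts)), n_skipped = 0L)
}

# profile on an arbitrary grid via the exported constructor
toy_profile <- function(values, mids = NULL) {
  if (is.null(mids)) {
    edges <- chromdecay:::make_bin_edges(35e3, 5e5, length(values), "log")
    mids <- chromdecay:::bin_midpoints(edges, "log")
  }
  normalized_profile(mids, values)
}

# --- independent oracles ----------------------------------------------------

# brute-force average-rank Spearman: Pearson correlation of hand-built ranks
spearman_oracle <- function(a, b) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  ra <- avg_rank(a)
  rb <- avg_rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# fine-grid Riemann midpoint sums for the area metrics, on the same
# piecewise-linear interpolation of the profiles
riemann_area_rates <- function(proxy, ref, n_grid = 1e6) {
  x <- proxy$bin_mid_bp
  g <- seq(min(x), max(x), length.out = n_grid + 1)
  gm <- (g[-1] + g[-length(g)]) / 2
  dg <- diff(g)
  pa <- approx(x, proxy$value, gm)$y
  pb <- approx(x, ref$value, gm)$y
  area_p <- sum(pa * dg)
  area_r <- sum(pb * dg)
  c(
    fpr = sum(pmax(pa - pb, 0) * dg) / area_p,
    fnr = sum(pmax(pb - pa, 0) * dg) / area_r
  )
}

# quantile-integral form of the 1-D Wasserstein distance between discrete
# distributions: W1 = int_0^1 |Qa(u) - Qb(u)| du on a fine u-grid
wasserstein_quantile_oracle <- function(mids, wa, wb, n_grid = 2e5) {
  wa <- wa / sum(wa)
  wb <- wb / sum(wb)
  u <- (seq_len(n_grid) - 0.5) / n_grid
  qa <- mids[findInterval(u, cumsum(wa), left.open = TRUE) + 1]
  qb <- mids[findInterval(u, cumsum(wb), left.open = TRUE) + 1]
  mean(abs(qa - qb))
}

# random positive piecewise-linear profile pair on a shared grid
random_profile_pair <- function(n_bins = 12) {
  edges <- chromdecay:::make_bin_edges(35e3, 5e5, n_bins, "log")
  mids <- chromdecay:::bin_midpoints(edges, "log")
  a <- stats::runif(n_bins, 0.02, 1)
  b <- stats::runif(n_bins, 0.02, 1)
  list(
    proxy = normalized_profile(mids, a),
    ref = normalized_profile(mids, b)
  )
}
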