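# Profile standardization and proxy-vs-reference concordance metrics:
# Spearman rho, 1-D Wasserstein distance, area-based FPR/FNR and F1.

#' Standardize a signal into a max-1 normalized decay profile
#'
#' Bins a contact set (summing counts) or a score table (averaging scores)
#' over a consistent distance range and divides by the maximum so the
#' profile peaks at 1.0. Profiles being compared must share one bin grid;
#' [compare_profiles()] takes care of that.
#'
#' @param signal A [contact_set()], `score_table`, or [decay_profile()]
#'   (used as already-binned values).
#' @param range_bp Length-2 distance range in bp (default 35 kb - 500 kb).
#' @param n_bins Number of log-spaced bins (default 30).
#' @param value_col For score tables: which column to aggregate
#'   (`"raw_score"` by default; pass `"penalized_score"` after
#'   [apply_penalty()]).
#' @param label Source label stored on the result.
#' @return A `normalized_profile` tibble with `bin_mid_bp` and `value`
#'   (max = 1), and attributes `edges` and `source_label`. Empty bins get
#'   value 0.
#' @export
standardize_profile <- function(signal, range_bp = c(35e3, 5e5), n_bins = 30,
                                value_col = "raw_score", label = NULL) {
  edges <- make_bin_edges(range_bp[1], range_bp[2], n_bins, "log")
  mids <- bin_midpoints(edges, "log")
  if (inherits(signal, "contact_set")) {
    b <- assign_bins(signal$distance_bp, edges)
    agg <- vapply(seq_len(n_bins), function(i) sum(signal$count[which(b == i)]), 0)
    label <- label %||% attr(signal, "source_label")
  } else if (inherits(signal, "score_table")) {
    if (!value_col %in% names(signal)) {
      abort(paste0("score table has no `", value_col, "` column"))
    }
    b <- assign_bins(signal$distance_bp, edges)
    agg <- vapply(seq_len(n_bins), function(i) {
      v <- signal[[value_col]][which(b == i)]
      if (length(v) == 0) 0 else mean(v)
    }, 0)
  } else if (inherits(signal, "decay_profile")) {
    if (nrow(signal) != n_bins || max(abs(log(signal$bin_mid_bp / mids))) > 1e-6) {
      abort("decay_profile signal must already be on the requested bin grid")
    }
    agg <- signal$value
  } else {
    abort("signal must be a contact_set, score_table, or decay_profile")
  }
  normalized_profile(mids, agg, edges = edges, label = label)
}

#' Build a max-1 normalized profile from values at bin midpoints
#'
#' @param bin_mid_bp Strictly increasing bin midpoints in bp.
#' @param values Non-negative signal values; divided by their maximum.
#' @param edges Optional bin edges, stored as an attribute.
#' @param label Optional source label.
#' @return A `normalized_profile` tibble.
#' @export
normalized_profile <- function(bin_mid_bp, values, edges = NULL, label = NULL) {
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("profile values must be finite and >= 0")
  }
  m <- max(values)
  if (m <= 0) abort("cannot normalize an all-zero profile")
  out <- tibble(bin_mid_bp = as.numeric(bin_mid_bp), value = values / m)
  structure(out,
    class = c("normalized_profile", class(out)),
    edges = edges, source_label = label
  )
}

check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "normalized_profile"), inherits(b, "normalized_profile"))
  if (nrow(a) != nrow(b) || max(abs(log(a$bin_mid_bp / b$bin_mid_bp))) > 1e-9) {
    abort("profiles must share one bin grid; standardize both with the same range and n_bins")
  }
  invisible(TRUE)
}

#' Spearman concordance between two normalized profiles
#'
#' Rank correlation (average ranks for ties) of the two profiles' values
#' over the shared bin grid, measuring how monotonically the proxy tracks
#' the reference.
#'
#' @param a,b `normalized_profile`s on the same grid with >= 3 bins.
#' @return Spearman rho in \[-1, 1\], or `NA` with a warning when either
#'   profile has zero variance.
#' @export
spearman_concordance <- function(a, b) {
  check_same_grid(a, b)
  if (nrow(a) < 3) abort("need at least 3 bins for a rank correlation")
  if (stats::sd(a$value) == 0 || stats::sd(b$value) == 0) {
    warn("Spearman undefined: a profile has zero variance")
    return(NA_real_)
  }
  as.numeric(cor(a$value, b$value, method = "spearman"))
}

#' 1-D Wasserstein (earth mover's) distance between profiles
#'
#' Both profiles are renormalized to total mass 1 and treated as discrete
#' distributions over their bin midpoints; the distance is
#' \eqn{\sum_i |F_a(i) - F_b(i)| \Delta mid_i}, the closed-form optimal
#' transport cost in one dimension. Units are bp.
#'
#' @param a,b `normalized_profile`s on the same grid.
#' @return Non-negative transport distance in bp.
#' @export
wasserstein_distance <- function(a, b) {
  check_same_grid(a, b)
  if (sum(a$value) <= 0 || sum(b$value) <= 0) {
    abort("Wasserstein distance needs positive total mass in both profiles")
  }
  pa <- a$value / sum(a$value)
  pb <- b$value / sum(b$value)
  ca <- cumsum(pa)
  cb <- cumsum(pb)
  m <- length(pa)
  sum(abs(ca[-m] - cb[-m]) * diff(a$bin_mid_bp))
}

# Piecewise-linear curves between bin mids with crossing points inserted,
# so positive/negative parts integrate exactly and the area identities
# (precision = 1 - FPR etc.) hold to machine precision.
refine_crossings <- function(x, ya, yb) {
  d <- ya - yb
  xs <- x
  as <- ya
  bs <- yb
  ins_x <- ins_a <- ins_b <- numeric()
  for (i in seq_len(length(x) - 1)) {
    if (d[i] * d[i + 1] < 0) {
      t <- d[i] / (d[i] - d[i + 1])
      ins_x <- c(ins_x, x[i] + t * (x[i + 1] - x[i]))
      ins_a <- c(ins_a, ya[i] + t * (ya[i + 1] - ya[i]))
      ins_b <- c(ins_b, yb[i] + t * (yb[i + 1] - yb[i]))
    }
  }
  o <- order(c(xs, ins_x))
  list(x = c(xs, ins_x)[o], a = c(as, ins_a)[o], b = c(bs, ins_b)[o])
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Area-based false positive and false negative rates
#'
#' Treats both max-1 normalized profiles as piecewise-linear curves over the
#' bin midpoints.
#' `FPR = integral of max(proxy - ref, 0) / integral of proxy`:
#' the fraction of the proxy's area that exceeds the reference.
#' `FNR = integral of max(ref - proxy, 0) / integral of ref`:
#' the fraction of the reference's area the proxy fails to cover.
#' Crossing points are inserted before trapezoidal integration so the
#' positive-part areas are exact for piecewise-linear curves.
#'
#' @param proxy,ref `normalized_profile`s on the same grid.
#' @return Named numeric vector `c(fpr = ..., fnr = ...)`, both in \[0, 1\].
#' @export
area_error_rates <- function(proxy, ref) {
  check_same_grid(proxy, ref)
  r <- refine_crossings(proxy$bin_mid_bp, proxy$value, ref$value)
  area_proxy <- trapz(r$x, r$a)
  area_ref <- trapz(r$x, r$b)
  if (area_proxy <= 0) abort("zero area under the proxy curve; FPR undefined")
  if (area_ref <= 0) abort("zero area under the reference curve; FNR undefined")
  fpr <- trapz(r$x, pmax(r$a - r$b, 0)) / area_proxy
  fnr <- trapz(r$x, pmax(r$b - r$a, 0)) / area_ref
  c(fpr = min(max(fpr, 0), 1), fnr = min(max(fnr, 0), 1))
}

#' F1 score from overlap areas
#'
#' Precision is the overlap area `integral of min(proxy, ref)` over the
#' proxy area, recall the overlap over the reference area, and
#' `F1 = 2 P R / (P + R)`. Under these definitions `P = 1 - FPR` and
#' `R = 1 - FNR` exactly (the overlap is each curve's area minus its excess
#' area), so the F1 is a deterministic function of the area error rates.
#'
#' @param proxy,ref `normalized_profile`s on the same grid.
#' @return F1 in \[0, 1\]; 0 when the curves do not overlap.
#' @export
f1_from_areas <- function(proxy, ref) {
  check_same_grid(proxy, ref)
  r <- refine_crossings(proxy$bin_mid_bp, proxy$value, ref$value)
  overlap <- trapz(r$x, pmin(r$a, r$b))
  if (overlap <= 0) {
    return(0)
  }
  area_proxy <- trapz(r$x, r$a)
  area_ref <- trapz(r$x, r$b)
  precision <- overlap / area_proxy
  recall <- overlap / area_ref
  2 * precision * recall / (precision + recall)
}

#' Compare a proxy signal against a reference decay profile
#'
#' Standardizes both signals on one shared bin grid and computes the full
#' concordance report: Spearman rho, Wasserstein distance, area FPR/FNR,
#' and F1.
#'
#' @param proxy_signal,ref_signal Anything [standardize_profile()] accepts,
#'   or an already-standardized `normalized_profile` (then it must be on the
#'   matching grid).
#' @param range_bp,n_bins Shared comparison grid (default 30 log-spaced bins
#'   over 35 kb - 500 kb).
#' @param proxy_value_col,ref_value_col Score column to aggregate when the
#'   corresponding signal is a score table.
#' @return A one-row `comparison_report` tibble with columns
#'   `spearman_rho`, `wasserstein_bp`, `fpr`, `fnr`, `f1`, `n_bins`,
#'   `range_min_bp`, `range_max_bp`.
#' @examples
#' cfg <- simulation_config(
#'   components = data.frame(pi = 1, beta = 1, alpha = 1),
#'   range_bp = c(35e3, 5e5), n_records = 1000, seed = 1
#' )
#' ref <- make_reference_profile(cfg)
#' compare_profiles(ref, ref)
#' @export
compare_profiles <- function(proxy_signal, ref_signal,
                             range_bp = c(35e3, 5e5), n_bins = 30,
                             proxy_value_col = "raw_score",
                             ref_value_col = "raw_score") {
  as_prof <- function(sig, col, what) {
    if (inherits(sig, "normalized_profile")) {
      return(sig)
    }
    tryCatch(
      standardize_profile(sig, range_bp, n_bins, value_col = col),
      error = function(e) {
        abort(paste0("standardizing the ", what, " signal failed: ", conditionMessage(e)))
      }
    )
  }
  proxy <- as_prof(proxy_signal, proxy_value_col, "proxy")
  ref <- as_prof(ref_signal, ref_value_col, "reference")
  metric <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("metric `", name, "` failed: ", conditionMessage(e)))
    })
  }
  rates <- metric("area_error_rates", area_error_rates(proxy, ref))
  out <- tibble(
    spearman_rho = metric("spearman_concordance", spearman_concordance(proxy, ref)),
    wasserstein_bp = metric("wasserstein_distance", wasserstein_distance(proxy, ref)),
    fpr = unname(rates["fpr"]),
    fnr = unname(rates["fnr"]),
    f1 = metric("f1_from_areas", f1_from_areas(proxy, ref)),
    n_bins = n_bins,
    range_min_bp = range_bp[1],
    range_max_bp = range_bp[2]
  )
  structure(out, class = c("comparison_report", class(out)))
}
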