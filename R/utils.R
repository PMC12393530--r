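# Internal helpers shared across modules.

# midpoint of a 0-based half-open interval, in bp
interval_midpoint <- function(start, end) (start + end) / 2

# anchor midpoint separation; anchors must be same-chromosome
anchor_distance <- function(start1, end1, start2, end2) {
  abs(interval_midpoint(start2, end2) - interval_midpoint(start1, end1))
}

# log-spaced or linear bin edges over [lo, hi]
make_bin_edges <- function(lo, hi, n_bins, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(lo > 0, hi > lo, n_bins >= 1)
  if (spacing == "log") {
    10^seq(log10(lo), log10(hi), length.out = n_bins + 1)
  } else {
    seq(lo, hi, length.out = n_bins + 1)
  }
}

# geometric midpoints for log-spaced edges, arithmetic otherwise
bin_midpoints <- function(edges, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  if (spacing == "log") sqrt(lo * hi) else (lo + hi) / 2
}

# half-open binning [edge_b, edge_{b+1}); values equal to the last edge are
# kept in the last bin so the range is closed on the right overall
assign_bins <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  b[x < edges[1] | x > edges[length(edges)]] <- NA_integer_
  b
}

# atomic write: run writer on a temp path in the target directory, then rename
write_atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
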