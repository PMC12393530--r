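#' Build a contact set from a data frame of locus pairs
#'
#' A contact set is a tibble of cis (same-chromosome) locus pairs, one row per
#' pair, with the genomic separation of the two anchors and a non-negative
#' contact weight. It is the raw material for distance-decay fitting.
#' Coordinates follow the BED convention: 0-based, half-open.
#'
#' @param x A data frame with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, and optionally `count` (defaults to 1 per row) and
#'   `distance_bp`. When `distance_bp` is absent it is computed as the
#'   absolute midpoint-to-midpoint separation of the two anchors in bp.
#' @param source_label Free-text provenance label stored as an attribute.
#' @param drop_trans Drop inter-chromosomal rows (with a message) instead of
#'   erroring. The decay model is strictly a function of linear distance, so
#'   trans pairs carry no usable signal.
#'
#' @return A `contact_set` tibble with columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `distance_bp`, `count`, and attributes
#'   `source_label` and `n_trans_dropped`.
#' @examples
#' df <- data.frame(
#'   chrom1 = "chr1", start1 = 100000, end1 = 105000,
#'   chrom2 = "chr1", start2 = 200000, end2 = 205000
#' )
#' contact_set(df)
#' @export
contact_set <- function(x, source_label = NA_character_, drop_trans = TRUE) {
  x <- as_tibble(x)
  needed <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "contact set is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  validate_intervals(x$chrom1, x$start1, x$end1, what = "anchor1")
  validate_intervals(x$chrom2, x$start2, x$end2, what = "anchor2")
  if (!"count" %in% names(x)) x$count <- 1
  if (any(!is.finite(x$count)) || any(x$count < 0)) {
    abort("contact counts must be finite and non-negative")
  }

  trans <- x$chrom1 != x$chrom2
  n_trans <- sum(trans)
  if (n_trans > 0) {
    if (!drop_trans) abort(paste0(n_trans, " trans (inter-chromosomal) row(s) present"))
    inform(paste0("dropped ", n_trans, " trans (inter-chromosomal) row(s)"))
    x <- x[!trans, , drop = FALSE]
  }
  if (!"distance_bp" %in% names(x)) {
    x$distance_bp <- anchor_distance(x$start1, x$end1, x$start2, x$end2)
  }
  if (any(!is.finite(x$distance_bp)) || any(x$distance_bp <= 0)) {
    abort("contact distances must be finite and > 0 (identical anchors are not contacts)")
  }
  x <- dplyr::relocate(x, dplyr::all_of(c(needed, "distance_bp", "count")))
  new_contact_set(x, source_label = source_label, n_trans_dropped = n_trans)
}

new_contact_set <- function(x, source_label = NA_character_, n_trans_dropped = 0L) {
  structure(
    x,
    class = c("contact_set", class(as_tibble(x))),
    source_label = source_label,
    n_trans_dropped = n_trans_dropped
  )
}

validate_intervals <- function(chrom, start, end, what = "interval") {
  bad <- which(is.na(chrom) | !nzchar(chrom) | !is.finite(start) |
    !is.finite(end) | start < 0 | end <= start)
  if (length(bad) > 0) {
    abort(paste0(
      "invalid ", what, " coordinates at row(s) ",
      paste(head(bad, 5), collapse = ", "),
      " (need chrom non-empty, start >= 0, end > start)"
    ))
  }
  invisible(TRUE)
}

#' Restrict a contact set to a genomic distance window
#'
#' Filtering is idempotent: applying the same bounds twice equals applying
#' them once.
#'
#' @param contacts A `contact_set`.
#' @param min_distance_bp,max_distance_bp Inclusive distance bounds in bp;
#'   `NULL` leaves that side unbounded.
#' @return The filtered `contact_set`; a warning is raised if no rows survive.
#' @export
filter_contacts <- function(contacts, min_distance_bp = NULL, max_distance_bp = NULL) {
  stopifnot(inherits(contacts, "contact_set"))
  keep <- rep(TRUE, nrow(contacts))
  if (!is.null(min_distance_bp)) keep <- keep & contacts$distance_bp >= min_distance_bp
  if (!is.null(max_distance_bp)) keep <- keep & contacts$distance_bp <= max_distance_bp
  out <- contacts[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("no contacts remain after distance filtering")
  }
  new_contact_set(
    out,
    source_label = attr(contacts, "source_label"),
    n_trans_dropped = attr(contacts, "n_trans_dropped") %||% 0L
  )
}

#' @export
print.contact_set <- function(x, ...) {
  lbl <- attr(x, "source_label")
  cat(
    "# contact_set: ", nrow(x), " cis contact(s)",
    if (!is.na(lbl)) paste0(" [", lbl, "]"), "\n",
    sep = ""
  )
  NextMethod()
}
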