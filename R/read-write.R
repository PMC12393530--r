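# File-format frontends: BEDPE contact lists, TSV score tables and binned
# profiles, JSON penalty-parameter files. All coordinates are 0-based
# half-open (BED convention); all distances are in bp.

#' Read a BEDPE loop/contact list
#'
#' Reads the 6+-column tab-separated BEDPE interchange format produced by
#' loop callers. Column 7, when present and numeric, is taken as the contact
#' count/weight (one loop call per row otherwise). Lines starting with `#`
#' are ignored. The per-row genomic distance is the absolute
#' midpoint-to-midpoint separation of the two anchors; trans
#' (inter-chromosomal) rows are dropped with a message because the decay
#' model is a function of linear distance only.
#'
#' @param path Path to a BEDPE file.
#' @param min_distance_bp,max_distance_bp Optional inclusive distance filter
#'   in bp applied after reading.
#' @param count_col Index of the column holding the contact weight, or `NULL`
#'   to auto-detect a numeric column 7 (unit weights otherwise).
#' @return A [contact_set()] tibble.
#' @export
read_bedpe <- function(path, min_distance_bp = NULL, max_distance_bp = NULL,
                       count_col = NULL) {
  if (!file.exists(path)) abort(paste0("BEDPE file not found: ", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    warn("BEDPE file contains no data lines; returning an empty contact set")
    return(contact_set(empty_contact_df(), source_label = basename(path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(paste0(
      "BEDPE line(s) with fewer than 6 tab-separated columns: line ",
      paste(head(line_no[nf < 6], 5), collapse = ", ")
    ))
  }
  get_col <- function(i) vapply(fields, `[[`, "", i)
  start1 <- suppressWarnings(as.numeric(get_col(2)))
  end1 <- suppressWarnings(as.numeric(get_col(3)))
  start2 <- suppressWarnings(as.numeric(get_col(5)))
  end2 <- suppressWarnings(as.numeric(get_col(6)))
  bad <- !is.finite(start1) | !is.finite(end1) | !is.finite(start2) |
    !is.finite(end2) | start1 < 0 | start2 < 0 | end1 <= start1 | end2 <= start2
  if (any(bad)) {
    abort(paste0(
      "malformed BEDPE coordinates (non-integer, negative, or end <= start) at line ",
      paste(head(line_no[bad], 5), collapse = ", ")
    ))
  }
  count <- rep(1, length(lines))
  ci <- count_col
  if (is.null(ci) && any(nf >= 7)) {
    c7 <- suppressWarnings(as.numeric(vapply(fields, function(f) {
      if (length(f) >= 7) f[[7]] else NA_character_
    }, "")))
    if (all(is.finite(c7) | nf < 7)) ci <- 7L
  }
  if (!is.null(ci)) {
    cv <- suppressWarnings(as.numeric(vapply(fields, function(f) {
      if (length(f) >= ci) f[[ci]] else "1"
    }, "")))
    if (any(!is.finite(cv))) {
      abort(paste0(
        "non-numeric count value at line ",
        paste(head(line_no[!is.finite(cv)], 5), collapse = ", ")
      ))
    }
    count <- cv
  }
  df <- tibble(
    chrom1 = get_col(1), start1 = start1, end1 = end1,
    chrom2 = get_col(4), start2 = start2, end2 = end2,
    count = count
  )
  out <- contact_set(df, source_label = basename(path))
  if (!is.null(min_distance_bp) || !is.null(max_distance_bp)) {
    out <- filter_contacts(out, min_distance_bp, max_distance_bp)
  }
  out
}

empty_contact_df <- function() {
  tibble(
    chrom1 = character(), start1 = numeric(), end1 = numeric(),
    chrom2 = character(), start2 = numeric(), end2 = numeric(),
    count = numeric()
  )
}

#' Write a contact set as BEDPE
#'
#' @param contacts A [contact_set()].
#' @param path Output path; written atomically (temp file + rename).
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(contacts, path) {
  stopifnot(inherits(contacts, "contact_set"))
  write_atomically(path, function(tmp) {
    df <- contacts[, c(
      "chrom1", "start1", "end1", "chrom2", "start2",
      "end2", "count"
    )]
    readr::write_tsv(df, tmp, col_names = FALSE)
  })
}

#' Read an interaction score table
#'
#' Score tables carry pairwise interaction scores (scATAC-seq
#' co-accessibility, sequence-model predictions, ...) with their genomic
#' distances. Required: a `raw_score` column plus either a `distance_bp`
#' column or the six anchor columns `chrom1,start1,end1,chrom2,start2,end2`
#' (the distance is then the anchor midpoint separation). Unknown extra
#' columns are preserved and passed through.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param score_kind One of `"coaccessibility"`, `"dl_prediction"`,
#'   `"other"`; stored as an attribute.
#' @return A `score_table` tibble with at least `distance_bp` and
#'   `raw_score`, row order preserved.
#' @export
read_score_table <- function(path, score_kind = c("other", "coaccessibility", "dl_prediction")) {
  score_kind <- match.arg(score_kind)
  if (!file.exists(path)) abort(paste0("score table not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  score_table(x, score_kind = score_kind)
}

#' Build a score table from a data frame
#'
#' @param x Data frame with `raw_score` and either `distance_bp` or the six
#'   anchor columns; see [read_score_table()].
#' @param score_kind Stored as attribute `score_kind`.
#' @return A `score_table` tibble.
#' @export
score_table <- function(x, score_kind = "other") {
  x <- as_tibble(x)
  if (!"raw_score" %in% names(x)) {
    abort("score table needs a `raw_score` column (expected columns: chrom1,start1,end1,chrom2,start2,end2[,distance_bp],raw_score)")
  }
  anchors <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!"distance_bp" %in% names(x)) {
    if (!all(anchors %in% names(x))) {
      abort(paste0(
        "score table needs either a `distance_bp` column or all anchor columns ",
        paste(anchors, collapse = ",")
      ))
    }
    validate_intervals(x$chrom1, x$start1, x$end1, what = "anchor1")
    validate_intervals(x$chrom2, x$start2, x$end2, what = "anchor2")
    x$distance_bp <- anchor_distance(x$start1, x$end1, x$start2, x$end2)
  }
  if (!is.numeric(x$raw_score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x$raw_score))))
    abort(paste0(
      "non-numeric raw_score at row(s) ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  if (any(!is.finite(x$distance_bp)) || any(x$distance_bp <= 0)) {
    bad <- which(!is.finite(x$distance_bp) | x$distance_bp <= 0)
    abort(paste0(
      "distance_bp must be finite and > 0; offending row(s) ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  structure(x, class = c("score_table", class(x)), score_kind = score_kind)
}

#' Write a score table as TSV
#'
#' @param scores A `score_table` (or plain data frame).
#' @param path Output path; written atomically.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  write_atomically(path, function(tmp) readr::write_tsv(as_tibble(scores), tmp))
}

#' Read / write a binned decay profile
#'
#' Profiles are tab-separated tables with columns `bin_start_bp`,
#' `bin_end_bp`, `bin_mid_bp`, `value`; bins must be sorted and
#' non-overlapping. The round trip `read_profile(write_profile(p))` is
#' lossless.
#'
#' @param path Path to a profile TSV.
#' @return A `decay_profile` tibble.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("profile not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("bin_start_bp", "bin_end_bp", "bin_mid_bp", "value")
  if (!all(needed %in% names(x))) {
    abort(paste0("profile needs columns ", paste(needed, collapse = ", ")))
  }
  decay_profile(x)
}

#' @rdname read_profile
#' @param profile A `decay_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "decay_profile"))
  write_atomically(path, function(tmp) readr::write_tsv(as_tibble(profile), tmp))
}

#' Build a decay profile from binned values
#'
#' @param x Data frame with `bin_start_bp`, `bin_end_bp`, `bin_mid_bp`,
#'   `value`.
#' @return A `decay_profile` tibble.
#' @export
decay_profile <- function(x) {
  x <- as_tibble(x)[, c("bin_start_bp", "bin_end_bp", "bin_mid_bp", "value")]
  if (nrow(x) > 0) {
    if (any(x$bin_end_bp <= x$bin_start_bp)) {
      abort("profile bins must satisfy bin_end_bp > bin_start_bp")
    }
    if (is.unsorted(x$bin_start_bp, strictly = TRUE) ||
      any(x$bin_start_bp[-1] < x$bin_end_bp[-nrow(x)] - 1e-9)) {
      abort("profile bins must be sorted and non-overlapping")
    }
    if (any(!is.finite(x$value)) || any(x$value < 0)) {
      abort("profile values must be finite and >= 0")
    }
  }
  structure(x, class = c("decay_profile", class(x)))
}

# ---- penalty parameter JSON files -----------------------------------------

#' Construct a penalty-parameter object
#'
#' Holds the fitted mixture \eqn{P(s) = \sum_i \pi_i \beta_i s^{-\alpha_i}}
#' together with fit metadata. Distances are always in bp, so the
#' \eqn{\beta_i} scale factors are on the bp scale.
#'
#' @param components Data frame with columns `pi`, `beta`, `alpha` and
#'   optionally `x_min`, `x_max` (log10 bp range hard-assigned to the
#'   component) and `r_squared`.
#' @param fit_range_bp Length-2 numeric, the distance window the model was
#'   fitted on.
#' @param species_label Free-text label.
#' @param normalization `"none"` or `"max_one_on_fit_range"` (the latter
#'   rescales the evaluated penalty to a maximum of 1 on the fit range so it
#'   only down-weights).
#' @param selection Optional per-n model-selection table (columns `n`, `bic`,
#'   `aic`, ...).
#' @param transitions_bp Optional numeric vector of regime-transition
#'   distances.
#' @param seed RNG seed recorded for provenance.
#' @param generated_by Optional provenance list (tool version, input hash...).
#' @return A `penalty_params` object.
#' @examples
#' p <- penalty_params(data.frame(pi = 1, beta = 1, alpha = 2.34),
#'   fit_range_bp = c(35e3, 5e5)
#' )
#' evaluate_penalty(p, 1e5)
#' @export
penalty_params <- function(components, fit_range_bp,
                           species_label = NA_character_,
                           normalization = c("max_one_on_fit_range", "none"),
                           selection = NULL, transitions_bp = numeric(),
                           seed = NA_integer_, generated_by = NULL) {
  normalization <- match.arg(normalization)
  components <- as_tibble(components)
  needed <- c("pi", "beta", "alpha")
  if (!all(needed %in% names(components))) {
    abort("components need columns pi, beta, alpha")
  }
  for (extra in c("x_min", "x_max", "r_squared")) {
    if (!extra %in% names(components)) components[[extra]] <- NA_real_
  }
  obj <- structure(
    list(
      species_label = species_label,
      components = components[, c("pi", "beta", "alpha", "x_min", "x_max", "r_squared")],
      fit_range_bp = as.numeric(fit_range_bp),
      n_components = nrow(components),
      normalization = normalization,
      selection = if (!is.null(selection)) as_tibble(selection) else NULL,
      transitions_bp = as.numeric(transitions_bp),
      distance_units = "bp",
      seed = seed,
      generated_by = generated_by
    ),
    class = "penalty_params"
  )
  validate_penalty_params(obj)
}

validate_penalty_params <- function(p, pi_tol = 1e-6) {
  comp <- p$components
  if (nrow(comp) < 1) abort("penalty needs at least one component")
  if (any(!is.finite(comp$alpha))) abort("component alpha values must be finite")
  if (any(!is.finite(comp$beta)) || any(comp$beta <= 0)) {
    abort("component beta values must be finite and > 0")
  }
  if (any(comp$pi <= 0) || any(comp$pi > 1)) {
    abort("component weights pi must lie in (0, 1]")
  }
  if (abs(sum(comp$pi) - 1) > pi_tol) {
    abort(paste0(
      "component weights must sum to 1 (got ",
      format(sum(comp$pi), digits = 10), ")"
    ))
  }
  if (length(p$fit_range_bp) != 2 || !all(is.finite(p$fit_range_bp)) ||
    p$fit_range_bp[1] <= 0 || p$fit_range_bp[1] >= p$fit_range_bp[2]) {
    abort("fit_range_bp must be [s_min, s_max] with 0 < s_min < s_max")
  }
  p
}

#' Read / write penalty parameters as JSON
#'
#' The JSON schema is
#' `{"species": str, "fit_range_bp": [int, int], "normalization": str,
#'   "components": [{"pi": f, "beta": f, "alpha": f}, ...]}`
#' plus optional `selection_table`, `transitions_bp`, `seed`, and
#' `generated_by` blocks. `read_penalty_params(write_penalty_params(p))` is
#' an identity within 1e-12 per field.
#'
#' @param path Path to a JSON parameter file.
#' @return A [penalty_params()] object.
#' @export
read_penalty_params <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter file not found: ", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$components)) abort("parameter JSON needs a `components` array")
  comp <- as_tibble(x$components)
  penalty_params(
    components = comp,
    fit_range_bp = x$fit_range_bp,
    species_label = x$species %||% NA_character_,
    normalization = x$normalization %||% "max_one_on_fit_range",
    selection = x$selection_table,
    transitions_bp = x$transitions_bp %||% numeric(),
    seed = x$seed %||% NA_integer_,
    generated_by = x$generated_by
  )
}

#' @rdname read_penalty_params
#' @param params A [penalty_params()] object.
#' @export
write_penalty_params <- function(params, path) {
  stopifnot(inherits(params, "penalty_params"))
  payload <- list(
    species = params$species_label,
    fit_range_bp = params$fit_range_bp,
    normalization = params$normalization,
    components = params$components,
    selection_table = params$selection,
    transitions_bp = params$transitions_bp,
    seed = params$seed,
    generated_by = params$generated_by
  )
  payload <- payload[!vapply(payload, is.null, TRUE)]
  write_atomically(path, function(tmp) {
    jsonlite::write_json(payload, tmp,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
  })
}

#' @export
print.penalty_params <- function(x, ...) {
  cat("# penalty_params: P(s) = sum_i pi_i beta_i s^-alpha_i\n")
  if (!is.na(x$species_label)) cat("  species:      ", x$species_label, "\n")
  cat(
    "  fit range:    ", format(x$fit_range_bp[1], big.mark = ","), "-",
    format(x$fit_range_bp[2], big.mark = ","), "bp\n"
  )
  cat("  normalization:", x$normalization, "\n")
  if (length(x$transitions_bp) > 0) {
    cat(
      "  transitions:  ",
      paste(sprintf("%.1f kb", x$transitions_bp / 1e3), collapse = ", "), "\n"
    )
  }
  print(x$components)
  invisible(x)
}
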