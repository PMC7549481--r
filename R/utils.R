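# Shared validation helpers. All user-facing errors go through rlang::abort
# with class "jakstatpd_error" so callers can catch them uniformly.

stop_jak <- function(msg, ...) {
  rlang::abort(paste0(msg, ...), class = "jakstatpd_error")
}

#' @noRd
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_jak(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Expression tables are wide tibbles: a `feature_id` character column followed
# by one numeric column per sample. These two helpers convert to/from the
# matrix form used internally for numerics.

#' Convert a wide expression tibble to a numeric matrix
#'
#' @param expr A tibble with a `feature_id` column and one numeric column per
#'   sample.
#' @return A numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
expr_matrix <- function(expr) {
  validate_expression(expr)
  m <- as.matrix(expr[setdiff(names(expr), "feature_id")])
  rownames(m) <- expr$feature_id
  m
}

#' Convert a numeric matrix back to a wide expression tibble
#'
#' @param m A numeric matrix with rownames (features) and colnames (samples).
#' @return A tibble with `feature_id` first, then one column per sample.
#' @export
expr_tibble <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_jak("matrix must carry feature rownames and sample colnames")
  }
  dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

#' Validate a wide expression tibble
#'
#' Checks the invariants every expression table must satisfy: a `feature_id`
#' column of unique ids, at least one feature, at least two unique sample
#' columns, and all-finite numeric values.
#'
#' @param expr Expression tibble.
#' @param min_samples Minimum number of sample columns (default 2).
#' @return `expr`, invisibly.
#' @export
validate_expression <- function(expr, min_samples = 2) {
  check_columns(expr, "feature_id", "expression table")
  sample_ids <- setdiff(names(expr), "feature_id")
  if (nrow(expr) < 1) stop_jak("expression table has no features")
  if (length(sample_ids) < min_samples) {
    stop_jak(sprintf(
      "expression table needs at least %d sample columns, found %d",
      min_samples, length(sample_ids)
    ))
  }
  dup_f <- unique(expr$feature_id[duplicated(expr$feature_id)])
  if (length(dup_f) > 0) {
    stop_jak("duplicate feature ids: ", paste(dup_f, collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    stop_jak("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  }
  vals <- as.matrix(expr[sample_ids])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(expr[sample_ids], is.numeric, logical(1)))
    stop_jak(
      "non-numeric expression column(s): ",
      paste(sample_ids[bad], collapse = ", ")
    )
  }
  if (any(!is.finite(vals))) {
    idx <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop_jak(sprintf(
      "non-finite expression value at feature '%s', sample '%s'",
      expr$feature_id[idx[1]], sample_ids[idx[2]]
    ))
  }
  invisible(expr)
}

#' Validate a sample metadata table
#'
#' @param meta Tibble with at least `sample_id`, `patient_id`, `group`,
#'   `visit_week`.
#' @return `meta`, invisibly.
#' @export
validate_meta <- function(meta) {
  check_columns(meta, c("sample_id", "patient_id", "group", "visit_week"),
                "sample metadata")
  bad_group <- setdiff(unique(meta$group), trial_groups())
  if (length(bad_group) > 0) {
    stop_jak("unknown group(s): ", paste(bad_group, collapse = ", "))
  }
  key <- paste(meta$patient_id, meta$visit_week)
  if (anyDuplicated(key)) {
    stop_jak(
      "duplicated (patient_id, visit_week) pairs: ",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    )
  }
  hc <- meta[meta$group == "healthy", ]
  if (nrow(hc) > 0 && any(hc$visit_week != 0)) {
    stop_jak("healthy controls must have visit_week 0 only")
  }
  invisible(meta)
}

#' Trial group labels
#'
#' The four groups used throughout: healthy controls plus the three trial
#' arms (placebo, 2 mg and 4 mg once-daily JAK1/JAK2 inhibitor).
#'
#' @return Character vector of group labels.
#' @export
trial_groups <- function() c("healthy", "placebo", "bari2mg", "bari4mg")

#' Treatment arms (excluding healthy controls)
#' @return Character vector of arm labels, placebo first.
#' @export
trial_arms <- function() c("placebo", "bari2mg", "bari4mg")

# relative dose scaling used by the generator: placebo 0, 2 mg = dose_ratio,
# 4 mg = 1
dose_scale <- function(arm, dose_ratio = 0.5) {
  unname(c(placebo = 0, bari2mg = dose_ratio, bari4mg = 1)[arm])
}
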