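# Readers and writers for the plain-text formats used at module boundaries:
# TSV for matrices and tables, GMT for gene signatures, SIF/TSV for
# interaction edges, YAML for run configuration. All TSVs are UTF-8,
# tab-separated, '.' decimal.

#' Read a log2 expression matrix from TSV
#'
#' First column holds feature ids, remaining columns one sample each
#' (header row carries the sample ids).
#'
#' @param path Path to a TSV file.
#' @return A wide expression tibble (`feature_id` + one column per sample).
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_jak("file not found: ", path)
  header <- strsplit(readLines(path, n = 1, warn = FALSE), "\t", fixed = TRUE)[[1]]
  dup_h <- unique(header[-1][duplicated(header[-1])])
  if (length(dup_h) > 0) {
    stop_jak("duplicate sample ids in header: ", paste(dup_h, collapse = ", "))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 3) {
    stop_jak("expression TSV needs a feature column and >= 2 sample columns: ", path)
  }
  names(raw)[1] <- "feature_id"
  sample_ids <- setdiff(names(raw), "feature_id")
  out <- raw
  for (s in sample_ids) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v) & !is.na(raw[[s]]))
    if (length(bad) > 0) {
      stop_jak(sprintf(
        "non-numeric value '%s' at row %d (feature '%s'), column '%s' in %s",
        raw[[s]][bad[1]], bad[1], raw$feature_id[bad[1]], s, path
      ))
    }
    out[[s]] <- v
  }
  validate_expression(out)
  out
}

#' Write an expression tibble to TSV
#'
#' @param expr Wide expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expected columns: sample_id, patient_id, group, visit_week, age, sex and
#' any cell-count covariates (e.g. leucocytes).
#'
#' @param path Path to a TSV file.
#' @return A metadata tibble, validated.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop_jak("file not found: ", path)
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_meta(meta)
  meta
}

#' Read longitudinal clinical scores (SLEDAI-2K) from TSV
#'
#' Expected columns: patient_id, visit_week, sledai2k.
#'
#' @param path Path to a TSV file.
#' @return A long tibble of trajectories.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop_jak("file not found: ", path)
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(tr, c("patient_id", "visit_week", "sledai2k"), "trajectories")
  validate_trajectories(tr)
  tr
}

#' Validate a trajectory table
#'
#' SLEDAI-2K scores are non-negative integers bounded by the maximum
#' attainable score (105); every patient must have a week-0 visit and
#' strictly increasing weeks.
#'
#' @param tr Trajectory tibble.
#' @return `tr`, invisibly.
#' @export
validate_trajectories <- function(tr) {
  if (any(tr$sledai2k < 0 | tr$sledai2k > 105 | tr$sledai2k != round(tr$sledai2k))) {
    stop_jak("sledai2k scores must be integers in [0, 105]")
  }
  by_pat <- split(tr$visit_week, tr$patient_id)
  no_base <- names(by_pat)[!vapply(by_pat, function(w) 0 %in% w, logical(1))]
  if (length(no_base) > 0) {
    stop_jak("patients missing week-0 visit: ", paste(no_base, collapse = ", "))
  }
  not_incr <- names(by_pat)[vapply(by_pat, function(w) any(diff(w) <= 0), logical(1))]
  if (length(not_incr) > 0) {
    stop_jak("visit weeks not strictly increasing for: ",
             paste(not_incr, collapse = ", "))
  }
  invisible(tr)
}

#' Read a cytokine measurement table from TSV
#'
#' Expected columns: analyte, patient_id, visit_week, concentration (may be
#' empty when censored), lloq, below_lloq.
#'
#' @param path Path to a TSV file.
#' @return A cytokine measurement tibble.
#' @export
read_cytokines <- function(path) {
  if (!file.exists(path)) stop_jak("file not found: ", path)
  cy <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(cy, c("analyte", "patient_id", "visit_week", "concentration",
                      "lloq", "below_lloq"), "cytokine table")
  cy$below_lloq <- as.logical(cy$below_lloq)
  if (any(is.na(cy$lloq)) || any(cy$lloq <= 0)) {
    stop_jak("every measurement needs a positive LLOQ")
  }
  cy
}

#' Write a generic tibble to TSV
#' @param x Tibble. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one signature per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are deduplicated with a warning.
#'
#' @param path Path to a GMT file.
#' @return A long tibble with columns `signature`, `description`, `gene`;
#'   zero rows for an empty file.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_jak("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble::tibble(signature = character(), description = character(),
                          gene = character())
  if (length(lines) == 0) return(empty)
  out <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_jak(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                       i, length(fields)))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      dup <- unique(genes[duplicated(genes)])
      rlang::warn(sprintf("GMT line %d ('%s'): duplicated gene(s) %s deduplicated",
                          i, fields[1], paste(dup, collapse = ", ")))
      genes <- unique(genes)
    }
    tibble::tibble(signature = fields[1], description = fields[2], gene = genes)
  })
  dplyr::bind_rows(out)
}

#' Write gene signatures to a GMT file
#'
#' @param signatures Long tibble with `signature`, `description`, `gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  check_columns(signatures, c("signature", "description", "gene"), "signatures")
  lines <- signatures |>
    dplyr::group_by(.data$signature, .data$description) |>
    dplyr::summarise(line = paste(.data$gene, collapse = "\t"), .groups = "drop") |>
    dplyr::mutate(line = paste(.data$signature, .data$description, .data$line,
                               sep = "\t"))
  writeLines(lines$line, path)
  invisible(path)
}

#' Extract one signature's genes from a GMT tibble
#'
#' @param signatures Long tibble as returned by [read_gmt()].
#' @param name Signature name.
#' @return Character vector of gene ids.
#' @export
signature_genes <- function(signatures, name) {
  g <- signatures$gene[signatures$signature == name]
  if (length(g) == 0) stop_jak("signature not found: ", name)
  unique(g)
}

#' Read a gene-gene interaction table (SIF or TSV)
#'
#' SIF lines are `source<TAB>relation<TAB>target`. A TSV with a header row
#' containing `source` and `target` columns (plus optional `mechanism` and
#' `directed`) is also accepted. Mechanisms are normalized to
#' transcription_regulation / phosphorylation / other. Self-loops are
#' dropped with a message.
#'
#' @param path Path to the edge file.
#' @return Tibble with columns `source`, `target`, `mechanism`, `directed`.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop_jak("file not found: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  has_header <- grepl("source", first, ignore.case = TRUE) &&
    grepl("target", first, ignore.case = TRUE)
  if (has_header) {
    e <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    names(e) <- tolower(names(e))
    check_columns(e, c("source", "target"), "interaction table")
    if (!"mechanism" %in% names(e)) e$mechanism <- "other"
    if (!"directed" %in% names(e)) e$directed <- TRUE
  } else {
    e <- readr::read_tsv(path, col_names = c("source", "mechanism", "target"),
                         show_col_types = FALSE, progress = FALSE)
    e$directed <- TRUE
  }
  normalize_edges(tibble::as_tibble(e[c("source", "target", "mechanism", "directed")]))
}

# canonicalizes mechanism labels and drops self-loops
normalize_edges <- function(edges) {
  mech <- tolower(gsub("[ -]", "_", edges$mechanism))
  mech[grepl("transcription", mech)] <- "transcription_regulation"
  mech[grepl("phospho", mech)] <- "phosphorylation"
  mech[!mech %in% c("transcription_regulation", "phosphorylation")] <- "other"
  edges$mechanism <- mech
  loops <- edges$source == edges$target
  if (any(loops)) {
    rlang::inform(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    edges <- edges[!loops, ]
  }
  edges
}

#' Default run configuration
#'
#' Central defaults shared by the pipeline stages: Monte Carlo iteration
#' count, significance level, visit schedule, the percentile used for the
#' STAT1/STAT2 co-elevation call and the MMRM options.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    rng_seed = 1L,
    n_permutations = 10000L,
    alpha = 0.05,
    visit_weeks = c(0, 2, 4, 12, 24),
    percentile_threshold = 95,
    mmrm = list(
      covariance = "spatial_power",
      estimation = "REML",
      covariates = c("age", "sex", "leucocytes"),
      log_covariates = "leucocytes",
      max_iter = 100L,
      tol = 1e-6
    )
  )
  utils::modifyList(cfg, list(...))
}

#' Read a YAML run-configuration file
#'
#' Keys present in the file override the package defaults; everything else
#' keeps its default.
#'
#' @param path Path to a YAML file (optional; `NULL` returns the defaults).
#' @return A configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_jak("file not found: ", path)
  user <- yaml::read_yaml(path)
  if (length(user) > 0) cfg <- utils::modifyList(cfg, user)
  if (cfg$n_permutations < 1) stop_jak("n_permutations must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_jak("alpha must be in (0, 1)")
  cfg
}
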