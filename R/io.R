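# CSV and JSON input/output: examination records, reference datasets, model
# configuration, and score tables.

.normalize_minus <- function(x) {
  # Unicode minus / en-dash pasted from reports -> ASCII hyphen-minus
  gsub("[−–]", "-", x)
}

#' Read examination records from CSV
#'
#' The header must contain the six feature names (any order, any case);
#' a `label` column is optional. Decimal separator is the dot; Unicode minus
#' signs are normalized before parsing. Unparseable cells are collected and
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @param validate Run [validate_records()] on the parsed records.
#' @return Data frame of examination records (plus `label` when present).
#' @export
read_exams <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE),
    error = function(e) stop("empty or unreadable examination file: ", path,
                             call. = FALSE))
  if (nrow(raw) == 0 || ncol(raw) == 0) stop("empty examination file: ", path)
  feats <- igri_features()
  lookup <- stats::setNames(names(raw), toupper(trimws(names(raw))))
  missing_cols <- setdiff(feats, names(lookup))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  has_label <- "LABEL" %in% names(lookup)
  errors <- character(0)
  parse_col <- function(col, name) {
    v <- suppressWarnings(as.numeric(.normalize_minus(col)))
    bad <- which(is.na(v) & nzchar(col))
    if (length(bad) > 0) {
      # +1 for the header line
      errors <<- c(errors, paste0("line ", bad + 1L, ": unparseable ", name,
                                  " value '", col[bad], "'"))
    }
    na_empty <- which(!nzchar(col))
    if (length(na_empty) > 0) {
      errors <<- c(errors, paste0("line ", na_empty + 1L, ": missing ", name))
    }
    v
  }
  cols <- lapply(feats, function(f) parse_col(raw[[lookup[[f]]]], f))
  names(cols) <- feats
  if (length(errors) > 0) {
    stop("parse error(s) in ", path, ":\n  ",
         paste(utils::head(errors, 10), collapse = "\n  "))
  }
  df <- as.data.frame(cols)
  if (has_label) {
    lab <- suppressWarnings(as.integer(raw[[lookup[["LABEL"]]]]))
    if (any(is.na(lab) | !(lab %in% c(0L, 1L)))) {
      stop("label column must contain only 0 and 1")
    }
    df$label <- lab
  }
  if (validate) validate_records(df) else df
}

#' Read / write a reference dataset as CSV
#'
#' The CSV carries the six normalized feature columns (values in `[0, 1]`)
#' plus `label`.
#'
#' @param path CSV file path.
#' @param provenance Provenance tag attached on read.
#' @return [read_reference()]: an [reference_dataset()].
#' @export
read_reference <- function(path, provenance = "user-supplied") {
  df <- utils::read.csv(path, check.names = FALSE)
  feats <- igri_features()
  names(df) <- toupper(names(df))
  names(df)[names(df) == "LABEL"] <- "label"
  if (!all(c(feats, "label") %in% names(df))) {
    stop("reference CSV must have the six feature columns and label")
  }
  reference_dataset(as.matrix(df[feats]), df$label, provenance = provenance)
}

#' @rdname read_reference
#' @param reference An [reference_dataset()] to write.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "igri_reference"))
  df <- as.data.frame(reference$x)
  df$label <- reference$label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Path of the packaged default model configuration
#'
#' JSON file holding the published normalization bounds, reversed-feature
#' set, importance weights, mixing ratio, threshold, neighbor count and
#' staging bins.
#'
#' @return File path inside the installed package.
#' @export
default_model_path <- function() {
  system.file("extdata", "default_model.json", package = "igri",
              mustWork = TRUE)
}

#' Read / write the model configuration JSON
#'
#' The JSON holds both the normalization specification and the index model;
#' reading validates every invariant (bounds ordered, weights summing to 1,
#' ratios summing to 1, threshold in (0, 1)) through the type constructors.
#'
#' @param path JSON file path.
#' @return [read_model()]: list with elements `spec` ([norm_spec()]) and
#'   `model` ([index_model()]).
#' @export
read_model <- function(path = default_model_path()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (part in c("normalization", "model")) {
    if (is.null(cfg[[part]])) stop("config error at $", part, ": missing")
  }
  bounds <- lapply(cfg$normalization$bounds, as.numeric)
  spec <- norm_spec(bounds, reversed = as.character(cfg$normalization$reversed))
  m <- cfg$model
  model <- index_model(
    weights = unlist(m$weights),
    base_ratio = m$base_ratio, nni_ratio = m$nni_ratio,
    threshold = m$threshold, k = m$k,
    staging_bins = unlist(m$staging_bins),
    border_margin = if (is.null(m$border_margin)) 0.05 else m$border_margin)
  list(spec = spec, model = model)
}

#' @rdname read_model
#' @param spec An [norm_spec()].
#' @param model An [index_model()].
#' @export
write_model <- function(spec, model, path) {
  cfg <- list(
    normalization = list(bounds = spec$bounds, reversed = spec$reversed),
    model = list(weights = as.list(model$weights),
                 base_ratio = model$base_ratio, nni_ratio = model$nni_ratio,
                 threshold = model$threshold, k = model$k,
                 staging_bins = as.list(model$staging_bins),
                 border_margin = model$border_margin))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a score table to CSV
#'
#' @param scores Data frame from [score_records()].
#' @param path Output CSV path; `""` writes to stdout.
#' @param round If `TRUE`, print normalized values, NNI and base at 4
#'   decimals and the final index at 3 (half-away-from-zero), mimicking the
#'   published tables; default writes full precision.
#' @export
write_scores <- function(scores, path, round = FALSE) {
  if (round) {
    four <- c(paste0(igri_features(), "_norm"), "nni", "base")
    for (col in intersect(four, names(scores))) {
      scores[[col]] <- round_half_up(scores[[col]], 4)
    }
    if ("igri" %in% names(scores)) {
      scores$igri <- round_half_up(scores$igri, 3)
    }
  }
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
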