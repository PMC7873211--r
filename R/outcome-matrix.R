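#' Construct an outcome matrix
#'
#' Container for a subjects-by-outcomes table with per-subject metadata
#' (treatment arm, dose, injury severity, ...). This is the object the
#' topology and syndromic PCA stages consume.
#'
#' @param outcomes Numeric matrix, subjects in rows, outcome variables in
#'   columns. Missing entries are `NA`. Row names are subject ids.
#' @param meta Data frame with one row per subject. Must contain a
#'   `subject_id` column matching the row names of `outcomes`.
#' @return An object of class `outcome_matrix`.
#' @export
outcome_matrix <- function(outcomes, meta) {
  outcomes <- as.matrix(outcomes)
  if (!is.numeric(outcomes)) stop("`outcomes` must be numeric")
  if (!is.data.frame(meta)) stop("`meta` must be a data frame")
  if (is.null(meta$subject_id)) stop("`meta` must have a subject_id column")
  meta$subject_id <- as.character(meta$subject_id)
  if (anyDuplicated(meta$subject_id))
    stop("duplicate subject ids in metadata")
  if (nrow(outcomes) != nrow(meta))
    stop("outcomes and metadata disagree on the number of subjects")
  if (is.null(rownames(outcomes))) rownames(outcomes) <- meta$subject_id
  if (!identical(rownames(outcomes), meta$subject_id))
    stop("outcome row names do not match metadata subject ids")
  structure(list(outcomes = outcomes, meta = meta), class = "outcome_matrix")
}

#' @export
print.outcome_matrix <- function(x, ...) {
  cat(sprintf(
    "<outcome_matrix> %d subjects x %d outcomes (%d metadata columns, %.1f%% missing)\n",
    nrow(x$outcomes), ncol(x$outcomes), ncol(x$meta),
    100 * mean(is.na(x$outcomes))
  ))
  invisible(x)
}

#' @export
dim.outcome_matrix <- function(x) dim(x$outcomes)

# Resolve a variable name against the outcome block or the metadata.
# Returns a numeric vector or a factor-ish metadata column.
outcome_variable <- function(x, var) {
  stopifnot(inherits(x, "outcome_matrix"))
  if (var %in% colnames(x$outcomes)) return(x$outcomes[, var])
  if (var %in% names(x$meta)) return(x$meta[[var]])
  stop(sprintf("variable '%s' not found in outcomes or metadata", var))
}
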