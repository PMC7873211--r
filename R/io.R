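#' Read a subjects-by-outcomes table
#'
#' CSV or TSV (by extension) with one header row, a subject-id column, and
#' declared metadata columns; every remaining column is a numeric outcome.
#' Empty cells and `"NA"` are missing values. Duplicate subject ids and
#' non-numeric outcome cells are errors (the offending row/column is named).
#'
#' @param path File path.
#' @param id_col Subject-id column name (default `"subject_id"`).
#' @param meta_cols Metadata column names kept out of the outcome block.
#' @return An [outcome_matrix()].
#' @export
read_outcome_table <- function(path, id_col = "subject_id",
                               meta_cols = c("arm", "dose", "severity")) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!id_col %in% names(df))
    stop(sprintf("subject-id column '%s' not found", id_col))
  ids <- df[[id_col]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate subject ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  meta_cols <- intersect(meta_cols, names(df))
  outcome_cols <- setdiff(names(df), c(id_col, meta_cols))
  out <- matrix(NA_real_, nrow(df), length(outcome_cols),
                dimnames = list(ids, outcome_cols))
  for (j in outcome_cols) {
    raw <- df[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in outcome column '%s', row %d",
                   raw[bad[1]], j, bad[1]))
    out[, j] <- num
  }
  meta <- df[, c(id_col, meta_cols), drop = FALSE]
  names(meta)[1] <- "subject_id"
  for (j in meta_cols) {
    num <- suppressWarnings(as.numeric(meta[[j]]))
    if (!anyNA(num[!is.na(meta[[j]])])) meta[[j]] <- num
  }
  outcome_matrix(out, meta)
}

#' Write an outcome table
#'
#' Inverse of [read_outcome_table()]: one header row, subject ids first,
#' metadata columns, then outcomes; missing entries written as `NA`. Floats
#' use 10 significant digits.
#'
#' @param x An [outcome_matrix()].
#' @param path Output path (`.csv` or `.tsv`).
#' @export
write_outcome_table <- function(x, path) {
  stopifnot(inherits(x, "outcome_matrix"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- cbind(x$meta, as.data.frame(x$outcomes))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- ifelse(is.na(v), NA_character_, format(v, digits = 10, trim = TRUE,
                                                  scientific = FALSE))
    out
  })
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a genes-by-samples count matrix (TSV)
#'
#' First column: gene ids; header row: sample ids.
#'
#' @param path File path.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a count (or any numeric genes-by-samples) matrix as TSV
#' @param m Matrix with gene row names and sample column names.
#' @param path Output path.
#' @param id_label Header label of the gene-id column.
#' @export
write_counts <- function(m, path, id_label = "gene") {
  df <- data.frame(rownames(m), format(m, digits = 10, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample-group table (TSV)
#'
#' @param path File path (columns: sample, group; header required).
#' @param counts Optional count matrix whose sample set must match.
#' @return Named character vector sample -> group, in the counts' column
#'   order when `counts` is given.
#' @export
read_groups <- function(path, counts = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("group table needs two columns: sample, group")
  groups <- stats::setNames(df[[2]], df[[1]])
  if (!is.null(counts)) {
    missing_samples <- setdiff(colnames(counts), names(groups))
    extra <- setdiff(names(groups), colnames(counts))
    if (length(missing_samples) || length(extra))
      stop(sprintf(
        "sample mismatch between counts and groups: missing [%s], extra [%s]",
        paste(missing_samples, collapse = ", "),
        paste(extra, collapse = ", ")))
    groups <- groups[colnames(counts)]
  }
  groups
}

#' Write a sample-group table as TSV
#' @param groups Named character vector sample -> group.
#' @param path Output path.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(
    data.frame(sample = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line — set name, description, then tab-separated
#' gene ids. Sets are intersected with `universe`; sets with no surviving
#' genes are dropped with a warning.
#'
#' @param path File path.
#' @param universe Gene-id universe (e.g. the rows of the count matrix).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) if (length(p) > 2) p[-(1:2)] else character(0))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gene_set_collection(sets, universe)
}

#' Write a Mapper graph as GraphML and JSON
#'
#' GraphML (via igraph) carries node attributes (size, bin, every attached
#' overlay) and the shared-member edge attribute; the JSON file additionally
#' carries full per-node member lists. Reading the files back reproduces the
#' graph.
#'
#' @param graph A `mapper_graph` (optionally with overlays attached via
#'   [add_overlay()]).
#' @param basepath Output path without extension; `.graphml` and `.json` are
#'   appended.
#' @return Invisibly, the two file paths.
#' @export
write_mapper_graph <- function(graph, basepath) {
  stopifnot(inherits(graph, "mapper_graph"))
  g <- as_igraph(graph)
  graphml <- paste0(basepath, ".graphml")
  json <- paste0(basepath, ".json")
  igraph::write_graph(g, graphml, format = "graphml")
  payload <- list(
    nodes = lapply(seq_len(nrow(graph$nodes)), function(i) {
      node <- list(
        id = graph$nodes$id[i], bin = graph$nodes$bin[i],
        cluster = graph$nodes$cluster[i], size = graph$nodes$size[i],
        members = graph$members[[i]]
      )
      if (!is.null(graph$overlays))
        node$overlays <- lapply(graph$overlays, `[[`, i)
      node
    }),
    edges = graph$edges,
    subjects = graph$subjects
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(graphml = graphml, json = json))
}

#' Read a Mapper graph back from its JSON export
#'
#' @param path Path to the `.json` file written by [write_mapper_graph()].
#' @return A `mapper_graph` (without lens coordinates).
#' @export
read_mapper_graph <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  nodes <- if (length(payload$nodes)) {
    data.frame(id = payload$nodes$id, bin = payload$nodes$bin,
               cluster = payload$nodes$cluster, size = payload$nodes$size)
  } else data.frame(id = integer(0), bin = integer(0), cluster = integer(0),
                    size = integer(0))
  members <- if (length(payload$nodes)) {
    lapply(payload$nodes$members, as.character)
  } else list()
  overlays <- NULL
  if (!is.null(payload$nodes$overlays)) {
    ov <- payload$nodes$overlays
    overlays <- lapply(as.list(ov), function(v) as.numeric(v))
  }
  edges <- as.data.frame(payload$edges)
  if (!nrow(edges))
    edges <- data.frame(from = integer(0), to = integer(0), shared = integer(0))
  structure(list(
    nodes = nodes, members = members,
    member_index = lapply(members, match, table = payload$subjects),
    edges = edges, subjects = as.character(payload$subjects),
    lens = NULL, config = NULL, overlays = overlays
  ), class = "mapper_graph")
}
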