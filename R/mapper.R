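#' Mapper configuration
#'
#' Parameters of the Mapper graph construction over subjects: the metric on
#' standardized outcomes, the lens (filter) projection, the cover
#' (resolution = bins per lens axis, gain = overlap fraction), the first-gap
#' histogram heuristic for within-bin clustering, and the bootstrap consensus
#' settings.
#'
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson between
#'   subject rows).
#' @param lens Either `"pca"` (projection onto the first two principal axes
#'   of the standardized outcome matrix) or a character vector of one or two
#'   outcome column names passed through as lens coordinates.
#' @param resolution Bins per lens axis (>= 1).
#' @param gain Overlap fraction in `[0, 1)`; each base interval is expanded
#'   symmetrically to width `w * (1 + gain)`.
#' @param cluster_histogram_bins Bins of the pairwise-distance histogram used
#'   by the first-gap clustering heuristic.
#' @param n_bootstrap Number of with-replacement subject resamples for the
#'   consensus step.
#' @param consensus_threshold Co-occurrence fraction in `[0, 1]` an edge must
#'   reach to survive in the consensus graph.
#' @param resample If `FALSE`, bootstrap replicates use the full data without
#'   resampling (diagnostic mode).
#' @param seed Integer seed for the resampling.
#' @return A `mapper_config` list.
#' @export
mapper_config <- function(metric = c("euclidean", "correlation"),
                          lens = "pca",
                          resolution = 10,
                          gain = 0.4,
                          cluster_histogram_bins = 10,
                          n_bootstrap = 30,
                          consensus_threshold = 0.5,
                          resample = TRUE,
                          seed = 1L) {
  metric <- match.arg(metric)
  if (resolution < 1) stop("resolution must be >= 1")
  if (gain < 0 || gain >= 1) stop("gain must be in [0, 1)")
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  if (consensus_threshold < 0 || consensus_threshold > 1)
    stop("consensus_threshold must be in [0, 1]")
  structure(list(
    metric = metric, lens = lens, resolution = as.integer(resolution),
    gain = gain, cluster_histogram_bins = as.integer(cluster_histogram_bins),
    n_bootstrap = as.integer(n_bootstrap),
    consensus_threshold = consensus_threshold,
    resample = isTRUE(resample), seed = as.integer(seed)
  ), class = "mapper_config")
}

#' Standardize an outcome matrix
#'
#' Each retained column is centered and scaled to sample (n-1) SD 1, computed
#' over non-missing entries; constant (or all-missing) columns are dropped
#' with a warning; remaining missing entries are imputed by the column mean,
#' i.e. 0 after standardization, so every subject can enter the metric space.
#'
#' @param outcomes An [outcome_matrix()] or a numeric matrix.
#' @return Numeric matrix with attributes `center`, `scale`, and `dropped`
#'   (names of dropped columns).
#' @export
standardize_outcomes <- function(outcomes) {
  x <- if (inherits(outcomes, "outcome_matrix")) outcomes$outcomes else as.matrix(outcomes)
  if (nrow(x) < 2) stop("need at least 2 subjects to standardize")
  mu <- apply(x, 2, mean, na.rm = TRUE)
  sdev <- apply(x, 2, stats::sd, na.rm = TRUE)
  constant <- !is.finite(sdev) | sdev == 0
  if (all(constant)) stop("all columns are constant; nothing to standardize")
  if (any(constant)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(x)[constant], collapse = ", ")))
  }
  keep <- which(!constant)
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], `/`)
  z[is.na(z)] <- 0
  attr(z, "center") <- mu[keep]
  attr(z, "scale") <- sdev[keep]
  attr(z, "dropped") <- colnames(x)[constant]
  z
}

#' Compute lens (filter) coordinates
#'
#' Default lens: projections of the standardized matrix onto the first two
#' eigenvectors of its correlation matrix (equivalently, the first two
#' principal axes). Alternatively, named columns of the standardized matrix
#' are passed through unchanged.
#'
#' @param z Standardized matrix from [standardize_outcomes()].
#' @param lens `"pca"` or a character vector of 1-2 column names.
#' @return Subjects x d matrix of lens coordinates, d in \{1, 2\}.
#' @export
compute_lens <- function(z, lens = "pca") {
  if (identical(lens, "pca")) {
    r <- stats::cor(z)
    e <- eigen(r, symmetric = TRUE)
    v <- e$vectors[, seq_len(min(2, ncol(z))), drop = FALSE]
    # deterministic sign: largest-magnitude element positive
    for (j in seq_len(ncol(v))) {
      k <- which.max(abs(v[, j]))
      if (v[k, j] < 0) v[, j] <- -v[, j]
    }
    out <- z %*% v
    colnames(out) <- paste0("lens", seq_len(ncol(out)))
    return(out)
  }
  if (!is.character(lens) || !length(lens) %in% 1:2)
    stop("`lens` must be \"pca\" or one or two column names")
  missing_cols <- setdiff(lens, colnames(z))
  if (length(missing_cols))
    stop(sprintf("lens column(s) not found: %s", paste(missing_cols, collapse = ", ")))
  z[, lens, drop = FALSE]
}

#' Build an overlapping axis-aligned cover of the lens space
#'
#' Per axis the observed range is split into `resolution` equal base
#' intervals of width w; each is expanded symmetrically to width
#' `w * (1 + gain)`. d-dimensional bins are Cartesian products of the axis
#' intervals. The union of bins covers every lens point.
#'
#' @param lens Subjects x d lens matrix (finite values).
#' @param resolution Bins per axis.
#' @param gain Overlap fraction in `[0, 1)`.
#' @return List of bins; each bin is a d x 2 matrix of `[lo, hi]` per axis,
#'   with an `axes` attribute recording its per-axis interval index.
#' @export
build_cover <- function(lens, resolution, gain) {
  lens <- as.matrix(lens)
  if (!all(is.finite(lens))) stop("lens values must be finite")
  d <- ncol(lens)
  axis_intervals <- lapply(seq_len(d), function(j) {
    rng <- range(lens[, j])
    if (diff(rng) == 0) {
      if (resolution > 1)
        stop(sprintf("axis %d has zero range; cover is degenerate for resolution > 1", j))
      return(matrix(c(rng[1], rng[2]), 1, 2))
    }
    w <- diff(rng) / resolution
    k <- seq_len(resolution)
    lo <- rng[1] + (k - 1) * w - gain * w / 2
    hi <- rng[1] + k * w + gain * w / 2
    cbind(lo, hi)
  })
  grid <- expand.grid(lapply(axis_intervals, function(a) seq_len(nrow(a))))
  bins <- lapply(seq_len(nrow(grid)), function(i) {
    b <- t(vapply(seq_len(d), function(j) axis_intervals[[j]][grid[i, j], ],
                  numeric(2)))
    dimnames(b) <- list(colnames(lens), c("lo", "hi"))
    attr(b, "axes") <- as.integer(grid[i, ])
    b
  })
  bins
}

# subjects (row indices of `lens`) falling inside a cover bin (closed bounds)
bin_members <- function(lens, bin) {
  inside <- rep(TRUE, nrow(lens))
  for (j in seq_len(ncol(lens)))
    inside <- inside & lens[, j] >= bin[j, 1] & lens[, j] <= bin[j, 2]
  which(inside)
}

pairwise_distances <- function(x, metric) {
  if (metric == "euclidean") return(stats::dist(x))
  if (nrow(x) < 2) return(stats::dist(x))
  stats::as.dist(1 - stats::cor(t(x)))
}

#' Cluster the members of one cover bin
#'
#' Single-linkage agglomeration on pairwise distances, cut at the first-gap
#' histogram heuristic: the pairwise distances are histogrammed into
#' `histogram_bins` equal bins over `[0, max distance]`; the cut threshold is
#' the lower edge of the first empty bin. If no bin is empty the members form
#' a single cluster.
#'
#' @param x Member submatrix (members x variables).
#' @param metric `"euclidean"` or `"correlation"`.
#' @param histogram_bins Number of histogram bins.
#' @return Integer vector of cluster labels (1-based), one per member.
#' @export
cluster_bin <- function(x, metric = "euclidean", histogram_bins = 10) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 1) return(1L)
  d <- pairwise_distances(x, metric)
  dmax <- max(d)
  if (dmax == 0) return(rep(1L, n))
  breaks <- seq(0, dmax, length.out = histogram_bins + 1)
  counts <- graphics::hist(as.numeric(d), breaks = breaks, plot = FALSE)$counts
  empty <- which(counts == 0)
  if (!length(empty)) return(rep(1L, n))
  threshold <- breaks[empty[1]]
  hc <- stats::hclust(d, method = "single")
  cl <- stats::cutree(hc, h = threshold * (1 - 1e-12))
  as.integer(cl)
}

#' Build a Mapper graph over subjects
#'
#' Standardizes the outcomes, computes the lens, covers the lens space with
#' overlapping bins, clusters each bin's members, and links clusters that
#' share subjects (the nerve of the clustered cover). Node ids are assigned
#' deterministically by (bin index, cluster index).
#'
#' @param outcomes An [outcome_matrix()] or numeric matrix.
#' @param config A [mapper_config()].
#' @return A `mapper_graph`: list with `nodes` (data frame: id, bin, cluster,
#'   size), `members` (list of subject-id vectors per node), `edges` (data
#'   frame: from, to, shared), `subjects`, `lens`, and `config`.
#' @export
build_mapper_graph <- function(outcomes, config = mapper_config()) {
  x <- if (inherits(outcomes, "outcome_matrix")) outcomes$outcomes else as.matrix(outcomes)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  sdev <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (all(!is.finite(sdev) | sdev == 0)) {
    # all subjects identical: the whole cohort is one cluster
    return(structure(list(
      nodes = data.frame(id = 1L, bin = 1L, cluster = 1L, size = nrow(x)),
      members = list(ids), member_index = list(seq_len(nrow(x))),
      edges = data.frame(from = integer(0), to = integer(0),
                         shared = integer(0)),
      subjects = ids, lens = NULL, config = config
    ), class = "mapper_graph"))
  }
  z <- standardize_outcomes(outcomes)
  lens <- compute_lens(z, config$lens)
  mapper_graph_from_standardized(z, lens, config,
    subject_ids = rownames(z) %||% as.character(seq_len(nrow(z))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# core construction on a pre-standardized matrix (shared with the bootstrap)
mapper_graph_from_standardized <- function(z, lens, config, subject_ids) {
  bins <- build_cover(lens, config$resolution, config$gain)
  nodes <- list(); members <- list()
  node_of_subject <- vector("list", nrow(z))
  nid <- 0L
  for (b in seq_along(bins)) {
    m <- bin_members(lens, bins[[b]])
    if (!length(m)) next
    cl <- cluster_bin(z[m, , drop = FALSE], config$metric,
                      config$cluster_histogram_bins)
    for (k in sort(unique(cl))) {
      nid <- nid + 1L
      idx <- m[cl == k]
      nodes[[nid]] <- data.frame(id = nid, bin = b, cluster = k,
                                 size = length(idx))
      members[[nid]] <- idx
      for (i in idx) node_of_subject[[i]] <- c(node_of_subject[[i]], nid)
    }
  }
  nodes <- if (nid) do.call(rbind, nodes) else
    data.frame(id = integer(0), bin = integer(0), cluster = integer(0),
               size = integer(0))
  # edges: node pairs sharing >= 1 member
  edge_key <- new.env(parent = emptyenv())
  for (ns in node_of_subject) {
    if (length(ns) < 2) next
    ns <- sort(ns)
    for (a in seq_len(length(ns) - 1)) for (bb in seq((a + 1), length(ns))) {
      key <- paste(ns[a], ns[bb], sep = "-")
      edge_key[[key]] <- (edge_key[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(edge_key)
  edges <- if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
    df <- data.frame(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]),
                     shared = vapply(keys, function(k) edge_key[[k]], integer(1)))
    df <- df[order(df$from, df$to), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else data.frame(from = integer(0), to = integer(0), shared = integer(0))
  structure(list(
    nodes = nodes,
    members = lapply(members, function(i) subject_ids[i]),
    member_index = members,
    edges = edges, subjects = subject_ids, lens = lens, config = config
  ), class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("<mapper_graph> %d nodes, %d edges over %d subjects\n",
              nrow(x$nodes), nrow(x$edges), length(x$subjects)))
  invisible(x)
}

#' Convert a Mapper graph to an igraph object
#'
#' @param graph A `mapper_graph`.
#' @return An [igraph::graph] with node attributes `size`, `bin`, and any
#'   overlays previously attached via [overlay()], and edge attribute
#'   `shared`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "mapper_graph"))
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  igraph::V(g)$name <- as.character(graph$nodes$id)
  igraph::V(g)$size <- graph$nodes$size
  igraph::V(g)$bin <- graph$nodes$bin
  if (!is.null(graph$overlays)) {
    for (v in names(graph$overlays))
      g <- igraph::set_vertex_attr(g, v, value = graph$overlays[[v]])
  }
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to))
    igraph::E(g)$shared <- graph$edges$shared
  }
  g
}

#' Bootstrap consensus Mapper
#'
#' Resamples subjects with replacement `n_bootstrap` times, rebuilds the
#' Mapper graph on each resample, and records for every subject pair the
#' fraction of replicates (among those where both were drawn) in which they
#' shared at least one node. The consensus graph is the full-data Mapper
#' graph with an edge kept only if the mean member co-occurrence across the
#' edge reaches `consensus_threshold`. Pairs never jointly resampled have
#' missing (`NA`) co-occurrence.
#'
#' @param outcomes An [outcome_matrix()] or numeric matrix.
#' @param config A [mapper_config()].
#' @return List with `cooccurrence` (subjects x subjects, `NA` where
#'   undefined), `graph` (consensus `mapper_graph`), and `full_graph`.
#' @export
bootstrap_consensus <- function(outcomes, config = mapper_config()) {
  if (config$n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  full <- build_mapper_graph(outcomes, config)
  n <- length(full$subjects)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  x <- if (inherits(outcomes, "outcome_matrix")) outcomes$outcomes else as.matrix(outcomes)
  withr::with_seed(config$seed, {
    for (b in seq_len(config$n_bootstrap)) {
      idx <- if (config$resample) sample.int(n, n, replace = TRUE) else seq_len(n)
      xb <- x[idx, , drop = FALSE]
      rownames(xb) <- sprintf("r%d", seq_len(n))
      gb <- tryCatch(build_mapper_graph(xb, config), error = function(e) NULL)
      if (is.null(gb)) next
      present <- sort(unique(idx))
      den[present, present] <- den[present, present] + 1
      co <- matrix(FALSE, n, n)
      for (mem in gb$member_index) {
        orig <- unique(idx[mem])
        co[orig, orig] <- TRUE
      }
      num <- num + co
    }
  })
  cooc <- num / den
  cooc[den == 0] <- NA_real_
  dimnames(cooc) <- list(full$subjects, full$subjects)

  keep <- logical(nrow(full$edges))
  if (nrow(full$edges)) {
    for (e in seq_len(nrow(full$edges))) {
      a <- full$member_index[[full$edges$from[e]]]
      b <- full$member_index[[full$edges$to[e]]]
      vals <- cooc[a, b, drop = FALSE]
      m <- mean(vals, na.rm = TRUE)
      keep[e] <- config$consensus_threshold == 0 ||
        (is.finite(m) && m >= config$consensus_threshold)
    }
  }
  consensus <- full
  consensus$edges <- full$edges[keep, , drop = FALSE]
  rownames(consensus$edges) <- NULL
  list(cooccurrence = cooc, graph = consensus, full_graph = full)
}

#' Per-node overlay values
#'
#' Numeric variables are summarized as the mean over node members (missing
#' excluded); categorical group membership is summarized as
#' `100 * members-in-group / node-size` (a value in `[0, 100]`).
#'
#' @param graph A `mapper_graph`.
#' @param outcomes The [outcome_matrix()] the graph was built from.
#' @param var Name of an outcome or metadata column.
#' @param level If given, `var` is treated as a grouping column and the
#'   overlay is the percentage of node members with `var == level`.
#' @return Numeric vector of per-node overlay values (named by node id). The
#'   overlay is also recorded in `graph$overlays` in the returned attribute
#'   `graph`.
#' @export
overlay <- function(graph, outcomes, var, level = NULL) {
  stopifnot(inherits(graph, "mapper_graph"))
  v <- outcome_variable(outcomes, var)
  ids <- if (inherits(outcomes, "outcome_matrix")) outcomes$meta$subject_id
         else rownames(outcomes) %||% as.character(seq_along(v))
  names(v) <- ids
  vals <- vapply(graph$members, function(m) {
    x <- v[m]
    if (is.null(level)) mean(as.numeric(x), na.rm = TRUE)
    else 100 * sum(x == level, na.rm = TRUE) / length(x)
  }, numeric(1))
  names(vals) <- as.character(graph$nodes$id)
  vals
}

#' Attach an overlay to a Mapper graph
#'
#' Convenience wrapper around [overlay()] that stores the computed values in
#' the graph's `overlays` list (used by [write_mapper_graph()]).
#'
#' @inheritParams overlay
#' @param name Name under which to store the overlay (default `var` or
#'   `var=level`).
#' @return The graph with the overlay attached.
#' @export
add_overlay <- function(graph, outcomes, var, level = NULL, name = NULL) {
  vals <- overlay(graph, outcomes, var, level)
  if (is.null(name))
    name <- if (is.null(level)) var else paste(var, level, sep = "=")
  if (is.null(graph$overlays)) graph$overlays <- list()
  graph$overlays[[name]] <- unname(vals)
  graph
}
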