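#' Network construction parameters
#'
#' Parameters of the four-step co-expression procedure: complete-linkage
#' clustering on `1 - bicor` distances, a static cut at the height
#' corresponding to the strongest `cut_quantile` of pairwise correlations,
#' minimum module size, and the eigengene merge threshold.
#'
#' @param min_module_size Minimum genes per module (default 12).
#' @param cut_quantile Fraction of pairwise distances below the cut height
#'   (default 0.10, i.e. the top 10% of pairwise correlations).
#' @param merge_threshold Eigengene correlation above which modules are
#'   merged (default 0.85).
#' @param signed If `TRUE` (default) distances use signed correlations
#'   (`1 - bicor`); if `FALSE`, `1 - |bicor|`.
#' @param rescue_fragments If `TRUE` (default), clusters below
#'   `min_module_size` at the cut participate in the eigengene-merging
#'   iteration as provisional fragments, and the minimum-size rule is
#'   enforced after merging. With few samples the static cut necessarily
#'   fragments coherent modules (the complete-linkage diameter of a module
#'   grows with correlation sampling noise), and merging is the step that
#'   reassembles them; fragments that fail to reach the minimum size remain
#'   unassigned. Set to `FALSE` to restrict merging to full-size modules.
#' @return A `network_params` list.
#' @export
network_params <- function(min_module_size = 12, cut_quantile = 0.10,
                           merge_threshold = 0.85, signed = TRUE,
                           rescue_fragments = TRUE) {
  if (cut_quantile <= 0 || cut_quantile >= 1)
    stop("cut_quantile must be in (0, 1)")
  if (merge_threshold <= 0 || merge_threshold >= 1)
    stop("merge_threshold must be in (0, 1)")
  structure(list(
    min_module_size = as.integer(min_module_size),
    cut_quantile = cut_quantile, merge_threshold = merge_threshold,
    signed = isTRUE(signed), rescue_fragments = isTRUE(rescue_fragments),
    linkage = "complete", distance = "1 - bicor"
  ), class = "network_params")
}

# biweight deviations for the rows of a matrix; rows with MAD = 0 fall back
# to Pearson-style (mean-centered, unit-weight) deviations.
bicor_deviations <- function(x, warn = TRUE) {
  med <- apply(x, 1, stats::median)
  madv <- apply(x, 1, stats::mad, constant = 1)
  fallback <- madv == 0
  if (any(fallback) && warn)
    warning(sprintf("%d row(s) have zero MAD; falling back to Pearson for them",
                    sum(fallback)))
  u <- (x - med) / (9 * madv)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  dev <- (x - med) * w
  if (any(fallback)) {
    xf <- x[fallback, , drop = FALSE]
    dev[fallback, ] <- xf - rowMeans(xf)
  }
  norms <- sqrt(rowSums(dev^2))
  bad <- norms == 0
  if (any(bad)) {
    dev[bad, ] <- NA_real_
    norms[bad] <- 1
  }
  list(dev = dev / norms, undefined = bad)
}

#' Biweight midcorrelation
#'
#' Robust correlation using Tukey biweight weights around the median:
#' `u_i = (x_i - median(x)) / (9 * MAD(x))` (MAD unscaled), weights
#' `w_i = (1 - u_i^2)^2` for `|u_i| < 1` and 0 otherwise; the correlation is
#' the cross-product of the weighted, normalized deviations. If either
#' vector has zero MAD it falls back to Pearson (mean-centered, unit
#' weights) with a warning; a constant vector under the fallback yields `NA`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  d <- bicor_deviations(rbind(x, y))
  if (any(d$undefined)) {
    warning("constant vector: correlation undefined")
    return(NA_real_)
  }
  max(-1, min(1, sum(d$dev[1, ] * d$dev[2, ])))
}

#' Biweight midcorrelation matrix
#'
#' All pairwise [bicor()] values between the rows of a genes x samples
#' matrix, computed with the same per-row weights as the pairwise definition
#' (symmetric, unit diagonal).
#'
#' @param expr Genes x samples numeric matrix.
#' @param warn Emit the Pearson-fallback warning for zero-MAD rows.
#' @return Genes x genes symmetric correlation matrix.
#' @export
bicor_matrix <- function(expr, warn = TRUE) {
  expr <- as.matrix(expr)
  d <- bicor_deviations(expr, warn = warn)
  r <- tcrossprod(d$dev)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  if (any(d$undefined)) {
    r[d$undefined, ] <- NA_real_
    r[, d$undefined] <- NA_real_
    diag(r)[d$undefined] <- NA_real_
  }
  dimnames(r) <- list(rownames(expr), rownames(expr))
  r
}

#' Flag outlier samples by standardized network connectivity
#'
#' Sample connectivity `K_i` is the mean inter-sample Pearson correlation of
#' sample i (over genes); samples with standardized connectivity
#' `Z.K < z_cut` are flagged and the screen is repeated after each removal
#' until no sample falls below the cut.
#'
#' @param expr Genes x samples matrix (log-scale expression).
#' @param z_cut Standardized-connectivity threshold (default -2).
#' @return Character vector of excluded sample ids (possibly empty).
#' @export
flag_outlier_samples <- function(expr, z_cut = -2) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 4) stop("need at least 4 samples")
  samples <- colnames(expr) %||% as.character(seq_len(ncol(expr)))
  excluded <- character(0)
  keep <- samples
  repeat {
    sub <- expr[, keep, drop = FALSE]
    r <- stats::cor(sub)
    k <- (rowSums(r) - 1) / (ncol(sub) - 1)
    zk <- (k - mean(k)) / stats::sd(k)
    worst <- which.min(zk)
    if (!is.finite(zk[worst]) || zk[worst] >= z_cut) break
    excluded <- c(excluded, keep[worst])
    keep <- keep[-worst]
    if (length(excluded) > length(samples) / 2)
      stop("outlier screen would remove more than half of the samples")
  }
  excluded
}

#' Summarize a module by its eigengene
#'
#' Gene rows are standardized (gene-wise z-scores; constant rows dropped),
#' and the eigengene is the first right-singular vector of the standardized
#' submatrix, scaled to unit variance across samples and oriented so its
#' mean correlation with the member genes is positive. `variance_explained`
#' is the first squared singular value over the total.
#'
#' @param expr_module Genes x samples matrix restricted to one module
#'   (>= 2 genes).
#' @return List: `eigengene` (length = samples, unit variance),
#'   `variance_explained`.
#' @export
module_eigengene <- function(expr_module) {
  x <- as.matrix(expr_module)
  if (nrow(x) < 2) stop("module must have at least 2 genes")
  sdev <- apply(x, 1, stats::sd)
  keep <- sdev > 0
  if (!any(keep)) stop("all module genes are constant")
  z <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) / sdev[keep]
  s <- svd(z)
  eg <- s$v[, 1]
  if (mean(stats::cor(t(z), eg)) < 0) eg <- -eg
  eg <- (eg - mean(eg)) / stats::sd(eg)
  list(
    eigengene = stats::setNames(eg, colnames(x)),
    variance_explained = s$d[1]^2 / sum(s$d^2)
  )
}

#' Detect co-expression modules (pre-merge)
#'
#' Steps 1-3 of the procedure: the biweight midcorrelation matrix is turned
#' into distances `D = 1 - bicor` (or `1 - |bicor|` for unsigned networks),
#' genes are clustered by complete linkage, and the dendrogram is cut at the
#' static height equal to the `cut_quantile` quantile of the off-diagonal
#' distances (so only the strongest `cut_quantile` of pairwise correlations
#' fall below the cut). Clusters with at least `min_module_size` members
#' become modules (labelled `M1`, `M2`, ... by decreasing size); all other
#' genes are `"unassigned"`. Eigengenes and kME are computed for the
#' resulting modules.
#'
#' @param expr Genes x samples matrix (log-scale expression, no missing
#'   values).
#' @param params A [network_params()].
#' @return A `module_set`: `labels` (named gene -> module), `eigengenes`
#'   (modules x samples), `variance_explained`, `kme`, `merge_log` (empty
#'   until [merge_modules()]), `cut_height`, `params`.
#' @export
detect_modules <- function(expr, params = network_params()) {
  expr <- as.matrix(expr)
  genes <- rownames(expr) %||% sprintf("g%d", seq_len(nrow(expr)))
  rownames(expr) <- genes
  if (nrow(expr) < params$min_module_size)
    stop("fewer genes than the minimum module size")
  r <- bicor_matrix(expr, warn = FALSE)
  D <- if (params$signed) 1 - r else 1 - abs(r)
  off <- D[lower.tri(D)]
  h <- stats::quantile(off, params$cut_quantile, na.rm = TRUE, names = FALSE)
  if (!is.finite(h)) stop("cut height is not finite")
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= params$min_module_size]
  labels <- rep("unassigned", length(genes))
  names(labels) <- genes
  if (length(big)) {
    ord <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(ord))
      labels[cl == as.integer(ord[i])] <- sprintf("M%d", i)
  }
  small <- setdiff(names(sizes), big)
  fragments <- lapply(small, function(s) genes[cl == as.integer(s)])
  names(fragments) <- sprintf("F%d", seq_along(fragments))
  ms <- structure(list(
    labels = labels, eigengenes = NULL, variance_explained = NULL,
    kme = NULL, merge_log = data.frame(
      module_a = character(0), module_b = character(0), cor = numeric(0)),
    fragments = fragments,
    cut_height = h, params = params, dendrogram = hc
  ), class = "module_set")
  refresh_eigengenes(ms, expr)
}

module_ids <- function(ms) {
  u <- setdiff(unique(ms$labels), "unassigned")
  u[order(as.integer(sub("^M", "", u)))]
}

refresh_eigengenes <- function(ms, expr) {
  mods <- module_ids(ms)
  if (!length(mods)) {
    ms$eigengenes <- matrix(numeric(0), 0, ncol(expr),
                            dimnames = list(NULL, colnames(expr)))
    ms$variance_explained <- numeric(0)
    ms$kme <- matrix(numeric(0), nrow(expr), 0,
                     dimnames = list(rownames(expr), NULL))
    return(ms)
  }
  eg <- t(vapply(mods, function(m) {
    module_eigengene(expr[names(ms$labels)[ms$labels == m], , drop = FALSE])$eigengene
  }, numeric(ncol(expr))))
  ve <- vapply(mods, function(m) {
    module_eigengene(expr[names(ms$labels)[ms$labels == m], , drop = FALSE])$variance_explained
  }, numeric(1))
  rownames(eg) <- mods
  ms$eigengenes <- eg
  ms$variance_explained <- stats::setNames(ve, mods)
  ms$kme <- compute_kme(expr, eg)
  ms
}

#' @export
print.module_set <- function(x, ...) {
  mods <- module_ids(x)
  cat(sprintf("<module_set> %d modules over %d genes (%d unassigned)\n",
              length(mods), length(x$labels), sum(x$labels == "unassigned")))
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(x$labels == m), integer(1))
    cat(" ", paste(sprintf("%s:%d", mods, sizes), collapse = " "), "\n")
  }
  invisible(x)
}

#' Iteratively merge similar modules by eigengene correlation
#'
#' While any pair of module eigengenes correlates (Pearson) above
#' `merge_threshold`, the highest-correlated pair is merged, its eigengene
#' is recomputed, and all pairwise correlations are re-evaluated. After
#' merging, modules are relabelled `M1`, `M2`, ... by decreasing size and
#' kME is recomputed. The `merge_log` records every merge in order.
#'
#' @param ms A `module_set` from [detect_modules()].
#' @param expr The expression matrix the modules were detected on.
#' @param merge_threshold Eigengene correlation threshold (default from
#'   `ms$params`).
#' @return The merged `module_set`.
#' @export
merge_modules <- function(ms, expr, merge_threshold = ms$params$merge_threshold) {
  stopifnot(inherits(ms, "module_set"))
  expr <- as.matrix(expr)
  log_rows <- ms$merge_log

  clusters <- lapply(module_ids(ms), function(m) names(ms$labels)[ms$labels == m])
  names(clusters) <- module_ids(ms)
  if (isTRUE(ms$params$rescue_fragments) && length(ms$fragments))
    clusters <- c(clusters, ms$fragments)
  if (length(clusters) >= 2) {
    eg <- t(vapply(clusters, function(g) cluster_eigengene(expr, g),
                   numeric(ncol(expr))))
    repeat {
      if (nrow(eg) < 2) break
      C <- suppressWarnings(stats::cor(t(eg)))
      C[!is.finite(C)] <- -Inf
      diag(C) <- -Inf
      best <- which(C == max(C), arr.ind = TRUE)[1, ]
      if (C[best[1], best[2]] <= merge_threshold) break
      i <- min(best); j <- max(best)
      log_rows <- rbind(log_rows, data.frame(
        module_a = rownames(C)[i], module_b = rownames(C)[j],
        cor = C[best[1], best[2]]))
      clusters[[i]] <- c(clusters[[i]], clusters[[j]])
      eg[i, ] <- cluster_eigengene(expr, clusters[[i]])
      clusters[[j]] <- NULL
      eg <- eg[-j, , drop = FALSE]
    }
  }

  # enforce the minimum module size and relabel by decreasing size
  sizes <- lengths(clusters)
  keep <- which(sizes >= ms$params$min_module_size)
  keep <- keep[order(-sizes[keep], keep)]
  labels <- rep("unassigned", length(ms$labels))
  names(labels) <- names(ms$labels)
  for (i in seq_along(keep))
    labels[clusters[[keep[i]]]] <- sprintf("M%d", i)
  ms$labels <- labels
  ms$fragments <- list()
  ms <- refresh_eigengenes(ms, expr)
  ms$merge_log <- log_rows
  ms
}

# eigengene of an arbitrary gene set; a singleton's eigengene is its own
# standardized profile
cluster_eigengene <- function(expr, genes) {
  x <- expr[genes, , drop = FALSE]
  if (nrow(x) == 1) {
    v <- as.numeric(x)
    if (stats::sd(v) == 0) return(rep(NA_real_, length(v)))
    return((v - mean(v)) / stats::sd(v))
  }
  module_eigengene(x)$eigengene
}

#' Gene-module membership strength (kME)
#'
#' `kME(g, m)` is the Pearson correlation of gene g's expression profile
#' across all samples with module m's eigengene, for every gene (assigned or
#' not) and every module. Constant genes get `NA` with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param eigengenes Modules x samples matrix.
#' @return Genes x modules correlation matrix.
#' @export
compute_kme <- function(expr, eigengenes) {
  expr <- as.matrix(expr)
  if (!nrow(eigengenes))
    return(matrix(numeric(0), nrow(expr), 0,
                  dimnames = list(rownames(expr), NULL)))
  constant <- apply(expr, 1, stats::sd) == 0
  if (any(constant))
    warning(sprintf("%d constant gene(s): kME undefined", sum(constant)))
  kme <- suppressWarnings(stats::cor(t(expr), t(eigengenes)))
  kme[constant, ] <- NA_real_
  dimnames(kme) <- list(rownames(expr), rownames(eigengenes))
  kme
}

#' Module-trait testing with reversion detection
#'
#' For each module eigengene, a one-way ANOVA across the ordered
#' reference / vehicle / treated groups with Tukey post-hocs. The reversion
#' flag is true when (a) the omnibus p is below `alpha`, (b) vehicle differs
#' from reference (Tukey adjusted p below `alpha`), and (c) the treated
#' group mean lies strictly between the vehicle and reference means.
#'
#' @param ms A `module_set` with eigengenes, or a modules x samples eigengene
#'   matrix.
#' @param groups Sample group labels, ordered reference / vehicle / treated
#'   (named by sample or aligned with the eigengene columns).
#' @param levels Optional explicit 3-vector giving the reference, vehicle,
#'   and treated labels (defaults to the order of first appearance).
#' @param alpha Significance level.
#' @return Data frame: `module`, `F`, `p`, `tukey_vehicle_ref_p`,
#'   `mean_reference`, `mean_vehicle`, `mean_treated`, `reversion`.
#' @export
module_trait_test <- function(ms, groups, levels = NULL, alpha = 0.05) {
  eg <- if (inherits(ms, "module_set")) ms$eigengenes else as.matrix(ms)
  if (is.null(levels)) levels <- unique(as.character(groups))
  if (length(levels) != 3)
    stop("need exactly three ordered groups (reference, vehicle, treated)")
  groups <- factor(as.character(groups), levels = levels)
  if (anyNA(groups)) stop("group labels outside the declared levels")
  if (any(table(groups) < 2)) stop("need at least 2 samples per group")
  out <- lapply(rownames(eg), function(m) {
    y <- eg[m, ]
    fit <- one_way_anova(y, groups)
    tk <- tukey_hsd(fit)
    pair <- paste(levels[2], levels[1], sep = "-")
    vr <- tk$p_adj[tk$pair %in% c(pair, paste(levels[1], levels[2], sep = "-"))]
    mr <- fit$group_means[[levels[1]]]
    mv <- fit$group_means[[levels[2]]]
    mt <- fit$group_means[[levels[3]]]
    between <- (mt > min(mr, mv)) && (mt < max(mr, mv))
    data.frame(
      module = m, F = fit$F, p = fit$p, tukey_vehicle_ref_p = vr,
      mean_reference = mr, mean_vehicle = mv, mean_treated = mt,
      reversion = fit$p < alpha && vr < alpha && between
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
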