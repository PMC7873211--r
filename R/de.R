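#' Log-CPM normalization of a count matrix
#'
#' Counts are scaled to counts-per-million within each sample, then
#' transformed as `log2(CPM + pseudocount)`.
#'
#' @param counts Non-negative integer genes x samples matrix.
#' @param pseudocount Added before the log (default 1).
#' @return Genes x samples log2-expression matrix.
#' @export
normalize_counts <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0] %||% which(lib == 0)
    stop(sprintf("zero library size for sample(s): %s",
                 paste(bad, collapse = ", ")))
  }
  log2(sweep(counts, 2, lib / 1e6, `/`) + pseudocount)
}

# vectorized Welch two-sample t test over matrix rows
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # both groups constant: equal means -> p = 1 by convention, else p = 0
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  t[degenerate & ma == mb] <- 0
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb)
}

#' Per-gene differential expression between two groups
#'
#' Welch two-sample t-test per gene on log-expression, with
#' Benjamini-Hochberg adjustment across all tested genes. The log2 fold
#' change is `mean(B) - mean(A)`.
#'
#' @param expr Genes x samples log-expression matrix.
#' @param groups Group label per sample (named or aligned with columns).
#' @param group_a,group_b Labels of the two groups to compare (fold change is
#'   B relative to A).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return Data frame: `gene`, `mean_a`, `mean_b`, `log2fc`, `t`, `p`,
#'   `p_adj`, `significant`.
#' @export
differential_expression <- function(expr, groups, group_a, group_b,
                                    alpha = 0.05) {
  expr <- as.matrix(expr)
  groups <- as.character(groups)
  if (length(groups) != ncol(expr))
    stop("one group label per sample is required")
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need at least 2 samples per group")
  w <- welch_rows(expr[, ia, drop = FALSE], expr[, ib, drop = FALSE])
  p_adj <- stats::p.adjust(w$p, method = "BH")
  data.frame(
    gene = rownames(expr) %||% sprintf("g%d", seq_len(nrow(expr))),
    mean_a = w$mean_a, mean_b = w$mean_b, log2fc = w$mean_b - w$mean_a,
    t = w$t, p = w$p, p_adj = p_adj, significant = p_adj < alpha,
    row.names = NULL
  )
}

#' Classify treatment reversal of injury-induced expression changes
#'
#' For genes significantly altered in the vehicle-vs-reference comparison:
#' `"full"` reversal when the treated-vs-vehicle change opposes the
#' vehicle-vs-reference change in sign AND the treated group is no longer
#' significantly different from the reference; `"partial"` when the sign
#' opposes but treated-vs-reference remains significant; `"none"` otherwise.
#' Genes not significantly altered by injury are `NA` (reversal is defined
#' only on the injury-affected set).
#'
#' @param de_vehicle_ref DE table (from [differential_expression()]) for
#'   vehicle vs reference (fold change = vehicle - reference).
#' @param de_treated_ref DE table for treated vs reference.
#' @return Data frame: `gene`, `reversal_class` (`"full"`, `"partial"`,
#'   `"none"`, or `NA`).
#' @export
classify_reversal <- function(de_vehicle_ref, de_treated_ref) {
  if (!identical(de_vehicle_ref$gene, de_treated_ref$gene))
    stop("the two DE tables must cover the same genes in the same order")
  mean_ref <- de_vehicle_ref$mean_a
  mean_veh <- de_vehicle_ref$mean_b
  mean_trt <- de_treated_ref$mean_b
  if (anyNA(mean_ref) || anyNA(mean_veh) || anyNA(mean_trt))
    stop("missing group mean")
  injury_sig <- de_vehicle_ref$significant
  opposes <- sign(mean_trt - mean_veh) == -sign(mean_veh - mean_ref) &
    (mean_trt - mean_veh) != 0
  cls <- rep(NA_character_, length(injury_sig))
  cls[injury_sig] <- "none"
  cls[injury_sig & opposes & !de_treated_ref$significant] <- "full"
  cls[injury_sig & opposes & de_treated_ref$significant] <- "partial"
  data.frame(gene = de_vehicle_ref$gene, reversal_class = cls,
             row.names = NULL)
}

#' Build the three-group DEG table with reversal classes
#'
#' Convenience wrapper running [differential_expression()] for the
#' vehicle-vs-reference, treated-vs-reference, and treated-vs-vehicle
#' comparisons and attaching the reversal classification.
#'
#' @param expr Genes x samples log-expression matrix.
#' @param groups Sample group labels.
#' @param reference,vehicle,treated The three group labels.
#' @param alpha Adjusted-p threshold.
#' @return List with the three DE tables (`vehicle_vs_reference`,
#'   `treated_vs_reference`, `treated_vs_vehicle`) and `reversal`.
#' @export
deg_table <- function(expr, groups, reference, vehicle, treated,
                      alpha = 0.05) {
  vr <- differential_expression(expr, groups, reference, vehicle, alpha)
  tr <- differential_expression(expr, groups, reference, treated, alpha)
  tv <- differential_expression(expr, groups, vehicle, treated, alpha)
  list(
    vehicle_vs_reference = vr,
    treated_vs_reference = tr,
    treated_vs_vehicle = tv,
    reversal = classify_reversal(vr, tr)
  )
}

#' Gene-set collection
#'
#' Named sets of gene ids with an explicit universe. Sets are intersected
#' with the universe; sets left empty are dropped with a warning.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of all testable gene ids.
#' @return A `gene_set_collection` list.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be named")
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("dropping empty gene set(s): %s",
                    paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail hypergeometric test per set:
#' `P(overlap >= observed)` given the universe size, set size, and size of
#' the significant list; Benjamini-Hochberg adjustment across sets.
#'
#' @param significant Character vector of significant gene ids (must be a
#'   subset of the collection's universe).
#' @param collection A [gene_set_collection()].
#' @return Data frame: `set`, `set_size`, `overlap`, `expected`, `p`,
#'   `p_adj`, sorted by p.
#' @export
geneset_enrichment <- function(significant, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  significant <- unique(as.character(significant))
  outside <- setdiff(significant, collection$universe)
  if (length(outside))
    stop(sprintf("significant genes outside the universe: %s",
                 paste(utils::head(outside, 5), collapse = ", ")))
  n_univ <- length(collection$universe)
  n_sig <- length(significant)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    if (length(s) > n_univ) stop("gene set larger than the universe")
    ov <- length(intersect(s, significant))
    p <- stats::phyper(ov - 1, length(s), n_univ - length(s), n_sig,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = ov,
               expected = n_sig * length(s) / n_univ, p = p)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
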