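#' Syndromic PCA by eigendecomposition of the outcome correlation matrix
#'
#' Components are the eigenvectors of the Pearson correlation matrix of the
#' outcomes (pairwise-complete by default, falling back to complete cases
#' with a warning if the pairwise estimate is not positive semidefinite).
#' Loadings are on the correlation scale (eigenvector times the square root
#' of its eigenvalue), so `loading(v, c)` is the correlation between variable
#' v and component c; each component explains `eigenvalue / p` of the total
#' variance. Eigenvectors are oriented so their largest-magnitude loading is
#' positive.
#'
#' @param outcomes An [outcome_matrix()] or numeric matrix (subjects x
#'   variables, `NA` allowed).
#' @return A `pca_model`: `loadings`, `eigenvalues`, `variance_explained`,
#'   `rotation` (unit eigenvectors), `variables`, plus empty `retained`,
#'   `audit`, `scores` slots filled by [retain_components()] and
#'   [score_subjects()].
#' @export
correlation_pca <- function(outcomes) {
  x <- if (inherits(outcomes, "outcome_matrix")) outcomes$outcomes else as.matrix(outcomes)
  sdev <- apply(x, 2, stats::sd, na.rm = TRUE)
  keep <- which(is.finite(sdev) & sdev > 0)
  if (length(keep) < 2) stop("need at least 2 non-constant variables")
  x <- x[, keep, drop = FALSE]
  r <- stats::cor(x, use = "pairwise.complete.obs")
  if (anyNA(r)) stop("pairwise-complete correlation not estimable for all variable pairs")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warning("pairwise-complete correlation matrix is not positive semidefinite; falling back to complete-case correlation")
    r <- stats::cor(x, use = "complete.obs")
  }
  e <- eigen(r, symmetric = TRUE)
  values <- pmax(e$values, 0)
  vectors <- e$vectors
  p <- ncol(x)
  loadings <- vectors %*% diag(sqrt(values), p, p)
  for (j in seq_len(p)) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      vectors[, j] <- -vectors[, j]
    }
  }
  comp <- paste0("PC", seq_len(p))
  dimnames(loadings) <- list(colnames(x), comp)
  dimnames(vectors) <- list(colnames(x), comp)
  structure(list(
    loadings = loadings,
    eigenvalues = stats::setNames(values, comp),
    variance_explained = stats::setNames(values / p, comp),
    rotation = vectors,
    correlation = r,
    variables = colnames(x),
    retained = NULL, audit = NULL, scores = NULL
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d variables; eigenvalues: %s\n",
              length(x$variables),
              paste(sprintf("%.2f", x$eigenvalues[seq_len(min(5, length(x$eigenvalues)))]),
                    collapse = ", ")))
  if (!is.null(x$retained))
    cat(sprintf("  retained: %s\n", paste(names(x$eigenvalues)[x$retained], collapse = ", ")))
  invisible(x)
}

# Scree elbow via the acceleration (second difference) of the sorted
# eigenvalue sequence, restricted to components on the scree floor (below the
# mean eigenvalue, which is 1 for a correlation matrix). Returns the elbow
# index; components strictly before the elbow are scree-admitted.
scree_elbow <- function(eigenvalues) {
  p <- length(eigenvalues)
  if (p < 3) return(p + 1L)  # no interior point: admit everything
  i <- 2:(p - 1)
  accel <- eigenvalues[i - 1] - 2 * eigenvalues[i] + eigenvalues[i + 1]
  floor_idx <- i[eigenvalues[i] < mean(eigenvalues)]
  if (!length(floor_idx)) return(p + 1L)
  floor_idx[which.max(accel[match(floor_idx, i)])]
}

#' Apply the three component-retention rules
#'
#' A component is retained when it passes all of: (1) the Kaiser rule
#' (eigenvalue > 1), (2) the scree rule (component index strictly before the
#' acceleration elbow of the eigenvalue sequence; the elbow is located on the
#' below-average "floor" of the scree), and (3) over-determination (at least
#' `min_loadings` loadings with absolute value above `loading_threshold`).
#' A per-rule audit is returned alongside the retained set.
#'
#' @param model A `pca_model` from [correlation_pca()].
#' @param kaiser Eigenvalue threshold (default 1).
#' @param loading_threshold Absolute loading threshold (default 0.4).
#' @param min_loadings Minimum number of above-threshold loadings (default 3).
#' @return The model with `retained` (integer component indices) and `audit`
#'   (data frame with each rule's verdict per component) filled in.
#' @export
retain_components <- function(model, kaiser = 1.0, loading_threshold = 0.4,
                              min_loadings = 3) {
  stopifnot(inherits(model, "pca_model"))
  if (length(model$variables) < min_loadings)
    stop(sprintf("over-determination rule needs at least %d variables", min_loadings))
  ev <- model$eigenvalues
  p <- length(ev)
  elbow <- scree_elbow(unname(ev))
  kaiser_ok <- ev > kaiser
  scree_ok <- seq_len(p) < elbow
  n_big <- colSums(abs(model$loadings) > loading_threshold)
  overdet_ok <- n_big >= min_loadings
  audit <- data.frame(
    component = names(ev), eigenvalue = unname(ev),
    kaiser = unname(kaiser_ok), scree = unname(scree_ok),
    n_loadings_above = unname(n_big), overdetermined = unname(overdet_ok),
    retained = unname(kaiser_ok & scree_ok & overdet_ok)
  )
  model$retained <- which(audit$retained)
  model$audit <- audit
  model$scree_elbow <- elbow
  model
}

#' Score subjects on retained components
#'
#' Subject scores are the standardized (mean-imputed, as in the topology
#' stage) outcome rows projected onto the retained eigenvectors, rescaled to
#' unit variance across subjects (z-scale). Subjects with all outcomes
#' missing get `NA` scores and are flagged with a warning.
#'
#' @param model A `pca_model` with retention applied.
#' @param outcomes The outcome table the model was fitted to.
#' @return The model with `scores` (subjects x retained components) filled in.
#' @export
score_subjects <- function(model, outcomes) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(model$retained)) stop("apply retain_components() before scoring")
  x <- if (inherits(outcomes, "outcome_matrix")) outcomes$outcomes else as.matrix(outcomes)
  x <- x[, model$variables, drop = FALSE]
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing))
    warning(sprintf("%d subject(s) have no observed outcomes; scores set to NA",
                    sum(all_missing)))
  z <- scale(x)
  z[is.na(z)] <- 0
  raw <- z %*% model$rotation[, model$retained, drop = FALSE]
  scores <- apply(raw, 2, function(s) {
    sdev <- stats::sd(s)
    if (sdev > 0) (s - mean(s)) / sdev else s
  })
  scores <- matrix(scores, nrow = nrow(raw),
                   dimnames = list(rownames(x),
                                   colnames(model$rotation)[model$retained]))
  scores[all_missing, ] <- NA_real_
  model$scores <- scores
  model
}

#' Dose-response testing with orthogonal polynomial contrasts
#'
#' One-way ANOVA of the scores over ordered dose groups, followed by
#' orthogonal polynomial contrasts (linear, quadratic, ...) built on the dose
#' values (equally spaced codes when no numeric doses are supplied) and
#' normalized to unit length. Each contrast is tested with
#' `t = sum(c_k m_k) / sqrt(MSE * sum(c_k^2 / n_k))` on the ANOVA residual
#' degrees of freedom. An inverted-U dose response is flagged when the
#' quadratic estimate is negative and its p-value is below `alpha`.
#'
#' @param scores Numeric vector of per-subject values (e.g. PC scores).
#' @param groups Ordered factor or vector of dose-group labels.
#' @param doses Optional numeric dose value per group level (in level order).
#' @param alpha Significance level for the inverted-U flag.
#' @return A `dose_response` list: `anova` (an [one_way_anova()] result),
#'   `contrasts` (data frame: order, estimate, t, df, p), `group_means`,
#'   `inverted_u`.
#' @export
test_dose_response <- function(scores, groups, doses = NULL, alpha = 0.05) {
  keep <- is.finite(scores)
  scores <- scores[keep]
  groups <- if (is.factor(groups)) factor(groups[keep]) else factor(groups[keep], levels = unique(groups[keep]))
  k <- nlevels(groups)
  if (k < 3)
    warning("fewer than 3 dose groups: polynomial contrasts beyond linear unavailable")
  tab <- table(groups)
  if (any(tab < 2)) stop("need at least 2 subjects per dose group")
  fit <- one_way_anova(scores, groups)
  C <- orthogonal_polynomial_contrasts(k, doses)
  m <- fit$group_means
  n_k <- fit$group_n
  est <- as.numeric(crossprod(C, m))
  se <- sqrt(fit$mse * colSums(C^2 / n_k))
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), fit$df_within, lower.tail = FALSE)
  contrasts <- data.frame(
    order = colnames(C), estimate = est, se = se, t = tval,
    df = fit$df_within, p = pval
  )
  quad <- contrasts[contrasts$order == "quadratic", , drop = FALSE]
  inverted_u <- nrow(quad) == 1 && quad$estimate < 0 && quad$p < alpha
  structure(list(
    anova = fit, contrasts = contrasts, group_means = m,
    group_n = n_k, inverted_u = inverted_u
  ), class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> F(%d, %d) = %.3f, p = %.4g; inverted-U: %s\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p,
              x$inverted_u))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
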