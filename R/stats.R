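#' One-way analysis of variance
#'
#' Standard between/within decomposition (fitted via [stats::aov()]), with
#' the pieces downstream stages need: F, degrees of freedom, p, group means
#' and sizes, and the mean squared error.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor; level order preserved for
#'   character input).
#' @return An `anova_result`: `F`, `df_between`, `df_within`, `p`,
#'   `group_means`, `group_n`, `mse`, and the underlying `fit`.
#' @export
one_way_anova <- function(values, groups) {
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  tab <- table(groups)
  if (any(tab == 0)) stop("every group must have at least one observation")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(values) - nlevels(groups) < 1)
    stop("need at least 1 residual degree of freedom")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  rownames(s) <- trimws(rownames(s))
  msw <- s["Residuals", "Mean Sq"]
  f <- s["groups", "F value"]
  p <- s["groups", "Pr(>F)"]
  if (stats::var(values) == 0) {
    f <- 0; p <- 1                      # all values equal
  } else if (!is.finite(f)) {
    # zero within-group variance with distinct group means
    f <- Inf; p <- 0
  }
  structure(list(
    F = unname(f), df_between = unname(s["groups", "Df"]),
    df_within = unname(s["Residuals", "Df"]), p = unname(p),
    group_means = tapply(values, groups, mean),
    group_n = as.numeric(tab), mse = unname(msw),
    ss_between = unname(s["groups", "Sum Sq"]),
    ss_within = unname(s["Residuals", "Sum Sq"]),
    fit = fit
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey HSD post-hoc comparisons
#'
#' All-pairs comparisons via the studentized range distribution with the
#' Tukey-Kramer unequal-n correction (through [stats::TukeyHSD()]).
#'
#' @param anova An `anova_result` from [one_way_anova()].
#' @return Data frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(anova) {
  stopifnot(inherits(anova, "anova_result"))
  tk <- stats::TukeyHSD(anova$fit)$groups
  data.frame(
    pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL
  )
}

#' Orthogonal polynomial contrast coefficients
#'
#' Coefficients for trend (linear, quadratic, ...) contrasts over `k` ordered
#' groups, built on the (optionally unequally spaced) dose values by
#' Gram-Schmidt orthogonalization of centered powers (via
#' [stats::contr.poly()]). Columns are unit-normalized and mutually
#' orthogonal.
#'
#' @param k Number of groups (>= 2).
#' @param doses Optional numeric dose value per group; equally spaced integer
#'   codes are used when absent. Duplicates are an error.
#' @return k x (k-1) coefficient matrix with columns `linear`, `quadratic`,
#'   `cubic`, `order4`, ...
#' @export
orthogonal_polynomial_contrasts <- function(k, doses = NULL) {
  if (k < 2) stop("need at least 2 groups")
  if (is.null(doses)) doses <- seq_len(k)
  if (length(doses) != k) stop("`doses` must give one value per group")
  if (anyDuplicated(doses)) stop("duplicate dose values")
  C <- stats::contr.poly(k, scores = doses)
  nm <- c("linear", "quadratic", "cubic")
  ord <- seq_len(k - 1)
  colnames(C) <- ifelse(ord <= 3, nm[pmin(ord, 3)], paste0("order", ord))
  C
}

#' Delta-delta-Ct relative quantification
#'
#' qPCR fold changes: `dCt = Ct_target - Ct_housekeeping` per condition,
#' `ddCt = dCt_condition - dCt_reference`, fold change `2^(-ddCt)`.
#' Replicate Ct values within a condition are averaged before differencing.
#'
#' @param ct_target,ct_housekeeping Numeric Ct vectors (same length).
#' @param condition Condition label per observation.
#' @param reference Reference condition label.
#' @return Data frame: `condition`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
delta_delta_ct <- function(ct_target, ct_housekeeping, condition, reference) {
  if (length(ct_target) != length(ct_housekeeping) ||
      length(ct_target) != length(condition))
    stop("ct_target, ct_housekeeping and condition must have equal length")
  if (anyNA(ct_housekeeping)) stop("missing housekeeping Ct value")
  if (anyNA(ct_target) || any(!is.finite(ct_target)))
    stop("Ct values must be finite")
  condition <- as.character(condition)
  if (!reference %in% condition)
    stop(sprintf("reference condition '%s' not present", reference))
  dct <- tapply(ct_target - ct_housekeeping, condition, mean)
  ddct <- dct - dct[[reference]]
  data.frame(
    condition = names(dct), delta_ct = as.numeric(dct),
    delta_delta_ct = as.numeric(ddct), fold_change = 2^(-as.numeric(ddct)),
    row.names = NULL
  )
}

#' Immunoreactive-area quantification
#'
#' Fraction of pixels above an intensity threshold, and (when a contralateral
#' image is supplied) the ipsilateral/contralateral laterality percentage:
#' `100 * (ipsi pixels > threshold) / (contra pixels > threshold)`.
#'
#' @param image Numeric intensity matrix (ipsilateral side).
#' @param threshold Intensity threshold for positive staining.
#' @param contralateral Optional intensity matrix for the uninjured side.
#' @return An `area_quant` list: `threshold`, `positive_fraction`,
#'   `laterality_percent` (`NA` with a warning when the contralateral side
#'   has no positive pixels).
#' @export
area_quantification <- function(image, threshold, contralateral = NULL) {
  image <- as.matrix(image)
  if (!length(image)) stop("empty image")
  rng <- range(image)
  if (threshold < rng[1] || threshold > rng[2])
    stop("threshold outside the intensity range of the image")
  positive_fraction <- sum(image > threshold) / length(image)
  laterality <- NA_real_
  if (!is.null(contralateral)) {
    contralateral <- as.matrix(contralateral)
    contra_pos <- sum(contralateral > threshold)
    if (contra_pos == 0) {
      warning("contralateral image has no supra-threshold pixels; laterality undefined")
    } else {
      laterality <- 100 * sum(image > threshold) / contra_pos
    }
  }
  structure(list(
    threshold = threshold, positive_fraction = positive_fraction,
    laterality_percent = laterality
  ), class = "area_quant")
}
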