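random_outcomes <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("s%02d", seq_len(n)), paste0("v", seq_len(p))))
}

test_that("perfectly correlated variables load on a single component", {
  x <- random_outcomes(12, 1, seed = 1)
  m <- correlation_pca(cbind(a = x[, 1], b = 2 * x[, 1]))
  expect_equal(unname(m$eigenvalues), c(2, 0), tolerance = 1e-12)
  expect_equal(unname(m$variance_explained[1]), 1)
})

test_that("eigenpairs match an independent SVD oracle and conserve the trace", {
  x <- random_outcomes(8, 4, seed = 2)
  m <- correlation_pca(x)
  z <- scale(x) / sqrt(nrow(x) - 1)
  s <- svd(z)  # singular values of scaled z-matrix give sqrt(eigenvalues)
  expect_equal(unname(m$eigenvalues), s$d^2, tolerance = 1e-8)
  for (j in 1:4)
    expect_gt(abs(sum(m$rotation[, j] * s$v[, j])), 1 - 1e-8)
  expect_equal(sum(m$eigenvalues), 4, tolerance = 1e-10)
  # loadings reconstruct the correlation matrix when all components are kept
  expect_equal(m$loadings %*% t(m$loadings), m$correlation,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("results are invariant to subject order and sign-conventioned", {
  x <- random_outcomes(20, 5, seed = 3)
  m1 <- correlation_pca(x)
  set.seed(4); m2 <- correlation_pca(x[sample(20), ])
  expect_equal(m1$loadings, m2$loadings, tolerance = 1e-10)
  # largest-magnitude loading of each component is positive
  for (j in seq_len(5))
    expect_gt(m1$loadings[which.max(abs(m1$loadings[, j])), j], 0)
})

fixture_model <- function(eigenvalues, loadings) {
  p <- length(eigenvalues)
  structure(list(
    loadings = loadings,
    eigenvalues = stats::setNames(eigenvalues, paste0("PC", seq_len(p))),
    variance_explained = stats::setNames(eigenvalues / p, paste0("PC", seq_len(p))),
    rotation = diag(p), correlation = diag(p),
    variables = paste0("v", seq_len(nrow(loadings))),
    retained = NULL, audit = NULL, scores = NULL
  ), class = "pca_model")
}

test_that("the three retention rules reproduce their printed behavior on fixtures", {
  # Kaiser: an eigenvalue of 0.99 is excluded no matter what else holds
  L <- matrix(0.9, 5, 5)
  m <- fixture_model(c(2.0, 0.99, 0.8, 0.7, 0.51), L)
  m <- retain_components(m)
  expect_false(m$audit$kaiser[2])
  expect_false(m$audit$retained[2])

  # over-determination: fewer than 3 loadings above |.4| excludes a component
  L2 <- cbind(c(0.9, 0.8, 0.7, 0.6), c(0.5, 0.45, 0.1, 0.0))
  L2 <- cbind(L2, matrix(0.05, 4, 2))
  m2 <- fixture_model(c(2.2, 1.3, 0.3, 0.2), L2)
  m2 <- retain_components(m2)
  expect_equal(m2$audit$n_loadings_above[1:2], c(4, 2))
  expect_true(m2$audit$kaiser[2])
  expect_false(m2$audit$retained[2])

  # scree acceleration elbow on the documented eigenvalue fixture admits 1..3
  m3 <- fixture_model(c(3.0, 1.5, 1.4, 0.3, 0.2), matrix(0.9, 5, 5))
  m3 <- retain_components(m3)
  expect_equal(m3$scree_elbow, 4)
  expect_equal(which(m3$audit$scree), 1:3)

  expect_error(retain_components(fixture_model(c(1.5, 0.5), matrix(0.9, 2, 2))),
               "at least 3 variables")
})

test_that("subject scores are unit-variance projections matching the formula oracle", {
  x <- random_outcomes(8, 4, seed = 5)
  m <- retain_components(correlation_pca(x), kaiser = 0, min_loadings = 0)
  m <- score_subjects(m, x)
  expect_true(ncol(m$scores) >= 1)
  for (j in seq_len(ncol(m$scores))) {
    expect_equal(mean(m$scores[, j]), 0, tolerance = 1e-10)
    expect_equal(sd(m$scores[, j]), 1, tolerance = 1e-10)
    oracle <- scale(x) %*% m$rotation[, j]
    expect_gt(abs(cor(m$scores[, j], oracle)), 1 - 1e-10)
  }
  # a subject sitting exactly at every variable mean scores 0
  xm <- rbind(x, center = colMeans(x))
  mm <- score_subjects(retain_components(correlation_pca(xm), kaiser = 0,
                                         min_loadings = 0), xm)
  expect_lt(abs(mm$scores["center", 1]), 0.15)  # means shift slightly with the added row
})

test_that("missing outcomes are mean-imputed and fully missing subjects flagged", {
  x <- random_outcomes(10, 4, seed = 6)
  x[3, ] <- NA
  m <- retain_components(correlation_pca(x), kaiser = 0, min_loadings = 0)
  expect_warning(m <- score_subjects(m, x), "no observed outcomes")
  expect_true(all(is.na(m$scores[3, ])))
  expect_false(anyNA(m$scores[-3, ]))
})

test_that("polynomial contrasts detect an inverted-U and hold their null level", {
  C <- orthogonal_polynomial_contrasts(3)
  expect_equal(C[, "quadratic"] / C[1, "quadratic"], c(1, -2, 1),
               ignore_attr = TRUE)

  set.seed(7)
  y <- c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1), rnorm(10, 0, 0.1))
  g <- rep(c("d0", "d1", "d2"), each = 10)
  dr <- test_dose_response(y, g)
  q <- dr$contrasts[dr$contrasts$order == "quadratic", ]
  expect_lt(q$p, 1e-3)
  expect_lt(q$estimate, 0)
  expect_true(dr$inverted_u)
  # oracle: direct contrast t formula
  cvec <- orthogonal_polynomial_contrasts(3)[, "quadratic"]
  mns <- tapply(y, g, mean)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / 27
  t_or <- sum(cvec * mns) / sqrt(mse * sum(cvec^2 / 10))
  expect_equal(q$t, t_or, tolerance = 1e-10)

  # exaggerating trend is not an inverted U
  set.seed(8)
  y2 <- c(rnorm(8), rnorm(8, 3), rnorm(8, 6))
  expect_false(test_dose_response(y2, rep(c("a", "b", "c"), each = 8))$inverted_u)
})
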