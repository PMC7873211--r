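planted_expr <- function(n_modules = 3, module_size = 50, n_background = 200,
                         within = 0.7, seed = 1) {
  cfg <- expr_sim_config(
    n_genes = n_modules * module_size + n_background,
    n_modules = n_modules, module_size = module_size,
    within_module_cor = within, n_injury_genes = 0, n_reversal_genes = 0,
    seed = seed)
  sim <- simulate_expression(cfg)
  list(expr = normalize_counts(sim$counts), truth = sim$truth,
       groups = sim$groups)
}

test_that("bicor has the core robust-correlation properties", {
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  expect_equal(bicor(3 * x + 2, y), bicor(x, y), tolerance = 1e-12)
  expect_equal(bicor(x, y), bicor(y, x), tolerance = 1e-12)
  expect_true(abs(bicor(x, y)) <= 1)

  # tracks Pearson on clean Gaussian data
  set.seed(2)
  f <- rnorm(1000)
  a <- sqrt(0.6) * f + sqrt(0.4) * rnorm(1000)
  b <- sqrt(0.6) * f + sqrt(0.4) * rnorm(1000)
  expect_lt(abs(bicor(a, b) - cor(a, b)), 0.02)

  # zero-MAD vectors fall back to Pearson with a warning
  xz <- c(rep(1, 48), 5, 1); yz <- rnorm(50)
  expect_warning(bz <- bicor(xz, yz), "MAD")
  expect_warning(bz2 <- bicor(xz, xz), "MAD")
  expect_equal(bz2, 1)
  w <- capture_warnings(bconst <- bicor(rep(2, 10), rnorm(10)))
  expect_true(is.na(bconst))
  expect_true(any(grepl("undefined", w)))
})

test_that("bicor shrugs off a gross outlier that wrecks Pearson", {
  set.seed(3)
  f <- rnorm(100)
  x <- sqrt(0.8) * f + sqrt(0.2) * rnorm(100)
  y <- sqrt(0.8) * f + sqrt(0.2) * rnorm(100)
  b0 <- bicor(x, y); p0 <- cor(x, y)
  y2 <- y; y2[1] <- 10 * sd(y); x2 <- x; x2[1] <- -10 * sd(x)
  expect_lt(abs(bicor(x2, y2) - b0), 0.05)
  expect_gt(abs(cor(x2, y2) - p0), 0.2)
})

test_that("the bicor matrix is symmetric, bounded, and matches the looped oracle", {
  set.seed(4)
  m <- matrix(rnorm(20 * 12), 20, 12)
  m[3, ] <- m[7, ]  # duplicated gene rows
  r <- bicor_matrix(m)
  expect_equal(r, t(r), tolerance = 1e-12)
  expect_true(all(abs(r) <= 1))
  expect_equal(unname(diag(r)), rep(1, 20))
  expect_equal(r[3, 7], 1)
  for (i in c(1, 5, 9)) for (j in c(2, 11, 20))
    expect_equal(r[i, j], suppressWarnings(bicor(m[i, ], m[j, ])),
                 tolerance = 1e-12)
})

test_that("the connectivity screen flags genuinely incoherent samples first", {
  set.seed(20)
  profile <- rnorm(300)
  good <- sapply(1:9, function(i) profile + rnorm(300, sd = 0.3))
  colnames(good) <- paste0("ok", 1:9)
  expect_length(flag_outlier_samples(good), 0)

  bad <- cbind(good, noise = rnorm(300, sd = 1))
  flagged <- flag_outlier_samples(bad)
  expect_identical(flagged[1], "noise")
  expect_lte(length(flagged), 2)
  expect_length(flag_outlier_samples(bad, z_cut = -Inf), 0)
  expect_error(flag_outlier_samples(good[, 1:3]), "at least 4")
})

test_that("tight clusters below the minimum size never become modules", {
  # 8 near-identical genes among independent background: even with a couple
  # of chance tag-along genes at the cut, the cluster stays below 12
  set.seed(6)
  n <- 24
  f <- rnorm(n)
  tight <- t(sapply(1:8, function(i) f + rnorm(n, sd = 0.05)))
  bg <- matrix(rnorm(80 * n), 80, n)
  expr <- rbind(tight, bg)
  rownames(expr) <- sprintf("g%02d", 1:88)
  ms <- detect_modules(expr, network_params())
  expect_equal(nrow(ms$eigengenes), 0)
  expect_true(all(ms$labels == "unassigned"))
  ms <- merge_modules(ms, expr)
  expect_equal(nrow(ms$eigengenes), 0)
})

test_that("no planted modules means no detected modules", {
  pe <- planted_expr(n_modules = 0, module_size = 0, n_background = 120, seed = 7)
  ms <- merge_modules(detect_modules(pe$expr), pe$expr)
  expect_equal(nrow(ms$eigengenes), 0)
})

test_that("detection agrees with a brute-force complete-linkage oracle on toy matrices", {
  for (seed in c(8, 81, 82)) {
    set.seed(seed)
    f1 <- rnorm(10); f2 <- rnorm(10)
    expr <- rbind(
      t(sapply(1:6, function(i) f1 + rnorm(10, sd = 0.2))),
      t(sapply(1:5, function(i) f2 + rnorm(10, sd = 0.2))),
      matrix(rnorm(40), 4, 10))
    rownames(expr) <- sprintf("g%02d", 1:15)
    ms <- detect_modules(expr, network_params(min_module_size = 4))
    # full partition at the cut = sized modules plus recorded fragments
    got <- integer(15); names(got) <- rownames(expr)
    k <- 0L
    for (m in setdiff(unique(ms$labels), "unassigned")) {
      k <- k + 1L; got[names(ms$labels)[ms$labels == m]] <- k
    }
    for (fr in ms$fragments) { k <- k + 1L; got[fr] <- k }
    D <- 1 - bicor_matrix(expr, warn = FALSE)
    h <- quantile(D[lower.tri(D)], 0.10, names = FALSE)
    oracle <- naive_complete_linkage(D, h)
    expect_true(same_partition(got, oracle))
  }
})

test_that("eigengenes match a dense-SVD oracle with member-positive orientation", {
  set.seed(9)
  prof <- rnorm(6)
  ident <- t(sapply(1:5, function(i) 2 * prof + 3))
  eg0 <- module_eigengene(ident)
  expect_equal(eg0$variance_explained, 1, tolerance = 1e-12)
  expect_equal(unname(eg0$eigengene), as.numeric(scale(prof)), tolerance = 1e-10)

  m <- matrix(rnorm(12 * 6), 12, 6) + rep(rnorm(6, sd = 1.5), each = 12)
  eg <- module_eigengene(m)
  z <- t(scale(t(m)))
  s <- svd(z)
  oracle <- s$v[, 1]
  expect_gt(abs(cor(eg$eigengene, oracle)), 1 - 1e-10)
  expect_equal(eg$variance_explained, s$d[1]^2 / sum(s$d^2), tolerance = 1e-10)
  expect_gt(mean(cor(t(z), eg$eigengene)), 0)  # oriented toward members
  # negating all member genes flips the eigengene
  egn <- module_eigengene(-m)
  expect_equal(unname(egn$eigengene), -unname(eg$eigengene), tolerance = 1e-10)
})

test_that("merging follows highest-first order with recomputation, like the hand-stepped oracle", {
  # engineer three modules whose eigengenes have known correlations
  set.seed(10)
  n <- 30
  raw <- matrix(rnorm(n * 3), n, 3)
  white <- qr.Q(qr(scale(raw)))  # exactly orthonormal columns
  target <- matrix(c(1, 0.92, 0.60,
                     0.92, 1, 0.55,
                     0.60, 0.55, 1), 3, 3)
  F <- white %*% chol(target)
  mk <- function(f, k) t(sapply(seq_len(k), function(i) f + rnorm(n, sd = 0.05)))
  expr <- rbind(mk(F[, 1], 15), mk(F[, 2], 15), mk(F[, 3], 15))
  rownames(expr) <- sprintf("g%02d", 1:45)
  labels <- setNames(rep(c("M1", "M2", "M3"), each = 15), rownames(expr))

  ms <- structure(list(
    labels = labels, fragments = list(),
    merge_log = data.frame(module_a = character(0), module_b = character(0),
                           cor = numeric(0)),
    params = network_params(min_module_size = 10), cut_height = NA
  ), class = "module_set")
  ms <- scimint:::refresh_eigengenes(ms, expr)

  # independent hand-stepped oracle using base svd/cor only
  eg_of <- function(rows) {
    z <- t(scale(t(expr[rows, , drop = FALSE])))
    v <- svd(z)$v[, 1]
    if (mean(cor(t(z), v)) < 0) v <- -v
    (v - mean(v)) / sd(v)
  }
  e1 <- eg_of(1:15); e2 <- eg_of(16:30); e3 <- eg_of(31:45)
  step1 <- c(cor(e1, e2), cor(e1, e3), cor(e2, e3))
  expect_gt(step1[1], 0.85)        # M1-M2 is the top pair
  expect_equal(which.max(step1), 1L)
  e12 <- eg_of(1:30)
  step2 <- cor(e12, e3)            # re-test after recomputation

  merged <- merge_modules(ms, expr)
  expect_equal(merged$merge_log$module_a[1], "M1")
  expect_equal(merged$merge_log$module_b[1], "M2")
  expect_equal(merged$merge_log$cor[1], max(step1), tolerance = 1e-10)
  if (step2 > 0.85) {
    expect_equal(nrow(merged$merge_log), 2)
    expect_equal(nrow(merged$eigengenes), 1)
  } else {
    expect_equal(nrow(merged$merge_log), 1)
    expect_equal(nrow(merged$eigengenes), 2)
  }

  # far-apart modules are left untouched
  target_far <- diag(3)
  Ff <- white %*% chol(target_far)
  expr_far <- rbind(mk(Ff[, 1], 15), mk(Ff[, 2], 15), mk(Ff[, 3], 15))
  rownames(expr_far) <- rownames(expr)
  msf <- ms; msf$labels <- labels
  msf <- scimint:::refresh_eigengenes(msf, expr_far)
  mf <- merge_modules(msf, expr_far)
  expect_equal(nrow(mf$merge_log), 0)
  expect_equal(nrow(mf$eigengenes), 3)
})

test_that("after merging no eigengene pair exceeds the threshold and kME separates members", {
  pe <- planted_expr(seed = 11)
  ms <- merge_modules(detect_modules(pe$expr), pe$expr)
  k <- nrow(ms$eigengenes)
  expect_gt(k, 1)
  C <- cor(t(ms$eigengenes))
  expect_lte(max(C[lower.tri(C)]), 0.85)

  kme <- ms$kme
  expect_true(all(abs(kme) <= 1 + 1e-12, na.rm = TRUE))
  for (m in rownames(ms$eigengenes)) {
    inm <- ms$labels == m
    expect_gt(mean(kme[inm, m]), mean(kme[!inm, m]))
  }
  # kME matches a looped Pearson oracle
  for (g in c(1, 50, 200)) for (m in seq_len(min(2, k)))
    expect_equal(kme[g, m], cor(pe$expr[g, ], ms$eigengenes[m, ]),
                 tolerance = 1e-10)
  # a gene identical to an eigengene has kME 1
  expr2 <- rbind(pe$expr, eigcopy = ms$eigengenes[1, ])
  k2 <- compute_kme(expr2, ms$eigengenes)
  expect_equal(k2["eigcopy", 1], 1, tolerance = 1e-12)
})

test_that("module assignment is invariant to gene order and affine rescaling", {
  pe <- planted_expr(n_modules = 2, module_size = 30, n_background = 60, seed = 12)
  ms1 <- merge_modules(detect_modules(pe$expr), pe$expr)
  set.seed(13)
  perm <- sample(nrow(pe$expr))
  scaled <- pe$expr[perm, ] * runif(nrow(pe$expr), 0.5, 3) + rnorm(nrow(pe$expr))
  ms2 <- merge_modules(detect_modules(scaled), scaled)
  expect_gt(adjusted_rand(ms1$labels[rownames(scaled)], ms2$labels), 0.999)
})

test_that("module-trait reversion flags require significance plus an intermediate treated mean", {
  groups <- rep(c("sham", "vehicle", "treated"), each = 5)
  flat <- matrix(rep(rnorm(15, sd = 1e-6), 1), 1, 15,
                 dimnames = list("M1", NULL))
  flat[1, ] <- flat[1, ] - mean(flat[1, ])
  tt0 <- module_trait_test(flat, groups)
  expect_false(tt0$reversion[1])

  set.seed(14)
  rev_eg <- matrix(c(rnorm(5, 0, 0.2), rnorm(5, 2, 0.2), rnorm(5, 1, 0.2)),
                   1, 15, dimnames = list("M1", NULL))
  tt1 <- module_trait_test(rev_eg, groups)
  expect_lt(tt1$p, 0.001)
  expect_true(tt1$reversion)
  # oracle check of the omnibus F from base aov
  f_or <- summary(aov(rev_eg[1, ] ~ factor(groups)))[[1]]$`F value`[1]
  expect_equal(tt1$F, f_or, tolerance = 1e-10)

  exag <- matrix(c(rnorm(5, 0, 0.2), rnorm(5, 2, 0.2), rnorm(5, 3, 0.2)),
                 1, 15, dimnames = list("M1", NULL))
  expect_false(module_trait_test(exag, groups)$reversion)
})
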