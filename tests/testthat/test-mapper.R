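make_points <- function(n, p, seed = 1, ...) {
  set.seed(seed)
  x <- matrix(rnorm(n * p, ...), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)), paste0("v", seq_len(p))))
  x
}

test_that("standardization centers, scales, imputes, and drops constants", {
  expect_equal(as.numeric(standardize_outcomes(matrix(c(0, 2), 2, 1))),
               c(-0.7071, 0.7071), tolerance = 1e-4)

  x <- make_points(5, 3, seed = 2)
  z <- standardize_outcomes(x)
  oracle <- apply(x, 2, function(v) (v - mean(v)) / sd(v))
  expect_equal(unname(z[, ]), unname(oracle), tolerance = 1e-12)

  xc <- cbind(x, const = 1)
  expect_warning(zc <- standardize_outcomes(xc), "constant")
  expect_false("const" %in% colnames(zc))

  xm <- x; xm[2, 1] <- NA
  zm <- standardize_outcomes(xm)
  expect_equal(zm[2, 1], 0)  # mean-imputed after standardization

  expect_error(standardize_outcomes(matrix(1, 4, 2)), "constant")
})

test_that("lens projections match an independent eigen-decomposition and pass-through", {
  x <- make_points(20, 4, seed = 3)
  z <- standardize_outcomes(x)
  lens <- compute_lens(z, "pca")
  e <- eigen(cov(z))  # z standardized: covariance ~ correlation
  for (j in 1:2)
    expect_gt(abs(cor(lens[, j], z %*% e$vectors[, j])), 1 - 1e-8)

  expect_equal(compute_lens(z, "v2")[, 1], z[, "v2"])
  expect_error(compute_lens(z, "nope"), "not found")

  # rank-1 data: second lens axis carries ~no variance
  b <- make_points(15, 1, seed = 4)
  r1 <- cbind(v1 = b[, 1], v2 = 2 * b[, 1], v3 = -b[, 1])
  lr <- compute_lens(standardize_outcomes(r1), "pca")
  expect_lt(var(lr[, 2]) / var(lr[, 1]), 1e-10)
})

test_that("the cover has the stated geometry and covers every point", {
  one <- build_cover(matrix(c(1, 5, 9), 3, 1), resolution = 1, gain = 0.5)
  expect_length(one, 1)
  expect_true(all(lengths(lapply(one, function(b) bin_members(matrix(c(1, 5, 9)), b))) == 3))

  bins <- build_cover(matrix(c(0, 8), 2, 1), resolution = 4, gain = 0.5)
  got <- t(vapply(bins, function(b) b[1, ], numeric(2)))
  expect_equal(unname(got),
               cbind(c(-0.5, 1.5, 3.5, 5.5), c(2.5, 4.5, 6.5, 8.5)))

  # coverage property over a parameter grid; gain 0 partitions the range
  set.seed(5)
  pts <- cbind(runif(60, -3, 7), runif(60, 0, 1))
  for (res in c(1, 2, 3, 5)) {
    for (gain in c(0, 0.25, 0.5)) {
      bins <- build_cover(pts, res, gain)
      counts <- rowSums(vapply(bins, function(b)
        seq_len(nrow(pts)) %in% bin_members(pts, b), logical(nrow(pts))))
      expect_true(all(counts >= 1))
      if (gain == 0) expect_true(all(counts == 1))
    }
  }
  expect_error(build_cover(matrix(1, 5, 1), resolution = 3, gain = 0.2),
               "zero range")
})

test_that("within-bin clustering matches a brute-force single-linkage oracle", {
  expect_equal(cluster_bin(matrix(1, 1, 2)), 1L)
  expect_equal(cluster_bin(matrix(c(0, 0.1, 10, 10.1), 4, 1)),
               c(1L, 1L, 2L, 2L))

  for (seed in 1:5) {
    x <- make_points(12, 3, seed = seed)
    got <- cluster_bin(x, "euclidean", histogram_bins = 10)
    d <- as.matrix(dist(x))
    dv <- d[lower.tri(d)]
    breaks <- seq(0, max(dv), length.out = 11)
    counts <- hist(dv, breaks = breaks, plot = FALSE)$counts
    empty <- which(counts == 0)
    want <- if (length(empty)) {
      naive_single_linkage(d, breaks[empty[1]])
    } else rep(1L, 12)
    expect_true(same_partition(got, want))
  }
})

test_that("the nerve graph has the expected degenerate and blob topology", {
  # identical subjects collapse to a single node with no edges
  same <- matrix(5, 6, 3, dimnames = list(sprintf("s%d", 1:6), paste0("v", 1:3)))
  g0 <- build_mapper_graph(same, mapper_config())
  expect_equal(nrow(g0$nodes), 1)
  expect_equal(g0$nodes$size, 6)
  expect_equal(nrow(g0$edges), 0)

  set.seed(9)
  x <- rbind(matrix(rnorm(60), 20, 3), matrix(rnorm(60, mean = 12), 20, 3))
  dimnames(x) <- list(sprintf("s%02d", 1:40), paste0("v", 1:3))
  g <- build_mapper_graph(x, mapper_config(lens = "v1", resolution = 3, gain = 0.4))
  expect_equal(igraph::components(as_igraph(g))$no, 2)
  # every subject appears in at least one node
  expect_setequal(unique(unlist(g$members)), rownames(x))
  # every edge's nodes share at least one member
  if (nrow(g$edges)) {
    shared <- vapply(seq_len(nrow(g$edges)), function(e)
      length(intersect(g$members[[g$edges$from[e]]],
                       g$members[[g$edges$to[e]]])), integer(1))
    expect_true(all(shared >= 1))
    expect_equal(shared, g$edges$shared)
  }
})

test_that("graph construction is invariant to subject order", {
  x <- make_points(30, 4, seed = 12)
  cfg <- mapper_config(resolution = 4, gain = 0.35)
  g1 <- build_mapper_graph(x, cfg)
  set.seed(1)
  perm <- sample(nrow(x))
  g2 <- build_mapper_graph(x[perm, ], cfg)
  expect_identical(graph_signature(g1), graph_signature(g2))
})

test_that("bootstrap consensus co-occurrence behaves at its limits and on blobs", {
  x <- make_points(16, 3, seed = 6)
  cfg1 <- mapper_config(resolution = 3, gain = 0.3, n_bootstrap = 1,
                        resample = FALSE, consensus_threshold = 0)
  bc1 <- bootstrap_consensus(x, cfg1)
  g <- bc1$full_graph
  # single no-resample replicate: co-occurrence is the co-membership indicator
  co_ind <- matrix(0, 16, 16)
  for (m in g$member_index) co_ind[m, m] <- 1
  expect_equal(unname(bc1$cooccurrence), co_ind)
  # threshold 0 keeps the full graph
  expect_identical(bc1$graph$edges, g$edges)

  set.seed(2)
  blob <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, mean = 10), 20, 2))
  dimnames(blob) <- list(sprintf("s%02d", 1:40), c("a", "b"))
  bc <- bootstrap_consensus(blob, mapper_config(
    lens = "a", resolution = 2, gain = 0.2, n_bootstrap = 50, seed = 5))
  co <- bc$cooccurrence
  within <- c(co[1:20, 1:20][lower.tri(diag(20))],
              co[21:40, 21:40][lower.tri(diag(20))])
  between <- co[1:20, 21:40]
  expect_gt(mean(within, na.rm = TRUE), 0.95)
  expect_lt(mean(between, na.rm = TRUE), 0.05)
  # consensus edges are a subset of full-data edges
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(bc$graph$edges) %in% key(bc$full_graph$edges)))
})

test_that("overlays average members and report group percentages in [0, 100]", {
  out <- outcome_matrix(
    matrix(c(2, 4, 6, 8), 4, 1, dimnames = list(paste0("s", 1:4), "score")),
    data.frame(subject_id = paste0("s", 1:4),
               arm = c("drug", "drug", "drug", "veh")))
  g <- structure(list(
    nodes = data.frame(id = 1:2, bin = 1:2, cluster = 1L, size = c(2L, 4L)),
    members = list(c("s1", "s2"), c("s1", "s2", "s3", "s4")),
    member_index = list(1:2, 1:4),
    edges = data.frame(from = 1L, to = 2L, shared = 2L),
    subjects = paste0("s", 1:4), lens = NULL, config = NULL
  ), class = "mapper_graph")
  expect_equal(unname(overlay(g, out, "score")), c(3, 5))
  pct <- overlay(g, out, "arm", level = "drug")
  expect_equal(unname(pct), c(100, 75))
  expect_true(all(pct >= 0 & pct <= 100))
  # node-size-weighted overlay mean over disjoint nodes reproduces the cohort fraction
  g2 <- g; g2$members <- list(c("s1", "s2"), c("s3", "s4"))
  g2$nodes$size <- c(2L, 2L)
  p2 <- overlay(g2, out, "arm", level = "drug")
  expect_equal(sum(p2 * g2$nodes$size) / sum(g2$nodes$size),
               100 * mean(out$meta$arm == "drug"))
  expect_error(overlay(g, out, "nope"), "not found")
})

test_that("subjects with identical profiles always share their nodes", {
  set.seed(30)
  base <- matrix(rnorm(36), 12, 3,
                 dimnames = list(sprintf("s%02d", 1:12), paste0("v", 1:3)))
  x <- rbind(base, dup1 = base[3, ], dup2 = base[3, ])
  g <- build_mapper_graph(x, mapper_config(resolution = 3, gain = 0.4))
  in_nodes <- function(s) which(vapply(g$members, function(m) s %in% m, logical(1)))
  expect_identical(in_nodes("dup1"), in_nodes("dup2"))
  expect_identical(in_nodes("dup1"), in_nodes("s03"))
})
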