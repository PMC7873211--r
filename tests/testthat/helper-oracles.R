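# Independent brute-force oracles used across the test files. These are
# deliberately naive implementations kept separate from the package's code
# paths.

# single-linkage agglomeration: repeatedly merge the two clusters with the
# smallest cross-pair distance while it is below `threshold`
naive_single_linkage <- function(dmat, threshold) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) < 2) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq((i + 1), length(clusters))) {
        d <- min(dmat[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    if (bestd >= threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# complete-linkage agglomeration cut at height h: merge the pair with the
# smallest maximum cross-pair distance while below h
naive_complete_linkage <- function(dmat, h) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) < 2) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq((i + 1), length(clusters))) {
        d <- max(dmat[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    if (bestd > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# TRUE when two label vectors describe the same partition
same_partition <- function(a, b) {
  a <- unname(a); b <- unname(b)
  ta <- outer(a, a, `==`); tb <- outer(b, b, `==`)
  isTRUE(all.equal(ta, tb))
}

# exhaustive hypergeometric upper tail: P(overlap >= k)
enum_hyper_tail <- function(k, set_size, universe, n_draw) {
  tot <- choose(universe, n_draw)
  kmax <- min(set_size, n_draw)
  if (k <= max(0, n_draw - (universe - set_size))) return(1)
  sum(vapply(k:kmax, function(x)
    choose(set_size, x) * choose(universe - set_size, n_draw - x), numeric(1))) / tot
}

# canonical signature of a mapper graph for isomorphism-by-members checks
graph_signature <- function(g) {
  node_sets <- lapply(g$members, function(m) sort(m))
  ord <- order(vapply(node_sets, paste, character(1), collapse = ","))
  rank <- match(seq_along(node_sets), ord)
  edges <- apply(g$edges, 1, function(e)
    paste(sort(c(rank[e[["from"]]], rank[e[["to"]]])), collapse = "~"))
  list(nodes = node_sets[ord], edges = sort(unname(edges)))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
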