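# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: bipartitions are enumerated from the raw
# edge matrix, and splits by exhaustive (feature, threshold) scans.

oracle_tips_below <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_tips_below, tree = tree))
}

# Nontrivial bipartitions, canonicalised by the side excluding the
# alphabetically first leaf.
oracle_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  ref <- all_tips[1]
  internal_children <- tree$edge[tree$edge[, 2] > nt, 2]
  out <- character(0)
  for (ch in internal_children) {
    side <- sort(oracle_tips_below(tree, ch))
    if (ref %in% side) side <- sort(setdiff(all_tips, side))
    if (length(side) >= 2 && length(side) <= nt - 2)
      out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

oracle_rf <- function(a, b) {
  sa <- oracle_bipartitions(a)
  sb <- oracle_bipartitions(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

# Exhaustive SSR scan over every (feature, midpoint-threshold) pair.
# Returns the minimal SSR and the set of features achieving it (within the
# same relative tolerance the implementation uses).
oracle_best_split <- function(X, y, min_leaf = 1L) {
  n <- length(y)
  best <- Inf
  per_feature <- rep(Inf, ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (t in (v[-1] + v[-length(v)]) / 2) {
      left <- y[X[, j] <= t]
      right <- y[X[, j] > t]
      if (length(left) < min_leaf || length(right) < min_leaf) next
      ssr <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
      per_feature[j] <- min(per_feature[j], ssr)
    }
    best <- min(best, per_feature[j])
  }
  if (!is.finite(best)) return(NULL)
  tied <- which(per_feature - best <= 1e-9 * max(1, abs(best)))
  list(ssr = best, features = tied)
}

random_labeled_tree <- function(n) {
  tr <- ape::rtopology(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  tr
}

mirror_lower_for_test <- function(m) {
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- 0
  m
}

# A matrix with NA holes matching the instance's mask, as a caller would
# load it from a file.
masked_values <- function(inst) {
  m <- inst$full_matrix
  m[inst$mask] <- NA_real_
  m
}
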