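#' Random-forest configuration
#'
#' Hyperparameters of the regression forest used inside the imputation
#' loop. The fractional parameters (`bootstrap_size`, `max_features`,
#' `max_depth`, `min_leaf`) are given in (0, 1] and resolved against the
#' training-set dimensions at fit time via [resolve_fraction()];
#' `max_depth = -1` disables the depth limit.
#'
#' @param bootstrap logical; train each tree on a with-replacement resample?
#' @param bootstrap_size fraction of rows drawn per bootstrap resample.
#' @param n_trees number of trees per forest.
#' @param max_features fraction of features examined at each node.
#' @param max_depth fraction of the training-set size bounding tree depth
#'   (in edges), or -1 for unlimited.
#' @param min_leaf fraction of rows a leaf must contain.
#' @param tiebreak how to resolve exact ties in split error: `"random"`
#'   (uniform among tied features) or `"q_priority"` (the tied feature
#'   ranked first in the target OTU's Q-matrix priority list).
#' @return An object of class `forest_config`.
#' @seealso [forest_profile()] for the two tuned default profiles.
#' @export
forest_config <- function(bootstrap = FALSE, bootstrap_size = 1,
                          n_trees = 30, max_features = 0.25,
                          max_depth = 1, min_leaf = 0.01,
                          tiebreak = c("random", "q_priority")) {
  tiebreak <- match.arg(tiebreak)
  for (nm in c("bootstrap_size", "max_features", "min_leaf")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1)
      stop(nm, " must be a single value in (0, 1]", call. = FALSE)
  }
  if (!(identical(as.numeric(max_depth), -1) ||
        (max_depth > 0 && max_depth <= 1)))
    stop("max_depth must be in (0, 1] or -1 (unlimited)", call. = FALSE)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  structure(list(bootstrap = isTRUE(bootstrap),
                 bootstrap_size = bootstrap_size,
                 n_trees = as.integer(n_trees),
                 max_features = max_features,
                 max_depth = max_depth,
                 min_leaf = min_leaf,
                 tiebreak = tiebreak),
            class = "forest_config")
}

#' Tuned forest configuration profiles
#'
#' The two hyperparameter profiles found to perform best on real datasets:
#' without bootstrap (30 trees, a quarter of the features per node,
#' min_leaf 0.01) and with bootstrap (full-size resamples, 50 trees, all
#' features, min_leaf 0.13). Both leave the depth limit at the dataset size.
#'
#' @param profile `"non-bootstrap"` or `"bootstrap"`.
#' @param tiebreak see [forest_config()].
#' @return A `forest_config`.
#' @export
forest_profile <- function(profile = c("non-bootstrap", "bootstrap"),
                           tiebreak = "random") {
  profile <- match.arg(profile)
  if (profile == "non-bootstrap") {
    forest_config(bootstrap = FALSE, n_trees = 30, max_features = 0.25,
                  max_depth = 1, min_leaf = 0.01, tiebreak = tiebreak)
  } else {
    forest_config(bootstrap = TRUE, bootstrap_size = 1, n_trees = 50,
                  max_features = 1, max_depth = 1, min_leaf = 0.13,
                  tiebreak = tiebreak)
  }
}

#' Resolve a fractional hyperparameter against a dataset dimension
#'
#' Fractional hyperparameters are scaled by the relevant dimension of the
#' data at hand: `max(minimum, ceiling(fraction * n))`. The ceiling, with a
#' floor of `minimum`, avoids zero-valued resolutions on small matrices.
#'
#' @param fraction value in (0, 1].
#' @param n the dimension (rows or features) to scale against.
#' @param minimum lower bound of the resolved count.
#' @return Integer count.
#' @examples
#' resolve_fraction(0.01, 55) # 1
#' resolve_fraction(0.13, 50) # 7
#' @export
resolve_fraction <- function(fraction, n, minimum = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  max(as.integer(minimum), as.integer(ceiling(fraction * n)))
}

#' Best SSR split of a training subset
#'
#' Scans the candidate features for the (feature, threshold) pair minimising
#' the sum of squared residuals
#' \eqn{SSR = \sum_{left}(y-\bar y_L)^2 + \sum_{right}(y-\bar y_R)^2},
#' with thresholds at midpoints of consecutive distinct sorted feature
#' values and both children required to hold at least `min_leaf` rows.
#' Features tying on SSR (relative tolerance 1e-9) are resolved either
#' uniformly at random or by the target OTU's Q-matrix priority list.
#'
#' @param X numeric matrix of training rows (columns indexed by OTU).
#' @param y numeric response (distances to the target OTU).
#' @param features columns of `X` to consider.
#' @param target_otu index of the OTU being imputed (for priority lookup).
#' @param min_leaf minimum rows per child (already resolved to a count).
#' @param tiebreak `"random"` or `"q_priority"`.
#' @param priorities priority table from [priority_table()] (required for
#'   `"q_priority"`).
#' @return A list `(feature, threshold, ssr)` or `NULL` when no legal split
#'   exists (the node becomes a leaf).
#' @export
best_split <- function(X, y, features = seq_len(ncol(X)), target_otu = NULL,
                       min_leaf = 1L, tiebreak = "random",
                       priorities = NULL) {
  n <- length(y)
  if (n < 2L * min_leaf) return(NULL)
  if (max(y) - min(y) <= 0) return(NULL)  # pure node
  nf <- length(features)
  f_ssr <- rep(Inf, nf)
  f_thr <- rep(NA_real_, nf)
  pos <- seq_len(n - 1L)
  for (fi in seq_len(nf)) {
    v <- X[, features[fi]]
    ord <- order(v)
    vs <- v[ord]
    ys <- y[ord]
    valid <- (vs[pos] < vs[pos + 1L]) & (pos >= min_leaf) &
      ((n - pos) >= min_leaf)
    if (!any(valid)) next
    cs <- cumsum(ys)
    css <- cumsum(ys * ys)
    ssr <- (css[pos] - cs[pos]^2 / pos) +
      ((css[n] - css[pos]) - (cs[n] - cs[pos])^2 / (n - pos))
    ssr[!valid] <- Inf
    kb <- which.min(ssr)
    f_ssr[fi] <- ssr[kb]
    f_thr[fi] <- (vs[kb] + vs[kb + 1L]) / 2
  }
  best <- min(f_ssr)
  if (!is.finite(best)) return(NULL)
  tied <- which(f_ssr - best <= 1e-9 * max(1, abs(best)))
  if (length(tied) == 1L) {
    pick <- tied
  } else if (tiebreak == "q_priority") {
    if (is.null(priorities) || is.null(target_otu))
      stop("q_priority tie-break needs a priority table and target OTU",
           call. = FALSE)
    rank <- match(features[tied], priorities[[target_otu]])
    pick <- tied[which.min(rank)]
  } else {
    pick <- tied[sample.int(length(tied), 1L)]
  }
  list(feature = features[pick], threshold = f_thr[pick], ssr = f_ssr[pick])
}

# Recursive CART-style tree growth on a row subset. Nodes draw a fresh
# random feature subset; recursion stops at depth, leaf-size, or purity.
grow_tree <- function(X, y, idx, depth, max_depth, mtry, min_leaf,
                      target_otu, tiebreak, priorities) {
  ys <- y[idx]
  if (length(idx) < 2L * min_leaf || depth >= max_depth ||
      max(ys) - min(ys) <= 0) {
    return(list(leaf = TRUE, value = mean(ys)))
  }
  nf <- ncol(X)
  feats <- if (mtry < nf) sort(sample.int(nf, mtry)) else seq_len(nf)
  sp <- best_split(X[idx, , drop = FALSE], ys, features = feats,
                   target_otu = target_otu, min_leaf = min_leaf,
                   tiebreak = tiebreak, priorities = priorities)
  if (is.null(sp)) return(list(leaf = TRUE, value = mean(ys)))
  go_left <- X[idx, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(X, y, idx[go_left], depth + 1L, max_depth, mtry,
                        min_leaf, target_otu, tiebreak, priorities),
       right = grow_tree(X, y, idx[!go_left], depth + 1L, max_depth, mtry,
                         min_leaf, target_otu, tiebreak, priorities))
}

predict_tree <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$value
}

#' Fit a regression forest for one target column
#'
#' Builds `n_trees` SSR-split regression trees. With bootstrap enabled each
#' tree trains on a with-replacement resample of the rows; feature subsets
#' are redrawn at every node. Leaf predictions are means of the training
#' targets they contain, so forest predictions always stay within the
#' observed target range. All randomness (bootstrap draws, feature subsets,
#' random tie-breaks) is consumed from the current RNG stream, making fits
#' reproducible under `set.seed()`.
#'
#' @param X numeric matrix of predictor columns (one per other OTU), rows =
#'   observations where the target is known.
#' @param y observed target distances.
#' @param target_otu OTU index of the imputed column, used by the
#'   `q_priority` tie-break. The priority table indexes features by their
#'   column position in `X`'s parent matrix, so `X` columns must be named
#'   by OTU index via `feature_otus`.
#' @param config a [forest_config()].
#' @param priorities optional [priority_table()].
#' @param feature_otus OTU index corresponding to each column of `X`
#'   (defaults to column position).
#' @return An object of class `regression_forest`.
#' @export
fit_forest <- function(X, y, target_otu = NULL,
                       config = forest_config(), priorities = NULL,
                       feature_otus = seq_len(ncol(X))) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0 || length(y) != n)
    stop("training set is empty or X rows != length(y)", call. = FALSE)
  min_leaf <- resolve_fraction(config$min_leaf, n)
  mtry <- resolve_fraction(config$max_features, ncol(X))
  max_depth <- if (identical(as.numeric(config$max_depth), -1)) Inf
               else resolve_fraction(config$max_depth, n)
  boot_n <- resolve_fraction(config$bootstrap_size, n)
  # priorities index OTUs; remap onto local column positions of X once
  local_prio <- NULL
  if (!is.null(priorities) && !is.null(target_otu)) {
    p <- priorities[[target_otu]]
    local_prio <- list()
    local_prio[[target_otu]] <- match(p[p %in% feature_otus], feature_otus)
  }
  trees <- vector("list", config$n_trees)
  for (t in seq_len(config$n_trees)) {
    idx <- if (config$bootstrap) sample.int(n, boot_n, replace = TRUE)
           else seq_len(n)
    trees[[t]] <- grow_tree(X, y, idx, 0L, max_depth, mtry, min_leaf,
                            target_otu, config$tiebreak, local_prio)
  }
  structure(list(trees = trees, n_features = ncol(X), y_range = range(y)),
            class = "regression_forest")
}

#' Predict with a regression forest
#'
#' Per query row, the mean of the per-tree leaf values.
#'
#' @param forest a `regression_forest` from [fit_forest()].
#' @param X query rows (feature layout as at training).
#' @return Numeric vector of predictions, one per row of `X`.
#' @export
predict_forest <- function(forest, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != forest$n_features)
    stop("query has ", ncol(X), " features, forest was trained on ",
         forest$n_features, call. = FALSE)
  apply(X, 1, function(x) {
    mean(vapply(forest$trees, predict_tree, numeric(1), x = x))
  })
}

#' Q-matrix priority lists for split tie-breaking
#'
#' For each OTU, ranks the remaining OTUs by ascending Q-matrix value (ties
#' by lowest index). The first entry for OTU x is the partner the
#' neighbor-joining criterion would agglomerate with x first; this ranking
#' resolves SSR ties in favour of phylogenetically closer features.
#'
#' @param Q a Q-matrix from [q_matrix()].
#' @return A list of integer vectors, one permutation of the other OTU
#'   indices per OTU.
#' @export
priority_table <- function(Q) {
  check_square_matrix(Q, "Q-matrix")
  n <- nrow(Q)
  if (n < 3) stop("Q-matrix needs at least 3 OTUs", call. = FALSE)
  lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    others[order(Q[i, others], others)]
  })
}

#' @export
print.forest_config <- function(x, ...) {
  cat("Regression-forest configuration\n")
  cat(sprintf("  trees: %d, bootstrap: %s (size %.2f)\n", x$n_trees,
              x$bootstrap, x$bootstrap_size))
  cat(sprintf("  max_features: %.2f, max_depth: %s, min_leaf: %.2f\n",
              x$max_features,
              if (identical(as.numeric(x$max_depth), -1)) "unlimited"
              else format(x$max_depth), x$min_leaf))
  cat(sprintf("  tie-break: %s\n", x$tiebreak))
  invisible(x)
}
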