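#' Least-squares fit between a distance matrix and a tree
#'
#' \deqn{S = \sum_{i \ne j} (\delta_{ij} - \theta_{ij})^2,}
#' where \eqn{\delta} are the matrix distances and \eqn{\theta} the tree's
#' patristic distances. Summation runs over ordered pairs, so each
#' unordered pair counts twice; candidate selection is unaffected by the
#' convention since all candidates are scored the same way. Zero iff the
#' matrix is additive and realised by the tree.
#'
#' @param D complete symmetric distance matrix with labels.
#' @param tree an `ape::phylo` over the same label set.
#' @return Nonnegative scalar.
#' @export
ls_score <- function(D, tree) {
  labels <- matrix_labels(D)
  if (!setequal(labels, tree$tip.label))
    stop("matrix labels and tree tips differ", call. = FALSE)
  P <- patristic_matrix(tree, labels = labels)
  sum((D - P)^2)
}

#' Minimum-evolution score of a tree
#'
#' The total branch length; under the minimum-evolution criterion the
#' candidate with the smallest total length wins.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return Scalar sum of branch lengths.
#' @export
me_score <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  sum(tree$edge.length)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' The number of nontrivial bipartitions (internal edges) present in one
#' tree but not the other; 0 iff the topologies agree, at most 2N-6 for a
#' pair of bifurcating trees on N leaves.
#'
#' @param a,b `ape::phylo` trees over the same leaf label set, >= 4 leaves.
#' @return Nonnegative integer.
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees must share the same leaf label set", call. = FALSE)
  if (length(a$tip.label) < 4)
    stop("Robinson-Foulds needs at least 4 leaves", call. = FALSE)
  as.integer(phangorn::RF.dist(a, b, check.labels = TRUE))
}

#' Normalised Robinson-Foulds distance
#'
#' RF divided by its maximum over bifurcating trees, 2N-6. Multiplying by
#' 100 gives the percentage of topological error introduced by an
#' imputation; 0 means the imputed tree matches the reference topology.
#'
#' @param rf Robinson-Foulds distance.
#' @param n number of leaves (N >= 4).
#' @return Value in \[0, 1\].
#' @export
nrf <- function(rf, n) {
  if (n < 4) stop("NRF is undefined for fewer than 4 leaves", call. = FALSE)
  if (rf < 0 || rf > 2 * n - 6)
    stop("rf must lie in [0, 2N-6]", call. = FALSE)
  rf / (2 * n - 6)
}
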