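#' Neighbor-joining Q-matrix
#'
#' The agglomeration criterion of neighbor joining,
#' \deqn{Q_{ij} = (N-2)\,\delta_{ij} - S_i - S_j, \qquad
#'       S_x = \sum_{i=1}^{N} \delta_{xi},}
#' with row sums taken over the full row (the diagonal zero contributes
#' nothing). The pair with the smallest Q value is the one NJ joins first;
#' the same ranking feeds the split tie-break priorities of the forest.
#'
#' @param D complete symmetric distance matrix, N >= 3.
#' @return Symmetric numeric matrix; the diagonal is set to `NA` as it has
#'   no meaning.
#' @export
q_matrix <- function(D) {
  check_square_matrix(D)
  n <- nrow(D)
  if (n < 3) stop("Q-matrix requires at least 3 OTUs", call. = FALSE)
  S <- rowSums(D)
  Q <- (n - 2) * D - outer(S, S, `+`)
  diag(Q) <- NA_real_
  dimnames(Q) <- dimnames(D)
  Q
}

#' Neighbor-joining tree from a complete distance matrix
#'
#' Standard Saitou–Nei agglomeration, producing an unrooted bifurcating
#' tree whose leaves carry the matrix labels. On additive input the
#' recovered topology matches the generating tree and patristic distances
#' reproduce the input exactly. Negative branch lengths, which NJ can
#' produce on non-additive input, are kept as computed so least-squares and
#' patristic scores see the unaltered tree.
#'
#' @param D complete symmetric distance matrix, N >= 3, labels as dimnames.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  check_square_matrix(D)
  if (nrow(D) < 3) stop("neighbor joining requires at least 3 OTUs",
                        call. = FALSE)
  if (anyNA(D)) stop("distance matrix has missing values; impute first",
                     call. = FALSE)
  if (!is_symmetric_num(D, tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  dimnames(D) <- list(matrix_labels(D), matrix_labels(D))
  ape::nj(D)
}

#' Patristic distance matrix of a tree
#'
#' Pairwise sums of branch lengths along leaf-to-leaf paths
#' (\eqn{\theta_{ij}}), the distances a tree implies.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param labels optional label order for the rows/columns of the result;
#'   defaults to the tree's tip order.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
patristic_matrix <- function(tree, labels = NULL) {
  m <- stats::cophenetic(tree)
  if (!is.null(labels)) {
    if (!setequal(labels, rownames(m)))
      stop("requested labels do not match the tree's tips", call. = FALSE)
    m <- m[labels, labels]
  }
  m
}

#' Serialize a tree to Newick
#'
#' @param tree an `ape::phylo`.
#' @return A single Newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Parse a Newick string
#'
#' @param text Newick text (one tree).
#' @return An `ape::phylo`.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || is.null(tree$tip.label))
    stop("malformed Newick string: ", substr(text, 1, 60), call. = FALSE)
  tree
}
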