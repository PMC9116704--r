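#' Branch-length samplers
#'
#' Convenience generators for branch lengths: i.i.d. uniform on (a, b) or
#' exponential with the given rate, truncated away from zero so all
#' branches are strictly positive.
#'
#' @param a,b uniform bounds (substitutions/site).
#' @param rate exponential rate.
#' @return A function of `n` returning `n` positive branch lengths.
#' @export
branch_uniform <- function(a = 0.1, b = 1) {
  force(a); force(b)
  if (a <= 0 || b <= a) stop("need 0 < a < b", call. = FALSE)
  function(n) stats::runif(n, a, b)
}

#' @rdname branch_uniform
#' @export
branch_exponential <- function(rate = 2) {
  force(rate)
  function(n) pmax(stats::rexp(n, rate), 1e-6)
}

#' Random unrooted bifurcating tree
#'
#' Draws a topology uniformly at random over all unrooted bifurcating
#' shapes on `n` leaves (sequential random edge attachment) and assigns
#' i.i.d. positive branch lengths.
#'
#' @param n number of leaves, >= 4.
#' @param branch_dist a function of `n` returning positive branch lengths;
#'   see [branch_uniform()].
#' @param seed optional integer seed.
#' @return An unrooted `ape::phylo` with `n` tips labelled `t1..tn`.
#' @export
random_tree <- function(n, branch_dist = branch_uniform(), seed = NULL) {
  if (n < 4) stop("need at least 4 leaves", call. = FALSE)
  with_seed(seed, {
    tree <- ape::rtopology(n, rooted = FALSE)
    tree$edge.length <- branch_dist(nrow(tree$edge))
    if (any(tree$edge.length <= 0))
      stop("branch_dist produced non-positive lengths", call. = FALSE)
    tree
  })
}

#' Synthetic ground-truth instance for imputation benchmarks
#'
#' Builds a random tree, takes its patristic distances as the complete
#' matrix — exactly additive when `noise_cv = 0`, otherwise each unordered
#' pair is multiplied by a lognormal factor with unit mean and coefficient
#' of variation `noise_cv` (multiplicative noise keeps distances positive)
#' — and masks a fraction of the pairs at random. This emulates the
#' benchmark setting in which missing entries are introduced into a known
#' complete matrix and recovery is scored against the generating tree.
#'
#' @param n number of OTUs, >= 4.
#' @param branch_dist branch-length sampler, see [random_tree()].
#' @param noise_cv coefficient of variation of multiplicative pair noise;
#'   0 gives an exactly additive matrix.
#' @param missing_fraction fraction of unordered pairs to mask (0 allowed:
#'   no mask).
#' @param seed optional integer seed; the instance is bit-reproducible
#'   under the same seed.
#' @return An object of class `phylimp_instance`: list with `truth_tree`,
#'   `full_matrix`, `mask`, `params` and `seed`.
#' @export
make_instance <- function(n, branch_dist = branch_uniform(),
                          noise_cv = 0, missing_fraction = 0.05,
                          seed = NULL) {
  with_seed(seed, {
    tree <- random_tree(n, branch_dist)
    D <- patristic_matrix(tree, labels = paste0("t", seq_len(n)))
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      fac <- matrix(1, n, n)
      up <- upper.tri(fac)
      fac[up] <- stats::rlnorm(sum(up), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      fac <- mirror_upper(fac)
      D <- D * fac
    }
    mask <- if (missing_fraction > 0) inject_missing(D, missing_fraction)
            else matrix(FALSE, n, n, dimnames = dimnames(D))
    structure(list(truth_tree = tree, full_matrix = D, mask = mask,
                   params = list(n = n, noise_cv = noise_cv,
                                 missing_fraction = missing_fraction),
                   seed = seed),
              class = "phylimp_instance")
  })
}

#' @export
print.phylimp_instance <- function(x, ...) {
  cat(sprintf("Synthetic instance: %d OTUs, noise CV %.2f, %.0f%% pairs masked (%d cells)\n",
              x$params$n, x$params$noise_cv,
              100 * x$params$missing_fraction, sum(x$mask)))
  invisible(x)
}
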