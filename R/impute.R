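#' Imputation configuration
#'
#' Bundles the forest hyperparameters with the matrix search strategy, the
#' candidate selector, and the stop criterion. The default —
#' triangular-candidate splitting with least-squares selection, random
#' tie-breaks and the least-squares stop rule — is the combination found to
#' behave best overall.
#'
#' @param forest a [forest_config()]; defaults to the non-bootstrap profile.
#' @param candidate_strategy how to symmetrise each iteration's raw matrix:
#'   `"split_three"` builds lower-triangular, upper-triangular and mean
#'   candidates and selects among them; `"symmetrize_each_column"` averages
#'   the matrix with its transpose after every column imputation;
#'   `"symmetrize_at_end"` averages once per iteration.
#' @param selector criterion choosing among the three candidates (only with
#'   `"split_three"`): `"ls"` (least-squares fit of each candidate to its
#'   own NJ tree), `"me"` (minimum total branch length of the candidates'
#'   NJ trees), or `"set_difference"` (closest to the previous iteration's
#'   matrix, no trees involved).
#' @param stop_criterion `"ls"` (stop when the matrix-to-own-NJ-tree
#'   least-squares fit stops improving) or `"set_difference"` (stop when
#'   consecutive matrices stop approaching each other).
#' @param max_iterations safety cap on imputation iterations.
#' @param seed optional integer seed applied by [impute_distances()].
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(forest = forest_profile("non-bootstrap"),
                              candidate_strategy = c("split_three",
                                                     "symmetrize_each_column",
                                                     "symmetrize_at_end"),
                              selector = c("ls", "me", "set_difference"),
                              stop_criterion = c("ls", "set_difference"),
                              max_iterations = 50L,
                              seed = NULL) {
  stopifnot(inherits(forest, "forest_config"))
  candidate_strategy <- match.arg(candidate_strategy)
  selector <- match.arg(selector)
  stop_criterion <- match.arg(stop_criterion)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(forest = forest,
                 candidate_strategy = candidate_strategy,
                 selector = selector,
                 stop_criterion = stop_criterion,
                 max_iterations = as.integer(max_iterations),
                 seed = seed),
            class = "imputation_config")
}

# Mirror one triangle of a square matrix onto the other.
mirror_lower <- function(m) { m[upper.tri(m)] <- t(m)[upper.tri(m)]; m }
mirror_upper <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; m }

#' Symmetrise an iteration's raw matrix and select the best candidate
#'
#' The column-by-column forest imputation leaves the working matrix
#' asymmetric. Under the `"split_three"` strategy, three symmetric
#' candidates are derived — the mirrored lower triangle, the mirrored upper
#' triangle, and the elementwise mean with the transpose — and one is
#' selected: by the least-squares fit of each candidate to its own NJ tree
#' (`"ls"`), by the total branch length of the candidates' NJ trees
#' (`"me"`), or by proximity to the previous iteration's matrix
#' (`"set_difference"`). The other strategies return the mean-symmetrised
#' matrix directly, with no phylogenetic criterion involved.
#'
#' @param M_raw square, possibly asymmetric matrix from the column loop.
#' @param M_prev the previous iteration's (symmetric) matrix.
#' @param config an [imputation_config()].
#' @return A list with `matrix` (the chosen symmetric matrix), `tree` (its
#'   NJ tree when the selector built one, else `NULL`), `score` (the
#'   winning selector score, `NA` when no selector ran) and `choice`.
#' @export
select_candidate <- function(M_raw, M_prev, config) {
  check_square_matrix(M_raw)
  if (config$candidate_strategy != "split_three") {
    m <- (M_raw + t(M_raw)) / 2
    diag(m) <- 0
    return(list(matrix = m, tree = NULL, score = NA_real_, choice = "mean"))
  }
  cands <- list(lower = mirror_lower(M_raw),
                upper = mirror_upper(M_raw),
                mean = (M_raw + t(M_raw)) / 2)
  cands <- lapply(cands, function(m) { diag(m) <- 0; m })
  if (config$selector == "set_difference") {
    scores <- vapply(cands, set_difference_error, numeric(1),
                     x_old = M_prev)
    w <- which.min(scores)
    return(list(matrix = cands[[w]], tree = NULL, score = scores[[w]],
                choice = names(cands)[w]))
  }
  trees <- lapply(cands, nj_tree)
  scores <- if (config$selector == "ls") {
    mapply(ls_score, cands, trees)
  } else {
    vapply(trees, me_score, numeric(1))
  }
  w <- which.min(scores)
  list(matrix = cands[[w]], tree = trees[[w]], score = scores[[w]],
       choice = names(cands)[w])
}

#' Per-iteration stop-criterion error
#'
#' Under `"set_difference"`, the normalised squared difference between the
#' current and previous matrices (convergence in matrix space). Under
#' `"ls"`, the least-squares fit of the current matrix to its own NJ tree:
#' iteration stops once the matrix stops getting closer to *some* tree,
#' i.e. once it is phylogenetically worse than its predecessor.
#'
#' @param M_curr,M_prev current and previous symmetric matrices.
#' @param tree_curr the current matrix's NJ tree if already built (avoids
#'   recomputation); `NULL` to build it here.
#' @param config an [imputation_config()].
#' @return Nonnegative scalar.
#' @export
stop_error <- function(M_curr, M_prev, tree_curr = NULL, config) {
  if (config$stop_criterion == "set_difference") {
    set_difference_error(M_curr, M_prev)
  } else {
    ls_score(M_curr, tree_curr %||% nj_tree(M_curr))
  }
}

#' Impute missing entries of a phylogenetic distance matrix
#'
#' The iterative random-forest imputation loop. Missing cells are first
#' filled with symmetrised column means. Then, per iteration, each column
#' with missing entries — visited in ascending order of missing count — is
#' regressed on all other columns with a regression forest trained on the
#' rows where the column is observed, and the forest's predictions are
#' written back immediately so later columns train on updated values. The
#' asymmetric result is symmetrised via [select_candidate()], and the loop
#' repeats while the stop-criterion error strictly improves, returning the
#' matrix of the last improving iteration. Observed input values are never
#' altered.
#'
#' When the forest tie-break is `"q_priority"`, OTU priority lists are
#' computed once from the Q-matrix of the initial-guess matrix.
#'
#' @param values square distance matrix; masked cells may hold `NA`.
#' @param mask logical missingness mask (`TRUE` = missing).
#' @param config an [imputation_config()].
#' @param seed integer seed governing all randomness of the run; `NULL`
#'   uses the current RNG state.
#' @return An object of class `phylimp_result`: a list with `imputed`
#'   (complete symmetric matrix preserving all observed values), `tree`
#'   (NJ tree of the imputed matrix), `iterations`, `error_trace`
#'   (stop-criterion value per iteration), `converged` and `config`.
#' @examples
#' inst <- make_instance(n = 8, missing_fraction = 0.05, seed = 1)
#' res <- impute_distances(inst$full_matrix, inst$mask, seed = 1)
#' rf_distance(res$tree, inst$truth_tree)
#' @export
impute_distances <- function(values, mask, config = imputation_config(),
                             seed = config$seed) {
  check_square_matrix(values)
  n <- nrow(values)
  if (n < 4) stop("imputation requires at least 4 OTUs", call. = FALSE)
  if (!identical(dim(mask), dim(values)))
    stop("mask and matrix dimensions differ", call. = FALSE)
  labels <- matrix_labels(values)
  dimnames(values) <- dimnames(mask) <- list(labels, labels)

  ord <- column_order(mask)$order
  if (length(ord) == 0) {
    tree <- nj_tree(values)
    return(structure(list(imputed = values, tree = tree, iterations = 1L,
                          error_trace = numeric(0), converged = TRUE,
                          config = config),
                     class = "phylimp_result"))
  }

  with_seed(seed, {
    M_init <- initial_guess(values, mask)
    priorities <- if (config$forest$tiebreak == "q_priority") {
      priority_table(q_matrix(M_init))
    } else NULL

    old_error <- Inf
    M_new <- M_init
    M_best <- M_init
    tree_best <- NULL
    trace <- numeric(0)
    converged <- TRUE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      M_old <- M_new
      W <- M_old
      for (c in ord) {
        miss_rows <- which(mask[, c])
        obs_rows <- setdiff(which(!mask[, c]), c)
        fo <- fit_forest(W[obs_rows, -c, drop = FALSE], W[obs_rows, c],
                         target_otu = c, config = config$forest,
                         priorities = priorities,
                         feature_otus = setdiff(seq_len(n), c))
        W[miss_rows, c] <- predict_forest(fo, W[miss_rows, -c, drop = FALSE])
        if (config$candidate_strategy == "symmetrize_each_column") {
          W <- (W + t(W)) / 2
          W <- reassert_observed(W, values, mask)
        }
      }
      cand <- select_candidate(W, M_old, config)
      M_cand <- reassert_observed(cand$matrix, values, mask)
      err <- if (config$candidate_strategy == "split_three" &&
                 config$selector == "ls" && config$stop_criterion == "ls" &&
                 identical(M_cand, cand$matrix)) {
        cand$score
      } else {
        stop_error(M_cand, M_old,
                   if (identical(M_cand, cand$matrix)) cand$tree else NULL,
                   config)
      }
      trace[iter] <- err
      if (err < old_error) {
        old_error <- err
        M_new <- M_cand
        M_best <- M_cand
        tree_best <- cand$tree
        if (iter >= config$max_iterations) {
          converged <- FALSE
          warning("stopped at max_iterations = ", config$max_iterations,
                  " while still improving; returning best-so-far",
                  call. = FALSE)
          break
        }
      } else {
        break
      }
    }
    tree <- if (!is.null(tree_best) && identical(M_best, M_new)) tree_best
            else nj_tree(M_best)
    structure(list(imputed = M_best, tree = tree, iterations = iter,
                   error_trace = trace, converged = converged,
                   config = config),
              class = "phylimp_result")
  })
}

#' Mean-only baseline imputation
#'
#' The initial-guess step alone: symmetrised column means, no forest and no
#' iteration. Serves as the reference point the iterative method is
#' expected to beat.
#'
#' @inheritParams impute_distances
#' @return A `phylimp_result` with `iterations = 0`.
#' @export
impute_mean_baseline <- function(values, mask) {
  m <- initial_guess(values, mask)
  m <- reassert_observed(m, values, mask)
  structure(list(imputed = m, tree = nj_tree(m), iterations = 0L,
                 error_trace = numeric(0), converged = TRUE,
                 config = NULL),
            class = "phylimp_result")
}

#' @export
print.phylimp_result <- function(x, ...) {
  n <- nrow(x$imputed)
  cat(sprintf("Imputed %dx%d distance matrix (%d iteration%s%s)\n",
              n, n, x$iterations, if (x$iterations == 1) "" else "s",
              if (x$converged) "" else ", hit iteration cap"))
  if (length(x$error_trace) > 0)
    cat("  stop-criterion trace:",
        paste(signif(x$error_trace, 4), collapse = " -> "), "\n")
  cat("  NJ tree:", write_newick(x$tree), "\n")
  invisible(x)
}
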