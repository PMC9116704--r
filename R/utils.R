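`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Sets the global RNG seed for the duration of `code` and restores the
#' previous RNG state afterwards, so seeded helpers do not disturb the
#' caller's random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation (Lehmer step per index); keeps results
# reproducible across nested loops without correlated streams. Always < 2^31.
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (i in c(...)) {
    x <- (x * 48271 + as.numeric(i) + 1) %% 2147483647
  }
  as.integer(x + 1)
}

# Shared validation for square labeled distance matrices.
check_square_matrix <- function(values, what = "distance matrix") {
  if (!is.matrix(values) || !is.numeric(values))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(values) != ncol(values))
    stop(what, " must be square, got ", nrow(values), "x", ncol(values),
         call. = FALSE)
  invisible(values)
}

matrix_labels <- function(values) {
  lab <- rownames(values) %||% colnames(values)
  if (is.null(lab)) lab <- paste0("t", seq_len(nrow(values)))
  lab
}

is_symmetric_num <- function(m, tol = 1e-9) {
  isTRUE(all.equal(m, t(m), tolerance = tol, check.attributes = FALSE))
}
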