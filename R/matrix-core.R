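#' Read a pairwise distance matrix with missing entries
#'
#' Reads a square labeled matrix of evolutionary distances
#' (substitutions/site) in either the PHYLIP square dialect (first line: the
#' number of taxa; then one row per OTU with the label followed by N
#' whitespace-separated values) or CSV with a header row and a leading label
#' column. Cells carrying one of `missing_tokens` are flagged as missing.
#'
#' @param path file to read.
#' @param format `"phylip_square"` or `"csv"`.
#' @param missing_tokens character vector of sentinels marking missing cells.
#' @return A list with components `values` (numeric matrix, `NA` at missing
#'   cells, zero diagonal) and `mask` (logical matrix, `TRUE` = missing).
#' @examples
#' f <- tempfile()
#' m <- matrix(c(0, .5, .5, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' write_distance_matrix(m, path = f)
#' read_distance_matrix(f)
#' @export
read_distance_matrix <- function(path,
                                 format = c("phylip_square", "csv"),
                                 missing_tokens = c("NA", "?", "-1")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "phylip_square") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n) || n < 1)
      stop("first line must be the number of taxa, got '", lines[1], "'",
           call. = FALSE)
    if (length(lines) < n + 1)
      stop("expected ", n, " matrix rows, found ", length(lines) - 1,
           call. = FALSE)
    labels <- character(n)
    cells <- matrix(NA_character_, n, n)
    for (i in seq_len(n)) {
      tok <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      if (length(tok) != n + 1)
        stop("row ", i, ": expected label + ", n, " values, found ",
             length(tok) - 1, " values (matrix not square?)", call. = FALSE)
      labels[i] <- tok[1]
      cells[i, ] <- tok[-1]
    }
  } else {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                          na.strings = character(0))
    labels <- df[[1]]
    cells <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(cells) != ncol(cells))
      stop("matrix not square: ", nrow(cells), " rows vs ", ncol(cells),
           " value columns", call. = FALSE)
    if (!identical(unname(colnames(cells)), unname(labels)))
      stop("row labels and column header disagree", call. = FALSE)
    n <- nrow(cells)
  }
  if (anyDuplicated(labels))
    stop("duplicate OTU labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  mask <- matrix(cells %in% missing_tokens, n, n)
  values <- suppressWarnings(matrix(as.numeric(cells), n, n))
  bad <- which(is.na(values) & !mask, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("unparseable value at row ", bad[1, 1], ", column ", bad[1, 2],
         ": '", cells[bad[1, 1], bad[1, 2]], "'", call. = FALSE)
  dmask <- which(diag(mask))
  if (length(dmask) > 0)
    stop("missing token on the diagonal at row ", dmask[1],
         " ('", labels[dmask[1]], "'); self-distances must be observed",
         call. = FALSE)
  neg <- which(values < 0 & !mask, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative distance at row ", neg[1, 1], ", column ", neg[1, 2],
         ": ", values[neg[1, 1], neg[1, 2]], call. = FALSE)
  values[mask] <- NA_real_
  diag(values) <- 0
  diag(mask) <- FALSE
  dimnames(values) <- dimnames(mask) <- list(labels, labels)
  list(values = values, mask = mask)
}

#' Write a distance matrix, emitting a sentinel at masked cells
#'
#' @param values numeric square matrix with OTU labels as dimnames.
#' @param mask optional logical matrix; `TRUE` cells are written as
#'   `missing_token`.
#' @param path output file.
#' @param format `"phylip_square"` or `"csv"`.
#' @param missing_token sentinel to emit for masked cells.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(values, mask = NULL, path,
                                  format = c("phylip_square", "csv"),
                                  missing_token = "NA") {
  format <- match.arg(format)
  check_square_matrix(values)
  n <- nrow(values)
  if (is.null(mask)) mask <- matrix(FALSE, n, n)
  if (!identical(dim(mask), dim(values)))
    stop("mask and matrix dimensions differ", call. = FALSE)
  labels <- matrix_labels(values)
  cells <- matrix(sprintf("%.15g", values), n, n)
  cells[mask] <- missing_token
  if (format == "phylip_square") {
    rows <- vapply(seq_len(n), function(i) {
      paste(c(labels[i], cells[i, ]), collapse = " ")
    }, character(1))
    writeLines(c(as.character(n), rows), path)
  } else {
    df <- data.frame(otu = labels, cells, check.names = FALSE)
    colnames(df) <- c("", labels)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Mask a fraction of pairwise distances at random
#'
#' Selects `floor(fraction * N(N-1)/2)` unordered off-diagonal pairs
#' uniformly at random and marks both symmetric cells missing. Pairs whose
#' removal would leave a column without any observed off-diagonal entry are
#' rejected and redrawn, so every OTU keeps at least one known distance.
#'
#' @param values complete symmetric distance matrix.
#' @param fraction fraction of unordered pairs to mask, in (0, 1].
#' @param seed optional integer seed for reproducible masks.
#' @return Logical mask matrix (`TRUE` = missing), symmetric with a
#'   `FALSE` diagonal.
#' @export
inject_missing <- function(values, fraction, seed = NULL) {
  check_square_matrix(values)
  n <- nrow(values)
  if (!is_symmetric_num(values))
    stop("matrix must be complete and symmetric before masking", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  npairs <- n * (n - 1) / 2
  k <- floor(fraction * npairs)
  mask <- matrix(FALSE, n, n, dimnames = dimnames(values))
  if (k == 0) return(mask)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  with_seed(seed, {
    for (attempt in 1:50) {
      ord <- sample.int(nrow(pairs))
      obs <- rep(n - 1L, n)  # observed off-diagonal entries per column
      taken <- integer(0)
      for (p in ord) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        if (obs[i] >= 2L && obs[j] >= 2L) {
          obs[i] <- obs[i] - 1L; obs[j] <- obs[j] - 1L
          taken <- c(taken, p)
          if (length(taken) == k) break
        }
      }
      if (length(taken) == k) {
        for (p in taken) {
          mask[pairs[p, 1], pairs[p, 2]] <- TRUE
          mask[pairs[p, 2], pairs[p, 1]] <- TRUE
        }
        return(mask)
      }
    }
    stop("cannot mask ", k, " pairs of ", npairs,
         " while keeping one observed distance per OTU; ",
         "reduce the missing fraction", call. = FALSE)
  })
}

#' Column-mean initial guess with symmetrisation
#'
#' Fills each missing cell with the mean of the observed off-diagonal
#' entries of its column, then replaces every pair of cells (i,j), (j,i) by
#' their average, so the imputation loop starts from a symmetric matrix.
#' Observed cells of a symmetric input are unchanged.
#'
#' @param values distance matrix (missing cells may hold `NA`).
#' @param mask logical missingness mask.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
initial_guess <- function(values, mask) {
  check_square_matrix(values)
  n <- nrow(values)
  m <- values
  for (c in seq_len(n)) {
    obs <- which(!mask[, c])
    obs <- obs[obs != c]
    if (length(obs) == 0)
      stop("column ", c, " (", matrix_labels(values)[c], ") has no observed ",
           "off-diagonal entry; remove this OTU before imputing",
           call. = FALSE)
    miss <- which(mask[, c])
    if (length(miss) > 0) m[miss, c] <- mean(values[obs, c])
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Imputation order of columns by ascending missing count
#'
#' Columns are visited starting from the one with fewest missing entries;
#' ties go to the lowest index. Fully observed columns are skipped.
#'
#' @param mask logical missingness mask.
#' @return A list with `order` (column indices to impute, possibly empty)
#'   and `missing_counts` (per-column missing-cell counts).
#' @export
column_order <- function(mask) {
  counts <- colSums(mask)
  sel <- which(counts > 0)
  list(order = sel[order(counts[sel], sel)],
       missing_counts = as.integer(counts))
}

#' Normalised squared difference between two matrices
#'
#' The convergence/selection statistic
#' \deqn{\sum_{i,j} (X_{new}[i,j]-X_{old}[i,j])^2 / \sum_{i,j} X_{new}[i,j]^2,}
#' summed over all cells. Zero iff the matrices are identical, and invariant
#' under scaling both matrices by a common factor.
#'
#' @param x_new,x_old numeric matrices of equal shape.
#' @return Nonnegative scalar.
#' @export
set_difference_error <- function(x_new, x_old) {
  if (!identical(dim(x_new), dim(x_old)))
    stop("matrices must share dimensions", call. = FALSE)
  denom <- sum(x_new^2)
  if (denom == 0)
    stop("reference matrix is all zeros; normalised difference undefined",
         call. = FALSE)
  sum((x_new - x_old)^2) / denom
}

# Restore observed input values into a working matrix.
reassert_observed <- function(m, values, mask) {
  keep <- !mask
  diag(keep) <- TRUE
  m[keep] <- values[keep]
  diag(m) <- 0
  m
}
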