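#' Benchmark specification
#'
#' Describes one evaluation campaign: which complete matrix to degrade,
#' which missing-data percentages to test, how many random masks per
#' percentage, how many imputation runs per mask, and which configuration
#' profiles to compare. The defaults mirror the evaluation protocol of
#' 5–60% missing data in steps of 5, 10 masks per percentage and 5 runs
#' per mask; desk-scale studies shrink these counts.
#'
#' @param source complete symmetric distance matrix (labels as dimnames).
#' @param percentages integer percentages of missing pairs to test.
#' @param masks_per_pct number of random masks drawn per percentage.
#' @param runs_per_mask number of imputation runs per mask (runs differ
#'   only through the stochastic components of the imputer).
#' @param profiles named list; each element is an [imputation_config()] or
#'   the string `"baseline"` for the mean-only imputer.
#' @param dataset label recorded in the report rows.
#' @param seed master seed; every mask and run seed derives from it.
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(source,
                           percentages = seq(5, 60, by = 5),
                           masks_per_pct = 10,
                           runs_per_mask = 5,
                           profiles = list(`non-bootstrap` = imputation_config()),
                           dataset = "dataset",
                           seed = 1) {
  check_square_matrix(source)
  if (!is_symmetric_num(source))
    stop("source matrix must be complete and symmetric", call. = FALSE)
  if (masks_per_pct < 1 || runs_per_mask < 1)
    stop("masks_per_pct and runs_per_mask must be >= 1", call. = FALSE)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))
  structure(list(source = source, percentages = as.integer(percentages),
                 masks_per_pct = as.integer(masks_per_pct),
                 runs_per_mask = as.integer(runs_per_mask),
                 profiles = profiles, dataset = dataset,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Run an imputation benchmark
#'
#' For every percentage x mask x run x profile cell: draw a mask (shared
#' across runs and profiles so comparisons are paired), impute, rebuild
#' the NJ tree from the imputed matrix and score it against the ground
#' truth — the NJ tree of the original complete matrix — with the
#' normalised Robinson-Foulds distance. Failed runs are recorded with an
#' error message, never dropped silently. Fully reproducible under the
#' spec's seed.
#'
#' @param spec a [benchmark_spec()].
#' @return An object of class `phylimp_benchmark`: list with `rows` (one
#'   data.frame row per run: dataset, pct_missing, mask_id, run_id,
#'   profile, rf, nrf_pct, ls, me, iterations, wall_time, error),
#'   `aggregates` (mean/min/max/sd of NRF per profile and percentage),
#'   `truth_tree` and `spec`.
#' @export
run_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  truth <- nj_tree(spec$source)
  n <- nrow(spec$source)
  rows <- list()
  for (pct in spec$percentages) {
    for (m in seq_len(spec$masks_per_pct)) {
      mask <- inject_missing(spec$source, pct / 100,
                             seed = derive_seed(spec$seed, pct, m))
      masked <- spec$source
      masked[mask] <- NA_real_
      for (r in seq_len(spec$runs_per_mask)) {
        run_seed <- derive_seed(spec$seed, pct, m, r)
        for (p in names(spec$profiles)) {
          prof <- spec$profiles[[p]]
          t0 <- proc.time()[["elapsed"]]
          res <- tryCatch({
            fit <- if (identical(prof, "baseline")) {
              impute_mean_baseline(masked, mask)
            } else {
              impute_distances(masked, mask, prof, seed = run_seed)
            }
            tree <- nj_tree(fit$imputed)
            rf <- rf_distance(tree, truth)
            data.frame(dataset = spec$dataset, pct_missing = pct,
                       mask_id = m, run_id = r, profile = p,
                       rf = rf, nrf_pct = 100 * nrf(rf, n),
                       ls = ls_score(fit$imputed, tree),
                       me = me_score(tree),
                       iterations = fit$iterations,
                       wall_time = proc.time()[["elapsed"]] - t0,
                       error = NA_character_)
          }, error = function(e) {
            data.frame(dataset = spec$dataset, pct_missing = pct,
                       mask_id = m, run_id = r, profile = p,
                       rf = NA_integer_, nrf_pct = NA_real_,
                       ls = NA_real_, me = NA_real_,
                       iterations = NA_integer_,
                       wall_time = proc.time()[["elapsed"]] - t0,
                       error = conditionMessage(e))
          })
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  rows <- do.call(rbind, rows)
  ok <- rows[is.na(rows$error), ]
  aggregates <- do.call(rbind, lapply(
    split(ok, list(ok$profile, ok$pct_missing), drop = TRUE),
    function(g) data.frame(dataset = g$dataset[1], profile = g$profile[1],
                           pct_missing = g$pct_missing[1],
                           mean_nrf = mean(g$nrf_pct),
                           min_nrf = min(g$nrf_pct),
                           max_nrf = max(g$nrf_pct),
                           sd_nrf = stats::sd(g$nrf_pct),
                           n_runs = nrow(g))))
  aggregates <- aggregates[order(aggregates$profile, aggregates$pct_missing), ]
  rownames(aggregates) <- NULL
  structure(list(rows = rows, aggregates = aggregates,
                 truth_tree = truth, spec = spec),
            class = "phylimp_benchmark")
}

#' Accumulated NRF over a benchmark grid
#'
#' Sums the per-cell mean NRF percentages over all (dataset, percentage)
#' cells of a benchmark report, the headline number for comparing
#' configurations across a whole grid. Errors if any requested cell has no
#' successful runs.
#'
#' @param rows per-run rows of a [run_benchmark()] report (or the report
#'   itself), possibly covering several datasets.
#' @param profile which profile to accumulate; defaults to the only one.
#' @param datasets,percentages the grid to cover; default: everything in
#'   `rows`.
#' @return Scalar accumulated NRF (percentage points).
#' @export
accumulate_nrf <- function(rows, profile = NULL, datasets = NULL,
                           percentages = NULL) {
  if (inherits(rows, "phylimp_benchmark")) rows <- rows$rows
  rows <- rows[is.na(rows$error), ]
  if (is.null(profile)) {
    profile <- unique(rows$profile)
    if (length(profile) > 1)
      stop("several profiles present; pick one with `profile=`",
           call. = FALSE)
  }
  rows <- rows[rows$profile == profile, ]
  datasets <- datasets %||% unique(rows$dataset)
  percentages <- percentages %||% sort(unique(rows$pct_missing))
  if (nrow(rows) == 0) stop("no rows to accumulate", call. = FALSE)
  total <- 0
  missing_cells <- character(0)
  for (d in datasets) {
    for (pct in percentages) {
      cell <- rows[rows$dataset == d & rows$pct_missing == pct, ]
      if (nrow(cell) == 0) {
        missing_cells <- c(missing_cells, paste0(d, "@", pct, "%"))
      } else {
        total <- total + mean(cell$nrf_pct)
      }
    }
  }
  if (length(missing_cells) > 0)
    stop("grid cells without runs: ", paste(missing_cells, collapse = ", "),
         call. = FALSE)
  total
}

#' @export
print.phylimp_benchmark <- function(x, ...) {
  cat(sprintf("Imputation benchmark: %s (%d OTUs), %d runs\n",
              x$spec$dataset, nrow(x$spec$source), nrow(x$rows)))
  print(x$aggregates, digits = 3)
  invisible(x)
}
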