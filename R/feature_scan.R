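# Stage-2 selection: evaluate the binary diagnosis model over an increasing
# feature-count grid under stratified k-fold cross-validation and pick the
# minimal count whose fold-averaged primary metric is within a tolerance of
# the best over the grid ("minimum number of CpG sites needed to achieve
# optimal results"). Fold assignment is fixed across all counts so the grid
# points are compared on identical splits.

#' Build a feature-count grid
#'
#' All multiples `start, start + step, ...` up to `total`, with `total`
#' appended when it is not already the last element (so the final grid point
#' always equals the full ranked feature count).
#'
#' @param start First count (`0 < start <= total`).
#' @param step Increment (> 0).
#' @param total Total available ranked features.
#' @return Strictly increasing integer vector ending in `total`.
#' @export
make_grid <- function(start, step, total) {
  start <- assert_count(start, "start")
  step <- assert_count(step, "step")
  total <- assert_count(total, "total")
  if (start > total) stopf("`start` (%d) exceeds `total` (%d)", start, total)
  g <- seq.int(start, total, by = step)
  if (g[length(g)] != total) g <- c(g, total)
  as.integer(g)
}

#' Cross-validated feature-count scan of the binary diagnosis model
#'
#' For each count `n` in the grid, takes the top-`n` probes of the
#' importance ranking, runs stratified k-fold cross-validation of the
#' multi-scale CNN (a fresh model per `(n, fold)`, seeded), and records
#' per-fold and fold-averaged accuracy/precision/recall/MCC/F1.
#'
#' @param beta Beta matrix (samples x probes).
#' @param y Binary labels.
#' @param ranking An `importance_ranking` (typically from
#'   [filter_nonzero()]); probes are consumed in ranking order.
#' @param grid Feature-count grid from [make_grid()]; its maximum must not
#'   exceed the ranking length.
#' @param k_folds Number of stratified folds (default 5).
#' @param cfg [msdcnn_config()] used for every fit.
#' @param primary_metric Metric driving [select_count()] (default `"mcc"`).
#' @param tol Selection tolerance (default 0.005).
#' @param seed Integer seed fixing folds and per-fit seeds.
#' @return A `scan_result`: `grid`, `per_count` (per-fold and averaged
#'   metrics for each count), `summary` (one row per count), and
#'   `selected_count`.
#' @export
scan_features <- function(beta, y, ranking, grid, k_folds = 5L,
                          cfg = msdcnn_config(), primary_metric = "mcc",
                          tol = 0.005, seed = 1L) {
  stopifnot(inherits(ranking, "importance_ranking"))
  grid <- as.integer(grid)
  if (any(diff(grid) <= 0L)) stopf("grid must be strictly increasing")
  if (max(grid) > nrow(ranking)) {
    stopf("grid maximum %d exceeds ranking length %d", max(grid),
          nrow(ranking))
  }
  k_folds <- assert_count(k_folds, "k_folds", min = 2L)
  y <- as.integer(y)
  fold <- stratified_folds(y, k_folds, seed = derive_seed(seed, "folds"))
  per_count <- list()
  for (n in grid) {
    cpgs <- ranking$cpg_id[seq_len(n)]
    X <- beta[, cpgs, drop = FALSE]
    rows <- vector("list", k_folds)
    for (k in seq_len(k_folds)) {
      tr <- which(fold != k)
      te <- which(fold == k)
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) {
        stopf("fold %d is missing a class", k)
      }
      fit_cfg <- cfg
      fit_cfg$seed <- derive_seed(seed, sprintf("fit-%d-%d", n, k))
      model <- build_msdcnn(n, fit_cfg)
      model <- train_binary(model, X[tr, , drop = FALSE], y[tr])
      m <- binary_metrics(confusion(y[te], diagnose(model,
                                                    X[te, , drop = FALSE])))
      rows[[k]] <- data.frame(fold = k, t(unclass(m)))
    }
    folds_df <- do.call(rbind, rows)
    avg <- colMeans(folds_df[, -1L, drop = FALSE])
    per_count[[as.character(n)]] <- list(folds = folds_df, avg = avg)
  }
  summary <- data.frame(
    n_features = grid,
    do.call(rbind, lapply(per_count, `[[`, "avg")), row.names = NULL)
  out <- structure(list(grid = grid, per_count = per_count,
                        summary = summary, k_folds = k_folds,
                        primary_metric = primary_metric,
                        selection_tolerance = tol, selected_count = NA_integer_),
                   class = "scan_result")
  out$selected_count <- select_count(out, primary_metric, tol)
  out
}

#' Minimal feature count achieving near-optimal performance
#'
#' Returns the smallest grid count whose fold-averaged `primary_metric` is
#' within `tol` of the grid maximum.
#'
#' @param scan A `scan_result` from [scan_features()].
#' @param primary_metric Metric column (default the scan's, `"mcc"`).
#' @param tol Tolerance below the maximum still counted as optimal.
#' @return Integer count, an element of the scan grid.
#' @export
select_count <- function(scan, primary_metric = NULL, tol = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  if (is.null(primary_metric)) primary_metric <- scan$primary_metric
  if (is.null(tol)) tol <- scan$selection_tolerance
  vals <- scan$summary[[primary_metric]]
  if (is.null(vals)) stopf("unknown metric '%s'", primary_metric)
  ok <- vals >= max(vals) - tol
  scan$grid[which(ok)[1L]]
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d counts (%d..%d), %d-fold CV, selected %d by %s (tol %g)\n",
              length(x$grid), min(x$grid), max(x$grid), x$k_folds,
              x$selected_count, x$primary_metric, x$selection_tolerance))
  print(x$summary, digits = 4)
  invisible(x)
}
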