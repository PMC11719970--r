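# Stage-1 screen: a randomized-tree ensemble on the binary task yields
# per-probe importances (normalized impurity decrease); probes with exactly
# zero importance are dropped and the rest ranked in descending order.

#' Fit tree-ensemble importances for every CpG probe
#'
#' Trains a seeded ensemble of randomized decision trees (bootstrap samples,
#' `mtry` candidate probes per split, Gini impurity) on the binary labels
#' and returns every probe with its normalized total-impurity-decrease
#' importance, ranked descending. Probes the ensemble never splits on get an
#' importance of exactly 0; importances over the full fit sum to 1.
#'
#' @param beta Beta matrix (samples x probes).
#' @param y Binary labels (0/1), one per sample; both classes required.
#' @param n_trees Ensemble size (default 500).
#' @param mtry Candidate probes per split; default `floor(sqrt(p))`.
#' @param min_node Minimum samples per leaf (default 1).
#' @param seed Integer seed (ensemble is deterministic under a fixed seed).
#' @return An `importance_ranking`: data.frame of `cpg_id`, `importance`
#'   sorted by decreasing importance (ties broken by `cpg_id`), with
#'   attribute `n_input` (probe count of the fit).
#' @export
fit_importances <- function(beta, y, n_trees = 500L, mtry = NULL,
                            min_node = 1L, seed = 1L) {
  y <- as.integer(y)
  if (length(y) != nrow(beta)) stopf("labels/sample count mismatch")
  if (!all(y %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  if (min(table(y)) < 2L) stopf("need at least 2 samples per class")
  p <- ncol(beta)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  fit <- rf_fit_cpp(unname(beta), y, 2L, as.integer(n_trees),
                    as.integer(mtry), as.integer(min_node), as.integer(seed))
  ranking <- data.frame(cpg_id = colnames(beta),
                        importance = as.numeric(fit$importance),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$importance, ranking$cpg_id), ]
  rownames(ranking) <- NULL
  attr(ranking, "n_input") <- p
  class(ranking) <- c("importance_ranking", "data.frame")
  ranking
}

#' Drop zero-importance probes from a ranking
#'
#' Removes entries with importance exactly 0 (impurity importances are
#' exactly zero for probes never split on), preserving order. Idempotent.
#'
#' @param ranking An `importance_ranking`.
#' @return The filtered ranking; `n_input` records the original probe count.
#' @export
filter_nonzero <- function(ranking) {
  stopifnot(inherits(ranking, "importance_ranking"))
  keep <- ranking$importance != 0
  if (!any(keep)) stopf("all importances are zero; nothing survives the filter")
  out <- ranking[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- attr(ranking, "n_input")
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Refit the ensemble on a probe subset and report held-out metrics
#'
#' Used to compare the full probe set against the nonzero-importance subset:
#' the ensemble is refit on the given probes and evaluated on held-out data,
#' either a stratified split or stratified k-fold cross-validation.
#'
#' @param beta Beta matrix.
#' @param y Binary labels.
#' @param cpgs Probe subset (must be columns of `beta`).
#' @param method `"split"` (stratified holdout) or `"cv"`.
#' @param test_fraction Holdout fraction for `method = "split"`.
#' @param k_folds Folds for `method = "cv"`.
#' @param n_trees,mtry,min_node Ensemble settings, as in
#'   [fit_importances()].
#' @param seed Integer seed.
#' @return Named metric vector as from [binary_metrics()] (averaged over
#'   folds for `method = "cv"`).
#' @export
evaluate_subset <- function(beta, y, cpgs, method = c("split", "cv"),
                            test_fraction = 0.2, k_folds = 5L,
                            n_trees = 500L, mtry = NULL, min_node = 1L,
                            seed = 1L) {
  method <- match.arg(method)
  if (length(cpgs) == 0L) stopf("empty probe subset")
  miss <- setdiff(cpgs, colnames(beta))
  if (length(miss) > 0L) stopf("probe '%s' not in the matrix", miss[1L])
  X <- beta[, cpgs, drop = FALSE]
  y <- as.integer(y)
  fit_and_score <- function(tr, te) {
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
    fit <- rf_fit_cpp(unname(X[tr, , drop = FALSE]), y[tr], 2L,
                      as.integer(n_trees), as.integer(mtry),
                      as.integer(min_node), as.integer(derive_seed(seed, "fit")))
    pred <- rf_predict_cpp(fit$forest, unname(X[te, , drop = FALSE]), 2L)
    binary_metrics(confusion(y[te], pred))
  }
  if (method == "split") {
    sp <- stratified_split(y, train_fraction = 1 - test_fraction, seed = seed)
    fit_and_score(sp$train, sp$test)
  } else {
    fold <- stratified_folds(y, k_folds, seed = seed)
    rows <- lapply(seq_len(k_folds), function(k) {
      fit_and_score(which(fold != k), which(fold == k))
    })
    out <- colMeans(do.call(rbind, rows))
    attr(out, "degenerate") <- unique(unlist(lapply(rows, attr, "degenerate")))
    out
  }
}
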