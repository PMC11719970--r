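# Shared fixtures. Heavy fixtures (trained networks) are computed lazily and
# cached for the session so several tests can share one training run.

.fixtures <- new.env(parent = emptyenv())

# Small, fast MSDCNN settings used where the test target is plumbing rather
# than accuracy.
fast_msdcnn_cfg <- function(epochs = 8L, seed = 1L, padding = "same") {
  msdcnn_config(filters_per_block = c(4L, 8L), dense_units = 16L,
                epochs = epochs, patience = 2L, padding = padding,
                seed = seed)
}

fast_resdegnet_cfg <- function(epochs = 30L, seed = 1L) {
  resdegnet_config(block_channels = c(8L, 16L, 32L), epochs = epochs,
                   seed = seed)
}

# Separable four-class cohort + 8:2 split + trained residual model, shared
# by the clustering-recovery and classifier acceptance tests.
multiclass_fixture <- function() {
  if (!is.null(.fixtures$multiclass)) return(.fixtures$multiclass)
  cohort <- generate_multiclass_cohort(cohort_config(
    n_samples_per_class = 100L, n_cpgs = 200L,
    n_informative_per_class = 15L, effect_delta = 0.4, precision = 50,
    age_slope_sd = 0, seed = 21L))
  split <- stratified_split(cohort$labels, 0.8, seed = 5L)
  model <- build_resdegnet(ncol(cohort$beta), fast_resdegnet_cfg(seed = 13L))
  model <- train_multiclass(model, cohort$beta[split$train, , drop = FALSE],
                            cohort$labels[split$train])
  .fixtures$multiclass <- list(cohort = cohort, split = split, model = model)
  .fixtures$multiclass
}

# Two 5-cliques (unit weights) joined by one weak edge: the canonical
# fixture whose optimal partition is known by exhaustive search.
two_clique_graph <- function() {
  edges <- NULL
  for (g in 0:1) {
    for (i in 1:4) {
      for (j in (i + 1):5) edges <- rbind(edges, c(g * 5 + i, g * 5 + j, 1))
    }
  }
  edges <- rbind(edges, c(1, 6, 0.1))
  igraph::graph_from_data_frame(
    data.frame(from = paste0("n", edges[, 1]), to = paste0("n", edges[, 2]),
               weight = edges[, 3]),
    directed = FALSE)
}

# Independent brute-force binary metrics used as the oracle against
# binary_metrics(); written from the definitions, not the package code.
oracle_binary_metrics <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1); fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0); tn <- sum(y_true == 0 & y_pred == 0)
  n <- tp + fp + fn + tn
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(accuracy = (tp + tn) / n, precision = prec, recall = rec, f1 = f1,
    mcc = mcc)
}

# Exhaustive TPR - FPR maximisation over every threshold at which the
# piecewise-constant ROC can change, plus sentinels.
oracle_best_j <- function(scores, y_true) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  best <- -Inf
  for (thr in cand) {
    pred <- scores > thr
    j <- sum(pred & y_true == 1) / sum(y_true == 1) -
      sum(pred & y_true == 0) / sum(y_true == 0)
    if (j > best) best <- j
  }
  best
}
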