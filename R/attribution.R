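# Per-CpG, per-class Shapley attribution of the model's predicted class
# probabilities, estimated by permutation sampling: along each sampled
# feature ordering, features are switched one at a time from the baseline
# vector to the sample's actual values and the marginal change in every
# class probability is credited to the switched feature. Estimates satisfy
# additivity (per sample and class the attributions sum to
# f(x) - f(baseline)) up to Monte-Carlo error. An exact coalition-
# enumeration mode exists for <= 12 features and serves as the test oracle's
# counterpart.

predict_fun_for <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "resdegnet_model")) {
    return(function(X) predict_proba(model, X))
  }
  if (inherits(model, "msdcnn_model")) {
    return(function(X) matrix(predict_scores(model, X), ncol = 1L,
                              dimnames = list(NULL, "disease")))
  }
  stopf("unsupported model type for attribution")
}

#' Permutation-sampling Shapley attributions
#'
#' @param model A trained `resdegnet_model`, `msdcnn_model`, or a function
#'   mapping a (rows x features) matrix to a (rows x classes) output matrix.
#' @param X Input matrix (samples x features) to attribute.
#' @param baseline Reference input vector of model width; default the
#'   feature-wise mean of `X`.
#' @param n_permutations Sampled feature orderings per sample (default 128).
#' @param seed Integer seed.
#' @param exact If `TRUE` (features <= 12), compute exact Shapley values by
#'   enumerating all coalitions instead of sampling.
#' @return Array samples x features x classes of attributions, with
#'   attributes `baseline`, `n_permutations`, `seed`.
#' @export
shapley_attributions <- function(model, X, baseline = NULL,
                                 n_permutations = 128L, seed = 1L,
                                 exact = FALSE) {
  f <- predict_fun_for(model)
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(baseline)) baseline <- colMeans(X)
  if (length(baseline) != p) stopf("baseline width %d does not match %d features",
                                   length(baseline), p)
  if (!exact) {
    n_permutations <- assert_count(n_permutations, "n_permutations")
  } else if (p > 12L) {
    stopf("exact enumeration is limited to 12 features (got %d)", p)
  }
  probe_out <- f(matrix(baseline, 1L, p, dimnames = list(NULL, colnames(X))))
  n_class <- ncol(probe_out)
  class_names <- colnames(probe_out)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_class))
  n <- nrow(X)
  out <- array(0, dim = c(n, p, n_class),
               dimnames = list(rownames(X), colnames(X), class_names))

  if (exact) {
    # all 2^p coalitions; weight |S|! (p-|S|-1)! / p!
    subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
    sizes <- rowSums(subsets)
    lw <- lgamma(sizes + 1) + lgamma(p - sizes) - lgamma(p + 1)
    for (i in seq_len(n)) {
      Z <- matrix(baseline, nrow(subsets), p, byrow = TRUE)
      for (j in seq_len(p)) Z[subsets[, j], j] <- X[i, j]
      colnames(Z) <- colnames(X)
      V <- f(Z)
      for (j in seq_len(p)) {
        without <- which(!subsets[, j])
        # index of S union {j}: flipping bit j adds 2^(j-1) rows in expand.grid order
        with_j <- without + 2^(j - 1L)
        wts <- exp(lw[without])  # |S|! (p-|S|-1)! / p! with S = coalition without j
        contrib <- (V[with_j, , drop = FALSE] - V[without, , drop = FALSE]) * wts
        out[i, j, ] <- colSums(contrib)
      }
    }
  } else {
    rng_seed <- derive_seed(seed, "shapley")
    with_seed(rng_seed, {
      for (i in seq_len(n)) {
        phi <- matrix(0, p, n_class)
        for (r in seq_len(n_permutations)) {
          perm <- sample.int(p)
          Z <- matrix(baseline, p + 1L, p, byrow = TRUE)
          for (j in seq_len(p)) {
            Z[(j + 1L):(p + 1L), perm[j]] <- X[i, perm[j]]
          }
          colnames(Z) <- colnames(X)
          V <- f(Z)
          dV <- V[-1L, , drop = FALSE] - V[-(p + 1L), , drop = FALSE]
          phi[perm, ] <- phi[perm, ] + dV
        }
        out[i, , ] <- phi / n_permutations
      }
    })
  }
  attr(out, "baseline") <- baseline
  attr(out, "n_permutations") <- if (exact) NA_integer_ else n_permutations
  attr(out, "seed") <- seed
  out
}

#' Mean attribution over samples
#'
#' Arithmetic mean of per-sample attributions, per feature and class — the
#' data behind the attribution heatmap.
#'
#' @param attributions Array from [shapley_attributions()].
#' @return An `attribution_matrix`: features x classes numeric matrix with
#'   the estimator attributes carried over.
#' @export
mean_attribution <- function(attributions) {
  if (length(dim(attributions)) != 3L) stopf("expected a samples x features x classes array")
  if (dim(attributions)[1L] < 1L) stopf("need at least one sample")
  m <- apply(attributions, c(2L, 3L), mean)
  structure(m, class = c("attribution_matrix", class(m)),
            baseline = attr(attributions, "baseline"),
            n_permutations = attr(attributions, "n_permutations"),
            seed = attr(attributions, "seed"))
}

#' Export a mean-attribution table
#'
#' Writes a TSV with one row per CpG: the per-class mean attribution plus a
#' per-class rank column (1 = largest attribution). Values are rounded to 6
#' decimals and round-trip losslessly at that precision.
#'
#' @param m An `attribution_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_heatmap_table <- function(m, path) {
  if (!inherits(m, "attribution_matrix")) stopf("expected an attribution_matrix")
  vals <- round(unclass(m), 6L)
  ranks <- apply(-vals, 2L, rank, ties.method = "first")
  colnames(ranks) <- paste0("rank_", colnames(vals))
  out <- data.table::data.table(cpg_id = rownames(vals))
  out <- cbind(out, data.table::as.data.table(vals),
               data.table::as.data.table(ranks))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
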