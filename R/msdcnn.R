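# Multi-scale 1D CNN for binary healthy/disease diagnosis: three parallel
# branches with kernel sizes 3, 5, 7, each built from repeated
# [conv -> conv -> pool] blocks with ReLU on every convolution; branch
# outputs are flattened and concatenated, passed through a dense hidden
# layer and a single sigmoid output unit. Trained with Adam on binary
# cross-entropy; the decision threshold is picked on a validation split by
# maximizing TPR - FPR.

#' Configuration for the multi-scale binary diagnosis model
#'
#' @param kernel_sizes Kernel size per branch (default the three scales
#'   3, 5, 7; must be odd).
#' @param blocks_per_branch conv-conv-pool repetitions per branch.
#' @param filters_per_block Filters for both convolutions of each block;
#'   length `blocks_per_branch`.
#' @param pool_kind `"max"` or `"average"` pooling after every two
#'   convolutions.
#' @param pool_size Pooling window (and stride).
#' @param dense_units Hidden dense layer width.
#' @param padding Convolution padding, `"valid"` (default) or `"same"`.
#' @param learning_rate,batch_size,epochs Adam optimisation settings.
#' @param patience Early-stopping patience on validation loss (0 disables).
#' @param validation_fraction Fraction of the training samples held out
#'   (stratified) for early stopping and threshold selection.
#' @param seed Integer seed for initialisation, splits and shuffling.
#' @return Configuration of class `msdcnn_config`.
#' @export
msdcnn_config <- function(kernel_sizes = c(3L, 5L, 7L),
                          blocks_per_branch = 2L,
                          filters_per_block = c(32L, 64L),
                          pool_kind = c("max", "average"),
                          pool_size = 2L,
                          dense_units = 64L,
                          padding = c("valid", "same"),
                          learning_rate = 1e-3,
                          batch_size = 32L,
                          epochs = 50L,
                          patience = 5L,
                          validation_fraction = 0.2,
                          seed = 1L) {
  pool_kind <- match.arg(pool_kind)
  padding <- match.arg(padding)
  if (any(kernel_sizes %% 2L == 0L)) stopf("kernel sizes must be odd")
  blocks_per_branch <- assert_count(blocks_per_branch, "blocks_per_branch")
  if (length(filters_per_block) != blocks_per_branch) {
    stopf("`filters_per_block` must have one entry per block")
  }
  if (any(filters_per_block < 1L)) stopf("filters must be strictly positive")
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 blocks_per_branch = blocks_per_branch,
                 filters_per_block = as.integer(filters_per_block),
                 pool_kind = pool_kind, pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units), padding = padding,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "msdcnn_config")
}

msdcnn_net <- function(cfg) {
  branch <- function(k) {
    layers <- list()
    for (b in seq_len(cfg$blocks_per_branch)) {
      f <- cfg$filters_per_block[b]
      layers <- c(layers,
                  list(nn_conv(k, f, pad = cfg$padding),
                       nn_conv(k, f, pad = cfg$padding),
                       nn_pool(cfg$pool_size, cfg$pool_kind)))
    }
    c(layers, list(nn_flatten()))
  }
  list(nn_branches(lapply(cfg$kernel_sizes, branch)),
       nn_dense(cfg$dense_units, act = "relu"),
       nn_dense(1L, act = "linear"))
}

#' Build an (untrained) multi-scale binary diagnosis model
#'
#' @param n_features Input width: number of CpG probes the model consumes.
#'   Must be large enough for every branch's convolution/pooling stack.
#' @param cfg An [msdcnn_config()].
#' @return Model object of class `msdcnn_model`.
#' @export
build_msdcnn <- function(n_features, cfg = msdcnn_config()) {
  n_features <- assert_count(n_features, "n_features")
  stopifnot(inherits(cfg, "msdcnn_config"))
  net <- msdcnn_net(cfg)
  init <- with_seed(cfg$seed, nn_init(net, c(n_features, 1L)))
  structure(list(net = net, params = init$params, n_features = n_features,
                 cfg = cfg, history = NULL, threshold = NULL,
                 trained = FALSE),
            class = "msdcnn_model")
}

#' @export
print.msdcnn_model <- function(x, ...) {
  cat(sprintf("msdcnn_model: %d input CpGs, branches k = %s, %strained\n",
              x$n_features, paste(x$cfg$kernel_sizes, collapse = "/"),
              if (x$trained) "" else "un"))
  if (!is.null(x$threshold)) {
    cat(sprintf("  threshold %.4f (J = %.4f)\n", x$threshold$threshold,
                x$threshold$j))
  }
  invisible(x)
}

check_width <- function(model, beta) {
  if (ncol(beta) != model$n_features) {
    stopf("input has %d probes but the model expects %d", ncol(beta),
          model$n_features)
  }
}

#' Train the binary diagnosis model
#'
#' Minimises binary cross-entropy with Adam. A stratified validation split
#' (`validation_fraction` of the training samples) drives early stopping
#' and the TPR - FPR threshold selection; the test split must never be used
#' here.
#'
#' @param model An untrained or trained `msdcnn_model`.
#' @param beta Beta matrix (samples x probes), probe order fixed.
#' @param y Binary labels (0 = healthy, 1 = disease), one per sample.
#' @return The trained model with `history` and `threshold` filled in.
#' @export
train_binary <- function(model, beta, y) {
  stopifnot(inherits(model, "msdcnn_model"))
  check_width(model, beta)
  y <- as.integer(y)
  if (length(y) != nrow(beta)) stopf("labels/sample count mismatch")
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  cfg <- model$cfg
  vf <- cfg$validation_fraction
  if (vf > 0) {
    sp <- stratified_split(y, train_fraction = 1 - vf,
                           seed = derive_seed(cfg$seed, "val-split"))
    tr_idx <- sp$train
    val_idx <- sp$test
  } else {
    tr_idx <- seq_len(nrow(beta))
    val_idx <- integer(0)
  }
  val <- if (length(val_idx) > 0L) {
    list(X = beta[val_idx, , drop = FALSE], target = y[val_idx])
  }
  fit <- with_seed(derive_seed(cfg$seed, "train"), {
    nn_train(model$net, model$params, beta[tr_idx, , drop = FALSE],
             y[tr_idx], loss = "bce", lr = cfg$learning_rate,
             epochs = cfg$epochs, batch_size = cfg$batch_size, val = val,
             patience = cfg$patience)
  })
  model$params <- fit$params
  model$history <- fit$history
  model$trained <- TRUE
  thr_idx <- if (length(val_idx) > 0L && length(unique(y[val_idx])) == 2L) {
    val_idx
  } else {
    tr_idx
  }
  model$threshold <- roc_and_threshold(predict_scores(model,
                                                      beta[thr_idx, ,
                                                           drop = FALSE]),
                                       y[thr_idx])
  model
}

#' Per-sample disease scores from the sigmoid head
#'
#' Deterministic at inference; scores lie in the open interval (0, 1).
#'
#' @param model A `msdcnn_model`.
#' @param beta Beta matrix with the model's probe width.
#' @return Numeric vector of scores, named by sample id when available.
#' @export
predict_scores <- function(model, beta) {
  stopifnot(inherits(model, "msdcnn_model"))
  check_width(model, beta)
  z <- nn_logits(model$net, model$params, beta)
  s <- pmin(pmax(sigmoid(as.numeric(z)), 1e-12), 1 - 1e-12)
  names(s) <- rownames(beta)
  s
}

#' Thresholded binary diagnosis
#'
#' Predicts 1 exactly when the score strictly exceeds the threshold (a
#' score equal to the threshold yields 0).
#'
#' @param model A trained `msdcnn_model`.
#' @param beta Beta matrix.
#' @param threshold Optional threshold (numeric, or a result of
#'   [roc_and_threshold()]); defaults to the model's validation-selected one.
#' @return Integer vector of 0/1 predictions.
#' @export
diagnose <- function(model, beta, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$threshold
  if (is.list(threshold)) threshold <- threshold$threshold
  if (is.null(threshold)) stopf("no threshold available; train the model first")
  scores <- predict_scores(model, beta)
  structure(as.integer(scores > threshold), names = names(scores))
}
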