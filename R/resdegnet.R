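# Residual four-class prediction network: 1D conv stem -> max pool -> three
# residual blocks (2, 3 and 3 convolutions; channels increasing; strided
# convolutions shrink the sequence in blocks 2 and 3, with a 1x1 strided
# linear projection on the skip path whenever shape changes) -> global
# average pooling -> dense softmax over the four classes. Trained with Adam
# on categorical cross-entropy; stratified 5-fold CV on the training split
# produces the per-fold report, then a final fit on the full split. The GAP
# activations serve as per-sample embeddings for clustering.

#' Configuration for the residual multi-class model
#'
#' @param stem_filters,stem_kernel Stem convolution width and kernel.
#' @param pool_size Max-pool window after the stem.
#' @param block_channels Channels of the three residual blocks
#'   (non-decreasing).
#' @param block_strides List of per-convolution strides for the three
#'   blocks; lengths fix the convolution counts (2, 3, 3).
#' @param kernel_size Kernel size inside residual blocks.
#' @param learning_rate,batch_size,epochs Adam settings.
#' @param validation_fraction,patience Early-stopping settings for the final
#'   fit (0 disables).
#' @param seed Integer seed.
#' @return Configuration of class `resdegnet_config`.
#' @export
resdegnet_config <- function(stem_filters = 32L, stem_kernel = 7L,
                             pool_size = 2L,
                             block_channels = c(32L, 64L, 128L),
                             block_strides = list(c(1L, 1L), c(2L, 1L, 1L),
                                                  c(2L, 1L, 1L)),
                             kernel_size = 3L,
                             learning_rate = 1e-3, batch_size = 32L,
                             epochs = 60L, validation_fraction = 0,
                             patience = 0L, seed = 1L) {
  if (length(block_channels) != 3L) stopf("need three residual block channel counts")
  if (any(diff(block_channels) < 0L)) {
    stopf("block channels must be non-decreasing")
  }
  if (length(block_strides) != 3L ||
      !identical(lengths(block_strides), c(2L, 3L, 3L))) {
    stopf("block 1 has 2 convolutions and blocks 2-3 have 3 each; `block_strides` lengths must be (2, 3, 3)")
  }
  structure(list(stem_filters = as.integer(stem_filters),
                 stem_kernel = as.integer(stem_kernel),
                 pool_size = as.integer(pool_size),
                 block_channels = as.integer(block_channels),
                 block_strides = lapply(block_strides, as.integer),
                 kernel_size = as.integer(kernel_size),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "resdegnet_config")
}

resdegnet_nets <- function(cfg) {
  features <- list(nn_conv(cfg$stem_kernel, cfg$stem_filters, pad = "same"),
                   nn_pool(cfg$pool_size, "max"))
  for (b in 1:3) {
    features <- c(features, list(nn_resblock(cfg$block_channels[b],
                                             cfg$kernel_size,
                                             cfg$block_strides[[b]])))
  }
  features <- c(features, list(nn_gap()))
  list(features = features, head = list(nn_dense(4L, act = "linear")))
}

#' Build an (untrained) residual multi-class model
#'
#' @param n_features Input width (number of biomarker CpGs); must survive
#'   the configured pooling and stride reductions.
#' @param cfg A [resdegnet_config()].
#' @return Model object of class `resdegnet_model` with the fixed class
#'   order of [degenerative_classes()].
#' @export
build_resdegnet <- function(n_features, cfg = resdegnet_config()) {
  n_features <- assert_count(n_features, "n_features")
  stopifnot(inherits(cfg, "resdegnet_config"))
  nets <- resdegnet_nets(cfg)
  init <- with_seed(cfg$seed, {
    f <- nn_init(nets$features, c(n_features, 1L))
    h <- nn_init(nets$head, f$shape)
    list(features = f, head = h)
  })
  structure(list(nets = nets,
                 params = list(features = init$features$params,
                               head = init$head$params),
                 embedding_dim = init$features$shape,
                 n_features = n_features, cfg = cfg,
                 classes = degenerative_classes(),
                 history = NULL, cv_report = NULL, trained = FALSE),
            class = "resdegnet_model")
}

#' @export
print.resdegnet_model <- function(x, ...) {
  cat(sprintf("resdegnet_model: %d input CpGs -> %d-d GAP embedding -> 4 classes, %strained\n",
              x$n_features, x$embedding_dim, if (x$trained) "" else "un"))
  if (!is.null(x$cv_report)) print(x$cv_report, digits = 4)
  invisible(x)
}

resdeg_full_net <- function(model) c(model$nets$features, model$nets$head)
resdeg_full_params <- function(model) c(model$params$features,
                                        model$params$head)

to_class_factor <- function(y, classes) {
  y <- as.character(y)
  if (all(y %in% onehot_codes())) y <- decode_onehot(y)
  bad <- setdiff(unique(y), classes)
  if (length(bad) > 0L) stopf("unknown class label '%s'", bad[1L])
  factor(y, levels = classes)
}

onehot_matrix <- function(f) {
  Y <- matrix(0, length(f), nlevels(f))
  Y[cbind(seq_along(f), as.integer(f))] <- 1
  Y
}

#' Train the multi-class model with cross-validated reporting
#'
#' Runs stratified `k_folds`-fold cross-validation on the supplied training
#' split (fresh seeded model per fold) to produce the per-fold
#' accuracy/precision/recall/F1 report with its `Avg` row, then fits a
#' final model on the whole split.
#'
#' @param model A `resdegnet_model`.
#' @param beta Training beta matrix (samples x biomarker probes).
#' @param y Class labels (names, or one-hot strings).
#' @param k_folds CV folds (default 5).
#' @return The trained model with `cv_report` and `history` filled in.
#' @export
train_multiclass <- function(model, beta, y, k_folds = 5L) {
  stopifnot(inherits(model, "resdegnet_model"))
  check_width(model, beta)
  f <- to_class_factor(y, model$classes)
  if (nlevels(droplevels(f)) < 4L) stopf("all four classes must be present")
  counts <- table(f)
  if (max(counts) > 2 * min(counts)) {
    warning("classes are strongly imbalanced; metrics may be dominated by the majority class")
  }
  cfg <- model$cfg
  fold <- stratified_folds(f, k_folds, seed = derive_seed(cfg$seed, "cv"))
  rows <- vector("list", k_folds)
  for (k in seq_len(k_folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, paste0("fold", k))
    fm <- build_resdegnet(model$n_features, fold_cfg)
    fm <- fit_resdegnet(fm, beta[tr, , drop = FALSE], f[tr])
    pred <- predict_classes(fm, beta[te, , drop = FALSE])
    m <- multiclass_metrics(as.character(f[te]), pred, model$classes)
    rows[[k]] <- data.frame(fold = paste0("K=", k), t(unclass(m)))
  }
  rep_df <- do.call(rbind, rows)
  rep_df <- rbind(rep_df,
                  data.frame(fold = "Avg",
                             t(colMeans(rep_df[, -1L, drop = FALSE]))))
  rownames(rep_df) <- NULL
  model <- fit_resdegnet(model, beta, f)
  model$cv_report <- rep_df
  model
}

# Single fit on the given data (internal; used per CV fold and for the
# final model).
fit_resdegnet <- function(model, beta, f) {
  cfg <- model$cfg
  Y <- onehot_matrix(f)
  vf <- cfg$validation_fraction
  if (vf > 0) {
    sp <- stratified_split(f, train_fraction = 1 - vf,
                           seed = derive_seed(cfg$seed, "val-split"))
    val <- list(X = beta[sp$test, , drop = FALSE],
                target = Y[sp$test, , drop = FALSE])
    tr <- sp$train
  } else {
    val <- NULL
    tr <- seq_len(nrow(beta))
  }
  net <- resdeg_full_net(model)
  params <- resdeg_full_params(model)
  fit <- with_seed(derive_seed(cfg$seed, "train"), {
    nn_train(net, params, beta[tr, , drop = FALSE], Y[tr, , drop = FALSE],
             loss = "ce", lr = cfg$learning_rate, epochs = cfg$epochs,
             batch_size = cfg$batch_size, val = val, patience = cfg$patience)
  })
  n_feat_layers <- length(model$nets$features)
  model$params <- list(features = fit$params[seq_len(n_feat_layers)],
                       head = fit$params[-seq_len(n_feat_layers)])
  model$history <- fit$history
  model$trained <- TRUE
  model
}

#' Class probabilities from the softmax head
#'
#' @param model A trained `resdegnet_model`.
#' @param beta Beta matrix with the model's probe width.
#' @return Matrix samples x 4; rows sum to 1, columns named by class.
#' @export
predict_proba <- function(model, beta) {
  stopifnot(inherits(model, "resdegnet_model"))
  check_width(model, beta)
  z <- nn_logits(resdeg_full_net(model), resdeg_full_params(model), beta)
  p <- softmax_rows(z)
  dimnames(p) <- list(rownames(beta), model$classes)
  p
}

#' Hard class predictions (argmax of the class probabilities)
#' @param model A trained `resdegnet_model`.
#' @param beta Beta matrix.
#' @return Character vector of class labels.
#' @export
predict_classes <- function(model, beta) {
  p <- predict_proba(model, beta)
  model$classes[max.col(p, ties.method = "first")]
}

#' Global-average-pooling sample embeddings
#'
#' The activations of the GAP layer (one value per final-block channel),
#' used as sample embeddings for community clustering.
#'
#' @param model A trained `resdegnet_model`.
#' @param beta Beta matrix.
#' @return Matrix samples x `embedding_dim`, rownames preserved.
#' @export
extract_embeddings <- function(model, beta) {
  stopifnot(inherits(model, "resdegnet_model"))
  check_width(model, beta)
  emb <- nn_forward(model$nets$features, model$params$features,
                    as_seq_array(beta))$out
  rownames(emb) <- rownames(beta)
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  emb
}
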