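test_that("resdegnet configuration enforces the block structure", {
  expect_error(resdegnet_config(block_channels = c(8L, 16L)), "three")
  expect_error(resdegnet_config(block_channels = c(16L, 8L, 32L)),
               "non-decreasing")
  expect_error(resdegnet_config(block_strides = list(1L, c(2L, 1L, 1L),
                                                     c(2L, 1L, 1L))),
               "\\(2, 3, 3\\)")
})

test_that("forward pass emits a softmax 4-vector; builds are seeded", {
  cfg <- fast_resdegnet_cfg(seed = 3L)
  m <- build_resdegnet(110, cfg)
  p <- predict_proba(m, matrix(0.5, 3, 110))
  expect_identical(dim(p), c(3L, 4L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_identical(colnames(p), degenerative_classes())
  m2 <- build_resdegnet(110, cfg)
  expect_identical(predict_proba(m, matrix(0.2, 1, 110)),
                   predict_proba(m2, matrix(0.2, 1, 110)))
  # stride/pool reductions below length 1 raise a sizing error
  expect_error(build_resdegnet(1, cfg), "sizing error")
  # duplicated rows give duplicated probabilities
  set.seed(1)
  X <- matrix(runif(4 * 110), 4, 110); X[3, ] <- X[1, ]
  pp <- predict_proba(m, X)
  expect_equal(pp[3, ], pp[1, ])
})

test_that("residual blocks become the identity (up to projection) when the
           body convolutions are zeroed", {
  ns <- asNamespace("methylscreen")
  m <- build_resdegnet(40, fast_resdegnet_cfg(seed = 5L))
  params <- m$params$features
  # zero every body conv in every residual block
  for (i in seq_along(m$nets$features)) {
    if (m$nets$features[[i]]$type == "resblock") {
      for (j in seq_along(params[[i]]$convs)) {
        params[[i]]$convs[[j]]$W[] <- 0
        params[[i]]$convs[[j]]$b[] <- 0
      }
    }
  }
  set.seed(2)
  X <- ns$as_seq_array(matrix(runif(2 * 40), 2, 40))
  full <- ns$nn_forward(m$nets$features, params, X)$out
  # the same forward with blocks replaced by their skip paths only
  skip_net <- list(); skip_params <- list()
  for (i in seq_along(m$nets$features)) {
    spec <- m$nets$features[[i]]
    if (spec$type == "resblock") {
      if (is.null(params[[i]]$proj)) next  # identity skip: drop the layer
      skip_net <- c(skip_net, list(ns$nn_conv(1L, spec$out_ch,
                                              prod(spec$strides), "valid",
                                              act = "linear")))
      skip_params <- c(skip_params, list(params[[i]]$proj))
    } else {
      skip_net <- c(skip_net, list(spec))
      skip_params <- c(skip_params, list(params[[i]]))
    }
  }
  skipped <- ns$nn_forward(skip_net, skip_params, X)$out
  expect_equal(full, skipped, tolerance = 1e-12)
})

test_that("the CV report carries an exact Avg row and embeddings have the
           configured width", {
  fx <- multiclass_fixture()
  rep_df <- fx$model$cv_report
  expect_identical(rep_df$fold, c(paste0("K=", 1:5), "Avg"))
  avg <- as.numeric(rep_df[6L, -1L])
  expect_identical(avg, unname(colMeans(as.matrix(rep_df[1:5, -1L]))))
  emb <- extract_embeddings(fx$model,
                            fx$cohort$beta[fx$split$test, , drop = FALSE])
  expect_identical(ncol(emb), fx$model$embedding_dim)
  expect_identical(ncol(emb), 32L)
  expect_true(all(is.finite(emb)))
  # identical samples -> identical embeddings
  two <- fx$cohort$beta[c(1, 1), , drop = FALSE]
  e2 <- extract_embeddings(fx$model, two)
  expect_equal(e2[1, ], e2[2, ])
})

test_that("labels are validated and imbalance warned about", {
  co <- generate_multiclass_cohort(cohort_config(
    n_samples_per_class = 12L, n_cpgs = 40L, n_informative_per_class = 4L,
    seed = 3L))
  m <- build_resdegnet(40, fast_resdegnet_cfg(epochs = 1L))
  expect_error(train_multiclass(m, co$beta, rep("mystery", nrow(co$beta))),
               "unknown class")
  labs3 <- co$labels
  labs3[labs3 == "healthy"] <- "breast_cancer"
  expect_error(train_multiclass(m, co$beta, labs3), "four classes")
  onehot <- encode_onehot(co$labels)
  expect_equal(methylscreen:::to_class_factor(onehot,
                                              degenerative_classes()),
               factor(co$labels, degenerative_classes()),
               ignore_attr = TRUE)
})
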