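test_that("build_msdcnn validates configuration and input width", {
  expect_error(msdcnn_config(kernel_sizes = c(3, 4, 7)), "odd")
  expect_error(msdcnn_config(filters_per_block = c(8L)), "one entry per block")
  expect_error(msdcnn_config(filters_per_block = c(0L, 8L)), "positive")
  # receptive-field check: width 4 cannot feed two pooled valid-conv blocks
  expect_error(build_msdcnn(4, fast_msdcnn_cfg(padding = "valid")),
               "sizing error")
})

test_that("forward pass is a sigmoid score with seeded determinism", {
  cfg <- fast_msdcnn_cfg(seed = 31L)
  m1 <- build_msdcnn(60, cfg)
  m2 <- build_msdcnn(60, cfg)
  zeros <- matrix(0, 1, 60)
  s1 <- predict_scores(m1, zeros)
  expect_gt(s1, 0); expect_lt(s1, 1)
  expect_identical(s1, predict_scores(m2, zeros))
  # row independence and batch-size invariance at inference
  set.seed(2)
  X <- matrix(runif(6 * 60), 6, 60)
  X[4, ] <- X[1, ]
  s <- predict_scores(m1, X)
  expect_equal(s[4], s[1])
  one_by_one <- vapply(1:6, function(i) {
    predict_scores(m1, X[i, , drop = FALSE])
  }, 0)
  expect_equal(unname(s), one_by_one, tolerance = 1e-6)
  expect_error(predict_scores(m1, X[, 1:59]), "expects 60")
})

test_that("branch kernel permutation preserves the set of branch widths", {
  ns <- asNamespace("methylscreen")
  dims_for <- function(kernels) {
    cfg <- msdcnn_config(kernel_sizes = kernels,
                         filters_per_block = c(4L, 8L), seed = 1L)
    net <- ns$msdcnn_net(cfg)
    branches <- net[[1L]]$branches
    sort(vapply(branches, function(b) ns$nn_init(b, c(80L, 1L))$shape, 0L))
  }
  expect_identical(dims_for(c(3L, 5L, 7L)), dims_for(c(7L, 3L, 5L)))
})

test_that("training records history and selects a validation threshold", {
  co <- generate_binary_cohort(cohort_config(
    n_samples_per_class = 40L, n_cpgs = 60L, n_informative_per_class = 8L,
    effect_delta = 0.4, precision = 50, seed = 6L))
  cfg <- fast_msdcnn_cfg(epochs = 1L, seed = 4L)
  cfg$patience <- 0L
  m <- train_binary(build_msdcnn(60, cfg), co$beta, co$labels)
  expect_identical(nrow(m$history), 1L)   # one epoch, one loss entry
  expect_true(m$trained)
  expect_true(is.finite(m$threshold$threshold))
  expect_error(train_binary(build_msdcnn(60, cfg), co$beta,
                            rep(1L, nrow(co$beta))),
               "both classes")
  # same seed, same data -> identical fit
  m2 <- train_binary(build_msdcnn(60, cfg), co$beta, co$labels)
  expect_identical(m$params, m2$params)
  expect_identical(m$threshold, m2$threshold)
})

test_that("diagnose applies the strict > threshold rule", {
  co <- generate_binary_cohort(cohort_config(
    n_samples_per_class = 30L, n_cpgs = 60L, n_informative_per_class = 8L,
    effect_delta = 0.4, precision = 50, seed = 9L))
  m <- train_binary(build_msdcnn(60, fast_msdcnn_cfg(epochs = 2L, seed = 2L)),
                    co$beta, co$labels)
  s <- predict_scores(m, co$beta)
  expect_identical(unname(diagnose(m, co$beta, threshold = max(s))),
                   rep(0L, nrow(co$beta)))         # score == thr -> 0
  expect_identical(unname(diagnose(m, co$beta, threshold = 0)),
                   rep(1L, nrow(co$beta)))         # 0 sentinel -> all 1
  expect_identical(diagnose(m, co$beta, threshold = list(threshold = 0.5)),
                   structure(as.integer(s > 0.5), names = names(s)))
})
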