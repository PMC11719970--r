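# Backpropagation of the conv-net engine is verified against central finite
# differences on small networks covering every layer type. Seeds are fixed;
# ReLU kinks make finite differences unreliable at unlucky parameter draws,
# so tolerances assume the checked points sit away from kinks (verified for
# these seeds).

ns <- asNamespace("methylscreen")

fd_check <- function(net, input_len, X, target, loss, tol = 1e-6,
                     eps = 1e-6) {
  init <- ns$nn_init(net, c(input_len, 1L))
  params <- init$params
  loss_fn <- function(p) {
    z <- ns$nn_forward(net, p, ns$as_seq_array(X))$out
    if (loss == "bce") ns$bce_loss(z, target) else ns$ce_loss(z, target)
  }
  f <- ns$nn_forward(net, params, ns$as_seq_array(X))
  dz <- if (loss == "bce") {
    matrix((ns$sigmoid(f$out) - target) / nrow(X), ncol = 1L)
  } else {
    (ns$softmax_rows(f$out) - target) / nrow(X)
  }
  grads <- ns$nn_backward(net, params, f$caches, dz)$grads
  assign_path <- function(p, path, val) {
    if (length(path) == 1L) { p[[path]] <- val; return(p) }
    p[[path[1L]]] <- assign_path(p[[path[1L]]], path[-1L], val)
    p
  }
  max_dev <- 0
  walk <- function(path, node, gnode) {
    if (is.null(node)) return(invisible())
    if (is.numeric(node)) {
      for (i in seq_along(node)) {
        up <- node; up[i] <- node[i] + eps
        dn <- node; dn[i] <- node[i] - eps
        num <- (loss_fn(assign_path(params, path, up)) -
                  loss_fn(assign_path(params, path, dn))) / (2 * eps)
        max_dev <<- max(max_dev, abs(num - gnode[i]))
      }
      return(invisible())
    }
    for (i in seq_along(node)) walk(c(path, i), node[[i]], gnode[[i]])
  }
  walk(integer(0), params, grads)
  max_dev
}

test_that("branch/conv/pool/dense gradients match finite differences", {
  set.seed(42)
  net <- list(
    ns$nn_branches(list(
      list(ns$nn_conv(3, 2, pad = "valid"), ns$nn_conv(3, 2, pad = "valid"),
           ns$nn_pool(2, "max"), ns$nn_flatten()),
      list(ns$nn_conv(5, 3, pad = "valid"), ns$nn_pool(2, "average"),
           ns$nn_flatten()))),
    ns$nn_dense(4, act = "relu"), ns$nn_dense(1, act = "linear"))
  X <- matrix(runif(5 * 12), 5, 12)
  expect_lt(fd_check(net, 12L, X, c(0, 1, 1, 0, 1), "bce"), 1e-6)
})

test_that("residual block gradients match finite differences", {
  set.seed(7)
  net_id <- list(ns$nn_resblock(1, 3, c(1L, 1L)), ns$nn_gap(),
                 ns$nn_dense(2, act = "linear"))
  X <- matrix(runif(4 * 10), 4, 10)
  Y <- diag(2)[c(1, 2, 1, 2), ]
  expect_lt(fd_check(net_id, 10L, X, Y, "ce"), 1e-6)
  set.seed(19)
  net_proj <- list(ns$nn_conv(3, 2, pad = "same"), ns$nn_pool(2, "max"),
                   ns$nn_resblock(4, 3, c(2L, 1L, 1L)), ns$nn_gap(),
                   ns$nn_dense(2, act = "linear"))
  X2 <- matrix(runif(4 * 14), 4, 14)
  expect_lt(fd_check(net_proj, 14L, X2, Y, "ce"), 1e-6)
})

test_that("training reduces the loss on a separable toy problem", {
  set.seed(12)
  X <- matrix(runif(60 * 16), 60, 16)
  y <- rep(c(0, 1), each = 30)
  X[, 5] <- 0.2 + 0.6 * y   # linearly separable coordinate
  net <- list(ns$nn_conv(3, 4, pad = "same"), ns$nn_pool(2, "max"),
              ns$nn_flatten(), ns$nn_dense(8, act = "relu"),
              ns$nn_dense(1, act = "linear"))
  init <- ns$nn_init(net, c(16L, 1L))
  fit <- ns$nn_train(net, init$params, X, y, loss = "bce", lr = 1e-2,
                     epochs = 20L, batch_size = 16L)
  expect_lt(tail(fit$history$loss, 1), 0.25 * fit$history$loss[1L])
  # loss is non-increasing over epochs within tolerance
  expect_true(all(diff(fit$history$loss) < 0.05))
})

test_that("sizing errors are raised for inputs too short for the stack", {
  expect_error(ns$nn_init(list(ns$nn_conv(7, 2, pad = "valid")), c(4L, 1L)),
               "sizing error")
  expect_error(ns$nn_init(list(ns$nn_pool(2, "max")), c(1L, 1L)),
               "sizing error")
})
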