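# Minimal 1D conv-net engine backing the two network architectures.
# Batched activations are (batch, length, channels) arrays between conv /
# pool layers and plain matrices after flatten / GAP. Convolution and
# pooling run in C++ (im2col + GEMM); dense layers, ReLU, losses and Adam
# are plain matrix code. Layer specs are nested lists so composite layers
# (parallel branches, residual blocks) recurse naturally.
#
# Not exported: the public surface is build_msdcnn() / build_resdegnet()
# and their train / predict functions.

nn_conv <- function(k, out_ch, stride = 1L, pad = c("valid", "same"),
                    act = c("relu", "linear")) {
  pad <- match.arg(pad)
  act <- match.arg(act)
  list(type = "conv", k = as.integer(k), out_ch = as.integer(out_ch),
       stride = as.integer(stride), pad = pad, act = act)
}

nn_pool <- function(size, kind = c("max", "average")) {
  list(type = "pool", size = as.integer(size), kind = match.arg(kind))
}

nn_flatten <- function() list(type = "flatten")
nn_gap <- function() list(type = "gap")

nn_dense <- function(units, act = c("linear", "relu")) {
  list(type = "dense", units = as.integer(units), act = match.arg(act))
}

nn_branches <- function(branches) list(type = "branches", branches = branches)

# A residual block: `convs` (all ReLU, 'same' padding) on the body; the skip
# path is the identity, or a 1x1 strided linear projection whenever channel
# count or total stride changes the shape.
nn_resblock <- function(out_ch, k, strides) {
  list(type = "resblock", out_ch = as.integer(out_ch), k = as.integer(k),
       strides = as.integer(strides))
}

pad_width <- function(spec) {
  if (spec$pad == "same") (spec$k - 1L) %/% 2L else 0L
}

conv_out_length <- function(L, k, stride, pad) {
  num <- L + 2L * pad - k
  if (num < 0L) return(0L)
  num %/% stride + 1L
}

# He-normal initialisation; uses the current RNG stream (callers seed it).
init_conv <- function(spec, in_ch) {
  fan_in <- spec$k * in_ch
  list(W = matrix(rnorm(fan_in * spec$out_ch, 0, sqrt(2 / fan_in)),
                  fan_in, spec$out_ch),
       b = rep(0, spec$out_ch))
}

init_dense <- function(units, d_in) {
  list(W = matrix(rnorm(d_in * units, 0, sqrt(2 / d_in)), d_in, units),
       b = rep(0, units))
}

# Initialise parameters for a spec list given the input shape, returning
# list(params, shape). Shapes are c(L, C) for sequence activations or a
# single integer for flat ones. Raises sizing errors for inputs too short
# for the configured kernels / pooling / strides.
nn_init <- function(net, shape) {
  params <- vector("list", length(net))
  for (i in seq_along(net)) {
    spec <- net[[i]]
    # note: `params[i] <- list(...)`, not `[[<-`, so NULL (parameter-free
    # layers) does not delete the slot
    params[i] <- list(switch(
      spec$type,
      conv = {
        if (length(shape) != 2L) stopf("conv layer needs sequence input")
        p <- init_conv(spec, shape[2L])
        L_out <- conv_out_length(shape[1L], spec$k, spec$stride,
                                 pad_width(spec))
        if (L_out < 1L) {
          stopf("sizing error: length %d too small for kernel %d (stride %d, padding '%s')",
                shape[1L], spec$k, spec$stride, spec$pad)
        }
        shape <- c(L_out, spec$out_ch)
        p
      },
      pool = {
        L_out <- (shape[1L] - spec$size) %/% spec$size + 1L
        if (shape[1L] < spec$size || L_out < 1L) {
          stopf("sizing error: length %d too small for pool size %d",
                shape[1L], spec$size)
        }
        shape <- c(L_out, shape[2L])
        NULL
      },
      flatten = {
        shape <- shape[1L] * shape[2L]
        NULL
      },
      gap = {
        shape <- shape[2L]
        NULL
      },
      dense = {
        if (length(shape) != 1L) stopf("dense layer needs flat input")
        p <- init_dense(spec$units, shape)
        shape <- spec$units
        p
      },
      branches = {
        outs <- lapply(spec$branches, nn_init, shape = shape)
        dims <- vapply(outs, function(o) {
          if (length(o$shape) != 1L) {
            stopf("each branch must end in a flatten layer")
          }
          o$shape
        }, 0L)
        shape <- sum(dims)
        list(branches = lapply(outs, `[[`, "params"))
      },
      resblock = {
        in_ch <- shape[2L]
        convs <- vector("list", length(spec$strides))
        ch <- in_ch
        L <- shape[1L]
        for (j in seq_along(spec$strides)) {
          cspec <- nn_conv(spec$k, spec$out_ch, spec$strides[j], "same")
          convs[[j]] <- init_conv(cspec, ch)
          L <- conv_out_length(L, spec$k, spec$strides[j], pad_width(cspec))
          if (L < 1L) stopf("sizing error: residual block reduces length below 1")
          ch <- spec$out_ch
        }
        total_stride <- prod(spec$strides)
        proj <- NULL
        if (in_ch != spec$out_ch || total_stride != 1L) {
          proj <- init_conv(nn_conv(1L, spec$out_ch, total_stride, "valid"),
                            in_ch)
          L_skip <- conv_out_length(shape[1L], 1L, total_stride, 0L)
          if (L_skip != L) stopf("residual skip/body length mismatch (%d vs %d)",
                                 L_skip, L)
        }
        shape <- c(L, spec$out_ch)
        list(convs = convs, proj = proj)
      },
      stopf("unknown layer type '%s'", spec$type)))
  }
  list(params = params, shape = shape)
}

conv_apply_fwd <- function(X, par, spec) {
  Y <- conv1d_fwd_cpp(X, par$W, par$b, spec$k, spec$stride, pad_width(spec))
  if (spec$act == "relu") {
    mask <- Y > 0
    list(out = Y * mask, cache = list(X = X, mask = mask))
  } else {
    list(out = Y, cache = list(X = X, mask = NULL))
  }
}

conv_apply_bwd <- function(dY, par, spec, cache) {
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  g <- conv1d_bwd_cpp(cache$X, par$W, dY, spec$k, spec$stride,
                      pad_width(spec))
  list(dX = g$dX, grads = list(W = g$dW, b = as.numeric(g$db)))
}

# Forward pass; returns list(out, caches) where caches[[i]] holds what
# layer i needs for its backward pass.
nn_forward <- function(net, params, X) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    spec <- net[[i]]
    par <- params[[i]]
    r <- switch(
      spec$type,
      conv = conv_apply_fwd(X, par, spec),
      pool = {
        f <- pool1d_fwd_cpp(X, spec$size, spec$kind == "max")
        list(out = f$Y, cache = list(idx = f$idx, dimX = dim(X)))
      },
      flatten = {
        d <- dim(X)
        list(out = matrix(X, d[1L], d[2L] * d[3L]),
             cache = list(dimX = d))
      },
      gap = {
        d <- dim(X)
        list(out = colMeans(aperm(X, c(2L, 1L, 3L))),
             cache = list(dimX = d))
      },
      dense = {
        Z <- X %*% par$W + rep(par$b, each = nrow(X))
        if (spec$act == "relu") {
          mask <- Z > 0
          list(out = Z * mask, cache = list(X = X, mask = mask))
        } else {
          list(out = Z, cache = list(X = X, mask = NULL))
        }
      },
      branches = {
        outs <- vector("list", length(spec$branches))
        bc <- vector("list", length(spec$branches))
        for (bidx in seq_along(spec$branches)) {
          f <- nn_forward(spec$branches[[bidx]], par$branches[[bidx]], X)
          outs[[bidx]] <- f$out
          bc[[bidx]] <- f$caches
        }
        list(out = do.call(cbind, outs),
             cache = list(branch_caches = bc,
                          dims = vapply(outs, ncol, 0L)))
      },
      resblock = {
        body <- X
        body_caches <- vector("list", length(spec$strides))
        ch_in <- dim(X)[3L]
        for (j in seq_along(spec$strides)) {
          cspec <- nn_conv(spec$k, spec$out_ch, spec$strides[j], "same")
          f <- conv_apply_fwd(body, par$convs[[j]], cspec)
          body_caches[[j]] <- f$cache
          body <- f$out
        }
        if (is.null(par$proj)) {
          skip <- X
          proj_cache <- NULL
        } else {
          pf <- conv_apply_fwd(X, par$proj,
                               nn_conv(1L, spec$out_ch, prod(spec$strides),
                                       "valid", act = "linear"))
          skip <- pf$out
          proj_cache <- pf$cache
        }
        list(out = body + skip,
             cache = list(body_caches = body_caches,
                          proj_cache = proj_cache))
      })
    caches[[i]] <- r$cache
    X <- r$out
  }
  list(out = X, caches = caches)
}

# Backward pass: gradient of the loss wrt every parameter (mirrors the
# params structure) plus the input gradient.
nn_backward <- function(net, params, caches, dOut) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    spec <- net[[i]]
    par <- params[[i]]
    cache <- caches[[i]]
    r <- switch(
      spec$type,
      conv = conv_apply_bwd(dOut, par, spec, cache),
      pool = list(dX = pool1d_bwd_cpp(dOut, cache$idx,
                                      as.integer(cache$dimX), spec$size,
                                      spec$kind == "max"),
                  grads = NULL),
      flatten = list(dX = array(dOut, cache$dimX), grads = NULL),
      gap = {
        d <- cache$dimX
        dX <- array(0, d)
        g <- dOut / d[2L]
        for (l in seq_len(d[2L])) dX[, l, ] <- g
        list(dX = dX, grads = NULL)
      },
      dense = {
        dZ <- if (!is.null(cache$mask)) dOut * cache$mask else dOut
        list(dX = dZ %*% t(par$W),
             grads = list(W = t(cache$X) %*% dZ, b = colSums(dZ)))
      },
      branches = {
        off <- 0L
        dX <- NULL
        bg <- vector("list", length(spec$branches))
        for (bidx in seq_along(spec$branches)) {
          cols <- off + seq_len(cache$dims[bidx])
          off <- off + cache$dims[bidx]
          bb <- nn_backward(spec$branches[[bidx]], par$branches[[bidx]],
                            cache$branch_caches[[bidx]],
                            dOut[, cols, drop = FALSE])
          bg[[bidx]] <- bb$grads
          dX <- if (is.null(dX)) bb$dX else dX + bb$dX
        }
        list(dX = dX, grads = list(branches = bg))
      },
      resblock = {
        dBody <- dOut
        cg <- vector("list", length(spec$strides))
        for (j in rev(seq_along(spec$strides))) {
          cspec <- nn_conv(spec$k, spec$out_ch, spec$strides[j], "same")
          bb <- conv_apply_bwd(dBody, par$convs[[j]], cspec,
                               cache$body_caches[[j]])
          cg[[j]] <- bb$grads
          dBody <- bb$dX
        }
        if (is.null(par$proj)) {
          dX <- dBody + dOut
          pg <- NULL
        } else {
          pb <- conv_apply_bwd(dOut, par$proj,
                               nn_conv(1L, spec$out_ch, prod(spec$strides),
                                       "valid", act = "linear"),
                               cache$proj_cache)
          dX <- dBody + pb$dX
          pg <- pb$grads
        }
        list(dX = dX, grads = list(convs = cg, proj = pg))
      })
    grads[i] <- list(r$grads)
    dOut <- r$dX
  }
  list(dX = dOut, grads = grads)
}

# --- losses ------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Numerically stable binary cross-entropy from logits.
bce_loss <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

ce_loss <- function(z, Y) {
  p <- softmax_rows(z)
  -mean(log(pmax(rowSums(p * Y), 1e-300)))
}

# --- Adam --------------------------------------------------------------

# Recursively map over parallel nested parameter structures.
param_map <- function(f, ...) {
  dots <- list(...)
  x <- dots[[1L]]
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) return(do.call(f, dots))
  out <- vector("list", length(x))
  names(out) <- names(x)
  for (i in seq_along(x)) {
    # `[i] <- list(...)` keeps NULL results (parameter-free layers) in place
    out[i] <- list(do.call(param_map, c(list(f), lapply(dots, `[[`, i))))
  }
  out
}

adam_init <- function(params) {
  list(m = param_map(function(p) p * 0, params),
       v = param_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- param_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

as_seq_array <- function(X) {
  if (length(dim(X)) == 3L) return(X)
  array(as.numeric(X), dim = c(nrow(X), ncol(X), 1L))
}

# --- training loop -----------------------------------------------------

# X: n x p matrix; target: numeric 0/1 vector (loss "bce") or one-hot
# matrix (loss "ce"). Optional validation data enables early stopping with
# the given patience (0 disables). Uses the current RNG stream for batch
# shuffling; callers seed it.
nn_train <- function(net, params, X, target, loss = c("bce", "ce"),
                     lr = 1e-3, epochs = 10L, batch_size = 32L,
                     val = NULL, patience = 0L) {
  loss <- match.arg(loss)
  n <- nrow(X)
  Xarr <- as_seq_array(X)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(params = params, val = Inf, epoch = 0L)
  bad_epochs <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- Xarr[idx, , , drop = FALSE]
      f <- nn_forward(net, params, Xb)
      z <- f$out
      if (loss == "bce") {
        yb <- target[idx]
        l <- bce_loss(z, yb)
        dz <- matrix((sigmoid(z) - yb) / length(idx), ncol = 1L)
      } else {
        Yb <- target[idx, , drop = FALSE]
        l <- ce_loss(z, Yb)
        dz <- (softmax_rows(z) - Yb) / length(idx)
      }
      if (!is.finite(l)) {
        stopf("non-finite training loss at epoch %d (lr too high or degenerate input)",
              epoch)
      }
      b <- nn_backward(net, params, f$caches, dz)
      upd <- adam_step(params, b$grads, state, lr)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + l
      n_batches <- n_batches + 1L
    }
    val_loss <- NA_real_
    if (!is.null(val)) {
      vz <- nn_forward(net, params, as_seq_array(val$X))$out
      val_loss <- if (loss == "bce") bce_loss(vz, val$target) else {
        ce_loss(vz, val$target)
      }
      if (val_loss < best$val - 1e-9) {
        best <- list(params = params, val = val_loss, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epoch_loss / n_batches,
                                val_loss = val_loss))
    if (!is.null(val) && patience > 0L && bad_epochs >= patience) break
  }
  if (!is.null(val) && patience > 0L && is.finite(best$val)) {
    params <- best$params
  }
  list(params = params, history = history)
}

nn_logits <- function(net, params, X) {
  nn_forward(net, params, as_seq_array(X))$out
}
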