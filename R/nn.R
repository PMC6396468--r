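# Minimal feed-forward network engine used by the scoring modules.
#
# Supports the layer types the module architectures need: dense, 1-D
# convolution (valid or same padding, stride 1), ReLU, dropout, batch
# normalization, global average pooling over positions, and flatten.
# Activations are base-R arrays: 2-D (n, features) for dense stages, 3-D
# (n, positions, channels) for convolutional stages. Training is sigmoid
# cross-entropy on the final linear output with the Adam optimizer; the
# sigmoid itself is folded into the loss so a module's forward pass returns
# the pre-activation score.

glorot_init <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

layer_dense <- function(din, dout) {
  list(type = "dense",
       params = list(W = glorot_init(din, dout, din, dout),
                     b = rep(0, dout)))
}

layer_conv1d <- function(cin, cout, k, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  list(type = "conv1d", k = as.integer(k), cin = cin, cout = cout,
       padding = padding,
       params = list(W = glorot_init(k * cin, cout, k * cin, k * cout),
                     b = rep(0, cout)))
}

layer_relu <- function() list(type = "relu", params = list())

layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate, params = list())
}

layer_batchnorm <- function(d, eps = 1e-3, momentum = 0.99) {
  list(type = "batchnorm", eps = eps, momentum = momentum,
       params = list(gamma = rep(1, d), beta = rep(0, d)),
       state = list(mean = rep(0, d), var = rep(1, d)))
}

layer_gap <- function() list(type = "gap", params = list())

layer_flatten <- function() list(type = "flatten", params = list())

# --- helpers -----------------------------------------------------------------

# (n, L, C) -> (n*Lo, k*C) patch matrix; stride 1
im2col <- function(Xp, k, Lo) {
  d <- dim(Xp); n <- d[1]; C <- d[3]
  M <- matrix(0, n * Lo, k * C)
  for (j in seq_len(k)) {
    blk <- Xp[, j:(j + Lo - 1L), , drop = FALSE]
    dim(blk) <- c(n * Lo, C)
    M[, ((j - 1L) * C + 1L):(j * C)] <- blk
  }
  M
}

pad_positions <- function(X, pl, pr) {
  if (pl == 0L && pr == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1], d[2] + pl + pr, d[3]))
  Xp[, (pl + 1L):(pl + d[2]), ] <- X
  Xp
}

as_feature_matrix <- function(X) {
  # collapse a 3-D (n, L, C) activation to (n*L, C); identity on 2-D
  if (length(dim(X)) == 3L) {
    d <- dim(X)
    Xm <- aperm(X, c(2, 1, 3))          # (L, n, C): rows vary within-sample
    dim(Xm) <- c(d[1] * d[2], d[3])
    list(m = Xm, d = d)
  } else list(m = X, d = NULL)
}

from_feature_matrix <- function(M, d) {
  if (is.null(d)) return(M)
  dim(M) <- c(d[2], d[1], d[3])
  aperm(M, c(2, 1, 3))
}

# --- forward / backward ------------------------------------------------------

layer_forward <- function(layer, X, training = FALSE) {
  switch(layer$type,
    dense = {
      Y <- X %*% layer$params$W
      Y <- sweep(Y, 2L, layer$params$b, "+")
      list(out = Y, cache = list(X = X), layer = layer)
    },
    conv1d = {
      k <- layer$k
      d <- dim(X); L <- d[2]
      if (layer$padding == "same") {
        pl <- (k - 1L) %/% 2L; pr <- (k - 1L) - pl
      } else pl <- pr <- 0L
      Lp <- L + pl + pr
      Lo <- Lp - k + 1L
      if (Lo < 1L) stop("input too short for convolution kernel")
      Xp <- pad_positions(X, pl, pr)
      M <- im2col(Xp, k, Lo)
      Y2 <- M %*% layer$params$W
      Y2 <- sweep(Y2, 2L, layer$params$b, "+")
      list(out = array(Y2, c(d[1], Lo, layer$cout)),
           cache = list(M = M, n = d[1], L = L, Lp = Lp, Lo = Lo,
                        pl = pl, cin = d[3]),
           layer = layer)
    },
    relu = {
      list(out = pmax(X, 0), cache = list(pos = X > 0), layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (stats::runif(length(X)) >= layer$rate) / (1 - layer$rate)
        Y <- X * mask
        attributes(Y) <- attributes(X)
        list(out = Y, cache = list(mask = mask), layer = layer)
      } else list(out = X, cache = list(mask = NULL), layer = layer)
    },
    batchnorm = {
      fm <- as_feature_matrix(X)
      x <- fm$m
      if (training) {
        mu <- colMeans(x)
        v <- colMeans(sweep(x, 2L, mu)^2)
        layer$state$mean <- layer$momentum * layer$state$mean + (1 - layer$momentum) * mu
        layer$state$var <- layer$momentum * layer$state$var + (1 - layer$momentum) * v
      } else {
        mu <- layer$state$mean
        v <- layer$state$var
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(sweep(x, 2L, mu), 2L, inv, "*")
      y <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L, layer$params$beta, "+")
      list(out = from_feature_matrix(y, fm$d),
           cache = list(xhat = xhat, inv = inv, d3 = fm$d, training = training),
           layer = layer)
    },
    gap = {
      d <- dim(X)
      Y <- colMeans(aperm(X, c(2, 1, 3)), dims = 1L)   # (n, C)
      list(out = Y, cache = list(d = d), layer = layer)
    },
    flatten = {
      d <- dim(X)
      Y <- X
      dim(Y) <- c(d[1], d[2] * d[3])
      list(out = Y, cache = list(d = d), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
    dense = {
      list(dX = dY %*% t(layer$params$W),
           grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
    },
    conv1d = {
      n <- cache$n; Lo <- cache$Lo; k <- layer$k; cin <- cache$cin
      dY2 <- dY
      dim(dY2) <- c(n * Lo, layer$cout)
      dW <- crossprod(cache$M, dY2)
      db <- colSums(dY2)
      dM <- dY2 %*% t(layer$params$W)
      dXp <- array(0, c(n, cache$Lp, cin))
      for (j in seq_len(k)) {
        blk <- dM[, ((j - 1L) * cin + 1L):(j * cin), drop = FALSE]
        dim(blk) <- c(n, Lo, cin)
        dXp[, j:(j + Lo - 1L), ] <- dXp[, j:(j + Lo - 1L), ] + blk
      }
      dX <- dXp[, (cache$pl + 1L):(cache$pl + cache$L), , drop = FALSE]
      list(dX = dX, grads = list(W = dW, b = db))
    },
    relu = {
      dX <- dY * cache$pos
      list(dX = dX, grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = list())
      else {
        dX <- dY * cache$mask
        attributes(dX) <- attributes(dY)
        list(dX = dX, grads = list())
      }
    },
    batchnorm = {
      fm <- as_feature_matrix(dY)
      dy <- fm$m
      xhat <- cache$xhat; inv <- cache$inv
      N <- nrow(dy)
      dgamma <- colSums(dy * xhat)
      dbeta <- colSums(dy)
      dxhat <- sweep(dy, 2L, layer$params$gamma, "*")
      if (cache$training) {
        # standard batch-norm backward through the batch statistics
        t1 <- sweep(dxhat, 2L, colSums(dxhat) / N)
        t2 <- sweep(xhat, 2L, colSums(dxhat * xhat) / N, "*")
        dx <- sweep(t1 - t2, 2L, inv, "*")
      } else {
        dx <- sweep(dxhat, 2L, inv, "*")
      }
      list(dX = from_feature_matrix(dx, cache$d3),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    gap = {
      d <- cache$d
      dXp <- array(rep(as.vector(dY / d[2]), each = d[2]), c(d[2], d[1], d[3]))
      list(dX = aperm(dXp, c(2, 1, 3)), grads = list())
    },
    flatten = {
      dX <- dY
      dim(dX) <- cache$d
      list(dX = dX, grads = list())
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_forward <- function(net, X, training = FALSE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], X, training = training)
    X <- fw$out
    net$layers[[i]] <- fw$layer          # batch-norm running stats
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches, net = net)
}

nn_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  dY <- dOut
  for (i in rev(seq_along(net$layers))) {
    bw <- layer_backward(net$layers[[i]], caches[[i]], dY)
    grads[[i]] <- bw$grads
    dY <- bw$dX
  }
  grads
}

# Numerically stable mean sigmoid cross-entropy with logits; y may be
# fractional in [0, 1].
bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(l) lapply(l$params, function(p) {
    list(m = array(0, dim = dim(p) %||% length(p)),
         v = array(0, dim = dim(p) %||% length(p)))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      p <- net$layers[[i]]$params[[nm]]
      p[] <- p - lr * as.vector(mhat) / (sqrt(as.vector(vhat)) + eps)
      net$layers[[i]]$params[[nm]] <- p
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

slice_rows <- function(X, idx) {
  if (length(dim(X)) == 3L) X[idx, , , drop = FALSE]
  else if (length(dim(X)) == 2L) X[idx, , drop = FALSE]
  else X[idx]
}

# Mini-batch sigmoid cross-entropy training with Adam, early stopping on the
# validation loss, and restoration of the best-epoch weights.
train_network <- function(net, X, Y, Xval, Yval, lr = 1e-3, batch_size = 64L,
                          epochs = 100L, patience = 5L) {
  Y <- as.matrix(Y)
  Yval <- as.matrix(Yval)
  n <- if (is.null(dim(X))) length(X) else dim(X)[1]
  stopifnot(n == nrow(Y), n >= 1L)
  state <- adam_init(net)
  t <- 0L
  best <- list(net = net, val = Inf, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tr_losses <- c()
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      Xb <- slice_rows(X, idx)
      Yb <- Y[idx, , drop = FALSE]
      fw <- nn_forward(net, Xb, training = TRUE, keep_cache = TRUE)
      net <- fw$net
      z <- fw$out
      loss <- bce_with_logits(z, Yb)
      if (!is.finite(loss)) stop("training diverged (non-finite loss)")
      tr_losses <- c(tr_losses, loss)
      dZ <- (sigmoid(z) - Yb) / length(z)
      grads <- nn_backward(net, fw$caches, dZ)
      t <- t + 1L
      upd <- adam_step(net, grads, state, t, lr = lr)
      net <- upd$net
      state <- upd$state
    }
    val <- bce_with_logits(nn_forward(net, Xval)$out, Yval)
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(tr_losses),
                                 val_loss = val))
    if (val < best$val - 1e-9) {
      best <- list(net = net, val = val, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(net = best$net, log = log, best_epoch = best$epoch, best_val = best$val)
}

nn_count_params <- function(net) {
  sum(vapply(net$layers, function(l) {
    sum(vapply(l$params, length, integer(1))) +
      if (l$type == "batchnorm") length(l$state$mean) * 2L else 0L
  }, numeric(1)))
}
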