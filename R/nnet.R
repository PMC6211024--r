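# Minimal 1-D convolutional network engine used by the denoising
# autoencoder. Tensors are stored channels-first as (C, L, B) arrays so that
# convolutions reduce to one indexed gather (im2col) plus one BLAS matmul and
# no dimension permutation is ever needed on the hot path. All layers are
# mutable environments holding parameters, gradients and forward caches.
#
# Modes:
#   "train" - dropout active, batchnorm uses batch statistics and updates
#             running averages
#   "mc"    - dropout active (Monte-Carlo sampling), batchnorm uses running
#             statistics
#   "infer" - dropout off, batchnorm uses running statistics

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

layer_conv <- function(k, c_in, c_out) {
  if (k %% 2L == 0L) stop("convolution kernels must be odd-sized")
  new_layer("conv", k = as.integer(k), c_in = as.integer(c_in),
            c_out = as.integer(c_out),
            W = matrix(stats::rnorm(k * c_in * c_out, 0,
                                    sqrt(2 / (k * c_in))), k * c_in, c_out),
            b = numeric(c_out))
}

layer_dense <- function(d_in, d_out) {
  new_layer("dense", d_in = as.integer(d_in), d_out = as.integer(d_out),
            W = matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)),
                       d_in, d_out),
            b = numeric(d_out))
}

layer_batchnorm <- function(c_f, momentum = 0.9, eps = 1e-5) {
  new_layer("batchnorm", c_f = as.integer(c_f), momentum = momentum, eps = eps,
            gamma = rep(1, c_f), beta = rep(0, c_f),
            run_mean = rep(0, c_f), run_var = rep(1, c_f))
}

layer_relu <- function() new_layer("relu")
layer_dropout <- function(p) new_layer("dropout", p = p)
layer_pool <- function(size, kind) new_layer("pool", s = as.integer(size),
                                             kind = kind)
layer_upsample <- function(size, target_len)
  new_layer("upsample", s = as.integer(size),
            target_len = as.integer(target_len))
layer_flatten <- function() new_layer("flatten")
layer_reshape <- function(c_f, len) new_layer("reshape", c_f = as.integer(c_f),
                                              len = as.integer(len))

layer_forward <- function(layer, X, mode, cache) {
  switch(layer$type,
    conv = {
      if (cache) layer$cache <- list(X = X)
      conv1d_fwd(X, layer$W, layer$b, layer$k)
    },
    dense = {
      if (cache) layer$cache <- list(X = X)
      crossprod(layer$W, X) + layer$b
    },
    batchnorm = {
      d <- dim(X)
      Xm <- X; dim(Xm) <- c(d[1L], prod(d[-1L]))
      if (mode == "train") {
        mu <- rowMeans(Xm)
        v <- rowMeans(Xm * Xm) - mu * mu
        v <- pmax(v, 0)
        layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
        layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
        inv_std <- 1 / sqrt(v + layer$eps)
        xhat <- (Xm - mu) * inv_std
        Y <- layer$gamma * xhat + layer$beta
        dim(Y) <- d
        if (cache) layer$cache <- list(xhat = xhat, inv_std = inv_std, d = d,
                                       batch_stats = TRUE)
        Y
      } else {
        # running statistics reduce to one fused affine map per channel
        a <- layer$gamma / sqrt(layer$run_var + layer$eps)
        bb <- layer$beta - layer$run_mean * a
        if (cache) layer$cache <- list(a = a, d = d, batch_stats = FALSE)
        bn_affine(X, a, bb)
      }
    },
    relu = {
      if (cache) layer$cache <- list(X = X)
      relu_fwd(X)
    },
    dropout = {
      if (mode == "infer" || layer$p <= 0) {
        if (cache) layer$cache <- list(mask = NULL)
        X
      } else {
        out <- dropout_fwd(X, layer$p, cache)
        if (cache) layer$cache <- list(mask = out$mask)
        out$Y
      }
    },
    pool = {
      d <- dim(X)
      out <- pool_fwd(X, layer$s, layer$kind == "max", cache)
      if (cache) layer$cache <- list(idx = out$idx, d = d,
                                     L_out = d[2L] %/% layer$s)
      out$Y
    },
    upsample = {
      if (cache) layer$cache <- list(L = dim(X)[2L])
      upsample_fwd(X, layer$s, layer$target_len)
    },
    flatten = {
      d <- dim(X)
      if (cache) layer$cache <- list(d = d)
      dim(X) <- c(d[1L] * d[2L], d[3L])
      X
    },
    reshape = {
      B <- ncol(X)
      dim(X) <- c(layer$c_f, layer$len, B)
      X
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, dY) {
  switch(layer$type,
    conv = {
      g <- conv1d_bwd(layer$cache$X, layer$W, dY, layer$k)
      layer$dW <- g$dW
      layer$db <- as.numeric(g$db)
      g$dX
    },
    dense = {
      X <- layer$cache$X
      dim(dY) <- c(layer$d_out, ncol(X))
      layer$dW <- X %*% t(dY)
      layer$db <- rowSums(dY)
      layer$W %*% dY
    },
    batchnorm = {
      cc <- layer$cache
      if (!cc$batch_stats) return(dY * cc$a)
      dYm <- dY; dim(dYm) <- dim(cc$xhat)
      layer$dgamma <- rowSums(dYm * cc$xhat)
      layer$dbeta <- rowSums(dYm)
      dxhat <- dYm * layer$gamma
      N <- ncol(dxhat)
      dX <- (cc$inv_std / N) *
        (N * dxhat - rowSums(dxhat) - cc$xhat * rowSums(dxhat * cc$xhat))
      dim(dX) <- cc$d
      dX
    },
    relu = relu_bwd(layer$cache$X, dY),
    dropout = {
      if (is.null(layer$cache$mask)) dY else dY * layer$cache$mask
    },
    pool = {
      cc <- layer$cache
      if (layer$kind == "max") {
        maxpool_bwd(dY, cc$idx, cc$d[1L], cc$d[2L], cc$d[3L])
      } else {
        C <- cc$d[1L]; L <- cc$d[2L]; B <- cc$d[3L]; s <- layer$s
        dX <- array(0, c(C, L, B))
        for (j in seq_len(s)) {
          pos <- seq(j, by = s, length.out = cc$L_out)
          dX[, pos, ] <- dY / s
        }
        dX
      }
    },
    upsample = upsample_bwd(dY, layer$s, layer$cache$L),
    flatten = {
      dim(dY) <- layer$cache$d
      dY
    },
    reshape = {
      dim(dY) <- c(layer$c_f * layer$len, dim(dY)[3L])
      dY
    },
    stop("unknown layer type: ", layer$type))
}

net_forward <- function(layers, X, mode = "infer", cache = FALSE,
                        upto = length(layers)) {
  for (i in seq_len(upto)) X <- layer_forward(layers[[i]], X, mode, cache)
  X
}

net_backward <- function(layers, dY) {
  for (i in rev(seq_along(layers))) dY <- layer_backward(layers[[i]], dY)
  dY
}

net_clear_caches <- function(layers) {
  for (l in layers) if (!is.null(l$cache)) l$cache <- NULL
  invisible(NULL)
}

# names of trainable parameter fields per layer type
layer_param_names <- function(layer) {
  switch(layer$type,
         conv = c("W", "b"),
         dense = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         character(0))
}

rmsprop_step <- function(layers, lr, rho = 0.9, eps = 1e-8) {
  for (l in layers) {
    for (nm in layer_param_names(l)) {
      g <- get(paste0("d", nm), envir = l)
      cache_nm <- paste0("rms_", nm)
      r <- if (exists(cache_nm, envir = l)) get(cache_nm, envir = l) else 0
      r <- rho * r + (1 - rho) * g * g
      assign(cache_nm, r, envir = l)
      assign(nm, get(nm, envir = l) - lr * g / (sqrt(r) + eps), envir = l)
    }
  }
  invisible(NULL)
}
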