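#' Denoising-autoencoder configuration
#'
#' Describes the convolutional denoising autoencoder: an encoder of
#' `n_conv_blocks` blocks, each `dropout -> convolution -> batch
#' normalization -> ReLU -> pooling`, followed by `dropout -> fully-connected`
#' to a `q`-dimensional latent code; the decoder is a mirror reversal with
#' up-sampling in place of pooling and a linear final convolution (so
#' negative accelerations remain reconstructable). A dropout layer precedes
#' every weight layer; at the input the dropout role is played by the
#' denoising corruption (masking plus optional additive Gaussian noise).
#'
#' Two presets are provided. `"fog"` (gait-style windows, e.g. 32 samples):
#' 4 blocks, 64 filters each, kernels 5/5/3/3, max pooling. `"smm"`
#' (stereotypy-style windows, e.g. 90 samples): 3 blocks, 64 filters,
#' kernels 9/5/3, average pooling. Both use pool size 2 and `q = 64`.
#'
#' @param arch_preset `"fog"`, `"smm"` or `"custom"`.
#' @param n_conv_blocks Number of encoder blocks (custom).
#' @param filters Integer vector of filter counts per block.
#' @param kernel_sizes Integer vector of odd kernel sizes per block.
#' @param pool_type `"max"` or `"avg"`.
#' @param pool_size Pooling factor per block.
#' @param q Latent dimension.
#' @param dropout Dropout probability before every weight layer, in
#'   `[0, 1)`; 0 disables dropout (useful for deterministic checks).
#' @param input_mask_prob Corruption masking probability at the input;
#'   defaults to `dropout`.
#' @param gaussian_sd Additive Gaussian corruption (in standardized signal
#'   units); 0 disables it.
#' @param learning_rate,batch_size,epochs RMSprop optimizer settings.
#' @param seed Integer seed controlling initialization, corruption, dropout
#'   and shuffling.
#' @return An object of class `dae_config`.
#' @export
dae_config <- function(arch_preset = c("fog", "smm", "custom"),
                       n_conv_blocks = NULL, filters = NULL,
                       kernel_sizes = NULL, pool_type = NULL, pool_size = 2L,
                       q = 64L, dropout = 0.1,
                       input_mask_prob = NULL, gaussian_sd = 0.1,
                       learning_rate = 1e-3, batch_size = 100L, epochs = 30L,
                       seed = 1L) {
  arch_preset <- match.arg(arch_preset)
  preset <- switch(arch_preset,
    fog = list(n = 4L, filters = c(32L, 32L, 32L, 32L),
               kernels = c(5L, 5L, 3L, 3L), pool = "max"),
    smm = list(n = 3L, filters = c(64L, 64L, 64L),
               kernels = c(9L, 5L, 3L), pool = "avg"),
    custom = list(n = NULL, filters = NULL, kernels = NULL, pool = "max"))
  n_conv_blocks <- if (is.null(n_conv_blocks)) preset$n else as.integer(n_conv_blocks)
  filters <- if (is.null(filters)) preset$filters else as.integer(filters)
  kernel_sizes <- if (is.null(kernel_sizes)) preset$kernels else as.integer(kernel_sizes)
  pool_type <- if (is.null(pool_type)) preset$pool else match.arg(pool_type, c("max", "avg"))
  if (is.null(n_conv_blocks) || is.null(filters) || is.null(kernel_sizes))
    stop("custom preset requires n_conv_blocks, filters and kernel_sizes")
  if (length(filters) != n_conv_blocks || length(kernel_sizes) != n_conv_blocks)
    stop("filters and kernel_sizes must have length n_conv_blocks")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (q < 1L) stop("latent dimension q must be >= 1")
  if (is.null(input_mask_prob)) input_mask_prob <- dropout
  structure(list(arch_preset = arch_preset, n_conv_blocks = n_conv_blocks,
                 filters = filters, kernel_sizes = kernel_sizes,
                 pool_type = pool_type, pool_size = as.integer(pool_size),
                 q = as.integer(q), dropout = dropout,
                 input_mask_prob = input_mask_prob, gaussian_sd = gaussian_sd,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "dae_config")
}

#' Build an untrained denoising autoencoder
#'
#' Assembles the encoder/decoder layer stack for a given window shape and
#' initializes the weights (He initialization, seeded by `cfg$seed`).
#'
#' @param cfg A [dae_config()].
#' @param input_shape `c(w, c)`: window length in samples and channel count.
#' @return An object of class `dae_model`.
#' @export
build_dae <- function(cfg, input_shape) {
  stopifnot(inherits(cfg, "dae_config"), length(input_shape) == 2L)
  w <- as.integer(input_shape[1L]); ch <- as.integer(input_shape[2L])
  s <- cfg$pool_size
  lens <- integer(cfg$n_conv_blocks + 1L)
  lens[1L] <- w
  for (i in seq_len(cfg$n_conv_blocks)) {
    nxt <- lens[i] %/% s
    if (nxt < 1L)
      stop("window of ", w, " samples collapses below 1 at pooling block ", i,
           "; reduce n_conv_blocks or pool_size")
    lens[i + 1L] <- nxt
  }
  set.seed(cfg$seed)
  delta <- cfg$dropout
  enc <- list()
  c_prev <- ch
  for (i in seq_len(cfg$n_conv_blocks)) {
    # the input-side dropout of block 1 is realized by the denoising
    # corruption applied in train_dae()/mc_predict(), not a layer
    if (i > 1L) enc <- c(enc, list(layer_dropout(delta)))
    enc <- c(enc, list(layer_conv(cfg$kernel_sizes[i], c_prev, cfg$filters[i]),
                       layer_batchnorm(cfg$filters[i]),
                       layer_relu(),
                       layer_pool(s, cfg$pool_type)))
    c_prev <- cfg$filters[i]
  }
  flat_dim <- c_prev * lens[cfg$n_conv_blocks + 1L]
  enc <- c(enc, list(layer_dropout(delta), layer_flatten(),
                     layer_dense(flat_dim, cfg$q)))
  dec <- list(layer_dropout(delta), layer_dense(cfg$q, flat_dim),
              layer_reshape(c_prev, lens[cfg$n_conv_blocks + 1L]))
  for (i in rev(seq_len(cfg$n_conv_blocks))) {
    c_out <- if (i > 1L) cfg$filters[i - 1L] else ch
    dec <- c(dec, list(layer_upsample(s, lens[i]),
                       layer_dropout(delta),
                       layer_conv(cfg$kernel_sizes[i], cfg$filters[i], c_out)))
    if (i > 1L) dec <- c(dec, list(layer_batchnorm(c_out), layer_relu()))
    # final block: linear output, no batchnorm/ReLU
  }
  structure(list(layers = c(enc, dec), n_encoder_layers = length(enc),
                 input_shape = c(w, ch), q = cfg$q, config = cfg,
                 trained = FALSE, training_history = NULL),
            class = "dae_model")
}

# (C, L, B) tensor from a window set, and back to the flat n x p layout used
# by the scoring functions (feature order matches flatten_windows()).
ws_to_tensor <- function(ws) aperm(ws$windows, c(3L, 2L, 1L))

tensor_to_flat <- function(Y) {
  d <- dim(Y)
  Y <- aperm(Y, c(2L, 1L, 3L))
  dim(Y) <- c(d[1L] * d[2L], d[3L])
  t(Y)
}

# denoising corruption: zero-masking at rate p_mask plus additive Gaussian
corrupt_input <- function(X, p_mask, gaussian_sd) {
  if (p_mask <= 0 && gaussian_sd <= 0) return(X)
  corrupt_fwd(X, p_mask, gaussian_sd)
}

#' Train a denoising autoencoder on normal windows
#'
#' Each optimization step corrupts the input batch (masking at
#' `input_mask_prob`, plus Gaussian noise when `gaussian_sd > 0`) and
#' regresses onto the clean batch under mean-squared-error loss with the
#' RMSprop optimizer. The caller is expected to pass only normal-movement
#' windows (see [select_normal_training()]).
#'
#' @param model An untrained or trained [build_dae()] model.
#' @param train A [window_set()] of training windows.
#' @param valid Optional [window_set()] for per-epoch validation loss.
#' @param verbose Print per-epoch losses?
#' @return The trained `dae_model` with `$training_history` (per-epoch mean
#'   training loss and, if requested, validation loss).
#' @export
train_dae <- function(model, train, valid = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "dae_model"), inherits(train, "window_set"))
  cfg <- model$config
  X_all <- ws_to_tensor(train)
  n <- dim(X_all)[3L]
  if (n == 0L) stop("empty training set")
  set.seed(cfg$seed + 1L)
  bs <- min(cfg$batch_size, n)
  hist_train <- numeric(cfg$epochs)
  hist_valid <- if (!is.null(valid)) numeric(cfg$epochs) else NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      Xb <- X_all[, , idx, drop = FALSE]
      Xc <- corrupt_input(Xb, cfg$input_mask_prob, cfg$gaussian_sd)
      Y <- net_forward(model$layers, Xc, mode = "train", cache = TRUE)
      err <- Y - Xb
      loss <- mean(err * err)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep,
             "; try a smaller learning rate")
      losses <- c(losses, loss)
      net_backward(model$layers, 2 * err / length(err))
      rmsprop_step(model$layers, cfg$learning_rate)
    }
    hist_train[ep] <- mean(losses)
    if (!is.null(valid)) {
      Xv <- ws_to_tensor(valid)
      Yv <- net_forward(model$layers, Xv, mode = "infer", cache = FALSE)
      hist_valid[ep] <- mean((Yv - Xv)^2)
    }
    if (verbose)
      message(sprintf("epoch %d/%d: train MSE %.5f%s", ep, cfg$epochs,
                      hist_train[ep],
                      if (!is.null(valid)) sprintf(", valid MSE %.5f", hist_valid[ep]) else ""))
  }
  net_clear_caches(model$layers)
  model$trained <- TRUE
  model$training_history <- data.frame(epoch = seq_len(cfg$epochs),
                                       train_loss = hist_train)
  if (!is.null(valid)) model$training_history$valid_loss <- hist_valid
  model
}

#' Monte-Carlo-dropout predictive mean and variance
#'
#' Runs `m` stochastic forward passes with dropout active at test time (and,
#' by default, the denoising input corruption as well, matching the
#' training-time forward process). Returns the per-element empirical mean
#' `M` and the population-form variance `V` (divisor `m`) of the `m`
#' reconstructions, as `n x p` matrices aligned with [flatten_windows()].
#'
#' @param model A trained `dae_model`.
#' @param X A [window_set()] to reconstruct.
#' @param m Number of MC draws (>= 2); 50 is the evaluation default.
#' @param corrupt Keep the input corruption active during sampling?
#' @param keep_draws Retain the individual draws (for verification); stored
#'   as an `m`-element list of `n x p` matrices.
#' @param seed Optional seed for the MC draws.
#' @return An object of class `predictive_stats` with fields `M`, `V`, `m`
#'   and optionally `draws`.
#' @export
mc_predict <- function(model, X, m = 50L, corrupt = TRUE,
                       keep_draws = FALSE, seed = NULL) {
  stopifnot(inherits(model, "dae_model"), inherits(X, "window_set"))
  if (!model$trained) warning("mc_predict on an untrained model")
  m <- as.integer(m)
  if (m < 2L) stop("m must be >= 2 (variance is degenerate otherwise)")
  if (!is.null(seed)) set.seed(seed)
  Xt <- ws_to_tensor(X)
  cfg <- model$config
  acc <- NULL; acc2 <- NULL
  draws <- if (keep_draws) vector("list", m) else NULL
  for (i in seq_len(m)) {
    Xc <- if (corrupt) corrupt_input(Xt, cfg$input_mask_prob, cfg$gaussian_sd) else Xt
    Y <- net_forward(model$layers, Xc, mode = "mc", cache = FALSE)
    Yf <- tensor_to_flat(Y)
    if (is.null(acc)) { acc <- Yf; acc2 <- Yf * Yf }
    else { acc <- acc + Yf; acc2 <- acc2 + Yf * Yf }
    if (keep_draws) draws[[i]] <- Yf
  }
  M <- acc / m
  V <- pmax(acc2 / m - M * M, 0)
  structure(list(M = M, V = V, m = m, draws = draws),
            class = "predictive_stats")
}

#' Deterministic latent encodings
#'
#' Forward pass through the encoder with dropout off and batch normalization
#' in inference mode; no input corruption. Repeated calls give identical
#' output.
#'
#' @param model A trained `dae_model`.
#' @param X A [window_set()].
#' @return Numeric matrix `n x q` of bottleneck activations.
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "dae_model"), inherits(X, "window_set"))
  Z <- net_forward(model$layers, ws_to_tensor(X), mode = "infer",
                   cache = FALSE, upto = model$n_encoder_layers)
  t(Z)
}

#' Deterministic reconstruction
#'
#' Full forward pass with dropout off and no corruption.
#'
#' @param model A trained `dae_model`.
#' @param X A [window_set()].
#' @return Numeric matrix `n x p` of reconstructions.
#' @export
reconstruct <- function(model, X) {
  stopifnot(inherits(model, "dae_model"), inherits(X, "window_set"))
  tensor_to_flat(net_forward(model$layers, ws_to_tensor(X), mode = "infer",
                             cache = FALSE))
}

#' @export
print.dae_model <- function(x, ...) {
  cat(sprintf("<dae_model> %s preset: input (%d x %d), %d blocks, q = %d, dropout = %g%s\n",
              x$config$arch_preset, x$input_shape[1L], x$input_shape[2L],
              x$config$n_conv_blocks, x$q, x$config$dropout,
              if (x$trained) sprintf(" [trained, final MSE %.4f]",
                                     utils::tail(x$training_history$train_loss, 1))
              else " [untrained]"))
  invisible(x)
}
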