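test_that("presets satisfy the reconstruction/encoding shape contracts", {
  m_fog <- build_dae(dae_config("fog", seed = 1), c(32L, 9L))
  ws <- toy_window_set(n = 4, w = 32, ch = 9, n_abnormal = 0)
  Y <- reconstruct(m_fog, ws)
  expect_equal(dim(Y), c(4L, 32L * 9L))
  expect_true(all(is.finite(Y)))
  m_smm <- build_dae(dae_config("smm", seed = 1), c(90L, 9L))
  ws2 <- toy_window_set(n = 3, w = 90, ch = 9, n_abnormal = 0)
  expect_equal(dim(encode(m_smm, ws2)), c(3L, 64L))
  expect_equal(dim(reconstruct(m_smm, ws2)), c(3L, 90L * 9L))
})

test_that("a pooling cascade that collapses the window is rejected by block", {
  cfg <- dae_config("custom", n_conv_blocks = 4, filters = rep(8L, 4),
                    kernel_sizes = rep(3L, 4), pool_size = 2, q = 4, seed = 1)
  expect_error(build_dae(cfg, c(8L, 2L)), "block 4")
})

test_that("training reduces the loss and is seed-deterministic", {
  cfg <- synth_config(n_subjects = 1, duration = 70, sample_rate = 32,
                      n_channels = 4, anomaly_type = "none", seed = 31)
  ws <- segment(generate_recording(cfg, 1), preprocess_config(step_samples = 10))
  ws <- apply_standardizer(ws, fit_standardizer(ws))
  dcfg <- tiny_dae_config(epochs = 12L)
  m1 <- train_dae(build_dae(dcfg, c(32L, 4L)), ws)
  h1 <- m1$training_history$train_loss
  expect_lt(tail(h1, 1), h1[1])
  m2 <- train_dae(build_dae(dcfg, c(32L, 4L)), ws)
  expect_identical(h1, m2$training_history$train_loss)
  # monotone trend on block averages (small learning rate regime)
  blocks <- tapply(h1, rep(1:3, each = 4), mean)
  expect_true(all(diff(blocks) < 0))
})

test_that("the autoencoder can overfit a tiny window set", {
  set.seed(11)
  ws <- toy_window_set(n = 8, w = 16, ch = 2, n_abnormal = 0, seed = 11)
  cfg <- dae_config("custom", n_conv_blocks = 1, filters = 32L,
                    kernel_sizes = 5L, q = 24L, dropout = 0.05,
                    input_mask_prob = 0.05, gaussian_sd = 0.05,
                    epochs = 400L, batch_size = 8L,
                    learning_rate = 2e-3, seed = 3)
  m <- train_dae(build_dae(cfg, c(16L, 2L)), ws)
  X <- flatten_windows(ws)
  mse <- mean((reconstruct(m, ws) - X)^2)
  expect_lt(mse, 0.05 * var(as.vector(X)))
})

test_that("MC statistics match a brute-force recomputation from the draws", {
  tm <- trained_tiny_model()
  ws <- subset_windows(tm$train_ws, 1:6)
  ps <- mc_predict(tm$model, ws, m = 7, keep_draws = TRUE, seed = 12)
  stack <- simplify2array(ps$draws)        # n x p x m
  M_bf <- apply(stack, c(1, 2), mean)
  V_bf <- apply(stack, c(1, 2), function(v) mean((v - mean(v))^2))
  expect_equal(ps$M, M_bf, tolerance = 1e-12)
  expect_equal(ps$V, V_bf, tolerance = 1e-12)
  expect_true(all(ps$V >= 0))
  expect_error(mc_predict(tm$model, ws, m = 1), "m must be")
})

test_that("predictive variance vanishes when dropout and corruption are off", {
  ws <- toy_window_set(n = 5, w = 32, ch = 4, n_abnormal = 0)
  cfg0 <- tiny_dae_config(dropout = 0, gaussian_sd = 0, input_mask_prob = 0)
  m0 <- build_dae(cfg0, c(32L, 4L))
  m0$trained <- TRUE   # variance is architecture-level, not fit-level
  ps <- mc_predict(m0, ws, m = 5, seed = 2)
  expect_equal(max(ps$V), 0)
  expect_equal(ps$M, normwear:::tensor_to_flat(normwear:::net_forward(m0$layers, normwear:::ws_to_tensor(ws),
                                                mode = "infer")),
               tolerance = 1e-12)
})

test_that("encodings are deterministic and identical for duplicated windows", {
  tm <- trained_tiny_model()
  ws <- subset_windows(tm$train_ws, 1:4)
  dup <- bind_windows(ws, subset_windows(ws, 1))
  E1 <- encode(tm$model, dup)
  E2 <- encode(tm$model, dup)
  expect_identical(E1, E2)
  expect_equal(E1[5, ], E1[1, ], tolerance = 1e-12)
  expect_equal(ncol(E1), tm$model$q)
})

test_that("analytic gradients agree with central differences", {
  cfg <- dae_config("custom", n_conv_blocks = 2, filters = c(4L, 3L),
                    kernel_sizes = c(3L, 3L), pool_type = "avg", q = 5L,
                    dropout = 0.2, gaussian_sd = 0, seed = 7)
  m <- build_dae(cfg, c(12L, 2L))
  set.seed(42)
  X <- array(rnorm(2 * 12 * 3), c(2, 12, 3))
  Tgt <- array(rnorm(2 * 12 * 3), c(2, 12, 3))
  set.seed(99)
  Y <- normwear:::net_forward(m$layers, X, mode = "train", cache = TRUE)
  normwear:::net_backward(m$layers, 2 * (Y - Tgt) / length(Y))
  eps <- 1e-5
  worst <- 0
  for (l in m$layers) {
    for (nm in normwear:::layer_param_names(l)) {
      P <- get(nm, envir = l); G <- get(paste0("d", nm), envir = l)
      for (ii in sample(seq_along(P), min(3, length(P)))) {
        P2 <- P; P2[ii] <- P[ii] + eps; assign(nm, P2, envir = l)
        set.seed(99)
        lp <- mean((normwear:::net_forward(m$layers, X, "train", FALSE) - Tgt)^2)
        P2[ii] <- P[ii] - eps; assign(nm, P2, envir = l)
        set.seed(99)
        lm_ <- mean((normwear:::net_forward(m$layers, X, "train", FALSE) - Tgt)^2)
        assign(nm, P, envir = l)
        num <- (lp - lm_) / (2 * eps)
        worst <- max(worst, abs(num - G[ii]) /
                       max(1e-6, abs(num) + abs(G[ii])))
      }
    }
  }
  expect_lt(worst, 1e-3)
})
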