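# Shared fixtures: everything is generated in code at test time.

# a small annotated recording with a deterministic pattern
toy_recording <- function(n = 200, ch = 3, rate = 32, anns = NULL, seed = 1) {
  set.seed(seed)
  samples <- matrix(rnorm(n * ch), n, ch)
  if (is.null(anns)) anns <- rep(1L, n)
  signal_recording(samples, rate, anns, subject_id = "T1")
}

# a window set with known labels, built directly (bypassing segmentation)
toy_window_set <- function(n = 12, w = 16, ch = 2, n_abnormal = 3, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(n * w * ch), c(n, w, ch))
  frac <- c(rep(0, n - n_abnormal), runif(n_abnormal, 0.5, 1))
  labels <- ifelse(frac >= 0.5, "abnormal", "normal")
  window_set(arr, labels, frac, rep("T1", n),
             meta = list(sample_rate = 32, window_seconds = w / 32))
}

# small architecture used wherever a test needs a real (but cheap) network
tiny_dae_config <- function(..., epochs = 10L, seed = 7) {
  dae_config("custom", n_conv_blocks = 2, filters = c(8L, 8L),
             kernel_sizes = c(5L, 3L), pool_type = "max", q = 8L,
             epochs = epochs, batch_size = 32L, seed = seed, ...)
}

# one trained tiny model on synthetic gait windows, memoized across tests
.tiny_model_env <- new.env()
trained_tiny_model <- function() {
  if (is.null(.tiny_model_env$model)) {
    cfg <- synth_config(n_subjects = 1, duration = 80, sample_rate = 32,
                        n_channels = 4, anomaly_type = "none", seed = 5)
    rec <- generate_recording(cfg, 1)
    ws <- segment(rec, preprocess_config(step_samples = 16))
    std <- fit_standardizer(ws)
    ws <- apply_standardizer(ws, std)
    model <- build_dae(tiny_dae_config(), c(32L, 4L))
    .tiny_model_env$model <- train_dae(model, ws)
    .tiny_model_env$train_ws <- ws
  }
  list(model = .tiny_model_env$model, train_ws = .tiny_model_env$train_ws)
}

# small multi-subject dataset + eval config for LOSO-level tests
tiny_loso_setup <- function(n_subjects = 3, duration = 120, seed = 21,
                            anomaly_rate = 0.2, m = 8L, n_repeats = 1L,
                            methods = "normative", base_seed = 3L,
                            heteroscedastic_channels = NULL, delta = 0.1) {
  scfg <- synth_config(n_subjects = n_subjects, duration = duration,
                       sample_rate = 32, n_channels = 4,
                       anomaly_rate = anomaly_rate, seed = seed,
                       heteroscedastic_channels = heteroscedastic_channels)
  ecfg <- eval_config(methods = methods, n_repeats = n_repeats,
                      base_seed = base_seed, m = m, delta = delta,
                      dae = tiny_dae_config(epochs = 4L),
                      max_reference = 150L)
  list(dataset = generate_dataset(scfg), cfg = ecfg)
}
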