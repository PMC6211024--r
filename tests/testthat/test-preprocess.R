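test_that("linear resampling preserves affine signals and identity rate", {
  n <- 128
  ramp <- cbind(seq(0, 2, length.out = n), 3 - 0.5 * seq(0, 2, length.out = n))
  rec <- signal_recording(ramp, 64, rep(1L, n))
  for (rate in c(32, 90)) {
    rs <- resample_linear(rec, rate)
    t_new <- (seq_len(nrow(rs$samples)) - 1L) / rate
    expected <- cbind(2 / ((n - 1) / 64) * t_new, 3 - 0.5 * 2 / ((n - 1) / 64) * t_new)
    expect_equal(unname(rs$samples), expected, tolerance = 1e-10)
  }
  expect_identical(resample_linear(rec, 64)$samples, rec$samples)
})

test_that("resampling a sine matches direct evaluation on the new grid", {
  rate0 <- 64; n <- 64 * 4
  tt <- (seq_len(n) - 1L) / rate0
  rec <- signal_recording(cbind(sin(2 * pi * 2 * tt)), rate0, rep(1L, n))
  rs <- resample_linear(rec, 32)
  t_new <- (seq_len(nrow(rs$samples)) - 1L) / 32
  # linear interpolation error bound for f'' bounded: h^2/8 * max|f''|
  bound <- (1 / rate0)^2 / 8 * (2 * pi * 2)^2
  expect_lt(max(abs(rs$samples[, 1] - sin(2 * pi * 2 * t_new))), bound + 1e-12)
})

test_that("resampling maps annotations by nearest original timestep", {
  anns <- c(rep(1L, 32), rep(2L, 32))
  rec <- signal_recording(matrix(0, 64, 1), 64, anns)
  rs <- resample_linear(rec, 32)
  expect_identical(rs$annotations, anns[seq(1, 64, by = 2)])
})

test_that("high-pass removes DC and preserves passband sines", {
  n <- 64 * 8; rate <- 64
  tt <- (seq_len(n) - 1L) / rate
  const <- matrix(5, n, 1)
  rec <- signal_recording(const, rate, rep(1L, n))
  hp <- highpass(rec, 0.1)
  expect_lt(max(abs(hp$samples)), 5 * 1e-6 + 1e-8)

  sine <- sin(2 * pi * 5 * tt)
  rec2 <- signal_recording(cbind(sine + 3, sine), rate, rep(1L, n))
  hp2 <- highpass(rec2, 0.1)
  core <- seq(rate, n - rate)   # ignore filter edge transients
  # passband amplitude preserved within 1%
  expect_lt(abs(sd(hp2$samples[core, 2]) - sd(sine[core])) / sd(sine[core]),
            0.01)
  # linearity: sine + constant gives exactly the filtered sine alone
  expect_equal(hp2$samples[core, 1], hp2$samples[core, 2], tolerance = 1e-9)
  expect_error(highpass(rec2, 32), "Nyquist")
})

test_that("segmentation counts match the sliding-window formula and brute force", {
  mk <- function(L) signal_recording(matrix(seq_len(L), L, 1), 32, rep(1L, L))
  cfg <- preprocess_config(window_seconds = 1, step_samples = 10)
  expect_equal(n_windows(segment(mk(32), cfg)), 1L)
  expect_equal(n_windows(segment(mk(100), cfg)), 7L)
  set.seed(4)
  for (i in 1:20) {
    L <- sample(10:200, 1); w <- sample(2:min(L, 50), 1)
    s <- sample(seq_len(w), 1)
    cfg_i <- preprocess_config(window_seconds = w / 32, step_samples = s)
    brute <- sum(vapply(seq_len(L), function(st) st + w - 1 <= L &&
                          (st - 1) %% s == 0, logical(1)))
    expect_equal(n_windows(segment(mk(L), cfg_i)), brute,
                 info = sprintf("L=%d w=%d s=%d", L, w, s))
  }
})

test_that("window labels follow the abnormal-fraction threshold (>= rule)", {
  anns <- c(rep(1L, 16), rep(2L, 16))
  rec <- signal_recording(matrix(0, 32, 1), 32, anns)
  ws <- segment(rec, preprocess_config(step_samples = 10))
  expect_equal(ws$abnormal_fraction, 0.5)
  expect_equal(ws$labels, "abnormal")       # exactly at threshold
  ws2 <- segment(rec, preprocess_config(step_samples = 10,
                                        abnormal_fraction_threshold = 0.51))
  expect_equal(ws2$labels, "normal")
})

test_that("no window spans an excluded gap; runs are segmented independently", {
  anns <- c(rep(1L, 40), rep(0L, 5), rep(1L, 40))
  rec <- signal_recording(matrix(seq_len(85), 85, 1), 32, anns)
  ws <- segment(rec, preprocess_config(step_samples = 5))
  # each run of 40 yields floor((40-32)/5)+1 = 2 windows
  expect_equal(n_windows(ws), 4L)
  # window values must be contiguous sample indices (never jump the gap)
  for (j in seq_len(4)) expect_equal(diff(ws$windows[j, , 1]), rep(1, 31))
  # all runs too short -> empty set with warning
  rec2 <- signal_recording(matrix(0, 20, 1), 32, rep(1L, 20))
  expect_warning(empty <- segment(rec2, preprocess_config(step_samples = 10)),
                 "window")
  expect_equal(n_windows(empty), 0L)
})

test_that("training selection honors purity, matching a brute-force filter", {
  ws <- toy_window_set(n = 10, n_abnormal = 3)
  ws$abnormal_fraction <- c(rep(0, 7), 0.03, 0.4, 0.8)
  ws$labels <- ifelse(ws$abnormal_fraction >= 0.5, "abnormal", "normal")
  expect_equal(n_windows(select_normal_training(ws, 1)), 7L)
  kept <- select_normal_training(ws, 0.9)
  expect_equal(n_windows(kept), sum(ws$abnormal_fraction <= 0.1))
  pure <- subset_windows(ws, 1:7)
  expect_identical(select_normal_training(pure, 1)$windows, pure$windows)
  all_ab <- subset_windows(ws, 9:10)
  expect_error(select_normal_training(all_ab, 1), "purity")
})

test_that("standardizer uses training statistics only", {
  tr <- toy_window_set(n = 20, w = 8, ch = 2, n_abnormal = 0, seed = 2)
  std <- fit_standardizer(tr)
  z <- apply_standardizer(tr, std)
  for (c_i in 1:2) {
    v <- as.vector(z$windows[, , c_i])
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) * sqrt((length(v) - 1) / length(v)) - 1), 1e-6)
  }
  # held-out set transformed with hand-computed training stats
  te <- toy_window_set(n = 5, w = 8, ch = 2, n_abnormal = 0, seed = 3)
  zt <- apply_standardizer(te, std)
  mu1 <- mean(tr$windows[, , 1]); sd1 <- sd(as.vector(tr$windows[, , 1])) *
    sqrt((20 * 8 - 1) / (20 * 8))
  expect_equal(zt$windows[, , 1], (te$windows[, , 1] - mu1) / sd1,
               tolerance = 1e-12)
  # constant channel: floored scale, no blow-up
  tr$windows[, , 2] <- 4
  expect_warning(std2 <- fit_standardizer(tr), "floored")
  expect_true(all(is.finite(apply_standardizer(tr, std2)$windows)))
})
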