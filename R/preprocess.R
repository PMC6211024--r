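#' Preprocessing configuration
#'
#' Bundles the segmentation parameters used throughout the pipeline. The
#' defaults follow the freezing-of-gait processing chain: keep (or resample
#' to) 32 Hz, no high-pass, 1-second windows slid by 10 samples, a window is
#' labeled abnormal when at least half of its timesteps are abnormal, and
#' training keeps only windows that are entirely normal.
#'
#' For the stereotypy-style chain use `target_rate = 90`,
#' `highpass_cutoff = 0.1` and `step_samples = round(0.13 * 90)` (87% overlap
#' between consecutive 90-sample windows).
#'
#' @param target_rate Target sampling rate in Hz, or `NULL` to keep the
#'   recording's native rate.
#' @param highpass_cutoff High-pass cutoff in Hz, or `NULL` for no filtering.
#' @param window_seconds Window length in seconds.
#' @param step_samples Sliding-window step in samples at the target rate.
#' @param abnormal_fraction_threshold A window is labeled abnormal when its
#'   fraction of abnormal timesteps is at least this value.
#' @param training_purity Fraction of a training window that must be normal;
#'   1 keeps only windows with zero abnormal timesteps.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = NULL, highpass_cutoff = NULL,
                              window_seconds = 1, step_samples = 10L,
                              abnormal_fraction_threshold = 0.5,
                              training_purity = 1) {
  cfg <- list(target_rate = target_rate, highpass_cutoff = highpass_cutoff,
              window_seconds = window_seconds,
              step_samples = as.integer(step_samples),
              abnormal_fraction_threshold = abnormal_fraction_threshold,
              training_purity = training_purity)
  if (!is.null(target_rate) && target_rate <= 0) stop("target_rate must be positive")
  if (window_seconds <= 0) stop("window_seconds must be positive")
  if (cfg$step_samples < 1L) stop("step_samples must be >= 1")
  if (abnormal_fraction_threshold < 0 || abnormal_fraction_threshold > 1)
    stop("abnormal_fraction_threshold must lie in [0, 1]")
  if (training_purity <= 0 || training_purity > 1)
    stop("training_purity must lie in (0, 1]")
  class(cfg) <- "preprocess_config"
  cfg
}

window_length_samples <- function(cfg, rate) {
  w <- as.integer(round(cfg$window_seconds * rate))
  if (w < 2L) stop("window length in samples must be >= 2")
  if (cfg$step_samples > w) stop("step_samples must not exceed window length")
  w
}

#' Resample a recording by per-channel linear interpolation
#'
#' Each channel is linearly interpolated onto a uniform grid at `target_rate`
#' spanning the original duration. Annotations are carried over from the
#' nearest original timestep (labels are categorical and must not be
#' interpolated).
#'
#' @param rec A [signal_recording()].
#' @param target_rate New rate in Hz.
#' @return A resampled [signal_recording()].
#' @export
resample_linear <- function(rec, target_rate) {
  stopifnot(inherits(rec, "signal_recording"))
  if (target_rate <= 0) stop("target_rate must be positive")
  n <- nrow(rec$samples)
  if (n < 2L) stop("recording too short to resample (need >= 2 samples)")
  if (isTRUE(all.equal(target_rate, rec$sample_rate))) {
    rec$sample_rate <- target_rate
    return(rec)
  }
  t_old <- (seq_len(n) - 1L) / rec$sample_rate
  n_new <- floor(t_old[n] * target_rate) + 1L
  t_new <- (seq_len(n_new) - 1L) / target_rate
  out <- apply(rec$samples, 2L, function(y)
    stats::approx(t_old, y, xout = t_new, rule = 2)$y)
  nearest <- pmin(pmax(round(t_new * rec$sample_rate) + 1L, 1L), n)
  signal_recording(out, target_rate, rec$annotations[nearest], rec$label_map,
                   subject_id = rec$subject_id,
                   channel_names = rec$channel_names)
}

#' Zero-phase high-pass filter
#'
#' Removes slow trends and DC offsets: each channel is demeaned exactly and
#' then passed through an order-2 Butterworth high-pass applied forward and
#' backward (zero phase lag). Constant offsets are removed exactly;
#' passband amplitudes are preserved away from the recording edges (a very
#' low cutoff has a transient of roughly `1/cutoff` seconds at either end).
#'
#' @param rec A [signal_recording()].
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist rate.
#' @return A filtered [signal_recording()].
#' @export
highpass <- function(rec, cutoff) {
  stopifnot(inherits(rec, "signal_recording"))
  nyq <- rec$sample_rate / 2
  if (cutoff <= 0 || cutoff >= nyq)
    stop("cutoff must lie in (0, Nyquist) = (0, ", nyq, ") Hz")
  bf <- signal::butter(2, cutoff / nyq, type = "high")
  out <- apply(rec$samples, 2L, function(y)
    as.numeric(signal::filtfilt(bf, y - mean(y))))
  signal_recording(out, rec$sample_rate, rec$annotations, rec$label_map,
                   subject_id = rec$subject_id,
                   channel_names = rec$channel_names)
}

# Contiguous runs of non-excluded timesteps, as (start, end) index pairs.
non_excluded_runs <- function(rec) {
  keep <- annotation_roles(rec) != "excluded"
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Segment a recording into labeled sliding windows
#'
#' Excluded-annotation timesteps are dropped first; each remaining contiguous
#' run is segmented independently (no window ever spans an excluded gap).
#' Within a run of length `L`, windows of `w` samples start at offsets
#' `0, s, 2s, ...`, giving `floor((L - w) / s) + 1` windows. A window's
#' `abnormal_fraction` is the fraction of its timesteps annotated abnormal;
#' it is labeled `"abnormal"` when that fraction reaches
#' `cfg$abnormal_fraction_threshold`.
#'
#' @param rec A [signal_recording()] (already resampled/filtered as desired).
#' @param cfg A [preprocess_config()].
#' @return A [window_set()]; empty (with a warning) when every run is
#'   shorter than the window length.
#' @export
segment <- function(rec, cfg) {
  stopifnot(inherits(rec, "signal_recording"),
            inherits(cfg, "preprocess_config"))
  w <- window_length_samples(cfg, rec$sample_rate)
  s <- cfg$step_samples
  roles <- annotation_roles(rec)
  runs <- non_excluded_runs(rec)
  ch <- ncol(rec$samples)
  starts_all <- integer(0)
  for (i in seq_len(nrow(runs))) {
    L <- runs[i, "end"] - runs[i, "start"] + 1L
    if (L < w) next
    k <- (L - w) %/% s + 1L
    starts_all <- c(starts_all, runs[i, "start"] + s * (seq_len(k) - 1L))
  }
  meta <- list(sample_rate = rec$sample_rate,
               channel_names = rec$channel_names,
               window_seconds = cfg$window_seconds,
               step_samples = s,
               abnormal_fraction_threshold = cfg$abnormal_fraction_threshold)
  n <- length(starts_all)
  if (n == 0L) {
    warning("no run long enough for a ", w, "-sample window; empty window set")
    return(window_set(array(0, c(0L, w, ch)), character(0), numeric(0),
                      character(0), meta))
  }
  arr <- array(0, dim = c(n, w, ch))
  frac <- numeric(n)
  is_ab <- roles == "abnormal"
  for (j in seq_len(n)) {
    idx <- starts_all[j]:(starts_all[j] + w - 1L)
    arr[j, , ] <- rec$samples[idx, ]
    frac[j] <- mean(is_ab[idx])
  }
  labels <- ifelse(frac >= cfg$abnormal_fraction_threshold,
                   "abnormal", "normal")
  window_set(arr, labels, frac, rep(rec$subject_id, n), meta)
}

#' Select pure-normal training windows
#'
#' Keeps windows whose abnormal fraction is at most `1 - purity`; with
#' `purity = 1` (the default pipeline) only windows containing zero abnormal
#' timesteps survive, mirroring training on normal movement only.
#'
#' @param ws A labeled [window_set()].
#' @param purity Fraction in `(0, 1]`.
#' @return The filtered [window_set()].
#' @export
select_normal_training <- function(ws, purity = 1) {
  stopifnot(inherits(ws, "window_set"))
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  keep <- ws$abnormal_fraction <= 1 - purity + 1e-12
  if (!any(keep)) stop("no training windows survive the purity filter")
  subset_windows(ws, keep)
}

#' Fit a per-channel standardizer on training windows
#'
#' Computes per-channel mean and standard deviation over all training
#' timesteps. Zero-variance channels get their scale floored at `1e-8` (with
#' a warning) so standardization never divides by zero.
#'
#' @param train A non-empty [window_set()].
#' @return An object of class `standardizer` with `$mean` and `$sd` per
#'   channel.
#' @export
fit_standardizer <- function(train) {
  stopifnot(inherits(train, "window_set"))
  if (n_windows(train) == 0L) stop("cannot fit standardizer on empty set")
  d <- dim(train$windows)
  m <- matrix(train$windows, nrow = d[1L] * d[2L], ncol = d[3L])
  mu <- colMeans(m)
  sd_ <- sqrt(colMeans(m^2) - mu^2)
  if (any(sd_ < 1e-8)) {
    warning("zero-variance channel(s): scale floored at 1e-8")
    sd_ <- pmax(sd_, 1e-8)
  }
  structure(list(mean = mu, sd = sd_), class = "standardizer")
}

#' Apply a fitted standardizer to a window set
#'
#' @param ws A [window_set()].
#' @param stats A `standardizer` from [fit_standardizer()] (training
#'   statistics only; never refit on held-out data).
#' @return The standardized [window_set()].
#' @export
apply_standardizer <- function(ws, stats) {
  stopifnot(inherits(ws, "window_set"), inherits(stats, "standardizer"))
  d <- dim(ws$windows)
  if (length(stats$mean) != d[3L]) stop("channel count mismatch")
  arr <- ws$windows
  for (c_i in seq_len(d[3L]))
    arr[, , c_i] <- (arr[, , c_i] - stats$mean[c_i]) / stats$sd[c_i]
  ws$windows <- arr
  ws
}

#' Run the full preprocessing chain on one recording
#'
#' Optional resampling, optional high-pass, then segmentation.
#'
#' @param rec A [signal_recording()].
#' @param cfg A [preprocess_config()].
#' @return A [window_set()].
#' @export
preprocess_recording <- function(rec, cfg) {
  if (!is.null(cfg$target_rate)) rec <- resample_linear(rec, cfg$target_rate)
  if (!is.null(cfg$highpass_cutoff)) rec <- highpass(rec, cfg$highpass_cutoff)
  segment(rec, cfg)
}
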