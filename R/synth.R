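#' Synthetic IMU dataset configuration
#'
#' Describes a multi-subject synthetic accelerometer study: each subject
#' walks with a quasi-periodic gait signal (a subject-specific fundamental in
#' `gait_freq_range` plus decaying harmonics, per-channel random phases and
#' amplitudes, additive Gaussian noise), whose intensity drifts slowly over
#' the session (the `envelope_range` activity envelope — people speed up and
#' slow down), interrupted by annotated anomaly
#' episodes. Two anomaly flavors are supported: `"tremor"` mimics
#' trembling-in-place freezing episodes — the gait component is suppressed
#' to `gait_suppression` of its amplitude while a high-frequency (default
#' 6-8 Hz) tremor oscillation is superimposed, so episode energy stays
#' comparable to normal walking while the spectral content changes sharply;
#' `"stereotypy"` replaces the gait signal outright with a repetitive
#' oscillation (default 2-4 Hz), mimicking rocking/flapping.
#' Episode onsets follow a Poisson process with
#' uniformly drawn durations, calibrated so the expected fraction of abnormal
#' time is `anomaly_rate`.
#'
#' @param n_subjects Number of subjects.
#' @param duration Seconds of recording per subject.
#' @param sample_rate Sampling rate in Hz.
#' @param n_channels Number of acceleration channels (default 9, three
#'   3-axis sensors).
#' @param gait_freq_range Interval (Hz) for the subject fundamental.
#' @param n_harmonics Number of harmonics above the fundamental.
#' @param base_amplitude Gait amplitude in signal units.
#' @param envelope_range Interval of the slow multiplicative activity
#'   envelope on the gait component (anomaly bursts are not modulated:
#'   tremor amplitude does not depend on how vigorously the subject was
#'   walking). Set to `c(1, 1)` for a stationary gait.
#' @param envelope_period Approximate period (seconds) of the activity
#'   envelope; each subject draws its own period and phase.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param heteroscedastic_channels Optional named numeric vector mapping
#'   channel index to a noise-sd multiplier (e.g. `c(`3` = 10)`), used to
#'   emulate sensors with very different noise floors.
#' @param heteroscedastic_subjects Subject indices the noise multipliers
#'   apply to; `NULL` (default) applies them to every subject. Restricting
#'   them to one subject emulates a degraded sensor on that participant.
#' @param anomaly_type One of `"tremor"`, `"stereotypy"`, `"none"`.
#' @param anomaly_freq_range Interval (Hz) of the anomaly oscillation;
#'   defaults to 6-8 Hz for tremor and 2-4 Hz for stereotypy.
#' @param anomaly_amplitude_factor Anomaly amplitude as a multiple of
#'   `base_amplitude`.
#' @param gait_suppression Fraction of the gait amplitude retained during a
#'   tremor episode (stepping halts during freezing); ignored for
#'   stereotypy, which replaces the gait entirely.
#' @param anomaly_rate Expected fraction of abnormal time, in `[0, 1)`.
#' @param anomaly_duration_range Interval (seconds) of episode durations.
#' @param seed Integer seed; identical config + seed gives identical data.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 4L, duration = 300, sample_rate = 32,
                         n_channels = 9L,
                         gait_freq_range = c(1.5, 2.5), n_harmonics = 3L,
                         base_amplitude = 1,
                         envelope_range = c(1, 1),
                         envelope_period = 45,
                         noise_sd = 0.3,
                         heteroscedastic_channels = NULL,
                         heteroscedastic_subjects = NULL,
                         anomaly_type = c("tremor", "stereotypy", "none"),
                         anomaly_freq_range = NULL,
                         anomaly_amplitude_factor = 2,
                         gait_suppression = 1,
                         anomaly_rate = 0.15,
                         anomaly_duration_range = c(2, 6),
                         seed = 1L) {
  anomaly_type <- match.arg(anomaly_type)
  if (is.null(anomaly_freq_range))
    anomaly_freq_range <- switch(anomaly_type,
                                 tremor = c(6, 8),
                                 stereotypy = c(2, 4),
                                 none = c(0, 0))
  cfg <- list(n_subjects = as.integer(n_subjects), duration = duration,
              sample_rate = sample_rate, n_channels = as.integer(n_channels),
              gait_freq_range = gait_freq_range,
              n_harmonics = as.integer(n_harmonics),
              base_amplitude = base_amplitude,
              envelope_range = envelope_range,
              envelope_period = envelope_period,
              noise_sd = noise_sd,
              heteroscedastic_channels = heteroscedastic_channels,
              heteroscedastic_subjects = heteroscedastic_subjects,
              anomaly_type = anomaly_type,
              anomaly_freq_range = anomaly_freq_range,
              anomaly_amplitude_factor = anomaly_amplitude_factor,
              gait_suppression = gait_suppression,
              anomaly_rate = anomaly_rate,
              anomaly_duration_range = anomaly_duration_range,
              seed = as.integer(seed))
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (duration <= 0 || sample_rate <= 0) stop("duration and sample_rate must be positive")
  if (anomaly_rate < 0 || anomaly_rate >= 1) stop("anomaly_rate must lie in [0, 1)")
  if (anomaly_rate > 0.8) stop("anomaly_rate too high to place non-overlapping episodes")
  if (max(anomaly_freq_range) >= sample_rate / 2 && anomaly_type != "none")
    stop("anomaly frequencies must stay below Nyquist")
  class(cfg) <- "synth_config"
  cfg
}

# Independent substreams derived from the master seed, so that e.g. changing
# how noise is drawn never changes which fundamental a subject gets.
synth_substream_seed <- function(seed, subject_index, facet) {
  offset <- switch(facet, subject = 0L, noise = 1L, anomaly = 2L)
  (as.integer(seed) * 1009L + subject_index * 97L + offset * 31L) %% 2147483629L
}

# Poisson-process episode placement with uniform durations; returns a logical
# abnormal mask of length n. Episode count is drawn so that the expected
# covered fraction equals anomaly_rate.
place_anomaly_episodes <- function(n, rate_hz, cfg) {
  mask <- rep(FALSE, n)
  if (cfg$anomaly_rate <= 0 || cfg$anomaly_type == "none")
    return(mask)
  mean_dur <- mean(cfg$anomaly_duration_range)
  expected_n <- cfg$duration * cfg$anomaly_rate / mean_dur
  n_ep <- stats::rpois(1L, expected_n)
  if (n_ep == 0L) return(mask)
  durs <- stats::runif(n_ep, cfg$anomaly_duration_range[1L],
                       cfg$anomaly_duration_range[2L])
  durs_s <- pmax(1L, round(durs * rate_hz))
  starts <- sort(sample.int(max(1L, n - max(durs_s)), n_ep, replace = TRUE))
  for (i in seq_len(n_ep)) {
    idx <- starts[i]:min(n, starts[i] + durs_s[i] - 1L)
    mask[idx] <- TRUE
  }
  mask
}

#' Generate one subject's synthetic recording
#'
#' @param cfg A [synth_config()].
#' @param subject_index Which subject (1-based); determines the subject's
#'   random effects via a dedicated substream of `cfg$seed`.
#' @return A [signal_recording()] annotated 1 (normal) / 2 (abnormal).
#' @export
generate_recording <- function(cfg, subject_index = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- as.integer(round(cfg$duration * cfg$sample_rate))
  tt <- (seq_len(n) - 1L) / cfg$sample_rate
  ch <- cfg$n_channels

  # subject-level random effects
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); expr
  }
  sub <- withr_seed(synth_substream_seed(cfg$seed, subject_index, "subject"), {
    list(f0 = stats::runif(1, cfg$gait_freq_range[1L], cfg$gait_freq_range[2L]),
         amp = cfg$base_amplitude *
           stats::runif(ch, 0.6, 1.4),
         phase = matrix(stats::runif(ch * (cfg$n_harmonics + 1L), 0, 2 * pi),
                        nrow = cfg$n_harmonics + 1L),
         harm_w = matrix(stats::runif(ch * (cfg$n_harmonics + 1L), 0.5, 1),
                         nrow = cfg$n_harmonics + 1L),
         env_period = cfg$envelope_period * stats::runif(1, 0.7, 1.3),
         env_phase = stats::runif(1, 0, 2 * pi),
         f_anom = stats::runif(1, cfg$anomaly_freq_range[1L],
                               cfg$anomaly_freq_range[2L]))
  })

  # slow activity envelope: walking intensity drifts over the session
  env_mid <- mean(cfg$envelope_range)
  env_half <- diff(cfg$envelope_range) / 2
  envelope <- env_mid + env_half * sin(2 * pi * tt / sub$env_period +
                                         sub$env_phase)

  # gait: fundamental + decaying harmonics, per-channel phase/amplitude
  gait <- matrix(0, n, ch)
  for (c_i in seq_len(ch)) {
    sig <- 0
    for (h in 0:cfg$n_harmonics) {
      sig <- sig + sub$harm_w[h + 1L, c_i] / (h + 1) *
        sin(2 * pi * sub$f0 * (h + 1) * tt + sub$phase[h + 1L, c_i])
    }
    gait[, c_i] <- sub$amp[c_i] * envelope * sig
  }

  mask <- withr_seed(synth_substream_seed(cfg$seed, subject_index, "anomaly"),
                     place_anomaly_episodes(n, cfg$sample_rate, cfg))

  if (any(mask)) {
    a_amp <- cfg$base_amplitude * cfg$anomaly_amplitude_factor
    anom <- sapply(seq_len(ch), function(c_i)
      a_amp * sin(2 * pi * sub$f_anom * tt + sub$phase[1L, c_i] + c_i))
    if (cfg$anomaly_type == "tremor") {
      # freezing flavor: stepping halts (suppressed gait) + tremor burst
      gait[mask, ] <- cfg$gait_suppression * gait[mask, ] + anom[mask, ]
    } else {                      # stereotypy replaces the gait signal
      gait[mask, ] <- anom[mask, ]
    }
  }

  noise_scale <- rep(cfg$noise_sd, ch)
  hc_applies <- !is.null(cfg$heteroscedastic_channels) &&
    (is.null(cfg$heteroscedastic_subjects) ||
       subject_index %in% cfg$heteroscedastic_subjects)
  if (hc_applies) {
    hc <- cfg$heteroscedastic_channels
    noise_scale[as.integer(names(hc))] <- cfg$noise_sd * as.numeric(hc)
  }
  noise <- withr_seed(synth_substream_seed(cfg$seed, subject_index, "noise"),
                      matrix(stats::rnorm(n * ch), n, ch))
  samples <- gait + sweep(noise, 2L, noise_scale, `*`)

  signal_recording(samples, cfg$sample_rate,
                   ifelse(mask, 2L, 1L),
                   subject_id = paste0("S", subject_index))
}

#' Generate a multi-subject synthetic dataset
#'
#' @param cfg A [synth_config()].
#' @return List of [signal_recording()], subjects `"S1"` ... `"Sn"`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  lapply(seq_len(cfg$n_subjects), function(i) generate_recording(cfg, i))
}
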