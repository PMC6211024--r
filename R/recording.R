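#' Construct an annotated multi-channel sensor recording
#'
#' A `signal_recording` holds one subject's uniformly sampled multi-channel
#' acceleration stream together with a per-timestep integer annotation and a
#' label map giving each annotation value a role: `"excluded"` (not part of
#' the experiment), `"normal"`, or `"abnormal"`.
#'
#' @param samples Numeric matrix, time along rows, one column per channel.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param annotations Integer vector, one entry per sample row.
#' @param label_map Named list or vector mapping annotation values (as names)
#'   to one of `"excluded"`, `"normal"`, `"abnormal"`. Defaults to the
#'   Daphnet-style convention `0 = excluded, 1 = normal, 2 = abnormal`.
#' @param subject_id Subject identifier string.
#' @param channel_names Optional channel names; defaults to `ch1..chC`.
#'
#' @return An object of class `signal_recording`.
#' @export
signal_recording <- function(samples, sample_rate, annotations,
                             label_map = default_label_map(),
                             subject_id = "S1", channel_names = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar")
  if (ncol(samples) < 1L) stop("recording needs at least one channel")
  annotations <- as.integer(annotations)
  if (length(annotations) != nrow(samples))
    stop("annotations length (", length(annotations),
         ") must equal number of sample rows (", nrow(samples), ")")
  label_map <- validate_label_map(label_map)
  missing_lab <- setdiff(unique(annotations), as.integer(names(label_map)))
  if (length(missing_lab))
    stop("annotation value(s) without a label_map entry: ",
         paste(missing_lab, collapse = ", "))
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples))
    stop("channel_names length must equal channel count")
  colnames(samples) <- channel_names
  structure(
    list(subject_id = as.character(subject_id),
         sample_rate = as.numeric(sample_rate),
         channel_names = as.character(channel_names),
         samples = samples,
         annotations = annotations,
         label_map = label_map),
    class = "signal_recording")
}

#' Default Daphnet-style annotation map
#'
#' Annotation 0 marks timesteps outside the experiment (excluded from
#' windowing), 1 normal movement, 2 abnormal movement (e.g. a freezing
#' episode).
#'
#' @return Named character vector suitable for [signal_recording()].
#' @export
default_label_map <- function() {
  c(`0` = "excluded", `1` = "normal", `2` = "abnormal")
}

validate_label_map <- function(label_map) {
  lm <- unlist(label_map)
  if (is.null(names(lm)) || any(!nzchar(names(lm))))
    stop("label_map must be named by annotation value")
  if (anyNA(suppressWarnings(as.integer(names(lm)))))
    stop("label_map names must be integer annotation values")
  bad <- setdiff(lm, c("excluded", "normal", "abnormal"))
  if (length(bad))
    stop("label_map roles must be excluded/normal/abnormal, got: ",
         paste(bad, collapse = ", "))
  lm
}

#' Per-timestep annotation roles of a recording
#'
#' @param rec A [signal_recording()].
#' @return Character vector of `"excluded"`, `"normal"`, `"abnormal"`.
#' @export
annotation_roles <- function(rec) {
  stopifnot(inherits(rec, "signal_recording"))
  unname(rec$label_map[as.character(rec$annotations)])
}

#' @export
print.signal_recording <- function(x, ...) {
  roles <- annotation_roles(x)
  cat(sprintf("<signal_recording> subject %s: %d samples x %d channels @ %g Hz\n",
              x$subject_id, nrow(x$samples), ncol(x$samples), x$sample_rate))
  tab <- table(factor(roles, levels = c("excluded", "normal", "abnormal")))
  cat("  annotations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec A [signal_recording()].
#' @return Integer row count.
#' @export
n_samples <- function(rec) nrow(rec$samples)
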