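#' Read a Daphnet-style annotated accelerometer file
#'
#' Parses the space-separated text layout used by the Daphnet freezing-of-gait
#' recordings: one row per timestep with a timestamp in milliseconds, nine
#' acceleration channels (three 3-axis sensors), and one integer annotation.
#' Rows whose annotation maps to `"excluded"` are kept in the stream and only
#' flagged via the annotation; filtering happens downstream during windowing.
#'
#' @param path Path to the text file.
#' @param label_map Annotation-to-role map; see [default_label_map()].
#' @param sample_rate Declared sampling rate in Hz (Daphnet: 64).
#' @param subject_id Subject identifier; defaults to the file name.
#' @param channel_names Optional names for the 9 channels.
#' @return A [signal_recording()] with 9 channels.
#' @export
read_daphnet_file <- function(path, label_map = default_label_map(),
                              sample_rate = 64,
                              subject_id = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, comment.char = "")
  if (length(nf) == 0L) stop("empty file: ", path)
  bad <- which(nf != 11L)
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: expected 11 columns, found %d",
                 path, bad[1L], nf[bad[1L]]))
  raw <- utils::read.table(path, header = FALSE, comment.char = "")
  num <- vapply(raw, is.numeric, logical(1))
  if (!all(num)) {
    col <- which(!num)[1L]
    val <- suppressWarnings(as.numeric(as.character(raw[[col]])))
    stop(sprintf("parse error in %s at line %d: non-numeric value in column %d",
                 path, which(is.na(val))[1L], col))
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  signal_recording(as.matrix(raw[, 2:10]), sample_rate,
                   as.integer(raw[[11L]]), label_map,
                   subject_id = subject_id, channel_names = channel_names)
}

#' Write a recording in the Daphnet text layout
#'
#' Inverse of [read_daphnet_file()] for 9-channel recordings: timestamp (ms,
#' derived from the sample index and rate), 9 channels, annotation.
#'
#' @param rec A 9-channel [signal_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_daphnet_file <- function(rec, path) {
  stopifnot(inherits(rec, "signal_recording"))
  if (ncol(rec$samples) != 9L)
    stop("Daphnet layout requires exactly 9 channels")
  ts <- round((seq_len(nrow(rec$samples)) - 1L) / rec$sample_rate * 1000)
  tab <- cbind(ts, rec$samples, rec$annotations)
  utils::write.table(tab, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a generic CSV recording
#'
#' Expects a header row naming the channels plus one label column holding the
#' integer annotations.
#'
#' @param path CSV path.
#' @param sample_rate Sampling rate in Hz.
#' @param label_column Name of the annotation column.
#' @param label_map Annotation-to-role map.
#' @param subject_id Subject identifier; defaults to the file name.
#' @return A [signal_recording()].
#' @export
read_csv_recording <- function(path, sample_rate, label_column = "label",
                               label_map = default_label_map(),
                               subject_id = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty file: ", path)
  if (!label_column %in% names(tab))
    stop("label column '", label_column, "' not found in ", path)
  chans <- setdiff(names(tab), label_column)
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  signal_recording(as.matrix(tab[, chans, drop = FALSE]), sample_rate,
                   as.integer(tab[[label_column]]), label_map,
                   subject_id = subject_id, channel_names = chans)
}

#' Write a recording as CSV
#'
#' @param rec A [signal_recording()].
#' @param path Output path.
#' @param label_column Name for the annotation column.
#' @return Invisibly, `path`.
#' @export
write_csv_recording <- function(rec, path, label_column = "label") {
  df <- as.data.frame(rec$samples)
  df[[label_column]] <- rec$annotations
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Window container: flat binary array file (doubles, little-endian) plus a
# JSON metadata sidecar at <path>.json. The binary blob holds the window
# array and the abnormal fractions so numeric round trips are bitwise exact.
container_magic <- "normwear-windows-v1"

#' Save a window set to a portable container
#'
#' Writes `<path>` (binary doubles: window array then abnormal fractions) and
#' `<path>.json` (dimensions, labels, subject ids, metadata). The round trip
#' through [load_windows()] is lossless.
#'
#' @param ws A [window_set()].
#' @param path Output path for the binary blob; the JSON sidecar is written
#'   next to it.
#' @return Invisibly, `path`.
#' @export
save_windows <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  d <- dim(ws$windows)
  meta <- list(magic = container_magic, dims = as.integer(d),
               labels = ws$labels, subject_ids = ws$subject_ids,
               meta = ws$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(ws$windows), con, size = 8L, endian = "little")
  writeBin(ws$abnormal_fraction, con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a window set saved by [save_windows()]
#'
#' @param path Path given to [save_windows()].
#' @return The reconstructed [window_set()].
#' @export
load_windows <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stop("window container incomplete: need both ", path, " and ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$magic, container_magic))
    stop("not a window container (bad magic): ", side)
  d <- as.integer(meta$dims)
  n_expect <- prod(d) + d[1L]
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n_expect + 1L, size = 8L,
                  endian = "little")
  if (length(vals) != n_expect)
    stop("corrupt window container (expected ", n_expect, " doubles, read ",
         length(vals), "): ", path)
  arr <- array(vals[seq_len(prod(d))], dim = d)
  frac <- vals[prod(d) + seq_len(d[1L])]
  ws_meta <- meta$meta
  if (is.null(ws_meta)) ws_meta <- list()
  window_set(arr, as.character(meta$labels), frac,
             as.character(meta$subject_ids), as.list(ws_meta))
}
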