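#' Construct a set of fixed-length labeled windows
#'
#' A `window_set` is the unit of data the autoencoder and scoring functions
#' operate on: `n` windows of `w` timesteps by `c` channels, each carrying a
#' window-level label (`"normal"`/`"abnormal"`), the fraction of
#' abnormal-annotated timesteps it contains, and the subject it came from.
#' The flattened feature dimension is `p = w * c`.
#'
#' @param windows Numeric array `n x w x c`.
#' @param labels Character vector of `"normal"`/`"abnormal"`, length `n`.
#' @param abnormal_fraction Numeric vector in `[0, 1]`, length `n`.
#' @param subject_ids Character vector, length `n`.
#' @param meta List of provenance fields (sample rate, channel names, window
#'   seconds, labeling threshold).
#'
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, labels, abnormal_fraction, subject_ids,
                       meta = list()) {
  if (length(dim(windows)) != 3L) stop("windows must be an n x w x c array")
  storage.mode(windows) <- "double"
  n <- dim(windows)[1L]
  labels <- as.character(labels)
  subject_ids <- as.character(subject_ids)
  abnormal_fraction <- as.numeric(abnormal_fraction)
  if (length(labels) != n || length(subject_ids) != n ||
      length(abnormal_fraction) != n)
    stop("labels, abnormal_fraction and subject_ids must each have length n")
  bad <- setdiff(unique(labels), c("normal", "abnormal"))
  if (length(bad)) stop("labels must be normal/abnormal, got: ",
                        paste(bad, collapse = ", "))
  if (any(abnormal_fraction < 0 | abnormal_fraction > 1, na.rm = TRUE))
    stop("abnormal_fraction must lie in [0, 1]")
  structure(
    list(windows = windows, labels = labels,
         abnormal_fraction = abnormal_fraction,
         subject_ids = subject_ids, meta = meta),
    class = "window_set")
}

#' Number of windows in a window set
#' @param ws A [window_set()].
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1L]

#' Flattened feature dimension of a window set
#' @param ws A [window_set()].
#' @return Integer `p = w * c`.
#' @export
feature_dim <- function(ws) prod(dim(ws$windows)[2:3])

#' Flatten windows to an n x p matrix
#'
#' Each window (`w x c`) is flattened column-major (time fastest within a
#' channel), giving the `n x p` matrix the scoring functions operate on.
#'
#' @param ws A [window_set()].
#' @return Numeric matrix `n x p`.
#' @export
flatten_windows <- function(ws) {
  d <- dim(ws$windows)
  matrix(ws$windows, nrow = d[1L], ncol = d[2L] * d[3L])
}

#' Subset a window set by index
#' @param ws A [window_set()].
#' @param idx Integer or logical index over windows.
#' @return A [window_set()] containing the selected windows.
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE],
             ws$labels[idx], ws$abnormal_fraction[idx],
             ws$subject_ids[idx], ws$meta)
}

#' Concatenate window sets
#' @param ... [window_set()] objects with identical window shape.
#' @return A single combined [window_set()]; metadata taken from the first.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !inherits(sets[[1L]], "window_set"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L)
  shapes <- vapply(sets, function(s) dim(s$windows)[2:3], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("window sets have differing window shapes")
  w <- shapes[1, 1]; ch <- shapes[2, 1]
  n_tot <- sum(vapply(sets, n_windows, integer(1)))
  arr <- array(0, dim = c(n_tot, w, ch))
  at <- 1L
  for (s in sets) {
    n <- n_windows(s)
    if (n > 0L) arr[at:(at + n - 1L), , ] <- s$windows
    at <- at + n
  }
  window_set(arr,
             unlist(lapply(sets, `[[`, "labels")),
             unlist(lapply(sets, `[[`, "abnormal_fraction")),
             unlist(lapply(sets, `[[`, "subject_ids")),
             sets[[1L]]$meta)
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows of %d x %d (p = %d)\n",
              d[1], d[2], d[3], d[2] * d[3]))
  cat(sprintf("  labels: %d normal, %d abnormal; subjects: %s\n",
              sum(x$labels == "normal"), sum(x$labels == "abnormal"),
              paste(unique(x$subject_ids), collapse = ", ")))
  invisible(x)
}
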