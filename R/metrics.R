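as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("normal", "abnormal"))
    if (length(bad)) stop("labels must be normal/abnormal or 0/1")
    as.integer(labels == "abnormal")
  } else {
    labels <- as.integer(labels)
    if (any(!labels %in% c(0L, 1L))) stop("numeric labels must be 0/1")
    labels
  }
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' abnormal window outranks a randomly chosen normal one, with ties counted
#' one half.
#'
#' @param scores Numeric scores, higher = more abnormal.
#' @param labels `"normal"`/`"abnormal"` strings or 0/1 integers
#'   (1 = abnormal).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)                      # average ranks handle ties as 1/2
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over score thresholds of precision
#' times the recall increment, with no interpolation between points. Tied
#' scores form a single threshold. A constant scorer gets the abnormal
#' prevalence; a perfect ranker gets 1.
#'
#' @inheritParams auc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n_pos <- sum(y == 1L)
  if (n_pos == 0L) stop("AUPR undefined: no abnormal windows")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  # keep only the last row of each tied-score block
  last <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}
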