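#' Normative probability map (per-feature deviation z-scores)
#'
#' Computes the deviation of each test window from its MC-dropout predictive
#' distribution, per feature:
#' \deqn{Z = (X - M) / \sqrt{\max(V, \mathrm{floor})}}
#' where `M` and `V` are the predictive mean and variance. The scores are
#' z-scores: deviations in units of the predictive standard deviation. A
#' variance floor keeps the map finite where the predictive variance is
#' numerically zero. Set `denominator = "variance"` to divide by `V` itself
#' instead of its square root (ranking-equivalent when `V` is roughly
#' constant across features).
#'
#' @param X_flat Numeric `n x p` matrix of (flattened) test windows; see
#'   [flatten_windows()].
#' @param stats A `predictive_stats` object from [mc_predict()].
#' @param variance_floor Positive floor applied to `V`.
#' @param denominator `"sd"` (default) or `"variance"`.
#' @return An `n x p` matrix of class `npm_matrix`.
#' @export
npm <- function(X_flat, stats, variance_floor = 1e-6,
                denominator = c("sd", "variance")) {
  denominator <- match.arg(denominator)
  X_flat <- as.matrix(X_flat)
  if (!all(dim(X_flat) == dim(stats$M)))
    stop("shape mismatch: X is ", paste(dim(X_flat), collapse = "x"),
         " but predictive stats are ", paste(dim(stats$M), collapse = "x"))
  if (variance_floor <= 0) stop("variance_floor must be positive")
  Vf <- pmax(stats$V, variance_floor)
  Z <- if (denominator == "sd") (X_flat - stats$M) / sqrt(Vf)
       else (X_flat - stats$M) / Vf
  class(Z) <- c("npm_matrix", class(Z))
  Z
}

#' Reconstruction-error deviation map (no uncertainty weighting)
#'
#' The reconstruction-based baseline: `Z = X - M`, ignoring the predictive
#' variance. Equals [npm()] with unit variance everywhere.
#'
#' @inheritParams npm
#' @return An `n x p` matrix of class `npm_matrix`.
#' @export
reconstruction_npm <- function(X_flat, stats) {
  X_flat <- as.matrix(X_flat)
  if (!all(dim(X_flat) == dim(stats$M)))
    stop("shape mismatch: X is ", paste(dim(X_flat), collapse = "x"),
         " but predictive stats are ", paste(dim(stats$M), collapse = "x"))
  Z <- X_flat - stats$M
  class(Z) <- c("npm_matrix", class(Z))
  Z
}

#' Block-maxima summary of a deviation map
#'
#' Reduces each window's `p`-dimensional deviation map to a single extreme
#' deviation statistic: take the magnitudes (or signed values when
#' `use_abs = FALSE`), keep the `k = max(1, ceiling(top_fraction * p))`
#' largest, drop `floor(trim_fraction * k)` from each end of the sorted top
#' set, and average the rest — a trimmed mean of the top 1% by default (the
#' 90% trimmed mean when `trim_fraction = 0.05` per tail). When `k` is so
#' small that trimming would empty the set, trimming is skipped.
#'
#' @param Z An `n x p` deviation matrix (from [npm()] or
#'   [reconstruction_npm()]).
#' @param top_fraction Fraction of features in the top set.
#' @param trim_fraction Fraction trimmed from each end of the top set.
#' @param use_abs Summarize `|Z|` (default) or signed `Z`.
#' @return Numeric vector of length `n`.
#' @export
summarize_block_maxima <- function(Z, top_fraction = 0.01,
                                   trim_fraction = 0.05, use_abs = TRUE) {
  Z <- as.matrix(Z)
  if (nrow(Z) == 0L || ncol(Z) == 0L) stop("empty deviation matrix")
  p <- ncol(Z)
  k <- max(1L, as.integer(ceiling(top_fraction * p)))
  drop_k <- as.integer(floor(trim_fraction * k))
  if (2L * drop_k >= k) drop_k <- 0L
  A <- if (use_abs) abs(Z) else Z
  apply(A, 1L, function(row) {
    top <- sort(row, decreasing = TRUE)[seq_len(k)]
    if (drop_k > 0L) top <- sort(top)[(drop_k + 1L):(k - drop_k)]
    mean(top)
  })
}

#' Normative abnormality probabilities
#'
#' Fits a generalized extreme value distribution to reference summary
#' statistics (block-maxima summaries of held-out *normal* windows) and
#' evaluates its CDF at the test summaries. The resulting scores lie in
#' `[0, 1]`; higher means more abnormal. Because the CDF is monotone, score
#' rankings (hence AUC) coincide with rankings by the raw summaries.
#'
#' @param train_stats_s Numeric vector of reference summaries from normal
#'   windows never taken from the test subject.
#' @param test_s Numeric vector of test-window summaries.
#' @return An object of class `score_result` with fields `scores`, `method`
#'   and `params` (the fitted `gevd_params`).
#' @export
normative_score <- function(train_stats_s, test_s) {
  params <- fit_gevd(train_stats_s)
  scores <- gevd_cdf(params, test_s)
  structure(list(scores = scores, method = "normative", params = params),
            class = "score_result")
}

#' Fit a one-class SVM on latent encodings
#'
#' RBF-kernel one-class SVM on the `n x q` latent matrix of normal training
#' windows, the latent-space novelty baseline. Defaults follow the
#' conventional parameter-free setting `nu = 0.5`, `gamma = 1/q`.
#'
#' @param latent_train Numeric `n x q` matrix from [encode()].
#' @param nu Upper bound on the training outlier fraction.
#' @param gamma RBF kernel width; defaults to `1/q`.
#' @return An object of class `ocsvm_model`.
#' @export
fit_ocsvm <- function(latent_train, nu = 0.5, gamma = NULL) {
  latent_train <- as.matrix(latent_train)
  if (nrow(latent_train) == 0L) stop("empty latent training matrix")
  q <- ncol(latent_train)
  if (is.null(gamma)) gamma <- 1 / q
  fit <- e1071::svm(latent_train, y = NULL, type = "one-classification",
                    kernel = "radial", nu = nu, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, q = q, nu = nu, gamma = gamma),
            class = "ocsvm_model")
}

#' Score windows with a fitted one-class SVM
#'
#' Higher scores mean more abnormal (the SVM decision value is negated).
#'
#' @param model An [fit_ocsvm()] model.
#' @param latent_test Numeric `n x q` latent matrix.
#' @return An object of class `score_result`.
#' @export
ocsvm_score <- function(model, latent_test) {
  stopifnot(inherits(model, "ocsvm_model"))
  latent_test <- as.matrix(latent_test)
  if (ncol(latent_test) != model$q)
    stop("latent dimension mismatch: model expects q = ", model$q,
         ", got ", ncol(latent_test))
  dv <- attr(stats::predict(model$fit, latent_test, decision.values = TRUE),
             "decision.values")
  structure(list(scores = -as.numeric(dv), method = "ocsvm",
                 params = list(nu = model$nu, gamma = model$gamma)),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> method %s: %d windows, score range [%.4g, %.4g]\n",
              x$method, length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}
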