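fake_stats <- function(M, V, m = 10) {
  structure(list(M = M, V = V, m = m, draws = NULL),
            class = "predictive_stats")
}

test_that("deviation maps match elementwise brute force", {
  set.seed(5)
  X <- matrix(rnorm(35), 5, 7)
  M <- matrix(rnorm(35), 5, 7)
  V <- matrix(rexp(35), 5, 7)
  st <- fake_stats(M, V)
  Z <- npm(X, st, variance_floor = 1e-6)
  for (i in 1:5) for (j in 1:7)
    expect_equal(Z[i, j], (X[i, j] - M[i, j]) / sqrt(max(V[i, j], 1e-6)))
  expect_equal(unclass(npm(M, st))[, ], matrix(0, 5, 7)[, ])
  expect_equal(unclass(npm(X, fake_stats(M, matrix(1, 5, 7))))[, ], X - M)
  expect_equal(unclass(reconstruction_npm(X, st))[, ], X - M)
  expect_equal(unclass(reconstruction_npm(M, st))[, ], matrix(0, 5, 7)[, ])
  expect_error(npm(X[, 1:3], st), "mismatch")
  expect_error(reconstruction_npm(X[, 1:3], st), "mismatch")
  # variance-denominator variant for the literal form
  Zv <- npm(X, st, denominator = "variance")
  expect_equal(Zv[2, 3], (X[2, 3] - M[2, 3]) / max(V[2, 3], 1e-6))
})

test_that("block-maxima summary equals an independent sort/trim/mean oracle", {
  # constant top set
  z <- matrix(0, 1, 1000); z[1, 1:10] <- 10
  expect_equal(summarize_block_maxima(z), 10)
  expect_equal(summarize_block_maxima(matrix(0, 2, 1000)), c(0, 0))
  # randomized oracle
  brute <- function(row, top_fraction, trim_fraction) {
    p <- length(row)
    k <- max(1, ceiling(top_fraction * p))
    top <- sort(abs(row), decreasing = TRUE)[1:k]
    dk <- floor(trim_fraction * k)
    if (2 * dk >= k) dk <- 0
    mean(sort(top)[(dk + 1):(k - dk)])
  }
  set.seed(8)
  Z <- matrix(rt(6 * 500, df = 3), 6, 500)
  for (tf in c(0.01, 0.05, 0.2)) {
    got <- summarize_block_maxima(Z, top_fraction = tf, trim_fraction = 0.1)
    want <- apply(Z, 1, brute, top_fraction = tf, trim_fraction = 0.1)
    expect_equal(got, want)
  }
})

test_that("block-maxima summary is permutation-invariant and scale-equivariant", {
  set.seed(9)
  Z <- matrix(rnorm(3 * 200), 3, 200)
  s0 <- summarize_block_maxima(Z, top_fraction = 0.05)
  perm <- Z[, sample(200)]
  expect_equal(summarize_block_maxima(perm, top_fraction = 0.05), s0)
  expect_equal(summarize_block_maxima(3.5 * Z, top_fraction = 0.05), 3.5 * s0)
})

test_that("GEV distribution functions satisfy closed-form identities", {
  for (xi in c(-0.4, 0, 0.2, 0.5))
    expect_equal(pgevd(1.3, mu = 1.3, sigma = 2, xi = xi), exp(-1))
  # support clamping
  expect_equal(pgevd(-2, mu = 0, sigma = 1, xi = 0.5), 0)
  expect_equal(pgevd(-2.5, mu = 0, sigma = 1, xi = 0.5), 0)
  expect_equal(pgevd(2.1, mu = 0, sigma = 1, xi = -0.5), 1)
  # quantile/CDF inverse pair
  p <- c(0.01, 0.2, 0.5, 0.9, 0.99)
  for (xi in c(-0.3, 0, 0.4))
    expect_equal(pgevd(qgevd(p, 1, 2, xi), 1, 2, xi), p, tolerance = 1e-12)
})

test_that("GEV CDF matches quadrature of the density", {
  for (xi in c(-0.3, 0, 0.25)) {
    lower <- if (xi > 0) -1 / xi + 1e-9 else -30
    for (x in c(-1.5, -0.2, 0.7, 2.4)) {
      if (x <= lower) next
      quad <- stats::integrate(dgevd, lower, x, mu = 0, sigma = 1, xi = xi,
                               rel.tol = 1e-10, abs.tol = 1e-10)$value
      expect_equal(pgevd(x, 0, 1, xi), quad, tolerance = 1e-6)
    }
  }
})

test_that("GEV maximum likelihood recovers known parameters", {
  set.seed(77)
  s <- rgevd(5000, mu = 0, sigma = 1, xi = 0.2)
  fit <- fit_gevd(s)
  expect_gt(fit$mu, -0.1); expect_lt(fit$mu, 0.1)
  expect_gt(fit$sigma, 0.9); expect_lt(fit$sigma, 1.1)
  expect_gt(fit$xi, 0.1); expect_lt(fit$xi, 0.3)
  # MLE beats the generating parameters on its own sample
  expect_gte(fit$loglik, gevd_loglik(c(0, 1, 0.2), s))
  # location equivariance under a constant shift
  fit2 <- fit_gevd(s + 3)
  expect_equal(fit2$mu, fit$mu + 3, tolerance = 0.02)
  expect_equal(fit2$sigma, fit$sigma, tolerance = 0.02)
  expect_equal(fit2$xi, fit$xi, tolerance = 0.02)
  expect_error(fit_gevd(rep(1, 50)), "degenerate")
  expect_error(fit_gevd(s[1:10]), "at least 30")
})

test_that("normative scores are tail probabilities with monotone ranking", {
  set.seed(31)
  ref <- rgevd(400, mu = 2, sigma = 0.5, xi = 0.1)
  test_s <- c(ref[1:50], max(ref) + 10)
  sc <- normative_score(ref, test_s)
  expect_true(all(sc$scores >= 0 & sc$scores <= 1))
  expect_gt(tail(sc$scores, 1), 0.99)
  expect_equal(order(sc$scores), order(test_s))
  med <- stats::median(ref)
  sc_med <- normative_score(ref, med)
  expect_equal(sc_med$scores, 0.5, tolerance = 0.12)
})

test_that("one-class SVM flags far outliers and respects the nu bound", {
  set.seed(6)
  lat <- matrix(rnorm(300 * 4, sd = 0.3), 300, 4)
  oc <- fit_ocsvm(lat)
  expect_equal(oc$gamma, 1 / 4)
  far <- matrix(10 * 0.3, 1, 4)
  s_far <- ocsvm_score(oc, far)$scores
  s_train <- ocsvm_score(oc, lat)$scores
  expect_gt(s_far, max(s_train))
  # nu = 0.5 bounds the training outlier fraction (with slack)
  expect_lte(mean(s_train > 0), 0.55)
  # duplicate rows score identically; dimension mismatch errors
  dup <- lat[c(1, 1, 2), ]
  s_dup <- ocsvm_score(oc, dup)$scores
  expect_equal(s_dup[1], s_dup[2], tolerance = 1e-12)
  expect_error(ocsvm_score(oc, lat[, 1:3]), "mismatch")
})
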