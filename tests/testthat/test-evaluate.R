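test_that("AUC matches a quadratic pair-counting oracle, ties count half", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  auc_brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(14)
  for (i in 1:10) {
    y <- rbinom(50, 1, 0.3)
    if (sum(y) == 0 || sum(y) == 50) next
    s <- sample(rnorm(20), 50, replace = TRUE)   # duplicates force ties
    expect_equal(auc(s, y), auc_brute(s, y))
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
  expect_equal(auc(c(1, 2), c("abnormal", "normal")), 0)
})

test_that("AUPR matches the exhaustive threshold staircase", {
  expect_equal(aupr(c(5, 4, 1, 2, 3), c(1, 1, 0, 0, 0)), 1)
  pi0 <- 0.25
  expect_equal(aupr(rep(1, 20), rep(c(1, 0, 0, 0), 5)), pi0)
  aupr_brute <- function(s, y) {
    ths <- sort(unique(s), decreasing = TRUE)
    prev_rec <- 0; total <- 0
    for (th in ths) {
      sel <- s >= th
      prec <- sum(y[sel]) / sum(sel)
      rec <- sum(y[sel]) / sum(y)
      total <- total + prec * (rec - prev_rec)
      prev_rec <- rec
    }
    total
  }
  set.seed(15)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.25)
    if (sum(y) == 0) next
    s <- sample(rnorm(15), 40, replace = TRUE)
    expect_equal(aupr(s, y), aupr_brute(s, y))
  }
  expect_error(aupr(1:4, rep(0, 4)), "no abnormal")
})

test_that("aggregation reproduces hand-computed means and table shapes", {
  res <- data.frame(
    held_out_subject = rep(c("S1", "S2"), each = 2),
    method = "normative",
    repeat_index = rep(1:2, 2),
    auc = c(0.8, 0.9, 0.6, 0.7), aupr = c(0.5, 0.5, 0.3, 0.1),
    n_test_normal = 10, n_test_abnormal = 5,
    skipped = FALSE, train_subjects = "x")
  rep_ <- aggregate_report(res)
  expect_equal(rep_$per_subject$mean_auc, c(0.85, 0.65))
  expect_equal(rep_$per_subject$sd_auc,
               c(sd(c(0.8, 0.9)), sd(c(0.6, 0.7))))
  expect_equal(rep_$overall$mean_auc, 0.75)   # mean of per-subject means
  expect_equal(rep_$overall$mean_aupr, mean(c(0.5, 0.2)))
  # single repeat -> zero sd
  one <- aggregate_report(res[res$repeat_index == 1, ])
  expect_equal(one$per_subject$sd_auc, c(0, 0))
  # markdown: header + separator + subjects x methods + one mean row/method
  expect_length(strsplit(rep_$markdown, "\n")[[1]], 2 + 2 + 1)
})

test_that("LOSO is deterministic, skips single-class subjects, never leaks", {
  setup <- tiny_loso_setup()
  res <- loso_experiment(setup$dataset, setup$cfg)
  expect_true(all(!res$skipped))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  res2 <- loso_experiment(setup$dataset, setup$cfg)
  expect_equal(res$auc, res2$auc, tolerance = 1e-12)

  # held-out subject never appears in its own training pool
  for (i in seq_len(nrow(res)))
    expect_false(grepl(res$held_out_subject[i], res$train_subjects[i]))
  prov <- attr(res, "provenance")
  for (pv in prov) {
    expect_false(pv$held_out_subject %in% pv$fit_subjects)
    expect_false(pv$held_out_subject %in% pv$ref_subjects)
    expect_true(pv$fit_all_normal)
  }

  # a subject without abnormal windows is reported as skipped, not scored
  all_normal <- generate_recording(
    synth_config(n_subjects = 1, duration = 60, sample_rate = 32,
                 n_channels = 4, anomaly_type = "none", seed = 99), 1)
  all_normal$subject_id <- "S99"
  res3 <- loso_experiment(c(setup$dataset, list(all_normal)), setup$cfg)
  s99 <- res3[res3$held_out_subject == "S99", ]
  expect_true(all(s99$skipped))
  expect_true(all(is.na(s99$auc)))
})

test_that("a one-delta dropout sweep equals a plain LOSO run", {
  setup <- tiny_loso_setup(seed = 33)
  sweep <- dropout_sweep(setup$dataset, setup$cfg, deltas = 0.1)
  res <- loso_experiment(setup$dataset, setup$cfg)
  res <- res[res$method == "normative" & !res$skipped, ]
  expect_equal(nrow(sweep), 1L)
  expect_equal(sweep$mean_auc, mean(res$auc), tolerance = 1e-12)
  expect_equal(sweep$delta, 0.1)
})

test_that("rank AUC equals trapezoidal ROC integration on tie-free scores", {
  set.seed(44)
  y <- rep(c(0, 1), c(30, 20))
  s <- rnorm(50)
  roc_auc <- function(s, y) {
    ths <- c(Inf, sort(unique(s), decreasing = TRUE))
    tpr <- vapply(ths, function(t) mean(s[y == 1] >= t), numeric(1))
    fpr <- vapply(ths, function(t) mean(s[y == 0] >= t), numeric(1))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  expect_equal(auc(s, y), roc_auc(s, y), tolerance = 1e-12)
})
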