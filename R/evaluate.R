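#' Evaluation configuration for leave-one-subject-out experiments
#'
#' @param methods Subset of `c("normative", "reconstruction", "ocsvm")`.
#' @param n_repeats Number of repetitions (re-randomizing network
#'   initialization, corruption, dropout and MC draws); 5 by default so a
#'   standard deviation can be reported over the mean AUCs.
#' @param base_seed Base seed; repeat `r` uses `base_seed + r`.
#' @param m MC draws for the predictive mean/variance (default 50).
#' @param delta Dropout probability (default 0.1). Overrides only the
#'   network dropout of the DAE config; the denoising corruption level is
#'   part of the training objective and is not tied to `delta`.
#' @param train_subject_filter Optional character vector restricting the
#'   training pool to specific subjects (the "normal-only training" regime);
#'   the held-out subject is always excluded from training regardless.
#' @param preprocess A [preprocess_config()].
#' @param dae A [dae_config()]; its `dropout` and `seed` are overridden per
#'   fold by `delta` and the repeat seed.
#' @param top_fraction,trim_fraction,use_abs Block-maxima summary settings;
#'   see [summarize_block_maxima()].
#' @param reference_fraction Fraction of the pooled normal training windows
#'   held out (never shown to the autoencoder) as the GEVD reference
#'   population.
#' @param max_reference Cap on the number of reference windows (keeps the MC
#'   sampling cost of large training pools bounded).
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(methods = c("normative", "reconstruction", "ocsvm"),
                        n_repeats = 5L, base_seed = 1L, m = 50L, delta = 0.1,
                        train_subject_filter = NULL,
                        preprocess = preprocess_config(),
                        dae = dae_config(),
                        top_fraction = 0.01, trim_fraction = 0.05,
                        use_abs = TRUE,
                        reference_fraction = 0.2, max_reference = 400L) {
  methods <- match.arg(methods, c("normative", "reconstruction", "ocsvm"),
                       several.ok = TRUE)
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  if (reference_fraction <= 0 || reference_fraction >= 1)
    stop("reference_fraction must lie in (0, 1)")
  structure(list(methods = methods, n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed), m = as.integer(m),
                 delta = delta, train_subject_filter = train_subject_filter,
                 preprocess = preprocess, dae = dae,
                 top_fraction = top_fraction, trim_fraction = trim_fraction,
                 use_abs = use_abs,
                 reference_fraction = reference_fraction,
                 max_reference = as.integer(max_reference)),
            class = "eval_config")
}

score_fold_methods <- function(model, train_ws, ref_ws, test_ws, cfg) {
  out <- list()
  need_mc <- any(c("normative", "reconstruction") %in% cfg$methods)
  if (need_mc) {
    ps_ref <- mc_predict(model, ref_ws, m = cfg$m)
    ps_test <- mc_predict(model, test_ws, m = cfg$m)
    Xr <- flatten_windows(ref_ws)
    Xt <- flatten_windows(test_ws)
    if ("normative" %in% cfg$methods) {
      s_ref <- summarize_block_maxima(npm(Xr, ps_ref),
                                      cfg$top_fraction, cfg$trim_fraction,
                                      cfg$use_abs)
      s_test <- summarize_block_maxima(npm(Xt, ps_test),
                                       cfg$top_fraction, cfg$trim_fraction,
                                       cfg$use_abs)
      out$normative <- normative_score(s_ref, s_test)
    }
    if ("reconstruction" %in% cfg$methods) {
      s_ref <- summarize_block_maxima(reconstruction_npm(Xr, ps_ref),
                                      cfg$top_fraction, cfg$trim_fraction,
                                      cfg$use_abs)
      s_test <- summarize_block_maxima(reconstruction_npm(Xt, ps_test),
                                       cfg$top_fraction, cfg$trim_fraction,
                                       cfg$use_abs)
      out$reconstruction <- normative_score(s_ref, s_test)
      out$reconstruction$method <- "reconstruction"
    }
  }
  if ("ocsvm" %in% cfg$methods) {
    oc <- fit_ocsvm(encode(model, train_ws))
    out$ocsvm <- ocsvm_score(oc, encode(model, test_ws))
  }
  out
}

#' Leave-one-subject-out novelty-detection experiment
#'
#' For each held-out subject and each repetition: pool the pure-normal
#' windows of the remaining subjects (or of `train_subject_filter`), split
#' off a GEVD reference set, fit the per-channel standardizer and the
#' denoising autoencoder on the remaining training windows, score every
#' window of the held-out subject with each requested method, and compute
#' AUC and AUPR against the window labels. Subjects whose windows are
#' single-class cannot be scored and are reported as skipped. No window of
#' the held-out subject ever enters training, standardization or the GEVD
#' reference population.
#'
#' @param dataset List of [signal_recording()] (>= 2 subjects).
#' @param cfg An [eval_config()].
#' @param verbose Print fold progress?
#' @return A data frame of fold results (one row per held-out subject,
#'   method and repeat) with columns `held_out_subject`, `method`,
#'   `repeat_index`, `auc`, `aupr`, `n_test_normal`, `n_test_abnormal`,
#'   `skipped`, `train_subjects`. The `"provenance"` attribute records, per
#'   fold, which subjects' windows entered autoencoder fitting and the GEVD
#'   reference set, for leakage auditing.
#' @export
loso_experiment <- function(dataset, cfg = eval_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "eval_config"))
  if (length(dataset) < 2L) stop("need at least 2 subjects for LOSO")
  subjects <- vapply(dataset, `[[`, character(1), "subject_id")
  if (anyDuplicated(subjects)) stop("duplicate subject ids in dataset")
  wsets <- lapply(dataset, preprocess_recording, cfg = cfg$preprocess)
  names(wsets) <- subjects

  rows <- list()
  prov <- list()   # per-fold subject bookkeeping (leakage audit)
  for (rep_i in seq_len(cfg$n_repeats)) {
    seed_r <- cfg$base_seed + rep_i
    for (held in subjects) {
      pool_ids <- setdiff(
        if (is.null(cfg$train_subject_filter)) subjects
        else intersect(subjects, cfg$train_subject_filter),
        held)
      if (length(pool_ids) == 0L)
        stop("no training subjects left for held-out subject ", held)
      train_all <- bind_windows(wsets[pool_ids])
      train_all <- select_normal_training(train_all,
                                          cfg$preprocess$training_purity)
      test_ws <- wsets[[held]]
      n_ab <- sum(test_ws$labels == "abnormal")
      n_no <- sum(test_ws$labels == "normal")
      if (n_ab == 0L || n_no == 0L) {
        for (meth in cfg$methods)
          rows[[length(rows) + 1L]] <- data.frame(
            held_out_subject = held, method = meth, repeat_index = rep_i,
            auc = NA_real_, aupr = NA_real_,
            n_test_normal = n_no, n_test_abnormal = n_ab, skipped = TRUE,
            train_subjects = paste(pool_ids, collapse = "+"))
        next
      }
      # held-out reference split for the GEVD (never used to fit the DAE)
      set.seed(seed_r)
      n_tr <- n_windows(train_all)
      n_ref <- min(max(30L, round(cfg$reference_fraction * n_tr)),
                   cfg$max_reference, n_tr - 1L)
      ref_idx <- sample.int(n_tr, n_ref)
      ref_ws <- subset_windows(train_all, ref_idx)
      fit_ws <- subset_windows(train_all, setdiff(seq_len(n_tr), ref_idx))

      prov[[length(prov) + 1L]] <- list(
        repeat_index = rep_i, held_out_subject = held,
        fit_subjects = unique(fit_ws$subject_ids),
        ref_subjects = unique(ref_ws$subject_ids),
        fit_all_normal = all(fit_ws$abnormal_fraction <=
                               1 - cfg$preprocess$training_purity + 1e-12))
      std <- fit_standardizer(fit_ws)
      fit_ws <- apply_standardizer(fit_ws, std)
      ref_ws <- apply_standardizer(ref_ws, std)
      test_std <- apply_standardizer(test_ws, std)

      # delta controls the network dropout only; the denoising corruption
      # level is part of the training objective and stays at its configured
      # value, so a dropout sweep varies the uncertainty estimator alone
      dcfg <- cfg$dae
      dcfg$dropout <- cfg$delta
      dcfg$seed <- seed_r
      w_len <- dim(fit_ws$windows)[2L]
      ch <- dim(fit_ws$windows)[3L]
      model <- build_dae(dcfg, c(w_len, ch))
      model <- train_dae(model, fit_ws)
      set.seed(seed_r + 7L)
      scored <- score_fold_methods(model, fit_ws, ref_ws, test_std, cfg)
      for (meth in names(scored)) {
        sc <- scored[[meth]]$scores
        rows[[length(rows) + 1L]] <- data.frame(
          held_out_subject = held, method = meth, repeat_index = rep_i,
          auc = auc(sc, test_ws$labels), aupr = aupr(sc, test_ws$labels),
          n_test_normal = n_no, n_test_abnormal = n_ab, skipped = FALSE,
          train_subjects = paste(pool_ids, collapse = "+"))
        if (verbose)
          message(sprintf("repeat %d, held-out %s, %s: AUC %.3f",
                          rep_i, held, meth,
                          rows[[length(rows)]]$auc))
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "provenance") <- prov
  res
}

#' Dropout sensitivity sweep
#'
#' Runs [loso_experiment()] at each dropout level and aggregates the
#' normative-method AUC.
#'
#' @param dataset List of [signal_recording()].
#' @param cfg An [eval_config()].
#' @param deltas Dropout probabilities to evaluate.
#' @return Data frame with columns `delta`, `mean_auc`, `sd_auc` (mean and
#'   sd over scored folds and repeats).
#' @export
dropout_sweep <- function(dataset, cfg = eval_config(),
                          deltas = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  if (length(deltas) == 0L) stop("deltas must be non-empty")
  rows <- lapply(deltas, function(d) {
    cfg_d <- cfg
    cfg_d$delta <- d
    res <- loso_experiment(dataset, cfg_d)
    res <- res[res$method == "normative" & !res$skipped, ]
    data.frame(delta = d, mean_auc = mean(res$auc), sd_auc = stats::sd(res$auc))
  })
  do.call(rbind, rows)
}

#' Aggregate fold results into per-subject and overall tables
#'
#' Per subject and method, the mean and standard deviation of AUC/AUPR over
#' repeats; the overall row per method is the unweighted mean of the
#' per-subject means.
#'
#' @param results Fold table from [loso_experiment()].
#' @return List with `per_subject` and `overall` data frames and a
#'   `markdown` character rendering of the per-subject table.
#' @export
aggregate_report <- function(results) {
  if (nrow(results) == 0L) stop("empty results table")
  scored <- results[!results$skipped, ]
  agg <- do.call(rbind, lapply(
    split(scored, list(scored$held_out_subject, scored$method), drop = TRUE),
    function(g) data.frame(
      held_out_subject = g$held_out_subject[1L], method = g$method[1L],
      mean_auc = mean(g$auc), sd_auc = ifelse(nrow(g) > 1, stats::sd(g$auc), 0),
      mean_aupr = mean(g$aupr),
      sd_aupr = ifelse(nrow(g) > 1, stats::sd(g$aupr), 0))))
  rownames(agg) <- NULL
  agg <- agg[order(agg$method, agg$held_out_subject), ]
  overall <- do.call(rbind, lapply(split(agg, agg$method), function(g)
    data.frame(method = g$method[1L],
               mean_auc = mean(g$mean_auc), mean_aupr = mean(g$mean_aupr))))
  rownames(overall) <- NULL
  md <- c("| subject | method | AUC (mean ± sd) | AUPR (mean ± sd) |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %.3f ± %.3f | %.3f ± %.3f |",
                  agg$held_out_subject, agg$method,
                  agg$mean_auc, agg$sd_auc, agg$mean_aupr, agg$sd_aupr),
          sprintf("| Mean | %s | %.3f | %.3f |",
                  overall$method, overall$mean_auc, overall$mean_aupr))
  list(per_subject = agg, overall = overall, markdown = paste(md, collapse = "\n"))
}

#' Write an aggregated report to disk
#'
#' @param report Output of [aggregate_report()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "per_subject.csv")
  p2 <- file.path(dir, "overall.csv")
  p3 <- file.path(dir, "report.md")
  utils::write.csv(report$per_subject, p1, row.names = FALSE)
  utils::write.csv(report$overall, p2, row.names = FALSE)
  writeLines(report$markdown, p3)
  invisible(c(p1, p2, p3))
}
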