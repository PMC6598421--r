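#' Plan a k-fold partition
#'
#' Uniformly shuffles `1:n` under the seed and cuts the shuffled order
#' into `k` contiguous, near-equal folds (sizes differ by at most 1);
#' every index is assigned to exactly one fold.
#'
#' @param n Number of examples (`n >= k`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `k`, `assignments` (integer vector of
#'   fold ids, one per example) and `seed`.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  stopifnot(k >= 2)
  if (n < k) stop("need at least as many examples as folds (n=", n,
                  ", k=", k, ")")
  # salt the seed so the shuffle stream is independent of other consumers
  # of the same top-level seed (e.g. the corpus generator)
  perm <- with_seed(salt_seed(seed, 101L), sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignments <- integer(n)
  assignments[perm] <- rep(seq_len(k), times = sizes)
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed)), class = "fold_plan")
}

#' Classification metrics in percent
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, and AUC
#' -- the probability that a randomly chosen positive example is scored
#' above a randomly chosen negative one (ties counting one half) --
#' computed by the rank (Mann-Whitney) formula. All values are reported
#' on the 0-100 percent scale. A zero denominator defines the affected
#' metric as 0 with a warning; with single-class labels the AUC is
#' undefined and reported as `NA`.
#'
#' @param labels True binary labels.
#' @param pred_labels Predicted binary labels.
#' @param probs Optional predicted probabilities (needed for AUC).
#' @return Named list `precision`, `recall`, `f1`, `auc` (percent).
#' @export
compute_metrics <- function(labels, pred_labels, probs = NULL) {
  stopifnot(length(labels) == length(pred_labels))
  tp <- sum(labels == 1 & pred_labels == 1)
  fp <- sum(labels == 0 & pred_labels == 1)
  fn <- sum(labels == 1 & pred_labels == 0)
  precision <- if (tp + fp == 0) {
    warning("no positive predictions; precision defined as 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    warning("no positive labels; recall defined as 0")
    0
  } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  auc <- NA_real_
  if (!is.null(probs)) {
    stopifnot(length(probs) == length(labels))
    n1 <- sum(labels == 1)
    n0 <- sum(labels == 0)
    if (n1 == 0 || n0 == 0) {
      auc <- NA_real_  # undefined for single-class labels
    } else {
      r <- rank(probs)  # average ranks handle ties as 1/2
      auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(precision = 100 * precision, recall = 100 * recall, f1 = 100 * f1,
       auc = 100 * auc)
}

fold_seeds <- function(seed, k) {
  with_seed(salt_seed(seed, 202L), sample.int(2^20, k))
}

stratified_split <- function(labels, train_frac, seed) {
  with_seed(seed, {
    tr <- logical(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_tr <- max(1L, round(train_frac * length(idx)))
      if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
      if (n_tr < 1L) n_tr <- 1L
      tr[sample(idx, n_tr)] <- TRUE
    }
    tr
  })
}

subset_encoded <- function(enc, idx) {
  structure(list(text = enc$text[idx, , drop = FALSE],
                 hash = enc$hash[idx, , drop = FALSE],
                 label = enc$label[idx], post_id = enc$post_id[idx]),
            class = "encoded_examples")
}

#' Cross-validate one model on one dataset variant
#'
#' For each fold the model is reset and trained on the other `k - 1`
#' folds; the deep model further splits its training folds into a
#' stratified 70% training / 30% validation set used only for
#' early stopping. The held-out fold is predicted, so every example
#' receives exactly one out-of-fold prediction. Under the default
#' `vocab_scope = "train_only"` the dictionary is rebuilt from the
#' training folds of each iteration; `"full_corpus"` builds it once on
#' the whole variant. Precision/recall/F1 are computed from the pooled
#' out-of-fold predictions (or averaged per fold with
#' `metric_aggregation = "fold_mean"`); AUC is computed from pooled
#' out-of-fold probabilities over the whole dataset
#' (`auc_mode = "pooled_oof"`) or, for the literal train-on-everything
#' reading, by refitting on the full dataset and scoring it
#' (`auc_mode = "resubstitution"`).
#'
#' @param variant A `dataset_variant` from [make_variants()].
#' @param model One of `"deep"`, `"decision_tree"`, `"random_forest"`,
#'   `"svm"`.
#' @param plan A [make_folds()] plan covering the variant.
#' @param config A [model_config()].
#' @param metric_aggregation `"pooled"` (default) or `"fold_mean"`.
#' @param auc_mode `"pooled_oof"` (default) or `"resubstitution"`.
#' @param verbose Print fold progress.
#' @return List with `metrics` (precision/recall/f1/auc, percent),
#'   `oof` (data.frame `post_id,label,prob,pred,fold`), `model`,
#'   `variant`.
#' @export
cross_validate <- function(variant, model, plan, config = model_config(),
                           metric_aggregation = c("pooled", "fold_mean"),
                           auc_mode = c("pooled_oof", "resubstitution"),
                           verbose = FALSE) {
  metric_aggregation <- match.arg(metric_aggregation)
  auc_mode <- match.arg(auc_mode)
  posts <- variant$posts
  n <- length(posts)
  stopifnot(length(plan$assignments) == n)
  labels <- vapply(posts, function(p) as.integer(p$label), integer(1))
  if (anyNA(labels)) stop("variant must be fully labeled")
  seeds <- fold_seeds(config$seed, plan$k + 1L)
  full_vocab <- if (config$vocab_scope == "full_corpus") {
    build_vocabulary(posts)
  }
  prob <- pred <- rep(NA_real_, n)
  for (f in seq_len(plan$k)) {
    test_idx <- which(plan$assignments == f)
    train_idx <- which(plan$assignments != f)
    res <- tryCatch(
      run_fold(posts, labels, train_idx, test_idx, model, config,
               full_vocab, seeds[f]),
      error = function(e) stop(sprintf("model '%s' failed in fold %d: %s",
                                       model, f, conditionMessage(e)),
                               call. = FALSE))
    prob[test_idx] <- res$prob
    pred[test_idx] <- res$label
    if (verbose) message(sprintf("fold %d/%d done", f, plan$k))
  }
  oof <- data.frame(
    post_id = vapply(posts, function(p) p$post_id, character(1)),
    label = labels, prob = prob, pred = as.integer(pred),
    fold = plan$assignments)
  if (metric_aggregation == "pooled") {
    metrics <- compute_metrics(labels, pred, prob)
  } else {
    per_fold <- lapply(seq_len(plan$k), function(f) {
      idx <- plan$assignments == f
      suppressWarnings(compute_metrics(labels[idx], pred[idx]))
    })
    metrics <- list(
      precision = mean(vapply(per_fold, `[[`, numeric(1), "precision")),
      recall = mean(vapply(per_fold, `[[`, numeric(1), "recall")),
      f1 = mean(vapply(per_fold, `[[`, numeric(1), "f1")),
      auc = NA_real_)
  }
  if (auc_mode == "pooled_oof") {
    if (metric_aggregation != "pooled") {
      metrics$auc <- compute_metrics(labels, pred, prob)$auc
    }
  } else {
    all_idx <- seq_len(n)
    res <- run_fold(posts, labels, all_idx, all_idx, model, config,
                    full_vocab, seeds[plan$k + 1L])
    r <- rank(res$prob)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    metrics$auc <- 100 * (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) /
      (n1 * n0)
  }
  list(model = model, variant = variant$name, metrics = metrics, oof = oof)
}

run_fold <- function(posts, labels, train_idx, test_idx, model, config,
                     full_vocab, seed) {
  vocab <- if (is.null(full_vocab)) build_vocabulary(posts[train_idx]) else
    full_vocab
  if (model == "deep") {
    cfg <- config
    cfg$seed <- as.integer(seed)
    variant_like <- list(posts = posts)
    enc_all <- encode_variant(structure(variant_like,
                                        class = "dataset_variant"),
                              vocab, cfg)
    enc_train <- subset_encoded(enc_all, train_idx)
    enc_test <- subset_encoded(enc_all, test_idx)
    in_train <- stratified_split(enc_train$label, 0.7, seed + 17L)
    net <- build_deep_model(cfg, vocab$size + 1L)
    net <- train_deep(net, subset_encoded(enc_train, which(in_train)),
                      subset_encoded(enc_train, which(!in_train)), cfg)
    out <- predict(net, enc_test)
  } else {
    x_train <- term_features(posts[train_idx], vocab,
                             config$baseline_features)
    x_test <- term_features(posts[test_idx], vocab,
                            config$baseline_features)
    fit <- train_baseline(model, x_train, labels[train_idx], seed = seed)
    out <- predict(fit, x_test, threshold = config$decision_threshold)
  }
  out
}

#' Compare all models across the three ablation variants
#'
#' Runs [cross_validate()] for each requested model on each of the three
#' dataset variants and assembles the 12-row comparison table
#' (model x variant with precision, recall, F1 and AUC in percent).
#'
#' @param clean_corpus Labeled cleaned corpus from [clean_posts()].
#' @param models Character vector of model kinds.
#' @param k Number of folds (default 10).
#' @param config A [model_config()].
#' @param seed Seed for the fold plans.
#' @param verbose Print progress.
#' @return List with `report` (data.frame: model, variant, precision,
#'   recall, f1, auc) and `oof` (named list of out-of-fold prediction
#'   frames, one per report row).
#' @export
compare_variants <- function(clean_corpus,
                             models = c("deep", "decision_tree",
                                        "random_forest", "svm"),
                             k = 10L, config = model_config(),
                             seed = 7L, verbose = FALSE) {
  variants <- make_variants(clean_corpus)
  rows <- list()
  oof <- list()
  for (v in variants) {
    plan <- make_folds(length(v$posts), k, seed)
    for (m in models) {
      if (verbose) message(sprintf("evaluating %s on %s ...", m, v$name))
      cv <- cross_validate(v, m, plan, config)
      key <- paste(m, v$name, sep = ".")
      oof[[key]] <- cv$oof
      rows[[key]] <- data.frame(
        model = m, variant = v$name,
        precision = cv$metrics$precision, recall = cv$metrics$recall,
        f1 = cv$metrics$f1, auc = cv$metrics$auc)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report, oof = oof)
}

#' Write the comparison report and out-of-fold predictions
#'
#' The report CSV mirrors the model-by-variant table (percentages to two
#' decimals); each out-of-fold frame is written as
#' `oof_<model>_<variant>.csv`.
#'
#' @param result Output of [compare_variants()].
#' @param dir Output directory.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep2 <- result$report
  for (col in c("precision", "recall", "f1", "auc")) {
    rep2[[col]] <- round(rep2[[col]], 2)
  }
  utils::write.csv(rep2, file.path(dir, "report.csv"), row.names = FALSE)
  for (key in names(result$oof)) {
    utils::write.csv(result$oof[[key]],
                     file.path(dir, paste0("oof_", gsub("\\.", "_", key),
                                           ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
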