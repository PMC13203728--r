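#' Evaluate predictions against labels
#'
#' Computes the primary metrics: overall accuracy (%), support-weighted mean
#' of per-class F1 scores (%), and the row-normalized confusion matrix
#' (rows = true class, each row summing to 1 where its support is
#' positive).
#'
#' @param truth character vector of true labels.
#' @param predicted character vector of predicted labels.
#' @param levels class ordering for the confusion matrix.
#' @return an object of class `eval_report` with `accuracy`, `weighted_f1`
#'   (both in percent), `confusion` (row-normalized), `counts` (raw
#'   confusion counts) and `support`.
#' @export
eval_report <- function(truth, predicted, levels = SMR_CLASSES) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  unknown <- setdiff(unique(truth), levels)
  if (length(unknown) > 0) {
    stop("labels outside the class set: ", paste(unknown, collapse = ", "))
  }
  t_f <- factor(truth, levels = levels)
  p_f <- factor(predicted, levels = levels)
  counts <- table(truth = t_f, predicted = p_f)
  support <- rowSums(counts)
  accuracy <- 100 * sum(diag(counts)) / length(truth)
  f1 <- vapply(seq_along(levels), function(k) {
    tp <- counts[k, k]
    prec <- if (sum(counts[, k]) > 0) tp / sum(counts[, k]) else 0
    rec <- if (support[k] > 0) tp / support[k] else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  weighted_f1 <- 100 * sum(f1 * support) / sum(support)
  confusion <- counts / pmax(support, 1)
  structure(list(accuracy = accuracy, weighted_f1 = weighted_f1,
                 confusion = unclass(confusion), counts = unclass(counts),
                 support = support, f1 = 100 * f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%%  weighted F1 %.2f%%  (n = %d)\n",
              x$accuracy, x$weighted_f1, sum(x$support)))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Evaluate a decoder on a labeled epoch set
#'
#' @param model a `conformer_model`.
#' @param test an [epoch_set()] with labels.
#' @param normalize apply the checkpoint's normalization statistics first.
#' @return an [eval_report()].
#' @export
evaluate_model <- function(model, test, normalize = !is.null(model$norm_stats)) {
  if (n_epochs(test) == 0) stop("test set is empty")
  pred <- predict_classes(model, test, normalize)
  eval_report(test$labels, pred, levels = model$class_levels)
}

#' Offline pre-training with AO-aware cross-validation
#'
#' The full offline pipeline on one recording: filter chain, fold plan,
#' per-fold augmentation (after partitioning), per-fold normalization
#' statistics (training portion only), decoder training and MI-only
#' evaluation; finally a deployment model refit on the whole dataset.
#'
#' @param recording the raw offline [eeg_recording()].
#' @param model_cfg a [model_config()]; `n_samples` must match the epoch
#'   length after downsampling.
#' @param train_cfg a [train_config()] (offline phase).
#' @param n_folds number of folds (default 5).
#' @param target_rate epoch sampling rate after decimation (default 250).
#' @param aug an [augmentation_spec()].
#' @param seed master seed; fold assignment, initialization and shuffling
#'   derive from it.
#' @param refit also train the deployment model on all data (default TRUE).
#' @return list with `fold_reports` (one [eval_report()] per fold),
#'   `mean_accuracy`, `mean_weighted_f1`, and `model` (the deployment
#'   checkpoint with its `norm_stats`, or NULL when `refit = FALSE`).
#' @export
pretrain_cv <- function(recording, model_cfg = model_config(),
                        train_cfg = train_config("offline"),
                        n_folds = 5, target_rate = 250,
                        aug = augmentation_spec(), seed = 1L,
                        refit = TRUE) {
  filtered <- offline_filter_chain(recording)
  trials <- unique(filtered$events[, c("trial_id", "class", "kind")])
  plan <- make_fold_plan(trials, n_folds, seed = seed)
  reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- augment_epochs(filtered, plan[[f]]$train_ids, aug, seed = seed + f)
    te <- augment_epochs(filtered, plan[[f]]$test_ids, aug, seed = seed + f)
    tr <- downsample_epochs(tr, target_rate)
    te <- downsample_epochs(te, target_rate)
    stats <- zscore_fit(tr)
    model <- conformer_init(model_cfg, seed = seed)
    cfg_f <- train_cfg
    cfg_f$seed <- train_cfg$seed + f
    model <- fit_conformer(model, zscore_apply(tr, stats), cfg_f)
    model$norm_stats <- stats
    reports[[f]] <- evaluate_model(model, te)
  }
  final <- NULL
  if (refit) {
    all_tr <- augment_epochs(filtered, trials$trial_id, aug, seed = seed)
    all_tr <- downsample_epochs(all_tr, target_rate)
    stats <- zscore_fit(all_tr)
    final <- conformer_init(model_cfg, seed = seed)
    final <- fit_conformer(final, zscore_apply(all_tr, stats), train_cfg)
    final$norm_stats <- stats
  }
  list(fold_reports = reports,
       mean_accuracy = mean(vapply(reports, `[[`, 1, "accuracy")),
       mean_weighted_f1 = mean(vapply(reports, `[[`, 1, "weighted_f1")),
       model = final)
}
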