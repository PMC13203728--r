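#' AO-aware stratified cross-validation plan
#'
#' Only the pure motor-imagery (MI) trials are partitioned into folds,
#' stratified by class; every AO+MI trial joins the training set of every
#' fold, because the online deployment phase is scored exclusively on MI.
#' With the canonical 90 AO + 45 MI trials per class, each fold trains on
#' 126 trials and tests on 9 per class.
#'
#' @param trials data.frame with columns `trial_id`, `class`, `kind`
#'   (`"MI"` for pure MI; anything else is treated as AO-side and kept in
#'   training).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the stratified shuffle.
#' @return an object of class `fold_plan`: a list of `n_folds` elements,
#'   each with `train_ids` and `test_ids` (trial ids). Test partitions are
#'   MI-only, disjoint and exhaustive over MI trials.
#' @export
make_fold_plan <- function(trials, n_folds = 5, seed = 1L) {
  stopifnot(all(c("trial_id", "class", "kind") %in% names(trials)))
  mi <- trials[trials$kind == "MI", , drop = FALSE]
  ao_ids <- trials$trial_id[trials$kind != "MI"]
  counts <- table(mi$class)
  short <- names(counts)[counts < n_folds]
  if (nrow(mi) == 0 || length(short) > 0) {
    stop("insufficient MI trials for ", n_folds, "-fold CV in class(es): ",
         paste(if (nrow(mi) == 0) unique(trials$class) else short,
               collapse = ", "))
  }
  with_seed(seed, {
    test_sets <- vector("list", n_folds)
    for (cls in unique(mi$class)) {
      ids <- sample(mi$trial_id[mi$class == cls])
      fold_of <- rep(seq_len(n_folds), length.out = length(ids))
      for (f in seq_len(n_folds)) {
        test_sets[[f]] <- c(test_sets[[f]], ids[fold_of == f])
      }
    }
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- sort(test_sets[[f]])
      list(train_ids = sort(c(ao_ids, setdiff(mi$trial_id, test))),
           test_ids = test)
    })
    structure(folds, class = "fold_plan", n_folds = n_folds)
  })
}

#' Sliding-segment augmentation specification
#'
#' Movement-class trials yield `n_segments` overlapping windows of
#' `segment_s` seconds starting at the event trigger and advancing by
#' `step_s`; rest segments are anchored `rest_offset_s` seconds before the
#' trigger. Augmentation is applied only *after* train/test partitioning so
#' no augmented sample spans the partition boundary.
#'
#' @param n_segments segments per trial (default 5).
#' @param segment_s segment length in seconds (default 2).
#' @param step_s inter-segment offset in seconds (default 0.1).
#' @param rest_offset_s rest-class anchor relative to the trigger (default
#'   -3).
#' @return an object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(n_segments = 5, segment_s = 2, step_s = 0.1,
                              rest_offset_s = -3) {
  structure(list(n_segments = n_segments, segment_s = segment_s,
                 step_s = step_s, rest_offset_s = rest_offset_s),
            class = "augmentation_spec")
}

#' Extract augmented epochs for a set of trials
#'
#' For each selected movement trial, cuts `n_segments` overlapping segments
#' anchored at the event trigger (consecutive segments share
#' `segment_s - step_s` seconds). Optionally adds rest-class segments
#' anchored `rest_offset_s` before each trial's trigger, and balances the
#' rest class down to the mean movement-class count by seeded random
#' subsampling (rest candidates are otherwise about three times as
#' abundant). Segments that would leave the recording are skipped with a
#' warning.
#'
#' @param recording the source [eeg_recording()] (filtered).
#' @param trial_ids trial ids to draw from (e.g. one fold's training ids).
#' @param spec an [augmentation_spec()].
#' @param include_rest also cut rest-class segments (default TRUE).
#' @param balance_rest subsample rest to the mean movement-class count
#'   (default TRUE).
#' @param seed seed for the rest subsample.
#' @return an [epoch_set()]; `meta$offset_s` records each segment's offset.
#' @export
augment_epochs <- function(recording, trial_ids, spec = augmentation_spec(),
                           include_rest = TRUE, balance_rest = TRUE,
                           seed = 1L) {
  ev <- recording$events
  ev <- ev[ev$trial_id %in% trial_ids, , drop = FALSE]
  if ("attempt" %in% names(ev)) ev <- ev[ev$attempt == 1, , drop = FALSE]
  pieces <- list()
  for (i in seq_len(spec$n_segments)) {
    off <- (i - 1) * spec$step_s
    pieces[[i]] <- suppressWarnings(
      extract_epochs(recording, spec$segment_s, off, events = ev))
  }
  if (include_rest) {
    for (i in seq_len(spec$n_segments)) {
      off <- spec$rest_offset_s + (i - 1) * spec$step_s
      pieces[[spec$n_segments + i]] <- suppressWarnings(
        extract_epochs(recording, spec$segment_s, off, events = ev,
                       label = "rest"))
    }
  }
  kept <- sum(vapply(pieces, n_epochs, 1L))
  expected <- nrow(ev) * spec$n_segments * (1L + include_rest)
  if (kept < expected) {
    warning(expected - kept, " augmented segment(s) fell outside the ",
            "recording and were skipped")
  }
  out <- do.call(bind_epochs, pieces)
  if (include_rest && balance_rest) {
    is_rest <- out$labels == "rest"
    n_move <- table(out$labels[!is_rest])
    target <- round(mean(n_move))
    if (sum(is_rest) > target) {
      with_seed(seed, {
        keep_rest <- sample(which(is_rest), target)
        out <- subset_epochs(out, sort(c(which(!is_rest), keep_rest)))
      })
    }
  }
  out
}
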