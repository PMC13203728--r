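make_trials <- function(n_ao = 90, n_mi = 45,
                        classes = SMR_MOVEMENT_CLASSES) {
  do.call(rbind, lapply(seq_along(classes), function(k) {
    n <- n_ao + n_mi
    data.frame(trial_id = (k - 1) * n + seq_len(n), class = classes[k],
               kind = rep(c("AO+MI", "MI"), c(n_ao, n_mi)))
  }))
}

test_that("the AO-aware fold plan reproduces the canonical 126/9 split", {
  trials <- make_trials(90, 45, classes = "left_hand")
  fp <- make_fold_plan(trials, 5, seed = 1)
  for (f in 1:5) {
    expect_equal(length(fp[[f]]$train_ids), 126)
    expect_equal(length(fp[[f]]$test_ids), 9)
  }
})

test_that("fold test sets are MI-only, disjoint and exhaustive", {
  trials <- make_trials(12, 10)
  fp <- make_fold_plan(trials, 5, seed = 2)
  mi_ids <- trials$trial_id[trials$kind == "MI"]
  ao_ids <- trials$trial_id[trials$kind == "AO+MI"]
  all_test <- unlist(lapply(fp, `[[`, "test_ids"))
  expect_equal(sort(all_test), sort(mi_ids))       # exhaustive, no dupes
  expect_equal(anyDuplicated(all_test), 0)
  for (f in 1:5) {
    expect_true(all(ao_ids %in% fp[[f]]$train_ids)) # AO always trains
    expect_length(intersect(fp[[f]]$train_ids, fp[[f]]$test_ids), 0)
    # class stratification: 2 MI test trials per class per fold
    cls <- trials$class[match(fp[[f]]$test_ids, trials$trial_id)]
    expect_true(all(table(cls) == 2))
  }
})

test_that("fold assignment is seed-stable, seeds differ, shortages error", {
  trials <- make_trials(6, 10)
  a <- make_fold_plan(trials, 5, seed = 3)
  b <- make_fold_plan(trials, 5, seed = 3)
  expect_identical(a, b)
  c <- make_fold_plan(trials, 5, seed = 4)
  expect_false(identical(lapply(a, `[[`, "test_ids"),
                         lapply(c, `[[`, "test_ids")))
  short <- make_trials(6, 3)
  expect_error(make_fold_plan(short, 5), "left_hand")
})

test_that("augmentation cuts five overlapping segments per trial", {
  plan <- build_offline_protocol(1, seed = 5)
  rec <- synthesize_recording(tiny_sim_config(seed = 6), plan)
  ids <- plan$trial_id[plan$class == "left_hand"]   # 9 trials
  ep <- augment_epochs(rec, ids, include_rest = FALSE)
  expect_equal(n_epochs(ep), 9 * 5)
  # segments i and i+1 share exactly segment - step seconds of samples
  one <- subset_epochs(ep, which(ep$meta$trial_id == ids[1]))
  ord <- order(one$meta$offset_s)
  fs <- rec$sampling_rate
  shift <- round(0.1 * fs)
  a <- one$data[, , ord[1]]
  b <- one$data[, , ord[2]]
  expect_equal(a[, (shift + 1):(2 * fs)], b[, 1:(2 * fs - shift)],
               tolerance = 1e-12)
  # n_segments = 1 with zero offset is plain epoching
  plain <- augment_epochs(rec, ids, augmentation_spec(n_segments = 1),
                          include_rest = FALSE)
  direct <- extract_epochs(rec, 2, 0,
                           events = rec$events[rec$events$trial_id %in% ids, ])
  expect_equal(plain$data, direct$data)
})

test_that("rest segments are anchored pre-trigger and balanced by
          subsampling", {
  plan <- build_offline_protocol(1, seed = 7)
  rec <- synthesize_recording(tiny_sim_config(seed = 8), plan)
  ep <- augment_epochs(rec, plan$trial_id, seed = 9)
  tab <- table(ep$labels)
  expect_equal(unname(tab[["rest"]]), 45)           # balanced to 9 trials x 5
  rest_meta <- ep$meta[ep$labels == "rest", ]
  expect_true(all(rest_meta$offset_s <= -2.6 + 1e-9))
})

test_that("the warm-up schedule is piecewise linear with the documented
          anchors", {
  # closed-form anchors
  expect_equal(lr_at_epoch(10, 3e-4, 10, 100), 3e-4)    # peak at n_warmup
  expect_equal(lr_at_epoch(100, 3e-4, 10, 100), 0)      # zero at the end
  expect_equal(lr_at_epoch(55, 3e-4, 10, 100), 1.5e-4)  # midpoint of decay
  # continuity at the junction
  eps_grid <- lr_at_epoch(c(9, 10, 11), 3e-4, 10, 100)
  expect_equal(eps_grid[2] - eps_grid[1], 3e-4 / 10)
  expect_lt(abs(eps_grid[3] - eps_grid[2]), 3e-4 / 10)
  # non-negative and maximal at n_warmup over the whole range
  lrs <- lr_at_epoch(1:100, 3e-4, 10, 100)
  expect_true(all(lrs >= 0))
  expect_equal(which.max(lrs), 10)
  expect_error(lr_at_epoch(0, 3e-4, 10, 100), "\\[1")
  expect_error(lr_at_epoch(101, 3e-4, 10, 100), "\\[1")
  expect_error(lr_at_epoch(5, 3e-4, 100, 100), "smaller")
})

test_that("evaluation metrics match a brute-force contingency oracle", {
  # perfect predictions
  truth <- rep(SMR_CLASSES, each = 3)
  r <- eval_report(truth, truth)
  expect_equal(r$accuracy, 100)
  expect_equal(r$weighted_f1, 100)
  expect_equal(unclass(r$confusion), diag(4), ignore_attr = TRUE)
  # constant predictor on balanced data
  r2 <- eval_report(truth, rep("rest", 12))
  expect_equal(r2$accuracy, 25)
  # random case against hand-computed per-class F1
  set.seed(10)
  tr <- sample(SMR_CLASSES, 50, replace = TRUE)
  pr <- sample(SMR_CLASSES, 50, replace = TRUE)
  r3 <- eval_report(tr, pr)
  f1s <- numeric(4); sup <- numeric(4)
  for (k in seq_along(SMR_CLASSES)) {
    cls <- SMR_CLASSES[k]
    tp <- sum(tr == cls & pr == cls)
    fp <- sum(tr != cls & pr == cls)
    fn <- sum(tr == cls & pr != cls)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    sup[k] <- sum(tr == cls)
  }
  expect_equal(r3$accuracy, 100 * mean(tr == pr))
  expect_equal(r3$weighted_f1, 100 * sum(f1s * sup) / sum(sup),
               tolerance = 1e-9)
  # confusion rows sum to one where supported
  expect_equal(unname(rowSums(r3$confusion)[sup > 0]),
               rep(1, sum(sup > 0)), tolerance = 1e-6)
  expect_error(eval_report(c("left_hand", "unknown"), c("rest", "rest")),
               "outside")
})

test_that("decoding collapses to chance when no ERD is injected", {
  # lower anchor of the ERD-depth/accuracy relationship: with attenuation 0
  # the classes are statistically identical and held-out accuracy must sit
  # in the chance band, far below what depth 0.4 supports
  plan <- build_offline_protocol(2, seed = 41)
  cfg <- tiny_sim_config(seed = 42,
                         erd_map = list(left_hand = c(C4 = 0),
                                        right_hand = c(C3 = 0),
                                        both_feet = c(Cz = 0)))
  rec <- synthesize_recording(cfg, plan)
  filtered <- offline_filter_chain(rec)
  trials <- unique(filtered$events[, c("trial_id", "class", "kind")])
  shuffle_with_seed <- function(s, n) { set.seed(s); sample(n) }
  ord <- shuffle_with_seed(43, nrow(trials))
  test_ids <- trials$trial_id[ord[1:18]]
  train_ids <- trials$trial_id[ord[-(1:18)]]
  tr <- downsample_epochs(augment_epochs(filtered, train_ids, seed = 44), 125)
  te <- downsample_epochs(augment_epochs(filtered, test_ids, seed = 44), 125)
  stats <- zscore_fit(tr)
  m <- conformer_init(tiny_model_config(n_samples = 250, dropout = 0.5),
                      seed = 45)
  m <- fit_conformer(m, zscore_apply(tr, stats),
                     train_config("offline", epochs = 20, batch_size = 50,
                                  n_warmup = 3, lr_max = 4e-4, seed = 46))
  m$norm_stats <- stats
  expect_lt(evaluate_model(m, te)$accuracy, 40)
})

test_that("training reduces the loss and is reproducible under a seed", {
  cfg <- grad_check_config()
  set.seed(20)
  # separable toy data: class-specific constant patterns plus noise
  n <- 24
  labels <- rep(SMR_CLASSES, each = n / 4)
  X <- array(rnorm(2 * 30 * n, sd = 0.3), c(2, 30, n))
  for (i in seq_len(n)) {
    k <- match(labels[i], SMR_CLASSES)
    X[1, , i] <- X[1, , i] + sin(2 * pi * k * (1:30) / 30)
  }
  ep <- epoch_set(X, labels, 250, c("C3", "C4"))
  tc <- train_config("offline", epochs = 30, batch_size = 8, n_warmup = 3,
                     lr_max = 1e-3, seed = 30)
  m1 <- fit_conformer(conformer_init(cfg, seed = 21), ep, tc)
  expect_lt(tail(m1$loss_trace, 1), m1$loss_trace[1])
  m2 <- fit_conformer(conformer_init(cfg, seed = 21), ep, tc)
  expect_identical(m1$weights, m2$weights)
  # unknown labels abort
  bad <- ep; bad$labels[1] <- "surprise"
  expect_error(fit_conformer(conformer_init(cfg, seed = 21), bad, tc),
               "unknown label")
})
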