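# brute-force oracle: first position whose trailing run of identical
# non-rest labels reaches the required length
smooth_oracle <- function(preds, required = 5, rest = "rest") {
  n <- length(preds)
  for (i in seq_len(n)) {
    if (i >= required && preds[i] != rest &&
        all(preds[(i - required + 1):i] == preds[i])) {
      return(list(command = preds[i], index = i))
    }
  }
  list(command = rest, index = NA_integer_)
}

test_that("temporal smoothing confirms only runs of five identical non-rest
          predictions", {
  expect_equal(smooth_decode(rep("left_hand", 5))$command, "left_hand")
  expect_equal(smooth_decode(rep("left_hand", 5))$index, 5)
  mixed <- c(rep("left_hand", 4), rep("right_hand", 4))
  expect_equal(smooth_decode(mixed)$command, "rest")
  expect_equal(smooth_decode(rep("rest", 10))$command, "rest")
  # confirmation can never come earlier than required - 1 steps after the
  # run's first prediction
  out <- smooth_decode(c("rest", rep("both_feet", 7)))
  expect_equal(out$index, 6)                       # run starts at 2
  expect_gte(out$index - 2, 4)
})

test_that("smoothing equals the brute-force oracle on random streams", {
  set.seed(1)
  for (rep_i in 1:200) {
    preds <- sample(SMR_CLASSES, 40, replace = TRUE)
    expect_identical(smooth_decode(preds), smooth_oracle(preds))
  }
  # and on short/edge-length streams
  for (n in 1:6) {
    for (rep_i in 1:30) {
      preds <- sample(SMR_CLASSES, n, replace = TRUE)
      expect_identical(smooth_decode(preds), smooth_oracle(preds))
    }
  }
})

# a scripted decoder: returns `label` whenever the window end falls inside a
# classification window, per-attempt behavior controlled by `script`
make_scripted_decoder <- function(label) {
  function(eps) rep(label, n_epochs(eps))
}

online_fixture <- function(n_trials = 2, seed = 31) {
  plan <- build_online_protocol(n_trials, seed = seed)
  cfg <- tiny_sim_config(seed = seed)
  rec <- synthesize_recording(cfg, plan)
  list(plan = plan, stream = online_filter(rec), rec = rec)
}

test_that("a decoder emitting the cue class succeeds on attempt one with a
          plausible motion onset", {
  fx <- online_fixture()
  t1 <- fx$plan[fx$plan$trial_id == 1, ]
  out <- run_online_trial(make_scripted_decoder(t1$class[1]), fx$stream, t1)
  expect_true(out$success)
  expect_equal(out$attempts, 1)
  expect_false(out$force_passed)
  # earliest confirmation: 5 predictions into the window = cue + 2 + 0.5 s
  expect_equal(out$motion_onset, t1$onset[1] + 2 + 0.5, tolerance = 1e-9)
})

test_that("a decoder stuck on rest exhausts three attempts and force-passes", {
  fx <- online_fixture()
  t1 <- fx$plan[fx$plan$trial_id == 1, ]
  out <- run_online_trial(make_scripted_decoder("rest"), fx$stream, t1)
  expect_false(out$success)
  expect_true(out$force_passed)
  expect_equal(out$attempts, 3)
  expect_true(is.na(out$motion_onset))
})

test_that("success on the final attempt is not a force-pass", {
  fx <- online_fixture()
  t1 <- fx$plan[fx$plan$trial_id == 1, ]
  cue <- t1$class[1]
  calls <- new.env(); calls$n <- 0
  decoder <- function(eps) {
    calls$n <- calls$n + 1
    # attempts 1-2 (first two calls): wrong class; attempt 3: the cue
    if (calls$n < 3) {
      wrong <- setdiff(SMR_MOVEMENT_CLASSES, cue)[1]
      rep(wrong, n_epochs(eps))
    } else {
      rep(cue, n_epochs(eps))
    }
  }
  out <- run_online_trial(decoder, fx$stream, t1)
  expect_true(out$success)
  expect_equal(out$attempts, 3)
  expect_false(out$force_passed)
})

test_that("session labeling anchors successes at motion onset - 2.5 s and
          failures at cue onset", {
  fx <- online_fixture(n_trials = 2, seed = 32)
  filtered <- offline_filter_chain(fx$rec)
  t1 <- fx$plan[fx$plan$trial_id == 1, ]
  t2 <- fx$plan[fx$plan$trial_id == 2, ]
  ok <- run_online_trial(make_scripted_decoder(t1$class[1]), fx$stream, t1)
  fail <- run_online_trial(make_scripted_decoder("rest"), fx$stream, t2)
  ep <- label_session(list(ok, fail), filtered)
  expect_equal(n_epochs(ep), 2 * 5 + 2 * 5)         # MI + rest segments
  mi1 <- ep$meta[ep$labels == t1$class[1] & ep$meta$trial_id == 1, ]
  fs <- filtered$sampling_rate
  expect_equal(min(mi1$t0), floor((ok$motion_onset - 2.5) * fs) / fs,
               tolerance = 1e-9)
  mi2 <- ep$meta[ep$meta$trial_id == 2 & ep$labels != "rest", ]
  expect_equal(min(mi2$t0), floor(fail$cue_onset * fs) / fs,
               tolerance = 1e-9)
  # empty outcome list gives an empty set
  expect_equal(n_epochs(label_session(list(), filtered)), 0)
})

test_that("adaptation with zero epochs leaves the report unchanged, real
          fine-tuning moves the weights", {
  fx <- online_fixture(n_trials = 6, seed = 33)
  filtered <- offline_filter_chain(fx$rec)
  outcomes <- lapply(unique(fx$plan$trial_id), function(id) {
    tp <- fx$plan[fx$plan$trial_id == id, ]
    run_online_trial(make_scripted_decoder(tp$class[1]), fx$stream, tp)
  })
  sessions <- list(list(filtered = filtered, outcomes = outcomes))
  m <- conformer_init(tiny_model_config(), seed = 40)
  m$norm_stats <- zscore_fit(
    downsample_epochs(label_session(outcomes, filtered), 250))
  frozen <- adapt_model(m, sessions,
                        train_config("online", epochs = 0, seed = 41),
                        seed = 42)
  expect_equal(frozen$pre$accuracy, frozen$post$accuracy)
  expect_identical(frozen$model$weights, m$weights)
  tuned <- adapt_model(m, sessions,
                       train_config("online", epochs = 1, seed = 41),
                       seed = 42)
  expect_false(identical(tuned$model$weights, m$weights))
  # empty dataset is a warning no-op
  expect_warning(none <- adapt_model(m, list()), "unchanged")
  expect_identical(none$model$weights, m$weights)
})
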