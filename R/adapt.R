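#' Domain-incremental fine-tuning on accumulated online sessions
#'
#' Implements one adaptation round. Trials from the current and all previous
#' sessions (full replay — sessions are never discarded) are pooled and
#' split 8:2 into training and testing at the *trial* level, stratified by
#' cue class and seed-controlled. Only then is each side expanded into
#' overlapping segments ([label_session()]), so no augmented sample spans
#' the split. The existing model is evaluated on the test side
#' (pre-report), fine-tuned on the balanced training side with the online
#' schedule (20 epochs, batch 16, fixed learning rate 2e-5), and evaluated
#' again (post-report). Failed (force-passed) trials enter training with
#' their cue label by default, so the decoder learns from both successful
#' and unsuccessful control attempts.
#'
#' The model is always updated from its current weights, never reinitialized;
#' normalization statistics stay frozen at their pre-training values.
#'
#' @param model the current `conformer_model` checkpoint (with
#'   `norm_stats`).
#' @param sessions list of sessions, each a list with `filtered` (the
#'   offline-chain filtered session [eeg_recording()]) and `outcomes` (from
#'   [run_online_session()]).
#' @param train_cfg a [train_config()] (online phase).
#' @param spec an [augmentation_spec()].
#' @param target_rate epoch rate expected by the model (default 250).
#' @param split training fraction of the 8:2 split (default 0.8).
#' @param include_failed keep force-passed trials (cue-labeled) in the
#'   dataset (default TRUE).
#' @param seed seed for the stratified split and rest balancing.
#' @return list with `model` (updated), `pre` and `post` ([eval_report()]s
#'   on the held-out split before and after fine-tuning).
#' @export
adapt_model <- function(model, sessions, train_cfg = train_config("online"),
                        spec = augmentation_spec(), target_rate = 250,
                        split = 0.8, include_failed = TRUE, seed = 1L) {
  if (length(sessions) == 0) {
    warning("no sessions to adapt on; returning the model unchanged")
    return(list(model = model, pre = NULL, post = NULL))
  }
  # pool trials as (session, trial index, cue)
  pool <- do.call(rbind, lapply(seq_along(sessions), function(s) {
    oc <- sessions[[s]]$outcomes
    keep <- if (include_failed) seq_along(oc) else which(
      vapply(oc, `[[`, TRUE, "success"))
    if (length(keep) == 0) return(NULL)
    data.frame(session = s, trial = keep,
               cue = vapply(oc[keep], `[[`, "", "cue"))
  }))
  if (is.null(pool) || nrow(pool) == 0) {
    warning("adaptation dataset is empty; returning the model unchanged")
    return(list(model = model, pre = NULL, post = NULL))
  }
  with_seed(seed, {
    test_rows <- integer(0)
    for (cls in unique(pool$cue)) {
      rows <- which(pool$cue == cls)
      n_test <- max(1, round((1 - split) * length(rows)))
      if (length(rows) > 1) test_rows <- c(test_rows, sample(rows, n_test))
    }
    if (length(test_rows) == 0) {
      # degenerate pools (a single trial per class) still need a held-out
      # side for the before/after reports
      test_rows <- sample(nrow(pool), 1)
    }
    train_rows <- setdiff(seq_len(nrow(pool)), test_rows)
  })

  cut_side <- function(rows) {
    parts <- lapply(unique(pool$session[rows]), function(s) {
      tr <- pool$trial[rows][pool$session[rows] == s]
      label_session(sessions[[s]]$outcomes[tr], sessions[[s]]$filtered, spec)
    })
    downsample_epochs(do.call(bind_epochs, parts), target_rate)
  }
  test_ep <- cut_side(test_rows)
  train_ep <- cut_side(train_rows)

  # balance rest down to the mean movement-class count (training side only)
  is_rest <- train_ep$labels == "rest"
  target <- round(mean(table(train_ep$labels[!is_rest])))
  if (sum(is_rest) > target) {
    with_seed(seed + 1L, {
      keep_rest <- sample(which(is_rest), target)
      train_ep <- subset_epochs(train_ep, sort(c(which(!is_rest), keep_rest)))
    })
  }

  pre <- evaluate_model(model, test_ep)
  if (train_cfg$epochs > 0) {
    model <- fit_conformer(model, zscore_apply(train_ep, model$norm_stats),
                           train_cfg)
  }
  post <- evaluate_model(model, test_ep)
  list(model = model, pre = pre, post = post)
}

#' Run a multi-session online campaign with adaptation
#'
#' Simulates and decodes `n_sessions` consecutive online feedback sessions.
#' Session 1 is decoded with the pretrained checkpoint as-is; after each
#' session except the last, the model is fine-tuned on all sessions
#' collected so far ([adapt_model()]). Session-to-session non-stationarity
#' is injected through per-session drift built from a base channel-gain
#' draw followed by a multiplicative random walk, plus an optional rhythm
#' SNR scale.
#'
#' Each session is scored two ways: `command_accuracy` (% of cue trials
#' confirmed correctly within three attempts) and `epoch_accuracy` (% of
#' that session's labeled epochs classified correctly by the model in use
#' *during* the session, i.e. before any further adaptation). As a
#' catastrophic-forgetting probe, `s1_accuracy_now` reports the current
#' model's accuracy on session 1's labeled epochs after each adaptation
#' round (reported, not asserted: full session replay is the default
#' accumulation policy).
#'
#' @param model pretrained `conformer_model` with `norm_stats`.
#' @param config a [sim_config()] for the online sessions.
#' @param n_sessions number of sessions (default 3).
#' @param n_trials cue trials per session (default 9).
#' @param drift_base a [drift_spec()] for the initial offline-to-online
#'   shift (drawn once); `NULL` disables drift entirely.
#' @param walk_sd per-session multiplicative gain random-walk sd (default
#'   0.05).
#' @param train_cfg online [train_config()].
#' @param target_rate epoch rate expected by the model (default 250).
#' @param seed master seed for plans, recordings, drift and adaptation.
#' @return list with `trajectory` (data.frame: session, command_accuracy,
#'   epoch_accuracy, pre/post adaptation accuracy where applicable),
#'   `sessions` (accumulated session data), and `model` (final checkpoint).
#' @export
run_campaign <- function(model, config, n_sessions = 3, n_trials = 9,
                         drift_base = drift_spec(gain_sd = 0.3,
                                                 snr_scale = 0.7),
                         walk_sd = 0.05,
                         train_cfg = train_config("online"),
                         target_rate = 250, seed = 1L) {
  n_ch <- length(config$channel_names)
  gains <- rep(1, n_ch)
  if (!is.null(drift_base)) {
    gains <- with_seed(seed * 1000L + 1L,
                       pmax(rnorm(n_ch, 1, drift_base$gain_sd), 0.05))
  }
  sessions <- list()
  s1_epochs <- NULL
  traj <- data.frame(session = integer(0), command_accuracy = numeric(0),
                     epoch_accuracy = numeric(0), adapt_pre = numeric(0),
                     adapt_post = numeric(0), s1_accuracy_now = numeric(0))
  for (s in seq_len(n_sessions)) {
    plan <- build_online_protocol(n_trials, seed = seed * 1000L + 10L + s)
    cfg_s <- config
    cfg_s$seed <- config$seed + 100L * s
    rec <- synthesize_recording(cfg_s, plan)
    if (!is.null(drift_base)) {
      if (s > 1) {
        gains <- gains * with_seed(seed * 1000L + 20L + s,
                                   pmax(rnorm(n_ch, 1, walk_sd), 0.05))
      }
      rec <- apply_session_drift(
        rec, drift_spec(gain = gains, offset = rep(0, n_ch),
                        snr_scale = drift_base$snr_scale))
    }
    run <- run_online_session(model, rec, plan)
    filtered <- offline_filter_chain(rec)
    sessions[[s]] <- list(filtered = filtered, outcomes = run$outcomes)
    sess_ep <- downsample_epochs(
      label_session(run$outcomes, filtered), target_rate)
    if (s == 1) s1_epochs <- sess_ep
    epoch_acc <- evaluate_model(model, sess_ep)$accuracy
    pre <- NA_real_; post <- NA_real_; s1_now <- NA_real_
    if (s < n_sessions) {
      ad <- adapt_model(model, sessions, train_cfg,
                        target_rate = target_rate, seed = seed * 1000L + s)
      model <- ad$model
      if (!is.null(ad$pre)) { pre <- ad$pre$accuracy; post <- ad$post$accuracy }
      s1_now <- evaluate_model(model, s1_epochs)$accuracy
    }
    traj <- rbind(traj, data.frame(
      session = s, command_accuracy = run$command_accuracy,
      epoch_accuracy = epoch_acc, adapt_pre = pre, adapt_post = post,
      s1_accuracy_now = s1_now))
  }
  list(trajectory = traj, sessions = sessions, model = model)
}
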