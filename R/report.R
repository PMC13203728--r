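#' Assemble a results bundle
#'
#' Collects the quantitative outputs of an experiment into one structure:
#' the session performance trajectory (pre-training plus online sessions),
#' row-normalized confusion matrices, ERD/ERS tables, and optionally a 2-D
#' t-SNE embedding of penultimate features (perplexity 20, PCA
#' initialization, fixed seed).
#'
#' @param eval_reports named list of [eval_report()]s in trajectory order
#'   (e.g. pretraining, session 1..3).
#' @param erd_results optional named list of `erd_result`s.
#' @param features optional points x features matrix of penultimate
#'   features to embed.
#' @param feature_labels optional labels aligned with `features` rows.
#' @param perplexity,seed t-SNE parameters.
#' @return an object of class `report_bundle` with `trajectory` (one row
#'   per report: accuracy, weighted F1), `confusions`, `erd_tables`,
#'   `embedding` (data.frame with coordinates and labels, or NULL).
#' @export
report_bundle <- function(eval_reports, erd_results = NULL, features = NULL,
                          feature_labels = NULL, perplexity = 20, seed = 1L) {
  stopifnot(length(eval_reports) >= 1)
  nm <- names(eval_reports)
  if (is.null(nm)) nm <- paste0("stage_", seq_along(eval_reports))
  trajectory <- data.frame(
    stage = nm,
    accuracy = vapply(eval_reports, `[[`, 1, "accuracy"),
    weighted_f1 = vapply(eval_reports, `[[`, 1, "weighted_f1"),
    row.names = NULL)
  embedding <- NULL
  if (!is.null(features)) {
    Y <- tsne_embed(features, perplexity = perplexity, seed = seed)
    embedding <- data.frame(Y, label = feature_labels %||%
                              rep(NA_character_, nrow(Y)))
  }
  structure(
    list(trajectory = trajectory,
         confusions = lapply(eval_reports, `[[`, "confusion"),
         erd_tables = if (is.null(erd_results)) NULL else
           lapply(erd_results, `[[`, "table"),
         embedding = embedding),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  print(x$trajectory, digits = 4)
  invisible(x)
}

#' Experiment configuration for the end-to-end pipeline
#'
#' Bundles every knob that determines a full run, so a run is reproducible
#' from its manifest alone.
#'
#' @param sim a [sim_config()].
#' @param model a [model_config()].
#' @param offline,online [train_config()]s for the two phases.
#' @param n_runs offline acquisition runs.
#' @param n_folds cross-validation folds.
#' @param n_sessions,n_trials online campaign shape.
#' @param drift a [drift_spec()] for the campaign (NULL = drift-free).
#' @param target_rate epoch rate after decimation.
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(), model = model_config(),
                              offline = train_config("offline"),
                              online = train_config("online"),
                              n_runs = 15, n_folds = 5,
                              n_sessions = 3, n_trials = 9,
                              drift = drift_spec(gain_sd = 0.3, snr_scale = 0.7),
                              target_rate = 250, seed = 1L,
                              out_dir = tempfile("smrbci_run_")) {
  structure(list(sim = sim, model = model, offline = offline,
                 online = online, n_runs = n_runs, n_folds = n_folds,
                 n_sessions = n_sessions, n_trials = n_trials,
                 drift = drift, target_rate = target_rate,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL                      # path does not affect the science
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline end to end
#'
#' simulate -> preprocess -> pretrain (AO-aware k-fold CV plus full refit)
#' -> online sessions with adaptation between them -> ERD analysis ->
#' report. Every stage is seeded from `config$seed`; rerunning with the
#' same configuration reproduces the same manifest hash.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return an object of class `run_manifest`: `config_hash`, `package
#'   version`, per-stage `artifacts` (file paths), stage `timings`
#'   (seconds), and `results` (the [report_bundle()] plus the CV and
#'   campaign outputs).
#' @export
end_to_end <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  artifacts <- list()
  timings <- c()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    if (verbose) message("stage: ", name)
    out <- tryCatch(force(code), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  plan <- stage("simulate", build_offline_protocol(config$n_runs,
                                                   seed = config$seed))
  rec <- stage("synthesize", synthesize_recording(config$sim, plan))
  edf <- file.path(config$out_dir, "offline.edf")
  stage("export", write_recording(rec, edf))
  artifacts$offline_edf <- edf

  cv <- stage("pretrain", pretrain_cv(
    rec, config$model, config$offline, config$n_folds,
    config$target_rate, seed = config$seed))
  ckpt <- file.path(config$out_dir, "pretrained.ckpt")
  stage("checkpoint", save_checkpoint(cv$model, ckpt))
  artifacts$checkpoint <- ckpt

  campaign <- stage("campaign", run_campaign(
    cv$model, config$sim, config$n_sessions, config$n_trials,
    drift_base = config$drift, train_cfg = config$online,
    target_rate = config$target_rate, seed = config$seed))

  erd <- stage("erd", erd_analysis(rec, "offline"))
  erd_tsv <- file.path(config$out_dir, "erd_offline.tsv")
  write.table(erd$table, erd_tsv, sep = "\t", quote = FALSE)
  artifacts$erd_table <- erd_tsv

  reports <- c(list(pretraining = structure(
    list(accuracy = cv$mean_accuracy, weighted_f1 = cv$mean_weighted_f1,
         confusion = cv$fold_reports[[1]]$confusion),
    class = "eval_report")),
    stats::setNames(
      lapply(seq_len(config$n_sessions), function(s) {
        structure(list(accuracy = campaign$trajectory$epoch_accuracy[s],
                       weighted_f1 = NA_real_, confusion = NULL),
                  class = "eval_report")
      }), paste0("session_", seq_len(config$n_sessions))))
  bundle <- stage("report", report_bundle(reports, list(offline = erd)))
  traj_tsv <- file.path(config$out_dir, "trajectory.tsv")
  write.table(bundle$trajectory, traj_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  artifacts$trajectory <- traj_tsv

  structure(
    list(config_hash = config_hash(config),
         package_version = as.character(utils::packageVersion("smrbci")),
         artifacts = artifacts, timings = timings,
         results = list(cv = cv[c("fold_reports", "mean_accuracy",
                                  "mean_weighted_f1")],
                        campaign = campaign["trajectory"],
                        erd = erd, bundle = bundle)),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> config", x$config_hash, "\n")
  cat("stages:", paste(sprintf("%s (%.1fs)", names(x$timings), x$timings),
                       collapse = ", "), "\n")
  invisible(x)
}
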