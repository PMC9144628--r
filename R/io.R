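#' Load a grid-electrode sEMG dataset from MAT files
#'
#' Reads every `.mat` file in a directory into [recording()] objects. Field
#' names inside the MAT files are configurable via `field_map` because
#' releases differ; defaults match the common layout (`data` = samples x
#' channels, scalar `gesture`, `subject`, `trial`). Channel count and the
#' per-database gesture inventory (8 gestures for DB-a/DB-b, 12 for DB-c)
#' are validated.
#'
#' @param directory directory containing the MAT files.
#' @param db one of `"a"`, `"b"`, `"c"` (sets the expected gesture count),
#'   or `NA` to skip that check.
#' @param field_map named list with entries `signal`, `gesture`, `subject`,
#'   `repetition` giving the MAT variable names.
#' @param n_channels expected electrode count.
#' @param fs sampling rate of the recordings in Hz.
#' @return list of [recording()] objects.
#' @export
load_capgmyo <- function(directory, db = c("a", "b", "c"),
                         field_map = list(signal = "data", gesture = "gesture",
                                          subject = "subject", repetition = "trial"),
                         n_channels = 128, fs = 1000) {
  if (!is.na(db[1])) db <- match.arg(db)
  if (!dir.exists(directory))
    stop("load_capgmyo: directory not found: ", directory,
         " (this loader needs the externally downloaded dataset)")
  files <- sort(list.files(directory, pattern = "\\.mat$", full.names = TRUE))
  if (!length(files))
    stop("load_capgmyo: no .mat files in ", directory,
         "; expected one file per subject/gesture/trial")
  recs <- lapply(files, function(f) {
    vars <- read_mat5(f)
    for (fld in c("signal", "gesture", "subject")) {
      if (is.null(vars[[field_map[[fld]]]]))
        stop("load_capgmyo: ", f, " lacks field '", field_map[[fld]], "' (", fld, ")")
    }
    sig <- vars[[field_map$signal]]
    # stored convention is samples x channels; transpose unless already C x T
    if (nrow(sig) != n_channels && nrow(sig) >= ncol(sig)) sig <- t(sig)
    if (nrow(sig) != n_channels)
      stop(sprintf("load_capgmyo: %s has %d channels, expected %d", f, nrow(sig), n_channels))
    rep_val <- vars[[field_map$repetition]]
    recording(sig, fs, gesture = vars[[field_map$gesture]][1],
              subject = vars[[field_map$subject]][1],
              repetition = if (is.null(rep_val)) 1L else rep_val[1])
  })
  gestures <- sort(unique(vapply(recs, function(r) r$gesture, integer(1))))
  expected <- c(a = 8L, b = 8L, c = 12L)
  if (!is.na(db[1]) && length(gestures) > expected[[db]])
    stop(sprintf("load_capgmyo: found %d gesture classes, DB-%s defines %d",
                 length(gestures), db, expected[[db]]))
  recs
}

#' Run the full pipeline from a configuration
#'
#' Executes synthesize -> preprocess -> featurize -> train (supervised or
#' meta) and writes all artifacts (resolved configuration, metrics, logs,
#' checkpoint) under a run directory. Re-running an identical configuration
#' reproduces identical metrics.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized sections: `synth` (arguments of [synth_config()]), `feature`
#'   (`mode`, plus [stft_config()] arguments), `network` (`variant`,
#'   `cell_channels`, `reduction`), `task` (`"supervised"` or `"meta"`),
#'   `train` ([train_config()] arguments), `meta` ([meta_config()] arguments
#'   plus `n_meta_batches`, `ways`, `shots`, `train_subjects`,
#'   `val_subjects`, `test_subjects`), `data` (optional `capgmyo_dir`, `db`),
#'   `out_dir`, `seed`.
#' @return list of result objects; artifacts on disk under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("run_pipeline: config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("run_pipeline [%s]: %s", name, conditionMessage(e)), call. = FALSE))
  }
  logf <- file.path(out_dir, "log.jsonl")
  jlog <- function(...) cat(jsonlite::toJSON(list(...), auto_unbox = TRUE), "\n",
                            file = logf, append = TRUE)

  recs <- stage("data", {
    if (!is.null(config$data$dataset_dir)) {
      read_dataset(config$data$dataset_dir)
    } else if (!is.null(config$data$capgmyo_dir)) {
      if (!dir.exists(config$data$capgmyo_dir))
        stop("external data required: CapgMyo directory '", config$data$capgmyo_dir,
             "' does not exist (download it separately)")
      load_capgmyo(config$data$capgmyo_dir, config$data$db %||% "a")
    } else {
      scfg <- do.call(synth_config, c(config$synth %||% list(),
                                      if (is.null(config$synth$seed)) list(seed = seed)))
      generate_dataset(scfg)
    }
  })
  jlog(stage = "data", n_recordings = length(recs))

  samples <- stage("preprocess", lapply(recs, preprocess_recording))
  fmode <- config$feature$mode %||% "stft"
  feats <- stage("featurize", {
    scfg <- stft_config(window_kind = config$feature$window_kind %||% "hann",
                        window_len = config$feature$window_len %||% 64,
                        hop = config$feature$hop %||% 29)
    featurize_samples(samples, fmode, scfg)
  })
  pool <- make_pool(feats)
  jlog(stage = "featurize", mode = fmode, feature_dim = dim(pool$x)[1:3])

  net_cfg <- network_config(dim(pool$x)[1:3],
                            n_classes = length(unique(pool$gesture)),
                            cell_channels = config$network$cell_channels,
                            variant = config$network$variant %||% "csac",
                            reduction = config$network$reduction %||% 4)
  theta0 <- init_params(net_cfg, seed = seed)
  task <- config$task %||% "supervised"

  result <- if (task == "meta") stage("meta", {
    m <- config$meta %||% list()
    mcfg <- meta_config(alpha = m$alpha %||% 0.1, beta = m$beta %||% 0.001,
                        meta_batch = m$meta_batch %||% 8,
                        inner_steps_train = m$inner_steps_train %||% 1,
                        inner_steps_test = m$inner_steps_test %||% 5,
                        second_order = m$second_order %||% TRUE, seed = seed)
    subj <- sort(unique(pool$subject))
    tr_s <- m$train_subjects %||% subj[seq_len(max(1, length(subj) - 2))]
    va_s <- m$val_subjects %||% setdiff(subj, tr_s)[1]
    te_s <- m$test_subjects %||% setdiff(subj, c(tr_s, va_s))
    pools <- split_pool_by_subject(pool, tr_s, va_s, te_s)
    fit <- meta_train(theta0, net_cfg, pools$train, mcfg,
                      n_meta_batches = m$n_meta_batches %||% 100,
                      N = m$ways %||% 5, K = m$shots %||% 5,
                      val_pool = if (length(va_s)) pools$val else NULL)
    test <- meta_test(fit$best_theta, net_cfg, pools$test, mcfg,
                      n_tasks = m$test_tasks %||% 100,
                      N = m$ways %||% 5, K = m$shots %||% 5, seed = seed + 1L)
    utils::write.csv(fit$log, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    save_checkpoint(fit$best_theta, net_cfg, file.path(out_dir, "checkpoint.rds"))
    jlog(stage = "meta", pre_acc = test$mean_acc_pre, final_acc = test$mean_acc_final,
         best_acc = test$mean_acc_best)
    list(fit = fit, test = test)
  }) else stage("supervised", {
    tcfg <- train_config(lr = config$train$lr %||% 0.001,
                         epochs = config$train$epochs %||% 300,
                         batch = config$train$batch %||% 64, seed = seed)
    idx <- split_dataset(pool, tcfg$split, seed = seed)
    fit <- train_supervised(theta0, net_cfg, pool, idx, tcfg)
    test_acc <- pool_accuracy(fit$theta, net_cfg, pool, idx$test, stats = fit$stats)
    utils::write.csv(fit$history, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    save_checkpoint(fit$theta, net_cfg, file.path(out_dir, "checkpoint.rds"),
                    stats = fit$stats)
    jlog(stage = "supervised", test_acc = test_acc)
    list(fit = fit, test_acc = test_acc)
  })
  config$resolved_seed <- seed
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(result)
}

#' Subject-disjoint split of a featurized pool
#'
#' Episodic counterpart of [make_fewshot_splits()]: partitions a `semg_pool`
#' into meta-train / meta-validation / meta-test pools with no subject in
#' more than one pool.
#'
#' @param pool a `semg_pool`.
#' @param train_subjects,val_subjects,test_subjects pairwise-disjoint
#'   subject index vectors.
#' @return named list `train`, `val`, `test` of `semg_pool` objects.
#' @export
split_pool_by_subject <- function(pool, train_subjects, val_subjects, test_subjects) {
  sets <- list(train = train_subjects, val = val_subjects, test = test_subjects)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(sets[[i]], sets[[j]])))
      stop("split_pool_by_subject: subject sets overlap")
  lapply(sets, function(s) subset_pool(pool, pool$subject %in% s))
}

subset_pool <- function(pool, keep) {
  idx <- which(keep)
  structure(list(x = pool$x[, , , idx, drop = FALSE],
                 gesture = pool$gesture[idx], subject = pool$subject[idx],
                 id = seq_along(idx)),
            class = "semg_pool")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
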