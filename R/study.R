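#' Canned synthetic study profiles
#'
#' Two ready-made generator configurations used throughout the package's
#' examples, tests and reproduction script:
#'
#' * `"easy"` — the benign small-scale condition: 8 subjects, 8 gestures,
#'   25 repetitions on a 4x4 grid, moderate sensor noise, mild subject
#'   effects (log-gain SD 0.2, electrode shift up to 1 column). Classes are
#'   cleanly separable from per-channel band-power profiles. The
#'   strong-shift profile uses 50 repetitions — about 400 windows per
#'   subject, the scale of real grid-sEMG corpora — so the within-cohort
#'   classifier has enough data to generalize to its own subjects.
#' * `"strong-shift"` — same geometry but severe subject effects (log-gain
#'   SD 0.5, circular electrode shift up to 2 of 4 columns, continuous
#'   electrode-placement jitter of SD 0.75 electrodes), the regime where a
#'   conventionally pretrained model fails on new subjects: the fractional
#'   placement offset of an unseen subject is never represented in the
#'   training cohort.
#'
#' @param name profile name.
#' @param seed generator seed.
#' @return a [synth_config()].
#' @export
synth_profile <- function(name = c("easy", "strong-shift"), seed = 10L) {
  name <- match.arg(name)
  switch(name,
    easy = synth_config(n_subjects = 8, n_gestures = 8, n_repetitions = 25,
                        grid = c(4, 4), subject_gain_sd = 0.2,
                        subject_shift_max = 1, noise_sd = 0.3, seed = seed),
    `strong-shift` = synth_config(n_subjects = 8, n_gestures = 8, n_repetitions = 50,
                                  grid = c(4, 4), subject_gain_sd = 0.5,
                                  subject_shift_max = 2, subject_jitter_sd = 0.75,
                                  noise_sd = 0.3, seed = seed))
}

#' Generate, preprocess and featurize a study profile
#'
#' Runs the full data pipeline (synthesis, band-stop filtering, windowing,
#' normalization, spectrogram features) for a profile and returns the
#' featurized pool. Spectrograms use the log1p-compressed magnitude, the
#' variance-stabilized representation used by the packaged studies.
#'
#' @param config a [synth_config()], e.g. from [synth_profile()].
#' @param log1p use log-compressed spectrogram magnitudes.
#' @return a `semg_pool`.
#' @export
build_study_pool <- function(config, log1p = TRUE) {
  recs <- generate_dataset(config)
  samples <- lapply(recs, preprocess_recording)
  make_pool(featurize_samples(samples, "stft", stft_config(log1p = log1p)))
}

#' New-subject adaptation study (meta-learning)
#'
#' The package's desk-scale version of the inter-subject experiment:
#' meta-train on subjects 1-6 of the easy profile, meta-validate on subject
#' 7, meta-test 5-way 5-shot tasks on the held-out subject 8, reporting
#' query accuracy before and after inner-loop adaptation.
#'
#' Defaults are sized for a workstation run: 300 outer updates of 8 tasks
#' (2400 tasks), second-order meta-gradients with the forward-difference
#' Hessian-vector product, a zero-initialized classifier head, a compact
#' 16-8-8-8 channel plan, and an outer learning rate of 0.02 matched to the
#' short schedule. The full-scale protocol (20000 tasks, Adam at 0.001,
#' central-difference second order) is reached by raising `n_meta_batches`
#' and passing `beta = 0.001`, `hvp = "central"`.
#'
#' @param seed seed for initialization, task sampling and testing.
#' @param pool optional pre-built easy-profile pool (saves regeneration).
#' @param n_meta_batches outer updates.
#' @param meta_batch tasks per outer update.
#' @param N,K task geometry (N-way, K support + K query per class).
#' @param beta outer learning rate.
#' @param second_order differentiate through the inner step.
#' @param hvp Hessian-vector-product scheme, see [meta_config()].
#' @param inner_steps_test adaptation steps at test time.
#' @param n_test_tasks meta-test task count.
#' @param cell_channels network channel plan.
#' @return list with the fitted parameters, the training log, the
#'   [meta_test()] summary, and scalars `acc_pre`, `acc_post`, `acc_best`.
#' @export
adaptation_study <- function(seed = 0L, pool = NULL, n_meta_batches = 300,
                             meta_batch = 8, N = 5, K = 5, beta = 0.02,
                             second_order = TRUE, hvp = "forward",
                             inner_steps_test = 10, n_test_tasks = 30,
                             cell_channels = c(8, 8, 8)) {
  if (is.null(pool)) pool <- build_study_pool(synth_profile("easy"))
  subjects <- sort(unique(pool$subject))
  ns <- length(subjects)
  pools <- split_pool_by_subject(pool, subjects[1:(ns - 2)],
                                 subjects[ns - 1], subjects[ns])
  net_cfg <- network_config(dim(pool$x)[1:3], n_classes = N,
                            cell_channels = cell_channels)
  theta0 <- init_params(net_cfg, seed = seed, zero_head = TRUE)
  mcfg <- meta_config(alpha = 0.1, beta = beta, meta_batch = meta_batch,
                      second_order = second_order, hvp = hvp,
                      inner_steps_test = inner_steps_test, seed = seed)
  fit <- meta_train(theta0, net_cfg, pools$train, mcfg, n_meta_batches,
                    N = N, K = K, val_pool = pools$val, val_every = 50,
                    val_tasks = 10, val_steps = 3)
  test <- meta_test(fit$best_theta, net_cfg, pools$test, mcfg,
                    n_tasks = n_test_tasks, N = N, K = K,
                    seed = seed + 1000L)
  list(theta = fit$best_theta, net_cfg = net_cfg, log = fit$log, test = test,
       acc_pre = test$mean_acc_pre, acc_post = test$mean_acc_final,
       acc_best = test$mean_acc_best)
}

#' Pretrain-transfer study (conventional baseline)
#'
#' The package's desk-scale version of the pretrained-model ablation: train
#' a conventional classifier on subjects 1-6 of the strong-shift profile
#' (70/30 train/validation) and evaluate the frozen model on subjects 7-8.
#' The within-subjects validation accuracy is high while the new-subject
#' test accuracy collapses — the failure mode that motivates meta-learning.
#'
#' @param seed training seed.
#' @param pool optional pre-built strong-shift pool.
#' @param epochs training epochs (desk default 30).
#' @param batch minibatch size.
#' @param cell_channels network channel plan.
#' @return the [pretrain_transfer_eval()] result (`val_acc`, `test_acc`,
#'   `gap`, model state).
#' @export
transfer_study <- function(seed = 0L, pool = NULL, epochs = 30, batch = 32,
                           cell_channels = c(16, 16, 8)) {
  if (is.null(pool)) pool <- build_study_pool(synth_profile("strong-shift"))
  subjects <- sort(unique(pool$subject))
  ns <- length(subjects)
  net_cfg <- network_config(dim(pool$x)[1:3],
                            n_classes = length(unique(pool$gesture)),
                            cell_channels = cell_channels)
  cfg <- train_config(epochs = epochs, batch = batch,
                      lr_drop_epoch = max(1, round(epochs / 2)), seed = seed)
  pretrain_transfer_eval(init_params(net_cfg, seed = seed), net_cfg, pool,
                         train_subjects = subjects[1:(ns - 2)],
                         test_subjects = subjects[(ns - 1):ns], cfg)
}
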