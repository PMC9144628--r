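#' Supervised training configuration
#'
#' Defaults mirror the within-corpus protocol: Adam at learning rate 0.001
#' dropped to 0.0001 after 150 of 300 epochs, batch 64, weight decay 1e-4,
#' and a stratified 6:2:2 train/validation/test split.
#'
#' @param lr initial learning rate.
#' @param lr_late learning rate after `lr_drop_epoch`.
#' @param lr_drop_epoch epoch after which the late rate applies.
#' @param epochs training epochs.
#' @param batch minibatch size.
#' @param weight_decay L2 coefficient added to the gradient.
#' @param split train/val/test proportions (sum 1).
#' @param seed RNG seed.
#' @return object of class `semg_train_config`.
#' @export
train_config <- function(lr = 0.001, lr_late = 0.0001, lr_drop_epoch = 150,
                         epochs = 300, batch = 64, weight_decay = 1e-4,
                         split = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(split) - 1) > 1e-8) stop("train_config: split must sum to 1")
  if (any(split <= 0)) stop("train_config: split ratios must be positive")
  structure(list(lr = lr, lr_late = lr_late, lr_drop_epoch = as.integer(lr_drop_epoch),
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 weight_decay = weight_decay, split = split, seed = as.integer(seed)),
            class = "semg_train_config")
}

#' Learning rate in effect at a given epoch
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch number.
#' @return the scheduled learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (epoch > cfg$lr_drop_epoch) cfg$lr_late else cfg$lr
}

#' Stratified train/validation/test split of a sample pool
#'
#' Random partition, stratified by class so every class appears in every
#' pool in (approximately) the given proportions; deterministic given the
#' seed.
#'
#' @param pool a `semg_pool` (or any list with a `gesture` vector and
#'   indexable samples via `id`).
#' @param ratios positive proportions summing to 1.
#' @param seed RNG seed.
#' @return list `train`, `val`, `test` of sample indices into the pool.
#' @export
split_dataset <- function(pool, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8 || any(ratios <= 0))
    stop("split_dataset: ratios must be positive and sum to 1")
  set.seed(seed)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (g in sort(unique(pool$gesture))) {
    members <- sample(pool$id[pool$gesture == g])
    n <- length(members)
    if (n < 3) stop(sprintf("split_dataset: class %d has %d samples; need >= 3 to stratify", g, n))
    n1 <- max(1L, round(ratios[1] * n))
    n2 <- max(1L, round(ratios[2] * n))
    if (n1 + n2 >= n) { n1 <- n - 2L; n2 <- 1L }
    idx$train <- c(idx$train, members[seq_len(n1)])
    idx$val <- c(idx$val, members[n1 + seq_len(n2)])
    idx$test <- c(idx$test, members[(n1 + n2 + 1L):n])
  }
  idx
}

# accuracy of a parameter set on an index subset of a pool, in eval mode
pool_accuracy <- function(theta, net_cfg, pool, idx, stats = NULL, batch = 256L) {
  hits <- 0
  for (s in seq(1, length(idx), by = batch)) {
    sel <- idx[s:min(s + batch - 1L, length(idx))]
    probs <- net_predict(theta, pool$x[, , , sel, drop = FALSE], net_cfg,
                         training = is.null(stats), stats = stats)
    hits <- hits + sum(max.col(probs) == pool$gesture[sel])
  }
  hits / length(idx)
}

#' Conventional supervised training
#'
#' Minimizes the cross-entropy on the training pool with Adam, the two-stage
#' learning-rate schedule and L2 weight decay; tracks running batch-norm
#' statistics for evaluation and returns the checkpoint with the best
#' validation accuracy.
#'
#' @param theta initial parameters ([init_params()]).
#' @param net_cfg the [network_config()].
#' @param pool a `semg_pool` holding all samples.
#' @param idx split indices from [split_dataset()] (`train` and `val` used).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list `theta` (best-validation checkpoint), `stats` (its running
#'   batch-norm statistics), `history` (per-epoch data.frame: lr, train
#'   loss, train accuracy, val accuracy), `final_theta`.
#' @export
train_supervised <- function(theta, net_cfg, pool, idx, cfg, verbose = FALSE) {
  set.seed(cfg$seed)
  opt <- adam_state(theta)
  stats <- NULL
  nE <- cfg$epochs
  history <- data.frame(epoch = seq_len(nE), lr = rep(NA_real_, nE),
                        train_loss = rep(NA_real_, nE),
                        train_acc = rep(NA_real_, nE), val_acc = rep(NA_real_, nE))
  best <- list(theta = theta, stats = NULL, val = -Inf)
  train_idx <- idx$train
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, ep)
    ord <- sample(train_idx)
    ep_loss <- 0
    ep_hits <- 0
    nb <- 0L
    for (s in seq(1, length(ord), by = cfg$batch)) {
      sel <- ord[s:min(s + cfg$batch - 1L, length(ord))]
      if (length(sel) < 2) next # batch statistics need >= 2 samples
      lg <- net_loss_grad(theta, pool$x[, , , sel, drop = FALSE],
                          pool$gesture[sel], net_cfg)
      if (!is.finite(lg$loss)) stop("train_supervised: loss diverged at epoch ", ep)
      st <- adam_step(theta, lg$grad, opt, lr, weight_decay = cfg$weight_decay)
      theta <- st$theta
      opt <- st$state
      ep_loss <- ep_loss + lg$loss
      ep_hits <- ep_hits + sum(max.col(lg$probs) == pool$gesture[sel])
      nb <- nb + 1L
      stats <- update_bn_stats_list(stats, lg$bn_stats)
    }
    val_acc <- pool_accuracy(theta, net_cfg, pool, idx$val, stats = stats)
    history$lr[ep] <- lr
    history$train_loss[ep] <- ep_loss / max(nb, 1L)
    history$train_acc[ep] <- ep_hits / length(train_idx)
    history$val_acc[ep] <- val_acc
    if (val_acc >= best$val) best <- list(theta = theta, stats = stats, val = val_acc)
    if (verbose)
      message(sprintf("epoch %d | lr %g | train loss %.4f | val acc %.3f",
                      ep, lr, history$train_loss[ep], val_acc))
  }
  list(theta = best$theta, stats = best$stats, history = history,
       final_theta = theta, final_stats = stats)
}

#' Pretrain-then-transfer evaluation on unseen subjects
#'
#' Trains a model on the pooled samples of the training subjects (70/30
#' train/validation split, stratified by class) and evaluates the frozen
#' best-validation checkpoint on the samples of the held-out subjects. The
#' gap between the two accuracies quantifies how badly a conventionally
#' pretrained model transfers across subjects.
#'
#' @param theta initial parameters.
#' @param net_cfg the [network_config()].
#' @param pool a `semg_pool` over all subjects.
#' @param train_subjects,test_subjects disjoint subject index vectors.
#' @param cfg a [train_config()].
#' @param verbose print progress.
#' @return list `val_acc`, `test_acc`, `gap` (val - test, in accuracy
#'   points), plus the fitted model (`theta`, `stats`, `history`).
#' @export
pretrain_transfer_eval <- function(theta, net_cfg, pool, train_subjects,
                                   test_subjects, cfg, verbose = FALSE) {
  ov <- intersect(train_subjects, test_subjects)
  if (length(ov)) stop("pretrain_transfer_eval: subjects overlap: ",
                       paste(ov, collapse = ","))
  tr_all <- pool$id[pool$subject %in% train_subjects]
  te <- pool$id[pool$subject %in% test_subjects]
  if (!length(tr_all) || !length(te))
    stop("pretrain_transfer_eval: empty train or test subject pool")
  sub <- list(gesture = pool$gesture[tr_all], id = tr_all)
  spl <- split_dataset(sub, c(0.7, 0.15, 0.15), seed = cfg$seed)
  idx <- list(train = spl$train, val = c(spl$val, spl$test)) # 70/30
  fit <- train_supervised(theta, net_cfg, pool, idx, cfg, verbose = verbose)
  val_acc <- pool_accuracy(fit$theta, net_cfg, pool, idx$val, stats = fit$stats)
  test_acc <- pool_accuracy(fit$theta, net_cfg, pool, te, stats = fit$stats)
  list(val_acc = val_acc, test_acc = test_acc, gap = val_acc - test_acc,
       n_val = length(idx$val), n_test = length(te),
       theta = fit$theta, stats = fit$stats, history = fit$history)
}
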