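test_that("stratified splitting hits 6:2:2 and partitions the pool", {
  pool <- dummy_pool(n_classes = 5, n_subjects = 4, per_cell = 5) # 100 samples
  idx <- split_dataset(pool, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(vapply(idx, length, integer(1)), c(train = 60L, val = 20L, test = 20L))
  all_idx <- unname(sort(unlist(idx)))
  expect_equal(all_idx, pool$id) # union = input, pairwise disjoint
  expect_identical(idx, split_dataset(pool, c(0.6, 0.2, 0.2), seed = 1))
  # every class present in every pool
  for (p in idx) expect_setequal(unique(pool$gesture[p]), 1:5)
  tiny <- dummy_pool(n_classes = 2, n_subjects = 1, per_cell = 2)
  expect_error(split_dataset(tiny), "stratify")
  expect_error(split_dataset(pool, c(0.5, 0.5, 0.2)), "sum to 1")
})

test_that("the learning-rate schedule drops after epoch 150", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 1), 0.001)
  expect_equal(lr_at_epoch(cfg, 150), 0.001)
  expect_equal(lr_at_epoch(cfg, 151), 0.0001)
  expect_equal(cfg$epochs, 300L)
  expect_equal(cfg$batch, 64L)
  expect_equal(cfg$weight_decay, 1e-4)
})

test_that("zero-epoch training returns the initial parameters untouched", {
  pool <- easy_pool()
  netc <- easy_net_cfg(8)
  th0 <- init_params(netc, seed = 1)
  idx <- split_dataset(pool, seed = 1)
  fit <- train_supervised(th0, netc, pool, idx, train_config(epochs = 0, seed = 1))
  expect_param_equal(fit$final_theta, th0)
  expect_equal(nrow(fit$history), 0)
})

test_that("supervised training learns the easy profile well above chance", {
  pool <- easy_pool()
  netc <- easy_net_cfg(8)
  idx <- split_dataset(pool, seed = 7)
  cfg <- train_config(epochs = 18, batch = 32, lr_drop_epoch = 8, lr_late = 3e-4, seed = 7)
  fit <- train_supervised(init_params(netc, seed = 7), netc, pool, idx, cfg)
  expect_gt(max(fit$history$train_acc), 0.5) # chance = 0.125
  expect_equal(fit$history$lr[9], 3e-4) # schedule recorded in the history
  # best-validation checkpointing: returned model at least as good as final
  expect_gte(max(fit$history$val_acc), fit$history$val_acc[nrow(fit$history)])
  best_acc <- semgmeta:::pool_accuracy(fit$theta, netc, pool, idx$val, stats = fit$stats)
  expect_equal(best_acc, max(fit$history$val_acc), tolerance = 1e-12)
})

test_that("shuffled labels are memorized but do not generalize", {
  pool <- study_pool()
  sub <- semgmeta:::subset_pool(pool, pool$subject %in% 1:2)
  set.seed(5)
  sub$gesture <- sample(sub$gesture) # destroy the label-signal link
  netc <- easy_net_cfg(8)
  idx <- split_dataset(sub, c(0.6, 0.2, 0.2), seed = 5)
  fit <- train_supervised(init_params(netc, 5), netc, sub, idx,
                          train_config(epochs = 15, batch = 32,
                                       lr_drop_epoch = 10, seed = 5))
  h <- fit$history
  expect_gt(h$train_acc[15], 0.3)  # memorization (chance = 0.125)
  expect_lt(max(h$val_acc), 0.3)   # validation stays near chance
})

test_that("pretraining rejects overlapping subject sets", {
  pool <- easy_pool()
  netc <- easy_net_cfg(8)
  expect_error(pretrain_transfer_eval(init_params(netc, 1), netc, pool,
                                      1:6, 6:8, train_config(epochs = 1)),
               "overlap")
})
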