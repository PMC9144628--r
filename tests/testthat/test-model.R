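sigmoid <- function(z) 1 / (1 + exp(-z))

test_that("channel attention: zero weights halve the input exactly", {
  X <- array(stats::rnorm(2 * 3 * 3), c(2, 3, 3))
  p <- list(W1 = matrix(0, 1, 2), W2 = matrix(0, 2, 1))
  expect_equal(channel_attention(X, p), 0.5 * X, tolerance = 0)
})

test_that("channel attention matches scalar arithmetic on a hand-set example", {
  X <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2)) # 2 channels, 2x2
  p <- list(W1 = matrix(c(0.3, -0.2), 1, 2), W2 = matrix(c(0.5, 1.5), 2, 1))
  # independent brute-force arithmetic
  gap <- apply(X, 1, mean); gmp <- apply(X, 1, max)
  pool <- gap + gmp
  h <- max(sum(p$W1 * pool), 0)
  a <- sigmoid(as.numeric(p$W2) * h)
  expected <- X * array(rep(a, 4), c(2, 2, 2))
  expect_equal(channel_attention(X, p), expected, tolerance = 1e-12)
})

test_that("attention gating never amplifies: |Y| < |X| where X is nonzero", {
  set.seed(4)
  X <- array(stats::rnorm(4 * 5 * 6), c(4, 5, 6))
  pc <- list(W1 = matrix(stats::rnorm(2 * 4), 2, 4), W2 = matrix(stats::rnorm(4 * 2), 4, 2))
  Yc <- channel_attention(X, pc)
  expect_true(all(abs(Yc) < abs(X) | X == 0)) # sigmoid in (0, 1)
  ps <- list(w1 = 0.7, w2 = -0.4, W3 = matrix(stats::rnorm(9), 3, 3))
  Ys <- spatial_attention(X, ps)
  expect_true(all(abs(Ys) < abs(X) | X == 0))
})

test_that("spatial attention: zero weights halve; 1x1 unit map matches by hand", {
  X <- array(stats::rnorm(3 * 4 * 4), c(3, 4, 4))
  p0 <- list(w1 = 0, w2 = 0, W3 = matrix(0, 1, 1))
  expect_equal(spatial_attention(X, p0), 0.5 * X, tolerance = 0)

  X1 <- array(c(0.5, -1, 2, 0.25), c(1, 2, 2)) # single channel 2x2
  p1 <- list(w1 = 1, w2 = 1, W3 = matrix(1, 1, 1))
  # by hand: gap = gmp = X; A = sigmoid(relu(2 X)); Y = X * A
  A <- sigmoid(pmax(2 * X1[1, , ], 0))
  expect_equal(spatial_attention(X1, p1)[1, , ], X1[1, , ] * A, tolerance = 1e-12)
})

test_that("cells produce the documented shapes and non-negative outputs", {
  cfg <- network_config(c(33, 33, 128), n_classes = 8) # full-scale plan
  th <- init_params(cfg, seed = 1)
  X <- array(stats::rnorm(128 * 33 * 33), c(128, 33, 33))
  out <- csac_cell(X, th$cells[[1]], "csac")
  expect_equal(dim(out), c(64L, 16L, 16L)) # 128x33x33 -> 64x16x16
  expect_true(all(out >= 0)) # post-ReLU (pool preserves sign)
  out_cnn <- csac_cell(X, init_params(network_config(c(33, 33, 128), 8,
                                                     variant = "cnn"), 1)$cells[[1]], "cnn")
  expect_equal(dim(out_cnn), dim(out)) # replacement keeps the shape
})

test_that("variant parameter counts stay within 20% of each other", {
  for (plan in list(NULL, c(8, 8, 8))) {
    counts <- vapply(c("csac", "sac", "cac", "cnn"), function(v) {
      cfg <- network_config(c(33, 33, if (is.null(plan)) 128 else 16), 8,
                            cell_channels = plan, variant = v)
      param_count(init_params(cfg, 1))
    }, numeric(1))
    expect_lt(max(counts) / min(counts) - 1, 0.20)
  }
})

test_that("forward pass returns normalized, deterministic probabilities", {
  cfg <- easy_net_cfg(8)
  th <- init_params(cfg, seed = 3)
  set.seed(5)
  one <- array(stats::rnorm(33 * 33 * 16), c(33, 33, 16))
  X <- array(0, c(33, 33, 16, 4))
  for (b in 1:4) X[, , , b] <- one # identical inputs
  pr <- net_predict(th, X, cfg)
  expect_equal(rowSums(pr), rep(1, 4), tolerance = 1e-6)
  expect_true(all(pr >= 0))
  for (b in 2:4) expect_equal(pr[b, ], pr[1, ], tolerance = 1e-12)
  expect_error(net_predict(th, X[, 1:10, , , drop = FALSE], cfg), "match config")
})

test_that("permuting the classifier rows permutes the class probabilities", {
  cfg <- easy_net_cfg(5)
  th <- init_params(cfg, seed = 2)
  X <- array(stats::rnorm(33 * 33 * 16 * 2), c(33, 33, 16, 2))
  pr <- net_predict(th, X, cfg)
  perm <- c(3, 1, 5, 2, 4)
  th2 <- th
  th2$fc_W <- th$fc_W[perm, ]
  th2$fc_b <- th$fc_b[perm]
  expect_equal(net_predict(th2, X, cfg), pr[, perm], tolerance = 1e-12)
})

test_that("cross-entropy reproduces closed-form values", {
  expect_equal(cross_entropy(c(1, 0, 0), 1), 0)
  expect_equal(cross_entropy(rep(1 / 8, 8), 3), log(8), tolerance = 1e-12)
  expect_equal(cross_entropy(c(0.7, 0.2, 0.1), 1), -log(0.7), tolerance = 1e-12)
  expect_gt(cross_entropy(c(0, 1), 1), 20) # clamped, large but finite
})

test_that("analytic gradients match central finite differences on a tiny net", {
  # evaluation point chosen away from ReLU/max-pool kinks, where the loss is
  # differentiable and central differences are valid
  cfg <- network_config(c(5, 5, 4), n_classes = 2, cell_channels = c(4, 4, 4))
  th <- init_params(cfg, seed = 21)
  set.seed(22)
  X <- array(stats::rnorm(5 * 5 * 4 * 3), c(5, 5, 4, 3))
  y <- c(1L, 2L, 1L)
  ana <- semgmeta:::param_flatten(net_loss_grad(th, X, y, cfg)$grad)
  fl <- semgmeta:::param_flatten(th)
  eps <- 1e-5
  num <- vapply(seq_along(fl), function(i) {
    fp <- fl; fp[i] <- fp[i] + eps
    fm <- fl; fm[i] <- fm[i] - eps
    (net_loss_grad(semgmeta:::param_unflatten(fp, th), X, y, cfg)$loss -
     net_loss_grad(semgmeta:::param_unflatten(fm, th), X, y, cfg)$loss) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - ana)) / max(abs(num)), 1e-4)
})

test_that("checkpoints round-trip and describe_model reports every stage", {
  cfg <- easy_net_cfg(8)
  th <- init_params(cfg, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(th, cfg, path)
  back <- load_checkpoint(path)
  expect_param_equal(back$params, th)
  d <- describe_model(cfg)
  expect_equal(nrow(d), 5)
  expect_equal(sum(d$params), param_count(th))
})
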