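test_that("inner adaptation reproduces closed-form gradient descent", {
  # scalar quadratic L(theta) = 0.5 (theta - c)^2
  cc <- 3.7
  lg <- function(th) list(loss = 0.5 * (th - cc)^2, grad = th - cc)
  th0 <- -1.2
  expect_identical(inner_adapt(th0, lg, alpha = 0), th0)
  one <- inner_adapt(th0, lg, alpha = 0.25, steps = 1)
  expect_identical(one, th0 - 0.25 * (th0 - cc)) # machine precision
  five <- inner_adapt(th0, lg, alpha = 0.25, steps = 5)
  expect_equal(five - cc, (th0 - cc) * 0.75^5, tolerance = 1e-14)
})

test_that("inner step on a linear-softmax model matches finite differences", {
  x <- c(1.3, -0.8)
  y <- 1L
  loss_of <- function(w) {
    logits <- c(sum(w[1:2] * x), sum(w[3:4] * x))
    p <- exp(logits - max(logits)); p <- p / sum(p)
    -log(p[y])
  }
  lg <- function(w) {
    logits <- c(sum(w[1:2] * x), sum(w[3:4] * x))
    p <- exp(logits - max(logits)); p <- p / sum(p)
    d <- p; d[y] <- d[y] - 1
    list(loss = -log(p[y]), grad = c(d[1] * x, d[2] * x))
  }
  w0 <- c(0.2, -0.1, 0.4, 0.3)
  eps <- 1e-6
  gfd <- vapply(1:4, function(i) {
    wp <- w0; wp[i] <- wp[i] + eps
    wm <- w0; wm[i] <- wm[i] - eps
    (loss_of(wp) - loss_of(wm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(gfd - lg(w0)$grad)) / max(abs(gfd)), 1e-4)
  expect_equal(inner_adapt(w0, lg, 0.1), w0 - 0.1 * lg(w0)$grad, tolerance = 1e-15)
})

test_that("meta-gradients match the MAML algebra on quadratic losses", {
  # support L_s = 0.5 (th-a)' A (th-a), query L_q = 0.5 ||th-b||^2
  A <- matrix(c(2, 0.5, 0.5, 1), 2)
  a <- c(1, -1); b <- c(0.5, 2)
  sup <- function(th) list(loss = 0.5 * crossprod(th - a, A %*% (th - a))[1],
                           grad = as.numeric(A %*% (th - a)), probs = NULL)
  qry <- function(th) list(loss = 0.5 * sum((th - b)^2), grad = th - b, probs = NULL)
  th0 <- c(0.3, 0.9)
  alpha <- 0.1
  th1 <- th0 - alpha * as.numeric(A %*% (th0 - a))

  fo <- semgmeta:::task_meta_grad(th0, sup, qry, alpha, 1, second_order = FALSE)
  expect_equal(fo$adapted, th1, tolerance = 1e-12)
  expect_equal(fo$grad, th1 - b, tolerance = 1e-12) # plain query gradient at theta'

  so <- semgmeta:::task_meta_grad(th0, sup, qry, alpha, 1, second_order = TRUE)
  closed <- as.numeric((diag(2) - alpha * A) %*% (th1 - b)) # (I - alpha H) g_q
  expect_equal(so$grad, closed, tolerance = 1e-6) # numerical Hessian-vector

  # alpha -> 0: the meta-gradient degenerates to the plain query gradient
  z <- semgmeta:::task_meta_grad(th0, sup, qry, 0, 1, second_order = TRUE)
  expect_equal(z$grad, th0 - b, tolerance = 1e-12)
})

test_that("meta-training with beta = 0 leaves the parameters untouched", {
  pool <- easy_pool()
  cfg <- easy_net_cfg(5)
  th0 <- init_params(cfg, seed = 1)
  mcfg <- meta_config(alpha = 0.1, beta = 0, meta_batch = 1, second_order = FALSE,
                      outer_optimizer = "sgd", seed = 2)
  fit <- meta_train(th0, cfg, pool, mcfg, n_meta_batches = 2, N = 5, K = 1)
  expect_param_equal(fit$theta, th0)
  expect_equal(nrow(fit$log), 2)
  expect_true(all(is.finite(fit$log$query_loss)))
})

test_that("one FOMAML update equals the hand-rolled two-loop computation", {
  pool <- easy_pool()
  cfg <- easy_net_cfg(5)
  th0 <- init_params(cfg, seed = 3)
  mcfg <- meta_config(alpha = 0.05, beta = 0.01, meta_batch = 1,
                      second_order = FALSE, outer_optimizer = "sgd",
                      clip_norm = Inf, seed = 42)
  fit <- meta_train(th0, cfg, pool, mcfg, n_meta_batches = 1, N = 5, K = 1)
  # oracle: replay the same task draw and do the two loops by hand
  set.seed(42)
  task <- sample_task(pool, 5, 1)
  sup <- semgmeta:::task_batch(pool, task$support_idx, task$support_y)
  qry <- semgmeta:::task_batch(pool, task$query_idx, task$query_y)
  g_sup <- net_loss_grad(th0, sup$x, sup$y, cfg)$grad
  th1 <- semgmeta:::param_axpy(th0, g_sup, -0.05)
  g_qry <- net_loss_grad(th1, qry$x, qry$y, cfg)$grad
  expected <- semgmeta:::param_axpy(th0, g_qry, -0.01)
  expect_param_equal(fit$theta, expected, tol = 1e-12)
})

test_that("meta-testing reports per-step accuracies with the right geometry", {
  pool <- easy_pool()
  cfg <- easy_net_cfg(5)
  th <- init_params(cfg, seed = 4)
  mcfg0 <- meta_config(inner_steps_test = 0, seed = 1)
  r0 <- meta_test(th, cfg, pool, mcfg0, n_tasks = 3, N = 5, K = 1, seed = 5)
  expect_equal(dim(r0$acc), c(3L, 1L)) # zero-shot only
  expect_equal(r0$mean_acc_pre, r0$mean_acc_final)
  mcfg2 <- meta_config(inner_steps_test = 2, seed = 1)
  r2 <- meta_test(th, cfg, pool, mcfg2, n_tasks = 3, N = 5, K = 1, seed = 5)
  expect_equal(dim(r2$acc), c(3L, 3L))
  expect_length(r2$mean_by_step, 3)
  expect_true(all(r2$acc_topk >= r2$acc)) # top-5 >= top-1 by construction
  expect_error(meta_test(th, cfg, pool, mcfg2, n_tasks = 0), "empty")
})
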