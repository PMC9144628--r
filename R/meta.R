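#' Meta-learning configuration
#'
#' Hyperparameters of MAML training and testing. Defaults follow the study
#' conditions: fast (inner) learning rate 0.1, meta learning rate 0.001 with
#' Adam, one inner iteration during meta-training, and task batches of 8.
#'
#' @param alpha inner-loop (fast) learning rate.
#' @param beta outer-loop (meta) learning rate.
#' @param meta_batch tasks per meta-update.
#' @param inner_steps_train inner gradient steps during meta-training.
#' @param inner_steps_test inner gradient steps during meta-testing; query
#'   accuracy is recorded after every step.
#' @param outer_optimizer `"adam"` or `"sgd"`.
#' @param second_order if `TRUE`, the meta-gradient flows through the inner
#'   update (Hessian-vector products); if `FALSE`, first-order MAML.
#' @param clip_norm global-norm ceiling for the averaged meta-gradient
#'   (`Inf` disables); gradient clipping is the customary stabilizer of the
#'   outer loop.
#' @param hvp `"central"` or `"forward"` finite-difference Hessian-vector
#'   product for second-order meta-gradients; forward differences reuse the
#'   inner-loop gradient and cost one evaluation instead of two.
#' @param n_tasks default task-stream length.
#' @param seed RNG seed.
#' @return object of class `semg_meta_config`.
#' @export
meta_config <- function(alpha = 0.1, beta = 0.001, meta_batch = 8,
                        inner_steps_train = 1, inner_steps_test = 5,
                        outer_optimizer = c("adam", "sgd"), second_order = TRUE,
                        clip_norm = 10, hvp = c("central", "forward"),
                        n_tasks = 20000, seed = 1L) {
  outer_optimizer <- match.arg(outer_optimizer)
  hvp <- match.arg(hvp)
  if (alpha < 0 || beta < 0) stop("meta_config: learning rates must be >= 0")
  if (meta_batch < 1) stop("meta_config: meta_batch must be >= 1")
  if (clip_norm <= 0) stop("meta_config: clip_norm must be positive")
  structure(list(alpha = alpha, beta = beta, meta_batch = as.integer(meta_batch),
                 inner_steps_train = as.integer(inner_steps_train),
                 inner_steps_test = as.integer(inner_steps_test),
                 outer_optimizer = outer_optimizer, second_order = isTRUE(second_order),
                 clip_norm = clip_norm, hvp = hvp,
                 n_tasks = as.integer(n_tasks), seed = as.integer(seed)),
            class = "semg_meta_config")
}

#' Inner-loop adaptation (fast weights)
#'
#' Performs `steps` plain gradient-descent updates
#' `theta' = theta - alpha * grad L(theta)` of the full parameter set on the
#' support loss. The original parameters are never mutated.
#'
#' @param theta parameter list (any nested list of numeric arrays, or a bare
#'   numeric vector).
#' @param loss_grad function `theta -> list(loss, grad)` with `grad` shaped
#'   like `theta`; for a network use [net_loss_grad()] closed over the
#'   support batch.
#' @param alpha fast learning rate.
#' @param steps number of updates (>= 0).
#' @return adapted parameters, same shape as `theta`.
#' @export
inner_adapt <- function(theta, loss_grad, alpha, steps = 1) {
  for (s in seq_len(steps)) {
    lg <- loss_grad(theta)
    if (!is.finite(lg$loss)) stop("inner_adapt: non-finite support loss at step ", s)
    theta <- if (is.list(theta)) param_axpy(theta, lg$grad, -alpha)
             else theta - alpha * lg$grad
  }
  theta
}

# Hessian-vector product of a scalar loss via finite differences of its
# gradient. Central: H v ~ (g(theta + eps v) - g(theta - eps v)) / (2 eps),
# two gradient evaluations, O(eps^2) accurate. Forward: reuses the gradient
# g0 = g(theta) already computed by the inner loop, one extra evaluation,
# O(eps) accurate — ample for optimization.
hvp_fd <- function(theta, grad_fn, v, eps_scale = 1e-4, g0 = NULL) {
  vflat <- param_flatten(v)
  vn <- sqrt(sum(vflat^2))
  if (vn == 0) return(param_map(v, function(x) x * 0))
  tn <- sqrt(sum(param_flatten(theta)^2))
  eps <- eps_scale * max(1, tn) / vn
  gp <- grad_fn(param_axpy(theta, v, eps))$grad
  if (is.null(g0)) {
    gm <- grad_fn(param_axpy(theta, v, -eps))$grad
    param_map2(gp, gm, function(a, b) (a - b) / (2 * eps))
  } else {
    param_map2(gp, g0, function(a, b) (a - b) / eps)
  }
}

# Meta-gradient of one task. First-order: query gradient at the adapted
# parameters. Second-order: backpropagate through the inner trajectory,
# v <- (I - alpha H_support(theta_k)) v at every inner step (exact algebra;
# the Hessian-vector product is computed by finite differences of the
# support gradient, see hvp_fd).
task_meta_grad <- function(theta, support_lg, query_lg, alpha, steps, second_order,
                           hvp = c("central", "forward")) {
  hvp <- match.arg(hvp)
  traj <- vector("list", steps + 1)
  grads <- vector("list", steps)
  traj[[1]] <- theta
  th <- theta
  for (s in seq_len(steps)) {
    grads[[s]] <- support_lg(th)$grad
    th <- param_axpy(th, grads[[s]], -alpha)
    traj[[s + 1]] <- th
  }
  q <- query_lg(th)
  v <- q$grad
  if (second_order && steps > 0) {
    for (s in rev(seq_len(steps))) {
      hv <- hvp_fd(traj[[s]], support_lg, v,
                   g0 = if (hvp == "forward") grads[[s]] else NULL)
      v <- param_axpy(v, hv, -alpha)
    }
  }
  list(grad = v, query_loss = q$loss, query_probs = q$probs, adapted = th)
}

adam_state <- function(theta) {
  list(m = param_map(theta, function(x) x * 0),
       v = param_map(theta, function(x) x * 0), t = 0L)
}

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  if (weight_decay > 0) grad <- param_axpy(grad, theta, weight_decay)
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grad, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grad, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(state$m, state$v,
                    function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  list(theta = param_axpy(theta, upd, -lr), state = state)
}

#' MAML meta-training
#'
#' For every meta-batch of tasks: adapt a copy of the meta-parameters on the
#' task's support set (`inner_steps_train` gradient steps at rate `alpha`),
#' evaluate the adapted copy's query loss, and update the meta-parameters
#' with the outer optimizer on the mean query loss across the batch. With
#' `second_order = TRUE` the outer gradient flows through the inner update.
#'
#' @param theta initial parameters from [init_params()].
#' @param net_cfg the [network_config()].
#' @param pool training `semg_pool`.
#' @param cfg a [meta_config()]; `n_meta_batches * meta_batch` tasks are
#'   sampled from `pool` under `cfg$seed`.
#' @param n_meta_batches number of outer updates.
#' @param N,K task geometry.
#' @param val_pool optional validation pool: every `val_every` meta-batches
#'   the current parameters are meta-tested on `val_tasks` tasks and the
#'   best-validation checkpoint is returned.
#' @param val_every,val_tasks validation cadence and size.
#' @param val_steps inner steps used for validation scoring (defaults to
#'   `cfg$inner_steps_test`); fewer steps make selection cheaper.
#' @param verbose print progress.
#' @return list `theta` (final), `best_theta` (best validation checkpoint, or
#'   final when no validation pool), `log` (data.frame per meta-batch:
#'   query loss, query accuracy, validation accuracy when measured).
#' @export
meta_train <- function(theta, net_cfg, pool, cfg, n_meta_batches,
                       N = 5, K = 5, val_pool = NULL, val_every = 50,
                       val_tasks = 20, val_steps = NULL, verbose = FALSE) {
  set.seed(cfg$seed)
  opt <- if (cfg$outer_optimizer == "adam") adam_state(theta) else NULL
  log <- data.frame(meta_batch = seq_len(n_meta_batches), query_loss = NA_real_,
                    query_acc = NA_real_, val_acc = NA_real_)
  best_theta <- theta
  best_val <- -Inf
  for (mb in seq_len(n_meta_batches)) {
    gsum <- NULL
    loss_acc <- 0
    acc_acc <- 0
    for (ti in seq_len(cfg$meta_batch)) {
      task <- sample_task(pool, N, K)
      sup <- task_batch(pool, task$support_idx, task$support_y)
      qry <- task_batch(pool, task$query_idx, task$query_y)
      sup_lg <- function(p) net_loss_grad(p, sup$x, sup$y, net_cfg)
      qry_lg <- function(p) net_loss_grad(p, qry$x, qry$y, net_cfg)
      tg <- task_meta_grad(theta, sup_lg, qry_lg, cfg$alpha,
                           cfg$inner_steps_train, cfg$second_order, hvp = cfg$hvp)
      gsum <- if (is.null(gsum)) tg$grad else param_axpy(gsum, tg$grad, 1)
      loss_acc <- loss_acc + tg$query_loss
      acc_acc <- acc_acc + topk_accuracy(tg$query_probs, qry$y, 1)
    }
    gmean <- param_map(gsum, function(x) x / cfg$meta_batch)
    if (is.finite(cfg$clip_norm)) {
      gn <- sqrt(sum(param_flatten(gmean)^2))
      if (gn > cfg$clip_norm)
        gmean <- param_map(gmean, function(x) x * (cfg$clip_norm / gn))
    }
    if (cfg$outer_optimizer == "adam") {
      st <- adam_step(theta, gmean, opt, cfg$beta)
      theta <- st$theta
      opt <- st$state
    } else {
      theta <- param_axpy(theta, gmean, -cfg$beta)
    }
    log$query_loss[mb] <- loss_acc / cfg$meta_batch
    log$query_acc[mb] <- acc_acc / cfg$meta_batch
    if (!is.finite(log$query_loss[mb]))
      stop("meta_train: query loss diverged at meta-batch ", mb)
    if (!is.null(val_pool) && (mb %% val_every == 0 || mb == n_meta_batches)) {
      vcfg <- cfg
      if (!is.null(val_steps)) vcfg$inner_steps_test <- as.integer(val_steps)
      # validation must not perturb the training task stream
      rng_state <- get(".Random.seed", envir = globalenv())
      vres <- meta_test(theta, net_cfg, val_pool, vcfg, n_tasks = val_tasks,
                        N = N, K = K, seed = cfg$seed + 7919L)
      assign(".Random.seed", rng_state, envir = globalenv())
      log$val_acc[mb] <- vres$mean_acc_final
      if (vres$mean_acc_final > best_val) {
        best_val <- vres$mean_acc_final
        best_theta <- theta
      }
    }
    if (verbose && mb %% 10 == 0)
      message(sprintf("meta-batch %d | query loss %.4f | query acc %.3f",
                      mb, log$query_loss[mb], log$query_acc[mb]))
  }
  if (is.null(val_pool)) best_theta <- theta
  list(theta = theta, best_theta = best_theta, log = log)
}

#' MAML meta-testing on held-out tasks
#'
#' For each test task: record the unadapted (step-0) query accuracy, then
#' perform `inner_steps_test` gradient steps on the support set, recording
#' query top-1 and top-k accuracy after every step.
#'
#' @param theta meta-trained parameters.
#' @param net_cfg the [network_config()].
#' @param pool test `semg_pool` (held-out subjects).
#' @param cfg a [meta_config()].
#' @param n_tasks number of test tasks.
#' @param N,K task geometry.
#' @param topk the additional k for top-k reporting (capped at N).
#' @param seed RNG seed for the task stream.
#' @return list with `acc` (tasks x (steps+1) matrix of top-1 accuracy per
#'   inner step, column 1 = step 0), `acc_topk`, per-step means and SDs,
#'   `mean_acc_pre` (step 0), `mean_acc_final` (last step), and
#'   `mean_acc_best` (best fixed step).
#' @export
meta_test <- function(theta, net_cfg, pool, cfg, n_tasks = 100, N = 5, K = 5,
                      topk = 5, seed = 1L) {
  if (n_tasks < 1) stop("meta_test: empty task stream")
  tasks <- task_stream(pool, n_tasks, N, K, seed)
  kk <- min(topk, N)
  steps <- cfg$inner_steps_test
  acc <- matrix(NA_real_, n_tasks, steps + 1)
  acck <- matrix(NA_real_, n_tasks, steps + 1)
  for (i in seq_len(n_tasks)) {
    task <- tasks[[i]]
    sup <- task_batch(pool, task$support_idx, task$support_y)
    qry <- task_batch(pool, task$query_idx, task$query_y)
    sup_lg <- function(p) net_loss_grad(p, sup$x, sup$y, net_cfg)
    th <- theta
    probs <- net_predict(th, qry$x, net_cfg, training = TRUE)
    acc[i, 1] <- topk_accuracy(probs, qry$y, 1)
    acck[i, 1] <- topk_accuracy(probs, qry$y, kk)
    for (s in seq_len(steps)) {
      th <- inner_adapt(th, sup_lg, cfg$alpha, 1)
      probs <- net_predict(th, qry$x, net_cfg, training = TRUE)
      acc[i, s + 1] <- topk_accuracy(probs, qry$y, 1)
      acck[i, s + 1] <- topk_accuracy(probs, qry$y, kk)
    }
  }
  list(acc = acc, acc_topk = acck,
       mean_by_step = colMeans(acc), sd_by_step = apply(acc, 2, stats::sd),
       mean_topk_by_step = colMeans(acck),
       mean_acc_pre = mean(acc[, 1]), mean_acc_final = mean(acc[, steps + 1]),
       mean_acc_best = max(colMeans(acc)))
}
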