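#' Configuration of the attention convolution network
#'
#' The network (CSAC-Net) is three attention-convolution cells followed by a
#' fully connected layer and softmax. Each cell applies a 3x3 convolution, a
#' channel-spatial attention module (CSAM: channel attention then spatial
#' attention), batch normalization, ReLU and 2x2 max pooling. Ablation
#' variants replace one or both attention stages by a channel-preserving
#' (depthwise) 3x3 convolution of matched complexity: `"sac"` drops channel
#' attention, `"cac"` drops spatial attention, `"cnn"` drops both.
#'
#' @param input_shape integer `c(H, W, C)` of one input feature map, e.g.
#'   `c(33, 33, 128)` for the spectrogram of a 128-channel grid.
#' @param n_classes number of gesture classes (>= 2).
#' @param cell_channels output channels of the three cells. Default
#'   `c(64, 64, 32)` for inputs with >= 64 channels (the full-scale plan
#'   128-64-64-32), `c(8, 8, 8)` otherwise.
#' @param variant `"csac"`, `"sac"`, `"cac"` or `"cnn"`.
#' @param reduction channel-attention bottleneck ratio r (must divide every
#'   cell channel count).
#' @param sam_kernel spatial-attention convolution size (odd).
#' @param bn_eps batch-normalization variance floor.
#' @return object of class `semg_net_config`, including the traced shapes of
#'   every cell output and the flattened classifier width.
#' @export
network_config <- function(input_shape, n_classes, cell_channels = NULL,
                           variant = c("csac", "sac", "cac", "cnn"),
                           reduction = 4, sam_kernel = 7, bn_eps = 1e-5) {
  variant <- match.arg(variant)
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3, n_classes >= 2)
  Cin <- input_shape[3]
  if (is.null(cell_channels))
    cell_channels <- if (Cin >= 64) c(64L, 64L, 32L) else c(8L, 8L, 8L)
  cell_channels <- as.integer(cell_channels)
  stopifnot(length(cell_channels) == 3)
  if (any(cell_channels %% reduction != 0))
    stop("network_config: reduction must divide every cell channel count")
  if (sam_kernel %% 2 != 1) stop("network_config: sam_kernel must be odd")

  # shape trace: 3x3 conv with pad 1 preserves H,W; pool halves (floor) and
  # no-ops on degenerate (< 2) dims so tiny inputs still flow
  h <- input_shape[1]; w <- input_shape[2]
  shapes <- vector("list", 3)
  for (i in 1:3) {
    if (h >= 2) h <- h %/% 2L
    if (w >= 2) w <- w %/% 2L
    shapes[[i]] <- c(h, w, cell_channels[i])
  }
  # large maps (raw-signal / spectrum inputs) are reduced to 4x4 by adaptive
  # average pooling so the classifier width stays fixed
  adaptive <- (h > 4L || w > 4L)
  hf <- min(h, 4L); wf <- min(w, 4L)
  fc_in <- hf * wf * cell_channels[3]

  structure(list(input_shape = input_shape, n_classes = as.integer(n_classes),
                 cell_channels = cell_channels, variant = variant,
                 reduction = as.integer(reduction), sam_kernel = as.integer(sam_kernel),
                 bn_eps = bn_eps, cell_shapes = shapes, adaptive = adaptive,
                 final_hw = c(hf, wf), fc_in = as.integer(fc_in)),
            class = "semg_net_config")
}

#' Initialize network parameters
#'
#' He-scaled Gaussian initialization for convolutions, Glorot-scaled for the
#' attention bottleneck and classifier; spatial-attention pooling weights
#' start at 1 (pass-through) and batch-norm at identity.
#'
#' @param cfg a [network_config()].
#' @param seed RNG seed.
#' @param zero_head if `TRUE` the classifier weights start at zero, the
#'   usual convention for meta-learned models: one inner gradient step from
#'   a zero head scores query samples by their similarity to class-mean
#'   support features, which makes few-shot adaptation effective from the
#'   first meta-update.
#' @return nested named list of numeric arrays (class `semg_net_params`).
#' @export
init_params <- function(cfg, seed = 1L, zero_head = FALSE) {
  set.seed(seed)
  he <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
  cells <- vector("list", 3)
  cin <- cfg$input_shape[3]
  for (i in 1:3) {
    cout <- cfg$cell_channels[i]
    cr <- cout %/% cfg$reduction
    cell <- list(conv_W = he(c(3, 3, cin, cout), 9 * cin), conv_b = numeric(cout))
    use_cam <- cfg$variant %in% c("csac", "cac")
    use_sam <- cfg$variant %in% c("csac", "sac")
    if (use_cam) {
      cell$cam_W1 <- matrix(stats::rnorm(cr * cout, 0, sqrt(2 / cout)), cr, cout)
      cell$cam_W2 <- matrix(stats::rnorm(cout * cr, 0, sqrt(2 / max(cr, 1))), cout, cr)
    }
    if (use_sam) {
      cell$sam_w1 <- 1
      cell$sam_w2 <- 1
      cell$sam_W3 <- matrix(stats::rnorm(cfg$sam_kernel^2, 0, sqrt(2 / cfg$sam_kernel^2)),
                            cfg$sam_kernel, cfg$sam_kernel)
    }
    if (!use_cam || !use_sam) { # depthwise replacement keeps complexity matched
      cell$dw_W <- he(c(3, 3, cout), 9)
      cell$dw_b <- numeric(cout)
    }
    cell$bn_gamma <- rep(1, cout)
    cell$bn_beta <- numeric(cout)
    cells[[i]] <- cell
    cin <- cout
  }
  fc_W <- if (zero_head) matrix(0, cfg$n_classes, cfg$fc_in)
          else matrix(stats::rnorm(cfg$n_classes * cfg$fc_in, 0, sqrt(1 / cfg$fc_in)),
                      cfg$n_classes, cfg$fc_in)
  p <- list(cells = cells, fc_W = fc_W, fc_b = numeric(cfg$n_classes))
  class(p) <- "semg_net_params"
  p
}

#' Total number of trainable parameters
#' @param params a parameter list from [init_params()].
#' @return integer count.
#' @export
param_count <- function(params) length(param_flatten(params))

## ---- parameter-list arithmetic (used by optimizers and MAML) ----

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(param_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

param_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, param_map, f = f)
    attributes(out) <- attributes(a)
    out
  } else f(a)
}

# theta + s * g, preserving structure
param_axpy <- function(theta, g, s) param_map2(theta, g, function(x, y) x + s * y)

param_flatten <- function(p) unlist(p, use.names = FALSE)

param_unflatten <- function(vec, skeleton) {
  i <- 0L
  fill <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, fill)
      attributes(out) <- attributes(x)
      return(out)
    }
    n <- length(x)
    v <- vec[(i + 1L):(i + n)]
    i <<- i + n
    attributes(v) <- attributes(x)
    v
  }
  out <- fill(skeleton)
  stopifnot(i == length(vec))
  out
}

## ---- exported attention operations (single feature map, C x H x W) ----

#' Channel attention gating
#'
#' Gates each channel of a feature map by
#' `a = sigmoid(W2 relu(W1 (GAP + GMP)))`, where GAP/GMP are global average
#' and max pooling over the spatial dimensions, so `Y[c,,] = a[c] * X[c,,]`.
#' With all-zero weights `a = sigmoid(0) = 0.5` exactly.
#'
#' @param X numeric array `C x H x W`.
#' @param p list with `W1` (C/r x C) and `W2` (C x C/r).
#' @return gated array of the same shape.
#' @export
channel_attention <- function(X, p) {
  stopifnot(length(dim(X)) == 3)
  d <- dim(X)
  if (ncol(p$W1) != d[1] || nrow(p$W2) != d[1])
    stop("channel_attention: weight/channel mismatch")
  Xb <- array(aperm(X, c(2, 3, 1)), c(d[2], d[3], d[1], 1))
  Y <- cpp_cam_fw(Xb, p$W1, p$W2)$Y
  aperm(array(Y, c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' Spatial attention gating
#'
#' Gates each spatial position of a feature map by the map
#' `A = sigmoid(W3 relu(w1 GAP + w2 GMP))`, where GAP/GMP pool across
#' channels per pixel and `W3` is a k x k convolution producing one
#' attention map, so `Y[c,,] = A * X[c,,]`.
#'
#' @param X numeric array `C x H x W`.
#' @param p list with scalars `w1`, `w2` and matrix `W3` (k x k, k odd).
#' @return gated array of the same shape.
#' @export
spatial_attention <- function(X, p) {
  stopifnot(length(dim(X)) == 3)
  d <- dim(X)
  Xb <- array(aperm(X, c(2, 3, 1)), c(d[2], d[3], d[1], 1))
  Y <- cpp_sam_fw(Xb, p$w1, p$w2, p$W3)$Y
  aperm(array(Y, c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' One attention-convolution cell
#'
#' Conv(3x3, pad 1) -> attention (per `variant`) -> batch norm (single-map
#' statistics) -> ReLU -> 2x2 max pool. Exposed mainly for inspection; the
#' full network applies the same stages on batches.
#'
#' @param X numeric array `C1 x H x W`.
#' @param cell parameter list for one cell (see [init_params()]).
#' @param variant one of `"csac"`, `"sac"`, `"cac"`, `"cnn"`.
#' @param bn_eps batch-norm epsilon.
#' @return array `C2 x H' x W'` with spatial dims halved (floor).
#' @export
csac_cell <- function(X, cell, variant = "csac", bn_eps = 1e-5) {
  stopifnot(length(dim(X)) == 3)
  d <- dim(X)
  Xb <- array(aperm(X, c(2, 3, 1)), c(d[2], d[3], d[1], 1))
  out <- cell_forward(Xb, cell, variant, bn_eps)$out
  do <- dim(out)
  aperm(array(out, do[1:3]), c(3, 1, 2))
}

#' Cross-entropy loss of a predicted distribution
#'
#' `-sum_i y_i log(p_i)` with predictions clamped at 1e-12; zero exactly when
#' the prediction puts all mass on the true class.
#'
#' @param pred probability vector (sums to 1).
#' @param truth one-hot vector, or a single 1-based class index.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(pred, truth) {
  if (length(truth) == 1) {
    y <- numeric(length(pred))
    y[truth] <- 1
    truth <- y
  }
  stopifnot(length(pred) == length(truth))
  -sum(truth * log(pmax(pred, 1e-12)))
}

## ---- batched cell forward/backward ----

cell_forward <- function(X, cell, variant, bn_eps, training = TRUE, stats = NULL) {
  cache <- list(X = X)
  Y <- cpp_conv2d_fw(X, cell$conv_W, cell$conv_b, 1L)
  cache$conv_out <- Y
  if (variant %in% c("csac", "cac")) {
    cam <- cpp_cam_fw(Y, cell$cam_W1, cell$cam_W2)
    cache$cam <- cam
    cache$cam_in <- Y
    Y <- cam$Y
  }
  if (variant %in% c("sac", "cnn", "cac")) { # depthwise replacement stage
    cache$dw_in <- Y
    Y <- cpp_dwconv2d_fw(Y, cell$dw_W, cell$dw_b, 1L)
  }
  if (variant %in% c("csac", "sac")) {
    sam <- cpp_sam_fw(Y, cell$sam_w1, cell$sam_w2, cell$sam_W3)
    cache$sam <- sam
    cache$sam_in <- Y
    Y <- sam$Y
  }
  if (training || is.null(stats)) {
    bn <- cpp_bn_fw(Y, cell$bn_gamma, cell$bn_beta, bn_eps)
    cache$bn_in <- Y
    cache$bn_mu <- bn$mu
    cache$bn_var <- bn$var
    Y <- bn$Y
  } else {
    Y <- bn_eval(Y, cell$bn_gamma, cell$bn_beta, stats$mu, stats$var, bn_eps)
  }
  cache$bn_out <- Y
  Y <- pmax_keepdim(Y)
  d <- dim(Y)
  if (d[1] >= 2 && d[2] >= 2) {
    mp <- cpp_maxpool2_fw(Y)
    cache$pool_amax <- mp$amax
    cache$pool_indim <- d
    Y <- mp$Y
  }
  list(out = Y, cache = cache)
}

pmax_keepdim <- function(Y) {
  d <- dim(Y)
  Y <- pmax(Y, 0)
  dim(Y) <- d
  Y
}

bn_eval <- function(X, gamma, beta, mu, var, eps) {
  d <- dim(X)
  M <- matrix(X, d[1] * d[2], d[3] * d[4])
  g <- rep(gamma / sqrt(var + eps), d[4])
  off <- rep(beta - gamma * mu / sqrt(var + eps), d[4])
  M <- sweep(sweep(M, 2, g, "*"), 2, off, "+")
  array(M, d)
}

cell_backward <- function(dY, cell, cache, variant, bn_eps) {
  g <- list()
  if (!is.null(cache$pool_amax))
    dY <- cpp_maxpool2_bw(cache$pool_indim, cache$pool_amax, dY)
  mask <- cache$bn_out > 0
  dY <- dY * mask
  dim(dY) <- dim(cache$bn_out)
  bnb <- cpp_bn_bw(cache$bn_in, cell$bn_gamma, cache$bn_mu, cache$bn_var, bn_eps, dY)
  g$bn_gamma <- as.numeric(bnb$dgamma)
  g$bn_beta <- as.numeric(bnb$dbeta)
  dY <- bnb$dX
  if (variant %in% c("csac", "sac")) {
    samb <- cpp_sam_bw(cache$sam_in, cell$sam_w1, cell$sam_w2, cell$sam_W3, cache$sam, dY)
    g$sam_w1 <- samb$dw1
    g$sam_w2 <- samb$dw2
    g$sam_W3 <- samb$dW3
    dY <- samb$dX
  }
  if (variant %in% c("sac", "cnn", "cac")) {
    dwb <- cpp_dwconv2d_bw(cache$dw_in, cell$dw_W, dY, 1L)
    g$dw_W <- dwb$dW
    g$dw_b <- as.numeric(dwb$db)
    dY <- dwb$dX
  }
  if (variant %in% c("csac", "cac")) {
    camb <- cpp_cam_bw(cache$cam_in, cell$cam_W1, cell$cam_W2, cache$cam, dY)
    g$cam_W1 <- camb$dW1
    g$cam_W2 <- camb$dW2
    dY <- camb$dX
  }
  convb <- cpp_conv2d_bw(cache$X, cell$conv_W, dY, 1L)
  g$conv_W <- convb$dW
  g$conv_b <- as.numeric(convb$db)
  # order gradients like the parameter list
  list(grad = g[names(cell)], dX = convb$dX)
}

adaptive_avgpool_fw <- function(X, target) {
  d <- dim(X)
  bounds <- function(n, out) {
    s <- floor((0:(out - 1)) * n / out) + 1
    e <- ceiling((1:out) * n / out)
    cbind(s, e)
  }
  bh <- bounds(d[1], target[1]); bw <- bounds(d[2], target[2])
  Y <- array(0, c(target, d[3], d[4]))
  for (i in seq_len(target[1])) for (j in seq_len(target[2]))
    Y[i, j, , ] <- apply(X[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , , drop = FALSE],
                         c(3, 4), mean)
  list(Y = Y, bh = bh, bw = bw, indim = d)
}

adaptive_avgpool_bw <- function(dY, cache) {
  d <- cache$indim
  dX <- array(0, d)
  for (i in seq_len(nrow(cache$bh))) for (j in seq_len(nrow(cache$bw))) {
    hr <- cache$bh[i, 1]:cache$bh[i, 2]; wr <- cache$bw[j, 1]:cache$bw[j, 2]
    n <- length(hr) * length(wr)
    add <- outer(rep(1 / n, length(hr)), rep(1, length(wr)))
    for (c in seq_len(d[3])) for (b in seq_len(d[4]))
      dX[hr, wr, c, b] <- dX[hr, wr, c, b] + add * dY[i, j, c, b]
  }
  dX
}

#' Network forward pass
#'
#' Runs a batch through the three cells and the softmax classifier.
#'
#' @param params network parameters.
#' @param X batch array `H x W x C x B`.
#' @param cfg the [network_config()].
#' @param training if `TRUE` batch-norm uses batch statistics; if `FALSE`
#'   and `stats` is supplied, stored running statistics are used.
#' @param stats optional list of per-cell running batch-norm statistics.
#' @return list with `probs` (B x n matrix, rows sum to 1) and the layer
#'   caches needed for backpropagation.
#' @export
net_forward <- function(params, X, cfg, training = TRUE, stats = NULL) {
  stopifnot(length(dim(X)) == 4)
  if (!all(dim(X)[1:3] == cfg$input_shape))
    stop(sprintf("net_forward: input dims [%s] do not match config [%s]",
                 paste(dim(X)[1:3], collapse = ","), paste(cfg$input_shape, collapse = ",")))
  caches <- vector("list", 3)
  out <- X
  for (i in 1:3) {
    cf <- cell_forward(out, params$cells[[i]], cfg$variant, cfg$bn_eps,
                       training = training,
                       stats = if (is.null(stats)) NULL else stats[[i]])
    caches[[i]] <- cf$cache
    out <- cf$out
  }
  ad <- NULL
  if (cfg$adaptive && any(dim(out)[1:2] > cfg$final_hw)) {
    ad <- adaptive_avgpool_fw(out, cfg$final_hw)
    out <- ad$Y
  }
  d <- dim(out)
  flat <- matrix(out, d[1] * d[2] * d[3], d[4])
  logits <- params$fc_W %*% flat + params$fc_b
  lm <- apply(logits, 2, max)
  el <- exp(sweep(logits, 2, lm))
  probs <- sweep(el, 2, colSums(el), "/")
  list(probs = t(probs), caches = caches, flat = flat, flat_dim = d, adaptive = ad)
}

#' Mean cross-entropy loss and full parameter gradient of a batch
#'
#' Forward plus analytic backpropagation through every stage; the loss is the
#' batch mean of Eq.-style per-sample cross-entropy.
#'
#' @param params network parameters.
#' @param X batch array `H x W x C x B`.
#' @param y integer class labels (1-based), length B.
#' @param cfg the [network_config()].
#' @return list `loss`, `grad` (parameter-shaped list), `probs` (B x n).
#' @export
net_loss_grad <- function(params, X, y, cfg) {
  B <- dim(X)[4]
  stopifnot(length(y) == B)
  fw <- net_forward(params, X, cfg, training = TRUE)
  P <- t(fw$probs) # n x B
  loss <- -mean(log(pmax(P[cbind(y, seq_len(B))], 1e-12)))
  if (!is.finite(loss)) stop("net_loss_grad: non-finite loss")
  dlog <- P
  dlog[cbind(y, seq_len(B))] <- dlog[cbind(y, seq_len(B))] - 1
  dlog <- dlog / B
  gfc_W <- dlog %*% t(fw$flat)
  gfc_b <- rowSums(dlog)
  dflat <- t(params$fc_W) %*% dlog
  dY <- array(dflat, c(fw$flat_dim))
  if (!is.null(fw$adaptive)) dY <- adaptive_avgpool_bw(dY, fw$adaptive)
  gcells <- vector("list", 3)
  for (i in 3:1) {
    cb <- cell_backward(dY, params$cells[[i]], fw$caches[[i]], cfg$variant, cfg$bn_eps)
    gcells[[i]] <- cb$grad
    dY <- cb$dX
  }
  grad <- list(cells = gcells, fc_W = gfc_W, fc_b = gfc_b)
  class(grad) <- "semg_net_params"
  bn_stats <- lapply(fw$caches, function(cc)
    list(mu = as.numeric(cc$bn_mu), var = as.numeric(cc$bn_var)))
  list(loss = loss, grad = grad, probs = fw$probs, bn_stats = bn_stats)
}

#' Class probabilities for a batch (no gradient)
#'
#' @inheritParams net_loss_grad
#' @param training passed to [net_forward()]; meta-learning evaluation
#'   conventionally keeps batch-statistics normalization (`TRUE`).
#' @param stats optional running batch-norm statistics for `training = FALSE`.
#' @return B x n matrix of probabilities.
#' @export
net_predict <- function(params, X, cfg, training = TRUE, stats = NULL) {
  net_forward(params, X, cfg, training = training, stats = stats)$probs
}

# batch-norm running statistics (momentum update from per-batch stats)
update_bn_stats_list <- function(stats, batch_stats, momentum = 0.1) {
  if (is.null(stats)) stats <- vector("list", 3)
  for (i in 1:3) {
    mu <- batch_stats[[i]]$mu
    va <- batch_stats[[i]]$var
    if (is.null(stats[[i]])) stats[[i]] <- list(mu = mu, var = va)
    else stats[[i]] <- list(mu = (1 - momentum) * stats[[i]]$mu + momentum * mu,
                            var = (1 - momentum) * stats[[i]]$var + momentum * va)
  }
  stats
}

#' Save / load a model checkpoint
#'
#' Stores the parameters, configuration and running statistics in one RDS
#' archive.
#' @param params,cfg,stats model state.
#' @param path file path.
#' @export
save_checkpoint <- function(params, cfg, path, stats = NULL) {
  saveRDS(list(params = params, cfg = cfg, stats = stats, package = "semgmeta"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Describe a model: layer shapes and parameter counts
#' @param cfg a [network_config()].
#' @return data.frame of stage descriptions, printed for convenience.
#' @export
describe_model <- function(cfg) {
  p <- init_params(cfg, seed = 1L)
  rows <- list(data.frame(stage = "input", shape = paste(cfg$input_shape, collapse = "x"),
                          params = 0L))
  for (i in 1:3) {
    n <- param_count(structure(list(cells = list(p$cells[[i]])), class = "semg_net_params"))
    rows[[i + 1]] <- data.frame(stage = sprintf("cell%d (%s)", i, cfg$variant),
                                shape = paste(cfg$cell_shapes[[i]], collapse = "x"),
                                params = n)
  }
  rows[[5]] <- data.frame(stage = "classifier",
                          shape = sprintf("%d -> %d", cfg$fc_in, cfg$n_classes),
                          params = length(p$fc_W) + length(p$fc_b))
  out <- do.call(rbind, rows)
  out
}
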