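#' Build an episodic sample pool from featurized data
#'
#' Wraps a list of feature objects into the pool structure used by the task
#' sampler: a batch-ready feature array plus label, subject and identity
#' vectors.
#'
#' @param features list of `semg_features` (one model-input mode).
#' @return object of class `semg_pool` with fields `x` (H x W x C x n
#'   array), `gesture`, `subject`, `id`.
#' @export
make_pool <- function(features) {
  stopifnot(length(features) > 0)
  x <- feature_batch(features)
  structure(list(x = x,
                 gesture = vapply(features, function(f) f$gesture, integer(1)),
                 subject = vapply(features, function(f) f$subject, integer(1)),
                 id = seq_along(features)),
            class = "semg_pool")
}

#' @export
print.semg_pool <- function(x, ...) {
  cat(sprintf("<semg_pool> %d samples | %d classes | %d subjects | feature [%s]\n",
              length(x$id), length(unique(x$gesture)), length(unique(x$subject)),
              paste(dim(x$x)[1:3], collapse = " x ")))
  invisible(x)
}

#' Sample one N-way K-shot task
#'
#' Draws N classes uniformly without replacement, then 2K distinct samples
#' per class, splitting them K into the support set and K into the query set
#' (the "N-way, 2xK-shot, half for training and half for verification"
#' protocol). Support and query share the same classes but never share a
#' sample; labels are remapped to 1..N.
#'
#' @param pool a `semg_pool`.
#' @param N ways (classes per task).
#' @param K shots (support samples per class); the query set also has K per
#'   class.
#' @return object of class `semg_task` with `support_idx`, `query_idx`,
#'   `support_y`, `query_y` (remapped labels) and `class_map` (global class
#'   of each remapped label).
#' @export
sample_task <- function(pool, N = 5, K = 1) {
  classes <- sort(unique(pool$gesture))
  if (length(classes) < N)
    stop(sprintf("sample_task: pool has %d classes, need N = %d", length(classes), N))
  chosen <- sample(classes, N)
  sup <- integer(0); qry <- integer(0)
  sup_y <- integer(0); qry_y <- integer(0)
  for (i in seq_len(N)) {
    avail <- pool$id[pool$gesture == chosen[i]]
    if (length(avail) < 2 * K)
      stop(sprintf("sample_task: class %d has %d samples, need 2K = %d",
                   chosen[i], length(avail), 2 * K))
    pick <- sample(avail, 2 * K)
    sup <- c(sup, pick[seq_len(K)])
    qry <- c(qry, pick[K + seq_len(K)])
    sup_y <- c(sup_y, rep(i, K))
    qry_y <- c(qry_y, rep(i, K))
  }
  structure(list(support_idx = sup, query_idx = qry, support_y = sup_y,
                 query_y = qry_y, class_map = chosen),
            class = "semg_task")
}

#' Deterministic stream of tasks
#'
#' @param pool a `semg_pool`.
#' @param n_tasks number of tasks.
#' @param N,K task geometry, as in [sample_task()].
#' @param seed RNG seed; the same seed reproduces the identical sequence.
#' @return list of `semg_task`.
#' @export
task_stream <- function(pool, n_tasks, N = 5, K = 1, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_tasks), function(i) sample_task(pool, N, K))
}

# batch tensors of a task's support or query half
task_batch <- function(pool, idx, y) {
  list(x = pool$x[, , , idx, drop = FALSE], y = y)
}

#' Top-k classification accuracy
#'
#' Fraction of samples whose true label is among the k highest-scoring
#' classes; non-decreasing in k and equal to 1 when k is the class count.
#' Ties are broken by class order, matching the usual argsort convention.
#'
#' @param scores n x C matrix of per-class scores (probabilities or logits).
#' @param labels integer true labels (1-based), length n.
#' @param k number of top classes considered.
#' @return fraction in `[0, 1]`.
#' @export
topk_accuracy <- function(scores, labels, k = 1) {
  scores <- as.matrix(scores)
  if (k < 1) stop("topk_accuracy: k must be >= 1")
  if (k > ncol(scores)) stop("topk_accuracy: k exceeds the class count")
  hits <- vapply(seq_len(nrow(scores)), function(i) {
    ord <- order(scores[i, ], decreasing = TRUE)
    labels[i] %in% ord[seq_len(k)]
  }, logical(1))
  mean(hits)
}

#' Serialize tasks to a JSON manifest (sample identities per task)
#' @param tasks list of `semg_task`.
#' @param path output file.
#' @export
write_task_manifest <- function(tasks, path) {
  obj <- lapply(tasks, function(t)
    list(support = t$support_idx, query = t$query_idx, classes = t$class_map))
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}
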