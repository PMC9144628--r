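test_that("tasks have N*K support and N*K query samples over shared classes", {
  pool <- dummy_pool()
  set.seed(1)
  tk <- sample_task(pool, N = 5, K = 1)
  expect_length(tk$support_idx, 5)
  expect_length(tk$query_idx, 5)
  expect_setequal(unique(tk$support_y), unique(tk$query_y))
  tk5 <- sample_task(pool, N = 5, K = 2)
  expect_length(tk5$support_idx, 10)
  expect_equal(as.vector(table(tk5$support_y)), rep(2L, 5)) # K per class
  # label remapping is a bijection back to global classes
  expect_equal(tk5$class_map[tk5$support_y],
               pool$gesture[tk5$support_idx])
  expect_equal(tk5$class_map[tk5$query_y],
               pool$gesture[tk5$query_idx])
})

test_that("support and query sample sets never intersect across many tasks", {
  pool <- dummy_pool()
  set.seed(2)
  for (i in seq_len(1000)) {
    tk <- sample_task(pool, N = 5, K = 2)
    expect_length(intersect(tk$support_idx, tk$query_idx), 0)
  }
})

test_that("task sampling rejects pools that cannot fill the request", {
  pool <- dummy_pool(n_classes = 4)
  expect_error(sample_task(pool, N = 5, K = 1), "classes")
  # a class with only 2K-1 samples, N forcing its inclusion
  small <- dummy_pool(n_classes = 2, n_subjects = 1, per_cell = 3)
  expect_error(sample_task(small, N = 2, K = 2), "samples")
})

test_that("task streams are seed-reproducible and class-balanced", {
  pool <- dummy_pool()
  a <- task_stream(pool, 50, N = 5, K = 1, seed = 9)
  b <- task_stream(pool, 50, N = 5, K = 1, seed = 9)
  expect_identical(a, b)
  expect_length(task_stream(pool, 0, N = 5, K = 1, seed = 1), 0)
  # binomial expectation oracle: each of the 8 classes appears in a 5-way
  # task with probability 5/8
  tasks <- task_stream(pool, 10000, N = 5, K = 1, seed = 3)
  freq <- table(factor(unlist(lapply(tasks, `[[`, "class_map")), levels = 1:8)) / 10000
  expect_true(all(abs(freq - 5 / 8) < 0.02))
})

test_that("top-k accuracy matches hand enumeration and is monotone in k", {
  sc <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3))
  # hand enumeration: top-1 sets are {1} and {2}; top-2 sets {1,2} and {2,3}
  expect_equal(topk_accuracy(sc, c(2, 3), 1), 0)
  expect_equal(topk_accuracy(sc, c(2, 3), 2), 1)
  expect_equal(topk_accuracy(sc, c(3, 1), 2), 0) # neither label in its top-2
  expect_equal(topk_accuracy(sc, c(3, 3), 2), 0.5)
  expect_equal(topk_accuracy(sc, c(2, 3), 3), 1) # k = class count
  expect_equal(topk_accuracy(sc, c(1, 2), 1), 1)
  expect_error(topk_accuracy(sc, c(1, 2), 0), "k must be")
  expect_error(topk_accuracy(sc, c(1, 2), 4), "class count")
  set.seed(11)
  rs <- matrix(stats::rnorm(40 * 6), 40)
  lab <- sample(1:6, 40, replace = TRUE)
  accs <- vapply(1:6, function(k) topk_accuracy(rs, lab, k), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[6], 1)
})

test_that("task manifests serialize sample identities as JSON", {
  pool <- dummy_pool()
  tasks <- task_stream(pool, 3, N = 5, K = 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_task_manifest(tasks, path)
  back <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_length(back, 3)
  expect_equal(unlist(back[[1]]$support), tasks[[1]]$support_idx)
})
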