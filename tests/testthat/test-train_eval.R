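test_that("class weights are inverse-frequency with mean one", {
  expect_equal(compute_class_weights(c(10, 10, 10)), c(1, 1, 1))
  expect_equal(compute_class_weights(c(100, 50)), c(2/3, 4/3))
  expect_equal(mean(compute_class_weights(c(7, 3, 90, 12))), 1)
  expect_error(compute_class_weights(c(5, 0)), "missing class")
})

test_that("random over-sampling balances each dataset to its max class count", {
  x <- flat_epoch_set(10, 2)
  set.seed(1)
  expect_identical(n_epochs(random_oversample(x)), 20L)  # already balanced

  y <- x[c(1:10, 11:14)]  # counts 10 and 4
  set.seed(2); over <- random_oversample(y)
  expect_identical(as.integer(table(over$info$label)), c(10L, 10L))
  # duplicates come from the minority class itself
  expect_true(all(over$info$source_id[15:20] %in% y$info$source_id[11:14]))
  set.seed(2); again <- random_oversample(y)
  expect_identical(over$info$source_id, again$info$source_id)

  # per-dataset balancing: each dataset balanced independently
  z <- x[c(1:6, 11:12)]
  ds <- c(rep("A", 6), rep("B", 2))
  z2 <- x[c(1:2, 11:16)]
  both <- bind_epochs(z, z2)
  set.seed(3)
  over2 <- random_oversample(both, dataset = c(ds, c(rep("B", 8))))
  tab <- table(over2$info$label)
  expect_true(all(tab >= c(6, 6)))
})

test_that("chronological stratified folds partition each class contiguously", {
  x <- flat_epoch_set(20, 3)
  folds <- stratified_chrono_kfold(x, k = 10)
  expect_length(folds, 10)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_identical(sort(all_test), seq_len(n_epochs(x)))  # coverage, no overlap
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_identical(sort(c(f$train, f$val, f$test)), seq_len(n_epochs(x)))
    for (cl in 0:2) {
      ct <- f$test[x$info$label[f$test] == cl]
      expect_identical(length(ct), 2L)  # 20 epochs over 10 folds: parts of 2
      # chronological contiguity within the class
      times <- sort(x$info$recorded_at[ct])
      expect_identical(diff(times), 1)
    }
  }
  expect_error(stratified_chrono_kfold(x, k = 1), "k must be")
  expect_error(stratified_chrono_kfold(flat_epoch_set(3, 2), k = 10),
               "stratification error")
})

test_that("folds never split one source recording across parts", {
  # 12 recordings per class, 3 epochs each
  set.seed(8)
  parts <- list()
  for (cl in 0:1) for (r in 1:12) {
    parts[[length(parts) + 1L]] <-
      wb_epochs(matrix(rnorm(3 * 16), 3, 16), label = cl,
                source_id = sprintf("c%d_r%02d", cl, r), recorded_at = r)
  }
  x <- do.call(bind_epochs, parts)
  folds <- stratified_chrono_kfold(x, k = 4)
  for (f in folds) {
    test_src <- unique(x$info$source_id[f$test])
    other_src <- unique(x$info$source_id[c(f$train, f$val)])
    expect_length(intersect(test_src, other_src), 0)
    val_src <- unique(x$info$source_id[f$val])
    expect_length(intersect(val_src, unique(x$info$source_id[f$train])), 0)
  }
})

test_that("evaluation reports match direct metric arithmetic", {
  r <- eval_report(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L), 2)
  expect_equal(r$acc, 0.75)
  expect_equal(r$per_class$f1, c(2/3, 0.8))
  expect_equal(r$mf1, 11/15)
  expect_identical(r$confusion, matrix(c(1L, 0L, 1L, 2L), 2,
    dimnames = list(true = 0:1, pred = 0:1)))

  perfect <- eval_report(0:3, 0:3, 4)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$mf1, 1)

  # class absent from truth and predictions: F1 = 0, still averaged
  absent <- eval_report(c(0L, 0L, 1L), c(0L, 0L, 1L), 3)
  expect_equal(absent$per_class$f1[3], 0)
  expect_equal(absent$mf1, mean(c(1, 1, 0)))

  expect_error(eval_report(integer(0), integer(0), 2), "empty test set")
})

test_that("report internals agree with a brute-force computation on random labels", {
  brute <- function(yt, yp, C) {
    f1s <- numeric(C); tp_total <- 0
    for (c in 0:(C - 1)) {
      tp <- sum(yt == c & yp == c); fp <- sum(yt != c & yp == c)
      fn <- sum(yt == c & yp != c)
      pr <- if (tp + fp > 0) tp / (tp + fp) else 0
      re <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1s[c + 1] <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
      tp_total <- tp_total + tp
    }
    list(acc = tp_total / length(yt), mf1 = mean(f1s), f1 = f1s)
  }
  set.seed(44)
  for (i in 1:200) {
    C <- sample(2:8, 1)
    n <- sample(5:60, 1)
    yt <- sample(0:(C - 1), n, replace = TRUE)
    yp <- sample(0:(C - 1), n, replace = TRUE)
    r <- eval_report(yt, yp, C)
    b <- brute(yt, yp, C)
    expect_equal(r$acc, b$acc)
    expect_equal(r$mf1, b$mf1)
    expect_equal(r$per_class$f1, b$f1)
    # internal consistency: acc from trace, mf1 from mean of f1
    expect_equal(r$acc, sum(diag(r$confusion)) / r$n)
    expect_equal(r$mf1, mean(r$per_class$f1))
    expect_equal(sum(r$confusion), r$n)
  }
})

test_that("one-sided Mann-Whitney matches exact enumeration for small samples", {
  # independent oracle: enumerate all assignments of ranks to group b
  exact_p_greater <- function(a, b) {
    pooled <- c(a, b)
    r <- rank(pooled)
    u_b <- sum(r[(length(a) + 1):length(pooled)]) - length(b) * (length(b) + 1) / 2
    combos <- utils::combn(length(pooled), length(b))
    us <- apply(combos, 2, function(ix) sum(r[ix]) - length(b) * (length(b) + 1) / 2)
    mean(us >= u_b)
  }
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- mann_whitney_compare(a, b)
  expect_equal(res$p_value, 1 / 20)
  expect_equal(res$p_value, exact_p_greater(a, b))
  expect_equal(res$p_value, 0.05)
  expect_false(res$significant)  # p < 0.05 is strict
  expect_identical(res$method, "exact")

  set.seed(50)
  for (i in 1:20) {
    a2 <- round(runif(sample(3:6, 1)), 3)
    b2 <- round(runif(sample(3:6, 1)), 3)
    if (any(duplicated(c(a2, b2)))) next
    expect_equal(mann_whitney_compare(a2, b2)$p_value, exact_p_greater(a2, b2))
  }

  tied <- mann_whitney_compare(c(1, 2, 3), c(1, 2, 3))
  expect_false(tied$significant)
  expect_match(tied$method, "approximation")

  rev <- mann_whitney_compare(c(5, 6), c(1, 2))
  expect_gte(rev$p_value, 0.5)
  expect_false(rev$significant)
})

test_that("dual-microphone subtraction cancels shared noise", {
  x <- quantize16(runif(2400, -0.4, 0.4))
  n <- quantize16(runif(2400, -0.4, 0.4))
  near <- overlay(x, n, 1)
  expect_identical(dual_mic_subtract(near, n), x)  # exact on the 16-bit grid
  expect_identical(dual_mic_subtract(n, n), rep(0, 2400))
  expect_identical(dual_mic_subtract(x, numeric(2400)), x)
  expect_error(dual_mic_subtract(x, numeric(10)), "shape mismatch")

  xe <- toy_epochs(2, label = 4L)
  ne <- toy_epochs(2, f0 = 150, seed = 77)
  got <- dual_mic_subtract(overlay(xe, ne, 1), ne)
  expect_equal(got$samples, xe$samples)
  expect_identical(got$info$label, c(4L, 4L))
})

test_that("training is reproducible and validates its inputs", {
  set.seed(3)
  eps <- make_epoch_dataset(default_profiles(2), n_per_class = 24)
  cfg <- model_config(num_class = 2, input_len = 2400,
    frontend = list(list(filters = 4L, kernel = 8L, stride = 4L),
                    list(filters = 4L, kernel = 8L, stride = 4L),
                    list(filters = 6L, kernel = 4L, stride = 2L)),
    blocks = list(list(filters = 6L, kernel = 3L, pool = 2L),
                  list(filters = 8L, kernel = 3L, pool = 2L)),
    fc_sizes = c(16L, 8L), seed = 2L)
  idx <- seq_len(n_epochs(eps))
  tr <- idx[idx %% 4 != 0]; va <- idx[idx %% 4 == 0]
  tcfg <- train_config(max_epochs = 3, learning_rate = 1e-3, batch_size = 16, seed = 6)
  m1 <- train(build_model(cfg), eps[tr], eps[va], tcfg = tcfg)
  m2 <- train(build_model(cfg), eps[tr], eps[va], tcfg = tcfg)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$training_state$best_pass, m2$training_state$best_pass)

  expect_error(train_config(max_epochs = 0), "max_epochs")
  unlabeled <- eps[tr]
  unlabeled$info$label <- NA_integer_
  expect_error(train(build_model(cfg), unlabeled, eps[va], tcfg = tcfg),
               "labeled")
})
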