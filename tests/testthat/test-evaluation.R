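test_that("confusion matrices count and normalize correctly", {
  m <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unname(m), rbind(c(1, 1), c(0, 1)))

  perfect <- confusion_matrix(c(0, 1, 2, 1), c(0, 1, 2, 1), 3)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_equal(unname(confusion_matrix(c(0, 1, 2, 1), c(0, 1, 2, 1), 3,
                                       normalize = TRUE)),
               diag(3))

  set.seed(51)
  t0 <- sample(0:3, 60, replace = TRUE)
  p0 <- sample(0:3, 60, replace = TRUE)
  norm <- confusion_matrix(t0, p0, 4, normalize = TRUE)
  rs <- rowSums(norm)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))

  expect_error(confusion_matrix(c(0, 1), c(0), 2), "length")
})

test_that("metrics match the worked binary example and identities", {
  conf <- rbind(c(50, 10), c(10, 30))
  rep <- classification_metrics(conf)
  expect_equal(rep$accuracy, 0.8)
  pc <- tidy(rep)
  expect_equal(pc$precision[1], 5 / 6, tolerance = 1e-12)
  expect_equal(pc$recall[1], 5 / 6, tolerance = 1e-12)
  expect_equal(pc$f1[1], 5 / 6, tolerance = 1e-12) # P = R -> F1 = P
  expect_error(classification_metrics(matrix(0, 3, 3)), "all zero")
})

test_that("metrics equal a brute-force recount on random labels", {
  set.seed(52)
  N <- 5
  t0 <- sample(0:(N - 1), 1000, replace = TRUE)
  p0 <- sample(0:(N - 1), 1000, replace = TRUE)
  rep <- evaluate_predictions(t0, p0, N)
  # independent per-class recount straight from the label vectors
  for (k in 0:(N - 1)) {
    tp <- sum(t0 == k & p0 == k)
    fp <- sum(t0 != k & p0 == k)
    fn <- sum(t0 == k & p0 != k)
    tn <- sum(t0 != k & p0 != k)
    row <- tidy(rep)[k + 1, ]
    expect_equal(row$tp, tp)
    expect_equal(row$fp, fp)
    expect_equal(row$fn, fn)
    expect_equal(row$tn, tn)
    expect_equal(row$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(row$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
  }
  expect_equal(rep$accuracy, mean(t0 == p0))
  expect_equal(rep$f1, mean(tidy(rep)$f1))
  # structural identities
  expect_equal(sum(tidy(rep)$tp), sum(diag(rep$confusion)))
  expect_equal(sum(rep$confusion), 1000)
})

test_that("macro-F1 is invariant to class relabelling", {
  set.seed(53)
  for (i in 1:20) {
    t0 <- sample(0:3, 80, replace = TRUE)
    p0 <- sample(0:3, 80, replace = TRUE)
    perm <- sample(0:3)
    f1_a <- evaluate_predictions(t0, p0, 4)$f1
    f1_b <- evaluate_predictions(perm[t0 + 1], perm[p0 + 1], 4)$f1
    expect_equal(f1_a, f1_b, tolerance = 1e-12)
  }
})

test_that("F1 guard: zero precision and recall give zero F1", {
  conf <- rbind(c(0, 5), c(0, 7)) # class 0 never predicted, never correct
  rep <- classification_metrics(conf)
  expect_equal(tidy(rep)$f1[1], 0)
})

test_that("k-fold partitions are balanced, disjoint and covering", {
  for (seed in c(1, 7, 23)) {
    f <- kfold_assignments(10, 5, seed)
    expect_equal(sort(unique(f)), 1:5)
    expect_true(all(table(f) == 2))
  }
  for (seed in 1:100) {
    n <- 53
    f <- kfold_assignments(n, 5, seed)
    expect_equal(length(f), n)
    expect_lte(diff(range(table(f))), 1)
  }
  expect_identical(kfold_assignments(40, 5, 3), kfold_assignments(40, 5, 3))
})

test_that("k-fold harness recovers majority prevalence with a dummy pipeline", {
  ws <- small_benchmark(10L)
  # skew the labels so a majority class exists
  skew <- window_set(ws$windows[c(1:10, 11:14, 21:24)], ws$class_names, ws$rate)
  majority_pipeline <- function(train_ws, test_ws, seed) {
    labs <- window_labels(train_ws)
    maj <- as.integer(names(which.max(table(labs))))
    rep(maj, length(test_ws$windows))
  }
  cv <- kfold_cross_validate(skew, k = 3L, seed = 5, pipeline = majority_pipeline)
  expect_length(cv$reports, 3L)
  prevalence <- max(table(window_labels(skew))) / length(skew$windows)
  # with near-equal folds, the fold-mean accuracy is the prevalence up to
  # one window per fold
  accs <- vapply(cv$reports, `[[`, numeric(1), "accuracy")
  min_fold <- min(vapply(cv$reports, `[[`, numeric(1), "n"))
  expect_lte(abs(mean(accs) - prevalence), 1 / min_fold + 1e-12)
  expect_error(kfold_cross_validate(small_benchmark(3L), k = 5L, seed = 1,
                                    pipeline = majority_pipeline), "fewer than")
})

test_that("repeated holdout aggregates means and standard deviations", {
  ws <- small_benchmark(10L)
  oracle_pipeline <- function(train_ws, val_ws, test_ws, seed) {
    window_labels(test_ws) # perfect predictor
  }
  agg1 <- repeated_holdout(ws, n_reps = 1L, base_seed = 4,
                           pipeline = oracle_pipeline)
  expect_equal(agg1$f1, 1)
  expect_equal(unname(agg1$sd["f1"]), 0)

  # deterministic rerun
  agg2 <- repeated_holdout(ws, n_reps = 3L, base_seed = 4,
                           pipeline = oracle_pipeline)
  agg3 <- repeated_holdout(ws, n_reps = 3L, base_seed = 4,
                           pipeline = oracle_pipeline)
  expect_equal(glance(agg2), glance(agg3))

  # sd formula check against hand arithmetic on three synthetic accuracies
  flip_pipeline <- function(train_ws, val_ws, test_ws, seed) {
    labs <- window_labels(test_ws)
    n_wrong <- seed %% 3 # varies with the repetition seed
    if (n_wrong > 0) labs[seq_len(n_wrong)] <- (labs[seq_len(n_wrong)] + 1L) %% 3L
    labs
  }
  agg <- repeated_holdout(ws, n_reps = 3L, base_seed = 3,
                          pipeline = flip_pipeline)
  accs <- vapply(agg$reports, `[[`, numeric(1), "accuracy")
  expect_equal(agg$accuracy, mean(accs))
  expect_equal(unname(agg$sd["accuracy"]), sd(accs))
})
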