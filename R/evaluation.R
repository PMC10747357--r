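# Confusion matrices, one-vs-rest per-class metrics with macro averaging,
# repeated-holdout averaging and k-fold cross-validation harnesses.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of windows of true class `i` predicted as
#' class `j` (0-based labels index rows/columns 1..N). The normalized form
#' divides each row by its sum; an empty row stays all zeros.
#'
#' @param true Integer vector of true labels in `[0, N)`.
#' @param pred Integer vector of predicted labels, same length.
#' @param n_classes Number of classes `N`.
#' @param normalize Return row-normalized proportions (default `FALSE`).
#' @return An `N x N` numeric matrix with class-name dimnames.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
confusion_matrix <- function(true, pred, n_classes, normalize = FALSE) {
  if (length(true) != length(pred)) {
    stop("`true` and `pred` must have the same length", call. = FALSE)
  }
  if (any(true < 0 | true >= n_classes) || any(pred < 0 | pred >= n_classes)) {
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  }
  m <- matrix(0, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1),
                              pred = 0:(n_classes - 1)))
  tab <- table(factor(true, levels = 0:(n_classes - 1)),
               factor(pred, levels = 0:(n_classes - 1)))
  m[] <- as.numeric(tab)
  if (normalize) {
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest TP/FP/FN/TN and accuracy, precision, recall and F1
#' (`F1 = 2PR/(P+R)`, defined as 0 when `P + R = 0`), plus unweighted
#' (macro) averages — the headline "average F1" — and the overall fraction
#' correct.
#'
#' @param confusion Square count matrix (rows = true class).
#' @param class_names Optional class names for the per-class table.
#' @return An `eval_report`: `confusion`, `per_class` tibble, `accuracy`
#'   (overall fraction correct), and macro `precision`, `recall`, `f1`,
#'   `class_accuracy`.
#' @export
classification_metrics <- function(confusion, class_names = NULL) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop("`confusion` must be square", call. = FALSE)
  }
  total <- sum(confusion)
  if (total == 0) stop("`confusion` is all zero", call. = FALSE)
  n <- nrow(confusion)
  if (is.null(class_names)) {
    class_names <- if (!is.null(rownames(confusion))) rownames(confusion)
                   else as.character(0:(n - 1))
  }
  tp <- unname(diag(confusion))
  fp <- unname(colSums(confusion)) - tp
  fn <- unname(rowSums(confusion)) - tp
  tn <- total - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  class_acc <- (tp + tn) / total
  per_class <- tibble::tibble(
    class = class_names,
    tp = as.numeric(tp), fp = as.numeric(fp),
    fn = as.numeric(fn), tn = as.numeric(tn),
    accuracy = class_acc, precision = precision, recall = recall, f1 = f1
  )
  structure(
    list(confusion = confusion,
         per_class = per_class,
         n = total,
         accuracy = sum(tp) / total,
         precision = mean(precision),
         recall = mean(recall),
         f1 = mean(f1),
         class_accuracy = mean(class_acc)),
    class = "eval_report"
  )
}

#' Evaluate predictions directly
#'
#' Convenience wrapper: confusion matrix then [classification_metrics()].
#'
#' @inheritParams confusion_matrix
#' @param class_names Optional class names.
#' @return An `eval_report`.
#' @export
evaluate_predictions <- function(true, pred, n_classes, class_names = NULL) {
  classification_metrics(confusion_matrix(true, pred, n_classes),
                         class_names = class_names)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d | accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1
  ))
  if (!is.null(x$sd)) {
    cat(sprintf("  across %d repetition(s): F1 sd %.4f\n", x$n_reps, x$sd[["f1"]]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  x$per_class
}

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, accuracy = x$accuracy, precision = x$precision,
    recall = x$recall, f1 = x$f1
  )
}

# Average a list of eval_reports: mean and sd of the macro metrics, summed
# confusion matrix.
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  met <- function(f) vapply(reports, `[[`, numeric(1), f)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  out <- classification_metrics(
    Reduce(`+`, lapply(reports, `[[`, "confusion")),
    class_names = reports[[1]]$per_class$class
  )
  out$accuracy <- mean(met("accuracy"))
  out$precision <- mean(met("precision"))
  out$recall <- mean(met("recall"))
  out$f1 <- mean(met("f1"))
  out$sd <- c(accuracy = sd0(met("accuracy")), precision = sd0(met("precision")),
              recall = sd0(met("recall")), f1 = sd0(met("f1")))
  out$n_reps <- length(reports)
  out$reports <- reports
  out
}

#' Seeded k-fold partition
#'
#' @param n Number of items.
#' @param k Number of folds.
#' @param seed Seed.
#' @return Integer vector of fold assignments (1..k), sizes differing by at
#'   most 1.
#' @export
kfold_assignments <- function(n, k, seed = 1L) {
  stopifnot(k >= 2L, n >= k)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  with_seed(seed, sample(rep.int(seq_len(k), sizes)))
}

#' K-fold cross-validation of a window-classification pipeline
#'
#' Randomly partitions the windows into `k` near-equal folds; each fold is
#' held out in turn while the pipeline (wavelet-parameter selection,
#' transformation, training — everything) is fitted on the remaining folds
#' only, so no selection or training stage ever sees held-out windows.
#'
#' @param ws A `window_set`; every class must have at least `k` windows.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param pipeline A function `(train_ws, test_ws, seed)` returning predicted
#'   0-based labels for the test windows.
#' @return List with `reports` (one `eval_report` per fold), `mean` (their
#'   aggregate with metric standard deviations) and `folds` (the assignment
#'   vector).
#' @export
kfold_cross_validate <- function(ws, k = 5L, seed = 1L, pipeline) {
  stopifnot(inherits(ws, "window_set"), is.function(pipeline))
  labs <- window_labels(ws)
  counts <- table(factor(labs, levels = seq_along(ws$class_names) - 1L))
  if (any(counts < k)) {
    lacking <- ws$class_names[which(counts < k)[1]]
    stop(sprintf("class '%s' has fewer than k = %d windows", lacking, k),
         call. = FALSE)
  }
  folds <- kfold_assignments(length(ws$windows), k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    train_ws <- window_set(ws$windows[train_idx], ws$class_names, ws$rate)
    test_ws <- window_set(ws$windows[test_idx], ws$class_names, ws$rate)
    pred <- pipeline(train_ws, test_ws, stage_seed(seed, paste0("fold", f)))
    reports[[f]] <- evaluate_predictions(
      labs[test_idx], pred, length(ws$class_names), ws$class_names
    )
  }
  list(reports = reports, mean = aggregate_reports(reports), folds = folds)
}

#' Repeated random holdout evaluation
#'
#' Repeats [split_train_val_test()] with seeds `base_seed, base_seed + 1,
#' ...` and averages the resulting reports (mean and standard deviation per
#' macro metric), the usual "average measure over 10 repetitions" protocol.
#'
#' @param ws A `window_set`.
#' @param fractions Train/validation/test fractions.
#' @param n_reps Number of repetitions (default 10).
#' @param base_seed First split seed.
#' @param pipeline Function `(train_ws, val_ws, test_ws, seed)` returning
#'   predicted 0-based labels for the test windows.
#' @return An aggregated `eval_report` (with `$reports` holding the
#'   individual repetitions).
#' @export
repeated_holdout <- function(ws, fractions = c(0.7, 0.1, 0.2), n_reps = 10L,
                             base_seed = 1L, pipeline) {
  stopifnot(inherits(ws, "window_set"), n_reps >= 1L, is.function(pipeline))
  reports <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    seed_r <- base_seed + r - 1L
    parts <- split_train_val_test(ws, fractions, seed = seed_r)
    pred <- pipeline(parts$train, parts$validation, parts$test, seed_r)
    truth <- window_labels(parts$test)
    reports[[r]] <- evaluate_predictions(
      truth, pred, length(ws$class_names), ws$class_names
    )
  }
  aggregate_reports(reports)
}
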