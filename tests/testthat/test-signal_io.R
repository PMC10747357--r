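test_that("raw stream parsing maps activities through a sorted label table", {
  lines <- c(
    "1,Walking,0,0.1,0.2,9.8;",
    "1,Walking,50,0.2,0.1,9.7;",
    "1,Walking,100,0.3,0.0,9.6;"
  )
  rec <- parse_raw_stream(lines)
  expect_s3_class(rec, "multichannel_record")
  expect_equal(nrow(rec$values), 3L)
  expect_equal(ncol(rec$values), 3L)
  expect_equal(attr(rec, "label_table"), c(Walking = 0L))
  expect_equal(attr(rec, "skipped"), 0L)

  two <- parse_raw_stream(c(
    "1,Walking,0,0.1,0.2,9.8;",
    "1,Jogging,50,1.2,0.4,8.8;"
  ))
  expect_equal(attr(two, "label_table"), c(Jogging = 0L, Walking = 1L))
})

test_that("malformed rows are skipped and counted; structural errors abort", {
  good <- sprintf("1,Walking,%d,0.1,0.2,9.8;", seq(0, 450, by = 50))
  lines <- c(good[1:5], "1,Walking,225,NaN,0.2,9.8;", good[6:9])
  expect_warning(rec <- parse_raw_stream(lines), "skipped 1")
  expect_equal(nrow(rec$values), 9L)
  expect_equal(attr(rec, "skipped"), 1L)

  expect_error(parse_raw_stream(character(0)), "empty")
  expect_error(parse_raw_stream(c("1,Walking,0,0.1,0.2,9.8;", "1,Walking,5;")),
               "line 2")
})

test_that("rows are reordered by timestamp", {
  lines <- c("1,Walking,100,3,3,3;", "1,Walking,0,1,1,1;", "1,Walking,50,2,2,2;")
  rec <- parse_raw_stream(lines)
  expect_equal(rec$values[, 1], c(1, 2, 3))
})

test_that("window counts match the closed form and labels use majority vote", {
  rec <- tiny_record(1000L, rate = 20)
  ws <- segment_windows(rec, window_seconds = 10, overlap_fraction = 0.9)
  # L = 200, step = 20 -> floor((1000-200)/20)+1 = 41
  expect_equal(length(ws$windows), 41L)
  expect_equal(dim(ws$windows[[1]]$values), c(2L, 200L))

  # exact boundary: T = L gives exactly one window
  rec2 <- tiny_record(200L, rate = 20)
  ws2 <- segment_windows(rec2, 10, 0.9)
  expect_equal(length(ws2$windows), 1L)

  # majority labelling with earliest-index tie-break
  vals <- matrix(rnorm(8), ncol = 1)
  rec3 <- multichannel_record(vals, rate = 1, labels = c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L),
                              class_names = c("a", "b"))
  ws3 <- segment_windows(rec3, window_seconds = 8, overlap_fraction = 0)
  expect_equal(ws3$windows[[1]]$label, 0L) # 4-4 tie -> smaller index
})

test_that("segmentation count matches floor((T-L)/step)+1 under fuzzing", {
  set.seed(11)
  for (i in 1:25) {
    T_len <- sample(60:400, 1)
    rate <- sample(c(10, 20, 50), 1)
    win_s <- sample(1:3, 1)
    ov <- runif(1, 0, 0.95)
    L <- round(win_s * rate)
    if (L > T_len) next
    rec <- multichannel_record(matrix(rnorm(T_len), ncol = 1), rate = rate,
                               labels = rep(0L, T_len), class_names = "x")
    ws <- segment_windows(rec, win_s, ov)
    step <- max(1, round(L * (1 - ov)))
    expect_equal(length(ws$windows), floor((T_len - L) / step) + 1)
  }
})

test_that("non-overlapping windows reconstruct the truncated stream", {
  rec <- tiny_record(105L, rate = 10)
  ws <- segment_windows(rec, window_seconds = 2, overlap_fraction = 0)
  rebuilt <- do.call(cbind, lapply(ws$windows, `[[`, "values"))
  expect_equal(t(rebuilt), rec$values[seq_len(ncol(rebuilt)), ],
               ignore_attr = TRUE)
})

test_that("segmentation rejects invalid windows", {
  rec <- tiny_record(50L, rate = 20)
  expect_error(segment_windows(rec, 10, 0.5), "exceeds")
  expect_error(segment_windows(rec, 1, 1.0), "overlap")
})

test_that("train/val/test split has exact sizes, disjointness and coverage", {
  ws <- small_benchmark(10L) # 30 windows
  rec <- tiny_record(1000L)
  big <- segment_windows(rec, 5, 0.9) # 91 windows

  parts <- split_train_val_test(ws, c(0.7, 0.1, 0.2), seed = 3)
  expect_equal(length(parts$train$windows), 21L)
  expect_equal(length(parts$validation$windows), 3L)
  expect_equal(length(parts$test$windows), 6L)

  for (seed in c(1, 5, 99)) {
    p <- split_train_val_test(big, seed = seed)
    all_idx <- sort(unname(unlist(p$indices)))
    expect_equal(all_idx, seq_along(big$windows))
    expect_equal(length(intersect(p$indices$train, p$indices$test)), 0L)
    expect_equal(length(intersect(p$indices$train, p$indices$validation)), 0L)
  }

  # determinism
  p1 <- split_train_val_test(ws, seed = 42)
  p2 <- split_train_val_test(ws, seed = 42)
  expect_identical(p1$indices, p2$indices)

  # an empty part under rounding is rejected
  tiny <- window_set(ws$windows[1:4], ws$class_names, ws$rate)
  expect_error(split_train_val_test(tiny, c(0.7, 0.1, 0.2), seed = 1), "empty")
  expect_error(split_train_val_test(ws, c(0.5, 0.2, 0.2), seed = 1), "summing")
})

test_that("window archives round-trip through plain text", {
  ws <- small_benchmark(3L)
  path <- withr::local_tempdir()
  write_window_archive(ws, path)
  back <- read_window_archive(path)
  expect_equal(length(back$windows), length(ws$windows))
  expect_equal(back$class_names, ws$class_names)
  expect_equal(back$rate, ws$rate)
  expect_equal(back$windows[[5]]$values, ws$windows[[5]]$values,
               tolerance = 1e-12)
  expect_equal(window_labels(back), window_labels(ws))
})

test_that("as_tibble summarises windows one per row", {
  ws <- small_benchmark(4L)
  tb <- tibble::as_tibble(ws)
  expect_equal(nrow(tb), 12L)
  expect_setequal(tb$class, ws$class_names)
})
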