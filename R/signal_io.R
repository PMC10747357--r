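# Raw-stream parsing, sliding-window segmentation and dataset splitting.
# The sample unit of everything downstream is a fixed-length labelled window
# of shape (channels x samples); streams are per-axis channels of each
# inertial modality (channel-based splitting, fused late in the classifier).

#' Construct a multichannel sensor record
#'
#' @param values Numeric matrix, time steps x channels.
#' @param rate Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one per column.
#' @param labels Integer vector of per-sample 0-based class indices (length =
#'   rows of `values`), or a single class index for pre-segmented data.
#' @param class_names Character vector mapping class index -> name.
#' @param subject Subject identifier.
#' @return A `multichannel_record`.
#' @export
multichannel_record <- function(values, rate, channel_names = NULL,
                                labels = NULL, class_names = NULL,
                                subject = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L) {
    stop("`values` must be a numeric matrix with >= 1 row and column",
         call. = FALSE)
  }
  assert_scalar_num(rate, "rate", positive = TRUE)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(ncol(values)))
  }
  stopifnot(length(channel_names) == ncol(values))
  if (!is.null(labels) && length(labels) > 1L &&
      length(labels) != nrow(values)) {
    stop("per-sample `labels` must match the number of time steps",
         call. = FALSE)
  }
  structure(
    list(values = values, rate = rate, channel_names = channel_names,
         labels = labels, class_names = class_names, subject = subject),
    class = "multichannel_record"
  )
}

#' @export
print.multichannel_record <- function(x, ...) {
  cat(sprintf("<multichannel_record> %d samples x %d channels @ %g Hz",
              nrow(x$values), ncol(x$values), x$rate))
  if (!is.na(x$subject)) cat(sprintf(", subject %s", x$subject))
  cat("\n")
  invisible(x)
}

#' Parse a raw delimited inertial stream
#'
#' Reads rows of the common smartphone-logger form
#' `subject,activity,timestamp,x,y,z` (optionally `;`-terminated). Activity
#' strings are mapped to dense 0-based indices through a lexicographically
#' sorted label table so the mapping is stable across input orderings. Rows
#' are reordered by timestamp; rows with non-numeric axis readings are
#' skipped with a warning and counted.
#'
#' @param text_source A file path or a character vector of lines.
#' @param delim Field delimiter (default `","`).
#' @param trailing Trailing line terminator stripped before parsing
#'   (default `";"`).
#' @param rate Sampling rate (Hz) recorded on the result (default 20, the
#'   usual phone-accelerometer logging rate).
#' @return A `multichannel_record` whose `labels` are per-sample class
#'   indices; attributes `skipped` (bad-line count) and `label_table` (named
#'   integer vector) report parse outcomes. A `parsed` tibble of the clean
#'   rows is attached as attribute `rows`.
#' @export
#' @examples
#' lines <- c("1,Walking,0,0.1,0.2,9.8;", "1,Walking,50,0.2,0.1,9.7;")
#' rec <- parse_raw_stream(lines)
#' attr(rec, "label_table")
parse_raw_stream <- function(text_source, delim = ",", trailing = ";",
                             rate = 20) {
  lines <- if (length(text_source) == 1L && file.exists(text_source)) {
    readLines(text_source, warn = FALSE)
  } else {
    as.character(text_source)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty input stream", call. = FALSE)
  if (nzchar(trailing)) {
    lines <- sub(paste0(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", trailing), "+$"),
                 "", lines)
  }
  parts <- strsplit(lines, delim, fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != 6L)) {
    bad <- which(lens != 6L)[1]
    stop(sprintf("line %d has %d fields, expected 6", bad, lens[bad]),
         call. = FALSE)
  }
  m <- matrix(trimws(unlist(parts)), ncol = 6L, byrow = TRUE)
  subject <- m[, 1]
  activity <- m[, 2]
  timestamp <- suppressWarnings(as.numeric(m[, 3]))
  axes <- suppressWarnings(matrix(as.numeric(m[, 4:6]), ncol = 3L))
  ok <- is.finite(timestamp) & apply(is.finite(axes), 1L, all)
  skipped <- sum(!ok)
  if (skipped > 0L) {
    warning(sprintf("skipped %d line(s) with non-numeric values", skipped),
            call. = FALSE)
  }
  if (!any(ok)) stop("no parseable rows in input", call. = FALSE)
  ord <- order(timestamp[ok])
  keep <- which(ok)[ord]
  label_levels <- sort(unique(activity[keep]))
  label_table <- stats::setNames(seq_along(label_levels) - 1L, label_levels)
  rows <- tibble::tibble(
    subject = subject[keep],
    activity = activity[keep],
    timestamp = timestamp[keep],
    x = axes[keep, 1], y = axes[keep, 2], z = axes[keep, 3]
  )
  rec <- multichannel_record(
    values = cbind(x = rows$x, y = rows$y, z = rows$z),
    rate = rate,
    channel_names = c("x", "y", "z"),
    labels = unname(label_table[rows$activity]),
    class_names = label_levels,
    subject = if (length(unique(rows$subject)) == 1L) rows$subject[1] else NA_character_
  )
  attr(rec, "skipped") <- skipped
  attr(rec, "label_table") <- label_table
  attr(rec, "rows") <- rows
  rec
}

#' Construct a window set
#'
#' @param windows List of windows, each a list with `values` (channels x
#'   samples matrix), `label` (0-based class index) and optional `subject`.
#' @param class_names Character vector of class names.
#' @param rate Sampling rate in Hz.
#' @return A `window_set`.
#' @export
window_set <- function(windows, class_names, rate) {
  if (length(windows) == 0L) stop("`windows` must be non-empty", call. = FALSE)
  shapes <- vapply(windows, function(w) dim(w$values), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("all windows must share the same channel count and length",
         call. = FALSE)
  }
  labels <- vapply(windows, function(w) as.integer(w$label), integer(1))
  if (any(labels < 0L) || any(labels >= length(class_names))) {
    stop("window labels must index `class_names`", call. = FALSE)
  }
  assert_scalar_num(rate, "rate", positive = TRUE)
  structure(
    list(windows = windows, class_names = as.character(class_names),
         rate = rate),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows[[1]]$values)
  cat(sprintf(
    "<window_set> %d windows of %d channel(s) x %d samples @ %g Hz, %d classes\n",
    length(x$windows), d[1], d[2], x$rate, length(x$class_names)
  ))
  print(table(factor(window_labels(x), levels = seq_along(x$class_names) - 1L,
                     labels = x$class_names)))
  invisible(x)
}

#' Labels of a window set
#' @param ws A `window_set`.
#' @return Integer vector of 0-based class indices, one per window.
#' @export
window_labels <- function(ws) {
  vapply(ws$windows, function(w) as.integer(w$label), integer(1))
}

#' Summarise a window set as a tibble
#' @param x A `window_set`.
#' @param ... Unused.
#' @return One row per window: index, label index, class name, subject.
#' @exportS3Method tibble::as_tibble
as_tibble.window_set <- function(x, ...) {
  labs <- window_labels(x)
  tibble::tibble(
    window = seq_along(x$windows),
    label = labs,
    class = x$class_names[labs + 1L],
    subject = vapply(x$windows, function(w) {
      if (is.null(w$subject)) NA_character_ else as.character(w$subject)
    }, character(1))
  )
}

#' Cut sliding windows from a record
#'
#' Windows of `window_seconds * rate` samples (rounded) start at 0 and advance
#' by `step = round(L * (1 - overlap_fraction))` samples (half-away-from-zero
#' rounding, floored at 1), giving `floor((T - L)/step) + 1` windows. Each
#' window's label is the majority per-sample label within it, ties broken
#' towards the earliest-occurring (smallest) label index. Channels become rows
#' of the window matrices.
#'
#' @param record A `multichannel_record` with labels.
#' @param window_seconds Window length in seconds.
#' @param overlap_fraction Fractional overlap between consecutive windows, in
#'   `[0, 1)`; 0.9 reproduces the usual 10 s / 90 % phone-HAR setting.
#' @return A `window_set`.
#' @export
segment_windows <- function(record, window_seconds, overlap_fraction = 0) {
  stopifnot(inherits(record, "multichannel_record"))
  assert_scalar_num(window_seconds, "window_seconds", positive = TRUE)
  assert_prob_fraction(overlap_fraction, "overlap_fraction")
  T_len <- nrow(record$values)
  L <- as.integer(round_half_up(window_seconds * record$rate))
  if (L < 1L) stop("window shorter than one sample", call. = FALSE)
  if (L > T_len) {
    stop(sprintf("window length %d exceeds stream length %d", L, T_len),
         call. = FALSE)
  }
  step <- max(1L, as.integer(round_half_up(L * (1 - overlap_fraction))))
  starts <- seq.int(0L, T_len - L, by = step)
  labels <- record$labels
  if (is.null(labels)) stop("record has no labels to segment", call. = FALSE)
  if (length(labels) == 1L) labels <- rep(labels, T_len)
  windows <- lapply(starts, function(s0) {
    idx <- (s0 + 1L):(s0 + L)
    win_labs <- labels[idx]
    tab <- table(win_labs)
    winners <- as.integer(names(tab)[tab == max(tab)])
    list(
      values = t(record$values[idx, , drop = FALSE]),
      label = min(winners),
      subject = record$subject
    )
  })
  class_names <- record$class_names
  if (is.null(class_names)) {
    class_names <- paste0("class", seq_len(max(labels) + 1L) - 1L)
  }
  window_set(windows, class_names, record$rate)
}

#' Split a window set into train/validation/test partitions
#'
#' A seeded random permutation is partitioned by the rounded fractions, any
#' rounding remainder going to the training set. The three parts are disjoint
#' and cover the input.
#'
#' @param ws A `window_set`.
#' @param fractions Numeric triple summing to 1 (default `c(0.7, 0.1, 0.2)`,
#'   the usual 70/10/20 protocol).
#' @param seed Integer seed.
#' @return List with elements `train`, `validation`, `test` (each a
#'   `window_set`) and `indices`, the window indices of each part.
#' @export
split_train_val_test <- function(ws, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be 3 positive numbers summing to 1", call. = FALSE)
  }
  n <- length(ws$windows)
  n_val <- as.integer(round_half_up(n * fractions[2]))
  n_test <- as.integer(round_half_up(n * fractions[3]))
  n_train <- n - n_val - n_test
  sizes <- c(train = n_train, validation = n_val, test = n_test)
  if (any(sizes <= 0L) && all(fractions >= 0.05)) {
    stop(sprintf("split produces an empty partition (sizes %s) for %d windows",
                 paste(sizes, collapse = "/"), n), call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  idx <- list(
    train = perm[seq_len(n_train)],
    validation = perm[n_train + seq_len(n_val)],
    test = perm[n_train + n_val + seq_len(n_test)]
  )
  subset_ws <- function(i) {
    window_set(ws$windows[i], ws$class_names, ws$rate)
  }
  list(
    train = subset_ws(idx$train),
    validation = subset_ws(idx$validation),
    test = subset_ws(idx$test),
    indices = idx
  )
}

#' Write a window set to a plain-text archive
#'
#' The archive is a directory holding `meta.yaml` (rate, class names, shape)
#' and `windows.csv` (long format: window, label, subject, channel, sample,
#' value), the same container [read_window_archive()] loads, so synthetic
#' fixtures round-trip through the raw-data path.
#'
#' @param ws A `window_set`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_window_archive <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ws$windows[[1]]$values)
  yaml::write_yaml(
    list(rate = ws$rate, class_names = as.list(ws$class_names),
         n_channels = d[1], window_length = d[2]),
    file.path(path, "meta.yaml")
  )
  long <- purrr::map_dfr(seq_along(ws$windows), function(i) {
    w <- ws$windows[[i]]
    tibble::tibble(
      window = i,
      label = as.integer(w$label),
      subject = if (is.null(w$subject)) NA_character_ else as.character(w$subject),
      channel = rep(seq_len(nrow(w$values)), each = ncol(w$values)),
      sample = rep(seq_len(ncol(w$values)), times = nrow(w$values)),
      value = as.vector(t(w$values))
    )
  })
  utils::write.csv(long, file.path(path, "windows.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a window-set archive written by [write_window_archive()]
#'
#' @param path Archive directory.
#' @return A `window_set`.
#' @export
read_window_archive <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  long <- utils::read.csv(file.path(path, "windows.csv"),
                          stringsAsFactors = FALSE)
  nc <- meta$n_channels
  L <- meta$window_length
  windows <- lapply(split(long, long$window), function(df) {
    df <- df[order(df$channel, df$sample), ]
    list(
      values = matrix(df$value, nrow = nc, ncol = L, byrow = TRUE),
      label = df$label[1],
      subject = df$subject[1]
    )
  })
  windows <- windows[order(as.integer(names(windows)))]
  window_set(unname(windows), unlist(meta$class_names), meta$rate)
}
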