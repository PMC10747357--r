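# End-to-end orchestration: segment -> select wavelet parameters ->
# transform -> train -> evaluate, plus the ablation variants (no_cwt feeds
# raw windows as normalized images to the same network; no_rab swaps the
# residual attention blocks for plain convolutions) and the scale sweep.

#' Transform a window set into scalogram image batches
#'
#' Each channel of each window is wavelet-transformed over integer scales
#' `1..scale_count` and rendered as a normalized image
#' ([scalogram_to_image()]); channels stack along the third array dimension.
#'
#' @param ws A `window_set`.
#' @param sigma Morlet shape factor.
#' @param scale_count Number of integer scales.
#' @param image_size `c(H, W)` of the output images.
#' @return List with `x`, an array `(H, W, channels, n_windows)`, and `y`,
#'   the 0-based labels.
#' @export
windows_to_scalogram_images <- function(ws, sigma, scale_count,
                                        image_size = c(64L, 64L)) {
  stopifnot(inherits(ws, "window_set"))
  d <- dim(ws$windows[[1]]$values)
  nc <- d[1]
  n <- length(ws$windows)
  dt <- 1 / ws$rate
  scales <- seq_len(scale_count)
  x <- array(0, c(image_size[1], image_size[2], nc, n))
  for (i in seq_len(n)) {
    vals <- ws$windows[[i]]$values
    for (ch in seq_len(nc)) {
      s <- cwt_transform(as.numeric(vals[ch, ]), scales, sigma, dt)
      x[, , ch, i] <- scalogram_to_image(s, image_size, channel = ch)
    }
  }
  list(x = x, y = window_labels(ws))
}

#' Render raw windows as normalized images (no-CWT ablation input)
#'
#' Each window's channels-by-time matrix is min-max normalized and bilinearly
#' resized to the image size, entering the network as a single-plane image so
#' the classifier is identical across ablation variants.
#'
#' @param ws A `window_set`.
#' @param image_size `c(H, W)`.
#' @return List with `x` of shape `(H, W, 1, n_windows)` and labels `y`.
#' @export
windows_to_raw_images <- function(ws, image_size = c(64L, 64L)) {
  stopifnot(inherits(ws, "window_set"))
  n <- length(ws$windows)
  x <- array(0, c(image_size[1], image_size[2], 1L, n))
  for (i in seq_len(n)) {
    m <- ws$windows[[i]]$values
    rng <- range(m)
    norm <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
    x[, , 1L, i] <- resize_bilinear(norm, image_size[1], image_size[2])
  }
  list(x = x, y = window_labels(ws))
}

#' Experiment configuration
#'
#' Bundles data source, candidate grids, model and training settings, the
#' evaluation protocol and the variant into one seeded, reproducible run
#' description.
#'
#' @param data A `window_set`, or a `synthetic_spec` generated at run time.
#' @param grid A [scale_grid()] of shape-factor / scale-count candidates.
#' @param model_cfg A [model_config()]; its `input_channels` and `n_classes`
#'   are overridden to match the data.
#' @param train_cfg A [train_config()].
#' @param variant `"dwcnn"` (full), `"no_cwt"` (raw-signal images, no
#'   wavelet stage) or `"no_rab"` (plain convolutions instead of residual
#'   attention blocks).
#' @param fractions Train/validation/test fractions.
#' @param selection_sample_size Training windows sampled for wavelet
#'   parameter selection (default 64).
#' @param forced_sigma,forced_scale_count Optional overrides that bypass the
#'   corresponding selection stage.
#' @param output_dir Optional directory for run artifacts (config echo,
#'   selection evidence, history, report, confusion matrix).
#' @param seed Global seed; fans out to the split, selection, initialisation
#'   and shuffling stages via [stage_seed()].
#' @return An `experiment_config`.
#' @export
experiment_config <- function(data,
                              grid = scale_grid(),
                              model_cfg = model_config(),
                              train_cfg = train_config(),
                              variant = c("dwcnn", "no_cwt", "no_rab"),
                              fractions = c(0.7, 0.1, 0.2),
                              selection_sample_size = 64L,
                              forced_sigma = NULL,
                              forced_scale_count = NULL,
                              output_dir = NULL,
                              seed = 1L) {
  variant <- match.arg(variant)
  if (!inherits(data, "window_set") && !inherits(data, "synthetic_spec")) {
    stop("`data` must be a window_set or a synthetic_spec", call. = FALSE)
  }
  structure(
    list(data = data, grid = grid, model_cfg = model_cfg,
         train_cfg = train_cfg, variant = variant, fractions = fractions,
         selection_sample_size = as.integer(selection_sample_size),
         forced_sigma = forced_sigma,
         forced_scale_count = forced_scale_count,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Echo of the configuration with plain-scalar fields, for the artifact file.
config_echo <- function(cfg, sel = NULL) {
  list(
    variant = cfg$variant,
    seed = cfg$seed,
    fractions = as.list(cfg$fractions),
    sigma_grid = as.list(cfg$grid$sigma_candidates),
    scale_grid = as.list(cfg$grid$scale_count_candidates),
    forced_sigma = cfg$forced_sigma,
    forced_scale_count = cfg$forced_scale_count,
    image_size = as.list(cfg$model_cfg$image_size),
    conv_filters = as.list(cfg$model_cfg$conv_filters),
    fusion_mode = cfg$model_cfg$fusion_mode,
    pool_stride = cfg$model_cfg$pool_stride,
    attention_enabled = cfg$model_cfg$attention_enabled,
    rab_enabled = cfg$model_cfg$rab_enabled,
    learning_rate = cfg$train_cfg$learning_rate,
    batch_size = cfg$train_cfg$batch_size,
    max_epochs = cfg$train_cfg$max_epochs,
    selected_sigma = if (is.null(sel)) NULL else sel$sigma_star,
    selected_scale_count = if (is.null(sel)) NULL else sel$scale_count_star
  )
}

#' Run one end-to-end experiment
#'
#' Stages: obtain windows (generating synthetic data if needed), split
#' train/validation/test, select wavelet parameters on training windows only
#' (skipped entirely for the `no_cwt` variant or when both parameters are
#' forced), transform windows to images, build and train the classifier,
#' evaluate on the held-out test windows. Every stage seed derives from the
#' global seed, so an identical configuration reproduces the run exactly.
#' Artifacts (config echo, selection evidence, history, report, confusion
#' matrix) are written to `cfg$output_dir` when set.
#'
#' @param cfg An [experiment_config()].
#' @return A `run_result`: `report` (an `eval_report` on the test set),
#'   `trained` (the `trained_model`), `selection` (a `selection_result` or
#'   `NULL`), and the window `splits`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  fail <- function(stage, e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  }
  ws <- tryCatch(
    if (inherits(cfg$data, "synthetic_spec")) generate_dataset(cfg$data)
    else cfg$data,
    error = function(e) fail("data", e)
  )
  nc <- nrow(ws$windows[[1]]$values)
  n_classes <- length(ws$class_names)

  parts <- tryCatch(
    split_train_val_test(ws, cfg$fractions, seed = stage_seed(cfg$seed, "split")),
    error = function(e) fail("split", e)
  )

  sel <- NULL
  if (cfg$variant != "no_cwt") {
    need_selection <- is.null(cfg$forced_sigma) || is.null(cfg$forced_scale_count)
    if (need_selection) {
      sel <- tryCatch(
        select_for_window_set(parts$train, cfg$grid,
                              sample_size = cfg$selection_sample_size,
                              seed = stage_seed(cfg$seed, "selection")),
        error = function(e) fail("selection", e)
      )
    }
    sigma <- if (!is.null(cfg$forced_sigma)) cfg$forced_sigma else sel$sigma_star
    a_count <- if (!is.null(cfg$forced_scale_count)) cfg$forced_scale_count
               else sel$scale_count_star
  }

  mc <- cfg$model_cfg
  img <- mc$image_size
  to_images <- function(part) {
    if (cfg$variant == "no_cwt") windows_to_raw_images(part, img)
    else windows_to_scalogram_images(part, sigma, a_count, img)
  }
  tr <- tryCatch(to_images(parts$train), error = function(e) fail("transform", e))
  va <- tryCatch(to_images(parts$validation), error = function(e) fail("transform", e))
  te <- tryCatch(to_images(parts$test), error = function(e) fail("transform", e))

  mc$input_channels <- dim(tr$x)[3]
  mc$n_classes <- n_classes
  if (cfg$variant == "no_rab") mc$rab_enabled <- FALSE
  mc <- do.call(model_config, list(
    image_size = mc$image_size, input_channels = mc$input_channels,
    n_classes = mc$n_classes, conv_kernel = mc$conv_kernel,
    rab_kernel = mc$rab_kernel, conv_filters = mc$conv_filters,
    conv_stride = mc$conv_stride, conv_padding = mc$conv_pad,
    pool_size = mc$pool_size, pool_stride = mc$pool_stride,
    pool_padding = mc$pool_padding,
    attention_enabled = mc$attention_enabled, rab_enabled = mc$rab_enabled,
    fusion_mode = mc$fusion_mode, se_reduction = mc$se_reduction,
    fc_relu = mc$fc_relu
  ))

  model <- tryCatch(build_model(mc, seed = stage_seed(cfg$seed, "init")),
                    error = function(e) fail("build", e))
  tcfg <- cfg$train_cfg
  tcfg$seed <- stage_seed(cfg$seed, "train")
  trained <- tryCatch(
    train_model(model, tr$x, tr$y, va$x, va$y, tcfg),
    error = function(e) fail("train", e)
  )
  pred <- tryCatch(predict(trained, te$x), error = function(e) fail("predict", e))
  report <- evaluate_predictions(te$y, pred$labels, n_classes, ws$class_names)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config_echo(cfg, sel), file.path(cfg$output_dir, "config.yaml"))
    if (!is.null(sel)) {
      utils::write.csv(sel$entropies,
                       file.path(cfg$output_dir, "selection_entropy.csv"),
                       row.names = FALSE)
      utils::write.csv(sel$periodicities,
                       file.path(cfg$output_dir, "selection_periodicity.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(trained$history, file.path(cfg$output_dir, "history.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(report), file.path(cfg$output_dir, "report_per_class.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(accuracy = report$accuracy, precision = report$precision,
           recall = report$recall, macro_f1 = report$f1, n = report$n),
      file.path(cfg$output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA
    )
    utils::write.csv(
      confusion_matrix(te$y, pred$labels, n_classes, normalize = TRUE),
      file.path(cfg$output_dir, "confusion_normalized.csv")
    )
  }

  structure(
    list(report = report, trained = trained, selection = sel,
         splits = parts, config = cfg),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> variant %s, seed %d\n",
              x$config$variant, x$config$seed))
  print(x$report)
  invisible(x)
}

#' Sweep the wavelet scale count
#'
#' Bypasses the periodicity-based selection, forcing each candidate scale
#' count in turn and recording the test macro-F1, so the payoff of the
#' automatic selection can be inspected across the supported grid.
#'
#' @param cfg An [experiment_config()] (variant should use the wavelet
#'   stage).
#' @param counts Scale counts to force (default `c(32, 64, 128)`).
#' @param n_reps Repetitions per count (seeds `cfg$seed + 0:(n_reps-1)`);
#'   default 1.
#' @return A tibble: `scale_count`, `mean_f1`, `sd_f1`, `mean_accuracy`.
#' @export
scale_sweep <- function(cfg, counts = c(32L, 64L, 128L), n_reps = 1L) {
  stopifnot(inherits(cfg, "experiment_config"), length(counts) >= 1L)
  rows <- lapply(counts, function(a) {
    f1s <- numeric(n_reps)
    accs <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      cfg_r <- cfg
      cfg_r$forced_scale_count <- as.integer(a)
      cfg_r$seed <- cfg$seed + r - 1L
      cfg_r$output_dir <- NULL
      res <- run_experiment(cfg_r)
      f1s[r] <- res$report$f1
      accs[r] <- res$report$accuracy
    }
    tibble::tibble(
      scale_count = as.integer(a),
      mean_f1 = mean(f1s),
      sd_f1 = if (n_reps > 1L) stats::sd(f1s) else 0,
      mean_accuracy = mean(accs)
    )
  })
  dplyr::bind_rows(rows)
}

#' Desk-scale benchmark configurations
#'
#' The model/training settings used with [default_benchmark()]-sized data:
#' 16x16 images, 8/16 filters, stride-2 pooling, Adam at 1e-3 with batch 64
#' for at most 30 epochs and patience 5. Small enough to train on one CPU in
#' minutes while exercising every component.
#'
#' @param variant Experiment variant.
#' @param seed Global seed.
#' @param data Optional window set; defaults to [default_benchmark()].
#' @param ... Overrides forwarded to [experiment_config()].
#' @return An [experiment_config()].
#' @export
benchmark_config <- function(variant = "dwcnn", seed = 1L, data = NULL, ...) {
  if (is.null(data)) data <- default_benchmark()
  settings <- list(
    data = data,
    grid = scale_grid(c(2, 6, 10), c(32L, 64L, 128L)),
    model_cfg = model_config(
      image_size = c(16L, 16L), input_channels = 3L, n_classes = 3L,
      conv_filters = c(8L, 16L), pool_stride = 2L
    ),
    train_cfg = train_config(learning_rate = 1e-3, batch_size = 64L,
                             max_epochs = 30L, patience = 5L),
    variant = variant,
    selection_sample_size = 16L,
    seed = seed
  )
  overrides <- list(...)
  settings[names(overrides)] <- overrides
  do.call(experiment_config, settings)
}
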