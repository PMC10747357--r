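# The scalogram classifier: Conv(5x5) -> RAB -> Conv(5x5) -> MaxPool(2x2) ->
# RAB -> MaxPool(2x2) -> FC(softmax). RAB = residual attention block: two 3x3
# convolutions with batch norm, a squeeze-and-excitation channel gate, an
# identity skip connection and a final ReLU. Channels can enter as stacked
# image planes of one network ("stacked") or pass one-per-tower through
# shared weights with features concatenated before the FC head ("late",
# the channel-based late-fusion reading).

#' Model configuration
#'
#' @param image_size Integer pair `c(H, W)` of the input images (default
#'   `c(64, 64)`).
#' @param input_channels Number of sensor channels feeding the model.
#' @param n_classes Number of activity classes (>= 2).
#' @param conv_kernel Kernel size of the two plain convolution stages
#'   (default 5).
#' @param rab_kernel Kernel size inside residual attention blocks (default 3).
#' @param conv_filters Integer pair: filter counts of the two convolution
#'   stages (the following RAB keeps its stage's count). Default `c(32, 64)`.
#' @param conv_stride Stride of the plain convolutions (default 1).
#' @param conv_padding Edge extension of the plain convolutions; `"same"`
#'   (default) derives `r = (kernel - 1)/2`, or give an integer `r`.
#' @param pool_size Pooling window (default 2).
#' @param pool_stride Pooling stride. Default 1 — pooling then smooths
#'   without downsampling; set 2 for conventional halving.
#' @param pool_padding `"same"` (default) or `"valid"`.
#' @param attention_enabled Use the channel-attention gate inside RABs
#'   (default `TRUE`); `FALSE` leaves pure residual blocks.
#' @param rab_enabled `FALSE` replaces each RAB by a plain 3x3 convolution
#'   (the no-RAB ablation).
#' @param fusion_mode `"late"` (default) or `"stacked"`.
#' @param se_reduction Bottleneck reduction of the attention gate (default 4).
#' @param fc_relu Rectify the FC logits before the softmax (default `FALSE`).
#' @return A `model_config`.
#' @export
model_config <- function(image_size = c(64L, 64L),
                         input_channels = 3L,
                         n_classes = 6L,
                         conv_kernel = 5L,
                         rab_kernel = 3L,
                         conv_filters = c(32L, 64L),
                         conv_stride = 1L,
                         conv_padding = "same",
                         pool_size = 2L,
                         pool_stride = 1L,
                         pool_padding = "same",
                         attention_enabled = TRUE,
                         rab_enabled = TRUE,
                         fusion_mode = c("late", "stacked"),
                         se_reduction = 4L,
                         fc_relu = FALSE) {
  fusion_mode <- match.arg(fusion_mode)
  stopifnot(length(image_size) == 2L, all(image_size >= 4L),
            input_channels >= 1L, n_classes >= 2L,
            conv_kernel >= 1L, rab_kernel >= 1L,
            length(conv_filters) == 2L, all(conv_filters >= 1L),
            conv_stride >= 1L, pool_size >= 1L, pool_stride >= 1L)
  r <- if (identical(conv_padding, "same")) (conv_kernel - 1L) %/% 2L
       else as.integer(conv_padding)
  structure(
    list(image_size = as.integer(image_size),
         input_channels = as.integer(input_channels),
         n_classes = as.integer(n_classes),
         conv_kernel = as.integer(conv_kernel),
         rab_kernel = as.integer(rab_kernel),
         conv_filters = as.integer(conv_filters),
         conv_stride = as.integer(conv_stride),
         conv_pad = as.integer(r),
         pool_size = as.integer(pool_size),
         pool_stride = as.integer(pool_stride),
         pool_padding = pool_padding,
         attention_enabled = isTRUE(attention_enabled),
         rab_enabled = isTRUE(rab_enabled),
         fusion_mode = fusion_mode,
         se_reduction = as.integer(se_reduction),
         fc_relu = isTRUE(fc_relu)),
    class = "model_config"
  )
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Create a residual attention block's parameters
#'
#' @param channels Channel count the block preserves.
#' @param kernel Convolution kernel size (default 3).
#' @param se_reduction Attention bottleneck reduction (default 4).
#' @return A `rab_block` layer object with zero-initialised running
#'   statistics; weights are drawn from the current RNG state.
#' @export
rab_block <- function(channels, kernel = 3L, se_reduction = 4L) {
  cr <- max(1L, channels %/% se_reduction)
  fan <- kernel * kernel * channels
  list(
    type = "rab",
    kernel = as.integer(kernel),
    channels = as.integer(channels),
    params = list(
      W1 = he_init(c(kernel, kernel, channels, channels), fan),
      b1 = numeric(channels),
      gamma1 = rep(1, channels), beta1 = numeric(channels),
      W2 = he_init(c(kernel, kernel, channels, channels), fan),
      b2 = numeric(channels),
      gamma2 = rep(1, channels), beta2 = numeric(channels),
      W_r = matrix(rnorm(cr * channels, sd = sqrt(2 / channels)), cr, channels),
      b_r = numeric(cr),
      W_e = matrix(rnorm(channels * cr, sd = sqrt(2 / cr)), channels, cr),
      b_e = numeric(channels)
    ),
    state = list(
      mean1 = numeric(channels), var1 = rep(1, channels),
      mean2 = numeric(channels), var2 = rep(1, channels)
    )
  )
}

rab_fwd <- function(layer, x, training, attention) {
  pad <- (layer$kernel - 1L) %/% 2L
  p <- layer$params
  c1 <- conv_forward(x, p$W1, p$b1, s = 1L, pad = pad)
  b1 <- bn_forward(c1$out, p$gamma1, p$beta1, layer$state$mean1,
                   layer$state$var1, training)
  r1 <- relu(b1$out)
  c2 <- conv_forward(r1, p$W2, p$b2, s = 1L, pad = pad)
  b2 <- bn_forward(c2$out, p$gamma2, p$beta2, layer$state$mean2,
                   layer$state$var2, training)
  if (attention) {
    se <- se_forward(b2$out, p$W_r, p$b_r, p$W_e, p$b_e)
    gated <- se$out
    se_cache <- se$cache
  } else {
    gated <- b2$out
    se_cache <- NULL
  }
  pre <- gated + x
  out <- relu(pre)
  list(
    out = out,
    cache = list(c1 = c1$cache, b1 = b1$cache, b1_out = b1$out,
                 c2 = c2$cache, b2 = b2$cache, se = se_cache,
                 pre = pre, attention = attention),
    state = list(mean1 = b1$run_mean, var1 = b1$run_var,
                 mean2 = b2$run_mean, var2 = b2$run_var)
  )
}

rab_bwd <- function(layer, dy, cache) {
  p <- layer$params
  dpre <- dy * (cache$pre > 0)
  dx_skip <- dpre
  if (cache$attention) {
    se <- se_backward(dpre, p$W_r, p$W_e, cache$se)
    dg <- se$dx
    grads_se <- list(dW_r = se$dW_r, db_r = se$db_r,
                     dW_e = se$dW_e, db_e = se$db_e)
  } else {
    dg <- dpre
    grads_se <- list(dW_r = p$W_r * 0, db_r = p$b_r * 0,
                     dW_e = p$W_e * 0, db_e = p$b_e * 0)
  }
  b2 <- bn_backward(dg, cache$b2)
  c2 <- conv_backward(b2$dx, p$W2, cache$c2)
  dr1 <- c2$dx * (cache$b1_out > 0)
  b1 <- bn_backward(dr1, cache$b1)
  c1 <- conv_backward(b1$dx, p$W1, cache$c1)
  list(
    dx = c1$dx + dx_skip,
    grads = list(W1 = c1$dW, b1 = c1$db, gamma1 = b1$dgamma, beta1 = b1$dbeta,
                 W2 = c2$dW, b2 = c2$db, gamma2 = b2$dgamma, beta2 = b2$dbeta,
                 W_r = grads_se$dW_r, b_r = grads_se$db_r,
                 W_e = grads_se$dW_e, b_e = grads_se$db_e)
  )
}

#' Forward pass of a residual attention block
#'
#' Applies conv-BN-ReLU-conv-BN, an optional per-channel
#' squeeze-and-excitation gate, the identity skip connection, and a final
#' ReLU. Shape is preserved.
#'
#' @param x Feature array `(H, W, C, N)` (or `(H, W, C)`, promoted to a
#'   batch of one).
#' @param block A [rab_block()] whose channel count matches `x`.
#' @param attention_enabled Apply the channel gate (default `TRUE`); `FALSE`
#'   reduces the block to the pure residual form.
#' @param training Use batch statistics in the normalization (default
#'   `FALSE`: running statistics).
#' @return Feature array of the same shape as `x`.
#' @export
rab_forward <- function(x, block, attention_enabled = TRUE, training = FALSE) {
  rank <- length(dim(x))
  x4 <- if (rank == 3L) array(x, c(dim(x), 1L)) else x
  if (dim(x4)[3] != block$channels) {
    stop("input channel count does not match the block", call. = FALSE)
  }
  out <- rab_fwd(block, x4, training, attention_enabled)$out
  if (rank == 3L) array(out, dim(out)[1:3]) else out
}

# ---- model assembly ----------------------------------------------------------

#' Build an untrained scalogram classifier
#'
#' Layer order: Conv(5x5) -> RAB -> Conv(5x5) -> MaxPool -> RAB -> MaxPool ->
#' FC(softmax). With `rab_enabled = FALSE`, each RAB is replaced by a plain
#' 3x3 convolution + ReLU (the no-RAB ablation). Layer output shapes are
#' pre-computed with [conv_output_size()] and validated; a non-positive
#' spatial size aborts naming the offending layer.
#'
#' @param cfg A [model_config()].
#' @param seed Seed for weight initialisation.
#' @return An untrained `wavehar_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  tower_cin <- if (cfg$fusion_mode == "late") 1L else cfg$input_channels
  n_towers <- if (cfg$fusion_mode == "late") cfg$input_channels else 1L
  f1 <- cfg$conv_filters[1]
  f2 <- cfg$conv_filters[2]

  shapes <- list(input = c(cfg$image_size, tower_cin))
  track <- function(prev, layer_name, out) {
    if (any(out[1:2] < 1)) {
      stop(sprintf("layer %s produces a non-positive spatial size", layer_name),
           call. = FALSE)
    }
    out
  }
  pool_shape <- function(sh) {
    g <- pool_geometry(sh[1], sh[2], cfg$pool_size, cfg$pool_size,
                       cfg$pool_stride, cfg$pool_padding)
    c(g$Hout, g$Wout, sh[3])
  }

  s1 <- track(NULL, "conv1", conv_output_size(
    cfg$image_size[1], cfg$image_size[2], cfg$conv_kernel, cfg$conv_kernel,
    cfg$conv_pad, cfg$conv_stride, f1
  ))
  s2 <- s1 # RAB preserves shape
  s3 <- track(NULL, "conv2", conv_output_size(
    s2[1], s2[2], cfg$conv_kernel, cfg$conv_kernel,
    cfg$conv_pad, cfg$conv_stride, f2
  ))
  s4 <- track(NULL, "maxpool1", pool_shape(s3))
  s5 <- s4
  s6 <- track(NULL, "maxpool2", pool_shape(s5))
  feat_dim <- prod(s6) * n_towers

  layers <- with_seed(seed, {
    mk_conv <- function(k, cin, cout, pad) {
      list(type = "conv", kernel = k, pad = pad, stride = cfg$conv_stride,
           params = list(W = he_init(c(k, k, cin, cout), k * k * cin),
                         b = numeric(cout)))
    }
    mk_rab_or_conv <- function(channels) {
      if (cfg$rab_enabled) {
        rab_block(channels, cfg$rab_kernel, cfg$se_reduction)
      } else {
        mk_conv(cfg$rab_kernel, channels, channels,
                (cfg$rab_kernel - 1L) %/% 2L)
      }
    }
    fc <- list(type = "fc",
               params = list(
                 W = matrix(rnorm(feat_dim * cfg$n_classes,
                                  sd = sqrt(2 / feat_dim)),
                            feat_dim, cfg$n_classes),
                 b = numeric(cfg$n_classes)
               ))
    list(
      conv1 = mk_conv(cfg$conv_kernel, tower_cin, f1, cfg$conv_pad),
      rab1 = mk_rab_or_conv(f1),
      conv2 = mk_conv(cfg$conv_kernel, f1, f2, cfg$conv_pad),
      pool1 = list(type = "maxpool"),
      rab2 = mk_rab_or_conv(f2),
      pool2 = list(type = "maxpool"),
      fc = fc
    )
  })

  structure(
    list(cfg = cfg, layers = layers, n_towers = n_towers,
         shapes = list(conv1 = s1, rab1 = s2, conv2 = s3, pool1 = s4,
                       rab2 = s5, pool2 = s6, features = feat_dim)),
    class = "wavehar_model"
  )
}

#' @export
print.wavehar_model <- function(x, ...) {
  cat(sprintf(
    "<wavehar_model> %dx%d images, %d channel(s), %s fusion, %d classes\n",
    x$cfg$image_size[1], x$cfg$image_size[2], x$cfg$input_channels,
    x$cfg$fusion_mode, x$cfg$n_classes
  ))
  cat(sprintf("  RABs %s, attention %s, %d flattened features\n",
              if (x$cfg$rab_enabled) "on" else "off (plain conv)",
              if (x$cfg$attention_enabled) "on" else "off",
              x$shapes$features))
  invisible(x)
}

# Forward through one tower (everything before the FC head).
tower_forward <- function(model, x, training) {
  cfg <- model$cfg
  layers <- model$layers
  caches <- list()
  states <- list()
  run_layer <- function(name, x) {
    ly <- layers[[name]]
    if (ly$type == "conv") {
      cf <- conv_forward(x, ly$params$W, ly$params$b, ly$stride, ly$pad)
      caches[[name]] <<- cf$cache
      relu(cf$out)
    } else if (ly$type == "rab") {
      rf <- rab_fwd(ly, x, training, cfg$attention_enabled)
      caches[[name]] <<- rf$cache
      states[[name]] <<- rf$state
      rf$out
    } else { # maxpool
      mf <- maxpool_forward(x, cfg$pool_size, cfg$pool_size,
                            cfg$pool_stride, cfg$pool_padding)
      caches[[name]] <<- mf$cache
      mf$out
    }
  }
  h <- run_layer("conv1", x)
  caches$conv1_out <- h
  h <- run_layer("rab1", h)
  if (layers$rab1$type == "conv") caches$rab1_out <- h
  h <- run_layer("conv2", h)
  caches$conv2_out <- h
  h <- run_layer("pool1", h)
  h <- run_layer("rab2", h)
  if (layers$rab2$type == "conv") caches$rab2_out <- h
  h <- run_layer("pool2", h)
  feat <- matrix(h, prod(dim(h)[1:3]), dim(h)[4])
  list(features = feat, caches = caches, states = states,
       out_dim = dim(h))
}

tower_backward <- function(model, dfeat, caches) {
  cfg <- model$cfg
  layers <- model$layers
  grads <- list()
  g2 <- caches$pool2$geom
  dh <- array(dfeat, c(g2$Hout, g2$Wout, caches$pool2$in_dim[3],
                       caches$pool2$in_dim[4]))
  back_layer <- function(name, dh) {
    ly <- layers[[name]]
    if (ly$type == "conv") {
      act <- caches[[paste0(name, "_out")]]
      dpre <- dh * (act > 0)
      cb <- conv_backward(dpre, ly$params$W, caches[[name]])
      grads[[name]] <<- list(W = cb$dW, b = cb$db)
      cb$dx
    } else if (ly$type == "rab") {
      rb <- rab_bwd(ly, dh, caches[[name]])
      grads[[name]] <<- rb$grads
      rb$dx
    } else {
      maxpool_backward(dh, caches[[name]])
    }
  }
  dh <- back_layer("pool2", dh)
  dh <- back_layer("rab2", dh)
  dh <- back_layer("pool1", dh)
  dh <- back_layer("conv2", dh)
  dh <- back_layer("rab1", dh)
  dh <- back_layer("conv1", dh)
  list(grads = grads, dx = dh)
}

# Full forward: returns class probabilities, caches for backward, and BN
# running-state updates.
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  d <- dim(x)
  stopifnot(length(d) == 4L)
  if (d[3] != cfg$input_channels) {
    stop("input channel count does not match the model", call. = FALSE)
  }
  tower_caches <- list()
  states <- NULL
  if (cfg$fusion_mode == "late") {
    feats <- vector("list", cfg$input_channels)
    for (ch in seq_len(cfg$input_channels)) {
      tf <- tower_forward(model, x[, , ch, , drop = FALSE], training)
      feats[[ch]] <- tf$features
      tower_caches[[ch]] <- tf$caches
      # running statistics advance once per forward: average the per-channel
      # batch statistics by applying updates sequentially
      if (training && length(tf$states)) {
        for (nm in names(tf$states)) {
          model$layers[[nm]]$state <- tf$states[[nm]]
        }
      }
    }
    feat <- do.call(rbind, feats)
  } else {
    tf <- tower_forward(model, x, training)
    feat <- tf$features
    tower_caches[[1]] <- tf$caches
    if (training && length(tf$states)) {
      for (nm in names(tf$states)) {
        model$layers[[nm]]$state <- tf$states[[nm]]
      }
    }
  }
  fc <- model$layers$fc$params
  z <- crossprod(fc$W, feat) + fc$b
  z_pre <- z
  if (cfg$fc_relu) z <- pmax(z, 0)
  probs <- softmax(z)
  list(probs = probs, logits = z, z_pre = z_pre, feat = feat,
       tower_caches = tower_caches, model = model)
}

# Backward from dlogits (gradient at the pre-softmax logits).
model_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg
  if (cfg$fc_relu) dlogits <- dlogits * (fwd$z_pre > 0)
  fcW <- model$layers$fc$params$W
  grads <- list(fc = list(
    W = tcrossprod(fwd$feat, dlogits),
    b = rowSums(dlogits)
  ))
  dfeat <- fcW %*% dlogits
  add_grads <- function(a, b) {
    if (is.null(a)) return(b)
    for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
    a
  }
  if (cfg$fusion_mode == "late") {
    per_tower <- model$shapes$pool2
    feat_per <- prod(per_tower)
    for (ch in seq_len(cfg$input_channels)) {
      rows <- (ch - 1L) * feat_per + seq_len(feat_per)
      tb <- tower_backward(model, dfeat[rows, , drop = FALSE],
                           fwd$tower_caches[[ch]])
      for (nm in names(tb$grads)) {
        grads[[nm]] <- add_grads(grads[[nm]], tb$grads[[nm]])
      }
    }
  } else {
    tb <- tower_backward(model, dfeat, fwd$tower_caches[[1]])
    grads <- c(grads, tb$grads)
  }
  grads
}

# ---- training ----------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam, learning rate 1e-4,
#' minibatch 128, 100 epochs, categorical cross-entropy.
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param batch_size Minibatch size (default 128).
#' @param max_epochs Maximum epochs (default 100).
#' @param seed Seed for shuffling (weight init is seeded at
#'   [build_model()]).
#' @param patience Early-stopping patience on validation accuracy (epochs
#'   without improvement); `Inf` (default) disables early stopping.
#' @param verbose Print a line every `verbose` epochs; 0 silences.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         max_epochs = 100L, seed = 1L, patience = Inf,
                         verbose = 0L) {
  assert_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  stopifnot(batch_size >= 1L, max_epochs >= 0L)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), optimizer = "adam",
         loss = "cross-entropy", seed = as.integer(seed), patience = patience,
         verbose = as.integer(verbose)),
    class = "train_config"
  )
}

adam_init <- function(layers) {
  st <- list()
  for (nm in names(layers)) {
    ps <- layers[[nm]]$params
    if (is.null(ps)) next
    st[[nm]] <- lapply(ps, function(p) list(m = p * 0, v = p * 0))
  }
  st
}

adam_step <- function(layers, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      s <- state[[nm]][[pn]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      layers[[nm]]$params[[pn]] <- layers[[nm]]$params[[pn]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[nm]][[pn]] <- s
    }
  }
  list(layers = layers, state = state)
}

#' Train a scalogram classifier
#'
#' Minibatch gradient descent with Adam on the categorical cross-entropy.
#' Per-epoch train loss/accuracy (averaged over minibatches) and validation
#' loss/accuracy (inference mode) are recorded; the returned parameters are
#' those of the best-validation-accuracy epoch (earliest epoch on ties).
#' Fully deterministic given the seeds.
#'
#' @param model An untrained `wavehar_model` from [build_model()].
#' @param train_x Image array `(H, W, C, N)`.
#' @param train_y Integer 0-based labels, length N.
#' @param val_x,val_y Validation images and labels (optional; without them
#'   the final-epoch parameters are returned).
#' @param tcfg A [train_config()].
#' @return A `trained_model`: the fitted `model`, a `history` tibble (epoch,
#'   train/validation loss and accuracy) and `best_epoch`.
#' @export
train_model <- function(model, train_x, train_y, val_x = NULL, val_y = NULL,
                        tcfg = train_config()) {
  stopifnot(inherits(model, "wavehar_model"), inherits(tcfg, "train_config"))
  n <- dim(train_x)[4]
  stopifnot(length(train_y) == n, n >= 1L)
  has_val <- !is.null(val_x) && !is.null(val_y)
  n_classes <- model$cfg$n_classes
  adam <- adam_init(model$layers)
  t_step <- 0L
  history <- list()
  best <- list(acc = -Inf, epoch = 0L, layers = model$layers)
  epochs_since_best <- 0L

  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- with_seed(stage_seed(tcfg$seed, paste0("shuffle", epoch)),
                     sample.int(n))
    batch_loss <- c()
    batch_acc <- c()
    for (start in seq.int(1L, n, by = tcfg$batch_size)) {
      idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
      xb <- train_x[, , , idx, drop = FALSE]
      yb <- train_y[idx]
      yh <- one_hot(yb, n_classes)
      fwd <- model_forward(model, xb, training = TRUE)
      model <- fwd$model # BN running statistics
      loss <- cross_entropy(t(yh), t(fwd$probs))
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d; aborting", epoch),
             call. = FALSE)
      }
      dlogits <- (fwd$probs - yh) / length(idx)
      grads <- model_backward(model, fwd, dlogits)
      t_step <- t_step + 1L
      upd <- adam_step(model$layers, grads, adam, t_step, tcfg$learning_rate)
      model$layers <- upd$layers
      adam <- upd$state
      batch_loss <- c(batch_loss, loss)
      batch_acc <- c(batch_acc,
                     mean(max.col(t(fwd$probs), ties.method = "first") - 1L == yb))
    }
    row <- list(epoch = epoch, train_loss = mean(batch_loss),
                train_acc = mean(batch_acc),
                val_loss = NA_real_, val_acc = NA_real_)
    if (has_val) {
      vf <- model_forward(model, val_x, training = FALSE)
      vy <- one_hot(val_y, n_classes)
      row$val_loss <- cross_entropy(t(vy), t(vf$probs))
      row$val_acc <- mean(max.col(t(vf$probs), ties.method = "first") - 1L == val_y)
      if (row$val_acc > best$acc) {
        best <- list(acc = row$val_acc, epoch = epoch, layers = model$layers)
        epochs_since_best <- 0L
      } else {
        epochs_since_best <- epochs_since_best + 1L
      }
    }
    history[[epoch]] <- tibble::as_tibble(row)
    if (tcfg$verbose > 0L && epoch %% tcfg$verbose == 0L) {
      message(sprintf("epoch %3d  loss %.4f acc %.3f val_acc %s", epoch,
                      row$train_loss, row$train_acc,
                      ifelse(is.na(row$val_acc), "-", sprintf("%.3f", row$val_acc))))
    }
    if (has_val && is.finite(tcfg$patience) &&
        epochs_since_best >= tcfg$patience) break
  }

  if (has_val && best$epoch > 0L) {
    model$layers <- best$layers
    best_epoch <- best$epoch
  } else {
    best_epoch <- if (length(history)) length(history) else 0L
  }
  structure(
    list(model = model,
         history = if (length(history)) dplyr::bind_rows(history) else
           tibble::tibble(epoch = integer(), train_loss = numeric(),
                          train_acc = numeric(), val_loss = numeric(),
                          val_acc = numeric()),
         best_epoch = best_epoch,
         tcfg = tcfg),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<trained_model> %d epoch(s), best epoch %d\n",
              nrow(h), x$best_epoch))
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final train acc %.3f, val acc %s\n", last$train_acc,
                ifelse(is.na(last$val_acc), "-", sprintf("%.3f", last$val_acc))))
  }
  invisible(x)
}

#' Predict activity classes for image batches
#'
#' @param object A `trained_model` (or bare `wavehar_model`).
#' @param images Image array `(H, W, C, N)`.
#' @param ... Unused.
#' @return List with `labels` (0-based, argmax with ties to the smaller
#'   index) and `probabilities` (samples x classes matrix).
#' @export
predict.trained_model <- function(object, images, ...) {
  model <- if (inherits(object, "trained_model")) object$model else object
  fwd <- model_forward(model, images, training = FALSE)
  probs <- t(fwd$probs)
  list(labels = max.col(probs, ties.method = "first") - 1L,
       probabilities = probs)
}

#' @export
predict.wavehar_model <- function(object, images, ...) {
  predict.trained_model(object, images, ...)
}

#' @exportS3Method generics::tidy
tidy.trained_model <- function(x, ...) {
  x$history
}

#' @exportS3Method generics::glance
glance.trained_model <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    return(tibble::tibble(epochs = 0L, best_epoch = 0L,
                          train_acc = NA_real_, val_acc = NA_real_))
  }
  be <- min(x$best_epoch, nrow(h))
  tibble::tibble(
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    train_acc = h$train_acc[be],
    val_acc = h$val_acc[be]
  )
}
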