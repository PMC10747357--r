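# Neural-network primitives: convolution (sparse im2col), batch
# normalization, ReLU, squeeze-and-excitation channel attention, residual
# attention blocks, max pooling, fully-connected softmax head, categorical
# cross-entropy. Every forward has a matching analytic backward; correctness
# is pinned by finite-difference gradient tests.
#
# Tensor convention: feature maps are arrays of dim (H, W, C, N) — rows,
# columns, channels, batch. All math is double precision.

#' Output size of a convolution or pooling stage
#'
#' `floor((q_l + 2 r - q_s) / s) + 1` per spatial dimension, with `K_C` output
#' channels. `r` is the edge-extension (padding) per side; an asymmetric
#' "same" pad of odd total is expressed through a fractional `r`.
#'
#' @param q_l,p_l Input height and width.
#' @param q_s,p_s Kernel height and width.
#' @param r Padding per side (total padding is `2 r`).
#' @param s Stride (>= 1).
#' @param K_C Number of kernels (output channels).
#' @return Integer vector `c(height, width, channels)`.
#' @export
#' @examples
#' conv_output_size(64, 64, 5, 5, r = 2, s = 1, K_C = 32)
conv_output_size <- function(q_l, p_l, q_s, p_s, r, s, K_C) {
  stopifnot(q_l >= 1, p_l >= 1, q_s >= 1, p_s >= 1, r >= 0, s >= 1, K_C >= 1)
  if (q_s > q_l + 2 * r || p_s > p_l + 2 * r) {
    stop("kernel larger than padded input", call. = FALSE)
  }
  c(
    height = as.integer(floor((q_l + 2 * r - q_s) / s) + 1),
    width = as.integer(floor((p_l + 2 * r - p_s) / s) + 1),
    channels = as.integer(K_C)
  )
}

# ---- im2col machinery -------------------------------------------------------

# Sparse gather matrix mapping a padded flattened image (Hp*Wp*C) to im2col
# rows (kh fastest, then kw, then channel) for every output position
# (row-major over output rows). Cached: geometry repeats across calls.
im2col_T <- function(H, W, C, kh, kw, pad_top, pad_bottom, pad_left,
                     pad_right, s) {
  Hp <- H + pad_top + pad_bottom
  Wp <- W + pad_left + pad_right
  Hout <- floor((Hp - kh) / s) + 1L
  Wout <- floor((Wp - kw) / s) + 1L
  if (Hout < 1L || Wout < 1L) stop("kernel larger than padded input", call. = FALSE)
  key <- paste("T", H, W, C, kh, kw, pad_top, pad_bottom, pad_left, pad_right,
               s, sep = "_")
  hit <- .wavehar_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- expand.grid(ki = seq_len(kh), kj = seq_len(kw), c = seq_len(C),
                   oi = seq_len(Hout), oj = seq_len(Wout))
  idx <- (g$c - 1L) * (Hp * Wp) +
    ((g$oj - 1L) * s + g$kj - 1L) * Hp +
    ((g$oi - 1L) * s + g$ki)
  Tm <- Matrix::sparseMatrix(
    i = seq_along(idx), j = idx, x = 1,
    dims = c(length(idx), Hp * Wp * C)
  )
  out <- list(Tm = Tm, Hout = Hout, Wout = Wout, Hp = Hp, Wp = Wp)
  .wavehar_cache[[key]] <- out
  out
}

pad_tensor <- function(x, pad_top, pad_bottom, pad_left, pad_right, value = 0) {
  d <- dim(x)
  if (pad_top == 0 && pad_bottom == 0 && pad_left == 0 && pad_right == 0) {
    return(x)
  }
  out <- array(value, c(d[1] + pad_top + pad_bottom,
                        d[2] + pad_left + pad_right, d[3], d[4]))
  out[pad_top + seq_len(d[1]), pad_left + seq_len(d[2]), , ] <- x
  out
}

# Forward convolution. pad = symmetric padding per side (integer).
conv_forward <- function(x, W, b, s = 1L, pad = 0L) {
  d <- dim(x)
  kd <- dim(W) # kh, kw, cin, cout
  stopifnot(kd[3] == d[3])
  tm <- im2col_T(d[1], d[2], d[3], kd[1], kd[2], pad, pad, pad, pad, s)
  xp <- pad_tensor(x, pad, pad, pad, pad)
  Xp <- matrix(xp, nrow = tm$Hp * tm$Wp * d[3], ncol = d[4])
  khkwc <- kd[1] * kd[2] * kd[3]
  n_out <- tm$Hout * tm$Wout
  Xcol <- matrix(as.matrix(tm$Tm %*% Xp), khkwc, n_out * d[4])
  Wmat <- matrix(W, khkwc, kd[4])
  Y <- crossprod(Wmat, Xcol) + b
  out <- aperm(array(Y, c(kd[4], tm$Hout, tm$Wout, d[4])), c(2, 3, 1, 4))
  list(out = out,
       cache = list(Xcol = Xcol, tm = tm, in_dim = d, k_dim = kd,
                    s = s, pad = pad))
}

conv_backward <- function(dy, W, cache) {
  kd <- cache$k_dim
  d <- cache$in_dim
  tm <- cache$tm
  khkwc <- kd[1] * kd[2] * kd[3]
  n_out <- tm$Hout * tm$Wout
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), kd[4], n_out * d[4])
  db <- rowSums(dym)
  dW <- array(tcrossprod(cache$Xcol, dym), kd)
  Wmat <- matrix(W, khkwc, kd[4])
  dXcol <- Wmat %*% dym
  dXp <- as.matrix(Matrix::crossprod(tm$Tm, matrix(dXcol, khkwc * n_out, d[4])))
  dxp <- array(dXp, c(tm$Hp, tm$Wp, d[3], d[4]))
  p <- cache$pad
  dx <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# ---- batch normalization ----------------------------------------------------

bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       eps = 1e-5, momentum = 0.9) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v[v < 0] <- 0
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
    new_mean <- run_mean
    new_var <- run_var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv_std, `*`)
  ym <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(out = y,
       cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma, dims = d,
                    training = training),
       run_mean = new_mean, run_var = new_var)
}

bn_backward <- function(dy, cache) {
  d <- cache$dims
  C <- d[3]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$gamma, `*`)
  if (cache$training) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dxm <- sweep(
      dxhat - matrix(m1, nrow(dxhat), C, byrow = TRUE) -
        cache$xhat * matrix(m2, nrow(dxhat), C, byrow = TRUE),
      2, cache$inv_std, `*`
    )
  } else {
    dxm <- sweep(dxhat, 2, cache$inv_std, `*`)
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- squeeze-and-excitation channel gate ------------------------------------

se_forward <- function(x, W_r, b_r, W_e, b_e) {
  d <- dim(x)
  hw <- d[1] * d[2]
  s <- matrix(colMeans(matrix(x, hw, d[3] * d[4])), d[3], d[4])
  z_pre <- W_r %*% s + b_r
  z1 <- relu(z_pre)
  g <- 1 / (1 + exp(-(W_e %*% z1 + b_e)))
  gex <- array(rep(g, each = hw), d)
  list(out = x * gex,
       cache = list(x = x, s = s, z_pre = z_pre, z1 = z1, g = g, gex = gex,
                    dims = d))
}

se_backward <- function(dy, W_r, W_e, cache) {
  d <- cache$dims
  hw <- d[1] * d[2]
  dx <- dy * cache$gex
  dg <- matrix(colSums(matrix(dy * cache$x, hw, d[3] * d[4])), d[3], d[4])
  dz2 <- dg * cache$g * (1 - cache$g)
  dW_e <- tcrossprod(dz2, cache$z1)
  db_e <- rowSums(dz2)
  dz1 <- crossprod(W_e, dz2) * (cache$z_pre > 0)
  dW_r <- tcrossprod(dz1, cache$s)
  db_r <- rowSums(dz1)
  ds <- crossprod(W_r, dz1)
  dx <- dx + array(rep(ds / hw, each = hw), d)
  list(dx = dx, dW_r = dW_r, db_r = db_r, dW_e = dW_e, db_e = db_e)
}

# ---- max pooling -------------------------------------------------------------

# TensorFlow-style "same" padding: output ceil(H/s), padding bottom/right
# heavy; pad value -Inf so padding never wins the max.
pool_geometry <- function(H, W, qm, pm, s, padding) {
  if (padding == "same") {
    Hout <- ceiling(H / s)
    Wout <- ceiling(W / s)
    pad_h <- max((Hout - 1) * s + qm - H, 0)
    pad_w <- max((Wout - 1) * s + pm - W, 0)
    list(Hout = Hout, Wout = Wout,
         top = pad_h %/% 2, bottom = pad_h - pad_h %/% 2,
         left = pad_w %/% 2, right = pad_w - pad_w %/% 2)
  } else {
    list(Hout = floor((H - qm) / s) + 1L, Wout = floor((W - pm) / s) + 1L,
         top = 0L, bottom = 0L, left = 0L, right = 0L)
  }
}

pool_T <- function(H, W, C, qm, pm, s, geom) {
  key <- paste("P", H, W, C, qm, pm, s, geom$top, geom$bottom, geom$left,
               geom$right, sep = "_")
  hit <- .wavehar_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + geom$top + geom$bottom
  Wp <- W + geom$left + geom$right
  g <- expand.grid(ki = seq_len(qm), kj = seq_len(pm),
                   oi = seq_len(geom$Hout), oj = seq_len(geom$Wout),
                   c = seq_len(C))
  idx <- (g$c - 1L) * (Hp * Wp) +
    ((g$oj - 1L) * s + g$kj - 1L) * Hp +
    ((g$oi - 1L) * s + g$ki)
  Tm <- Matrix::sparseMatrix(i = seq_along(idx), j = idx, x = 1,
                             dims = c(length(idx), Hp * Wp * C))
  .wavehar_cache[[key]] <- Tm
  Tm
}

maxpool_forward <- function(x, qm = 2L, pm = 2L, s = 1L, padding = "same") {
  d <- dim(x)
  geom <- pool_geometry(d[1], d[2], qm, pm, s, padding)
  if (geom$Hout < 1L || geom$Wout < 1L) {
    stop("pool window larger than input", call. = FALSE)
  }
  Tm <- pool_T(d[1], d[2], d[3], qm, pm, s, geom)
  xp <- pad_tensor(x, geom$top, geom$bottom, geom$left, geom$right,
                   value = -Inf)
  Xp <- matrix(xp, ncol = d[4])
  k <- qm * pm
  n_cols <- geom$Hout * geom$Wout * d[3]
  Pcol <- matrix(as.matrix(Tm %*% Xp), k, n_cols * d[4])
  mx <- Pcol[1, ]
  if (k > 1L) for (r in 2:k) mx <- pmax(mx, Pcol[r, ])
  # first-max routing for the backward pass
  mask <- matrix(FALSE, k, length(mx))
  taken <- rep(FALSE, length(mx))
  for (r in seq_len(k)) {
    sel <- !taken & (Pcol[r, ] == mx)
    mask[r, ] <- sel
    taken <- taken | sel
  }
  out <- array(mx, c(geom$Hout, geom$Wout, d[3], d[4]))
  list(out = out,
       cache = list(mask = mask, Tm = Tm, geom = geom, in_dim = d,
                    k = k, n_cols = n_cols))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  geom <- cache$geom
  dyv <- as.vector(dy)
  dXcol <- cache$mask * rep(dyv, each = cache$k)
  dXp <- as.matrix(Matrix::crossprod(
    cache$Tm, matrix(dXcol, cache$k * cache$n_cols, d[4])
  ))
  Hp <- d[1] + geom$top + geom$bottom
  Wp <- d[2] + geom$left + geom$right
  dxp <- array(dXp, c(Hp, Wp, d[3], d[4]))
  dxp[geom$top + seq_len(d[1]), geom$left + seq_len(d[2]), , , drop = FALSE]
}

#' Max pooling over a feature map
#'
#' Replaces each output position by the maximum over its pooling window.
#' `"same"` padding keeps `ceil(size / stride)` outputs per dimension (pad
#' value is treated as minus infinity); `"valid"` uses only full windows.
#'
#' @param x A numeric matrix (H x W) or array (H, W, C) / (H, W, C, N).
#' @param pool Integer pair, pooling window (default `c(2, 2)`).
#' @param stride Stride (default 1, the no-downsampling setting; use 2 for
#'   conventional halving).
#' @param padding `"same"` or `"valid"`.
#' @return Pooled object with the same rank as the input.
#' @export
#' @examples
#' max_pool(matrix(1:4, 2, byrow = TRUE), pool = c(2, 2), stride = 1)
max_pool <- function(x, pool = c(2L, 2L), stride = 1L, padding = "same") {
  padding <- match.arg(padding, c("same", "valid"))
  orig_dim <- dim(x)
  rank <- length(orig_dim)
  if (is.null(orig_dim)) stop("`x` must be a matrix or array", call. = FALSE)
  x4 <- switch(as.character(rank),
    "2" = array(x, c(orig_dim, 1L, 1L)),
    "3" = array(x, c(orig_dim, 1L)),
    "4" = x,
    stop("`x` must have 2-4 dimensions", call. = FALSE)
  )
  out <- maxpool_forward(x4, pool[1], pool[2], stride, padding)$out
  d <- dim(out)
  switch(as.character(rank),
    "2" = matrix(out, d[1], d[2]),
    "3" = array(out, d[1:3]),
    out
  )
}

# ---- dense head --------------------------------------------------------------

#' Numerically stable softmax
#'
#' @param z Numeric vector, or matrix with one sample per column.
#' @return Probabilities of the same shape; each sample sums to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    zc <- sweep(z, 2, apply(z, 2, max))
    e <- exp(zc)
    sweep(e, 2, colSums(e), `/`)
  } else {
    zc <- z - max(z)
    e <- exp(zc)
    e / sum(e)
  }
}

#' Fully connected layer with softmax output
#'
#' Computes `z = u W + B`, optionally rectifies the logits (`relu = TRUE`
#' gives `z = ReLU(u W + B)`), and returns `softmax(z)`. Log-sum-exp
#' stabilization is applied inside the softmax.
#'
#' @param u Input feature vector, or matrix with one sample per column
#'   (`d_in` rows).
#' @param W Weight matrix, `d_in x n_classes`.
#' @param B Bias vector, length `n_classes`.
#' @param relu Apply ReLU to the logits before the softmax (default `FALSE`,
#'   a plain linear-softmax head).
#' @return Probability vector/matrix over classes (samples as columns).
#' @export
fc_softmax <- function(u, W, B, relu = FALSE) {
  um <- if (is.matrix(u)) u else matrix(u, ncol = 1)
  if (!all(is.finite(um))) stop("non-finite input to fc_softmax", call. = FALSE)
  if (nrow(um) != nrow(W)) stop("feature/weight dimension mismatch", call. = FALSE)
  z <- crossprod(W, um) + B
  if (relu) z <- pmax(z, 0)
  p <- softmax(z)
  if (is.matrix(u)) p else as.vector(p)
}

#' Categorical cross-entropy loss
#'
#' `L = -(1/n) sum_samples sum_k y_k log(yhat_k)` with predictions clipped at
#' `1e-12`; reduces to the familiar binary form for two classes. Vectors are
#' treated as a single sample's class distribution; matrices hold one sample
#' per row.
#'
#' @param y_true One-hot labels (vector or samples-by-classes matrix).
#' @param y_pred Predicted probabilities, same shape.
#' @return A single non-negative number.
#' @export
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5)) # log 2
cross_entropy <- function(y_true, y_pred) {
  if (!identical(dim(y_true), dim(y_pred)) ||
      length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have the same shape", call. = FALSE)
  }
  p <- pmin(pmax(y_pred, 1e-12), 1)
  n <- if (is.matrix(y_true)) nrow(y_true) else 1L
  -sum(y_true * log(p)) / n
}

one_hot <- function(labels, n_classes) {
  m <- matrix(0, n_classes, length(labels))
  m[cbind(labels + 1L, seq_along(labels))] <- 1
  m
}
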