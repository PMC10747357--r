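# Morlet continuous wavelet transform and scalogram images.
#
# Conventions used throughout:
#   * time is measured in samples inside the transform; `dt` (seconds/sample)
#     multiplies the coefficients so their amplitude is sampling-rate aware;
#   * scales are dimensionless sample-unit scales, so the pseudo-frequency of
#     scale `a` is f = sigma / (2 * pi * a * dt) Hz;
#   * the signal is treated as zero outside the window (zero-padding boundary).

#' Morlet normalization constant
#'
#' The constant that makes the zero-mean-corrected Morlet wavelet unit-energy:
#' \eqn{c_\sigma = (1 + e^{-\sigma^2} - 2 e^{-3\sigma^2/4})^{-1/2}}. It tends
#' to 1 as \eqn{\sigma} grows and the correction term vanishes.
#'
#' @param sigma Shape factor, a positive number. Larger values trade time
#'   resolution for frequency resolution.
#' @return A single positive number.
#' @export
#' @examples
#' morlet_norm_constant(6)
morlet_norm_constant <- function(sigma) {
  assert_scalar_num(sigma, "sigma", positive = TRUE)
  (1 + exp(-sigma^2) - 2 * exp(-0.75 * sigma^2))^(-0.5)
}

#' Morlet wavelet parameters
#'
#' Bundles the shape factor with its derived normalization constant.
#'
#' @param sigma Shape factor (> 0).
#' @return An object of class `morlet_params` with fields `sigma` and
#'   `c_sigma`.
#' @export
morlet_params <- function(sigma) {
  structure(
    list(sigma = sigma, c_sigma = morlet_norm_constant(sigma)),
    class = "morlet_params"
  )
}

#' Evaluate the Morlet mother wavelet
#'
#' \eqn{\psi(t) = c_\sigma \pi^{-1/4} e^{-t^2/2} (e^{i\sigma t} -
#' e^{-\sigma^2/2})}. The subtracted constant enforces zero mean
#' (admissibility); the Gaussian envelope localizes the oscillation.
#'
#' @param t Numeric vector of (dimensionless) time points.
#' @param params A [morlet_params()] object, or a bare positive number taken
#'   as the shape factor.
#' @return Complex vector of the same length as `t`.
#' @export
#' @examples
#' morlet_psi(0, morlet_params(6))
morlet_psi <- function(t, params) {
  if (is.numeric(params)) params <- morlet_params(params)
  stopifnot(inherits(params, "morlet_params"))
  sigma <- params$sigma
  params$c_sigma * pi^(-0.25) * exp(-0.5 * t^2) *
    (exp(1i * sigma * t) - exp(-0.5 * sigma^2))
}

# Kernel-FFT cache: cwt_transform is called thousands of times on windows that
# share (n, sigma, scale set, dt); the wavelet kernel spectra depend only on
# those, so they are memoised here.
.wavehar_cache <- new.env(parent = emptyenv())

cwt_kernel_fft <- function(a, sigma, n) {
  m_half <- ceiling(10 * a) # envelope ~ exp(-50) at the cut: negligible
  pad_len <- stats::nextn(n + m_half + 1, 2)
  key <- sprintf("k_%.12g_%.12g_%d", sigma, a, pad_len)
  hit <- .wavehar_cache[[key]]
  if (!is.null(hit)) return(hit)
  u <- -m_half:m_half
  gk <- Conj(morlet_psi(-u / a, morlet_params(sigma)))
  kern <- complex(length.out = pad_len)
  kern[(u %% pad_len) + 1L] <- gk
  out <- list(fft = stats::fft(kern), pad_len = pad_len)
  .wavehar_cache[[key]] <- out
  out
}

#' Continuous wavelet transform of a single channel
#'
#' Computes \eqn{C(a, b) = |a|^{-1/2} \sum_k x_k \psi^*((k - b)/a)\, dt} for
#' every integer translation `b` in the window and every requested scale, with
#' the signal taken as zero outside the window. The default implementation
#' evaluates the sum by FFT-based convolution; `method = "direct"` evaluates
#' it term by term and is kept as the slow reference the fast path must match.
#'
#' @param signal Numeric vector, length >= 8.
#' @param scales Strictly positive numeric vector of scales (sample units).
#' @param sigma Morlet shape factor (> 0).
#' @param dt Sampling interval in seconds (> 0).
#' @param method `"fft"` (default) or `"direct"`.
#' @return A `scalogram` object: complex coefficient matrix
#'   (`length(scales)` rows x `length(signal)` columns) plus the `scales`,
#'   `dt` and `sigma` used.
#' @export
#' @examples
#' s <- cwt_transform(sin(2 * pi * 2 * seq(0, 2.54, by = 0.02)),
#'                    scales = 1:32, sigma = 6, dt = 0.02)
#' dim(s$coeffs)
cwt_transform <- function(signal, scales, sigma, dt, method = c("fft", "direct")) {
  method <- match.arg(method)
  if (!is.numeric(signal) || length(signal) == 0L) {
    stop("`signal` must be a non-empty numeric vector", call. = FALSE)
  }
  n <- length(signal)
  if (n < 8L) stop("`signal` must have at least 8 samples", call. = FALSE)
  if (!is.numeric(scales) || length(scales) == 0L || any(scales <= 0)) {
    stop("`scales` must be a vector of positive values", call. = FALSE)
  }
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("`scales` must be strictly increasing", call. = FALSE)
  }
  assert_scalar_num(sigma, "sigma", positive = TRUE)
  assert_scalar_num(dt, "dt", positive = TRUE)

  m <- length(scales)
  coeffs <- matrix(complex(length.out = m * n), nrow = m, ncol = n)
  if (method == "direct") {
    mp <- morlet_params(sigma)
    k <- 0:(n - 1)
    for (i in seq_len(m)) {
      a <- scales[i]
      # rows index k (signal samples), columns index b (translations)
      psi_mat <- Conj(morlet_psi(outer(k, k, "-") / a, mp))
      coeffs[i, ] <- (abs(a)^(-0.5) * dt) * as.vector(signal %*% psi_mat)
    }
  } else {
    for (i in seq_len(m)) {
      a <- scales[i]
      kern <- cwt_kernel_fft(a, sigma, n)
      xpad <- complex(length.out = kern$pad_len)
      xpad[seq_len(n)] <- signal
      conv <- stats::fft(stats::fft(xpad) * kern$fft, inverse = TRUE) / kern$pad_len
      coeffs[i, ] <- (abs(a)^(-0.5) * dt) * conv[seq_len(n)]
    }
  }
  structure(
    list(coeffs = coeffs, scales = as.numeric(scales), dt = dt, sigma = sigma),
    class = "scalogram"
  )
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf(
    "<scalogram> %d scales x %d samples, sigma = %g, dt = %g s\n",
    nrow(x$coeffs), ncol(x$coeffs), x$sigma, x$dt
  ))
  invisible(x)
}

#' Pseudo-frequency of a Morlet scale
#'
#' Maps a sample-unit scale to the frequency (Hz) at which the scaled Morlet
#' wavelet's spectrum peaks: \eqn{f = \sigma / (2 \pi a \, dt)}.
#'
#' @param scale Scale value(s) in sample units.
#' @param sigma Shape factor.
#' @param dt Sampling interval (seconds).
#' @return Frequency or frequencies in Hz.
#' @export
scale_to_frequency <- function(scale, sigma, dt) {
  sigma / (2 * pi * scale * dt)
}

# Bilinear resize with half-pixel-centre mapping; exact identity when the
# requested size equals the input size.
resize_bilinear <- function(mat, out_h, out_w) {
  in_h <- nrow(mat)
  in_w <- ncol(mat)
  if (in_h == out_h && in_w == out_w) return(mat)
  src_y <- pmin(pmax((seq_len(out_h) - 0.5) * in_h / out_h + 0.5, 1), in_h)
  src_x <- pmin(pmax((seq_len(out_w) - 0.5) * in_w / out_w + 0.5, 1), in_w)
  y0 <- pmin(floor(src_y), in_h - 1L)
  x0 <- pmin(floor(src_x), in_w - 1L)
  if (in_h == 1L) y0 <- rep(1, out_h)
  if (in_w == 1L) x0 <- rep(1, out_w)
  wy <- src_y - y0
  wx <- src_x - x0
  y1 <- pmin(y0 + 1L, in_h)
  x1 <- pmin(x0 + 1L, in_w)
  top <- mat[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
    mat[y0, x1, drop = FALSE] * outer(1 - wy, wx)
  bot <- mat[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
    mat[y1, x1, drop = FALSE] * outer(wy, wx)
  top + bot
}

#' Convert a scalogram to a fixed-size normalized image
#'
#' Takes coefficient magnitudes, min-max normalizes them to `[0, 1]` per image
#' (a constant matrix maps to all zeros), and resizes to the requested shape
#' by bilinear interpolation. Rows are ordered smallest scale at the top, i.e.
#' high pseudo-frequency first, matching the usual scalogram rendering.
#'
#' @param s A `scalogram` from [cwt_transform()].
#' @param size Integer vector `c(H, W)`, both >= 8.
#' @param channel Optional channel index recorded on the result.
#' @return A `scalogram_image`: an `H x W` matrix with values in `[0, 1]`.
#' @export
scalogram_to_image <- function(s, size = c(64L, 64L), channel = NA_integer_) {
  stopifnot(inherits(s, "scalogram"))
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 8L)) {
    stop("`size` must be c(H, W) with both dimensions >= 8", call. = FALSE)
  }
  mag <- abs(s$coeffs)
  rng <- range(mag)
  norm <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1]) else mag * 0
  px <- resize_bilinear(norm, size[1], size[2])
  # interpolation of values in [0,1] stays in [0,1]; clamp fp dust anyway
  px[px < 0] <- 0
  px[px > 1] <- 1
  structure(px, class = c("scalogram_image", "matrix"), channel = channel)
}
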