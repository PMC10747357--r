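# Shared fixtures, all generated in code.

# A tiny labelled record: T samples, 2 channels, two label segments.
tiny_record <- function(T_len = 100L, rate = 20) {
  set.seed(7)
  vals <- cbind(a = rnorm(T_len), b = rnorm(T_len))
  labels <- c(rep(0L, T_len %/% 2), rep(1L, T_len - T_len %/% 2))
  multichannel_record(vals, rate = rate, labels = labels,
                      class_names = c("walk", "jog"), subject = "s1")
}

# A small but learnable window set (subset of the canonical benchmark).
small_benchmark <- function(windows_per_class = 20L) {
  default_benchmark(windows_per_class = windows_per_class)
}

# Tiny model config for fast structural tests.
tiny_model_config <- function(...) {
  model_config(image_size = c(8L, 8L), input_channels = 2L, n_classes = 3L,
               conv_filters = c(2L, 3L), pool_stride = 2L, ...)
}

# Direct (slow) Shannon entropy used as an independent recount.
entropy_oracle <- function(mat) {
  mag <- abs(mat)
  d <- mag / sum(mag)
  d <- d[d > 0]
  -sum(d * log(d))
}

# Direct translation of the CWT sum, written independently of the package's
# direct method (plain double loop).
cwt_oracle <- function(signal, scales, sigma, dt) {
  n <- length(signal)
  csig <- (1 + exp(-sigma^2) - 2 * exp(-0.75 * sigma^2))^(-0.5)
  psi <- function(t) csig * pi^(-0.25) * exp(-t^2 / 2) *
    (exp(1i * sigma * t) - exp(-sigma^2 / 2))
  out <- matrix(0i, length(scales), n)
  for (ai in seq_along(scales)) {
    a <- scales[ai]
    for (b in 0:(n - 1)) {
      acc <- 0i
      for (k in 0:(n - 1)) {
        acc <- acc + signal[k + 1] * Conj(psi((k - b) / a))
      }
      out[ai, b + 1] <- abs(a)^(-0.5) * acc * dt
    }
  }
  out
}
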