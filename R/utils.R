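#' @importFrom stats fft rnorm runif sd var setNames
#' @importFrom utils head tail
NULL

# Internal input checkers. `what` names the offending argument in the error.
assert_scalar_num <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", what), call. = FALSE)
  }
  invisible(x)
}

assert_prob_fraction <- function(x, what) {
  assert_scalar_num(x, what)
  if (x < 0 || x >= 1) stop(sprintf("`%s` must lie in [0, 1)", what), call. = FALSE)
  invisible(x)
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive per-stage random seeds from one global seed
#'
#' One experiment seed fans out deterministically to the independent sources of
#' randomness in a run (data split, wavelet-selection subsample, weight
#' initialisation, minibatch shuffling) so that a single integer reproduces an
#' entire experiment while the stages stay decoupled.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`, a deterministic function of
#'   `seed` and `stage`.
#' @export
#' @examples
#' stage_seed(42, "split")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # Small string hash; keeps everything well inside 32-bit integer range.
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97 + 12345) %% .Machine$integer.max)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
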