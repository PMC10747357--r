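# Automatic selection of the Morlet shape factor (minimum Shannon entropy of
# the coefficient magnitudes, i.e. maximum sparsity) and of the scale count
# (maximum SVD periodicity ratio). Scale-count candidates are counts: a
# candidate `a` means the transform uses integer scales 1..a.

#' Candidate grids for wavelet parameter selection
#'
#' @param sigma_candidates Strictly increasing positive shape factors.
#' @param scale_count_candidates Strictly increasing positive integers; each
#'   candidate `a` denotes the scale range `1..a`. Defaults to the 32/64/128
#'   sweep used throughout the package.
#' @return A `scale_grid` object.
#' @export
scale_grid <- function(sigma_candidates = c(2, 6, 10),
                       scale_count_candidates = c(32L, 64L, 128L)) {
  sigma_candidates <- as.numeric(sigma_candidates)
  scale_count_candidates <- as.integer(scale_count_candidates)
  if (length(sigma_candidates) == 0L || any(sigma_candidates <= 0) ||
      is.unsorted(sigma_candidates, strictly = TRUE)) {
    stop("`sigma_candidates` must be non-empty, positive, strictly increasing",
         call. = FALSE)
  }
  if (length(scale_count_candidates) == 0L || any(scale_count_candidates <= 0) ||
      is.unsorted(scale_count_candidates, strictly = TRUE)) {
    stop("`scale_count_candidates` must be non-empty, positive, strictly increasing",
         call. = FALSE)
  }
  structure(
    list(sigma_candidates = sigma_candidates,
         scale_count_candidates = scale_count_candidates),
    class = "scale_grid"
  )
}

#' Shannon entropy of wavelet coefficient magnitudes
#'
#' Normalizes the coefficient magnitudes to a discrete distribution
#' \eqn{d_{ij} = |c_{ij}| / \sum |c_{ij}|} over all entries and returns
#' \eqn{H = -\sum d_{ij} \log d_{ij}} (natural log, with
#' \eqn{0 \log 0 := 0}). Lies in `[0, log(m * n)]`; small when the energy is
#' concentrated in few coefficients (a sparse, well-matched wavelet).
#'
#' @param s A `scalogram`, or a numeric/complex matrix of coefficients.
#' @return A single number.
#' @export
shannon_entropy <- function(s) {
  mat <- if (inherits(s, "scalogram")) s$coeffs else s
  if (!is.matrix(mat)) stop("`s` must be a scalogram or a matrix", call. = FALSE)
  mag <- abs(mat)
  total <- sum(mag)
  if (total == 0) stop("entropy undefined for an all-zero coefficient matrix",
                       call. = FALSE)
  d <- mag / total
  d <- d[d > 0]
  -sum(d * log(d))
}

#' SVD periodicity ratio of a scalogram
#'
#' Computes the singular values \eqn{\alpha_1 \ge \alpha_2 \ge \dots} of the
#' coefficient magnitude matrix and returns
#' \eqn{\delta = (\alpha_1 / \max(\alpha_2, \epsilon))^2} with
#' \eqn{\epsilon = 10^{-12}} guarding rank-1 matrices. A strongly periodic
#' signal yields a near-rank-1 scalogram and hence a large ratio.
#'
#' @param s A `scalogram` or a matrix.
#' @return A single number >= 1 (up to floating-point round-off).
#' @export
periodicity_ratio <- function(s) {
  mat <- if (inherits(s, "scalogram")) s$coeffs else s
  if (!is.matrix(mat)) stop("`s` must be a scalogram or a matrix", call. = FALSE)
  if (min(dim(mat)) < 2L) {
    stop("periodicity ratio needs a matrix with at least 2 rows and columns",
         call. = FALSE)
  }
  sv <- svd(abs(mat), nu = 0, nv = 0)$d
  (sv[1] / max(sv[2], 1e-12))^2
}

#' Select the Morlet shape factor by minimum entropy
#'
#' For each candidate shape factor, transforms the signal over integer scales
#' `1..max(scale_count_candidates)` and records the Shannon entropy of the
#' coefficients; returns the candidate attaining the minimum (ties broken
#' towards the smaller shape factor).
#'
#' @param signal Numeric vector.
#' @param grid A [scale_grid()] with at least 2 shape-factor candidates.
#' @param dt Sampling interval (seconds).
#' @return List with `sigma_star` and `entropies`, a tibble
#'   (`sigma`, `entropy`).
#' @export
select_shape_factor <- function(signal, grid, dt) {
  stopifnot(inherits(grid, "scale_grid"))
  if (length(grid$sigma_candidates) < 2L) {
    stop("need at least 2 shape-factor candidates", call. = FALSE)
  }
  a_max <- max(grid$scale_count_candidates)
  ent <- vapply(grid$sigma_candidates, function(sg) {
    shannon_entropy(cwt_transform(signal, seq_len(a_max), sg, dt))
  }, numeric(1))
  best <- which.min(ent) # which.min already takes the first (smallest sigma) tie
  list(
    sigma_star = grid$sigma_candidates[best],
    entropies = tibble::tibble(sigma = grid$sigma_candidates, entropy = ent)
  )
}

#' Select the scale count by maximum periodicity ratio
#'
#' For each candidate count `a`, transforms the signal over integer scales
#' `1..a` with the given shape factor and records the periodicity ratio;
#' returns the candidate attaining the maximum (ties broken towards the
#' smaller count).
#'
#' @param signal Numeric vector.
#' @param sigma Shape factor to use (typically the entropy-selected one).
#' @param grid A [scale_grid()] with at least 2 scale-count candidates.
#' @param dt Sampling interval (seconds).
#' @return List with `scale_count_star` and `periodicities`, a tibble
#'   (`scale_count`, `delta`).
#' @export
select_scale_count <- function(signal, sigma, grid, dt) {
  stopifnot(inherits(grid, "scale_grid"))
  if (length(grid$scale_count_candidates) < 2L) {
    stop("need at least 2 scale-count candidates", call. = FALSE)
  }
  delta <- vapply(grid$scale_count_candidates, function(a) {
    periodicity_ratio(cwt_transform(signal, seq_len(a), sigma, dt))
  }, numeric(1))
  best <- which.max(delta) # first maximum = smaller count on ties
  list(
    scale_count_star = grid$scale_count_candidates[best],
    periodicities = tibble::tibble(
      scale_count = grid$scale_count_candidates, delta = delta
    )
  )
}

#' Jointly select shape factor and scale count for one signal
#'
#' Runs the two selection stages in sequence: entropy-minimizing shape factor
#' first, then periodicity-maximizing scale count with the shape factor held
#' fixed at its selected value.
#'
#' @param signal Numeric vector.
#' @param grid A [scale_grid()].
#' @param dt Sampling interval (seconds).
#' @return A `selection_result`: `sigma_star`, `scale_count_star`, and both
#'   evidence tables.
#' @export
#' @examples
#' x <- sin(2 * pi * 3 * seq(0, 2.54, by = 0.02))
#' optimal_wavelet_params(x, scale_grid(c(2, 6, 10), c(16L, 32L)), dt = 0.02)
optimal_wavelet_params <- function(signal, grid, dt) {
  stopifnot(inherits(grid, "scale_grid"))
  if (length(grid$sigma_candidates) >= 2L) {
    p1 <- select_shape_factor(signal, grid, dt)
  } else {
    a_max <- max(grid$scale_count_candidates)
    h <- shannon_entropy(cwt_transform(signal, seq_len(a_max),
                                       grid$sigma_candidates, dt))
    p1 <- list(sigma_star = grid$sigma_candidates,
               entropies = tibble::tibble(sigma = grid$sigma_candidates,
                                          entropy = h))
  }
  if (length(grid$scale_count_candidates) >= 2L) {
    p2 <- select_scale_count(signal, p1$sigma_star, grid, dt)
  } else {
    a <- grid$scale_count_candidates
    d <- periodicity_ratio(cwt_transform(signal, seq_len(a), p1$sigma_star, dt))
    p2 <- list(scale_count_star = a,
               periodicities = tibble::tibble(scale_count = a, delta = d))
  }
  structure(
    list(sigma_star = p1$sigma_star,
         scale_count_star = p2$scale_count_star,
         entropies = p1$entropies,
         periodicities = p2$periodicities),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> sigma* = %g, scale count* = %d\n",
              x$sigma_star, x$scale_count_star))
  cat("entropy evidence:\n")
  print(x$entropies)
  cat("periodicity evidence:\n")
  print(x$periodicities)
  invisible(x)
}

#' Select wavelet parameters for a window set by majority vote
#'
#' Runs [optimal_wavelet_params()] on every channel of a seeded subsample of
#' windows (intended to be training windows only, so the selection never sees
#' test data) and aggregates the per-channel, per-window selections by
#' majority vote, ties going to the smaller value. The returned evidence
#' tables are the means of the per-signal tables.
#'
#' @param ws A `window_set`.
#' @param grid A [scale_grid()].
#' @param sample_size Maximum number of windows examined (default 64).
#' @param seed Seed for the subsample draw.
#' @return A `selection_result` with an extra `votes` tibble.
#' @export
select_for_window_set <- function(ws, grid, sample_size = 64L, seed = 1L) {
  stopifnot(inherits(ws, "window_set"), inherits(grid, "scale_grid"))
  n <- length(ws$windows)
  take <- if (n <= sample_size) seq_len(n) else {
    with_seed(seed, sample.int(n, sample_size))
  }
  dt <- 1 / ws$rate
  picks_sigma <- c()
  picks_count <- c()
  ent_tabs <- list()
  per_tabs <- list()
  for (i in take) {
    vals <- ws$windows[[i]]$values
    for (ch in seq_len(nrow(vals))) {
      sel <- optimal_wavelet_params(as.numeric(vals[ch, ]), grid, dt)
      picks_sigma <- c(picks_sigma, sel$sigma_star)
      picks_count <- c(picks_count, sel$scale_count_star)
      ent_tabs[[length(ent_tabs) + 1L]] <- sel$entropies
      per_tabs[[length(per_tabs) + 1L]] <- sel$periodicities
    }
  }
  majority <- function(x) {
    tab <- table(x)
    winners <- as.numeric(names(tab)[tab == max(tab)])
    min(winners) # tie -> smaller value
  }
  ent_mean <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(ent_tabs), .data$sigma),
    entropy = mean(.data$entropy), .groups = "drop"
  )
  per_mean <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(per_tabs), .data$scale_count),
    delta = mean(.data$delta), .groups = "drop"
  )
  structure(
    list(
      sigma_star = majority(picks_sigma),
      scale_count_star = as.integer(majority(picks_count)),
      entropies = ent_mean,
      periodicities = per_mean,
      votes = tibble::tibble(sigma = picks_sigma, scale_count = picks_count)
    ),
    class = "selection_result"
  )
}
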