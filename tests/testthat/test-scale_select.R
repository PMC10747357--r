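test_that("entropy matches hand-computed values and bounds", {
  # single nonzero entry -> degenerate distribution
  m <- matrix(0, 3, 3); m[2, 2] <- 5
  expect_equal(shannon_entropy(m), 0)

  # uniform magnitudes -> log(mn)
  expect_equal(shannon_entropy(matrix(1, 2, 2)), log(4), tolerance = 1e-12)

  # magnitudes (3, 1): frozen hand summation
  expect_equal(shannon_entropy(matrix(c(3, 1), 1, 2)), 0.562335144618808,
               tolerance = 1e-12)

  expect_error(shannon_entropy(matrix(0, 2, 2)), "all-zero")
})

test_that("entropy bounds hold on random matrices", {
  set.seed(31)
  for (i in 1:200) {
    nr <- sample(4:40, 1)
    nc <- sample(4:40, 1)
    m <- matrix(rnorm(nr * nc), nrow = nr)
    h <- shannon_entropy(m)
    expect_gte(h, 0)
    expect_lte(h, log(length(m)) + 1e-12)
  }
})

test_that("periodicity ratio follows the singular-value definition", {
  expect_equal(periodicity_ratio(diag(c(4, 2))), 4)
  expect_equal(periodicity_ratio(diag(2)), 1)

  # rank-1 matrix trips the epsilon guard
  set.seed(32)
  r1 <- outer(runif(5, 1, 2), runif(7, 1, 2))
  expect_gt(periodicity_ratio(r1), 1e20)

  # invariant to positive scaling
  m <- matrix(abs(rnorm(30)), 5, 6)
  expect_equal(periodicity_ratio(m), periodicity_ratio(7.3 * m),
               tolerance = 1e-9)

  expect_error(periodicity_ratio(matrix(1, 1, 5)), "at least 2")
})

test_that("shape-factor selection attains the minimum of its evidence table", {
  set.seed(33)
  grid <- scale_grid(c(2, 6, 10), c(16L, 32L))
  for (i in 1:5) {
    x <- rnorm(64)
    sel <- select_shape_factor(x, grid, 0.02)
    # independent recount: direct-method CWT + helper entropy
    h <- vapply(grid$sigma_candidates, function(sg) {
      entropy_oracle(cwt_transform(x, 1:32, sg, 0.02, method = "direct")$coeffs)
    }, numeric(1))
    expect_equal(sel$sigma_star, grid$sigma_candidates[which.min(h)])
    expect_equal(sel$entropies$entropy, h, tolerance = 1e-9)
  }
})

test_that("a matched shape factor yields sparser coefficients for a pure tone", {
  tvec <- seq(0, 2.54, by = 0.02)
  x <- cos(2 * pi * 3 * tvec)
  sel <- select_shape_factor(x, scale_grid(c(2, 6, 10), c(64L, 128L)), 0.02)
  h <- sel$entropies$entropy
  expect_equal(min(h), h[sel$entropies$sigma == sel$sigma_star])
  expect_true(all(h[sel$entropies$sigma != sel$sigma_star] > min(h)))
})

test_that("scale-count selection attains the maximum periodicity", {
  set.seed(34)
  grid <- scale_grid(c(2, 6), c(8L, 16L, 32L))
  for (i in 1:5) {
    x <- rnorm(64)
    sel <- select_scale_count(x, 6, grid, 0.02)
    d <- vapply(grid$scale_count_candidates, function(a) {
      sv <- svd(abs(cwt_transform(x, 1:a, 6, 0.02, method = "direct")$coeffs),
                nu = 0, nv = 0)$d
      (sv[1] / max(sv[2], 1e-12))^2
    }, numeric(1))
    expect_equal(sel$scale_count_star,
                 grid$scale_count_candidates[which.max(d)])
    expect_equal(sel$periodicities$delta, d, tolerance = 1e-6)
  }
})

test_that("joint selection is deterministic and consistent with its tables", {
  tvec <- seq(0, 2.54, by = 0.02)
  x <- sin(2 * pi * 2 * tvec) + 0.1 * sin(2 * pi * 7 * tvec)
  grid <- scale_grid(c(2, 6, 10), c(16L, 32L, 64L))
  r1 <- optimal_wavelet_params(x, grid, 0.02)
  r2 <- optimal_wavelet_params(x, grid, 0.02)
  expect_identical(r1, r2)
  expect_equal(r1$sigma_star,
               r1$entropies$sigma[which.min(r1$entropies$entropy)])
  expect_equal(r1$scale_count_star,
               r1$periodicities$scale_count[which.max(r1$periodicities$delta)])
})

test_that("periodic signals earn larger periodicity ratios than noise", {
  grid <- scale_grid(c(6, 10), c(16L, 32L))
  tvec <- seq(0, 1.27, by = 0.01)
  d_per <- numeric(20); d_noise <- numeric(20)
  set.seed(35)
  for (i in 1:20) {
    per <- sin(2 * pi * 4 * tvec + runif(1, 0, 2 * pi))
    noi <- rnorm(length(tvec))
    d_per[i] <- max(optimal_wavelet_params(per, grid, 0.01)$periodicities$delta)
    d_noise[i] <- max(optimal_wavelet_params(noi, grid, 0.01)$periodicities$delta)
  }
  expect_gt(mean(d_per), mean(d_noise))
})

test_that("window-set selection votes over channels and is leak-free by design", {
  ws <- small_benchmark(5L)
  grid <- scale_grid(c(2, 6), c(16L, 32L))
  sel <- select_for_window_set(ws, grid, sample_size = 4L, seed = 9)
  expect_s3_class(sel, "selection_result")
  expect_true(sel$sigma_star %in% grid$sigma_candidates)
  expect_true(sel$scale_count_star %in% grid$scale_count_candidates)
  # votes: sampled windows x channels
  expect_equal(nrow(sel$votes), 4L * 3L)
  # majority of the recorded votes is returned
  tab <- table(sel$votes$scale_count)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  expect_equal(sel$scale_count_star, as.integer(min(winners)))
  # deterministic
  sel2 <- select_for_window_set(ws, grid, sample_size = 4L, seed = 9)
  expect_equal(sel$sigma_star, sel2$sigma_star)
  expect_equal(sel$scale_count_star, sel2$scale_count_star)
})

test_that("degenerate grids and inputs propagate errors", {
  grid1 <- scale_grid(4, 16L)
  x <- sin(seq(0, 10, length.out = 64))
  r <- optimal_wavelet_params(x, grid1, 0.02)
  expect_equal(r$sigma_star, 4)
  expect_equal(r$scale_count_star, 16L)
  expect_equal(nrow(r$entropies), 1L)

  expect_error(select_shape_factor(rep(0, 64), scale_grid(c(2, 6), 16L), 0.02),
               "all-zero")
  expect_error(scale_grid(c(3, 2), 16L), "increasing")
})
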