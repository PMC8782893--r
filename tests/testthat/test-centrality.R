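# builds a 2x2x2 grid volume whose first `length(series)` voxels hold the
# given time series, with a mask covering exactly those voxels
volume_from_series <- function(series) {
  T <- length(series[[1]])
  arr <- array(0, dim = c(2, 2, 2, T))
  flat <- matrix(arr, nrow = 8)
  for (i in seq_along(series)) flat[i, ] <- series[[i]]
  msk <- array(FALSE, c(2, 2, 2))
  msk[seq_along(series)] <- TRUE
  list(vol = time_series_volume(array(flat, dim = c(2, 2, 2, T))),
       mask = brain_mask(msk))
}

test_that("time-series standardization matches hand arithmetic and drops constants", {
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  fx <- volume_from_series(list(x, rep(5, 9), rnorm(9)))
  out <- zscore_series(fx$vol, fx$mask)
  expect_equal(length(out$dropped), 1L)
  expect_equal(out$mask$n_voxels, 2L)
  z1 <- out$volume$data[1, 1, 1, ]
  # hand arithmetic: centered copy of (1,2,3) scaled by its n-1 sd
  expect_equal(z1, (x - 2) / sqrt(6 / 8), tolerance = 1e-12)

  fy <- tiny_volume(grid = c(5, 2, 1), T = 17, seed = 4)
  zo <- zscore_series(fy$vol, fy$mask)
  Z <- matrix(zo$volume$data, nrow = 10)
  expect_true(all(abs(rowMeans(Z)) < 1e-12))
  expect_true(all(abs(apply(Z, 1, var) - 1) < 1e-12))

  fz <- volume_from_series(list(rep(1, 10), rep(2, 10), rnorm(10), rnorm(10)))
  expect_error(zscore_series(volume_from_series(list(rep(1, 10), rep(2, 10)))$vol,
                             volume_from_series(list(rep(1, 10), rep(2, 10)))$mask),
               "empty")
  expect_silent(ignore <- zscore_series(fz$vol, fz$mask))
})

test_that("matrix-free rectified products equal the dense elementwise oracle", {
  # perfect correlation: M = [[1,1],[1,1]]
  x <- as.numeric(scale(rnorm(20)))
  Z2 <- rbind(x, x)
  expect_equal(rectified_matvec(Z2, c(1, 1)), c(2, 2), tolerance = 1e-10)
  expect_equal(rectified_matvec(Z2, c(0, 0)), c(0, 0))
  expect_error(rectified_matvec(Z2, c(1, 1, 1)), "mismatch")

  set.seed(8)
  Z <- zscore_rows_oracle(matrix(rnorm(40 * 30), 40, 30))
  M <- dense_rectified_oracle(Z)
  v <- rnorm(40)
  expect_equal(rectified_matvec(Z, v), as.numeric(M %*% v), tolerance = 1e-10)
  expect_equal(rectified_correlation_matrix(Z), M, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(M >= -1e-12))
  expect_equal(diag(M), rep(1, 40), tolerance = 1e-10)
})

test_that("power iteration handles symmetric and degenerate two-voxel cases", {
  x <- rnorm(25)
  same <- volume_from_series(list(x, x))
  m <- fast_ecm(same$vol, same$mask)
  expect_equal(m$values, c(1, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(m$eigenvalue, 2, tolerance = 1e-9)
  expect_true(m$converged)

  anti <- volume_from_series(list(x, -x))
  ma <- fast_ecm(anti$vol, anti$mask)
  # rectification zeroes the off-diagonal: identity matrix, uniform start is
  # the documented fixed point
  expect_equal(ma$values, c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(ma$eigenvalue, 1, tolerance = 1e-12)
  expect_equal(ma$n_iterations, 1L)
})

test_that("fast and dense centrality agree, with eigenvalue and Perron positivity", {
  for (s in 1:10) {
    fx <- tiny_volume(grid = c(4, 4, 4), T = 50, seed = 100 + s)
    mf <- fast_ecm(fx$vol, fx$mask, tol = 1e-12)
    md <- brute_force_ecm(fx$vol, fx$mask)
    expect_gt(sum(mf$values * md$values), 1 - 1e-8)
    expect_lt(abs(mf$eigenvalue - md$eigenvalue), 1e-6)
    expect_true(all(mf$values > 0))   # strictly positive rectified matrix
  }
  expect_error(brute_force_ecm(tiny_volume()$vol, tiny_volume()$mask, cap = 10), "cap")
})

test_that("centrality is invariant to positive rescaling of the series", {
  fx <- tiny_volume(grid = c(3, 3, 3), T = 40, seed = 6)
  m1 <- fast_ecm(fx$vol, fx$mask, tol = 1e-12)
  scaled <- time_series_volume(fx$vol$data * 3.7, fx$vol$voxel_size_mm)
  m2 <- fast_ecm(scaled, fx$mask, tol = 1e-12)
  expect_equal(m1$values, m2$values, tolerance = 1e-10)
})

test_that("a strongly connected middle voxel has the largest centrality", {
  set.seed(12)
  T <- 600
  s1 <- rnorm(T); s3 <- rnorm(T)
  mid <- (s1 + s3) / sqrt(2)
  fx <- volume_from_series(list(s1, mid, s3))
  m <- brute_force_ecm(fx$vol, fx$mask)
  expect_gt(m$values[2], max(m$values[c(1, 3)]))
})

test_that("Gaussianization follows the Blom formula and preserves ranks", {
  msk <- brain_mask(array(c(rep(TRUE, 5), rep(FALSE, 3)), c(2, 2, 2)))
  vals <- c(0.1, 0.2, 0.4, 0.5, 0.7)
  raw <- centrality_map(vals / sqrt(sum(vals^2)), msk, stage = "raw")
  g <- gaussianize_map(raw)
  expect_equal(g$values, qnorm((1:5 - 3 / 8) / (5 + 1 / 4)), tolerance = 1e-12)
  expect_equal(g$values[3], 0)
  expect_equal(g$stage, "gaussianized")
  expect_error(gaussianize_map(g), "raw")

  # ties share the average rank
  tied <- c(0.3, 0.3, 0.5, 0.6, 0.7)
  gt <- gaussianize_map(centrality_map(tied / sqrt(sum(tied^2)), msk))
  expect_equal(gt$values[1], gt$values[2])
  expect_equal(gt$values[1], qnorm((1.5 - 3 / 8) / 5.25))

  # rank preservation on a larger random map
  set.seed(9)
  n <- 10000
  mk <- brain_mask(array(c(rep(TRUE, n), rep(FALSE, 22^3 - n)), c(22, 22, 22)))
  x <- abs(rnorm(n)); x <- x / sqrt(sum(x^2))
  gg <- gaussianize_map(centrality_map(x, mk))
  expect_identical(rank(gg$values), rank(x))
  expect_lt(abs(mean(gg$values)), 0.01)
  expect_lt(abs(sd(gg$values) - 1), 0.02)
  # rank idempotence: re-Gaussianizing a rank-preserving re-embedding of the
  # output leaves the ranks (hence the values) unchanged
  y <- gg$values - min(gg$values) + 0.1; y <- y / sqrt(sum(y^2))
  gg2 <- gaussianize_map(centrality_map(y, mk))
  expect_equal(gg2$values, gg$values, tolerance = 1e-12)
})

test_that("motion residualization matches the normal-equation solve", {
  msk <- brain_mask(array(TRUE, c(2, 2, 1)))
  mkmap <- function(v) {
    r <- gaussianize_map(centrality_map(abs(v) / sqrt(sum(v^2)), msk))
    r
  }
  # perfect linear fit: values (1,2,3) on motion (0,1,2) -> zero residuals
  maps <- lapply(c(1, 2, 3), function(k) {
    m <- mkmap(rnorm(4))
    m$values <- rep(k, 4); m
  })
  res <- residualize_motion(maps, c(0, 1, 2))
  expect_equal(unlist(lapply(res, `[[`, "values")), rep(0, 12), tolerance = 1e-12)
  expect_equal(res[[1]]$stage, "residualized")

  # constant motion: warning + mean-centering only
  expect_warning(resc <- residualize_motion(maps, c(1, 1, 1)), "zero variance")
  expect_equal(resc[[2]]$values, rep(0, 4), tolerance = 1e-12)

  # random instance vs hand-computed OLS residuals, and orthogonality
  set.seed(14)
  maps20 <- lapply(1:20, function(i) mkmap(rnorm(4)))
  motion <- runif(20, 0.05, 0.4)
  r20 <- residualize_motion(maps20, motion)
  Y <- do.call(rbind, lapply(maps20, `[[`, "values"))
  X <- cbind(1, motion)
  Rhat <- Y - X %*% solve(t(X) %*% X, t(X) %*% Y)
  R <- do.call(rbind, lapply(r20, `[[`, "values"))
  expect_equal(R, Rhat, tolerance = 1e-10, ignore_attr = TRUE)
  for (v in 1:4) expect_lt(abs(cor(R[, v], motion)), 1e-10)
})
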