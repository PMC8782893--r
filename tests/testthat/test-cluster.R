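test_that("Bonferroni adjustment is exact arithmetic", {
  expect_identical(bonferroni_alpha(0.05, 4), 0.0125)
  expect_identical(bonferroni_alpha(0.07, 1), 0.07)
  expect_identical(bonferroni_alpha(0.05, 5), 0.01)
  expect_error(bonferroni_alpha(0, 4), "alpha")
  expect_error(bonferroni_alpha(0.05, 0), "n_contrasts")
})

test_that("smoothness estimation recovers a known 6 mm kernel within 15%", {
  set.seed(19)
  mask <- brain_mask(array(TRUE, c(30, 30, 30)), voxel_size_mm = c(3, 3, 3))
  Y <- t(vapply(1:20, function(i)
    smooth_wrap_oracle(array(rnorm(27000), c(30, 30, 30)), fwhm_vox = 2)[mask$data],
    numeric(27000)))
  attr(Y, "mask") <- mask
  est <- estimate_smoothness(Y)
  expect_true(all(abs(est$fwhm_mm - 6) / 6 < 0.15))
  expect_true(est$resels > 0 && est$resels <= est$n_voxels)
})

test_that("wider kernels yield strictly larger smoothness estimates", {
  set.seed(20)
  mask <- brain_mask(array(TRUE, c(24, 24, 24)), voxel_size_mm = c(3, 3, 3))
  est_at <- function(fwhm_mm) {
    Y <- t(vapply(1:12, function(i)
      smooth_wrap_oracle(array(rnorm(24^3), c(24, 24, 24)), fwhm_vox = fwhm_mm / 3)[mask$data],
      numeric(24^3)))
    attr(Y, "mask") <- mask
    mean(estimate_smoothness(Y)$fwhm_mm)
  }
  ests <- vapply(c(2, 4, 8), est_at, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("voxel size enters the smoothness estimate as a pure unit", {
  set.seed(21)
  mask <- brain_mask(array(TRUE, c(14, 14, 14)), voxel_size_mm = c(3, 3, 3))
  Y <- t(vapply(1:10, function(i)
    smooth_wrap_oracle(array(rnorm(14^3), c(14, 14, 14)), 2)[mask$data], numeric(14^3)))
  attr(Y, "mask") <- mask
  e1 <- estimate_smoothness(Y)
  e2 <- estimate_smoothness(Y, voxel_size_mm = c(6, 6, 6))
  expect_equal(e2$fwhm_mm, 2 * e1$fwhm_mm, tolerance = 1e-12)
  expect_equal(e2$resels, e1$resels, tolerance = 1e-12)
})

test_that("cluster formation matches a union-find oracle on random patterns", {
  gs <- c(8, 8, 6)
  mask <- brain_mask(array(TRUE, gs), voxel_size_mm = c(2, 2, 2))
  u <- qnorm(0.999)
  # empty map -> no clusters
  expect_equal(nrow(form_clusters(array(0, gs), mask, 0.001, "positive")$table), 0)
  # single suprathreshold voxel
  z1 <- array(0, gs); z1[3, 4, 2] <- 4
  fc1 <- form_clusters(z1, mask, 0.001, "positive")
  expect_equal(fc1$table$extent, 1L)
  expect_equal(unlist(fc1$table[1, c("peak_x_mm", "peak_y_mm", "peak_z_mm")]),
               c(4, 6, 2), ignore_attr = TRUE)
  expect_equal(fc1$table$max_z, 4)
  # random binary patterns, all three neighbor rules
  for (s in 1:8) {
    set.seed(400 + s)
    z <- array(ifelse(runif(prod(gs)) < 0.12, 5, 0), gs)
    for (conn in c(6, 18, 26)) {
      fc <- form_clusters(z, mask, 0.001, "positive", connectivity = conn)
      expect_equal(sort(fc$table$extent), component_sizes_oracle(z >= u, conn),
                   info = sprintf("seed %d conn %d", s, conn))
    }
  }
  # negative direction picks up only negative excursions
  zn <- array(0, gs); zn[1, 1, 1] <- -5; zn[5, 5, 5] <- 5
  fcn <- form_clusters(zn, mask, 0.001, "negative")
  expect_equal(nrow(fcn$table), 1L)
  expect_equal(fcn$table$max_z, -5)
})

test_that("random-field cluster p-values are monotone with correct limits", {
  smo <- structure(list(fwhm_mm = c(6, 6, 6), fwhm_vox = c(2, 2, 2),
                        resels = 1000, n_voxels = 8000),
                   class = "smoothness_estimate")
  for (u in c(2.5, 3.09, 4)) {
    p <- vapply(c(1, 2, 5, 10, 50, 200), rft_cluster_p, numeric(1), u = u, smooth = smo)
    expect_true(all(diff(p) < 0))
  }
  for (k in c(1, 5, 20)) {
    p <- vapply(c(2.5, 3.09, 3.5, 4), rft_cluster_p, numeric(1), extent = k, smooth = smo)
    expect_true(all(diff(p) < 0))
  }
  expect_lt(rft_cluster_p(8000, 3.09, smo), 1e-6)
  expect_error(rft_cluster_p(0, 3.09, smo), "extent")
  expect_error(rft_cluster_p(5, 0.5, smo), "exceed 1")
  # two-sided accounting doubles the expected cluster count
  p1 <- rft_cluster_p(10, 3.09, smo)
  p2 <- rft_cluster_p(10, 3.09, smo, two_sided = TRUE)
  expect_gt(p2, p1)
  expect_lt(p2, 2 * p1 + 1e-12)
})

test_that("predicted extent exceedance matches null-field simulation at upper percentiles", {
  # 300 null Gaussian fields of known FWHM; the leading-term Euler
  # characteristic overpredicts the count of 1-voxel clusters at this
  # smoothness, but the suprathreshold extent tail (what FWE control uses)
  # must be accurate at the upper percentiles
  mask <- brain_mask(array(TRUE, c(20, 20, 20)), voxel_size_mm = c(3, 3, 3))
  nf <- 300
  u <- qnorm(0.999)
  Y <- simulate_smooth_maps(nf, mask, 2, seed = 77)
  sizes <- integer(0)
  for (i in seq_len(nf)) {
    z <- array(0, c(20, 20, 20))
    z[mask$data] <- (Y[i, ] - mean(Y[i, ])) / sd(Y[i, ])
    sizes <- c(sizes, form_clusters(z, mask, 0.001, "positive")$table$extent)
  }
  smo <- structure(list(fwhm_mm = c(6, 6, 6), fwhm_vox = c(2, 2, 2),
                        resels = 1000, n_voxels = 8000),
                   class = "smoothness_estimate")
  Em <- smo$resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (u^2 - 1) * exp(-u^2 / 2)
  En <- smo$n_voxels * pnorm(u, lower.tail = FALSE) / Em
  beta <- (gamma(2.5) / En)^(2 / 3)
  for (k in unique(ceiling(quantile(sizes, c(0.90, 0.95))))) {
    emp <- sum(sizes >= k) / nf
    pred <- Em * exp(-beta * k^(2 / 3))
    expect_gt(emp / pred, 0.6)
    expect_lt(emp / pred, 1.67)
  }
})

test_that("cluster p-values are recomputable from their records", {
  mask <- brain_mask(array(TRUE, c(10, 10, 10)), voxel_size_mm = c(3, 3, 3))
  set.seed(55)
  z <- array(0, c(10, 10, 10))
  z[2:4, 2:4, 2:4] <- 4.2
  z[8, 8, 8] <- -4.5
  smo <- structure(list(fwhm_mm = c(5, 5, 5), fwhm_vox = c(5, 5, 5) / 3,
                        resels = 1000 / prod((c(5, 5, 5) / 3)), n_voxels = 1000),
                   class = "smoothness_estimate")
  ci <- cluster_inference(z, mask, smo, n_contrasts = 4)
  expect_equal(nrow(ci$table), 2)
  expect_setequal(ci$table$sign, c("positive", "negative"))
  for (i in seq_len(nrow(ci$table)))
    expect_equal(ci$table$p_fwe[i],
                 rft_cluster_p(ci$table$extent[i], ci$forming_u, smo, two_sided = TRUE),
                 tolerance = 1e-12)
  expect_equal(ci$alpha_corrected, 0.0125)
})

test_that("cluster means equal hand-computed averages", {
  mask <- brain_mask(array(TRUE, c(3, 3, 3)))
  Y <- matrix(3, 4, 27); attr(Y, "mask") <- mask
  expect_equal(extract_cluster_mean(Y, c(1, 5, 9)), rep(3, 4))
  set.seed(60)
  Y2 <- matrix(rnorm(4 * 27), 4, 27); attr(Y2, "mask") <- mask
  vox <- sample(27, 10)
  expect_equal(extract_cluster_mean(Y2, vox),
               apply(Y2[, vox], 1, function(r) sum(r) / 10), tolerance = 1e-12)
  expect_equal(extract_cluster_mean(Y2, 7), Y2[, 7])
  expect_error(extract_cluster_mean(Y2, integer(0)), "empty")
})
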