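# Shared fixtures and independent reference implementations ("oracles").
# Everything here is deliberately written by a different route than the
# package code it checks.

# small random volume + full mask
tiny_volume <- function(grid = c(4, 4, 3), T = 30, seed = 1, voxel = c(3, 3, 3)) {
  set.seed(seed)
  vol <- time_series_volume(array(rnorm(prod(grid) * T), dim = c(grid, T)),
                            voxel_size_mm = voxel)
  list(vol = vol, mask = brain_mask(array(TRUE, grid), voxel_size_mm = voxel))
}

# dense rectified correlation matrix by direct elementwise loops (oracle for
# rectified_matvec / rectified_correlation_matrix)
dense_rectified_oracle <- function(Z) {
  n <- nrow(Z); T <- ncol(Z)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      xi <- Z[i, ]; xj <- Z[j, ]
      M[i, j] <- (sum(pmax(xi, 0) * pmax(xj, 0)) + sum(pmax(-xi, 0) * pmax(-xj, 0))) / (T - 1)
      M[j, i] <- M[i, j]
    }
  }
  M
}

# z-score rows the pedestrian way
zscore_rows_oracle <- function(Z) {
  t(apply(Z, 1, function(x) (x - mean(x)) / sd(x)))
}

# union-find connected-components labeller (oracle for label_components /
# form_clusters); returns sorted multiset of component sizes
component_sizes_oracle <- function(supra, connectivity) {
  gs <- dim(supra)
  idx <- which(supra)
  if (!length(idx)) return(integer(0))
  id <- seq_along(idx)
  pos <- arrayInd(idx, gs)
  key <- setNames(seq_along(idx), paste(pos[, 1], pos[, 2], pos[, 3]))
  find <- function(i) { while (id[i] != i) { id[i] <<- id[id[i]]; i <- id[i] }; i }
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(offs != 0) > 0, ]
  keepo <- switch(as.character(connectivity),
                  "6" = rowSums(abs(offs)) == 1,
                  "18" = rowSums(abs(offs)) <= 2,
                  "26" = rep(TRUE, nrow(offs)))
  offs <- offs[keepo, ]
  for (a in seq_along(idx)) {
    for (o in seq_len(nrow(offs))) {
      nb <- pos[a, ] + as.numeric(offs[o, ])
      b <- key[paste(nb[1], nb[2], nb[3])]
      if (!is.na(b)) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) id[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  sort(as.integer(table(roots)))
}

# exhaustive two-sided signed-rank p-value over all 2^n sign assignments
signed_rank_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Vs <- signs %*% r
  p_le <- mean(Vs <= V + 1e-9)
  p_ge <- mean(Vs >= V - 1e-9)
  list(V = V, p = min(1, 2 * min(p_le, p_ge)))
}

# separable wrap-around Gaussian smoothing by explicit shift-and-add
# (independent of the package's circulant-matrix implementation)
smooth_wrap_oracle <- function(arr, fwhm_vox) {
  sigma <- fwhm_vox / sqrt(8 * log(2))
  gs <- dim(arr)
  for (ax in 1:3) {
    half <- floor(gs[ax] / 2)
    offs <- -half:(gs[ax] - half - 1)
    w <- exp(-offs^2 / (2 * sigma^2)); w <- w / sum(w)
    out <- array(0, gs)
    for (k in seq_along(offs)) {
      sh <- ((seq_len(gs[ax]) - 1 + offs[k]) %% gs[ax]) + 1
      out <- out + w[k] * switch(ax, arr[sh, , , drop = FALSE],
                                 arr[, sh, , drop = FALSE],
                                 arr[, , sh, drop = FALSE])
    }
    arr <- out
  }
  arr
}

# standardized-covariate null cohort for voxelwise runs
null_cohort <- function(n, seed) {
  generate_cohort(cohort_params(n_subjects = n, seed = seed), network = NULL)$cohort
}
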