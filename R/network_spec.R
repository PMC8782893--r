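#' Latent-network specification for synthetic volumes
#'
#' Describes the generative connectivity structure of synthetic resting-state
#' volumes: each voxel's time series is a nonnegative loading-weighted mixture
#' of a small number of latent temporal signals plus i.i.d. noise. The implied
#' voxel-by-voxel correlation matrix (and hence the true eigenvector
#' centrality map) is known analytically, which makes the generator usable as
#' a ground-truth oracle for the centrality estimator.
#'
#' @param loading_map list of 3D arrays (one per latent signal) of nonnegative
#'   spatial loadings, all on the same grid.
#' @param noise_sd standard deviation of the i.i.d. voxel noise (>= 0).
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param target_region integer vector of in-grid voxel indices (column-major)
#'   forming the region whose centrality drives the planted cross-lag effect.
#'   Defaults to the voxels where the first latent signal loads at more than
#'   half its maximum.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(loading_map, noise_sd = 0.5, voxel_size_mm = c(3, 3, 3),
                         target_region = NULL) {
  if (!is.list(loading_map) || !length(loading_map))
    stopf("loading_map must be a non-empty list of 3D arrays")
  gs <- dim(loading_map[[1]])
  if (length(gs) != 3L || any(gs < 2L)) stopf("grid_shape entries must be >= 2")
  for (j in seq_along(loading_map)) {
    L <- loading_map[[j]]
    if (!all(dim(L) == gs)) stopf("loading map %d is not on the shared grid", j)
    if (any(!is.finite(L)) || any(L < 0)) stopf("loadings must be finite and nonnegative")
    if (!any(L > 0)) stopf("latent signal %d has no voxel with a positive loading", j)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || !is.finite(noise_sd) || noise_sd < 0)
    stopf("noise_sd must be a nonnegative scalar")
  if (is.null(target_region)) {
    L1 <- loading_map[[1]]
    target_region <- which(L1 > max(L1) / 2)
  }
  target_region <- as.integer(target_region)
  if (any(target_region < 1L) || any(target_region > prod(gs)))
    stopf("target_region indices out of grid range")
  structure(list(n_latent = length(loading_map), loading_map = loading_map,
                 noise_sd = noise_sd, grid_shape = as.integer(gs),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 target_region = target_region),
            class = "network_spec")
}

#' Default latent-network specification
#'
#' Three smooth Gaussian "blob" networks on a small grid, placed at fixed
#' locations so the specification is fully deterministic. The first blob is
#' the target region carrying the planted cross-lag effect.
#'
#' @param grid_shape 3 voxel counts (default `c(6, 6, 6)`).
#' @param n_latent number of latent signals (default 3, placed at preset
#'   relative positions; at most 5).
#' @param noise_sd i.i.d. noise standard deviation (default 0.5).
#' @param voxel_size_mm voxel size (default 3 mm isotropic).
#' @param blob_radius_vox Gaussian radius of each loading blob, in voxels.
#' @return a [network_spec].
#' @export
default_network_spec <- function(grid_shape = c(6, 6, 6), n_latent = 3,
                                 noise_sd = 0.5, voxel_size_mm = c(3, 3, 3),
                                 blob_radius_vox = 1.4) {
  if (n_latent < 1 || n_latent > 5) stopf("n_latent must be between 1 and 5")
  centers_rel <- list(c(0.3, 0.3, 0.35), c(0.72, 0.65, 0.6), c(0.35, 0.75, 0.75),
                      c(0.75, 0.3, 0.7), c(0.5, 0.5, 0.3))
  gs <- as.integer(grid_shape)
  co <- as.matrix(expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]), z = seq_len(gs[3])))
  loadings <- lapply(seq_len(n_latent), function(j) {
    ctr <- 1 + centers_rel[[j]] * (gs - 1)
    d2 <- colSums((t(co) - ctr)^2)
    array(exp(-d2 / (2 * blob_radius_vox^2)), dim = gs)
  })
  network_spec(loadings, noise_sd = noise_sd, voxel_size_mm = voxel_size_mm)
}

#' Expected rectified similarity of two standardized Gaussian series
#'
#' For jointly Gaussian, zero-mean, unit-variance series with correlation
#' `r`, the population value of the rectified inner-product similarity
#' (positive parts with positive parts plus negative parts with negative
#' parts) is `(sqrt(1 - r^2) + r * (pi - acos(r))) / pi`. It equals 1 at
#' `r = 1`, `1/pi` at `r = 0`, and 0 at `r = -1`, and is the population
#' counterpart of the matrix entries used by [fast_ecm()].
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return numeric vector of rectified similarities in `[0, 1]`.
#' @export
rectified_similarity <- function(r) {
  r <- pmin(pmax(r, -1), 1)
  (sqrt(pmax(0, 1 - r^2)) + r * (pi - acos(r))) / pi
}

# analytic voxel-by-voxel Pearson correlation implied by a network_spec,
# for a subject whose latent-signal amplitudes are `coupling` (default all 1)
latent_correlation <- function(spec, coupling = NULL) {
  coupling <- coupling %||% rep(1, spec$n_latent)
  if (length(coupling) != spec$n_latent) stopf("need one coupling per latent signal")
  L <- vapply(seq_len(spec$n_latent),
              function(j) as.numeric(spec$loading_map[[j]]) * coupling[j],
              numeric(prod(spec$grid_shape)))
  C <- tcrossprod(L)                     # sum_j g_j^2 L_j L_j'
  v <- diag(C) + spec$noise_sd^2
  keep <- v > 0
  R <- C[keep, keep, drop = FALSE] / sqrt(outer(v[keep], v[keep]))
  diag(R) <- 1
  list(R = R, keep = keep)
}

#' Analytic ground-truth centrality of a latent-network specification
#'
#' Builds, explicitly and densely, the voxel-by-voxel rectified correlation
#' matrix implied by the specification (Gaussian mixture of latent signals
#' plus noise, entries mapped through [rectified_similarity()]) and returns
#' its principal eigenvector with nonnegative orientation and unit Euclidean
#' norm. Constant voxels (possible only when `noise_sd = 0`) are excluded
#' from the mask and reported via attribute `"excluded"`.
#'
#' @param spec a [network_spec].
#' @param coupling optional per-latent-signal amplitude multipliers (default
#'   all 1); used to obtain subject-specific ground truth.
#' @return a [centrality_map] (stage `"raw"`) on the mask of non-constant
#'   voxels, with attribute `"excluded"` (indices of dropped voxels).
#' @export
oracle_true_centrality <- function(spec, coupling = NULL) {
  lc <- latent_correlation(spec, coupling)
  M <- rectified_similarity(lc$R)
  diag(M) <- 1
  ev <- eigen(M, symmetric = TRUE)
  v <- principal_vector(ev, nrow(M))
  mask_arr <- array(FALSE, dim = spec$grid_shape)
  mask_arr[which(lc$keep)] <- TRUE
  mask <- brain_mask(mask_arr, voxel_size_mm = spec$voxel_size_mm)
  map <- centrality_map(v, mask, stage = "raw", eigenvalue = ev$values[1],
                        n_iterations = NA_integer_, converged = TRUE)
  excluded <- which(!lc$keep)
  if (length(excluded))
    warnf("%d constant voxel(s) excluded from the centrality mask", length(excluded))
  attr(map, "excluded") <- excluded
  map
}

# shared tie-break with the power iteration: on a (numerically) degenerate
# leading eigenspace return the uniform positive vector, which is the fixed
# point of power iteration started from the uniform vector
principal_vector <- function(ev, n, gap_tol = 1e-10) {
  l1 <- ev$values[1]
  l2 <- if (n >= 2) ev$values[2] else -Inf
  if (!is.finite(l1)) stopf("eigendecomposition failed")
  if (l1 - l2 <= gap_tol * max(abs(l1), 1)) return(rep(1 / sqrt(n), n))
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / sqrt(sum(v^2))
}
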