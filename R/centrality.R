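#' Standardize voxel time series within a mask
#'
#' Centers and scales each in-mask voxel time series to mean 0 and unit
#' variance (n - 1 denominator). Constant series cannot be standardized and
#' are removed from the mask; their count is reported.
#'
#' @param vol a [time_series_volume].
#' @param mask a [brain_mask] on the same grid.
#' @return list with `volume` (standardized [time_series_volume]; voxels
#'   outside the reduced mask are zeroed), `mask` (reduced [brain_mask]) and
#'   `dropped` (grid indices of removed constant voxels).
#' @export
zscore_series <- function(vol, mask) {
  Z <- masked_series(vol, mask)
  info <- standardize_rows(Z)
  idx <- which(mask$data)
  dropped <- idx[info$dropped_rows]
  keep_arr <- mask$data
  keep_arr[dropped] <- FALSE
  new_mask <- brain_mask(keep_arr, voxel_size_mm = mask$voxel_size_mm,
                         origin_mm = mask$origin_mm)
  arr <- array(0, dim = dim(vol$data))
  flat <- matrix(arr, nrow = prod(dim(vol$data)[1:3]))
  flat[which(keep_arr), ] <- info$Z
  out <- time_series_volume(array(flat, dim = dim(vol$data)),
                            voxel_size_mm = vol$voxel_size_mm,
                            repetition_time_s = vol$repetition_time_s)
  list(volume = out, mask = new_mask, dropped = dropped)
}

# voxels-by-time matrix of the in-mask series
masked_series <- function(vol, mask) {
  if (!all(dim(vol$data)[1:3] == dim(mask$data)))
    stopf("volume and mask are not on the same grid")
  flat <- matrix(vol$data, nrow = prod(dim(vol$data)[1:3]))
  Z <- flat[which(mask$data), , drop = FALSE]
  if (any(!is.finite(Z))) stopf("non-finite values inside the mask")
  Z
}

standardize_rows <- function(Z) {
  mu <- rowMeans(Z)
  Zc <- Z - mu
  s <- sqrt(rowSums(Zc^2) / (ncol(Z) - 1))
  dropped <- which(s == 0 | !is.finite(s))
  if (length(dropped)) {
    Zc <- Zc[-dropped, , drop = FALSE]
    s <- s[-dropped]
  }
  if (nrow(Zc) == 0) stopf("mask is empty after removing constant voxels")
  list(Z = Zc / s, dropped_rows = dropped)
}

#' Matrix-free product with the rectified correlation matrix
#'
#' Computes `M %*% v` where `M` is the rectified correlation matrix of the
#' standardized series `Z` (rows = voxels, unit variance with the n - 1
#' denominator): `M[x, y] = (<x+, y+> + <x-, y->) / (T - 1)` with `x+ =
#' max(x, 0)` and `x- = max(-x, 0)` elementwise. `M` is symmetric,
#' entrywise nonnegative, and has unit diagonal, so its dominant eigenvector
#' is unique and positive by Perron-Frobenius whenever `M` is irreducible.
#' The product is evaluated by stacking the rectified series, in
#' O(n_voxels * T) time and memory, without materializing `M`.
#'
#' @param Z standardized series matrix (voxels x T).
#' @param v numeric vector, one entry per voxel.
#' @return numeric vector `M %*% v`.
#' @export
rectified_matvec <- function(Z, v) {
  if (length(v) != nrow(Z)) stopf("dimension mismatch: %d voxels vs %d entries", nrow(Z), length(v))
  Zp <- pmax(Z, 0)
  Zn <- pmax(-Z, 0)
  as.numeric(Zp %*% crossprod(Zp, v) + Zn %*% crossprod(Zn, v)) / (ncol(Z) - 1)
}

#' Dense rectified correlation matrix
#'
#' Materializes the matrix whose products [rectified_matvec()] computes
#' implicitly; intended for oracles and small problems only.
#'
#' @param Z standardized series matrix (voxels x T).
#' @return dense symmetric matrix.
#' @export
rectified_correlation_matrix <- function(Z) {
  Zp <- pmax(Z, 0)
  Zn <- pmax(-Z, 0)
  (tcrossprod(Zp) + tcrossprod(Zn)) / (ncol(Z) - 1)
}

#' Fast eigenvector centrality mapping
#'
#' Computes the voxelwise eigenvector centrality map of a 4D volume by power
#' iteration on the rectified correlation matrix, evaluated matrix-free via
#' [rectified_matvec()]. Iteration starts from the uniform positive vector,
#' renormalizes to unit Euclidean norm each step, and stops when successive
#' vectors differ by less than `tol` in Euclidean norm (or at `max_iter`,
#' with a warning and `converged = FALSE`). On a degenerate spectrum (e.g.,
#' mutually anti-correlated series rectify to the identity matrix) the
#' uniform start vector is already a fixed point and is returned as the
#' documented tie-break.
#'
#' @param vol a [time_series_volume].
#' @param mask a [brain_mask]; constant voxels are dropped (see
#'   [zscore_series()]).
#' @param tol Euclidean convergence tolerance (default 1e-9).
#' @param max_iter maximum iterations (default 1000).
#' @return a [centrality_map] (stage `"raw"`): nonnegative, unit norm, with
#'   eigenvalue estimate, iteration count and convergence flag; attribute
#'   `"dropped"` lists removed constant voxels.
#' @export
fast_ecm <- function(vol, mask, tol = 1e-9, max_iter = 1000L) {
  if (!is.numeric(tol) || tol <= 0) stopf("tol must be > 0")
  if (!is_count(max_iter, 1)) stopf("max_iter must be >= 1")
  Z <- masked_series(vol, mask)
  st <- standardize_rows(Z)
  n <- nrow(st$Z)
  Zp <- pmax(st$Z, 0)
  Zn <- pmax(-st$Z, 0)
  Tm1 <- ncol(Z) - 1
  v <- rep(1 / sqrt(n), n)
  lambda <- NA_real_
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- as.numeric(Zp %*% crossprod(Zp, v) + Zn %*% crossprod(Zn, v)) / Tm1
    lambda <- sqrt(sum(w^2))
    if (lambda == 0) stopf("rectified correlation matrix annihilated the iterate")
    w <- w / lambda
    if (sqrt(sum((w - v)^2)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  if (!converged)
    warnf("power iteration did not converge in %d iterations (tol = %g)", max_iter, tol)
  out_mask <- reduced_mask(mask, st$dropped_rows)
  map <- centrality_map(v, out_mask, stage = "raw", eigenvalue = lambda,
                        n_iterations = iter, converged = converged)
  attr(map, "dropped") <- which(mask$data)[st$dropped_rows]
  map
}

reduced_mask <- function(mask, dropped_rows) {
  if (!length(dropped_rows)) return(mask)
  keep <- mask$data
  keep[which(mask$data)[dropped_rows]] <- FALSE
  brain_mask(keep, voxel_size_mm = mask$voxel_size_mm, origin_mm = mask$origin_mm)
}

#' Brute-force eigenvector centrality (dense oracle)
#'
#' Materializes the dense rectified correlation matrix and returns the
#' principal eigenvector from a full symmetric eigendecomposition, with
#' nonnegative orientation and unit norm. Uses the same degenerate-spectrum
#' tie-break as [fast_ecm()] (uniform vector). Intended as the independent
#' reference for the matrix-free path on small inputs.
#'
#' @param vol a [time_series_volume].
#' @param mask a [brain_mask].
#' @param cap refuse masks larger than this many voxels (default 5000).
#' @return a [centrality_map] (stage `"raw"`).
#' @export
brute_force_ecm <- function(vol, mask, cap = 5000L) {
  if (mask$n_voxels > cap)
    stopf("mask has %d voxels, above the dense cap of %d; use fast_ecm()", mask$n_voxels, cap)
  Z <- masked_series(vol, mask)
  st <- standardize_rows(Z)
  M <- rectified_correlation_matrix(st$Z)
  ev <- eigen(M, symmetric = TRUE)
  v <- principal_vector(ev, nrow(M))
  out_mask <- reduced_mask(mask, st$dropped_rows)
  centrality_map(v, out_mask, stage = "raw", eigenvalue = ev$values[1],
                 n_iterations = NA_integer_, converged = TRUE)
}

#' Rank-based inverse-normal (Gaussianizing) transform of a centrality map
#'
#' Transforms the in-mask values of a raw centrality map to a Gaussian shape
#' using Blom rank offsets: value with rank `r` among `n` maps to
#' `qnorm((r - 3/8) / (n + 1/4))`. Ties share the average rank; the
#' transform is strictly rank-preserving.
#'
#' @param map a [centrality_map] with stage `"raw"`.
#' @return a [centrality_map] with stage `"gaussianized"`.
#' @export
gaussianize_map <- function(map) {
  if (!inherits(map, "centrality_map")) stopf("map must be a centrality_map")
  if (map$stage != "raw") stopf("gaussianize_map expects a raw-stage map (got '%s')", map$stage)
  x <- map$values
  n <- length(x)
  if (n < 3L) stopf("need at least 3 in-mask voxels to Gaussianize")
  g <- qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  centrality_map(g, map$mask, stage = "gaussianized", eigenvalue = map$eigenvalue,
                 n_iterations = map$n_iterations, converged = map$converged)
}

#' Residualize centrality maps for head motion across subjects
#'
#' Per voxel, regresses the map value on an intercept and the per-subject
#' mean RMS motion by ordinary least squares across subjects, and returns
#' the residual maps. Intended to be applied separately per timepoint with
#' that scan's motion summary. If motion has zero variance the maps are
#' mean-centered only, with a warning.
#'
#' @param maps list of Gaussianized [centrality_map]s, one per subject, on a
#'   shared mask.
#' @param motion numeric vector of per-subject mean RMS motion.
#' @return list of [centrality_map]s with stage `"residualized"`.
#' @export
residualize_motion <- function(maps, motion) {
  if (length(maps) != length(motion)) stopf("need one motion value per map")
  if (length(maps) < 3L) stopf("need at least 3 subjects to residualize")
  for (m in maps) if (m$stage != "gaussianized")
    stopf("all maps must be gaussianized before residualization")
  Y <- stack_maps(maps)
  mask <- attr(Y, "mask")
  if (sd(motion) == 0) {
    warnf("motion has zero variance; maps mean-centered only")
    R <- sweep(Y, 2, colMeans(Y))
  } else {
    X <- cbind(1, motion)
    R <- qr.resid(qr(X), Y)
  }
  lapply(seq_len(nrow(R)), function(i)
    centrality_map(R[i, ], mask, stage = "residualized"))
}
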