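#' Generate paired baseline/follow-up 4D volumes for a cohort
#'
#' Each voxel's time series is a loading-weighted mixture of smooth latent
#' signals (stationary AR(1) Gaussian processes, unit marginal variance) plus
#' independent Gaussian noise. Between-subject variation is induced by
#' scaling the first (target) latent signal's amplitude with the subject's
#' latent connectivity trait: amplitude `1 + coupling_strength * conn`,
#' floored at 0.05 to preserve nonnegativity of the loadings. The default of
#' `T = 126` volumes corresponds to a 315 s acquisition at a 2.5 s repetition
#' time.
#'
#' @param spec a [network_spec].
#' @param cohort cohort table from [generate_cohort()] (uses columns
#'   `conn_t1`, `conn_t2`; both treated as 0 when absent).
#' @param T number of time points (>= 8).
#' @param seed integer seed; a fixed seed yields bit-identical arrays.
#' @param coupling_strength scaling of the target-signal amplitude per unit
#'   of the standardized connectivity trait.
#' @param ar_phi temporal AR(1) coefficient of the latent signals.
#' @return list with one element per subject, each a list with
#'   `time_series_volume` elements `t1` and `t2`, plus attribute `"mask"`
#'   (full-grid [brain_mask]).
#' @export
generate_paired_volumes <- function(spec, cohort, T = 126L, seed = 1L,
                                    coupling_strength = 0.25, ar_phi = 0.4) {
  if (!inherits(spec, "network_spec")) stopf("spec must be a network_spec")
  if (!is_count(T, 1) || T < 8L) stopf("T = %s is too short for correlation estimation (need T >= 8)", T)
  n <- nrow(cohort)
  conn1 <- cohort$conn_t1 %||% rep(0, n)
  conn2 <- cohort$conn_t2 %||% rep(0, n)
  nv <- prod(spec$grid_shape)
  L <- vapply(spec$loading_map, as.numeric, numeric(nv))  # nv x n_latent
  out <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      vols <- lapply(c(conn1[i], conn2[i]), function(cc) {
        g <- rep(1, spec$n_latent)
        g[1] <- max(1 + coupling_strength * cc, 0.05)
        S <- ar1_signals(spec$n_latent, T, ar_phi)          # n_latent x T
        X <- (L %*% (g * S)) + spec$noise_sd * matrix(rnorm(nv * T), nv, T)
        time_series_volume(array(X, dim = c(spec$grid_shape, T)),
                           voxel_size_mm = spec$voxel_size_mm)
      })
      names(vols) <- c("t1", "t2")
      vols
    })
  })
  names(out) <- cohort$subject_id %||% sprintf("S%04d", seq_len(n))
  attr(out, "mask") <- brain_mask(array(TRUE, spec$grid_shape),
                                  voxel_size_mm = spec$voxel_size_mm)
  out
}

# stationary AR(1) rows with unit marginal variance
ar1_signals <- function(k, T, phi) {
  S <- matrix(rnorm(k * T), k, T)
  if (phi != 0) {
    S[, 1] <- S[, 1]
    w <- sqrt(1 - phi^2)
    for (t in 2:T) S[, t] <- phi * S[, t - 1] + w * S[, t]
  }
  S
}

#' Simulate smooth Gaussian random maps
#'
#' Generates per-subject 3D maps as white Gaussian noise convolved with an
#' isotropic Gaussian kernel of the requested full width at half maximum
#' (in voxels), using circular (wrap-around) convolution so the field is
#' stationary with exactly known smoothness everywhere. These maps emulate
#' Gaussianized, residualized centrality maps under the null and are the
#' workhorse of the familywise-error calibration experiments.
#'
#' @param n_maps number of maps.
#' @param mask a [brain_mask]; smoothing is performed on the full grid and
#'   the maps are then restricted to the mask.
#' @param fwhm_vox kernel full width at half maximum, in voxels (scalar).
#' @param seed integer seed.
#' @return `n_maps` x `n_voxels` matrix with the mask attached as attribute
#'   `"mask"`.
#' @export
simulate_smooth_maps <- function(n_maps, mask, fwhm_vox = 2, seed = 1L) {
  gs <- dim(mask$data)
  sigma <- fwhm_vox / sqrt(8 * log(2))
  Ks <- lapply(gs, circulant_gaussian_kernel, sigma = sigma)
  with_seed(seed, {
    Y <- matrix(NA_real_, n_maps, mask$n_voxels)
    for (i in seq_len(n_maps)) {
      arr <- array(rnorm(prod(gs)), dim = gs)
      arr <- smooth_separable(arr, Ks)
      Y[i, ] <- arr[mask$data]
    }
    attr(Y, "mask") <- mask
    Y
  })
}

circulant_gaussian_kernel <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- floor(n / 2)
  offs <- -half:(n - half - 1)
  w <- exp(-offs^2 / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) K[i, ] <- w[((seq_len(n) - i - min(offs)) %% n) + 1]
  K
}

# apply per-axis kernel matrices to a 3D array (separable smoothing)
smooth_separable <- function(arr, Ks) {
  gs <- dim(arr)
  a <- Ks[[1]] %*% matrix(arr, gs[1], gs[2] * gs[3])
  arr <- array(a, gs)
  arr <- aperm(arr, c(2, 3, 1))
  a <- Ks[[2]] %*% matrix(arr, gs[2], gs[3] * gs[1])
  arr <- array(a, c(gs[2], gs[3], gs[1]))
  arr <- aperm(arr, c(2, 3, 1))
  a <- Ks[[3]] %*% matrix(arr, gs[3], gs[1] * gs[2])
  arr <- array(a, c(gs[3], gs[1], gs[2]))
  aperm(arr, c(2, 3, 1))
}
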