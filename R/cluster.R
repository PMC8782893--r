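#' Bonferroni-adjusted cluster alpha
#'
#' @param alpha familywise significance level in (0, 1).
#' @param n_contrasts number of contrasts corrected across (>= 1).
#' @return `alpha / n_contrasts`.
#' @examples
#' bonferroni_alpha(0.05, 4)  # 0.0125
#' @export
bonferroni_alpha <- function(alpha, n_contrasts) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stopf("alpha must be in (0, 1)")
  if (!is_count(n_contrasts, 1)) stopf("n_contrasts must be a positive integer")
  alpha / n_contrasts
}

#' Estimate image smoothness from residual maps
#'
#' Estimates the full width at half maximum (FWHM) of the implicit Gaussian
#' smoothing kernel per axis from the spatial first differences of
#' standardized residual maps. Residuals are standardized per voxel across
#' maps; for each axis the pooled variance `v` of first differences between
#' in-mask neighbors gives the lag-one spatial autocorrelation
#' `rho = 1 - v / 2`, and under a Gaussian autocorrelation function the
#' kernel FWHM is `voxel_size * sqrt(2 * log(2) / (-log(rho)))`. The resel
#' (resolution element) count is the mask volume divided by the product of
#' the per-axis FWHMs.
#'
#' @param resid subjects-by-voxels residual matrix carrying a `"mask"`
#'   attribute (see [residual_maps()]), or a list of 3D arrays plus `mask`.
#' @param mask optional [brain_mask] (required when `resid` has none
#'   attached).
#' @param voxel_size_mm optional override of the mask voxel size.
#' @return object of class `smoothness_estimate` with `fwhm_mm` (length 3),
#'   `fwhm_vox`, `resels`, and `n_voxels`.
#' @export
estimate_smoothness <- function(resid, mask = NULL, voxel_size_mm = NULL) {
  if (is.list(resid) && !is.matrix(resid)) {
    if (is.null(mask)) stopf("mask required when residuals are arrays")
    resid <- do.call(rbind, lapply(resid, function(a) a[mask$data]))
  } else {
    mask <- mask %||% attr(resid, "mask")
    if (is.null(mask)) stopf("residual matrix must carry a mask")
  }
  if (nrow(resid) < 3L) stopf("need at least 3 residual maps")
  vs <- voxel_size_mm %||% mask$voxel_size_mm
  Z <- scale(resid)
  keep_ok <- is.finite(colSums(Z))
  gs <- dim(mask$data)
  vox_idx <- which(mask$data)
  pos <- arrayInd(vox_idx, gs)
  lookup <- array(0L, gs)
  lookup[vox_idx] <- seq_along(vox_idx)
  fwhm_vox <- numeric(3)
  for (ax in 1:3) {
    shift <- pos
    shift[, ax] <- shift[, ax] + 1L
    inside <- shift[, ax] <= gs[ax]
    nb <- rep(0L, nrow(pos))
    nb[inside] <- lookup[shift[inside, , drop = FALSE]]
    pair <- which(nb > 0L & keep_ok & keep_ok[pmax(nb, 1L)])
    if (!length(pair)) stopf("no in-mask neighbor pairs along axis %d", ax)
    D <- Z[, pair, drop = FALSE] - Z[, nb[pair], drop = FALSE]
    v <- mean(D^2)
    if (!is.finite(v) || v == 0) stopf("zero spatial variance along axis %d", ax)
    rho <- min(max(1 - v / 2, 1e-6), 1 - 1e-6)
    fwhm_vox[ax] <- sqrt(2 * log(2) / (-log(rho)))
  }
  structure(list(fwhm_mm = fwhm_vox * vs, fwhm_vox = fwhm_vox,
                 resels = mask$n_voxels / prod(fwhm_vox),
                 n_voxels = mask$n_voxels),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("smoothness: FWHM = [%.2f, %.2f, %.2f] mm, %.1f resels over %d voxels\n",
              x$fwhm_mm[1], x$fwhm_mm[2], x$fwhm_mm[3], x$resels, x$n_voxels))
  invisible(x)
}

neighbor_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
         "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
         "26" = offs,
         stopf("connectivity must be 6, 18 or 26"))
}

# label connected components of a logical 3D array; returns integer array
label_components <- function(supra, connectivity = 26) {
  gs <- dim(supra)
  offs <- neighbor_offsets(connectivity)
  labels <- array(0L, gs)
  idx <- which(supra)
  if (!length(idx)) return(labels)
  pos <- arrayInd(idx, gs)
  inside <- array(FALSE, gs); inside[idx] <- TRUE
  cur <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      p <- arrayInd(v, gs)[1, ]
      nb <- sweep(offs, 2, p, `+`)
      okb <- nb[, 1] >= 1 & nb[, 1] <= gs[1] & nb[, 2] >= 1 & nb[, 2] <= gs[2] &
        nb[, 3] >= 1 & nb[, 3] <= gs[3]
      if (!any(okb)) next
      nb <- nb[okb, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * gs[1] + (nb[, 3] - 1L) * gs[1] * gs[2]
      new <- lin[inside[lin] & labels[lin] == 0L]
      if (length(new)) {
        labels[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  labels
}

#' Form suprathreshold clusters from a z-map
#'
#' Thresholds the map at the one-sided standard-normal quantile for
#' `forming_p` in the requested direction, finds connected components under
#' the chosen neighbor rule, and records each cluster's extent, peak
#' z-value, and peak coordinate in world mm (voxel index mapped through the
#' mask's voxel size and origin, MNI convention when the input is in MNI
#' space).
#'
#' @param zmap 3D array of z-values (NA allowed outside the mask).
#' @param mask a [brain_mask].
#' @param forming_p cluster-forming (uncorrected, one-sided) p threshold in
#'   (0, 0.5).
#' @param sign `"positive"` or `"negative"`.
#' @param connectivity neighbor rule: 6 (faces), 18 (+edges) or 26
#'   (+corners; default).
#' @return list with `table` (data.frame: cluster_id, peak_x_mm, peak_y_mm,
#'   peak_z_mm, max_z, extent, sign; p_fwe unset) and `voxels` (list of
#'   grid-index vectors per cluster). Empty table if nothing survives.
#' @export
form_clusters <- function(zmap, mask, forming_p = 0.001,
                          sign = c("positive", "negative"), connectivity = 26) {
  sign <- match.arg(sign)
  if (!is.numeric(forming_p) || forming_p <= 0 || forming_p >= 0.5)
    stopf("forming_p must be in (0, 0.5)")
  u <- qnorm(forming_p, lower.tail = FALSE)
  z <- zmap
  z[!mask$data] <- NA_real_
  supra <- if (sign == "positive") !is.na(z) & z >= u else !is.na(z) & z <= -u
  labels <- label_components(supra, connectivity)
  k <- max(labels)
  empty <- data.frame(cluster_id = integer(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      max_z = numeric(0), extent = integer(0),
                      sign = character(0), stringsAsFactors = FALSE)
  if (k == 0L) return(list(table = empty, voxels = list(), forming_u = u))
  vox <- vector("list", k)
  rows <- vector("list", k)
  for (ci in seq_len(k)) {
    vi <- which(labels == ci)
    vox[[ci]] <- vi
    zi <- z[vi]
    peak <- vi[which.max(abs(zi))]
    pc <- arrayInd(peak, dim(mask$data))[1, ]
    mm <- mask$origin_mm + (pc - 1L) * mask$voxel_size_mm
    rows[[ci]] <- data.frame(cluster_id = ci, peak_x_mm = mm[1], peak_y_mm = mm[2],
                             peak_z_mm = mm[3], max_z = zi[which.max(abs(zi))],
                             extent = length(vi), sign = sign,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$extent)
  list(table = tab[ord, , drop = FALSE], voxels = vox[ord], forming_u = u)
}

#' Gaussian-random-field cluster-level corrected p-value
#'
#' Computes the familywise-error corrected p-value of a cluster of `extent`
#' voxels formed at z-threshold `u`, from the expected Euler characteristic
#' of a 3D Gaussian field. The expected cluster count is
#' `E[m] = R * (4 log 2)^{3/2} (2 pi)^{-2} (u^2 - 1) exp(-u^2 / 2)` with `R`
#' the resel count (leading 3D term only; lower-dimensional boundary terms
#' are omitted), the expected suprathreshold volume is
#' `E[N] = n_voxels * (1 - Phi(u))` (doubled for two-sided inference), the
#' cluster-extent tail is `P(n >= k) = exp(-beta k^{2/3})` with `beta` set
#' so the tail's mean matches `E[N] / E[m]`, and finally
#' `p_fwe = 1 - exp(-E[m] * P(n >= k))`.
#'
#' @param extent cluster extent in voxels (>= 1).
#' @param u cluster-forming z-threshold (> 1; the Euler-characteristic
#'   density changes sign below 1).
#' @param smooth a [estimate_smoothness()] result.
#' @param two_sided if `TRUE`, account for excursions of both signs of one
#'   contrast (expected cluster count and volume doubled), which is how the
#'   pipeline controls the familywise error per contrast while reporting
#'   signed clusters.
#' @return corrected p-value in `[0, 1]`.
#' @export
rft_cluster_p <- function(extent, u, smooth, two_sided = FALSE) {
  if (!is_count(extent, 1)) stopf("extent must be a positive integer")
  if (!is.numeric(u) || u <= 1) stopf("forming threshold u must exceed 1")
  if (!inherits(smooth, "smoothness_estimate")) stopf("smooth must be a smoothness_estimate")
  side <- if (two_sided) 2 else 1
  Em <- side * smooth$resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (u^2 - 1) * exp(-u^2 / 2)
  EN <- side * smooth$n_voxels * pnorm(u, lower.tail = FALSE)
  if (!is.finite(Em) || Em <= 0 || !is.finite(EN) || EN <= 0)
    stopf("non-finite or nonpositive expected cluster statistics (Em = %g, EN = %g)", Em, EN)
  En <- EN / Em
  beta <- (gamma(2.5) / En)^(2 / 3)
  p <- -expm1(-Em * exp(-beta * extent^(2 / 3)))
  min(max(p, 0), 1)
}

#' Cluster-level inference on a z-map
#'
#' Forms signed clusters at the forming threshold in both directions,
#' assigns each a Gaussian-random-field corrected p-value (two-sided
#' accounting, so the familywise error of the contrast is controlled at
#' `alpha` across both signs), and flags significance at the
#' Bonferroni-adjusted level.
#'
#' @param zmap 3D z-array.
#' @param mask a [brain_mask].
#' @param smooth a [estimate_smoothness()] result.
#' @param forming_p cluster-forming one-sided p threshold.
#' @param alpha familywise level before contrast correction.
#' @param n_contrasts contrasts corrected across via [bonferroni_alpha()].
#' @param connectivity neighbor rule (6/18/26).
#' @return list with `table` (cluster records incl. `p_fwe` and
#'   `significant`) and `voxels` (grid-index vectors, same order).
#' @export
cluster_inference <- function(zmap, mask, smooth, forming_p = 0.001, alpha = 0.05,
                              n_contrasts = 4, connectivity = 26) {
  athr <- bonferroni_alpha(alpha, n_contrasts)
  res <- lapply(c("positive", "negative"), function(sgn)
    form_clusters(zmap, mask, forming_p, sgn, connectivity))
  tab <- do.call(rbind, lapply(res, `[[`, "table"))
  vox <- c(res[[1]]$voxels, res[[2]]$voxels)
  u <- res[[1]]$forming_u
  if (nrow(tab)) {
    tab$p_fwe <- vapply(tab$extent, rft_cluster_p, numeric(1),
                        u = u, smooth = smooth, two_sided = TRUE)
    tab$significant <- tab$p_fwe < athr
    ord <- order(tab$p_fwe, -tab$extent)
    tab <- tab[ord, , drop = FALSE]
    vox <- vox[ord]
    tab$cluster_id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  } else {
    tab$p_fwe <- numeric(0)
    tab$significant <- logical(0)
  }
  list(table = tab, voxels = vox, forming_u = u, alpha_corrected = athr)
}

#' Extract per-subject mean map values over a cluster
#'
#' The in-house equivalent of a mask-average utility: for each subject, the
#' arithmetic mean of map values over the cluster's voxels.
#'
#' @param maps list of [centrality_map]s (typically Gaussianized and
#'   motion-residualized) or a subjects-by-voxels matrix with a `"mask"`
#'   attribute.
#' @param cluster_voxels integer vector of grid indices (must lie inside the
#'   mask).
#' @return numeric vector, one mean per subject.
#' @export
extract_cluster_mean <- function(maps, cluster_voxels) {
  if (!length(cluster_voxels)) stopf("empty cluster mask")
  Y <- if (is.list(maps)) stack_maps(maps) else maps
  mask <- attr(Y, "mask")
  inmask <- which(mask$data)
  cols <- match(cluster_voxels, inmask)
  if (anyNA(cols)) stopf("%d cluster voxel(s) fall outside the analysis mask", sum(is.na(cols)))
  rowMeans(Y[, cols, drop = FALSE])
}
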