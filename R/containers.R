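#' Brain mask
#'
#' A binary 3D mask defining the analysis domain for centrality computation
#' and voxelwise modeling. Voxel indices inside the mask are ordered by R's
#' column-major array convention throughout the package.
#'
#' @param data 3D array coercible to logical (0/1).
#' @param voxel_size_mm length-3 numeric, voxel edge lengths in mm.
#' @param origin_mm length-3 numeric, world-space coordinate of the first
#'   voxel's center (mm). Together with `voxel_size_mm` this defines the
#'   affine used for reporting peak coordinates.
#' @return object of class `brain_mask` with fields `data` (logical array),
#'   `voxel_size_mm`, `origin_mm` and `n_voxels`.
#' @export
brain_mask <- function(data, voxel_size_mm = c(3, 3, 3), origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stopf("mask must be a 3D array")
  m <- array(as.logical(data), dim = dim(data))
  if (anyNA(m)) stopf("mask contains NA")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stopf("voxel_size_mm must be 3 positive lengths")
  n <- sum(m)
  if (n < 2L) stopf("mask must contain at least 2 voxels (has %d)", n)
  structure(list(data = m, voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_mm = as.numeric(origin_mm), n_voxels = n),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain_mask: %s grid, %d in-mask voxels, %.3g x %.3g x %.3g mm\n",
              paste(dim(x$data), collapse = "x"), x$n_voxels,
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' 4D voxel time-series volume
#'
#' @param data 4D array (x, y, z, time).
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param repetition_time_s sampling interval in seconds.
#' @return object of class `time_series_volume`.
#' @export
time_series_volume <- function(data, voxel_size_mm = c(3, 3, 3), repetition_time_s = 2.5) {
  d <- dim(data)
  if (length(d) != 4L) stopf("volume must be a 4D array (x, y, z, time)")
  if (d[4] < 8L) stopf("time dimension T = %d is too short (need T >= 8)", d[4])
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 T = d[4], repetition_time_s = repetition_time_s),
            class = "time_series_volume")
}

#' @export
print.time_series_volume <- function(x, ...) {
  cat(sprintf("time_series_volume: %s grid, T = %d (TR = %.3g s)\n",
              paste(dim(x$data)[1:3], collapse = "x"), x$T, x$repetition_time_s))
  invisible(x)
}

#' Centrality map
#'
#' Per-subject 3D map of voxelwise eigenvector centrality, tagged with its
#' processing stage: `"raw"` (nonnegative, unit Euclidean norm within the
#' mask), `"gaussianized"` (rank-based inverse-normal transformed across
#' in-mask voxels) or `"residualized"` (motion-regressed across subjects).
#'
#' @param values numeric vector, one value per in-mask voxel (column-major
#'   order), or a 3D array on the mask grid.
#' @param mask a [brain_mask].
#' @param stage one of `"raw"`, `"gaussianized"`, `"residualized"`.
#' @param eigenvalue dominant eigenvalue estimate (raw stage only).
#' @param n_iterations power-iteration count (`NA` for direct solvers).
#' @param converged logical convergence flag.
#' @return object of class `centrality_map`; `data` holds a 3D array with
#'   `NA` outside the mask, `values` the in-mask vector.
#' @export
centrality_map <- function(values, mask, stage = "raw", eigenvalue = NA_real_,
                           n_iterations = NA_integer_, converged = NA) {
  stage <- match.arg(stage, c("raw", "gaussianized", "residualized"))
  if (is.array(values) && length(dim(values)) == 3L) {
    if (!all(dim(values) == dim(mask$data))) stopf("map grid does not match mask grid")
    values <- values[mask$data]
  }
  if (length(values) != mask$n_voxels)
    stopf("expected %d in-mask values, got %d", mask$n_voxels, length(values))
  if (any(!is.finite(values))) stopf("centrality values must be finite inside the mask")
  if (stage == "raw") {
    if (any(values < -1e-12)) stopf("raw centrality must be nonnegative")
    nrm <- sqrt(sum(values^2))
    if (abs(nrm - 1) > 1e-8)
      stopf("raw centrality must have unit Euclidean norm (got %.12f)", nrm)
  }
  arr <- array(NA_real_, dim = dim(mask$data))
  arr[mask$data] <- values
  structure(list(data = arr, values = as.numeric(values), mask = mask,
                 eigenvalue = eigenvalue, stage = stage,
                 n_iterations = n_iterations, converged = converged),
            class = "centrality_map")
}

#' @export
print.centrality_map <- function(x, ...) {
  cat(sprintf("centrality_map [%s]: %d voxels", x$stage, x$mask$n_voxels))
  if (is.finite(x$eigenvalue)) cat(sprintf(", lambda = %.6g", x$eigenvalue))
  if (!is.na(x$n_iterations)) cat(sprintf(", %d iterations", x$n_iterations))
  if (!is.na(x$converged)) cat(sprintf(", converged = %s", x$converged))
  cat("\n")
  invisible(x)
}

#' Stack centrality maps into a subjects-by-voxels matrix
#'
#' @param maps list of [centrality_map] objects sharing one mask.
#' @return numeric matrix (length(maps) rows, n_voxels columns) with the
#'   shared mask attached as attribute `"mask"`.
#' @export
stack_maps <- function(maps) {
  if (!length(maps)) stopf("empty map list")
  mk <- maps[[1]]$mask
  for (m in maps) {
    if (!all(dim(m$mask$data) == dim(mk$data)) || !all(m$mask$data == mk$data))
      stopf("all maps must share one grid and mask")
  }
  Y <- do.call(rbind, lapply(maps, function(m) m$values))
  attr(Y, "mask") <- mk
  Y
}
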