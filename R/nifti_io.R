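# NIfTI-1 and table I/O. Volumes and maps travel as NIfTI; map processing
# stage and convergence metadata go in a JSON sidecar next to the image.

#' Write / read a 4D time-series volume as NIfTI-1
#'
#' @param vol a [time_series_volume].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly (writer); a [time_series_volume] (reader).
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel_size_mm, vol$repetition_time_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  time_series_volume(array(as.numeric(img), dim = dim(img)),
                     voxel_size_mm = pd[1:3],
                     repetition_time_s = if (length(pd) >= 4) pd[4] else 2.5)
}

#' Write / read a binary brain mask as NIfTI-1
#'
#' @param mask a [brain_mask].
#' @param path file path.
#' @return `path` invisibly (writer); a [brain_mask] (reader).
#' @export
write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::pixdim(img) <- mask$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path, origin_mm = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  brain_mask(array(as.numeric(img) != 0, dim = dim(img)),
             voxel_size_mm = RNifti::pixdim(img)[1:3], origin_mm = origin_mm)
}

#' Write / read a centrality map as NIfTI-1 with a JSON sidecar
#'
#' The 3D map (0 outside the mask) is written to `<prefix>.nii.gz` and the
#' processing stage, eigenvalue, iteration count and convergence flag to
#' `<prefix>.json`.
#'
#' @param map a [centrality_map].
#' @param prefix output path prefix.
#' @return the image path invisibly (writer); a [centrality_map] (reader).
#' @export
write_map_nifti <- function(map, prefix) {
  arr <- map$data
  arr[is.na(arr)] <- 0
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- map$mask$voxel_size_mm
  img_path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, img_path)
  meta <- list(stage = map$stage, eigenvalue = map$eigenvalue,
               n_iterations = map$n_iterations, converged = map$converged)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(img_path)
}

#' @rdname write_map_nifti
#' @param mask the [brain_mask] the map was computed on.
#' @export
read_map_nifti <- function(prefix, mask) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  centrality_map(array(as.numeric(img), dim = dim(img))[mask$data], mask,
                 stage = meta$stage,
                 eigenvalue = meta$eigenvalue %||% NA_real_,
                 n_iterations = meta$n_iterations %||% NA_integer_,
                 converged = meta$converged %||% NA)
}

#' Write / read a cohort phenotype table as comma-separated text
#'
#' Column header documented in [generate_cohort()]; logical diagnosis flags
#' are stored as 0/1.
#'
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (cn in c("meets_dx_t1", "meets_dx_t2"))
    if (cn %in% names(out)) out[[cn]] <- as.integer(out[[cn]])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("meets_dx_t1", "meets_dx_t2"))
    if (cn %in% names(out)) out[[cn]] <- as.logical(out[[cn]])
  out
}

#' Write a generated dataset to disk with a manifest
#'
#' Writes the phenotype table, mask, and per-subject/timepoint 4D volumes
#' under `dir`, plus a plain-text manifest listing every generated path and
#' the seed used.
#'
#' @param cohort cohort table.
#' @param volumes nested volume list from [generate_paired_volumes()].
#' @param dir output directory (created if needed).
#' @param seed the generation seed, recorded in the manifest.
#' @return path of the manifest file, invisibly.
#' @export
write_dataset <- function(cohort, volumes, dir, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "cohort.csv")
  write_cohort_csv(cohort, p)
  paths <- c(paths, p)
  mask <- attr(volumes, "mask")
  if (!is.null(mask)) {
    p <- file.path(dir, "mask.nii.gz")
    write_mask_nifti(mask, p)
    paths <- c(paths, p)
  }
  for (sid in names(volumes)) {
    for (tp in c("t1", "t2")) {
      p <- file.path(dir, sprintf("%s_%s.nii.gz", sid, tp))
      write_volume_nifti(volumes[[sid]][[tp]], p)
      paths <- c(paths, p)
    }
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c(sprintf("seed\t%d", seed), sprintf("file\t%s", paths)), manifest)
  invisible(manifest)
}
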