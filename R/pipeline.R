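#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end driver
#' [run_pipeline()]. Either `input` (a dataset directory produced by
#' [write_dataset()], containing `cohort.csv`, `mask.nii.gz` and per-scan
#' volumes) or `simulate` (parameters for in-memory synthetic generation)
#' must be provided.
#'
#' @param input optional dataset directory.
#' @param simulate optional list: `params` ([cohort_params()]), `network`
#'   ([network_spec]), `T` (volumes per scan), `coupling_strength`.
#' @param output_dir optional directory for artifacts (cluster tables,
#'   z-maps, report).
#' @param ecm list: `tol`, `max_iter` for [fast_ecm()].
#' @param model list: `dimensions` (subset of inattention/hyperactivity),
#'   `covariates` (cohort columns).
#' @param inference list: `forming_p`, `alpha`, `n_contrasts`,
#'   `connectivity`.
#' @param robustness list of toggles: `wilcoxon`, `zero_exclusion`,
#'   `trimming`, `trim_frac`, `zip`, `zip_zero_predictors` (`"connectivity"`
#'   to predict excess zeroes from baseline cluster connectivity only,
#'   `"full"` for the full covariate set).
#' @param seed master seed; all pipeline randomness derives from it.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, output_dir = NULL,
                            ecm = list(), model = list(), inference = list(),
                            robustness = list(), seed = 1L) {
  ecm <- utils::modifyList(list(tol = 1e-9, max_iter = 1000L), ecm)
  model <- utils::modifyList(list(dimensions = c("inattention", "hyperactivity"),
                                  covariates = c("mean_age", "sex", "interval", "medication")),
                             model)
  inference <- utils::modifyList(list(forming_p = 0.001, alpha = 0.05,
                                      n_contrasts = 4, connectivity = 26), inference)
  robustness <- utils::modifyList(list(wilcoxon = TRUE, zero_exclusion = TRUE,
                                       trimming = TRUE, trim_frac = 0.15, zip = TRUE,
                                       zip_zero_predictors = "connectivity"), robustness)
  if (is.null(input) && is.null(simulate))
    stopf("config error: provide either 'input' or 'simulate'")
  if (!is.null(input) && !file.exists(file.path(input, "cohort.csv")))
    stopf("config error: input path '%s' has no cohort.csv", input)
  if (inference$forming_p <= 0 || inference$forming_p >= 1 ||
      inference$alpha <= 0 || inference$alpha >= 1)
    stopf("config error: forming_p and alpha must lie in (0, 1)")
  if (!all(model$dimensions %in% c("inattention", "hyperactivity")))
    stopf("config error: unknown symptom dimension")
  if (!is.null(simulate)) {
    # no recursive merge here: params/network are structured objects that
    # must be taken whole, not field-merged into the defaults
    sim_defaults <- list(params = cohort_params(), network = default_network_spec(),
                         T = 126L, coupling_strength = 0.25)
    for (nm in names(sim_defaults))
      if (is.null(simulate[[nm]])) simulate[[nm]] <- sim_defaults[[nm]]
  }
  structure(list(input = input, simulate = simulate, output_dir = output_dir,
                 ecm = ecm, model = model, inference = inference,
                 robustness = robustness, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `simulate.params` block is passed to [cohort_params()].
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file values (e.g., from
#'   command-line flags).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stopf("config error: file '%s' not found", path)
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  if (!is.null(raw$simulate) && !is.null(raw$simulate$params) &&
      !inherits(raw$simulate$params, "cohort_params"))
    raw$simulate$params <- do.call(cohort_params, raw$simulate$params)
  do.call(pipeline_config, raw)
}

# restrict a centrality map to a (sub)mask
restrict_map <- function(map, mask) {
  if (all(dim(map$mask$data) == dim(mask$data)) && all(map$mask$data == mask$data))
    return(map)
  vals <- map$data[mask$data]
  centrality_map(vals, mask, stage = map$stage, eigenvalue = map$eigenvalue,
                 n_iterations = map$n_iterations, converged = map$converged)
}

#' Run the full longitudinal brain-behavior pipeline
#'
#' Executes, in order: family-member selection, eigenvector centrality
#' mapping of every scan, Gaussianization, per-timepoint motion
#' residualization, voxelwise cross-lagged modeling per symptom dimension,
#' smoothness estimation and cluster-level random-field inference at the
#' Bonferroni-adjusted alpha, and the robustness battery on significant
#' clusters (descriptive Wilcoxon change tests, cluster-mean path-model
#' refits, zero-symptom exclusion, interscan-interval trimming, and
#' zero-inflated Poisson control). Identical configuration and seed yield
#' identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: per-stage status and timings, per-contrast
#'   cluster tables, robustness outcomes, stage counts, and provenance
#'   (config hash, seed, package version, emitted files with checksums).
#'   On stage failure the report is returned with `status = "failed"`, the
#'   failing stage named, and all completed-stage artifacts retained.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  report <- list(status = "ok", stages = list(), clusters = list(),
                 robustness = list(), counts = list(),
                 provenance = list(seed = config$seed,
                                   config_hash = hash_object(unclass(config)),
                                   version = as.character(utils::packageVersion("neurocrosslag")),
                                   files = data.frame(path = character(0), md5 = character(0))))
  env <- new.env(parent = emptyenv())
  seeds <- derive_seeds(config$seed, 4L)

  stage <- function(name, fun) {
    if (report$status != "ok") return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      report$status <<- "failed"
      report$failed_stage <<- name
      report$error <<- conditionMessage(res)
      report$stages[[name]] <<- list(status = "failed", seconds = dt)
    } else {
      report$stages[[name]] <<- list(status = "ok", seconds = dt)
    }
    invisible(NULL)
  }

  stage("cohort", function() {
    if (!is.null(config$input)) {
      env$cohort <- read_cohort_csv(file.path(config$input, "cohort.csv"))
      env$mask <- read_mask_nifti(file.path(config$input, "mask.nii.gz"))
      env$truth <- NULL
    } else {
      gen <- generate_cohort(config$simulate$params, network = config$simulate$network)
      env$cohort <- gen$cohort
      env$truth <- gen$truth
    }
  })
  stage("family_selection", function() {
    sel <- select_family_member(env$cohort)
    report$counts$families_removed <<- attr(sel, "n_removed")
    env$cohort <- sel
  })
  stage("volumes", function() {
    if (!is.null(config$input)) {
      env$volumes <- setNames(lapply(env$cohort$subject_id, function(sid) {
        list(t1 = read_volume_nifti(file.path(config$input, sprintf("%s_t1.nii.gz", sid))),
             t2 = read_volume_nifti(file.path(config$input, sprintf("%s_t2.nii.gz", sid))))
      }), env$cohort$subject_id)
      attr(env$volumes, "mask") <- env$mask
    } else {
      env$volumes <- generate_paired_volumes(config$simulate$network, env$cohort,
                                             T = config$simulate$T, seed = seeds[2],
                                             coupling_strength = config$simulate$coupling_strength)
      env$mask <- attr(env$volumes, "mask")
    }
  })
  stage("ecm", function() {
    dropped <- 0L; nonconv <- 0L
    ecm_one <- function(vol) {
      m <- fast_ecm(vol, env$mask, tol = config$ecm$tol, max_iter = config$ecm$max_iter)
      dropped <<- dropped + length(attr(m, "dropped") %||% integer(0))
      if (!isTRUE(m$converged)) nonconv <<- nonconv + 1L
      gaussianize_map(m)
    }
    env$maps_t1 <- lapply(env$volumes, function(v) ecm_one(v$t1))
    env$maps_t2 <- lapply(env$volumes, function(v) ecm_one(v$t2))
    masks <- lapply(c(env$maps_t1, env$maps_t2), function(m) m$mask$data)
    common <- Reduce(`&`, masks)
    if (!all(common == env$mask$data)) {
      cm <- brain_mask(common, env$mask$voxel_size_mm, env$mask$origin_mm)
      env$maps_t1 <- lapply(env$maps_t1, restrict_map, mask = cm)
      env$maps_t2 <- lapply(env$maps_t2, restrict_map, mask = cm)
      env$mask <- cm
    }
    report$counts$voxels_dropped <<- dropped
    report$counts$nonconverged_scans <<- nonconv
  })
  stage("residualize", function() {
    env$maps_t1 <- residualize_motion(env$maps_t1, env$cohort$motion_t1)
    env$maps_t2 <- residualize_motion(env$maps_t2, env$cohort$motion_t2)
  })
  stage("voxelwise", function() {
    env$stat <- lapply(setNames(nm = config$model$dimensions), function(dim)
      voxelwise_crosslag(env$maps_t1, env$maps_t2, env$cohort, dim,
                         covariates = config$model$covariates))
    report$counts$fit_failures <<- sum(vapply(env$stat, `[[`, numeric(1), "n_failed"))
  })
  stage("cluster_inference", function() {
    inf <- config$inference
    env$cluster <- list()
    for (dim in config$model$dimensions) {
      sm <- estimate_smoothness(residual_maps(env$stat[[dim]]))
      for (contrast in c("CL1", "CL2")) {
        key <- paste(dim, contrast, sep = "_")
        env$cluster[[key]] <- cluster_inference(
          env$stat[[dim]][[paste0("z_", contrast)]], env$stat[[dim]]$mask, sm,
          forming_p = inf$forming_p, alpha = inf$alpha,
          n_contrasts = inf$n_contrasts, connectivity = inf$connectivity)
      }
    }
    report$clusters <<- lapply(env$cluster, `[[`, "table")
    report$counts$clusters_formed <<- sum(vapply(env$cluster, function(cl)
      nrow(cl$table), numeric(1)))
  })
  stage("robustness", function() {
    rb <- config$robustness
    out <- list()
    if (isTRUE(rb$wilcoxon)) {
      out$wilcoxon <- list(
        inattention = wilcoxon_change(env$cohort$inatt_t1, env$cohort$inatt_t2),
        hyperactivity = wilcoxon_change(env$cohort$hyper_t1, env$cohort$hyper_t2))
    }
    sig <- list()
    for (key in names(env$cluster)) {
      tab <- env$cluster[[key]]$table
      if (any(tab$significant))
        sig[[key]] <- env$cluster[[key]]$voxels[which(tab$significant)]
    }
    out$cluster_followup <- list()
    for (key in names(sig)) {
      dim <- sub("_CL[12]$", "", key)
      cols <- if (dim == "inattention") c("inatt_t1", "inatt_t2") else c("hyper_t1", "hyper_t2")
      for (ci in seq_along(sig[[key]])) {
        vox <- sig[[key]][[ci]]
        f1 <- extract_cluster_mean(env$maps_t1, vox)
        f2 <- extract_cluster_mean(env$maps_t2, vox)
        X <- env$cohort[, config$model$covariates, drop = FALSE]
        fu <- list(primary = fit_crosslag(env$cohort[[cols[1]]], env$cohort[[cols[2]]], f1, f2, X))
        if (isTRUE(rb$zero_exclusion)) {
          keep <- !(env$cohort[[cols[1]]] == 0 & env$cohort[[cols[2]]] == 0)
          if (sum(keep) >= 10 + ncol(X))
            fu$zero_excluded <- fit_crosslag(env$cohort[[cols[1]]][keep],
                                             env$cohort[[cols[2]]][keep],
                                             f1[keep], f2[keep], X[keep, , drop = FALSE])
        }
        if (isTRUE(rb$trimming)) {
          trimmed <- trim_interscan(cbind(env$cohort, .f1 = f1, .f2 = f2), rb$trim_frac)
          fu$trimmed <- fit_crosslag(trimmed[[cols[1]]], trimmed[[cols[2]]],
                                     trimmed$.f1, trimmed$.f2,
                                     trimmed[, config$model$covariates, drop = FALSE])
        }
        if (isTRUE(rb$zip) && nrow(env$cohort) >= 30) {
          count_X <- cbind(baseline = env$cohort[[cols[1]]], conn_t1 = f1,
                           as.matrix(X))
          zero_X <- if (identical(rb$zip_zero_predictors, "full")) count_X
                    else cbind(conn_t1 = f1)
          fu$zip <- fit_zip(env$cohort[[cols[2]]], count_X, zero_X)
        }
        out$cluster_followup[[sprintf("%s_cluster%d", key, ci)]] <- fu
      }
    }
    report$robustness <<- out
  })
  stage("artifacts", function() {
    if (is.null(config$output_dir)) return(invisible(NULL))
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (key in names(env$cluster)) {
      p <- file.path(config$output_dir, sprintf("clusters_%s.csv", key))
      write.csv(env$cluster[[key]]$table, p, row.names = FALSE)
      paths <- c(paths, p)
      zp <- file.path(config$output_dir, sprintf("zmap_%s", key))
      arr <- env$stat[[sub("_CL[12]$", "", key)]][[paste0("z_", sub("^.*_", "", key))]]
      arr[is.na(arr)] <- 0
      RNifti::writeNifti(RNifti::asNifti(arr, pixdim = env$mask$voxel_size_mm),
                         paste0(zp, ".nii.gz"))
      paths <- c(paths, paste0(zp, ".nii.gz"))
    }
    p <- file.path(config$output_dir, "cohort_selected.csv")
    write_cohort_csv(env$cohort, p)
    paths <- c(paths, p)
    report$provenance$files <<- data.frame(path = paths,
                                           md5 = unname(tools::md5sum(paths)),
                                           stringsAsFactors = FALSE)
  })
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: status = %s\n", x$status))
  for (nm in names(x$stages))
    cat(sprintf("  %-18s %-7s %7.2fs\n", nm, x$stages[[nm]]$status, x$stages[[nm]]$seconds))
  nsig <- sum(vapply(x$clusters, function(tb) sum(tb$significant), numeric(1)))
  cat(sprintf("  %d cluster table(s), %d significant cluster(s)\n",
              length(x$clusters), nsig))
  invisible(x)
}

# md5 of a serialized R object (provenance hashing)
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Familywise-error calibration experiment on null synthetic cohorts
#'
#' Repeatedly simulates cohorts whose symptom scores are independent of
#' smooth Gaussian centrality maps, runs the voxelwise cross-lagged mapping
#' and random-field cluster inference for one contrast, and reports the
#' fraction of simulations yielding any significant cluster - the empirical
#' familywise false-positive rate that the procedure is designed to keep at
#' or below `alpha`.
#'
#' @param n_runs number of null simulations.
#' @param n_subjects subjects per simulated cohort.
#' @param grid 3D grid shape of the simulated maps.
#' @param fwhm_vox smoothness of the simulated maps (FWHM, voxels).
#' @param forming_p cluster-forming one-sided p threshold.
#' @param alpha per-contrast familywise level tested.
#' @param dimension symptom dimension used for the fixed contrast (CL2:
#'   baseline connectivity to follow-up symptoms).
#' @param connectivity cluster neighbor rule.
#' @param seed master seed.
#' @return list: `fp_rate`, `mc_se` (binomial Monte-Carlo standard error),
#'   `n_runs`, `any_significant` (logical per run), `n_clusters_total`.
#' @export
fwe_null_experiment <- function(n_runs = 200, n_subjects = 60, grid = c(20, 20, 20),
                                fwhm_vox = 2, forming_p = 0.001, alpha = 0.05,
                                dimension = "inattention", connectivity = 26,
                                seed = 1L) {
  seeds <- matrix(derive_seeds(seed, 3L * n_runs), ncol = 3)
  mask <- brain_mask(array(TRUE, grid))
  any_sig <- logical(n_runs)
  n_clusters <- 0L
  for (r in seq_len(n_runs)) {
    cohort <- generate_cohort(cohort_params(n_subjects = n_subjects, seed = seeds[r, 1]),
                              network = NULL)$cohort
    F1 <- simulate_smooth_maps(n_subjects, mask, fwhm_vox, seed = seeds[r, 2])
    F2 <- simulate_smooth_maps(n_subjects, mask, fwhm_vox, seed = seeds[r, 3])
    sm <- voxelwise_crosslag(F1, F2, cohort, dimension)
    smooth <- estimate_smoothness(residual_maps(sm))
    cl <- cluster_inference(sm$z_CL2, sm$mask, smooth, forming_p = forming_p,
                            alpha = alpha, n_contrasts = 1,
                            connectivity = connectivity)
    any_sig[r] <- any(cl$table$significant)
    n_clusters <- n_clusters + nrow(cl$table)
  }
  rate <- mean(any_sig)
  list(fp_rate = rate, mc_se = sqrt(rate * (1 - rate) / n_runs), n_runs = n_runs,
       any_significant = any_sig, n_clusters_total = n_clusters)
}
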