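#' Fit a two-timepoint autoregressive cross-lagged path model
#'
#' Fits, on fully z-scored variables, the saturated two-equation path model
#' for one symptom/connectivity pair:
#' \deqn{S_2 = \beta_{AR1} S_1 + \beta_{CL2} F_1 + \gamma_S X + \epsilon_S}
#' \deqn{F_2 = \beta_{AR2} F_1 + \beta_{CL1} S_1 + \gamma_F X + \epsilon_F}
#' Because the model is saturated, maximum-likelihood point estimates
#' coincide with equation-wise ordinary least squares, which is how the fit
#' is computed. Standard errors are normal-theory OLS standard errors with
#' the residual degrees of freedom `n - p` per equation (a structural
#' equation modeling ML fit would differ only by the factor
#' `sqrt(n / (n - p))`); `z = estimate / se` and p-values are two-sided
#' standard-normal tails. The contemporaneous baseline association
#' `beta_CS1` is reported as the partial correlation of `S1` and `F1` given
#' the covariates, and `beta_CS2` as the correlation of the two equations'
#' residuals.
#'
#' @param S1,S2 symptom scores at baseline and follow-up.
#' @param F1,F2 connectivity values at baseline and follow-up.
#' @param X optional covariate matrix or data.frame (e.g., mean age, sex,
#'   interscan interval, medication code); each column is z-scored.
#' @return object of class `crosslag_fit` with elements `paths` (data.frame
#'   with rows AR1, AR2, CL1, CL2, CS1, CS2 and columns estimate, se, z, p),
#'   `covariates` (per-equation standardized covariate effects), `n`, and
#'   `residuals` (per-equation OLS residual vectors).
#' @export
fit_crosslag <- function(S1, S2, F1, F2, X = NULL) {
  vars <- list(S1 = S1, S2 = S2, F1 = F1, F2 = F2)
  n <- length(S1)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (length(v) != n) stopf("all variables must have equal length")
    if (anyNA(v) || any(!is.finite(v))) stopf("missing or non-finite values in '%s' (complete cases only)", nm)
  }
  Xm <- NULL
  if (!is.null(X)) {
    Xm <- as.matrix(X)
    if (nrow(Xm) != n) stopf("covariates must have one row per subject")
    if (anyNA(Xm)) stopf("missing values in covariates (complete cases only)")
    if (is.null(colnames(Xm))) colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
  }
  q <- if (is.null(Xm)) 0L else ncol(Xm)
  if (n < 10L + q) stopf("need at least %d subjects (have %d)", 10L + q, n)
  for (nm in names(vars)) vars[[nm]] <- zscore_vec(vars[[nm]], nm)
  if (!is.null(Xm)) for (j in seq_len(q)) Xm[, j] <- zscore_vec(Xm[, j], colnames(Xm)[j])

  eqS <- ols_equation(vars$S2, cbind(S1 = vars$S1, F1 = vars$F1), Xm)
  eqF <- ols_equation(vars$F2, cbind(F1 = vars$F1, S1 = vars$S1), Xm)

  # contemporaneous paths as (partial) correlations with t-based SEs
  P <- cbind(rep(1, n), Xm)
  qrP <- qr(P)
  rs <- qr.resid(qrP, vars$S1)
  rf <- qr.resid(qrP, vars$F1)
  cs1 <- cor(rs, rf)
  df1 <- n - 2L - q
  cs2 <- cor(eqS$residuals, eqF$residuals)
  df2 <- n - 4L - q
  cs_row <- function(r, df) {
    se <- sqrt((1 - r^2) / df)
    c(estimate = r, se = se, z = r / se, p = 2 * pnorm(-abs(r / se)))
  }
  paths <- rbind(
    AR1 = eqS$coef["S1", ],
    AR2 = eqF$coef["F1", ],
    CL1 = eqF$coef["S1", ],
    CL2 = eqS$coef["F1", ],
    CS1 = cs_row(cs1, df1),
    CS2 = cs_row(cs2, df2))
  structure(list(paths = as.data.frame(paths), n = n,
                 covariates = list(symptom_eq = eqS$covariates,
                                   connectivity_eq = eqF$covariates),
                 residuals = list(symptom_eq = eqS$residuals,
                                  connectivity_eq = eqF$residuals),
                 df = eqS$df),
            class = "crosslag_fit")
}

# one OLS equation on z-scored data; returns coefficient table for the two
# focal predictors and the covariate block
ols_equation <- function(y, focal, Xm) {
  D <- cbind(`(Intercept)` = 1, focal, Xm)
  fit <- lm.fit(D, y)
  p <- ncol(D)
  n <- length(y)
  df <- n - p
  if (fit$rank < p) stopf("design matrix is rank deficient (collinear predictors)")
  res <- fit$residuals
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(D)))
  se <- sqrt(sigma2 * diag(XtXinv))
  est <- fit$coefficients
  z <- est / se
  tab <- cbind(estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)))
  rownames(tab) <- colnames(D)
  focal_names <- colnames(focal)
  cov_names <- setdiff(rownames(tab), c("(Intercept)", focal_names))
  list(coef = tab[focal_names, , drop = FALSE],
       covariates = as.data.frame(tab[cov_names, , drop = FALSE]),
       residuals = res, df = df)
}

#' @export
print.crosslag_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cross-lagged panel model fit (n = %d)\n", x$n))
  tab <- x$paths
  tab$p <- format.pval(tab$p, digits = digits, eps = 1e-4)
  print(format(tab, digits = digits))
  invisible(x)
}

#' Simulate standardized cross-lagged panel data
#'
#' Draws continuous data exactly from the standardized saturated path model:
#' `(S1, F1)` standard bivariate normal with correlation `cs1`, follow-up
#' variables as the linear combinations with residual variances chosen so
#' every variable has unit variance, hence the supplied coefficients are the
#' true standardized path coefficients. Used for closed-loop parameter
#' recovery and confidence-interval calibration of [fit_crosslag()].
#'
#' @param n subjects.
#' @param beta_ar1,beta_ar2 autoregressive coefficients.
#' @param beta_cl1,beta_cl2 cross-lag coefficients (`beta_cl2`: baseline
#'   connectivity to follow-up symptoms).
#' @param cs1 baseline correlation of `S1` and `F1`.
#' @param n_covariates number of standard-normal null covariates appended.
#' @param seed integer seed.
#' @return data.frame with columns S1, S2, F1, F2 and any covariates.
#' @export
simulate_crosslag_data <- function(n, beta_ar1 = 0.5, beta_ar2 = 0.4,
                                   beta_cl1 = 0.1, beta_cl2 = -0.3, cs1 = 0.2,
                                   n_covariates = 0L, seed = 1L) {
  res_var <- function(ba, bc) {
    v <- 1 - (ba^2 + bc^2 + 2 * ba * bc * cs1)
    if (v <= 0) stopf("coefficients imply nonpositive residual variance")
    v
  }
  vS <- res_var(beta_ar1, beta_cl2)
  vF <- res_var(beta_ar2, beta_cl1)
  with_seed(seed, {
    S1 <- rnorm(n)
    F1 <- cs1 * S1 + sqrt(1 - cs1^2) * rnorm(n)
    S2 <- beta_ar1 * S1 + beta_cl2 * F1 + sqrt(vS) * rnorm(n)
    F2 <- beta_ar2 * F1 + beta_cl1 * S1 + sqrt(vF) * rnorm(n)
    out <- data.frame(S1 = S1, S2 = S2, F1 = F1, F2 = F2)
    if (n_covariates > 0)
      for (j in seq_len(n_covariates)) out[[paste0("x", j)]] <- rnorm(n)
    out
  })
}

#' Voxelwise cross-lagged mapping
#'
#' Applies [fit_crosslag()] at every in-mask voxel, using that voxel's
#' baseline and follow-up connectivity values as `F1`/`F2` and one symptom
#' dimension as `S1`/`S2`, with covariates mean age, sex, interscan interval
#' and medication. Computation is vectorized across voxels via the
#' Frisch-Waugh-Lovell decomposition, and per-voxel coefficients and
#' standard errors are identical to calling [fit_crosslag()] on that voxel's
#' data. The per-voxel t-statistics are mapped to standard-normal deviates
#' with [t_to_z()] (so null z-maps are exactly standard normal marginally,
#' as Gaussian random field inference assumes).
#'
#' @param maps_t1,maps_t2 per-subject maps: either lists of residualized
#'   [centrality_map]s or subjects-by-voxels matrices carrying a `"mask"`
#'   attribute (see [stack_maps()], [simulate_smooth_maps()]).
#' @param cohort cohort table with the symptom and covariate columns.
#' @param dimension `"inattention"` or `"hyperactivity"`.
#' @param covariates cohort columns used as covariates of no interest.
#' @return object of class `stat_maps`: 3D arrays `z_CL1`, `z_CL2`,
#'   `beta_CL1`, `beta_CL2` (NA outside the mask), per-equation residual
#'   matrices for smoothness estimation, the mask, the equation residual
#'   degrees of freedom and the count of failed voxels.
#' @export
voxelwise_crosslag <- function(maps_t1, maps_t2, cohort,
                               dimension = c("inattention", "hyperactivity"),
                               covariates = c("mean_age", "sex", "interval", "medication")) {
  dimension <- match.arg(dimension)
  F1 <- if (is.list(maps_t1)) stack_maps(maps_t1) else maps_t1
  F2 <- if (is.list(maps_t2)) stack_maps(maps_t2) else maps_t2
  mask <- attr(F1, "mask")
  mask2 <- attr(F2, "mask")
  if (is.null(mask)) stopf("maps_t1 must carry a mask")
  if (!is.null(mask2) && !all(mask$data == mask2$data)) stopf("grid/mask mismatch between timepoints")
  n <- nrow(F1)
  if (nrow(F2) != n || nrow(cohort) != n) stopf("subject count mismatch between maps and cohort")
  sym_cols <- switch(dimension, inattention = c("inatt_t1", "inatt_t2"),
                     hyperactivity = c("hyper_t1", "hyper_t2"))
  S1 <- zscore_vec(cohort[[sym_cols[1]]], sym_cols[1])
  S2 <- zscore_vec(cohort[[sym_cols[2]]], sym_cols[2])
  q <- length(covariates)
  Xm <- NULL
  if (q) {
    Xm <- vapply(covariates, function(cn) zscore_vec(cohort[[cn]], cn), numeric(n))
  }
  p_total <- 1L + q + 2L
  df <- n - p_total
  if (df < 1L) stopf("too few subjects for the covariate set")

  # z-score maps per voxel; zero-variance voxels fail
  sd1 <- apply(F1, 2, sd); sd2 <- apply(F2, 2, sd)
  ok <- sd1 > 0 & sd2 > 0
  F1z <- scale(F1[, ok, drop = FALSE])
  F2z <- scale(F2[, ok, drop = FALSE])

  # Frisch-Waugh-Lovell: residualize everything on [1, X]
  P <- cbind(rep(1, n), Xm)
  qrP <- qr(P)
  a <- qr.resid(qrP, S1)          # shared predictor
  yS <- qr.resid(qrP, S2)
  B1 <- qr.resid(qrP, F1z)
  B2 <- qr.resid(qrP, F2z)

  aa <- sum(a^2)
  ab <- as.numeric(crossprod(B1, a))
  bb <- colSums(B1^2)
  det <- aa * bb - ab^2
  good <- det > .Machine$double.eps * aa * pmax(bb, 1)

  # symptom equation: S2 ~ S1 + F1v (+X)  -> beta_AR1, beta_CL2
  ay <- sum(a * yS)
  by <- as.numeric(crossprod(B1, yS))
  bAR1 <- (bb * ay - ab * by) / det
  bCL2 <- (aa * by - ab * ay) / det
  rssS <- sum(yS^2) - (bAR1 * ay + bCL2 * by)
  seCL2 <- sqrt(pmax(rssS, 0) / df * aa / det)
  resS <- matrix(yS, n, ncol(B1)) - outer(a, bAR1) - B1 * rep(bCL2, each = n)

  # connectivity equation: F2v ~ F1v + S1 (+X) -> beta_AR2, beta_CL1
  ayF <- as.numeric(crossprod(B2, a))
  byF <- colSums(B1 * B2)
  yyF <- colSums(B2^2)
  bAR2 <- (aa * byF - ab * ayF) / det
  bCL1 <- (bb * ayF - ab * byF) / det
  rssF <- yyF - (bAR2 * byF + bCL1 * ayF)
  seCL1 <- sqrt(pmax(rssF, 0) / df * bb / det)
  resF <- B2 - B1 * rep(bAR2, each = n) - outer(a, bCL1)

  zCL2 <- t_to_z(bCL2 / seCL2, df)
  zCL1 <- t_to_z(bCL1 / seCL1, df)
  bad <- !good | !is.finite(zCL1) | !is.finite(zCL2)
  n_failed <- sum(!ok) + sum(bad)
  for (v in c("bCL1", "bCL2", "zCL1", "zCL2"))
    assign(v, replace(get(v), bad, NA_real_))

  to_arr <- function(vals) {
    full <- rep(NA_real_, mask$n_voxels)
    full[ok] <- vals
    arr <- array(NA_real_, dim = dim(mask$data))
    arr[mask$data] <- full
    arr
  }
  structure(list(z_CL1 = to_arr(zCL1), z_CL2 = to_arr(zCL2),
                 beta_CL1 = to_arr(bCL1), beta_CL2 = to_arr(bCL2),
                 residuals = list(symptom_eq = resS, connectivity_eq = resF),
                 resid_ok = ok, mask = mask, df = df, n = n,
                 dimension = dimension, n_failed = n_failed),
            class = "stat_maps")
}

#' Extract per-subject residual maps from a voxelwise fit
#'
#' Returns the OLS residuals of one path-model equation as a
#' subjects-by-voxels matrix with its (possibly reduced) mask attached, in
#' the form expected by [estimate_smoothness()].
#'
#' @param x a `stat_maps` object from [voxelwise_crosslag()].
#' @param equation `"connectivity_eq"` (default; residuals carry the spatial
#'   smoothness of the connectivity maps) or `"symptom_eq"`.
#' @return matrix with attribute `"mask"`.
#' @export
residual_maps <- function(x, equation = c("connectivity_eq", "symptom_eq")) {
  equation <- match.arg(equation)
  R <- x$residuals[[equation]]
  keep <- x$mask$data
  keep[which(x$mask$data)[!x$resid_ok]] <- FALSE
  attr(R, "mask") <- brain_mask(keep, voxel_size_mm = x$mask$voxel_size_mm,
                                origin_mm = x$mask$origin_mm)
  R
}

#' @export
print.stat_maps <- function(x, ...) {
  cat(sprintf("stat_maps [%s]: %d subjects, %d voxels, df = %d, %d failed voxel(s)\n",
              x$dimension, x$n, x$mask$n_voxels, x$df, x$n_failed))
  invisible(x)
}
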