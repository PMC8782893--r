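---
title: "Methods: centrality mapping, cross-lagged modeling, and cluster inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centrality mapping, cross-lagged modeling, and cluster inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocrosslag)
```

## The scientific question

Cross-sectional studies of attention-deficit/hyperactivity disorder (ADHD)
repeatedly report altered resting-state functional connectivity, but a
cross-section cannot say whether a connectivity difference is a *risk
factor* for later symptoms or a *consequence* of having them. With two
scans and two symptom assessments per child, an autoregressive cross-lagged
panel model separates the two directions: does baseline brain connectivity
predict follow-up symptoms beyond the stability of symptoms themselves, and
does baseline symptom load predict follow-up connectivity beyond the
stability of connectivity?

`neurocrosslag` implements that design end to end: a voxelwise connectivity
summary (eigenvector centrality), the voxelwise path model, cluster-level
inference under Gaussian random field (GRF) theory, the associated
robustness battery, and — because longitudinal clinical imaging data are
rarely shareable — a synthetic-data module with analytic ground truth that
the entire pipeline is validated against.

## Eigenvector centrality mapping

Each voxel is a node in a weighted graph over all in-mask voxels; its
centrality is its entry in the principal eigenvector of the connectivity
matrix $M$. For Perron–Frobenius to guarantee a unique, strictly positive
eigenvector, $M$ must be nonnegative. We use a rectified correlation: for
time series standardized to mean 0 and unit variance ($n-1$ denominator),
split each series into its positive and negative parts, $x^+ = \max(x, 0)$,
$x^- = \max(-x, 0)$, and define

$$M_{xy} = \frac{\langle x^+, y^+\rangle + \langle x^-, y^-\rangle}{T - 1}.$$

$M$ is symmetric, entrywise nonnegative, has unit diagonal, equals 1 for
identical series and 0 for exactly anti-correlated ones. Crucially,
$M = (Z^+ Z^{+\top} + Z^- Z^{-\top})/(T-1)$, so the power-iteration product
$Mv$ is computable from the two rectified series matrices in
$O(n_{\text{vox}} T)$ time and memory without ever materializing the
$n_{\text{vox}} \times n_{\text{vox}}$ matrix (`rectified_matvec()`,
`fast_ecm()`). The literature describing this rectified-correlation variant
does not print a formula; the definition above is this package's concrete
choice, and the dense oracle used in tests (`brute_force_ecm()`) applies
the identical formula through an independent code path. If the original
construction turns out to rectify the correlation itself
($\max(r, 0)$), the matrix-free trick no longer applies exactly; we
deliberately keep the version that preserves the matrix-free contract.

Numerical choices: power iteration starts from the uniform positive vector,
renormalizes to unit Euclidean norm each step, and stops when successive
iterates differ by less than `tol = 1e-9` (Euclidean), far below map-level
noise, or at `max_iter = 1000`. On a degenerate leading eigenspace (e.g.,
mutually anti-correlated series rectify to the identity) the uniform start
is already a fixed point and is returned — a deterministic, documented
tie-break that the dense solver replicates. Constant voxel series cannot be
standardized; they are dropped from the mask and counted.

For second-level modeling, each subject's map is rank-transformed to a
Gaussian shape across voxels (Blom offsets,
$\Phi^{-1}((r - 3/8)/(n + 1/4))$, ties sharing average ranks) and then
residualized voxelwise across subjects on that scan's mean RMS motion,
separately per timepoint. Gaussianization is *within subject across voxels*
(the map is what gets Gaussianized); an alternative convention operates per
voxel across subjects, and the across-subject residualization step already
provides the centering that convention would add.

## The cross-lagged panel model

For one symptom dimension $S$ (inattention or hyperactivity/impulsivity,
counts 0–9) and one connectivity value $F$ (a voxel or a cluster mean), on
fully z-scored variables:

$$S_2 = \beta_{AR1} S_1 + \beta_{CL2} F_1 + \gamma_S X + \epsilon_S,
\qquad
F_2 = \beta_{AR2} F_1 + \beta_{CL1} S_1 + \gamma_F X + \epsilon_F,$$

with covariates $X$ = mean age across timepoints, sex, interscan interval,
and a linear medication code (0/1/2), included in both equations. The model
is saturated, so maximum-likelihood point estimates coincide with
equation-wise ordinary least squares; that is how `fit_crosslag()` computes
them, with normal-theory standard errors at $n - p$ residual degrees of
freedom (an SEM ML fit differs only by the factor $\sqrt{n/(n-p)}$). The
contemporaneous associations are reported as $\beta_{CS1}$, the partial
correlation of $S_1$ and $F_1$ given $X$, and $\beta_{CS2}$, the
correlation of the two equations' residuals; their parameterization is not
fixed by the saturated model, and this choice mirrors how the double-headed
baseline and residual paths are usually drawn. Symptom counts enter the
path model as continuous variables; count-aware modeling is the robustness
module's job.

`voxelwise_crosslag()` maps the fit over all voxels via the
Frisch–Waugh–Lovell decomposition (everything residualized on $[1, X]$,
then closed-form 2-predictor solves vectorized across voxels); per-voxel
coefficients and standard errors are *identical* to `fit_crosslag()` at
that voxel, which is tested exactly. One deliberate refinement: the
per-voxel $t = \hat\beta/\mathrm{se}$ statistics are converted to exact
standard-normal deviates, $z = \Phi^{-1}(F_{t,\nu}(t))$, before
thresholding. GRF inference assumes Gaussian unit-variance fields; at
$n \approx 60$–170 the raw $t$ tails are heavy enough to inflate the
familywise error noticeably, and the conversion removes that distortion at
no cost.

## Cluster-level inference

Maps are thresholded at the one-sided $p \le 0.001$ normal quantile in each
direction ($u \approx 3.09$), connected components are formed under
26-connectivity (configurable to 6/18), and each cluster of extent $k$
receives a corrected p-value from the expected Euler characteristic of a 3D
Gaussian field:

$$E[m] = R \,(4\ln 2)^{3/2} (2\pi)^{-2} (u^2 - 1) e^{-u^2/2}, \qquad
P(n \ge k) = e^{-\beta k^{2/3}},$$

with $R$ the resel count from the estimated smoothness, $\beta$ set so the
extent tail's mean equals the expected cluster size
$E[N]/E[m]$, and $p_{\text{FWE}} = 1 - \exp(-E[m]\, P(n \ge k))$. Only the
leading 3D resel term is used; lower-dimensional boundary corrections are
omitted (a logged simplification — on the small masks this package targets,
the Monte-Carlo calibration below bounds the resulting error). Smoothness is
estimated from the per-subject residual maps of the connectivity equation:
residuals are standardized per voxel, the pooled variance $v$ of spatial
first differences gives the lag-one autocorrelation $\rho = 1 - v/2$, and
under a Gaussian autocorrelation the kernel FWHM per axis is
$\Delta\sqrt{2\ln 2 / (-\ln\rho)}$. A known 6 mm kernel on 3 mm voxels is
recovered within 15% per axis in the test suite.

Two accounting decisions matter for error control:

* **Signs.** Clusters are formed per direction and reported signed, but the
  corrected p-value doubles the expected cluster count and suprathreshold
  volume (`two_sided = TRUE`), so the familywise error of one *contrast* is
  controlled at $\alpha$ across both directions. Applying $\alpha$ per sign
  would silently run at $2\alpha$ per contrast.
* **Contrasts.** The four contrasts of interest (two cross-lag paths × two
  symptom dimensions) are Bonferroni-corrected:
  $p < 0.05/4 = 0.0125$ per cluster.

At the smoothness this package simulates (FWHM ≈ 2 voxels), the
leading-term Euler characteristic overpredicts the *count* of small
clusters on a lattice by roughly a factor of two, while the extent
exceedance at upper percentiles — the quantity FWE control actually uses —
is accurate; both facts are pinned down by Monte-Carlo tests, and the
familywise false-positive rate of the full procedure on null cohorts is
verified to stay at or below 0.05 (empirically ~0.02–0.04).

## The synthetic cohort and what it does (not) emulate

No clinical data ship with the package; `generate_cohort()` +
`generate_paired_volumes()` produce a cohort whose marginals match the
study population this pipeline targets, with complete ground truth:

* **Demographics.** Baseline age $\sim N(10.74, 2.54^2)$ years clamped to
  the 5–18 recruitment window; 33.53% female; interscan interval from a
  log-normal moment-matched to mean 2.56, SD 1.5 years and clamped to
  0.75–6.84 (a truncated normal with these moments would bias the mean up
  by ~0.3 y, misplacing the follow-up age of 13.3 y); medication code
  probabilities (0.55, 0.15, 0.30) approximating 35%/40% medicated per
  timepoint; mean RMS motion $N(0.20, 0.14^2)$ and $N(0.15, 0.10^2)$
  floored at 0.01, independent of connectivity by default with an optional
  contamination coefficient so residualization can be tested under both a
  pure-nuisance and a confounded regime.
* **Symptoms.** A persistent asymptomatic class (structural zeros at both
  timepoints) plus Poisson counts capped at 9. Follow-up log-rate is linear
  in the baseline count and in the subject's standardized baseline
  target-region connectivity $C$ (the planted cross-lag), with optional
  sex/age/interval effects defaulting to zero (known nulls for the
  covariate-adjustment code paths). Class probabilities 0.2148/0.2955 and
  intercepts 0.5668/−0.0283 were solved analytically (Gauss–Hermite
  integration over $C$; see `expected_zero_both()`) so that zero-at-both
  fractions are 22.16% (inattention) and 31.74% (hyperactivity/impulsivity),
  inattention is stable in expectation, and hyperactivity declines to ~60%
  of its baseline mean — the documented developmental courses of the two
  dimensions. No generative symptom model is published for this design;
  these are calibration choices, frozen once.
* **Two families.** The zero-inflated ("zip") family above gives count
  realism and closed-loop tests of the ZIP robustness model. A second
  "gaussian" family generates the follow-up count as a linear predictor
  plus Gaussian noise, rounded and clamped — the only way a *linear*
  standardized cross-lag weight is exactly recoverable by the path model,
  which is what the parameter-recovery tests require. Both families are
  first-class.
* **Volumes.** Each voxel's series is a nonnegative loading-weighted
  mixture of latent signals (stationary AR(1), $\phi = 0.4$, giving
  realistic temporal autocorrelation without hemodynamic modeling) plus
  i.i.d. noise; $T = 126$ volumes by default (315 s at a 2.5 s repetition
  time). Between-subject variation scales the target network's amplitude
  by $1 + 0.25\,C$. The implied voxel-by-voxel correlation matrix is known
  in closed form, and for bivariate Gaussian series the population
  rectified similarity is
  $(\sqrt{1-r^2} + r(\pi - \arccos r))/\pi$, so
  `oracle_true_centrality()` delivers an analytic ground-truth map the
  estimator is tested against (empirical centrality converges to it as $T$
  grows; cosine similarity > 0.99 by $T = 5000$).

What the generator does **not** emulate: hemodynamic response functions,
image-level head motion or scanner-noise physics, multi-site effects,
non-stationary smoothness, or heavy-tailed spatial autocorrelation of real
BOLD data. Passing tests therefore demonstrate the *statistical* properties
of the pipeline (exactness of estimators against oracles, calibration of
error control under the stated field model), not robustness to every
artifact of real acquisitions — the same caveat that applies to any
parametric simulation study, and the reason the random-field assumptions
should be kept in mind when the pipeline is pointed at real data.

## Problem sizes used in validation

The shipped experiments run at desk scale, chosen to make each check
statistically decisive while keeping the suite fast: familywise-error
calibration on 200 null cohorts of 60 subjects over a masked
20×20×20 grid at FWHM ≈ 2 voxels; parameter recovery over 200 simulated
cohorts of 150 subjects; matrix-free-vs-dense centrality agreement over 50
random volumes (tolerances $10^{-8}$ cosine, $10^{-6}$ eigenvalue);
zero-inflated Poisson recovery over 100 replicates of $n = 2000$; exact
signed-rank enumeration up to 12 nonzero pairs. End-to-end runs on
generated volumes use 8×8×8 grids with $T = 80$, where a planted
connectivity-to-inattention effect is recovered as a significant negative
cluster overlapping the planted region.

## Known limitations

* Two timepoints only: linear change, no growth curves, no ≥3-wave models.
* One subject per family (the selection rule is implemented); no familial
  random effects.
* Complete cases only; the cohort-construction rules guarantee complete
  rows, and no imputation is attempted.
* GRF cluster inference, not permutation; no TFCE, no peak-level FWE. The
  leading-resel simplification makes cluster p-values approximate on very
  small or very rough masks — the regime is monitored by the Monte-Carlo
  calibration tests rather than hidden.
* The "impairing" qualifier of the diagnostic interview is not
  operationalizable from symptom counts; the diagnosis flag uses the
  six-symptom count rule alone.
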