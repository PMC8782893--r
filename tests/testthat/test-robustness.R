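mini_cohort <- function(...) {
  defaults <- list(subject_id = "X", family_id = "F0",
                   inatt_t1 = 0L, inatt_t2 = 0L, hyper_t1 = 0L, hyper_t2 = 0L,
                   motion_t1 = 0.1, motion_t2 = 0.1, interval = 2)
  rows <- lapply(list(...), function(r) as.data.frame(utils::modifyList(defaults, r)))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

test_that("family selection prefers symptomatic members, then lowest motion", {
  single <- mini_cohort(list(subject_id = "A", family_id = "F1"))
  expect_equal(select_family_member(single)$subject_id, "A")

  # symptomatic member wins despite higher motion
  fam <- mini_cohort(
    list(subject_id = "A", family_id = "F1", inatt_t1 = 2L, motion_t1 = 0.5, motion_t2 = 0.5),
    list(subject_id = "B", family_id = "F1", motion_t1 = 0.05, motion_t2 = 0.05))
  expect_equal(select_family_member(fam)$subject_id, "A")

  # all zero-symptom: lowest average motion wins
  fam2 <- mini_cohort(
    list(subject_id = "A", family_id = "F1", motion_t1 = 0.21, motion_t2 = 0.21),
    list(subject_id = "B", family_id = "F1", motion_t1 = 0.14, motion_t2 = 0.14))
  expect_equal(select_family_member(fam2)$subject_id, "B")

  # motion tie: lexicographically smallest id, with a logged message
  fam3 <- mini_cohort(
    list(subject_id = "B2", family_id = "F1", motion_t1 = 0.1, motion_t2 = 0.1),
    list(subject_id = "A9", family_id = "F1", motion_t1 = 0.1, motion_t2 = 0.1))
  expect_message(sel <- select_family_member(fam3), "tie")
  expect_equal(sel$subject_id, "A9")

  # order independence across families
  multi <- mini_cohort(
    list(subject_id = "A", family_id = "F2", inatt_t1 = 1L),
    list(subject_id = "B", family_id = "F1", hyper_t2 = 3L, motion_t1 = 0.4, motion_t2 = 0.4),
    list(subject_id = "C", family_id = "F1"),
    list(subject_id = "D", family_id = "F2", motion_t1 = 0.01, motion_t2 = 0.01))
  s1 <- select_family_member(multi)
  s2 <- select_family_member(multi[c(4, 2, 1, 3), ])
  expect_setequal(s1$subject_id, s2$subject_id)
  expect_setequal(s1$subject_id, c("A", "B"))
  expect_equal(attr(s1, "n_removed"), 2L)
  expect_error(select_family_member(transform(multi, motion_t2 = NA)), "motion")
})

test_that("symptom-count diagnosis applies the six-symptom rule on either dimension", {
  expect_true(dsm5_diagnosis(6, 0))
  expect_false(dsm5_diagnosis(5, 5))
  expect_true(dsm5_diagnosis(0, 9))
  expect_equal(dsm5_diagnosis(c(7, 2, 0), c(0, 2, 6)), c(TRUE, FALSE, TRUE))
  expect_error(dsm5_diagnosis(10, 0), "0, 9")
  expect_error(dsm5_diagnosis(3.5, 0), "integer")
})

test_that("signed-rank change test handles the degenerate and small exact cases", {
  x <- c(2, 3, 1, 4, 5, 0)
  w0 <- wilcoxon_change(x, x)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)
  expect_equal(w0$n_effective, 0L)

  # six pairs with differences (1, 2, 3, -1, 4, 5) vs full enumeration
  t2 <- c(5, 5, 5, 5, 5, 5)
  t1 <- t2 + c(1, 2, 3, -1, 4, 5)
  w <- wilcoxon_change(t1, t2)
  ref <- signed_rank_enum_oracle(c(1, 2, 3, -1, 4, 5))
  expect_equal(w$statistic, ref$V)
  expect_equal(w$p, ref$p, tolerance = 1e-12)
  expect_equal(w$n_effective, 6L)
})

test_that("exact signed-rank path equals exhaustive enumeration on random counts", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(5:12, 1)
    t1 <- rpois(n, 3)
    t2 <- rpois(n, 2.2)
    w <- wilcoxon_change(t1, t2)
    if (w$n_effective == 0) next
    ref <- signed_rank_enum_oracle(t1 - t2)
    expect_equal(w$statistic, ref$V, info = sprintf("rep %d", rep))
    expect_equal(w$p, ref$p, tolerance = 1e-12, info = sprintf("rep %d", rep))
  }
})

test_that("signed-rank agrees with the base implementation on both branches", {
  # no ties: base wilcox.test computes the exact distribution too
  set.seed(34)
  t1 <- c(10.2, 3.1, 5.7, 8.8, 2.2, 9.9, 4.4, 6.1)
  t2 <- t1 - c(1.1, -1.3, 3.5, 0.7, -2.2, 4.4, 0.4, -1.6)  # distinct |differences|
  w <- wilcoxon_change(t1, t2)
  ref <- wilcox.test(t1, t2, paired = TRUE, exact = TRUE)
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  # large n with ties: identical normal approximation with corrections
  t1 <- rpois(60, 4); t2 <- rpois(60, 3)
  w2 <- wilcoxon_change(t1, t2)
  ref2 <- suppressWarnings(wilcox.test(t1, t2, paired = TRUE, correct = TRUE))
  expect_equal(w2$statistic, unname(ref2$statistic))
  expect_equal(w2$p, ref2$p.value, tolerance = 1e-10)
})

test_that("zero-symptom exclusion removes exactly the zero-zero rows", {
  co <- mini_cohort(
    list(subject_id = "A", family_id = "F1", inatt_t1 = 0L, inatt_t2 = 0L),
    list(subject_id = "B", family_id = "F2", inatt_t1 = 0L, inatt_t2 = 1L),
    list(subject_id = "C", family_id = "F3", inatt_t1 = 2L, inatt_t2 = 0L))
  out <- exclude_zero_subjects(co, "inattention")
  expect_setequal(out$subject_id, c("B", "C"))
  expect_equal(attr(out, "n_removed"), 1L)
  all0 <- mini_cohort(list(subject_id = "A", family_id = "F1"),
                      list(subject_id = "B", family_id = "F2"))
  expect_equal(nrow(exclude_zero_subjects(all0, "hyperactivity")), 0)
})

test_that("default generator yields the configured zero-zero exclusion fraction", {
  p <- cohort_params(n_subjects = 5000, seed = 77)
  g <- generate_cohort(p, network = NULL)$cohort
  out <- exclude_zero_subjects(g, "inattention")
  frac <- attr(out, "n_removed") / 5000
  expect_lt(abs(frac - 0.2216), 3 * sqrt(0.2216 * (1 - 0.2216) / 5000))
})

test_that("interval trimming floors per-tail counts and is order independent", {
  set.seed(35)
  co <- data.frame(subject_id = sprintf("S%03d", 1:167),
                   interval = sample(seq(0.75, 6.84, length.out = 167)))
  out <- trim_interscan(co, 0.15)
  expect_equal(nrow(out), 117)
  expect_equal(attr(out, "n_removed"), 50L)
  expect_equal(nrow(trim_interscan(co, 0)), 167)
  co20 <- co[1:20, ]
  expect_equal(nrow(trim_interscan(co20, 0.15)), 14)
  # retained set invariant to row order; range reported
  o1 <- trim_interscan(co, 0.15)
  o2 <- trim_interscan(co[sample(167), ], 0.15)
  expect_setequal(o1$subject_id, o2$subject_id)
  expect_equal(attr(o1, "interval_range"), range(o1$interval))
  expect_error(trim_interscan(co, 0.5), "frac")
})

test_that("zero-inflation-free data reduce to the Poisson fit", {
  set.seed(36)
  x <- rnorm(800)
  y <- rpois(800, exp(0.8 + 0.4 * x))
  zf <- fit_zip(y, cbind(x = x), cbind(x = x))
  pf <- glm(y ~ x, family = poisson())
  expect_equal(zf$count_coefficients$estimate, unname(coef(pf)), tolerance = 1e-4)
  # nesting: ZIP likelihood can never fall below the Poisson-only likelihood
  expect_gte(zf$loglik, zf$loglik_poisson - 1e-8)
})

test_that("ZIP degenerate and error paths behave as documented", {
  set.seed(37)
  y_nozero <- rpois(100, 8) + 1L
  expect_warning(zf <- fit_zip(y_nozero), "unidentified")
  expect_null(zf$zero_coefficients)
  expect_equal(zf$loglik, zf$loglik_poisson)
  expect_error(fit_zip(c(-1, rep(1, 40))), "nonnegative")
  expect_error(fit_zip(rpois(10, 2)), "at least 30")
})

test_that("ZIP estimates recover generating coefficients with shrinking bias", {
  truth <- c(b0 = 1, b1 = 0.3, g0 = -1, g1 = 0.6)
  fit_at <- function(n, seed) {
    set.seed(seed)
    x <- rnorm(n)
    y <- ifelse(runif(n) < plogis(truth["g0"] + truth["g1"] * x), 0L,
                rpois(n, exp(truth["b0"] + truth["b1"] * x)))
    zf <- fit_zip(y, cbind(x = x), cbind(x = x))
    c(zf$count_coefficients$estimate, zf$zero_coefficients$estimate)
  }
  med_bias <- vapply(c(200, 1000, 5000), function(n) {
    errs <- vapply(1:9, function(s) max(abs(fit_at(n, 700 + s) - truth)), numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_bias) < 0))
  # single large fit lands near the truth with plausible uncertainty
  set.seed(38)
  x <- rnorm(3000)
  y <- ifelse(runif(3000) < plogis(-1 + 0.6 * x), 0L, rpois(3000, exp(1 + 0.3 * x)))
  zf <- fit_zip(y, cbind(x = x), cbind(x = x))
  est <- c(zf$count_coefficients$estimate, zf$zero_coefficients$estimate)
  se <- c(zf$count_coefficients$se, zf$zero_coefficients$se)
  expect_true(all(abs(est - truth) < 3.5 * se))
  expect_true(zf$converged)
  expect_gte(zf$loglik, zf$loglik_poisson)
})
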