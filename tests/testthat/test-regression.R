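make_dataset <- function(mat, subjects, prefix = "f") {
  cohort_dataset(mat, subjects, toy_panel(ncol(mat), prefix))
}

test_that("within-cohort z-normalization centers, scales and is idempotent", {
  subj <- toy_subjects(3, 0)
  ds <- make_dataset(cbind(a = c(1, 2, 3), b = c(10, 20, 60)), subj)
  nds <- znormalize_within_cohort(ds)
  expect_equal(unname(nds$measurements[, 1]), c(-1, 0, 1))
  expect_equal(colMeans(nds$measurements), c(f0001 = 0, f0002 = 0))
  expect_equal(apply(nds$measurements, 2, sd), c(f0001 = 1, f0002 = 1))
  expect_identical(znormalize_within_cohort(nds), nds)
})

test_that("constant features are excluded rather than NaN-propagated", {
  subj <- toy_subjects(3, 0)
  ds <- make_dataset(cbind(c(1, 2, 3), c(5, 5, 5)), subj)
  expect_message(nds <- znormalize_within_cohort(ds), "zero-variance")
  expect_equal(ncol(nds$measurements), 1)
  expect_equal(nds$excluded_features, "f0002")
  expect_false(anyNA(nds$measurements))
})

test_that("OLS recovers exact and degenerate fits", {
  age <- c(20, 30, 40, 50, 60, 70)
  fit <- ols_fit(2 * age, data.frame(age = age))
  expect_equal(unname(fit$beta["age"]), 2, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  fit2 <- ols_fit(rep(7, 6), data.frame(age = age))
  expect_equal(unname(fit2$beta), c(7, 0), tolerance = 1e-12)
})

test_that("OLS matches the brute-force normal-equations oracle", {
  set.seed(42)
  for (rep in 1:5) {
    X <- data.frame(a = rnorm(6), b = rnorm(6), c = rnorm(6))
    y <- rnorm(6)
    fit <- ols_fit(y, X)
    expect_equal(unname(fit$beta), drop(bf_ols(y, X)), tolerance = 1e-10)
    # residual orthogonality to the design
    expect_lt(max(abs(crossprod(cbind(1, as.matrix(X)), fit$residuals))), 1e-8)
  }
})

test_that("rank-deficient designs error naming the collinear columns", {
  set.seed(1)
  X <- data.frame(a = rnorm(6), b = rnorm(6))
  X$c <- X$a + X$b
  expect_error(ols_fit(rnorm(6), X), "collinear")
  expect_error(ols_fit(rnorm(3), data.frame(a = rnorm(3), b = rnorm(3),
                                            c = rnorm(3))), "too few")
})

test_that("permutation p-values: constant response ties give p = 1", {
  subj <- toy_subjects(10, 10)
  mat <- cbind(rep(0, 20), rnorm(20))
  ds <- cohort_dataset(mat, subj, toy_panel(2))
  # constant feature is excluded by normalization; test the tie rule on the
  # raw engine instead with a pre-normalized dataset
  ds$normalized <- TRUE
  res <- permutation_pvalues(ds, drivers = "hcv", n_perm = 50, seed = 1)
  expect_equal(res$perm_p[res$feature_id == "f0001"], 1)
})

test_that("permutation p-values are reproducible and detect strong effects", {
  subj <- toy_subjects(25, 25)
  panel <- toy_panel(5)
  eff <- data.frame(feature_id = "f0001", driver = "hcv", beta = 2)
  ds <- simulate_measurements(subj, panel, eff, seed = 12)
  r1 <- permutation_pvalues(ds, drivers = "hcv", n_perm = 200, seed = 7)
  r2 <- permutation_pvalues(ds, drivers = "hcv", n_perm = 200, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$perm_p[r1$feature_id == "f0001"], 0)
  expect_error(permutation_pvalues(ds, drivers = "hcv", n_perm = 0),
               "n_perm")
})

test_that("freedman-lane scheme agrees with covariate permutation on null", {
  subj <- toy_subjects(30, 30)
  ds <- simulate_measurements(subj, toy_panel(40), seed = 19)
  p1 <- permutation_pvalues(ds, drivers = "hcv", n_perm = 300, seed = 3)
  p2 <- permutation_pvalues(ds, drivers = "hcv", n_perm = 300, seed = 3,
                            scheme = "freedman_lane")
  expect_equal(mean(p1$perm_p < 0.05), mean(p2$perm_p < 0.05),
               tolerance = 0.05)
  expect_gt(cor(p1$perm_p, p2$perm_p), 0.9)
})

test_that("covariates constant within a cohort are absent, not zero", {
  subj <- toy_subjects(10, 10, cohort = "aging")
  ds <- simulate_measurements(subj, toy_panel(3), seed = 2)
  res <- permutation_pvalues(ds, n_perm = 50, seed = 1)
  expect_false("hiv" %in% res$covariate)  # nobody HIV+ in the aging cohort
  expect_false("hcv" %in% res$covariate)
  expect_true(all(c("age", "sex") %in% res$covariate))
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  q <- qvalue_select(c(0.01, 0.02, 0.9), pi0 = 1)
  expect_equal(q$q, c(0.03, 0.03, 0.9), tolerance = 1e-12)
  expect_equal(qvalue_select(1)$q, 1)
  ties <- qvalue_select(rep(0.5, 100), pi0 = 1)
  expect_equal(ties$q, rep(0.5, 100), tolerance = 1e-12)
  expect_error(qvalue_select(c(0.5, 1.2)), "0, 1")
})

test_that("q-values are monotone in p and respect the BH lower bound", {
  set.seed(9)
  p <- runif(200)^1.5
  qs <- qvalue_select(p)
  pi0 <- attr(qs, "pi0")
  o <- order(p)
  expect_true(all(diff(qs$q[o]) >= -1e-12))
  # step-up estimate never undercuts the smallest achievable FDR level
  expect_true(all(qs$q >= pi0 * p - 1e-12))
  # significant set shrinks as the threshold tightens
  expect_lte(sum(qvalue_select(p, 0.05)$significant),
             sum(qvalue_select(p, 0.2)$significant))
})

test_that("detection rate increases with planted effect size", {
  subj <- toy_subjects(50, 50)
  panel <- toy_panel(40)
  rates <- vapply(c(0, 0.25, 0.5, 1.0), function(b) {
    eff <- data.frame(feature_id = panel$feature_id[1:20], driver = "hcv",
                      beta = b)
    ds <- simulate_measurements(subj, panel, eff, seed = 77)
    rr <- cohort_regression(ds, drivers = "hcv", n_perm = 200, seed = 5)
    mean(rr$significant[rr$feature_id %in% panel$feature_id[1:20]])
  }, numeric(1))
  expect_true(all(diff(rates) >= -0.05))  # non-decreasing up to MC noise
  expect_gt(rates[4], rates[1])
})
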