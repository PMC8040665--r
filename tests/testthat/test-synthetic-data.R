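test_that("generated cohorts match configured sizes, age ranges and flags", {
  subj <- generate_subjects(seed = 11)
  counts <- table(subj$cohort, subj$group)
  expect_equal(counts["aging", "case"], 60)
  expect_equal(counts["aging", "control"], 29)
  expect_equal(counts["hiv", "case"], 24)
  expect_equal(counts["hiv", "control"], 45)
  expect_equal(counts["hcv", "case"], 14)
  expect_equal(counts["hcv", "control"], 11)
  old <- subj[subj$cohort == "aging" & subj$group == "case", ]
  expect_true(all(old$age >= 61 & old$age <= 90))
  young <- subj[subj$cohort == "aging" & subj$group == "control", ]
  expect_true(all(young$age >= 22 & young$age <= 33))
  expect_true(all(subj$hiv[subj$cohort != "hiv" | subj$group != "case"] == 0))
  expect_true(all(subj$hiv[subj$cohort == "hiv" & subj$group == "case"] == 1))
  expect_true(all(subj$hcv[subj$cohort == "hcv" & subj$group == "case"] == 1))
})

test_that("subject generation is deterministic and handles edge configs", {
  expect_identical(generate_subjects(seed = 5), generate_subjects(seed = 5))
  empty <- generate_subjects(list(cohorts = list(
    hcv = list(case = list(n = 0, age = c(1, 2)),
               control = list(n = 0, age = c(1, 2))))), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(generate_subjects(list(cohorts = list(
    hcv = list(case = list(n = -1, age = c(1, 2))))), seed = 1),
    "negative")
  expect_error(generate_subjects(list(cohorts = list(
    hcv = list(case = list(n = 3, age = c(50, 40))))), seed = 1),
    "age range")
})

test_that("signaling panel enumerates the exact 12 x 7 grid per condition", {
  panel <- generate_panel()
  sig <- panel[panel$modality == "baseline_signaling", ]
  expect_equal(nrow(sig), 84)
  grid <- table(sig$cell_type, sig$signaling_param)
  expect_true(all(grid == 1))
  expect_equal(dim(grid), c(7L, 12L))
  resp <- panel[panel$modality == "stim_response", ]
  for (st in unique(resp$stimulus)) {
    expect_true(all(table(resp$cell_type[resp$stimulus == st],
                          resp$signaling_param[resp$stimulus == st]) == 1))
  }
  expect_false(anyDuplicated(panel$feature_id) > 0)
  expect_equal(nrow(panel), 357)
})

test_that("panel validation catches unknown parameters and empty blocks", {
  expect_error(generate_panel(signaling_params = c("pSTAT1", "pFAKE")),
               "unknown signaling parameter")
  no_serum <- generate_panel(analytes = character())
  expect_equal(sum(no_serum$modality == "serum_protein"), 0)
  expect_equal(signaling_pathway(c("pCREB", "IkBa", "pp38", "pSTAT4")),
               c("PSD", "PSAV", "MAPK", "STAT"))
})

test_that("null simulation gives centered independent features", {
  subj <- toy_subjects(100, 100)
  panel <- toy_panel(50)
  ds <- simulate_measurements(subj, panel, noise_sd = 1, seed = 3)
  mu <- colMeans(ds$measurements)
  se <- apply(ds$measurements, 2, sd) / sqrt(nrow(ds$measurements))
  expect_true(all(abs(mu) < 3 * se + 1e-12))
})

test_that("single-factor block with lambda 0.9 gives Spearman near 0.81", {
  # bivariate-normal conversion: rho_s = (6 / pi) * asin(rho / 2) gives
  # 0.796 for a Pearson correlation of 0.81
  subj <- toy_subjects(200, 0)
  panel <- toy_panel(6)
  cs <- data.frame(feature_id = panel$feature_id, block = "b1", lambda = 0.9)
  ds <- simulate_measurements(subj, panel, community_spec = cs, seed = 8)
  rho <- cor(ds$measurements, method = "spearman")
  offdiag <- rho[upper.tri(rho)]
  expect_true(all(abs(offdiag - 0.81) < 0.05))
  expect_error(simulate_measurements(subj, panel,
    community_spec = data.frame(feature_id = panel$feature_id[1],
                                block = "b", lambda = 1.2), seed = 1),
    "lambda")
})

test_that("within-block correlation converges to lambda squared", {
  subj <- toy_subjects(1000, 0)
  panel <- toy_panel(8)
  for (lam in c(0.5, 0.8)) {
    cs <- data.frame(feature_id = panel$feature_id, block = "b1", lambda = lam)
    ds <- simulate_measurements(subj, panel, community_spec = cs, seed = 21)
    r <- cor(ds$measurements)
    expect_lt(abs(mean(r[upper.tri(r)]) - lam^2), 0.03)
  }
})

test_that("planted effects are recoverable by OLS with nominal CI coverage", {
  subj <- toy_subjects(50, 50)
  panel <- toy_panel(1)
  eff <- data.frame(feature_id = panel$feature_id, driver = "hcv", beta = 1)
  covered <- vapply(1:100, function(s) {
    ds <- simulate_measurements(subj, panel, eff, seed = 100 + s)
    fit <- summary(lm(ds$measurements[, 1] ~ subj$hcv))$coefficients
    abs(fit[2, "Estimate"] - 1) <= qt(0.975, 98) * fit[2, "Std. Error"]
  }, logical(1))
  expect_gte(sum(covered), 93)
})

test_that("viral load follows the floored exponential decay", {
  subj <- toy_subjects(5, 2)
  panel <- toy_panel(4)
  spec <- default_longitudinal_spec(panel)
  spec$improve_features <- character()
  long <- simulate_longitudinal_hcv(subj, panel, spec, seed = 2)
  vl <- long$viral_load
  expect_equal(vl$viral_load[vl$timepoint == "pre"], rep(1e6, 5))
  wk1 <- vl$viral_load[vl$timepoint == "wk1"]
  expect_equal(wk1, rep(max(1e6 * exp(-2), 15), 5))
  expect_true(all(vl$viral_load >= 15))
  # complete panel: every subject at every timepoint
  expect_equal(nrow(long$subjects), 5 * 7)
  expect_true(all(table(long$subjects$subject_id) == 7))
})

test_that("null longitudinal config leaves pre and post exchangeable", {
  subj <- toy_subjects(14, 0)
  panel <- toy_panel(30)
  spec <- default_longitudinal_spec(panel)
  spec$improve_features <- character()
  spec$pulse_amplitude <- 0
  long <- simulate_longitudinal_hcv(subj, panel, spec, seed = 4)
  diffs <- paired_differences(long)
  dbar <- rowMeans(diffs)
  se <- apply(diffs, 1, sd) / sqrt(ncol(diffs))
  expect_true(all(abs(dbar) < 3 * se + 1e-12))
})

test_that("planted post-treatment improvement is recovered in the mean", {
  subj <- generate_subjects(seed = 31)
  panel <- generate_panel()
  spec <- default_longitudinal_spec(panel)
  long <- simulate_longitudinal_hcv(subj, panel, spec, seed = 6)
  diffs <- paired_differences(long)
  planted <- diffs[spec$improve_features, , drop = FALSE]
  dbar <- rowMeans(planted)
  # pooled across the 13 independent planted features
  pooled_se <- sd(dbar) / sqrt(length(dbar))
  expect_lt(abs(mean(dbar) - 1.5), 3 * pooled_se)
  expect_true(all(dbar > 0))  # every planted feature moves the right way
  expect_error(simulate_longitudinal_hcv(subj[subj$cohort == "aging", ],
                                         panel, spec, seed = 1),
               "no HCV")
})

test_that("generator output tables are byte-identical for identical seeds", {
  subj <- generate_subjects(seed = 3)
  panel <- generate_panel()
  d1 <- tempfile(); d2 <- tempfile()
  for (d in c(d1, d2)) {
    ds <- simulate_measurements(subj, panel, default_effects(panel),
                                default_community_spec(panel), seed = 9)
    write_dataset(ds, d)
  }
  for (f in c("subjects.tsv", "features.tsv", "matrix.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
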