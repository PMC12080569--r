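test_that("the Japanese eGFR equation evaluates correctly", {
  expect_equal(egfr_japanese(0.80, 59, FALSE),
               194 * 0.80^(-1.094) * 59^(-0.287))
  expect_rel(egfr_japanese(0.80, 59, FALSE), 76.9, 0.01)
  # female correction factor is exactly 0.739
  expect_equal(egfr_japanese(0.9, 60, TRUE) / egfr_japanese(0.9, 60, FALSE),
               0.739)
  # power law in creatinine
  expect_equal(egfr_japanese(1.6, 60, FALSE) / egfr_japanese(0.8, 60, FALSE),
               2^(-1.094))
  expect_error(egfr_japanese(0, 60, FALSE), "positive")
})

test_that("cohort draws respect the published ranges and medians", {
  spec <- cohort_spec(n_subjects = 4000, seed = 8)
  coh <- draw_cohort(spec)
  expect_true(all(coh$WT >= 49 & coh$WT <= 118))
  expect_true(all(coh$HBA1C0 >= 5.6 & coh$HBA1C0 <= 8.8))
  expect_true(all(coh$AGE >= 37 & coh$AGE <= 75))
  expect_true(all(coh$SCR >= 0.32 & coh$SCR <= 1.50))
  expect_true(all(coh$WT_CHANGE >= -10.8 & coh$WT_CHANGE <= 6.0))
  expect_lt(abs(median(coh$WT) - 77), 2)
  expect_lt(abs(median(coh$HBA1C0) - 6.8), 0.05)
  expect_lt(abs(mean(coh$SEX == 0) - 61 / 85), 0.03)
  # eGFR derives from the creatinine/age/sex equation
  expect_equal(coh$EGFR,
               egfr_japanese(coh$SCR, coh$AGE, coh$SEX == 1))
})

test_that("random effects reproduce the published variability at scale", {
  spec <- cohort_spec(n_subjects = 10000, seed = 3)
  coh <- draw_cohort(spec)
  expect_rel(sd(log(coh$cl_f) -
                  log(covariate_cl(229.3, 0.41, coh$WT))),
             sqrt(cv_to_omega2(0.139)), 0.05)
  expect_rel(sd(log(coh$t_half_i)), sqrt(cv_to_omega2(1.039)), 0.05)
})

test_that("cohorts and event tables are reproducible under a fixed seed", {
  spec <- cohort_spec(n_subjects = 12, seed = 99)
  c1 <- draw_cohort(spec)
  c2 <- draw_cohort(spec)
  expect_identical(c1, c2)
  t1 <- generate_event_table(c1, spec)
  t2 <- generate_event_table(c2, spec)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
})

test_that("zero IIV collapses every subject onto the typical parameters", {
  spec <- cohort_spec(n_subjects = 20, seed = 4)
  coh <- draw_cohort(spec, true_pk = pk_params(omega_cl = 0),
                     true_pd = pd_params(omega_thalf = 0))
  expect_equal(coh$cl_f, covariate_cl(229.3, 0.41, coh$WT))
  expect_equal(coh$t_half_i, rep(16.1, 20))
})

test_that("default-spec event tables approximate the study's usable counts", {
  spec <- cohort_spec(seed = 2024)
  tab <- generate_event_table(draw_cohort(spec), spec)
  cnt <- event_counts(tab)
  pd_n <- cnt$n[cnt$kind == "pd_obs"]
  expect_gte(pd_n, 495); expect_lte(pd_n, 510)
  pk_usable <- sum(tab$EVID == 0 & tab$DVID == 1 & tab$BLQ == 0)
  expect_gte(pk_usable, 400); expect_lte(pk_usable, 425)
  # covariates recorded on every row; weight declines on average
  expect_false(anyNA(tab$WT))
})

test_that("noise-free generation reproduces the model exactly", {
  spec <- cohort_spec(n_subjects = 6, seed = 13, missingness = 0)
  pk0 <- pk_params(sigma_prop = 0, omega_cl = 0)
  pd0 <- pd_params(sigma_add = 0, omega_thalf = 0)
  coh <- draw_cohort(spec, pk0, pd0)
  tab <- generate_event_table(coh, spec, true_pk = pk0, true_pd = pd0)
  expect_equal(sum(tab$BLQ), 0)
  # every scheduled observation present: 6 x (5 pk + 6 pd)
  cnt <- event_counts(tab)
  expect_equal(cnt$n[cnt$kind == "pk_obs"], 30L)
  expect_equal(cnt$n[cnt$kind == "pd_obs"], 36L)
  # trough concentrations match the analytic profile for one subject
  sub <- tab[tab$ID == 1, ]
  doses <- sub[sub$EVID == 1, ]
  obs <- sub[sub$EVID == 0 & sub$DVID == 1, ]
  pred <- conc_profile(obs$TIME, cl_f = covariate_cl(229.3, 0.41, doses$WT),
                       dose_times = doses$TIME, dose_amt = doses$AMT)$conc
  expect_equal(obs$DV, pred, tolerance = 1e-10)
})
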