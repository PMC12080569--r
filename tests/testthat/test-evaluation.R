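pk_fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- make_small_table(n_subjects = 15, seed = 27)
      tab <- suppressMessages(exclude_blq(fx$table))
      cache <<- list(
        table = tab, full_table = fx$table,
        fit = suppressMessages(
          fit_pk(tab, settings = fit_settings(compute_se = FALSE,
                                              maxit = 300)))
      )
    }
    cache
  }
})

test_that("prediction correction applies the documented formulas", {
  expect_equal(prediction_correct(4, 2, 3, "proportional"), 6)
  expect_equal(prediction_correct(6.8, 6.9, 6.7, "additive"), 6.6)
  # identity when the typical prediction equals the bin median
  expect_equal(prediction_correct(3.3, 2.5, 2.5, "proportional"), 3.3)
  expect_equal(prediction_correct(6.8, 6.5, 6.5, "additive"), 6.8)
  expect_warning(out <- prediction_correct(c(4, 4), c(0, 2), c(3, 3),
                                           "proportional"),
                 "non-positive")
  expect_true(is.na(out[1]) && !is.na(out[2]))
})

test_that("VPC percentiles are ordered and reproducible under a seed", {
  fx <- pk_fit_fixture()
  bins <- c(0, 45, 76, 110)
  v1 <- suppressWarnings(run_vpc(fx$fit, n_sim = 60, bins = bins, seed = 4))
  v2 <- suppressWarnings(run_vpc(fx$fit, n_sim = 60, bins = bins, seed = 4))
  expect_identical(v1$stats, v2$stats)
  wide <- tidyr::pivot_wider(v1$stats[, c("bin", "percentile", "observed",
                                          "simulated")],
                             names_from = "percentile",
                             values_from = c("observed", "simulated"))
  expect_true(all(wide$observed_5 <= wide$observed_50 &
                    wide$observed_50 <= wide$observed_95))
  expect_true(all(wide$simulated_5 <= wide$simulated_50 &
                    wide$simulated_50 <= wide$simulated_95))
  expect_warning(run_vpc(fx$fit, n_sim = 20, bins = bins, seed = 1),
                 "unstable")
})

test_that("VPC on self-simulated data covers the observed percentiles", {
  fx <- pk_fit_fixture()
  bins <- c(0, 45, 76, 110)
  vpc <- run_vpc(fx$fit, n_sim = 150, bins = bins, seed = 8)
  inside <- with(vpc$stats, observed >= sim_lo & observed <= sim_hi)
  expect_gte(mean(inside), 0.75) # small cohort, 9 checks
})

test_that("prediction correction absorbs covariate-driven shifts", {
  # if a covariate scales every record's typical prediction and observation
  # by the same subject factor, corrected percentiles only pick up the
  # common bin-median rescaling: their shape within a bin is untouched
  set.seed(42)
  dv <- rlnorm(60, log(3), 0.4)
  pred <- rlnorm(60, log(3), 0.2)
  shift <- rlnorm(60, 0, 0.3) # covariate-driven CL scaling per record
  med1 <- median(pred)
  med2 <- median(pred * shift)
  c1 <- prediction_correct(dv, pred, med1, "proportional")
  c2 <- prediction_correct(dv * shift, pred * shift, med2, "proportional")
  expect_equal(c2, c1 * med2 / med1, tolerance = 1e-12)
  expect_equal(quantile(c2, c(0.05, 0.5, 0.95)) / (med2 / med1),
               quantile(c1, c(0.05, 0.5, 0.95)), tolerance = 1e-12)
})

test_that("bootstrap is reproducible, and n_boot = 1 degenerates properly", {
  fx <- pk_fit_fixture()
  st <- fit_settings(compute_se = FALSE, maxit = 500, reltol = 1e-6,
                     polish = FALSE)
  b1 <- run_bootstrap(fx$table, fx$fit, n_boot = 3, seed = 10,
                      settings = st)
  b2 <- run_bootstrap(fx$table, fx$fit, n_boot = 3, seed = 10,
                      settings = st)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(all(b1$summary$lo <= b1$summary$median &
                    b1$summary$median <= b1$summary$hi))
  one <- run_bootstrap(fx$table, fx$fit, n_boot = 1, seed = 2,
                       settings = st)
  expect_equal(one$summary$median, one$summary$lo)
  expect_equal(one$summary$median, one$summary$hi)
})

test_that("goodness-of-fit records align predictions with observations", {
  fx <- pk_fit_fixture()
  gof <- gof_table(fx$fit)
  expect_equal(nrow(gof$records), fx$fit$n_obs)
  expect_equal(gof$records$res, gof$records$dv - gof$records$pred)
  # individual predictions should correlate decently on self-simulated data
  expect_gt(gof$summary$cor_ipred, 0.5)
})
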