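small_spec <- function(n = 60, seed = 5) cohort_spec(n_subjects = n,
                                                     seed = seed)

test_that("scenario baseline matches the cohort and percentiles are ordered", {
  spec <- small_spec()
  sc <- simulate_scenario(5, spec = spec, duration = 120,
                          grid = seq(0, 120, by = 10), noise = FALSE)
  coh <- draw_cohort(spec)
  expect_equal(sc$summary$median[1], median(coh$HBA1C0))
  expect_true(all(sc$summary$p5 <= sc$summary$median &
                    sc$summary$median <= sc$summary$p95))
  expect_equal(sc$end$time, 120)
})

test_that("no drug effect leaves the end-of-treatment median at baseline", {
  spec <- small_spec(seed = 9)
  sc <- simulate_scenario(5, spec = spec, pd = pd_params(emax = 0),
                          duration = 100, grid = c(0, 50, 100),
                          noise = FALSE)
  expect_equal(sc$end$median, sc$summary$median[1], tolerance = 1e-10)
})

test_that("paired scenarios are dose-monotone subject by subject", {
  spec <- small_spec(seed = 21)
  g <- seq(0, 150, by = 25)
  s5 <- simulate_scenario(5, spec = spec, duration = 150, grid = g,
                          noise = FALSE)
  s10 <- simulate_scenario(10, spec = spec, duration = 150, grid = g,
                           noise = FALSE)
  expect_true(all(s10$trajectories <= s5$trajectories + 1e-12))
  cmp <- compare_scenarios(s5, s10)
  expect_true(all(cmp$difference$d_median[-1] <= 0))
})

test_that("identical scenarios under the same seed are identical", {
  spec <- small_spec(seed = 33)
  g <- c(0, 60, 120)
  a <- simulate_scenario(5, spec = spec, duration = 120, grid = g)
  b <- simulate_scenario(5, spec = spec, duration = 120, grid = g)
  expect_identical(a$summary, b$summary)
  cmp <- compare_scenarios(a, b)
  expect_equal(cmp$difference$d_median, rep(0, 3))
})

test_that("the infinite-dose reference bounds finite doses from below", {
  spec <- small_spec(n = 40, seed = 14)
  g <- c(0, 90, 180)
  s10 <- simulate_scenario(10, spec = spec, duration = 180, grid = g,
                           noise = FALSE)
  sref <- simulate_scenario(Inf, spec = spec, duration = 180, grid = g,
                            noise = FALSE)
  expect_true(all(sref$trajectories <= s10$trajectories + 1e-12))
  cmp <- compare_scenarios(s10, s10, reference = sref)
  expect_true(is.finite(cmp$gap_to_maximal))
})

test_that("scenario grids must match for comparison", {
  spec <- small_spec(n = 10, seed = 2)
  a <- simulate_scenario(5, spec = spec, duration = 60, grid = c(0, 30, 60))
  b <- simulate_scenario(5, spec = spec, duration = 60, grid = c(0, 60))
  expect_error(compare_scenarios(a, b), "grids differ")
})
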