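test_that("body-weight power model evaluates correctly", {
  expect_equal(covariate_cl(229.3, 0.41, 77, 77), 229.3)
  expect_equal(covariate_cl(229.3, 0.41, 100, 77),
               229.3 * (100 / 77)^0.41)
  expect_equal(covariate_cl(229.3, 0, 49, 77), 229.3)
  expect_error(covariate_cl(229.3, 0.41, -1), "positive")
})

test_that("single-dose concentration has the right limits and units", {
  expect_equal(conc_single_dose(0, 5e6, 57.4, 229.3, 73.9), 0)
  expect_equal(conc_single_dose(1000, 5e6, 57.4, 229.3, 73.9), 0)
  # closed-form value at 24 h
  ka <- 57.4; cl <- 229.3; v <- 73.9; k <- cl / v
  expected <- (5e6 / v) * ka / (ka - k) * (exp(-k) - exp(-ka)) / 1000
  expect_equal(conc_single_dose(1, 5e6, ka, cl, v), expected)
  expect_gt(expected, 2); expect_lt(expected, 5)
})

test_that("analytic solution matches a brute-force ODE solver", {
  # grid of rate constants including the near-equal-rates corner
  cases <- expand.grid(ka = c(57.4, 5, 1.01), cl = c(229.3, 73.9, 74.6))
  tt <- c(0.05, 0.25, 1, 3)
  for (i in seq_len(nrow(cases))) {
    ka <- cases$ka[i]; cl <- cases$cl[i]; v <- 73.9
    rhs <- function(t, y, p) list(c(-ka * y[1], ka * y[1] - (cl / v) * y[2]))
    sol <- deSolve::lsoda(c(A = 5e6, C = 0), c(0, tt), rhs, NULL,
                          rtol = 1e-11, atol = 1e-9)
    ana <- conc_single_dose(tt, 5e6, ka, cl, v)
    num <- sol[-1, "C"] / v / 1000
    expect_lt(max(abs(ana - num) / num), 1e-6)
  }
})

test_that("equal absorption and elimination rates use the limiting form", {
  v <- 73.9; k <- 2; cl <- k * v
  got <- conc_single_dose(0.5, 5e6, k, cl, v)
  limit <- (5e6 / v) * k * 0.5 * exp(-k * 0.5) / 1000
  expect_equal(got, limit, tolerance = 1e-6)
  expect_true(is.finite(got))
})

test_that("repeated dosing superposes linearly and reaches steady state", {
  reg5 <- regimen(5, n_doses = 60)
  reg10 <- regimen(10, n_doses = 60)
  tt <- c(0, 10.5, 30, 45, 59.9)
  p5 <- conc_profile(tt, reg5, cl_f = 229.3)
  p10 <- conc_profile(tt, reg10, cl_f = 229.3)
  expect_true(all(p5$conc >= 0))
  expect_equal(p10$conc, 2 * p5$conc) # dose-proportional
  # periodicity at steady state
  c30 <- conc_profile(30, reg5, cl_f = 229.3)$conc
  c31 <- conc_profile(31, reg5, cl_f = 229.3)$conc
  expect_lt(abs(c30 - c31) / c30, 1e-8)
  # times before the first dose give zero
  expect_equal(conc_profile(-1, reg5, cl_f = 229.3)$conc, 0)
})

test_that("multi-dose trough agrees with the accumulation formula", {
  reg <- regimen(5, n_doses = 30)
  sup <- conc_profile(30, reg, cl_f = 229.3)$conc
  expect_rel(sup, steady_state_trough(5, 229.3), 1e-3)
})

test_that("average steady-state concentration equals dose / (CL tau)", {
  reg <- regimen(5, n_doses = 60)
  tt <- seq(50, 51, by = 0.0005)
  avg <- mean(conc_profile(tt, reg, cl_f = 229.3)$conc)
  expected <- 5e6 / 229.3 / 1 / 1000 # ng/L -> ng/mL
  expect_rel(avg, expected, 1e-3)
})

test_that("typical steady-state trough sits in the observed 2-5 ng/mL band", {
  trough <- steady_state_trough(5, cl_f = covariate_cl(229.3, 0.41, 77))
  expect_gt(trough, 2)
  expect_lt(trough, 5)
})
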