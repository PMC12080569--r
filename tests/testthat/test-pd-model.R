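test_that("Emax effect rate has its defining identities", {
  expect_equal(efc(23.7, 0.034, 23.7), 0.017) # half-maximal at EC50
  expect_equal(efc(0, 0.034, 23.7), 0)
  expect_equal(efc(Inf, 0.034, 23.7), 0.034)
  expect_error(efc(-1, 0.034, 23.7), "non-negative")
  # hill exponent steepens around EC50 but preserves the midpoint
  expect_equal(efc(23.7, 0.034, 23.7, hill = 3), 0.017)
  expect_lt(efc(10, 0.034, 23.7, hill = 3), efc(10, 0.034, 23.7))
})

test_that("HbA1c-level scaling anchors at floor and reference baseline", {
  expect_equal(ef(5.0, 0.03), 0)
  expect_equal(ef(8.0, 0.03), 0.03)
  expect_equal(ef(6.5, 0.03), 0.015)
  expect_equal(ef(4.2, 0.03), 0) # clipped below the floor
})

test_that("turnover derivative is stationary at baseline and saturates", {
  expect_equal(hba1c_derivative(6.8, conc = 0, h0 = 6.8), 0)
  expect_equal(hba1c_derivative(8.0, conc = 0, h0 = 8.0), 0)
  # saturation limit at the reference baseline
  pd <- pd_params()
  kout <- log(2) / pd$t_half
  expect_equal(hba1c_derivative(8.0, conc = Inf, h0 = 8.0, pd),
               kout * 8 - pd$emax - kout * 8)
  # no drug effect reduces to classic turnover pulling back to baseline
  pd0 <- pd_params(emax = 0)
  expect_gt(hba1c_derivative(6.0, conc = 50, h0 = 6.8, pd0), 0)
  expect_lt(hba1c_derivative(7.5, conc = 50, h0 = 6.8, pd0), 0)
})

test_that("no drug leaves the trajectory at baseline", {
  prof <- hba1c_profile(c(0, 10, 100, 365), h0 = 6.8,
                        conc_fn = function(t) rep(0, length(t)))
  expect_equal(prof$hba1c, rep(6.8, 4), tolerance = 1e-8)
})

test_that("constant exposure decays monotonically to the closed-form steady state", {
  pd <- pd_params()
  cfn <- function(t) rep(23.7, length(t))
  tt <- c(0, 5, 20, 50, 100, 200, 500, 1000)
  prof <- hba1c_profile(tt, h0 = 8, conc_fn = cfn)
  expect_true(all(diff(prof$hba1c) < 0))
  ss <- hba1c_steady_state(23.7, 8)
  expect_rel(prof$hba1c[8], ss, 1e-6)
  # the steady state solves kin - Efc (H-5)/3 - kout H = 0 directly
  kout <- log(2) / pd$t_half
  resid <- kout * 8 - 0.017 * (ss - 5) / 3 - kout * ss
  expect_lt(abs(resid), 1e-12)
})

test_that("exponential integrator matches the adaptive ODE solver on the same drive", {
  # identical piecewise-constant concentration drive for both integrators
  pd <- pd_params()
  step <- 0.05
  n_days <- 30
  grid <- seq(0, n_days, by = step)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  base_fn <- function(t) {
    conc_profile(t, regimen(5, n_doses = n_days + 1), cl_f = 229.3)$conc
  }
  cmid <- base_fn(mid)
  step_fn <- function(t) cmid[pmin(pmax(ceiling(t / step), 1), length(cmid))]
  tt <- c(0, 7, 15, 30)
  h_exp <- hba1c_profile(tt, 6.8, step_fn, pd, method = "exponential",
                         step = step)$hba1c
  h_ode <- hba1c_profile(tt, 6.8, step_fn, pd, method = "ode")$hba1c
  expect_lt(max(abs(h_exp - h_ode) / h_ode), 1e-6)
})

test_that("day-averaged fast path tracks the fine-step reference closely", {
  cfn <- function(t) conc_profile(t, regimen(5, n_doses = 400),
                                  cl_f = 229.3)$conc
  tt <- c(0, 30, 180, 365)
  h_fine <- hba1c_profile(tt, 6.8, cfn, method = "exponential")$hba1c
  h_daily <- hba1c_profile(tt, 6.8, cfn, method = "daily")$hba1c
  expect_lt(max(abs(h_fine - h_daily)), 5e-3)
})

test_that("trajectories respect the 5% floor and dose monotonicity", {
  pd <- pd_params()
  tt <- seq(0, 365, by = 5)
  # absurdly high constant exposure pushes toward, but never through, 5%
  h_hi <- hba1c_profile(tt, 5.4, function(t) rep(1e5, length(t)),
                        pd, t_half = 200)$hba1c
  expect_true(all(h_hi >= 5))
  c5 <- function(t) conc_profile(t, regimen(5, n_doses = 366),
                                 cl_f = 229.3)$conc
  c10 <- function(t) conc_profile(t, regimen(10, n_doses = 366),
                                  cl_f = 229.3)$conc
  h5 <- hba1c_profile(tt, 6.8, c5)$hba1c
  h10 <- hba1c_profile(tt, 6.8, c10)$hba1c
  expect_true(all(h10 <= h5 + 1e-12))
})

test_that("one-year typical 5 mg exposure lowers HbA1c from 6.8 toward ~6.5", {
  cfn <- function(t) conc_profile(t, regimen(5, n_doses = 366),
                                  cl_f = 229.3)$conc
  h365 <- hba1c_profile(365, 6.8, cfn)$hba1c
  expect_gt(h365, 6.4)
  expect_lt(h365, 6.7)
})
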