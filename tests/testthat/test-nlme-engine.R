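# Independent oracle: -2 log marginal likelihood by adaptive Gauss-Hermite
# quadrature (nodes centred and scaled at the conditional mode).
quadrature_m2ll <- function(subjects, omega2, sigma_add = 0,
                            sigma_prop = 0, n_nodes = 41) {
  gh <- statmod::gauss.quad(n_nodes, kind = "hermite")
  total <- 0
  for (sub in subjects) {
    nll <- function(eta) {
      f <- sub$pred(eta)
      v <- sigma_add^2 + (sigma_prop * f)^2
      0.5 * sum(log(2 * pi * v) + (sub$y - f)^2 / v) +
        0.5 * (log(2 * pi * omega2) + eta^2 / omega2)
    }
    mode <- stats::optimize(nll, c(-8, 8), tol = 1e-10)$minimum
    h <- 1e-4
    curv <- (nll(mode + h) - 2 * nll(mode) + nll(mode - h)) / h^2
    s <- 1 / sqrt(max(curv, 1e-8))
    # integral of exp(-nll(eta)) via substitution eta = mode + sqrt(2) s x
    vals <- vapply(gh$nodes, function(x) {
      eta <- mode + sqrt(2) * s * x
      exp(-nll(eta) + x^2) # weight function e^{-x^2} folded back in
    }, numeric(1))
    total <- total - 2 * log(sqrt(2) * s * sum(gh$weights * vals))
  }
  total
}

make_toy <- function(n_sub = 6, n_obs = 4, theta = 2, omega = 0.4,
                     sigma = 0.3, seed = 5, nonlinear = TRUE) {
  set.seed(seed)
  lapply(seq_len(n_sub), function(i) {
    eta <- rnorm(1, 0, omega)
    x <- seq(0.5, 2, length.out = n_obs)
    f <- if (nonlinear) theta * exp(eta) * exp(-0.5 * x) else
      theta * exp(eta) * x
    list(y = f + rnorm(n_obs, 0, sigma),
         pred = if (nonlinear) {
           function(eta) theta * exp(eta) * exp(-0.5 * x)
         } else {
           function(eta) theta * exp(eta) * x
         })
  })
}

test_that("individual parameters follow the log-normal random-effect model", {
  expect_equal(individual_params(229.3, 0), 229.3)
  expect_equal(individual_params(229.3, 0.1), 229.3 * exp(0.1))
  expect_equal(individual_params(c(100, 200), c(0.1, -0.1)),
               c(100, 200) * exp(c(0.1, -0.1)))
})

test_that("FOCE objective matches Gauss-Hermite quadrature on toy problems", {
  skip_if_not_installed("statmod")
  for (omega in c(0.2, 0.5, 1.0)) {
    for (sigma in c(0.1, 0.3)) {
      subjects <- make_toy(omega = omega, sigma = sigma,
                           seed = round(100 * omega + 10 * sigma))
      foce <- foce_objective(subjects, omega2 = omega^2,
                             sigma_add = sigma)$minus2ll
      quad <- quadrature_m2ll(subjects, omega2 = omega^2,
                              sigma_add = sigma)
      expect_lt(abs(foce - quad), 0.5)
    }
  }
  # proportional error (interaction) case
  subjects <- make_toy(sigma = 0.05, seed = 31)
  foce <- foce_objective(subjects, omega2 = 0.16,
                         sigma_prop = 0.15)$minus2ll
  quad <- quadrature_m2ll(subjects, omega2 = 0.16, sigma_prop = 0.15)
  expect_lt(abs(foce - quad), 0.5)
})

test_that("the adaptive-quadrature inner integral matches the external oracle", {
  skip_if_not_installed("statmod")
  # large omega: where Laplace and exact quadrature visibly part ways
  subjects <- make_toy(omega = 1.0, sigma = 0.3, seed = 44)
  agq <- foce_objective(subjects, omega2 = 1, sigma_add = 0.3,
                        inner = "agq")$minus2ll
  oracle <- quadrature_m2ll(subjects, omega2 = 1, sigma_add = 0.3)
  expect_lt(abs(agq - oracle), 1e-4)
  lap <- foce_objective(subjects, omega2 = 1, sigma_add = 0.3)$minus2ll
  expect_lt(abs(lap - oracle), 0.5)
  # in-package Hermite rule agrees with the reference implementation
  gh <- dapapkpd:::.gauss_hermite(21)
  ref <- statmod::gauss.quad(21, kind = "hermite")
  expect_equal(gh$nodes, ref$nodes, tolerance = 1e-10)
  expect_equal(gh$weights, ref$weights, tolerance = 1e-10)
})

test_that("omega = 0 reduces the objective to extended weighted least squares", {
  subjects <- make_toy(seed = 9)
  sigma <- 0.3
  got <- foce_objective(subjects, omega2 = 0, sigma_add = sigma)$minus2ll
  manual <- sum(vapply(subjects, function(sub) {
    r <- sub$y - sub$pred(0)
    sum((r / sigma)^2 + log(sigma^2) + log(2 * pi))
  }, numeric(1)))
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("objective is invariant to subject order and additive over duplicates", {
  subjects <- make_toy(seed = 12)
  f1 <- foce_objective(subjects, omega2 = 0.16, sigma_add = 0.3)$minus2ll
  f2 <- foce_objective(rev(subjects), omega2 = 0.16,
                       sigma_add = 0.3)$minus2ll
  expect_equal(f1, f2, tolerance = 1e-10)
  fdup <- foce_objective(c(subjects, subjects), omega2 = 0.16,
                         sigma_add = 0.3)$minus2ll
  expect_equal(fdup, 2 * f1, tolerance = 1e-8)
})

test_that("conditional modes concentrate on the true eta as data grow", {
  set.seed(77)
  eta_true <- 0.35
  x <- seq(0.1, 3, length.out = 200)
  f <- 2 * exp(eta_true) * exp(-0.5 * x)
  sub <- list(y = f + rnorm(200, 0, 0.05),
              pred = function(eta) 2 * exp(eta) * exp(-0.5 * x))
  res <- foce_objective(list(sub), omega2 = 0.25, sigma_add = 0.05)
  expect_lt(abs(res$eta[1] - eta_true), 0.02)
})

test_that("the AIC identity holds and counts only estimated parameters", {
  fx <- make_small_table(n_subjects = 6, seed = 41)
  fit <- suppressMessages(
    fit_pk(fx$table, settings = fit_settings(compute_se = FALSE,
                                             maxit = 200))
  )
  expect_equal(fit$aic, fit$minus2ll + 2 * fit$n_params)
  expect_equal(fit$n_params, 4) # theta_cl, theta_WT, omega2, sigma: ka/V fixed
})
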