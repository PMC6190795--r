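ref_params <- pk_params(0.116, 0.177, 0.0037, 0.0103)

test_that("terminal slope matches the published typical value", {
  h <- hybrid_constants(ref_params)
  expect_equal(signif(h[["beta"]], 3), 0.0111)
  expect_gt(h[["alpha"]], h[["beta"]])
})

test_that("hybrid constants satisfy the Vieta identities and the rate
           matrix eigenvalues", {
  set.seed(7)
  for (i in 1:25) {
    p <- pk_params(runif(1, 0.02, 0.5), runif(1, 0.02, 0.5),
                   runif(1, 5e-4, 0.02), runif(1, 5e-4, 0.05))
    h <- hybrid_constants(p)
    expect_equal(h[["alpha"]] + h[["beta"]],
                 h[["k10"]] + h[["k12"]] + h[["k21"]], tolerance = 1e-10)
    expect_equal(h[["alpha"]] * h[["beta"]],
                 h[["k21"]] * h[["k10"]], tolerance = 1e-10)
    # independent oracle: eigenvalues of the 2x2 micro-rate matrix
    A <- matrix(c(-(h[["k10"]] + h[["k12"]]), h[["k21"]],
                  h[["k12"]], -h[["k21"]]), 2, 2, byrow = TRUE)
    ev <- sort(eigen(A, only.values = TRUE)$values)
    expect_equal(ev, sort(c(-h[["alpha"]], -h[["beta"]])),
                 tolerance = 1e-10)
  }
  expect_error(pk_params(-1, 0.1, 0.01, 0.01),
               class = "cefapop_domain_error")
})

test_that("bolus concentration starts at dose/V1 and superposes", {
  expect_equal(concentration(ref_params, dose_events(0, 25), 0),
               25 / 0.116, tolerance = 1e-12)
  tt <- seq(0, 1440, by = 30)
  one <- concentration(ref_params, dose_events(0, 25), tt)
  shifted <- concentration(ref_params, dose_events(360, 25), tt)
  both <- concentration(ref_params, dose_events(c(0, 360), 25), tt)
  expect_equal(both, one + shifted, tolerance = 1e-12)
  # pre-dose baseline
  expect_equal(concentration(ref_params, dose_events(60, 25), 30), 0)
  # dose proportionality
  expect_equal(concentration(ref_params, dose_events(0, 50), tt),
               2 * one, tolerance = 1e-12)
})

test_that("closed form agrees with numeric integration of the ODE system", {
  skip_if_not_installed("deSolve")
  h <- hybrid_constants(ref_params)
  rhs <- function(t, a, p) {
    list(c(-(p$k10 + p$k12) * a[1] + p$k21 * a[2],
           p$k12 * a[1] - p$k21 * a[2]))
  }
  tt <- seq(0, 1440, by = 10)
  sol <- deSolve::lsoda(
    y = c(25, 0), times = tt, func = rhs,
    parms = list(k10 = h[["k10"]], k12 = h[["k12"]], k21 = h[["k21"]]),
    rtol = 1e-11, atol = 1e-13
  )
  ode_conc <- sol[, 2] / 0.116
  closed <- concentration(ref_params, dose_events(0, 25), tt)
  expect_lt(max(abs(closed - ode_conc) / pmax(ode_conc, 1e-12)), 1e-6)
})

test_that("log-concentration is affine with slope -beta in the terminal
           phase", {
  h <- hybrid_constants(ref_params)
  t0 <- 5 * log(2) / h[["alpha"]]
  tt <- seq(t0 + 200, t0 + 800, by = 10)
  cc <- concentration(ref_params, dose_events(0, 25), tt)
  slope <- coef(lm(log(cc) ~ tt))[["tt"]]
  expect_equal(slope, -h[["beta"]], tolerance = 1e-6)
})

test_that("secondary parameters follow the classical definitions", {
  s <- secondary_parameters(ref_params, dose = 25)
  expect_equal(s[["AUC"]], 25 / 0.0037, tolerance = 1e-12)
  expect_equal(signif(s[["Vz"]], 4), 0.3345)
  expect_equal(s[["Vss"]], 0.116 + 0.177)
  expect_equal(s[["MRT"]], s[["Vss"]] / 0.0037)
  expect_equal(s[["hl_beta"]], log(2) / s[["beta"]])
  expect_equal(s[["hl_alpha"]], log(2) / s[["alpha"]])
  # quadrature oracle: trapezoid AUC over 10 terminal half-lives
  tt <- seq(0, 10 * s[["hl_beta"]], by = 0.05)
  cc <- concentration(ref_params, dose_events(0, 25), tt)
  auc_trap <- sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
  expect_lt(abs(auc_trap - s[["AUC"]]) / s[["AUC"]], 0.005)
  expect_error(secondary_parameters(ref_params, dose = -1),
               class = "cefapop_domain_error")
})

test_that("concentration is positive and continuous over the horizon", {
  tt <- seq(0, 1440, by = 1)
  cc <- concentration(ref_params, dose_events(c(0, 360, 720, 1080), 25), tt)
  expect_true(all(cc > 0))
  jumps <- abs(diff(log(cc)))
  # only the dose instants may jump
  inter <- setdiff(seq_along(jumps), c(360, 720, 1080))
  expect_lt(max(jumps[inter]), 0.2)
})
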