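test_that("individual parameters reduce to typical values and apply
           covariate factors", {
  th <- list(tv = REF_TV, coef = numeric(0))
  p <- individual_parameters(th, rep(0, 4), NULL, pop_model_spec())
  expect_equal(unclass(p), REF_TV, tolerance = 1e-12)

  # body-weight power model on clearance
  sp <- pop_model_spec(covariate_term("CL", "bw", "power"))
  th_bw <- list(tv = REF_TV, coef = c(`CL~bw` = -0.2368))
  p10 <- individual_parameters(th_bw, rep(0, 4), list(bw = 10), sp)
  p30 <- individual_parameters(th_bw, rep(0, 4), list(bw = 30), sp)
  expect_equal(signif(p10[["CL"]] / REF_TV[["CL"]], 4), 1.178)
  expect_equal(signif(p30[["CL"]] / REF_TV[["CL"]], 3), 0.908)

  # diseased indicator on intercompartmental clearance
  sq <- pop_model_spec(covariate_term("Q", "health", "linear"))
  th_q <- list(tv = REF_TV, coef = c(`Q~health` = -0.267))
  pd <- individual_parameters(th_q, rep(0, 4), list(health = 1), sq)
  expect_equal(pd[["Q"]] / REF_TV[["Q"]], 0.733, tolerance = 1e-12)

  # leaving the positivity regime is an error
  th_bad <- list(tv = REF_TV, coef = c(`Q~health` = -1.2))
  expect_error(individual_parameters(th_bad, rep(0, 4), list(health = 1), sq),
               class = "cefapop_domain_error")

  # random effects act multiplicatively on the log scale
  pe <- individual_parameters(th, c(CL = 0.3), NULL, pop_model_spec())
  expect_equal(pe[["CL"]], REF_TV[["CL"]] * exp(0.3), tolerance = 1e-12)
})

test_that("combined residual variance follows pred^2 prop^2 + add^2", {
  sig <- c(prop = 0.257, add = 0.564)
  expect_equal(residual_variance(0, sig), 0.564^2)
  expect_equal(residual_variance(100, sig), 100^2 * 0.257^2 + 0.564^2)
  v <- residual_variance(seq(0, 50, by = 5), sig)
  expect_true(all(diff(v) > 0))
  expect_error(residual_variance(10, c(prop = 0, add = 0)),
               class = "cefapop_domain_error")
})

test_that("log-variance to CV% conversion is exact and has the first-order
           limit", {
  expect_equal(omega_to_cv(0), 0)
  expect_equal(round(omega_to_cv(0.130511), 2), 37.34)
  w <- seq(0.01, 0.1, by = 0.01)
  expect_lt(max(abs(omega_to_cv(w^2) / (100 * w) - 1)), 0.01)
  expect_error(omega_to_cv(-0.1), class = "cefapop_domain_error")
})

test_that("omega covariance converts to the published correlations", {
  omega <- reference_estimate()$omega
  corr <- omega_to_correlation(omega)
  expect_equal(round(corr["V1", "V2"], 2), 0.89)
  expect_equal(round(corr["CL", "Q"], 2), 0.43)
  expect_equal(diag(corr), setNames(rep(1, 4), colnames(omega)))
  expect_true(all(corr >= -1 & corr <= 1))
  expect_equal(omega_to_correlation(diag(c(0.1, 0.2, 0.3, 0.4))),
               diag(4), ignore_attr = TRUE)
  expect_error(omega_to_correlation(diag(c(0, 0.1, 0.1, 0.1))),
               class = "cefapop_domain_error")
})

test_that("FOCE objective matches adaptive quadrature on single-eta toys", {
  times <- c(5, 10, 15, 30, 60, 120, 180, 240, 480)
  w2 <- 0.130511
  sig <- c(prop = 0.257, add = 0.564)
  for (seed in c(11, 23, 47)) {
    set.seed(seed)
    eta_true <- rnorm(1, 0, sqrt(w2))
    y <- simulate_toy_subject(times, eta = c(0, 0, eta_true, 0),
                              sigma = sig, seed = seed + 1)
    ds <- study_dataset(toy_study_df(times, y))
    spec <- pop_model_spec(omega_structure = "full", eta = "CL")
    ofv <- as.numeric(foce_objective(ds, REF_TV, matrix(w2, 1, 1), sig,
                                     spec))
    oracle <- quad_m2ll_1eta(times, y, w2 = w2, sigma = sig)
    expect_lt(abs(ofv - oracle), 0.1)
  }
})

test_that("FOCE objective matches nested quadrature with two correlated
           etas", {
  times <- c(5, 10, 15, 30, 60, 120, 180, 240, 480)
  omega2 <- matrix(c(0.092598, 0.031062, 0.031062, 0.130511), 2, 2)
  sig <- c(prop = 0.257, add = 0.564)
  set.seed(31)
  etas <- MASS::mvrnorm(1, c(0, 0), omega2)
  y <- simulate_toy_subject(times, eta = c(etas[1], 0, etas[2], 0),
                            sigma = sig, seed = 32)
  ds <- study_dataset(toy_study_df(times, y))
  spec <- pop_model_spec(omega_structure = "full", eta = c("V1", "CL"))
  ofv <- as.numeric(foce_objective(ds, REF_TV, omega2, sig, spec))
  oracle <- quad_m2ll_2eta(times, y, omega2 = omega2, sigma = sig)
  expect_lt(abs(ofv - oracle), 0.1)
})

test_that("the vanishing-omega limit recovers extended least squares at
           eta = 0", {
  times <- c(10, 60, 240, 480)
  y <- simulate_toy_subject(times, seed = 5)
  ds <- study_dataset(toy_study_df(times, y))
  sig <- c(prop = 0.257, add = 0.564)
  spec <- pop_model_spec(omega_structure = "full", eta = "CL")
  ofv <- as.numeric(foce_objective(ds, REF_TV, matrix(1e-8, 1, 1), sig,
                                   spec))
  f <- concentration(pk_params(REF_TV[1], REF_TV[2], REF_TV[3], REF_TV[4]),
                     dose_events(0, 25), times)
  v <- f^2 * sig[1]^2 + sig[2]^2
  els <- sum(log(2 * pi * v) + (y - f)^2 / v)
  expect_equal(ofv, els, tolerance = 1e-4)
})

test_that("shrinkage follows 1 - SD(EBE)/omega", {
  a <- 0.2 / sqrt(2) # two-point sample with SD exactly 0.2
  etas <- cbind(V1 = c(-a, a), CL = c(-0.3 / sqrt(2), 0.3 / sqrt(2)))
  omega <- diag(c(0.3^2, 0.3^2))
  shr <- eta_shrinkage(etas, omega)
  expect_equal(unname(shr), c(1 - 0.2 / 0.3, 0), tolerance = 1e-12)
  # undefined when the population SD is zero
  shr0 <- eta_shrinkage(etas, diag(c(0, 0.09)))
  expect_true(is.na(shr0[[1]]))
  expect_error(eta_shrinkage(etas[1, , drop = FALSE], omega),
               class = "cefapop_domain_error")
})

test_that("singular omega is rejected with advice", {
  times <- c(10, 60, 240)
  y <- simulate_toy_subject(times, seed = 6)
  ds <- study_dataset(toy_study_df(times, y))
  omega <- matrix(c(0.1, 0.1, 0.1, 0.1), 2, 2) # rank 1
  spec <- pop_model_spec(omega_structure = "full", eta = c("V1", "CL"))
  expect_error(
    foce_objective(ds, REF_TV, omega, c(0.2, 0.5), spec),
    class = "cefapop_numeric_error"
  )
})
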