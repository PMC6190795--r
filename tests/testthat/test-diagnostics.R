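small_cfg <- generator_config(n_subjects = 12,
                              spec = pop_model_spec(omega_structure = "diagonal"))
small_spec <- pop_model_spec(omega_structure = "diagonal")

test_that("bootstrap resamples to the original subject count and is
           seed-reproducible", {
  ds <- suppressMessages(generate_study(small_cfg, seed = 31))
  b1 <- suppressWarnings(suppressMessages(bootstrap_popmodel(
    ds, small_spec, n_reps = 3, seed = 99,
    control = c(fast_ctrl, two_stage = FALSE))))
  expect_true(all(b1$replicates$n_subjects == 12))
  expect_equal(nrow(b1$replicates) + b1$n_failed, 3)
  # percentile ordering and the CV% definition hold for every parameter
  expect_true(all(b1$summary$p2.5 <= b1$summary$median + 1e-12))
  expect_true(all(b1$summary$median <= b1$summary$p97.5 + 1e-12))
  expect_equal(b1$summary$cv_pct,
               100 * b1$summary$se / b1$summary$mean)
  b2 <- suppressWarnings(suppressMessages(bootstrap_popmodel(
    ds, small_spec, n_reps = 3, seed = 99,
    control = c(fast_ctrl, two_stage = FALSE))))
  expect_identical(b1$summary, b2$summary)
  expect_error(bootstrap_popmodel(ds, small_spec, n_reps = 1),
               class = "cefapop_domain_error")
})

test_that("bootstrap precision of typical clearance is of the expected
           order at the full design", {
  ds <- suppressMessages(generate_study(generator_config(), seed = 55))
  b <- suppressWarnings(suppressMessages(bootstrap_popmodel(
    ds, pop_model_spec(), n_reps = 10, seed = 7,
    control = list(two_stage = FALSE, rel_tol = 1e-5))))
  cv_cl <- b$summary$cv_pct[b$summary$parameter == "tvCL"]
  # the emulated analysis reported 4.26%; accept the same order (x/÷2)
  expect_gt(cv_cl, 4.26 / 2)
  expect_lt(cv_cl, 4.26 * 2)
})

test_that("VPC bookkeeping conserves simulated records and collapses under
           zero variances", {
  ds <- suppressMessages(generate_study(small_cfg, seed = 13))
  ref <- reference_estimate()
  v <- vpc(ds, ref, n_reps = 40, seed = 2)
  expect_equal(v$n_simulated, n_observations(ds) * 40)
  expect_true(all(v$bands$sim_p10_lo <= v$bands$sim_p10 + 1e-12))
  expect_true(all(v$bands$sim_p10 <= v$bands$sim_p10_hi + 1e-12))

  # omega = 0, sigma = 0: all percentiles equal the typical curve
  degenerate <- ref
  degenerate$omega <- matrix(0, 4, 4)
  degenerate$sigma <- c(prop = 0, add = 0)
  v0 <- vpc(ds, degenerate, n_reps = 15, seed = 2)
  p <- pk_params(REF_TV[1], REF_TV[2], REF_TV[3], REF_TV[4])
  typical <- concentration(p, dose_events(0, 25), v0$bands$time)
  expect_equal(v0$bands$sim_p10, typical, tolerance = 1e-10)
  expect_equal(v0$bands$sim_p90, typical, tolerance = 1e-10)
})

test_that("a model simulated from itself keeps the observed median inside
           the simulated band", {
  ref <- reference_estimate()
  ok <- 0
  for (seed in 1:10) {
    ds <- suppressMessages(generate_study(generator_config(), seed = seed))
    v <- vpc(ds, ref, n_reps = 80, seed = seed + 1000)
    inside <- with(v$bands, obs_p50 >= sim_p50_lo & obs_p50 <= sim_p50_hi)
    if (mean(inside) >= 10 / 13) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("goodness-of-fit tables collapse to the data when there is no
           noise and no variability", {
  cfg0 <- generator_config(n_subjects = 5, omega = matrix(0, 4, 4),
                           sigma = c(0, 0),
                           spec = pop_model_spec(omega_structure = "none"))
  ds <- generate_study(cfg0, seed = 3)
  est <- reference_estimate()
  est$spec <- pop_model_spec(omega_structure = "none")
  est$omega <- matrix(0, 0, 0)
  est$sigma <- c(prop = 0.01, add = 0.01)
  g <- gof_tables(ds, est)
  expect_equal(g$pred, g$obs, tolerance = 1e-10)
  expect_equal(g$ipred, g$obs, tolerance = 1e-10)
  expect_equal(g$wres, rep(0, nrow(g)), tolerance = 1e-8)
})

test_that("individual weighted residuals on self-simulated data look like
           unit noise and individual predictions beat population ones", {
  cfg <- generator_config(
    samples_per_subject = list(counts = c(12, 13), probs = c(0, 1))
  )
  ds <- suppressMessages(generate_study(cfg, seed = 64))
  ref <- reference_estimate()
  g <- suppressMessages(gof_tables(ds, ref))
  expect_lt(abs(mean(g$iwres)), 0.1)
  expect_gt(sd(g$iwres), 0.85)
  expect_lt(sd(g$iwres), 1.15)
  # individual predictions absorb between-subject variability
  expect_lt(sd(g$obs - g$ipred), sd(g$obs - g$pred))
})
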