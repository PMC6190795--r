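test_that("threshold and percentage arithmetic match the published table
           construction", {
  cfg <- pta_config()
  expect_equal(signif(1 / cfg$unbound_fraction, 3), 1.56)
  expect_equal(signif(100 * 821 / cfg$horizon, 3), 57.0)
  # unbound fraction from the measured 36.2% serum protein binding
  expect_equal(round(1 - 0.362, 2), cfg$unbound_fraction)
  expect_error(pta_config(unbound_fraction = 0),
               class = "cefapop_domain_error")
  expect_error(pta_config(mic_grid = c(2, 1)),
               class = "cefapop_domain_error")
  expect_error(pta_config(dose_times = c(0, 2000)),
               class = "cefapop_domain_error")
})

test_that("time above threshold matches a brute-force fine-grid oracle", {
  cfg <- pta_config()
  tt <- seq(0, cfg$horizon, by = 0.01)
  set.seed(19)
  for (i in 1:5) {
    p <- pk_params(runif(1, 0.06, 0.25), runif(1, 0.08, 0.3),
                   runif(1, 0.002, 0.007), runif(1, 0.004, 0.02))
    cc <- concentration(p, dose_events(cfg$dose_times, cfg$dose), tt)
    for (thr in c(0.78, 3.12, 12.5)) {
      oracle <- sum(cc > thr) * 0.01
      expect_lt(abs(time_above_threshold(p, cfg, thr) - oracle), 0.5)
    }
  }
})

test_that("time above threshold has the right limits", {
  cfg <- pta_config()
  p <- pk_params(REF_TV[1], REF_TV[2], REF_TV[3], REF_TV[4])
  cmax <- concentration(p, dose_events(cfg$dose_times, cfg$dose), 1080)
  expect_equal(time_above_threshold(p, cfg, cmax * 2), 0)
  expect_equal(time_above_threshold(p, cfg, 1e-9), cfg$horizon,
               tolerance = 1e-6)
  expect_error(time_above_threshold(p, cfg, -1),
               class = "cefapop_domain_error")
})

test_that("population simulation preserves the omega covariance and is
           seed-stable", {
  ref <- reference_estimate()
  d1 <- simulate_population(ref, 500, seed = 77)
  d2 <- simulate_population(ref, 500, seed = 77)
  expect_identical(d1, d2)

  big <- simulate_population(ref, 100000, seed = 5)
  emp <- cov(log(as.matrix(big)))
  omega <- ref$omega
  # diagonal entries within 2% relative
  expect_lt(max(abs(diag(emp) / diag(omega) - 1)), 0.02)
  # off-diagonals within 0.02 on the correlation scale
  sc <- sqrt(tcrossprod(diag(omega)))
  expect_lt(max(abs((emp - omega) / sc)), 0.02)

  # degenerate population: every draw equals the typical subject
  zero <- ref
  zero$omega <- matrix(0, 4, 4)
  d0 <- simulate_population(zero, 50, seed = 1)
  expect_true(all(apply(d0, 2, function(x) diff(range(x))) == 0))
  expect_equal(unname(unlist(d0[1, ])), unname(REF_TV))

  bad <- ref
  bad$omega <- matrix(c(1, 2, 2, 1), 2, 2)[c(1, 2, 1, 2), c(1, 2, 1, 2)]
  expect_error(simulate_population(bad, 10, seed = 1),
               class = "cefapop_domain_error")
})

test_that("the PTA table is monotone in MIC with ordered quantiles", {
  ref <- reference_estimate()
  draws <- simulate_population(ref, 400, seed = 3)
  cfg <- pta_config(n_subjects = 400)
  res <- pta_table(draws, cfg)
  expect_equal(res$table$threshold,
               signif(cfg$mic_grid / 0.64, 3))
  expect_true(all(diff(res$table$time_q90) <= 0))
  expect_true(all(diff(res$table$time_q95) <= 0))
  expect_true(all(res$table$time_q95 <= res$table$time_q90))
  expect_equal(res$table$pct_q90,
               signif(100 * res$table$time_q90 / cfg$horizon, 3))
  # per-draw monotonicity across the grid
  times <- sapply(cfg$mic_grid / 0.64, function(thr) {
    time_above_threshold(draws[1:50, ], cfg, thr)
  })
  expect_true(all(apply(times, 1, function(r) all(diff(r) <= 0))))
  expect_error(pta_table(draws[1:10, ], cfg),
               class = "cefapop_domain_error")
})

test_that("the cutoff rule picks the largest attaining MIC", {
  # the published Q90 times against the 50%-of-24h target
  tab <- data.frame(
    mic = c(0.25, 0.5, 1, 2, 4, 8),
    threshold = c(0.39, 0.78, 1.56, 3.12, 6.25, 12.5),
    time_q90 = c(1345, 1169, 882, 821, 530, 463)
  )
  res <- structure(list(table = tab, config = pta_config()),
                   class = "pta_result")
  expect_equal(pkpd_cutoff(res), 2)

  # every MIC attains the full horizon -> top of the grid
  tab2 <- tab
  tab2$time_q90 <- rep(1440, 6)
  res2 <- structure(list(table = tab2, config = pta_config()),
                    class = "pta_result")
  expect_equal(pkpd_cutoff(res2), 8)

  # an unattainable target reports below-grid
  cfg_strict <- pta_config(target_fraction = 1.0)
  res3 <- structure(list(table = tab, config = cfg_strict),
                    class = "pta_result")
  expect_warning(out <- pkpd_cutoff(res3, cfg_strict), "below")
  expect_true(is.na(out))
})

test_that("omega = 0 collapses all quantiles onto the typical subject", {
  zero <- reference_estimate()
  zero$omega <- matrix(0, 4, 4)
  draws <- simulate_population(zero, 150, seed = 2)
  cfg <- pta_config(n_subjects = 150)
  res <- pta_table(draws, cfg)
  p <- pk_params(REF_TV[1], REF_TV[2], REF_TV[3], REF_TV[4])
  typical <- time_above_threshold(p, cfg, 3.12)
  row <- res$table[res$table$mic == 2, ]
  expect_equal(row$time_q90, typical, tolerance = 0.02)
  expect_equal(row$time_q95, typical, tolerance = 0.02)
})
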