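test_that("covariate draws match the emulated population margins", {
  cfg <- generator_config(n_subjects = 10000)
  cov <- generate_covariates(cfg, seed = 12)
  expect_lt(abs(mean(cov$bw) - 26.13), 1)
  expect_true(all(cov$bw >= 4.5 & cov$bw <= 56))
  expect_true(all(cov$age >= 0.66 & cov$age <= 14))
  expect_true(all(cov$creatinine >= 0.3 & cov$creatinine <= 1.88))
  expect_true(all(cov$surgery_time >= 20 & cov$surgery_time <= 260))
  expect_lt(abs(mean(cov$health == 0) - 19 / 78), 0.02)
  expect_lt(abs(mean(cov$breed == 0) - 27 / 78), 0.02)
  expect_lt(abs(mean(cov$sex == 0) - 32 / 78), 0.02)
  expect_identical(generate_covariates(cfg, seed = 12), cov)
  expect_error(
    generate_covariates(generator_config(
      covariates = utils::modifyList(
        cefapop:::default_covariate_config(),
        list(bw = list(mean = 26, sd = 1, min = 100, max = 50))
      )), seed = 1),
    class = "cefapop_domain_error"
  )
})

test_that("generated studies respect the published design margins", {
  ds <- generate_study(generator_config(), seed = 77)
  expect_equal(n_subjects(ds), 78)
  counts <- table(ds$data$id[ds$data$evid == 0])
  expect_true(all(counts >= 2 & counts <= 11))
  expect_equal(median(counts), 9)
  expect_gt(n_observations(ds), 570)
  expect_lt(n_observations(ds), 690)
  obs_times <- unique(ds$data$time[ds$data$evid == 0])
  expect_true(all(obs_times %in% cefapop:::PROTOCOL_TIMES))
  # every generated dataset passes its own validation on re-entry
  expect_s3_class(study_dataset(ds$data), "study_dataset")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_subjects = 20)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_study(generate_study(cfg, seed = 5), p1)
  write_study(generate_study(cfg, seed = 5), p2)
  expect_identical(readLines(p1), readLines(p2))
  # and differs under another seed
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_study(generate_study(cfg, seed = 6), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("zero variability puts every observation on the typical curve
           and BLOQ flags are consistent", {
  cfg0 <- generator_config(n_subjects = 6, omega = matrix(0, 4, 4),
                           sigma = c(0, 0))
  ds0 <- generate_study(cfg0, seed = 2)
  obs <- ds0$data[ds0$data$evid == 0, ]
  p <- pk_params(REF_TV[1], REF_TV[2], REF_TV[3], REF_TV[4])
  expect_equal(obs$conc,
               concentration(p, dose_events(0, 25), obs$time),
               tolerance = 1e-10)

  ds <- generate_study(generator_config(), seed = 30)
  obs <- ds$data[ds$data$evid == 0, ]
  expect_true(all(obs$conc[obs$bloq == 1] <= 0.2))
  expect_true(all(obs$conc[obs$bloq == 0] > 0.2))
})

test_that("simulated noise follows the combined error model", {
  # regression of squared residuals on squared predictions recovers the
  # proportional and additive variance components
  cfg <- generator_config(n_subjects = 12500)
  ds <- generate_study(cfg, seed = 91)
  obs <- ds$data[ds$data$evid == 0, ]
  expect_gt(nrow(obs), 90000)
  truth <- attr(ds, "true_params")
  idx <- match(obs$id, truth$id)
  f <- cefapop:::conc_rowwise(
    as.matrix(truth[idx, c("V1", "V2", "CL", "Q")]), 25, obs$time)
  # squared residuals have variance ~ 2 v^2, so weight by 1/v^2 (true v)
  v <- f^2 * 0.257^2 + 0.564^2
  fit <- lm(I((obs$conc - f)^2) ~ I(f^2), weights = 1 / v^2)
  expect_lt(abs(coef(fit)[[2]] / 0.257^2 - 1), 0.10)
  expect_lt(abs(coef(fit)[[1]] / 0.564^2 - 1), 0.10)
})

test_that("the recovery harness aggregates per-replicate estimates", {
  cfg <- generator_config(n_subjects = 10,
                          spec = pop_model_spec(omega_structure = "diagonal"))
  rep3 <- suppressWarnings(suppressMessages(recovery_experiment(
    cfg, n_replicates = 3, seed = 2,
    spec = pop_model_spec(omega_structure = "diagonal"),
    control = fast_ctrl
  )))
  expect_s3_class(rep3, "recovery_report")
  expect_equal(nrow(rep3$per_replicate) + rep3$n_failed, 3)
  expect_setequal(rep3$summary$parameter, c("V1", "V2", "CL", "Q"))
  expect_true(all(is.finite(rep3$summary$median_rel_bias)))
  expect_error(recovery_experiment(cfg, n_replicates = 2),
               class = "cefapop_domain_error")
})
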