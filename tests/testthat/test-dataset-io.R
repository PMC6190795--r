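test_that("a minimal well-formed file reads into a validated dataset", {
  df <- toy_study_df(times = c(10, 60), conc = c(50, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  ds <- read_study(path)
  expect_s3_class(ds, "study_dataset")
  expect_equal(n_subjects(ds), 1)
  expect_equal(n_observations(ds), 2)
  expect_equal(sum(ds$data$evid == 1), 1)
  expect_equal(ds$data$amt[ds$data$evid == 1], 25)
})

test_that("write/read roundtrip reproduces a generated study", {
  ds <- generate_study(generator_config(n_subjects = 15), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(ds, path)
  back <- read_study(path)
  expect_equal(back$data, ds$data, tolerance = 1e-12)
  expect_equal(n_observations(back), n_observations(ds))
  # one dose row plus k observation rows per subject
  per_id <- table(ds$data$id[ds$data$evid == 1])
  expect_true(all(per_id == 1))
})

test_that("column remapping via a dialect config works", {
  df <- toy_study_df(times = c(10, 60), conc = c(50, 20))
  names(df)[names(df) == "conc"] <- "DV"
  names(df)[names(df) == "amt"] <- "AMT"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  dialect_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("conc: DV", "amt: AMT"), dialect_path)
  ds <- read_study(path, dialect = dialect_path)
  expect_equal(n_observations(ds), 2)
  expect_equal(sort(ds$data$conc[ds$data$evid == 0]), c(20, 50))
})

test_that("malformed inputs are rejected with the documented errors", {
  # negative observation time, row cited
  df <- toy_study_df(times = c(-5, 60), conc = c(50, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(read_study(path), class = "cefapop_validation_error")
  expect_error(read_study(path), "row")

  # missing required column, named in the message
  df2 <- toy_study_df(times = 10, conc = 50)
  df2$conc <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path2, row.names = FALSE, quote = FALSE)
  expect_error(read_study(path2), class = "cefapop_format_error")
  expect_error(read_study(path2), "conc")

  # covariate varying within subject
  df3 <- toy_study_df(times = c(10, 60), conc = c(50, 20))
  df3$bw[3] <- 30
  expect_error(study_dataset(df3), class = "cefapop_validation_error")
  expect_error(study_dataset(df3), "varies within subject")

  # missing covariate
  df4 <- toy_study_df(times = 10, conc = 50)
  df4$age[1] <- NA
  expect_error(study_dataset(df4), class = "cefapop_validation_error")

  # categorical code outside its set
  df5 <- toy_study_df(times = 10, conc = 50, sex = 3)
  expect_error(study_dataset(df5), class = "cefapop_validation_error")

  # observation before the first dose
  df6 <- toy_study_df(times = c(10, 60), conc = c(50, 20))
  df6$time[1] <- 30 # dose moved after first observation
  expect_error(study_dataset(df6), class = "cefapop_validation_error")

  # non-positive concentration without a BLOQ flag
  df7 <- toy_study_df(times = c(10, 60), conc = c(-1, 20))
  expect_error(study_dataset(df7), class = "cefapop_validation_error")
})

test_that("writing rejects an empty dataset and unwritable paths", {
  ds <- generate_study(generator_config(n_subjects = 3), seed = 1)
  expect_error(write_study(ds, "/nonexistent-dir/x/y.csv"),
               class = "cefapop_io_error")
  ds$data <- ds$data[0, ]
  expect_error(write_study(ds, tempfile()),
               class = "cefapop_validation_error")
})

test_that("covariate summaries match the emulated population", {
  ds <- generate_study(generator_config(), seed = 42)
  s <- summarize_covariates(ds)
  bw <- s$continuous[s$continuous$covariate == "bw", ]
  cr <- s$continuous[s$continuous$covariate == "creatinine", ]
  # truncated-normal generators around the published moments
  expect_lt(abs(bw$mean - 26.13), 3)
  expect_lt(abs(cr$mean - 0.91), 0.15)
  expect_gte(bw$min, 4.5)
  expect_lte(bw$max, 56)
  # categorical counts conserve the subject count
  for (cv in unique(s$categorical$covariate)) {
    expect_equal(sum(s$categorical$n[s$categorical$covariate == cv]), 78)
  }
})

test_that("single-subject summaries use the declared SD convention", {
  ds <- study_dataset(toy_study_df(times = c(10, 60), conc = c(50, 20)))
  s <- summarize_covariates(ds)
  bw <- s$continuous[s$continuous$covariate == "bw", ]
  expect_equal(bw$mean, 20)
  expect_equal(bw$median, 20)
  expect_true(is.na(bw$sd))
})
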