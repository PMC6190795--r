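## End-to-end orchestration: simulate (or read) -> fit -> optional
## covariate search -> bootstrap / VPC -> PTA -> cutoff, with one master
## seed deterministically deriving every stage seed and all tables stamped
## with the seed and a configuration hash.

#' Pipeline run configuration
#'
#' @param output_dir Directory for all outputs (created if missing).
#' @param seed Master seed; stage seeds are derived from it.
#' @param generator A [generator_config()] used when `data_path` is
#'   `NULL`.
#' @param data_path Optional path of an existing study file to analyse
#'   instead of simulating one.
#' @param spec Base [pop_model_spec()] for the fit.
#' @param candidates Optional list of [covariate_candidate()] terms; when
#'   given, a stepwise search runs after the base fit.
#' @param n_bootstrap Bootstrap replicates (0 skips the bootstrap).
#' @param vpc_reps VPC replicates (0 skips the VPC).
#' @param pta A [pta_config()].
#' @param control Optimizer control for all fits.
#' @return Object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1,
                       generator = generator_config(), data_path = NULL,
                       spec = pop_model_spec(), candidates = NULL,
                       n_bootstrap = 100, vpc_reps = 500,
                       pta = pta_config(), control = list()) {
  structure(list(
    output_dir = output_dir, seed = as.integer(seed),
    generator = generator, data_path = data_path, spec = spec,
    candidates = candidates, n_bootstrap = n_bootstrap,
    vpc_reps = vpc_reps, pta = pta, control = control
  ), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys (all optional except `output_dir`): `output_dir`,
#' `seed`, `data_path`, `n_subjects`, `n_bootstrap`, `vpc_reps`,
#' `pta_n_subjects`, and `omega_structure`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$output_dir)) {
    stop_cefapop("cefapop_format_error",
                 "run config must name an output_dir")
  }
  gen_args <- list()
  if (!is.null(y$n_subjects)) gen_args$n_subjects <- y$n_subjects
  pta_args <- list()
  if (!is.null(y$pta_n_subjects)) pta_args$n_subjects <- y$pta_n_subjects
  spec <- pop_model_spec(
    omega_structure = y$omega_structure %||% "full"
  )
  run_config(
    output_dir = y$output_dir,
    seed = y$seed %||% 1,
    generator = do.call(generator_config, gen_args),
    data_path = y$data_path,
    spec = spec,
    n_bootstrap = y$n_bootstrap %||% 100,
    vpc_reps = y$vpc_reps %||% 500,
    pta = do.call(pta_config, pta_args)
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing every table (with seed and config
#' hash in a header comment), a machine-readable `summary.json`, and a
#' plain-text log. A rerun with the same configuration and master seed
#' reproduces every output.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `run_report`: key results
#'   (`fit`, `search`, `bootstrap`, `vpc`, `pta`, `cutoff`) and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      stop_cefapop("cefapop_io_error",
                   "cannot create output directory: ", out_dir)
    }
  }
  cfg_hash <- fnv1a_hash(paste(deparse(config), collapse = "\n"))
  seeds <- derive_seeds(config$seed, 4)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    writeLines(msg, log_con)
    message(msg)
  }
  stamp <- function(df, name) {
    path <- file.path(out_dir, name)
    write_stamped_table(df, path, seed = config$seed,
                        config_hash = cfg_hash)
    path
  }
  paths <- character(0)
  fail <- function(stage, e) {
    log_line("stage '", stage, "' FAILED: ", conditionMessage(e))
    stop_cefapop("cefapop_pipeline_error",
                 "pipeline aborted in stage '", stage, "': ",
                 conditionMessage(e))
  }

  # stage 1: data
  dataset <- tryCatch({
    if (!is.null(config$data_path)) {
      log_line("reading study data from ", config$data_path)
      read_study(config$data_path)
    } else {
      log_line("simulating study (", config$generator$n_subjects,
               " subjects, seed ", seeds[1], ")")
      ds <- generate_study(config$generator, seed = seeds[1])
      paths <- c(paths, file.path(out_dir, "study.csv"))
      write_study(ds, file.path(out_dir, "study.csv"))
      truth <- attr(ds, "true_params")
      if (!is.null(truth)) {
        paths <- c(paths, stamp(truth, "true_params.csv"))
      }
      ds
    }
  }, error = function(e) fail("data", e))
  log_line(n_subjects(dataset), " subjects, ", n_observations(dataset),
           " observations")

  # stage 2: base fit
  fit <- tryCatch(
    fit_popmodel(dataset, config$spec, control = config$control),
    error = function(e) fail("fit", e)
  )
  log_line(sprintf("base fit: OFV %.3f, BIC %.3f, converged %s",
                   fit$ofv, fit$bic, fit$converged))
  paths <- c(paths, stamp(estimate_table(fit), "estimate.csv"))
  ebes <- empirical_bayes(dataset, fit)
  paths <- c(paths, stamp(
    data.frame(ebes$params,
               ebes$etas[match(ebes$params$id, rownames(ebes$etas)), ,
                         drop = FALSE]),
    "ebe.csv"))
  paths <- c(paths, stamp(gof_tables(dataset, fit), "gof.csv"))

  # stage 3: covariate search (optional)
  search <- NULL
  if (!is.null(config$candidates) && length(config$candidates)) {
    search <- tryCatch(
      stepwise_search(dataset, config$spec, config$candidates,
                      control = config$control),
      error = function(e) fail("covariates", e)
    )
    log_line("covariate search selected: ",
             if (length(search$spec$terms)) {
               paste(names(search$spec$terms), collapse = ", ")
             } else "none")
    paths <- c(paths, stamp(search$trace, "covariate_trace.csv"))
    fit <- search$fit
  }

  # stage 4: bootstrap and VPC
  boot <- NULL
  if (config$n_bootstrap >= 2) {
    boot <- tryCatch(
      bootstrap_popmodel(dataset, fit$spec, n_reps = config$n_bootstrap,
                         seed = seeds[2], control = config$control),
      error = function(e) fail("bootstrap", e)
    )
    log_line("bootstrap: ", nrow(boot$replicates), " replicate(s), ",
             boot$n_failed, " failed")
    paths <- c(paths, stamp(boot$summary, "bootstrap_summary.csv"))
  }
  vpc_res <- NULL
  if (config$vpc_reps >= 1) {
    vpc_res <- tryCatch(
      vpc(dataset, fit, n_reps = config$vpc_reps, seed = seeds[3]),
      error = function(e) fail("vpc", e)
    )
    log_line("VPC: ", vpc_res$n_simulated, " simulated record(s)")
    paths <- c(paths, stamp(vpc_res$bands, "vpc_bands.csv"))
  }

  # stage 5: PTA and cutoff
  pta_res <- tryCatch({
    draws <- simulate_population(fit, config$pta$n_subjects,
                                 seed = seeds[4])
    pta_table(draws, config$pta)
  }, error = function(e) fail("pta", e))
  log_line("PK/PD cutoff: ",
           if (is.na(pta_res$cutoff)) "below grid" else
             paste0(pta_res$cutoff, " mg/L"))
  paths <- c(paths, stamp(pta_res$table, "pta_table.csv"))

  summary <- list(
    seed = config$seed, config_hash = cfg_hash,
    n_subjects = n_subjects(dataset),
    n_observations = n_observations(dataset),
    theta = as.list(fit$theta$tv), coef = as.list(fit$theta$coef),
    sigma = as.list(fit$sigma),
    bsv_cv_pct = if (length(fit$omega)) {
      as.list(setNames(omega_to_cv(diag(as.matrix(fit$omega))),
                       fit$spec$eta))
    } else NULL,
    ofv = fit$ofv, bic = fit$bic, converged = fit$converged,
    selected_covariates = if (!is.null(search)) {
      names(search$spec$terms)
    } else NULL,
    cutoff_mg_L = pta_res$cutoff
  )
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, json_path, log_path)
  log_line("pipeline complete")

  invisible(structure(
    list(fit = fit, search = search, bootstrap = boot, vpc = vpc_res,
         pta = pta_res, cutoff = pta_res$cutoff, dataset = dataset,
         paths = paths, config_hash = cfg_hash),
    class = "run_report"
  ))
}

#' @noRd
estimate_table <- function(fit) {
  tv <- fit$theta$tv
  sec <- secondary_parameters(
    pk_params(tv[["V1"]], tv[["V2"]], tv[["CL"]], tv[["Q"]]))
  rows <- data.frame(
    parameter = c(paste0("tv", names(tv)), "prop_sd", "add_sd",
                  names(sec), "ofv", "bic"),
    value = c(unname(tv), fit$sigma[["prop"]], fit$sigma[["add"]],
              unname(unclass(sec)), fit$ofv, fit$bic)
  )
  rows
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  print(x$fit)
  if (!is.null(x$pta)) print(x$pta)
  invisible(x)
}
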