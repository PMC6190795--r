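## Monte Carlo probability of target attainment: simulate the population
## under the multi-dose regimen, measure the time total serum
## concentration spends above MIC/fu thresholds, and derive the fT>MIC
## based PK/PD susceptibility cutoff.

#' Configuration of the target-attainment simulation
#'
#' Defaults reproduce the assessed regimen: 25 mg/kg IV boluses at 0, 360,
#' 720 and 1080 min over a 1440-min horizon, a doubling MIC grid
#' 0.25-8 mg/L, unbound fraction 0.64 (36% serum protein binding),
#' 2500 simulated subjects, population quantiles 90% and 95%, and a target
#' of free drug above MIC for 50% of the dosing interval.
#'
#' @param dose Dose per administration (mg/kg).
#' @param dose_times Administration times (min).
#' @param horizon Evaluation horizon (min); dose times must precede it.
#' @param mic_grid Ascending MIC grid (mg/L).
#' @param unbound_fraction Unbound drug fraction in serum, in (0, 1].
#' @param n_subjects Monte Carlo population size.
#' @param quantiles Population quantiles reported (fraction of subjects
#'   attaining at least the reported time).
#' @param target_fraction Target fraction of the horizon for the cutoff
#'   rule.
#' @param seed Default seed used when the simulation functions are not
#'   given one explicitly.
#' @return Object of class `pta_config`.
#' @export
pta_config <- function(dose = 25, dose_times = c(0, 360, 720, 1080),
                       horizon = 1440,
                       mic_grid = c(0.25, 0.5, 1, 2, 4, 8),
                       unbound_fraction = 0.64, n_subjects = 2500,
                       quantiles = c(0.90, 0.95), target_fraction = 0.50,
                       seed = 1) {
  if (unbound_fraction <= 0 || unbound_fraction > 1) {
    stop_cefapop("cefapop_domain_error",
                 "unbound_fraction must lie in (0, 1]")
  }
  if (any(dose_times >= horizon)) {
    stop_cefapop("cefapop_domain_error",
                 "all dose times must precede the horizon")
  }
  if (any(mic_grid <= 0) || is.unsorted(mic_grid, strictly = TRUE)) {
    stop_cefapop("cefapop_domain_error",
                 "mic_grid must be positive and strictly ascending")
  }
  if (any(quantiles <= 0 | quantiles >= 1)) {
    stop_cefapop("cefapop_domain_error", "quantiles must lie in (0, 1)")
  }
  structure(list(
    dose = dose, dose_times = sort(dose_times), horizon = horizon,
    mic_grid = mic_grid, unbound_fraction = unbound_fraction,
    n_subjects = n_subjects, quantiles = quantiles,
    target_fraction = target_fraction, seed = seed
  ), class = "pta_config")
}

#' Simulate individual parameter sets from a population estimate
#'
#' Draws random-effect vectors from the multivariate normal with the full
#' omega covariance (correlations preserved) and maps them through the
#' exponential model at the typical values. Covariate effects and residual
#' error are deliberately excluded: the draws are individual "true"
#' disposition curves.
#'
#' @param est A `pop_estimate` (e.g. [reference_estimate()] or a fit).
#' @param n_subjects Number of draws.
#' @param seed Integer seed.
#' @return Data frame with columns `V1`, `V2`, `CL`, `Q`, one row per
#'   simulated subject.
#' @export
simulate_population <- function(est, n_subjects = 2500, seed = 1) {
  spec <- est$spec
  k <- length(spec$eta)
  tv <- est$theta$tv[STRUCTURAL_PARAMS]
  set.seed(seed)
  full_eta <- matrix(0, n_subjects, 4,
                     dimnames = list(NULL, STRUCTURAL_PARAMS))
  if (k > 0) {
    omega <- as.matrix(est$omega)
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8 * max(abs(ev), 1e-12))) {
      stop_cefapop("cefapop_domain_error",
                   "omega is not positive semidefinite")
    }
    if (any(omega != 0)) {
      etas <- MASS::mvrnorm(n_subjects, rep(0, k), omega)
      if (is.null(dim(etas))) etas <- matrix(etas, ncol = k)
      full_eta[, spec$eta] <- etas
    }
  }
  out <- as.data.frame(sweep(exp(full_eta), 2, tv, `*`))
  names(out) <- STRUCTURAL_PARAMS
  out
}

#' Time above a total-concentration threshold
#'
#' Total measure of the set of times in `[0, horizon]` at which the
#' closed-form multi-dose curve exceeds `threshold`. After each bolus the
#' curve decays strictly within the inter-dose interval, so each interval
#' holds at most one down-crossing, located by bisection to better than
#' 0.01 min.
#'
#' @param params A [pk_params()] object, or a matrix/data frame of draws
#'   with columns `V1`, `V2`, `CL`, `Q`.
#' @param config A [pta_config()] (supplies regimen and horizon).
#' @param threshold Total serum concentration threshold (mg/L), > 0.
#' @return Minutes above threshold: scalar for a single parameter set,
#'   vector over rows otherwise.
#' @export
time_above_threshold <- function(params, config = pta_config(), threshold) {
  if (any(threshold <= 0)) {
    stop_cefapop("cefapop_domain_error", "threshold must be > 0")
  }
  single <- inherits(params, "pk_params") ||
    (is.numeric(params) && is.null(dim(params)))
  mat <- if (single) {
    matrix(unclass(as_pk_params(params)), nrow = 1)
  } else {
    as.matrix(as.data.frame(params)[, STRUCTURAL_PARAMS])
  }
  res <- time_above_cpp(mat, config$dose_times,
                        rep(config$dose, length(config$dose_times)),
                        config$horizon, threshold)
  if (single && length(threshold) == 1) res[1, 1] else drop(res)
}

#' Probability-of-target-attainment table
#'
#' For each MIC on the grid: the total-concentration threshold
#' `MIC / unbound_fraction`, the time above that threshold attained by at
#' least each population quantile of subjects (the `(1 - q)` percentile of
#' the per-subject time distribution, order statistics with linear
#' interpolation), and the same as a percentage of the horizon. The
#' PK/PD cutoff derived from the table (90% quantile, target fraction of
#' the horizon) is attached.
#'
#' @param draws Data frame of simulated subjects from
#'   [simulate_population()] (>= 100 rows).
#' @param config A [pta_config()].
#' @return Object of class `pta_result`: `table` (data frame: `mic`,
#'   `threshold`, then `time_q90`/`pct_q90`-style columns per quantile),
#'   `cutoff` (mg/L, `NA` when below the grid), `config`.
#' @export
pta_table <- function(draws, config = pta_config()) {
  draws <- as.data.frame(draws)
  if (nrow(draws) < 100) {
    stop_cefapop("cefapop_domain_error",
                 "pta_table needs at least 100 simulated subjects")
  }
  thresholds <- config$mic_grid / config$unbound_fraction
  times <- time_above_cpp(
    as.matrix(draws[, STRUCTURAL_PARAMS]), config$dose_times,
    rep(config$dose, length(config$dose_times)),
    config$horizon, thresholds
  )
  tab <- data.frame(mic = config$mic_grid,
                    threshold = signif_even(thresholds, 3))
  for (q in config$quantiles) {
    tq <- apply(times, 2, stats::quantile, probs = 1 - q, type = 8,
                names = FALSE)
    lab <- sprintf("q%02d", round(100 * q))
    tab[[paste0("time_", lab)]] <- tq
    tab[[paste0("pct_", lab)]] <- signif_even(100 * tq / config$horizon, 3)
  }
  res <- structure(list(table = tab, cutoff = NA_real_, config = config),
                   class = "pta_result")
  res$cutoff <- pkpd_cutoff(res, config, quiet = TRUE)
  res
}

#' @export
print.pta_result <- function(x, ...) {
  cat("Probability of target attainment (time above MIC/fu)\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (is.na(x$cutoff)) {
    cat("PK/PD cutoff: below the MIC grid\n")
  } else {
    cat(sprintf("PK/PD cutoff: %g mg/L (>= %.0f%% of a %g-min horizon in %d%% of subjects)\n",
                x$cutoff, 100 * x$config$target_fraction,
                x$config$horizon, round(100 * cutoff_quantile(x$config))))
  }
  invisible(x)
}

#' @noRd
cutoff_quantile <- function(config) {
  if (any(abs(config$quantiles - 0.90) < 1e-9)) 0.90 else config$quantiles[1]
}

#' PK/PD cutoff from a target-attainment table
#'
#' The largest MIC on the grid whose 90%-population-quantile time above
#' threshold reaches at least `target_fraction * horizon`. When no MIC
#' qualifies the cutoff is below the grid and `NA` is returned with a
#' warning.
#'
#' @param result A `pta_result` from [pta_table()].
#' @param config A [pta_config()] (defaults to the one in `result`).
#' @param quiet Suppress the below-grid warning.
#' @return The cutoff MIC (mg/L), or `NA_real_` if below the grid.
#' @export
pkpd_cutoff <- function(result, config = result$config, quiet = FALSE) {
  q <- cutoff_quantile(config)
  col <- paste0("time_", sprintf("q%02d", round(100 * q)))
  if (!col %in% names(result$table)) {
    stop_cefapop("cefapop_domain_error",
                 "the PTA table does not cover the ", 100 * q,
                 "% quantile")
  }
  target <- config$target_fraction * config$horizon
  ok <- result$table[[col]] >= target
  if (!any(ok)) {
    if (!quiet) {
      warning(sprintf(
        "no MIC on the grid attains %.0f%% of the horizon at the %d%% quantile; cutoff is below %g mg/L",
        100 * config$target_fraction, round(100 * q),
        min(result$table$mic)))
    }
    return(NA_real_)
  }
  max(result$table$mic[ok])
}
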