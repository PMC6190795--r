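## Model diagnostics: nonparametric bootstrap summaries, visual predictive
## check bands, and goodness-of-fit tables.

#' Predicted concentrations for every observation row, given per-subject
#' parameters (n x 4 matrix in subject order of `flat$ids`).
#' @noRd
pred_conc_flat <- function(flat, P) {
  out <- numeric(length(flat$obs_time))
  for (i in seq_along(flat$ids)) {
    o0 <- flat$obs_offset[i] + 1L
    o1 <- flat$obs_offset[i + 1L]
    if (o1 < o0) next
    d0 <- flat$dose_offset[i] + 1L
    d1 <- flat$dose_offset[i + 1L]
    p <- pk_params(P[i, 1], P[i, 2], P[i, 3], P[i, 4])
    out[o0:o1] <- concentration(
      p, dose_events(flat$dose_time[d0:d1], flat$dose_amt[d0:d1]),
      flat$obs_time[o0:o1]
    )
  }
  out
}

#' Nonparametric bootstrap of the population fit
#'
#' Each replicate resamples subjects with replacement to the original
#' subject count (design, covariates and observations travel together),
#' refits the model (started from the base estimate), and records the
#' typical values, residual SDs, between-subject CV%, and the secondary
#' parameters derived from the replicate's typical values. Replicates
#' whose fit fails are dropped and counted; more than 20% failures aborts.
#'
#' @param dataset A [study_dataset()].
#' @param spec A [pop_model_spec()].
#' @param n_reps Number of bootstrap replicates (>= 2; 1000 is a
#'   conventional production choice, small values keep test runs short).
#' @param seed Integer seed (replicate draws are derived from it).
#' @param dose Reference dose (mg/kg) for the secondary parameters.
#' @param control Optimizer control for the refits.
#' @return Object of class `boot_summary`: `summary` (per parameter:
#'   mean, se, cv_pct, median, p2.5, p97.5 across replicates),
#'   `replicates` (per-replicate parameter table), `n_failed`, `base_fit`.
#' @export
bootstrap_popmodel <- function(dataset, spec = pop_model_spec(),
                               n_reps = 1000, seed = 1, dose = 25,
                               control = list()) {
  if (n_reps < 2) {
    stop_cefapop("cefapop_domain_error", "n_reps must be >= 2")
  }
  base_fit <- fit_popmodel(dataset, spec, control = control)
  d <- dataset$data
  ids <- unique(d$id)
  n <- length(ids)
  rep_seeds <- derive_seeds(seed, n_reps)
  id_rows <- split(seq_len(nrow(d)), d$id)

  rows <- list()
  n_failed <- 0
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    draw <- sample(ids, n, replace = TRUE)
    pieces <- lapply(seq_along(draw), function(j) {
      block <- d[id_rows[[draw[j]]], , drop = FALSE]
      block$id <- sprintf("bs%04d_%s", j, draw[j])
      block
    })
    ds_r <- study_dataset(do.call(rbind, pieces))
    est <- tryCatch(
      suppressWarnings(fit_popmodel(
        dataset = ds_r, spec = spec,
        init = list(tv = base_fit$theta$tv, coef = base_fit$theta$coef,
                    omega = base_fit$omega, sigma = base_fit$sigma),
        control = control
      )),
      error = function(e) NULL
    )
    if (is.null(est) || !is.finite(est$ofv)) {
      n_failed <- n_failed + 1
      next
    }
    tv <- est$theta$tv
    sec <- secondary_parameters(
      pk_params(tv[["V1"]], tv[["V2"]], tv[["CL"]], tv[["Q"]]), dose)
    bsv <- if (length(est$omega)) {
      setNames(omega_to_cv(diag(as.matrix(est$omega))),
               paste0("bsv_", est$spec$eta))
    } else {
      NULL
    }
    rows[[length(rows) + 1]] <- data.frame(
      replicate = r, n_subjects = n_subjects(ds_r),
      tvV1 = tv[["V1"]], tvV2 = tv[["V2"]], tvCL = tv[["CL"]],
      tvQ = tv[["Q"]],
      prop_sd = est$sigma[["prop"]], add_sd = est$sigma[["add"]],
      AUC = sec[["AUC"]], Beta = sec[["beta"]],
      hl_beta = sec[["hl_beta"]], Alpha = sec[["alpha"]],
      hl_alpha = sec[["hl_alpha"]], Vss = sec[["Vss"]],
      MRT = sec[["MRT"]], Vz = sec[["Vz"]],
      t(bsv %||% setNames(numeric(0), character(0))),
      row.names = NULL
    )
  }
  if (n_failed / n_reps > 0.2) {
    stop_cefapop("cefapop_numeric_error",
                 sprintf("bootstrap aborted: %d of %d replicates failed",
                         n_failed, n_reps))
  }
  reps <- do.call(rbind, rows)
  param_cols <- setdiff(names(reps), "replicate")
  summ <- do.call(rbind, lapply(param_cols, function(cn) {
    x <- reps[[cn]]
    m <- mean(x)
    se <- stats::sd(x)
    data.frame(parameter = cn, mean = m, se = se,
               cv_pct = 100 * se / m, median = stats::median(x),
               p2.5 = unname(stats::quantile(x, 0.025)),
               p97.5 = unname(stats::quantile(x, 0.975)))
  }))
  structure(list(summary = summ, replicates = reps, n_failed = n_failed,
                 base_fit = base_fit),
            class = "boot_summary")
}

#' @export
print.boot_summary <- function(x, ...) {
  cat(sprintf("Bootstrap summary over %d replicate(s) (%d failed)\n",
              nrow(x$replicates) + x$n_failed, x$n_failed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates each subject's sampling design `n_reps` times from the
#' estimate (random effects from the omega covariance, residuals from the
#' combined error model), then compares observed 10/50/90 percentiles per
#' time bin with the simulation-based percentile bands (90% confidence
#' bands across replicates). Negative simulated concentrations are
#' retained for the percentile computation. Bins default to the distinct
#' observed (nominal) sampling times; bins without observations are
#' dropped with a warning.
#'
#' @param dataset A [study_dataset()].
#' @param est A `pop_estimate`.
#' @param n_reps Number of replicate studies (default 500).
#' @param seed Integer seed.
#' @param bins Optional numeric vector of bin centres (defaults to the
#'   distinct observation times).
#' @return Object of class `vpc_result`: `bands` (per bin: time, n_obs,
#'   observed p10/p50/p90, simulated p10/p50/p90 with `_lo`/`_hi` 90%
#'   bands), `n_reps`, `n_simulated` (observation count x `n_reps`).
#' @export
vpc <- function(dataset, est, n_reps = 500, seed = 1, bins = NULL) {
  d <- dataset$data
  obs <- d[d$evid == 0, c("id", "time", "conc")]
  flat_ids <- unique(d$id)
  covs <- subject_covariates(dataset)
  spec <- est$spec
  k <- length(spec$eta)
  omega <- if (k > 0) as.matrix(est$omega) else matrix(0, 0, 0)
  sigma <- unname(unlist(est$sigma))[1:2]
  mult <- covariate_multipliers(est$theta, covs, spec)
  tv <- est$theta$tv[STRUCTURAL_PARAMS]
  P0 <- sweep(mult, 2, tv, `*`)

  bins <- bins %||% sort(unique(obs$time))
  bin_of <- function(t) bins[max.col(-abs(outer(t, bins, `-`)))]
  obs$bin <- bin_of(obs$time)

  set.seed(seed)
  sims <- vector("list", length(flat_ids))
  for (i in seq_along(flat_ids)) {
    sid <- flat_ids[i]
    rows <- d[d$id == sid, , drop = FALSE]
    doses <- rows[rows$evid == 1, c("time", "amt")]
    tt <- rows$time[rows$evid == 0]
    if (!length(tt)) next
    if (k > 0 && any(omega != 0)) {
      etas_i <- MASS::mvrnorm(n_reps, rep(0, k), omega)
      if (is.null(dim(etas_i))) etas_i <- matrix(etas_i, ncol = k)
    } else {
      etas_i <- matrix(0, n_reps, max(k, 1))
    }
    full_eta <- matrix(0, n_reps, 4)
    colnames(full_eta) <- STRUCTURAL_PARAMS
    if (k > 0) full_eta[, spec$eta] <- etas_i[, seq_len(k)]
    pars <- sweep(exp(full_eta), 2, P0[i, ], `*`)
    V1 <- pars[, 1]; V2 <- pars[, 2]; CL <- pars[, 3]; Q <- pars[, 4]
    k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
    s <- k10 + k12 + k21
    beta <- 0.5 * (s - sqrt(pmax(s^2 - 4 * k21 * k10, 0)))
    alpha <- k21 * k10 / beta
    a1 <- (alpha - k21) / (alpha - beta)
    a2 <- (k21 - beta) / (alpha - beta)
    f <- matrix(0, n_reps, length(tt))
    for (dd in seq_len(nrow(doses))) {
      dt <- tt - doses$time[dd]
      on <- dt >= 0
      if (any(on)) {
        f[, on] <- f[, on] + (doses$amt[dd] / V1) *
          (a1 * exp(-outer(alpha, dt[on])) + a2 * exp(-outer(beta, dt[on])))
      }
    }
    e1 <- matrix(stats::rnorm(length(f), 0, sigma[1]), nrow(f))
    e2 <- matrix(stats::rnorm(length(f), 0, sigma[2]), nrow(f))
    y <- f * (1 + e1) + e2
    sims[[i]] <- data.frame(
      rep = rep(seq_len(n_reps), times = length(tt)),
      bin = rep(bin_of(tt), each = n_reps),
      y = as.vector(y)
    )
  }
  sim <- do.call(rbind, sims)

  probs <- c(0.10, 0.50, 0.90)
  used_bins <- sort(unique(obs$bin))
  empty <- setdiff(bins, used_bins)
  if (length(empty)) {
    warning("dropping empty VPC bin(s): ", paste(empty, collapse = ", "))
  }
  bands <- do.call(rbind, lapply(used_bins, function(b) {
    yo <- obs$conc[obs$bin == b]
    sb <- sim[sim$bin == b, ]
    # percentile per replicate, then median and 90% band across replicates
    per_rep <- vapply(split(sb$y, sb$rep), function(v) {
      stats::quantile(v, probs, names = FALSE)
    }, numeric(3))
    obs_q <- stats::quantile(yo, probs, names = FALSE)
    band <- apply(per_rep, 1, stats::quantile,
                  probs = c(0.05, 0.50, 0.95), names = FALSE)
    data.frame(
      time = b, n_obs = length(yo),
      obs_p10 = obs_q[1], obs_p50 = obs_q[2], obs_p90 = obs_q[3],
      sim_p10_lo = band[1, 1], sim_p10 = band[2, 1], sim_p10_hi = band[3, 1],
      sim_p50_lo = band[1, 2], sim_p50 = band[2, 2], sim_p50_hi = band[3, 2],
      sim_p90_lo = band[1, 3], sim_p90 = band[2, 3], sim_p90_hi = band[3, 3]
    )
  }))
  rownames(bands) <- NULL
  structure(list(bands = bands, n_reps = n_reps,
                 n_simulated = as.integer(nrow(obs) * n_reps)),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf(
    "Visual predictive check: %d replicate(s), %d simulated record(s), %d bin(s)\n",
    x$n_reps, x$n_simulated, nrow(x$bands)))
  invisible(x)
}

#' Goodness-of-fit tables
#'
#' Population predictions (`pred`, at eta = 0), individual predictions
#' (`ipred`, at the conditional modes), and weighted residuals
#' `(obs - pred)/sqrt(var(pred))` under the combined residual model
#' (`wres` against the population prediction, `iwres` against the
#' individual prediction), for every observation entering the fit.
#'
#' @param dataset A [study_dataset()].
#' @param est A `pop_estimate`.
#' @return Data frame with `id`, `time`, `obs`, `pred`, `ipred`, `wres`,
#'   `iwres`.
#' @export
gof_tables <- function(dataset, est) {
  ebes <- empirical_bayes(dataset, est)
  flat <- flatten_study(dataset)
  covs <- subject_covariates(dataset)
  mult <- covariate_multipliers(est$theta, covs, est$spec)
  P_typ <- sweep(mult, 2, est$theta$tv[STRUCTURAL_PARAMS], `*`)
  pred <- pred_conc_flat(flat, P_typ)
  sigma <- est$sigma
  out <- ebes$pred
  out$pred <- pred
  out$wres <- (out$obs - pred) / sqrt(residual_variance(pred, sigma))
  out$iwres <- (out$obs - out$ipred) /
    sqrt(residual_variance(out$ipred, sigma))
  out[c("id", "time", "obs", "pred", "ipred", "wres", "iwres")]
}
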