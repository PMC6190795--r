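## Maximum-likelihood estimation of the population model: outer
## quasi-Newton optimization over (log typical values, covariate
## coefficients, log-Cholesky omega factors, log residual SDs), with the
## FOCE-type objective evaluated in compiled code. Omega is parameterized
## through log-Cholesky factors so every iterate is positive definite.

#' @noRd
chol_to_omega <- function(par, k) {
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

#' @noRd
omega_to_chol <- function(omega) {
  k <- nrow(omega)
  L <- t(chol(omega))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

#' Naive two-stage initial values
#'
#' Per subject (>= 3 quantifiable observations): a log-linear fit to the
#' last three points gives the terminal slope; the trapezoid AUC plus the
#' extrapolated tail gives clearance; `Vz = CL/beta`. Typical-value seeds
#' are the medians across subjects with the heuristic split `V1 = 0.4 Vz`,
#' `V2 = 0.6 Vz`, and `Q = 2 CL`. Omega starts at 0.1 on the diagonal,
#' sigma at (0.2, 0.5).
#'
#' @param dataset A [study_dataset()].
#' @param spec A [pop_model_spec()].
#' @return List with `tv`, `coef`, `omega`, `sigma` initial values.
#' @export
initial_values <- function(dataset, spec = pop_model_spec()) {
  subs <- split_subjects(dataset)
  cl_i <- vz_i <- numeric(0)
  for (s in subs) {
    obs <- s$observations[s$observations$bloq == 0, ]
    if (nrow(obs) < 3) next
    obs <- obs[order(obs$time), ]
    tail_obs <- utils::tail(obs, 3)
    if (any(tail_obs$conc <= 0)) next
    sl <- stats::coef(stats::lm(log(conc) ~ time, data = tail_obs))[["time"]]
    if (!is.finite(sl) || sl >= 0) next
    beta_i <- -sl
    dose <- sum(s$doses$amount)
    # trapezoid from t=0 (carry first observed value back) plus tail
    tt <- c(0, obs$time)
    cc <- c(obs$conc[1], obs$conc)
    auc <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2) +
      utils::tail(obs$conc, 1) / beta_i
    if (auc <= 0) next
    cl_i <- c(cl_i, dose / auc)
    vz_i <- c(vz_i, dose / auc / beta_i)
  }
  if (!length(cl_i)) {
    stop_cefapop("cefapop_validation_error",
                 "no subject has enough observations to seed the fit")
  }
  cl0 <- stats::median(cl_i)
  vz0 <- stats::median(vz_i)
  k <- length(spec$eta)
  omega0 <- if (k > 0) diag(0.1, k) else matrix(0, 0, 0)
  list(
    tv = c(V1 = 0.4 * vz0, V2 = 0.6 * vz0, CL = cl0, Q = 2 * cl0),
    coef = setNames(rep(0, length(spec$terms)), names(spec$terms)),
    omega = omega0,
    sigma = c(prop = 0.2, add = 0.5)
  )
}

#' @noRd
pack_par <- function(init, spec, fix) {
  par <- log(init$tv[STRUCTURAL_PARAMS])
  names(par) <- paste0("log_tv", STRUCTURAL_PARAMS)
  lower <- rep(-Inf, 4)
  if (length(spec$terms)) {
    cf <- init$coef[names(spec$terms)]
    cf[is.na(cf)] <- 0
    names(cf) <- names(spec$terms)
    par <- c(par, cf)
    lower <- c(lower, rep(-Inf, length(cf)))
  }
  k <- length(spec$eta)
  est_omega <- k > 0 && is.null(fix$omega)
  if (est_omega) {
    if (spec$omega_structure == "full") {
      op <- omega_to_chol(init$omega)
      names(op) <- paste0("omchol", seq_along(op))
    } else {
      op <- 0.5 * log(diag(init$omega))
      names(op) <- paste0("logomsd", spec$eta)
    }
    par <- c(par, op)
    lower <- c(lower, rep(-Inf, length(op)))
  }
  est_sigma <- is.null(fix$sigma)
  if (est_sigma) {
    sp <- log(pmax(init$sigma, 1e-6))
    names(sp) <- c("log_prop", "log_add")
    par <- c(par, sp)
    lower <- c(lower, rep(log(1e-6), 2))
  }
  list(par = par, lower = lower, est_omega = est_omega,
       est_sigma = est_sigma)
}

#' @noRd
unpack_par <- function(par, spec, fix, packing) {
  i <- 4
  tv <- exp(par[seq_len(4)])
  names(tv) <- STRUCTURAL_PARAMS
  p <- length(spec$terms)
  coef <- setNames(numeric(0), character(0))
  if (p > 0) {
    coef <- par[i + seq_len(p)]
    names(coef) <- names(spec$terms)
    i <- i + p
  }
  k <- length(spec$eta)
  if (k == 0) {
    omega <- matrix(0, 0, 0)
  } else if (packing$est_omega) {
    if (spec$omega_structure == "full") {
      m <- k * (k + 1) / 2
      omega <- chol_to_omega(par[i + seq_len(m)], k)
      i <- i + m
    } else {
      omega <- diag(exp(2 * par[i + seq_len(k)]), k)
      i <- i + k
    }
  } else {
    omega <- as.matrix(fix$omega)
  }
  if (k > 0) dimnames(omega) <- list(spec$eta, spec$eta)
  if (packing$est_sigma) {
    sigma <- c(prop = exp(par[[i + 1]]), add = exp(par[[i + 2]]))
  } else {
    sigma <- as_sigma(fix$sigma)
  }
  list(theta = list(tv = tv, coef = coef), omega = omega, sigma = sigma)
}

#' Fit the population model
#'
#' Minimizes the FOCE-type objective over the typical values (log scale),
#' covariate coefficients, omega (log-Cholesky factors for a full
#' structure, log-SDs for diagonal) and residual SDs (log scale, floored
#' at 1e-6). For a full omega the fit runs in two stages: a diagonal-omega
#' fit first, then the full covariance started from it with zero
#' correlations. The optimizer path is deterministic given data and
#' starting values (no multi-start).
#'
#' @param dataset A [study_dataset()].
#' @param spec A [pop_model_spec()].
#' @param init Optional list with any of `tv`, `coef`, `omega`, `sigma` to
#'   override the [initial_values()] seeds.
#' @param fix Optional list: supply `omega` and/or `sigma` to hold them
#'   fixed at the given values instead of estimating them.
#' @param control List: `rel_tol` (outer relative OFV tolerance, default
#'   1e-5), `iter_max` (default 400), `eval_max` (default 2000),
#'   `two_stage` (default TRUE for full omega).
#' @return A `pop_estimate` object: `theta` (typical values + covariate
#'   coefficients), `omega` covariance with derived `omega_cor`
#'   correlations, `sigma`, `ofv`, `bic` (`ofv + k log n_obs` with `n_obs`
#'   the fitted observation count), `n_params`, `converged`, and fitting
#'   `details` (conditional modes at the optimum, counts, optimizer
#'   messages). Warns (does not error) on optimizer non-convergence.
#' @export
fit_popmodel <- function(dataset, spec = pop_model_spec(), init = NULL,
                         fix = list(), control = list()) {
  ctrl <- utils::modifyList(
    list(rel_tol = 1e-6, iter_max = 400, eval_max = 2000, two_stage = TRUE),
    control
  )
  base_init <- initial_values(dataset, spec)
  if (!is.null(init)) {
    for (nm in intersect(names(init), c("tv", "coef", "omega", "sigma"))) {
      base_init[[nm]] <- init[[nm]]
    }
    if (!is.null(init$coef)) {
      cf <- setNames(rep(0, length(spec$terms)), names(spec$terms))
      cf[names(init$coef)] <- init$coef
      base_init$coef <- cf
    }
  }
  base_init$tv <- base_init$tv[STRUCTURAL_PARAMS]
  k <- length(spec$eta)
  if (k > 0 && is.null(fix$omega) &&
      !isTRUE(all.equal(dim(as.matrix(base_init$omega)), c(k, k)))) {
    base_init$omega <- diag(0.1, k)
  }

  flat <- flatten_study(dataset)
  covs <- subject_covariates(dataset)

  if (k > 0 && spec$omega_structure == "full" && is.null(fix$omega) &&
      isTRUE(ctrl$two_stage)) {
    diag_spec <- spec
    diag_spec$omega_structure <- "diagonal"
    stage1 <- fit_stage(flat, covs, diag_spec, base_init, fix, ctrl)
    base_init <- list(tv = stage1$value$theta$tv,
                      coef = stage1$value$theta$coef,
                      omega = stage1$value$omega,
                      sigma = stage1$value$sigma)
  }

  res <- fit_stage(flat, covs, spec, base_init, fix, ctrl)
  val <- res$value
  n_params <- length(res$par)
  final <- foce_eval(flat, covs, val$theta, val$omega, val$sigma, spec)

  if (!res$converged) {
    warning("fit_popmodel: optimizer did not report convergence (",
            res$message, "); estimate returned with converged = FALSE")
  }
  est <- new_pop_estimate(
    theta = val$theta, omega = val$omega, sigma = val$sigma, spec = spec,
    ofv = final$ofv, n_params = n_params, n_obs = flat$n_obs_used,
    converged = res$converged,
    details = list(etas = final$etas, ipred = final$ipred,
                   obs_id = flat$obs_id,
                   optimizer = res$message, init = base_init,
                   n_outer_evals = res$evals)
  )
  est
}

#' One optimization stage over a fixed packing.
#' @noRd
fit_stage <- function(flat, covs, spec, init, fix, ctrl) {
  packing <- pack_par(init, spec, fix)
  # The inner search starts from eta = 0, so the objective is a
  # deterministic function of the parameters alone (no evaluation-history
  # warm start that would leak noise into finite-difference gradients).
  eval_at <- function(par, eta_start = matrix(0, 0, 0)) {
    val <- tryCatch(unpack_par(par, spec, fix, packing),
                    error = function(e) NULL)
    if (is.null(val)) return(NULL)
    res <- tryCatch(
      foce_eval(flat, covs, val$theta, val$omega, val$sigma, spec,
                eta_start = eta_start),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$ofv)) return(NULL)
    res
  }
  objective <- function(par) {
    res <- eval_at(par)
    if (is.null(res)) 1e10 else res$ofv
  }
  # Central-difference gradient with a step well above the residual noise
  # of the inner conditional-mode search. The perturbed evaluations start
  # the inner search from the base point's converged modes — still a
  # deterministic function of `par`, but roughly 3x cheaper.
  gradient <- function(par) {
    base <- eval_at(par)
    start <- if (is.null(base)) matrix(0, 0, 0) else base$etas
    g <- numeric(length(par))
    hstep <- 1e-4
    for (j in seq_along(par)) {
      pp <- pm <- par
      pp[j] <- par[j] + hstep
      pm[j] <- par[j] - hstep
      rp <- eval_at(pp, start)
      rm <- eval_at(pm, start)
      # failed evaluations behave like the objective's own sentinel so the
      # line search backs away from the failing region
      fp <- if (is.null(rp)) 1e10 else rp$ofv
      fm <- if (is.null(rm)) 1e10 else rm$ofv
      g[j] <- (fp - fm) / (2 * hstep)
    }
    g
  }
  opt <- stats::optim(
    par = packing$par, fn = objective, gr = gradient,
    method = "L-BFGS-B", lower = packing$lower,
    control = list(factr = max(ctrl$rel_tol / .Machine$double.eps, 1e7),
                   maxit = ctrl$iter_max)
  )
  converged <- opt$convergence == 0
  if (!converged) {
    # the box-constrained quasi-Newton stop test is conservative on flat
    # -2LL surfaces; accept stationarity (small gradient at the returned
    # optimum) as convergence
    g <- gradient(opt$par)
    converged <- all(is.finite(g)) &&
      max(abs(g)) < (ctrl$grad_tol %||% 1.0)
  }
  list(
    par = opt$par,
    value = unpack_par(opt$par, spec, fix, packing),
    ofv = opt$value,
    converged = converged,
    message = opt$message %||% "",
    evals = unname(opt$counts[1])
  )
}

#' Empirical Bayes estimates
#'
#' Per-subject conditional modes of the random effects at the fitted
#' population parameters, with the derived individual parameters,
#' individual predictions, and per-eta shrinkage
#' `1 - SD(EBE)/omega_sd`. Subjects with no quantifiable observations sit
#' at the prior mode (eta = 0).
#'
#' @param dataset A [study_dataset()].
#' @param est A `pop_estimate` from [fit_popmodel()] (or assembled
#'   manually, e.g. [reference_estimate()]).
#' @return An object of class `ebe_set`: list with `etas` (subjects x
#'   etas), `params` (data frame of individual V1/V2/CL/Q), `pred` (data
#'   frame with `id`, `time`, `obs`, `ipred`), and `shrinkage` (named
#'   per-eta vector).
#' @export
empirical_bayes <- function(dataset, est) {
  spec <- est$spec
  flat <- flatten_study(dataset)
  covs <- subject_covariates(dataset)
  res <- foce_eval(flat, covs, est$theta, est$omega, est$sigma, spec)
  k <- length(spec$eta)
  etas <- res$etas
  if (k > 0) {
    etas <- matrix(etas[, seq_len(k), drop = FALSE], ncol = k,
                   dimnames = list(flat$ids, spec$eta))
  } else {
    etas <- matrix(0, length(flat$ids), 0, dimnames = list(flat$ids, NULL))
  }
  mult <- covariate_multipliers(est$theta, covs, spec)
  tv <- est$theta$tv[STRUCTURAL_PARAMS]
  full_eta <- matrix(0, length(flat$ids), 4,
                     dimnames = list(flat$ids, STRUCTURAL_PARAMS))
  if (k > 0) full_eta[, spec$eta] <- etas
  params <- data.frame(id = flat$ids,
                       sweep(mult, 2, tv, `*`) * exp(full_eta),
                       row.names = NULL)
  pred <- data.frame(id = flat$obs_id, time = flat$obs_time,
                     obs = flat$obs_y, ipred = res$ipred)
  shr <- eta_shrinkage_matrix(etas, est$omega)
  structure(list(etas = etas, params = params, pred = pred,
                 shrinkage = shr),
            class = "ebe_set")
}

#' @export
print.ebe_set <- function(x, ...) {
  cat(sprintf("Empirical Bayes estimates for %d subject(s)\n", nrow(x$etas)))
  if (length(x$shrinkage)) {
    cat("  shrinkage:",
        paste(sprintf("%s %.3f", names(x$shrinkage), x$shrinkage),
              collapse = " | "), "\n")
  }
  invisible(x)
}

#' @noRd
eta_shrinkage_matrix <- function(etas, omega) {
  if (ncol(etas) == 0) return(setNames(numeric(0), character(0)))
  omega <- as.matrix(omega)
  out <- setNames(rep(NA_real_, ncol(etas)), colnames(etas))
  for (j in seq_len(ncol(etas))) {
    w <- sqrt(omega[j, j])
    if (w > 0 && nrow(etas) >= 2) {
      out[j] <- 1 - stats::sd(etas[, j]) / w
    }
  }
  out
}

#' Shrinkage of the empirical Bayes estimates
#'
#' `1 - SD(EBE_eta) / omega_sd` per random effect; values close to 1 mean
#' the individual estimates carry little information beyond the population
#' model. Can be negative. Undefined (reported `NA`) when the population
#' SD is 0.
#'
#' @param ebes An `ebe_set` from [empirical_bayes()] (or a numeric matrix
#'   of EBEs, subjects x etas).
#' @param omega Omega covariance matrix matching the eta columns.
#' @return Named numeric vector of per-eta shrinkage.
#' @export
eta_shrinkage <- function(ebes, omega) {
  etas <- if (inherits(ebes, "ebe_set")) ebes$etas else as.matrix(ebes)
  if (nrow(etas) < 2) {
    stop_cefapop("cefapop_domain_error",
                 "shrinkage needs at least 2 subjects")
  }
  eta_shrinkage_matrix(etas, omega)
}
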