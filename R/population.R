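## NLME layer: model specification, individual-parameter construction,
## residual model, omega transforms, and the FOCE-type objective (the
## heavy per-subject work lives in src/foce.cpp).

STRUCTURAL_PARAMS <- c("V1", "V2", "CL", "Q")

# default scaling references for the continuous covariates
COVARIATE_REFERENCES <- c(bw = 20, age = 8, creatinine = 0.9,
                          surgery_time = 80)

#' Covariate model term
#'
#' A single covariate effect on one structural parameter: either a power
#' model on a scaled continuous covariate,
#' `param = tv * (covariate/ref)^theta`, or a linear indicator effect for a
#' categorical covariate, `param = tv * (1 + theta * X)`.
#'
#' @param param Structural parameter name: one of `"V1"`, `"V2"`, `"CL"`,
#'   `"Q"`.
#' @param covariate Covariate column name (`bw`, `age`, `creatinine`,
#'   `surgery_time`, `health`, `breed`, `sex`).
#' @param form `"power"` (continuous) or `"linear"` (categorical
#'   indicator).
#' @param ref Reference (scaling) value for power terms; defaults to
#'   20 kg for body weight, 8 y for age, 0.9 mg/dL for creatinine and
#'   80 min for surgery time.
#' @return An object of class `covariate_term`.
#' @export
covariate_term <- function(param, covariate,
                           form = c("power", "linear"), ref = NULL) {
  form <- match.arg(form)
  if (!param %in% STRUCTURAL_PARAMS) {
    stop_cefapop("cefapop_domain_error", "unknown parameter: ", param)
  }
  if (!covariate %in% COVARIATE_COLUMNS) {
    stop_cefapop("cefapop_domain_error", "unknown covariate: ", covariate)
  }
  if (form == "power") {
    if (!covariate %in% CONTINUOUS_COVARIATES) {
      stop_cefapop("cefapop_domain_error",
                   "power terms require a continuous covariate")
    }
    ref <- ref %||% unname(COVARIATE_REFERENCES[covariate])
    if (!is.finite(ref) || ref <= 0) {
      stop_cefapop("cefapop_domain_error", "reference value must be > 0")
    }
  } else {
    if (covariate %in% CONTINUOUS_COVARIATES) {
      stop_cefapop("cefapop_domain_error",
                   "linear indicator terms require a categorical covariate")
    }
    ref <- NA_real_
  }
  structure(list(param = param, covariate = covariate, form = form,
                 ref = ref, name = paste0(param, "~", covariate)),
            class = "covariate_term")
}

#' Population model specification
#'
#' Describes the fitted model beyond the fixed two-compartment structure:
#' the active covariate terms, the random-effect (omega) structure, and
#' which structural parameters carry a random effect. The residual model is
#' always combined additive + proportional.
#'
#' @param terms List of [covariate_term()] objects (default none).
#' @param omega_structure `"full"` (covariances estimated), `"diagonal"`,
#'   or `"none"` (no random effects; plain extended-least-squares fit).
#' @param eta Character vector of parameters carrying a random effect
#'   (default all four).
#' @return An object of class `pop_model_spec`.
#' @export
pop_model_spec <- function(terms = list(),
                           omega_structure = c("full", "diagonal", "none"),
                           eta = STRUCTURAL_PARAMS) {
  omega_structure <- match.arg(omega_structure)
  if (inherits(terms, "covariate_term")) terms <- list(terms)
  for (tm in terms) {
    if (!inherits(tm, "covariate_term")) {
      stop_cefapop("cefapop_domain_error",
                   "terms must be covariate_term objects")
    }
  }
  nm <- vapply(terms, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop_cefapop("cefapop_domain_error", "duplicated covariate term: ",
                 nm[duplicated(nm)][1])
  }
  names(terms) <- nm
  eta <- intersect(STRUCTURAL_PARAMS, eta)
  if (omega_structure == "none") eta <- character(0)
  structure(list(terms = terms, omega_structure = omega_structure,
                 eta = eta),
            class = "pop_model_spec")
}

#' @export
print.pop_model_spec <- function(x, ...) {
  cat("Population model specification\n")
  cat("  structural: two-compartment IV bolus (V1, V2, CL, Q)\n")
  cat("  random effects:",
      if (length(x$eta)) paste(x$eta, collapse = ", ") else "none",
      sprintf("(%s omega)\n", x$omega_structure))
  cat("  residual: combined additive + proportional\n")
  if (length(x$terms)) {
    for (tm in x$terms) {
      cat(sprintf("  covariate: %s [%s%s]\n", tm$name, tm$form,
                  if (tm$form == "power") paste0(", ref ", tm$ref) else ""))
    }
  } else {
    cat("  covariates: none\n")
  }
  invisible(x)
}

#' Multiplicative covariate factors for each subject and parameter
#'
#' @param theta List with `tv` (named typical values) and `coef` (named
#'   coefficients, one per covariate term).
#' @param covariates Data frame of subject covariates (one row per
#'   subject).
#' @param spec A [pop_model_spec()].
#' @return Numeric matrix (subjects x 4) of multiplicative factors in the
#'   order V1, V2, CL, Q.
#' @export
covariate_multipliers <- function(theta, covariates, spec) {
  n <- nrow(covariates)
  mult <- matrix(1, n, 4, dimnames = list(NULL, STRUCTURAL_PARAMS))
  for (tm in spec$terms) {
    th <- theta$coef[[tm$name]]
    if (is.null(th) || is.na(th)) {
      stop_cefapop("cefapop_domain_error",
                   "no coefficient supplied for term ", tm$name)
    }
    x <- covariates[[tm$covariate]]
    fac <- if (tm$form == "power") {
      (x / tm$ref)^th
    } else {
      1 + th * x
    }
    if (any(fac <= 0)) {
      stop_cefapop("cefapop_domain_error",
                   "covariate term ", tm$name,
                   " drives a parameter non-positive (1 + theta*X <= 0)")
    }
    mult[, tm$param] <- mult[, tm$param] * fac
  }
  mult
}

#' Individual parameters from typical values, random effects and covariates
#'
#' `param_i = tv * prod[(cov/ref)^theta] * prod[(1 + theta*X)] * exp(eta)`.
#'
#' @param theta List with `tv` and `coef` (see [covariate_multipliers()]).
#' @param eta Named (or length-4, order V1/V2/CL/Q) numeric vector of
#'   log-scale random effects; parameters without a random effect take 0.
#' @param covariates One-row data frame (or named list) of covariates.
#' @param spec A [pop_model_spec()].
#' @return A [pk_params()] object.
#' @examples
#' th <- list(tv = c(V1 = 0.116, V2 = 0.177, CL = 0.0037, Q = 0.0103),
#'            coef = c(`CL~bw` = -0.2368))
#' sp <- pop_model_spec(covariate_term("CL", "bw", "power"))
#' individual_parameters(th, rep(0, 4), list(bw = 10), sp)
#' @export
individual_parameters <- function(theta, eta = rep(0, 4), covariates = NULL,
                                  spec = pop_model_spec()) {
  if (is.null(covariates)) covariates <- as.list(COVARIATE_REFERENCES)
  covariates <- as.data.frame(as.list(covariates))
  full_eta <- setNames(rep(0, 4), STRUCTURAL_PARAMS)
  if (!is.null(names(eta)) && all(names(eta) %in% STRUCTURAL_PARAMS)) {
    full_eta[names(eta)] <- eta
  } else {
    full_eta[seq_along(eta)] <- eta
  }
  mult <- covariate_multipliers(theta, covariates, spec)[1, ]
  tv <- theta$tv[STRUCTURAL_PARAMS]
  p <- tv * mult * exp(full_eta)
  pk_params(p[["V1"]], p[["V2"]], p[["CL"]], p[["Q"]])
}

#' Residual variance of the combined error model
#'
#' `var = (prop_sd * pred)^2 + add_sd^2`, the variance implied by
#' `C = f * (1 + e1) + e2`.
#'
#' @param pred Predicted concentration(s), µg/mL (>= 0).
#' @param sigma Numeric `c(prop, add)`: proportional SD (dimensionless) and
#'   additive SD (µg/mL).
#' @return Residual variance(s), (µg/mL)^2.
#' @export
residual_variance <- function(pred, sigma) {
  if (any(pred < 0)) {
    stop_cefapop("cefapop_domain_error", "pred must be >= 0")
  }
  sigma <- as_sigma(sigma)
  pred^2 * sigma[["prop"]]^2 + sigma[["add"]]^2
}

#' @noRd
as_sigma <- function(sigma) {
  sigma <- unlist(sigma)
  if (is.null(names(sigma)) || !all(c("prop", "add") %in% names(sigma))) {
    names(sigma) <- c("prop", "add")
  }
  sigma <- sigma[c("prop", "add")]
  if (any(!is.finite(sigma)) || any(sigma < 0) || all(sigma == 0)) {
    stop_cefapop("cefapop_domain_error",
                 "sigma components must be >= 0 and not both 0")
  }
  sigma
}

#' Convert a log-scale variance to a coefficient of variation
#'
#' `CV% = 100 * sqrt(exp(omega^2) - 1)` for an exponential
#' (log-normal) between-subject variability model.
#'
#' @param omega_sq Log-scale variance(s) (the omega-matrix diagonal), >= 0.
#' @return CV in percent.
#' @examples
#' omega_to_cv(0.130511)
#' @export
omega_to_cv <- function(omega_sq) {
  if (any(omega_sq < 0)) {
    stop_cefapop("cefapop_domain_error", "variances must be >= 0")
  }
  100 * sqrt(exp(omega_sq) - 1)
}

#' Correlation matrix of the random effects
#'
#' @param omega Symmetric positive-semidefinite covariance matrix with
#'   strictly positive diagonal.
#' @return Correlation matrix of the same dimension.
#' @examples
#' omega_to_correlation(reference_estimate()$omega)
#' @export
omega_to_correlation <- function(omega) {
  omega <- as.matrix(omega)
  if (any(diag(omega) <= 0)) {
    stop_cefapop("cefapop_domain_error",
                 "omega diagonal must be strictly positive")
  }
  s <- sqrt(diag(omega))
  cor_mat <- omega / tcrossprod(s)
  diag(cor_mat) <- 1
  cor_mat
}

## ---- flattening and objective ------------------------------------------

#' Flatten a study dataset into the arrays the compiled core consumes.
#' Observations flagged below the LOQ are excluded (with a one-time
#' message), per the package convention that BLOQ samples do not enter the
#' fit.
#' @noRd
flatten_study <- function(dataset) {
  d <- dataset$data
  ids <- unique(d$id)
  n_bloq <- sum(d$evid == 0 & d$bloq == 1)
  if (n_bloq > 0) {
    message(sprintf(
      "excluding %d observation(s) below the LOQ from fitting", n_bloq))
  }
  obs <- d[d$evid == 0 & d$bloq == 0, c("id", "time", "conc")]
  doses <- d[d$evid == 1, c("id", "time", "amt")]
  obs$idx <- match(obs$id, ids)
  doses$idx <- match(doses$id, ids)
  obs <- obs[order(obs$idx, obs$time), ]
  doses <- doses[order(doses$idx, doses$time), ]
  obs_counts <- tabulate(obs$idx, nbins = length(ids))
  dose_counts <- tabulate(doses$idx, nbins = length(ids))
  list(
    ids = ids,
    obs_time = obs$time, obs_y = obs$conc,
    obs_offset = c(0L, cumsum(obs_counts)),
    dose_time = doses$time, dose_amt = doses$amt,
    dose_offset = c(0L, cumsum(dose_counts)),
    obs_id = ids[obs$idx],
    n_obs_used = nrow(obs)
  )
}

#' FOCE-type objective function value
#'
#' Minus twice the approximate marginal log-likelihood of the population
#' model: per subject, the conditional mode of the random-effect vector is
#' located by penalized least squares, and the Laplace approximation is
#' accumulated with the residual variance evaluated at the individual
#' prediction (interaction). Observations flagged below the LOQ are
#' excluded.
#'
#' @param dataset A [study_dataset()].
#' @param theta List with `tv` (named typical values) and `coef`
#'   (covariate coefficients), or a bare named vector of typical values.
#' @param omega Covariance matrix of the random effects, dimension equal
#'   to `length(spec$eta)` (rows/columns in `spec$eta` order); ignored
#'   when the spec has no random effects.
#' @param sigma `c(prop, add)` residual SDs.
#' @param spec A [pop_model_spec()].
#' @return The objective function value (a scalar), with attributes
#'   `"etas"` (conditional modes, subjects x etas) and `"ipred"`
#'   (individual predictions for the fitted observations).
#' @export
foce_objective <- function(dataset, theta, omega, sigma,
                           spec = pop_model_spec()) {
  if (is.numeric(theta)) theta <- list(tv = theta, coef = numeric(0))
  flat <- flatten_study(dataset)
  res <- foce_eval(flat, subject_covariates(dataset), theta, omega,
                   as_sigma(sigma), spec)
  out <- res$ofv
  attr(out, "etas") <- res$etas
  attr(out, "ipred") <- res$ipred
  out
}

#' Low-level objective evaluation on pre-flattened data.
#' @noRd
foce_eval <- function(flat, covariates, theta, omega, sigma, spec,
                      eta_start = matrix(0, 0, 0)) {
  k <- length(spec$eta)
  mult <- covariate_multipliers(theta, covariates, spec)
  tv <- theta$tv[STRUCTURAL_PARAMS]
  if (any(!is.finite(tv)) || any(tv <= 0)) {
    stop_cefapop("cefapop_domain_error", "typical values must be positive")
  }
  P0 <- sweep(mult, 2, tv, `*`)
  if (k > 0) {
    omega <- as.matrix(omega)
    if (!isTRUE(all.equal(dim(omega), c(k, k)))) {
      stop_cefapop("cefapop_domain_error",
                   "omega must be ", k, "x", k, " for this spec")
    }
  } else {
    omega <- matrix(0, 0, 0)
  }
  eta_param <- match(spec$eta, STRUCTURAL_PARAMS) - 1L
  res <- foce_ofv_cpp(flat$obs_time, flat$obs_y, as.integer(flat$obs_offset),
                      flat$dose_time, flat$dose_amt,
                      as.integer(flat$dose_offset),
                      P0, omega, as.integer(eta_param), unname(sigma),
                      eta_start)
  if (!is.null(res$error)) {
    stop_cefapop("cefapop_numeric_error",
                 res$error,
                 if (!is.null(res$subject)) {
                   paste0(" (subject ", flat$ids[res$subject], ")")
                 } else "")
  }
  res
}

## ---- estimate container -------------------------------------------------

#' @noRd
new_pop_estimate <- function(theta, omega, sigma, spec, ofv, n_params,
                             n_obs, converged, details = list()) {
  bic <- if (is.finite(ofv) && is.finite(n_params) &&
             !is.na(n_obs) && n_obs > 0) {
    ofv + n_params * log(n_obs)
  } else {
    NA_real_
  }
  omega_cor <- if (length(omega) && all(diag(as.matrix(omega)) > 0)) {
    omega_to_correlation(omega)
  } else {
    NULL
  }
  structure(list(
    theta = theta, omega = omega, omega_cor = omega_cor,
    sigma = as_sigma(sigma), spec = spec,
    ofv = ofv, bic = bic, n_params = n_params, n_obs = n_obs,
    converged = converged, details = details
  ), class = "pop_estimate")
}

#' @export
print.pop_estimate <- function(x, ...) {
  cat("Population PK estimate (two-compartment IV bolus)\n")
  tv <- x$theta$tv
  cat(sprintf("  tvV1 %.4g L/kg | tvV2 %.4g L/kg | tvCL %.4g L/kg/min | tvQ %.4g L/kg/min\n",
              tv[["V1"]], tv[["V2"]], tv[["CL"]], tv[["Q"]]))
  if (length(x$theta$coef)) {
    cat("  covariate coefficients:\n")
    for (nm in names(x$theta$coef)) {
      cat(sprintf("    %s = %.4g\n", nm, x$theta$coef[[nm]]))
    }
  }
  if (length(x$omega)) {
    cv <- omega_to_cv(diag(as.matrix(x$omega)))
    cat("  BSV (CV%):", paste(sprintf("%s %.1f", colnames(x$omega) %||%
                                        x$spec$eta, cv), collapse = " | "),
        "\n")
  }
  cat(sprintf("  sigma: prop %.4g, add %.4g ug/mL\n",
              x$sigma[["prop"]], x$sigma[["add"]]))
  if (is.finite(x$ofv)) {
    cat(sprintf("  OFV %.3f | BIC %.3f | %d parameter(s) | %d observation(s) | converged: %s\n",
                x$ofv, x$bic, x$n_params, x$n_obs, x$converged))
  }
  invisible(x)
}
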