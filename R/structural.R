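#' Two-compartment disposition parameters
#'
#' Container for the primary structural parameters of the two-compartment
#' intravenous bolus model. Doses are expressed per kg body weight, so
#' volumes are in L/kg and clearances in L/kg/min.
#'
#' @param V1 Central volume of distribution (L/kg).
#' @param V2 Peripheral volume of distribution (L/kg).
#' @param CL Serum clearance (L/kg/min).
#' @param Q Intercompartmental clearance (L/kg/min).
#'
#' @return An object of class `pk_params`: a named numeric vector with
#'   elements `V1`, `V2`, `CL`, `Q`.
#' @examples
#' pk_params(V1 = 0.116, V2 = 0.177, CL = 0.0037, Q = 0.0103)
#' @export
pk_params <- function(V1, V2, CL, Q) {
  p <- c(V1 = as.numeric(V1), V2 = as.numeric(V2),
         CL = as.numeric(CL), Q = as.numeric(Q))
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop_cefapop("cefapop_domain_error",
                 "all of V1, V2, CL, Q must be finite and strictly positive")
  }
  structure(p, class = c("pk_params", "numeric"))
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment PK parameters (per kg):\n")
  print(unclass(x))
  invisible(x)
}

as_pk_params <- function(p) {
  if (inherits(p, "pk_params")) return(p)
  p <- unlist(p)
  pk_params(p[["V1"]], p[["V2"]], p[["CL"]], p[["Q"]])
}

#' Hybrid (macro) rate constants of the two-compartment model
#'
#' Converts clearance/volume parameters to micro constants
#' (`k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`) and the hybrid slopes:
#' the terminal slope `beta` is the smaller root of
#' \deqn{\lambda^2 - (k10 + k12 + k21)\lambda + k21 k10 = 0,}
#' computed as
#' `beta = 0.5 * (k12 + k21 + k10 - sqrt((k12 + k21 + k10)^2 - 4 k21 k10))`
#' and the distribution slope as `alpha = k21 * k10 / beta`.
#'
#' @param params A [pk_params()] object (or coercible named vector).
#' @return An object of class `hybrid_constants`: named numeric vector with
#'   `alpha`, `beta`, `k10`, `k12`, `k21` (all 1/min).
#' @examples
#' hybrid_constants(pk_params(0.116, 0.177, 0.0037, 0.0103))
#' @export
hybrid_constants <- function(params) {
  p <- as_pk_params(params)
  k10 <- p[["CL"]] / p[["V1"]]
  k12 <- p[["Q"]] / p[["V1"]]
  k21 <- p[["Q"]] / p[["V2"]]
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k21 * k10
  # disc = (k10 + k12 - k21)^2 + 4 k12 k21 > 0 always, but guard rounding
  disc <- max(disc, 0)
  beta <- 0.5 * (s - sqrt(disc))
  alpha <- k21 * k10 / beta
  if (!is.finite(alpha) || !is.finite(beta) || beta <= 0 ||
      (alpha - beta) / alpha < 1e-9) {
    stop_cefapop("cefapop_degenerate_roots",
                 "hybrid slopes are degenerate (alpha ~ beta); ",
                 "the biexponential solution is ill-conditioned here")
  }
  structure(c(alpha = alpha, beta = beta, k10 = k10, k12 = k12, k21 = k21),
            class = c("hybrid_constants", "numeric"))
}

#' Dose events
#'
#' @param time Dose times in minutes since the first dose (numeric vector).
#' @param amount Dose amounts in mg per kg body weight (recycled).
#' @return A data frame of class `dose_events` with columns `time`, `amount`.
#' @examples
#' dose_events(c(0, 360, 720, 1080), 25)
#' @export
dose_events <- function(time, amount) {
  amount <- rep_len(amount, length(time))
  if (any(!is.finite(time)) || any(time < 0)) {
    stop_cefapop("cefapop_domain_error", "dose times must be finite and >= 0")
  }
  if (any(!is.finite(amount)) || any(amount <= 0)) {
    stop_cefapop("cefapop_domain_error", "dose amounts must be > 0")
  }
  ord <- order(time)
  structure(data.frame(time = time[ord], amount = amount[ord]),
            class = c("dose_events", "data.frame"))
}

as_dose_events <- function(doses) {
  if (inherits(doses, "dose_events")) return(doses)
  if (is.data.frame(doses)) return(dose_events(doses$time, doses$amount))
  stop_cefapop("cefapop_domain_error",
               "doses must be a dose_events object or a data frame with ",
               "columns time and amount")
}

#' Closed-form serum concentration under intravenous bolus dosing
#'
#' Biexponential disposition with superposition over doses: each bolus of
#' `amount` mg/kg given at time `tau` contributes, for `t >= tau`,
#' \deqn{\frac{amount}{V1}\left[\frac{\alpha - k21}{\alpha - \beta}
#'   e^{-\alpha (t-\tau)} + \frac{k21 - \beta}{\alpha - \beta}
#'   e^{-\beta (t-\tau)}\right].}
#' Times before the first dose return 0 (pre-dose baseline).
#'
#' @param params A [pk_params()] object.
#' @param doses A [dose_events()] object (or data frame with `time`,
#'   `amount`).
#' @param t Numeric vector of times (minutes, >= 0).
#' @return Numeric vector of total serum concentrations (µg/mL).
#' @examples
#' p <- pk_params(0.116, 0.177, 0.0037, 0.0103)
#' concentration(p, dose_events(0, 25), c(0, 60, 480))
#' @export
concentration <- function(params, doses, t) {
  p <- as_pk_params(params)
  doses <- as_dose_events(doses)
  if (nrow(doses) == 0) {
    stop_cefapop("cefapop_domain_error", "at least one dose is required")
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_cefapop("cefapop_domain_error", "times must be finite and >= 0")
  }
  h <- hybrid_constants(p)
  a1 <- (h[["alpha"]] - h[["k21"]]) / (h[["alpha"]] - h[["beta"]])
  a2 <- (h[["k21"]] - h[["beta"]]) / (h[["alpha"]] - h[["beta"]])
  out <- numeric(length(t))
  for (d in seq_len(nrow(doses))) {
    dt <- t - doses$time[d]
    on <- dt >= 0
    if (any(on)) {
      c0 <- doses$amount[d] / p[["V1"]]
      out[on] <- out[on] +
        c0 * (a1 * exp(-h[["alpha"]] * dt[on]) +
              a2 * exp(-h[["beta"]] * dt[on]))
    }
  }
  out
}

#' Secondary (derived) disposition parameters
#'
#' Classical secondary parameters of the two-compartment bolus model:
#' hybrid slopes and their half-lives, total exposure `AUC = dose/CL`
#' (extrapolated to infinity), `Vss = V1 + V2`, terminal-phase volume
#' `Vz = CL/beta`, and `MRT = Vss/CL`.
#'
#' @param params A [pk_params()] object.
#' @param dose Single dose in mg/kg (default 25).
#' @return Named numeric vector of class `secondary_params` with elements
#'   `alpha`, `beta` (1/min), `hl_alpha`, `hl_beta` (min),
#'   `AUC` (µg·min/mL), `Vss`, `Vz` (L/kg), `MRT` (min).
#' @examples
#' secondary_parameters(pk_params(0.116, 0.177, 0.0037, 0.0103), dose = 25)
#' @export
secondary_parameters <- function(params, dose = 25) {
  p <- as_pk_params(params)
  if (!is.finite(dose) || dose <= 0) {
    stop_cefapop("cefapop_domain_error", "dose must be > 0")
  }
  h <- hybrid_constants(p)
  vss <- p[["V1"]] + p[["V2"]]
  structure(c(
    alpha = h[["alpha"]],
    beta = h[["beta"]],
    hl_alpha = log(2) / h[["alpha"]],
    hl_beta = log(2) / h[["beta"]],
    AUC = dose / p[["CL"]],
    Vss = vss,
    Vz = p[["CL"]] / h[["beta"]],
    MRT = vss / p[["CL"]]
  ), class = c("secondary_params", "numeric"))
}
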