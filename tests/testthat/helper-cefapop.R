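# Shared fixtures and independent oracles for the test suite.

REF_TV <- c(V1 = 0.116, V2 = 0.177, CL = 0.0037, Q = 0.0103)

# one-subject long-format frame with a time-0 bolus
toy_study_df <- function(times, conc, dose = 25, id = "s1", bloq = 0,
                         bw = 20, age = 8, creatinine = 0.9,
                         surgery_time = 80, health = 0, breed = 0,
                         sex = 0) {
  dose_row <- data.frame(
    id = id, evid = 1, time = 0, amt = dose, conc = NA_real_, bloq = 0,
    bw = bw, age = age, creatinine = creatinine,
    surgery_time = surgery_time, health = health, breed = breed, sex = sex)
  if (length(times) == 0) return(dose_row)
  obs_rows <- data.frame(
    id = id, evid = 0, time = times, amt = NA_real_, conc = conc,
    bloq = bloq, bw = bw, age = age, creatinine = creatinine,
    surgery_time = surgery_time, health = health, breed = breed, sex = sex)
  rbind(dose_row, obs_rows)
}

# simulate one subject's observations from the model at given eta;
# redraws (deterministically) until every sample is quantifiable so the
# toy dataset passes validation
simulate_toy_subject <- function(times, tv = REF_TV, eta = rep(0, 4),
                                 sigma = c(0.257, 0.564), dose = 25,
                                 seed = 1) {
  p <- pk_params(tv[1] * exp(eta[1]), tv[2] * exp(eta[2]),
                 tv[3] * exp(eta[3]), tv[4] * exp(eta[4]))
  f <- concentration(p, dose_events(0, dose), times)
  for (try in 0:100) {
    set.seed(seed + 1000 * try)
    y <- f * (1 + rnorm(length(times), 0, sigma[1])) +
      rnorm(length(times), 0, sigma[2])
    if (all(y > 0.21)) return(y)
  }
  stop("could not draw a fully quantifiable toy subject")
}

# exact marginal -2LL for one subject with a single eta, by adaptive
# quadrature (independent of the package's Laplace machinery)
quad_m2ll_1eta <- function(times, y, tv = REF_TV, w2, sigma, eta_on = "CL",
                           dose = 25) {
  lik <- function(eta) {
    vapply(eta, function(e) {
      p <- tv
      p[eta_on] <- p[eta_on] * exp(e)
      pe <- pk_params(p[["V1"]], p[["V2"]], p[["CL"]], p[["Q"]])
      f <- concentration(pe, dose_events(0, dose), times)
      v <- f^2 * sigma[1]^2 + sigma[2]^2
      exp(sum(dnorm(y, f, sqrt(v), log = TRUE))) * dnorm(e, 0, sqrt(w2))
    }, numeric(1))
  }
  half <- 8 * sqrt(w2)
  -2 * log(integrate(lik, -half, half, rel.tol = 1e-10, abs.tol = 0)$value)
}

# same with two etas (nested adaptive quadrature)
quad_m2ll_2eta <- function(times, y, tv = REF_TV, omega2, sigma,
                           eta_on = c("V1", "CL"), dose = 25) {
  oinv <- solve(omega2)
  ldet <- determinant(omega2)$modulus
  prior <- function(e1, e2) {
    q <- oinv[1, 1] * e1^2 + 2 * oinv[1, 2] * e1 * e2 + oinv[2, 2] * e2^2
    exp(-0.5 * (q + ldet + 2 * log(2 * pi)))
  }
  lik12 <- function(e1, e2) {
    p <- tv
    p[eta_on[1]] <- p[eta_on[1]] * exp(e1)
    p[eta_on[2]] <- p[eta_on[2]] * exp(e2)
    pe <- pk_params(p[["V1"]], p[["V2"]], p[["CL"]], p[["Q"]])
    f <- concentration(pe, dose_events(0, dose), times)
    v <- f^2 * sigma[1]^2 + sigma[2]^2
    exp(sum(dnorm(y, f, sqrt(v), log = TRUE))) * prior(e1, e2)
  }
  h1 <- 7 * sqrt(omega2[1, 1])
  h2 <- 7 * sqrt(omega2[2, 2])
  outer_fn <- function(e1v) {
    vapply(e1v, function(e1) {
      integrate(function(e2v) vapply(e2v, function(e2) lik12(e1, e2),
                                     numeric(1)),
                -h2, h2, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  -2 * log(integrate(outer_fn, -h1, h1, rel.tol = 1e-8)$value)
}

# fast optimizer settings for small test fits
fast_ctrl <- list(rel_tol = 1e-5)
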