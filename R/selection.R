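## Nested-model comparison and stepwise covariate model building under
## BIC add/delete thresholds (6.635 / 10.823, the chi-square criticals for
## P < 0.01 and P < 0.001 at 1 df on the -2LL scale).

#' Likelihood ratio test for nested fits
#'
#' @param ofv_reduced Objective function value (-2 log-likelihood) of the
#'   reduced model.
#' @param ofv_full OFV of the full (larger) model.
#' @param df Difference in parameter count (>= 1).
#' @param tolerance Allowed negative slack on the statistic before the
#'   comparison is declared invalid (default 1e-6).
#' @return List with `statistic` and `p_value` (upper-tail chi-square).
#' @examples
#' likelihood_ratio_test(106.6, 100, df = 1)
#' @export
likelihood_ratio_test <- function(ofv_reduced, ofv_full, df,
                                  tolerance = 1e-6) {
  if (df < 1) {
    stop_cefapop("cefapop_domain_error", "df must be >= 1")
  }
  statistic <- ofv_reduced - ofv_full
  if (statistic < -tolerance) {
    stop_cefapop("cefapop_domain_error",
                 "reduced model has lower OFV than the full model beyond ",
                 "tolerance; models are not nested or a fit failed")
  }
  statistic <- max(statistic, 0)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Covariate candidate for the stepwise search
#'
#' Identical in content to [covariate_term()]; the alias marks intent
#' (a term under consideration rather than one in the model).
#'
#' @inheritParams covariate_term
#' @return A `covariate_term` object.
#' @export
covariate_candidate <- function(param, covariate,
                                form = c("power", "linear"), ref = NULL) {
  covariate_term(param, covariate, form, ref)
}

#' Stepwise covariate search under BIC thresholds
#'
#' Forward phase: at each step every remaining candidate is added to the
#' current model singly and refitted; the best candidate is accepted if it
#' lowers BIC by at least `add_threshold`, ties broken lexicographically by
#' (parameter, covariate). Backward phase: a retained term is deleted
#' unless its removal raises BIC by at least `delete_threshold` (terms with
#' the smallest rise removed first). Deterministic given the data and the
#' candidate list; candidate fits that fail are skipped with a warning.
#'
#' @param dataset A [study_dataset()].
#' @param base_spec The starting [pop_model_spec()].
#' @param candidates List of [covariate_candidate()] terms.
#' @param add_threshold BIC drop required to add a term (default 6.635).
#' @param delete_threshold BIC rise required to retain a term in the
#'   backward phase (default 10.823).
#' @param control Optimizer control passed to [fit_popmodel()].
#' @return List of class `stepwise_result`: `spec` (final model), `fit`
#'   (its estimate), `trace` (data frame: step, phase, candidate,
#'   bic_before, bic_after, accepted).
#' @export
stepwise_search <- function(dataset, base_spec = pop_model_spec(),
                            candidates = list(),
                            add_threshold = 6.635,
                            delete_threshold = 10.823,
                            control = list()) {
  if (inherits(candidates, "covariate_term")) candidates <- list(candidates)
  cand_names <- vapply(candidates, `[[`, character(1), "name")
  names(candidates) <- cand_names

  current_spec <- base_spec
  current_fit <- fit_popmodel(dataset, current_spec, control = control)
  trace <- list()
  step <- 0L

  add_trace <- function(phase, candidate, before, after, accepted) {
    step <<- step + 1L
    trace[[step]] <<- data.frame(
      step = step, phase = phase, candidate = candidate,
      bic_before = before, bic_after = after, accepted = accepted
    )
  }

  refit_with <- function(spec, init_from) {
    # start from the current model's estimates (omega included), so the
    # diagonal pre-fit stage is unnecessary
    init <- list(tv = init_from$theta$tv, coef = init_from$theta$coef,
                 omega = init_from$omega, sigma = init_from$sigma)
    ctrl <- utils::modifyList(list(two_stage = FALSE), control)
    tryCatch(
      fit_popmodel(dataset, spec, init = init, control = ctrl),
      error = function(e) {
        warning("candidate fit failed and was skipped: ",
                conditionMessage(e))
        NULL
      }
    )
  }

  # forward additions
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    ord <- order(vapply(remaining, `[[`, character(1), "param"),
                 vapply(remaining, `[[`, character(1), "covariate"))
    remaining <- remaining[ord]
    fits <- list()
    bics <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      spec_i <- pop_model_spec(c(current_spec$terms,
                                 list(remaining[[i]])),
                               current_spec$omega_structure,
                               current_spec$eta)
      fit_i <- refit_with(spec_i, current_fit)
      if (!is.null(fit_i) && is.finite(fit_i$bic)) {
        fits[[i]] <- list(spec = spec_i, fit = fit_i)
        bics[i] <- fit_i$bic
      }
    }
    if (all(is.na(bics))) break
    best <- which.min(bics) # first minimum = lexicographic tie-break
    drop <- current_fit$bic - bics[best]
    accepted <- is.finite(drop) && drop >= add_threshold
    for (i in seq_along(remaining)) {
      if (!is.na(bics[i])) {
        add_trace("add", remaining[[i]]$name, current_fit$bic, bics[i],
                  accepted && i == best)
      }
    }
    if (!accepted) break
    current_spec <- fits[[best]]$spec
    current_fit <- fits[[best]]$fit
    remaining <- remaining[-best]
  }

  # backward deletions
  repeat {
    terms <- current_spec$terms
    if (!length(terms)) break
    rises <- rep(NA_real_, length(terms))
    fits <- list()
    for (i in seq_along(terms)) {
      spec_i <- pop_model_spec(terms[-i], current_spec$omega_structure,
                               current_spec$eta)
      fit_i <- refit_with(spec_i, current_fit)
      if (!is.null(fit_i) && is.finite(fit_i$bic)) {
        fits[[i]] <- list(spec = spec_i, fit = fit_i)
        rises[i] <- fit_i$bic - current_fit$bic
      }
    }
    if (all(is.na(rises))) break
    worst <- which.min(rises) # least informative term first
    deleted <- rises[worst] < delete_threshold
    add_trace("delete", terms[[worst]]$name, current_fit$bic,
              fits[[worst]]$fit$bic, deleted)
    if (!deleted) break
    current_spec <- fits[[worst]]$spec
    current_fit <- fits[[worst]]$fit
  }

  trace <- if (length(trace)) {
    do.call(rbind, trace)
  } else {
    data.frame(step = integer(0), phase = character(0),
               candidate = character(0), bic_before = numeric(0),
               bic_after = numeric(0), accepted = logical(0))
  }
  structure(list(spec = current_spec, fit = current_fit, trace = trace),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Stepwise covariate search\n")
  sel <- names(x$spec$terms)
  cat("  selected terms:",
      if (length(sel)) paste(sel, collapse = ", ") else "none", "\n")
  cat(sprintf("  final BIC %.3f after %d evaluated step(s)\n",
              x$fit$bic, nrow(x$trace)))
  invisible(x)
}

#' Clinical-relevance factor of a covariate effect
#'
#' The multiplicative factor applied to a typical value when the covariate
#' takes `covariate_value`: `(covariate/reference)^theta` for a power term
#' or `1 + theta * X` for a linear indicator term.
#'
#' @param form `"power"` or `"linear"`.
#' @param theta_value Fitted coefficient.
#' @param covariate_value Covariate value (indicator level for linear
#'   terms).
#' @param reference_value Scaling reference (power terms only).
#' @return The multiplicative factor (numeric scalar).
#' @examples
#' relevance_factor("power", -0.2368, 10, 20)
#' relevance_factor("linear", -0.267, 1)
#' @export
relevance_factor <- function(form = c("power", "linear"), theta_value,
                             covariate_value, reference_value = NULL) {
  form <- match.arg(form)
  if (form == "power") {
    if (is.null(reference_value) || reference_value <= 0 ||
        covariate_value <= 0) {
      stop_cefapop("cefapop_domain_error",
                   "power factors need positive covariate and reference")
    }
    (covariate_value / reference_value)^theta_value
  } else {
    1 + theta_value * covariate_value
  }
}

#' Annotate a relevance factor against an acceptance band
#'
#' A factor inside the band (default the bioequivalence-style 0.80-1.25)
#' is labelled not clinically relevant.
#'
#' @param factor Multiplicative factor from [relevance_factor()].
#' @param band Two-sided band (default `c(0.8, 1.25)`).
#' @return Logical: `TRUE` if the effect is clinically relevant (outside
#'   the band).
#' @export
relevance_verdict <- function(factor, band = c(0.8, 1.25)) {
  factor < band[1] | factor > band[2]
}
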