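---
title: "Population pharmacokinetics of intravenous cefazolin and the fT>MIC cutoff: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of intravenous cefazolin and the fT>MIC cutoff: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cefapop` implements a complete population-pharmacokinetic workflow for a
time-dependent antibiotic given as an intravenous bolus — built around
prophylactic cefazolin at 25 mg/kg in dogs undergoing surgery — together
with the Monte Carlo simulation step that turns the fitted population
model into a PK/PD susceptibility cutoff. This vignette explains the
models, the estimation machinery, the synthetic study generator, and the
numerical and design choices, in enough detail that a reader can judge
what the package's tests do and do not demonstrate.

## Structural model

Disposition follows a two-compartment model with instantaneous bolus
input, parameterized by clearances and volumes: central volume $V_1$
(L/kg), peripheral volume $V_2$ (L/kg), serum clearance $CL$ (L/kg/min)
and intercompartmental clearance $Q$ (L/kg/min). Doses are expressed per
kg of body weight, so body weight never enters the structural prediction;
it can act only through the covariate model. The micro constants are
$k_{10} = CL/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$, and the hybrid
slopes are the roots of
$\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{21}k_{10} = 0$:

$$\beta = \tfrac12\left[k_{12}+k_{21}+k_{10} -
  \sqrt{(k_{12}+k_{21}+k_{10})^2 - 4\,k_{21}k_{10}}\right],
  \qquad \alpha = \frac{k_{21}k_{10}}{\beta}.$$

The discriminant equals $(k_{10}+k_{12}-k_{21})^2 + 4k_{12}k_{21} > 0$,
so the roots are always distinct for valid parameters; `hybrid_constants()`
still guards the near-degenerate case with a diagnostic error rather than
switching to a repeated-root limit, because the fitted region never
approaches it. The closed-form concentration after a bolus of $D$ mg/kg at
time $\tau$ is

$$C(t) = \frac{D}{V_1}\left[\frac{\alpha - k_{21}}{\alpha-\beta}
  e^{-\alpha(t-\tau)} + \frac{k_{21}-\beta}{\alpha-\beta}
  e^{-\beta(t-\tau)}\right], \quad t \ge \tau,$$

and multi-dose curves are superpositions of shifted single-dose terms
(the kinetics are linear). Both exponential coefficients are positive
because $\alpha > k_{21} > \beta$ always; every inter-dose segment of the
curve is therefore strictly decreasing, a fact the target-attainment
engine exploits. Secondary parameters use the classical relations
$AUC = D/CL$ (extrapolated to infinity), $V_{ss} = V_1 + V_2$,
$V_z = CL/\beta$, $MRT = V_{ss}/CL$, and half-lives $\ln 2/\alpha$,
$\ln 2/\beta$. The closed form is validated in the test suite against an
independent numeric integration of the ODE system to a relative error
below $10^{-6}$.

## Statistical model

Between-subject variability is exponential on every structural parameter:
subject $i$'s clearance is $CL_i = \theta_{CL}\, e^{\eta_{CL,i}}$, and
likewise for $V_1$, $V_2$, $Q$. The four $\eta$ are jointly normal with
mean zero and a full $4\times4$ covariance $\Omega$ (the default;
diagonal and no-random-effect structures are available). A log-scale
variance $\omega^2$ converts to a coefficient of variation on the natural
scale as $CV\% = 100\sqrt{e^{\omega^2}-1}$.

The residual model is combined additive plus proportional,
$y_{ij} = f_{ij}(1+\varepsilon_{1,ij}) + \varepsilon_{2,ij}$, giving the
observation variance $v_{ij} = f_{ij}^2\sigma_{prop}^2 + \sigma_{add}^2$
with the *individual* prediction in the variance (interaction is always
on, since proportional error with conditional estimation is the stated
model). $\sigma_{prop}$ is dimensionless (its $100\times$ value is a CV%)
and $\sigma_{add}$ is in µg/mL.

Covariate effects are multiplicative on the typical values: continuous
covariates enter as power terms on scaled values,
$(x/x_{ref})^{\theta}$, with references 20 kg (body weight), 8 y (age),
0.9 mg/dL (creatinine) and 80 min (surgery time); categorical covariates
enter as linear indicator terms $(1+\theta X)$ with the coding 0 =
healthy/mongrel/male as the reference levels. A categorical coefficient
that drives $(1+\theta X) \le 0$ is a domain error, not a silent clamp.

## The conditional (FOCE-type) objective

The marginal likelihood integrates the joint density over each subject's
$\eta$. Writing $g_i(\eta) = -2\log p(y_i\mid\eta) - 2\log p(\eta)$, the
package locates the conditional mode $\hat\eta_i$ and accumulates the
Laplace-type approximation

$$-2\log L_i \approx \sum_j\left[\log(2\pi v_{ij}) +
  \frac{(y_{ij}-f_{ij})^2}{v_{ij}}\right]_{\hat\eta_i}
  + \log\det\Omega + \hat\eta_i'\Omega^{-1}\hat\eta_i
  + \log\det H_i,$$

with $H_i$ the curvature of $g_i/2$ at the mode. Two curvature estimates
exist: the exact (finite-difference) Hessian, and the Gauss-Newton form
$J'V^{-1}J + \Omega^{-1}$ obtained by linearizing the model about
$\hat\eta_i$. The exact form tracks the true marginal closely — the test
suite holds the objective within 0.1 of adaptive quadrature on one- and
two-$\eta$ toy subjects — but for sparse subjects its smallest eigenvalue
can graze zero in flat likelihood valleys, where its log-determinant
becomes numerically violent and the population objective stops being a
smooth function of its parameters. The Gauss-Newton form is bounded below
by the prior curvature $\Omega^{-1}$ and is perfectly stable, but alone
it can miss the quadrature value by a few tenths. `cefapop` therefore
blends the two continuously: a smoothstep weight driven by the smallest
exact eigenvalue (relative to the smallest eigenvalue of $\Omega^{-1}$)
selects the exact Hessian where curvature is healthy and degrades to the
Gauss-Newton form in flat valleys. The blend was chosen after observing
that either hard choice breaks one of the two requirements (accuracy or
outer-objective smoothness).

The inner search for $\hat\eta_i$ runs a Gauss-Newton phase followed by a
full-Hessian Newton polish, both Levenberg-damped with steps capped at 1
on the log scale (so a near-singular curvature cannot throw the iterate
into a distant basin), and stops on a gradient criterion
($\|\nabla h\|_\infty < 10^{-8}$). A pure step-size stop is not enough:
in flat valleys it halts short of the mode by amounts that vary
discontinuously with the population parameters. Subjects with no
quantifiable observations sit at the prior mode $\eta = 0$ and contribute
zero to the objective, which the formula reproduces automatically.

## Estimation

`fit_popmodel()` minimizes the objective over $\log$ typical values,
covariate coefficients, a log-Cholesky factorization of $\Omega$ (which
keeps every iterate positive definite), and $\log$ residual SDs floored
at $10^{-6}$. The outer optimizer is a box-constrained quasi-Newton
(L-BFGS-B) with explicit central-difference gradients (step $10^{-4}$;
the perturbed evaluations warm-start their inner searches from the base
point's modes, which is still a deterministic function of the
parameters). The default relative objective tolerance is $10^{-6}$; a
looser $10^{-5}$ was observed to stop about one objective unit short on
78-subject problems, which is visible in the typical values. For a full
$\Omega$ the fit runs in two stages — diagonal first, then the full
covariance started at zero correlations — purely as an initialization
device. The optimizer path contains no randomness, so a fit is exactly
reproducible from the data and settings; there is no multi-start.

Initial values are a naive two-stage construction: a log-linear fit to
each subject's last three quantifiable points gives a terminal slope,
trapezoid-plus-tail integration gives $CL_i = D/AUC_i$ and
$V_{z,i} = CL_i/\beta_i$; typical-value seeds are the medians with the
heuristic split $V_1 = 0.4V_z$, $V_2 = 0.6V_z$ and $Q = 2CL$ (reflecting
that distribution clearance exceeds elimination clearance for this kind
of drug), $\Omega$ starts at 0.1 on the diagonal and $\sigma$ at
(0.2, 0.5). The reported `converged` flag accepts either the optimizer's
own stop code or stationarity (gradient below 1) at the returned point.

`BIC = OFV + k\ln n` uses the number of fitted observations for $n$ (not
the subject count), the common pharmacometric convention for
extended-least-squares objectives. Observations flagged below the limit
of quantification (0.2 µg/mL) are excluded from fitting with a message;
the flag is retained in the data model. No censoring likelihood (M3-type)
is implemented.

## Covariate search and empirical Bayes diagnostics

`stepwise_search()` runs forward additions then backward deletions. At
each forward step every remaining candidate is added singly and refitted
(warm-started from the current estimates, skipping the diagonal
pre-stage); the best candidate is accepted if it lowers BIC by at least
6.635, ties broken lexicographically by (parameter, covariate). Backward,
a term survives only if removing it would raise BIC by at least 10.823 —
the chi-square criticals for $P<0.01$ and $P<0.001$ at one degree of
freedom, so the backward criterion is the stricter one. The phases run
sequentially, not interleaved. The trace records every evaluated step and
fully reconstructs the final model. Clinical relevance of a selected
effect is summarized by the multiplicative factor at ±50% of the
covariate reference, annotated against a bioequivalence-style 0.80–1.25
band by default (the band is a report annotation, configurable, not a
selection rule).

Empirical Bayes estimates are the conditional modes at the fitted
population parameters; per-$\eta$ shrinkage is
$1 - SD(\hat\eta)/\omega$. Weighted residuals use
$(y - f)/\sqrt{v(f)}$ with either the population prediction ($\eta = 0$)
or the individual prediction. On self-simulated data the individual
weighted residuals are close to unit normal but their SD sits a few
percent below 1, because the conditional modes absorb part of the
residual noise; the test suite checks the mean within 0.1 and the SD
within [0.85, 1.15] on a rich design where this absorption is smallest.

## Bootstrap and visual predictive check

The nonparametric bootstrap resamples *subjects* with replacement to the
original subject count (design, covariates and observations travel
together), refits each replicate starting from the base estimate, and
summarizes every primary and secondary parameter by mean, SE (the SD
across replicates — the standard bootstrap SE), CV%, median and the
2.5/97.5 percentiles. Replicates whose fit fails are dropped and counted;
more than 20% failures aborts. The production default is 1000 replicates;
tests run 3–10 on reduced designs to stay within desk-scale runtimes.

The VPC simulates each subject's own sampling design (default 500
replicates) with $\eta$ drawn from $\hat\Omega$ and residuals from the
combined error model, then compares observed 10/50/90 percentiles per
nominal sampling time with the median and 90% band of the same
percentiles across simulated replicates. Binning is by nominal time
because the design is nominal-time structured; empty bins are dropped
with a warning. Negative simulated concentrations are retained for the
percentile computation (percentile fidelity to the declared error model
matters more than physical plausibility of individual simulated points).
Record-keeping is exact: simulated records = observations × replicates.

## Monte Carlo target attainment and the PK/PD cutoff

`simulate_population()` draws $\eta$ vectors from the multivariate normal
with the full fitted $\Omega$ — preserving the correlations — and maps
them through the exponential model at the typical values. Covariate
effects and residual error are deliberately excluded: the draws are
individual "true" disposition curves, which is what a time-above-MIC
computation on underlying curves requires. The default regimen is
25 mg/kg at 0, 360, 720 and 1080 min over a 1440-min horizon with 2500
subjects.

For each MIC on the doubling grid 0.25–8 mg/L the total-concentration
threshold is MIC divided by the unbound fraction 0.64 (36% serum protein
binding); comparing the total curve against MIC/$f_u$ is algebraically
identical to comparing the free curve against MIC. Because each
inter-dose segment is strictly decreasing, each of the four segments
holds at most one down-crossing, located by bisection to better than
0.01 min; the per-subject time above threshold is the sum of segment
contributions, validated against a brute-force 0.01-min grid within
0.5 min. The "Q90" time for a MIC is the time attained or exceeded by
90% of subjects — the 10th percentile of the per-subject times
(order-statistic estimator with linear interpolation, type 8) — which is
the only reading consistent with Q95 times being shorter than Q90 times.
The PK/PD cutoff is the largest MIC whose Q90 time reaches the target
fraction (default 50%) of the horizon; if none qualifies the cutoff is
reported as below the grid with a diagnostic. Reported thresholds and
percentages are rounded to three significant figures (round-half-even).
Confidence intervals on the attainment quantiles are not computed.

With the reference typical values and omega, the simulated Q90 time
above 3.12 mg/L lands near 720 min — almost exactly the 50%-of-24 h
target — so the derived cutoff sits on a knife edge between 1 and 2 mg/L
and can flip with the Monte Carlo seed. The package reports whatever the
simulation produces; the neighbouring grid rows are far from their
decision boundaries and stable.

## The synthetic study generator

`generate_study()` emulates the design of the motivating clinical study:
78 dogs, one 25 mg/kg bolus at time 0, and per-dog sample counts on
2–11 drawn from a distribution calibrated so the median count is 9 and
the expected study total is ≈630 samples (probabilities 0.025–0.31 over
the counts 2–11, mass concentrated at 9). Each dog's times are a
uniformly random subset of the 13 post-dose protocol times
(5–480 min); the paper-level margins (count range, median, total) are
reproduced without inventing per-dog schedules. Covariates come from
truncated normal distributions matching the published mean/SD/range
(inverse-CDF sampling) and categorical frequencies 19/78 healthy, 27/78
mongrel, 32/23/23 male/female/neutered. The published body-weight
dispersion "26.13 ± 0.88" for a 4.5–56 kg range can only be a standard
error; the generator uses $SD = 0.88\sqrt{78} \approx 7.77$ kg.
Generating parameters default to the reference estimate (typical values,
full omega, combined residual SDs); covariate effects are off by default
so base-model recovery is the primary test, and are opt-in for power
studies. Observations at or below 0.2 µg/mL are flagged and excluded
from fitting, mirroring the assay's limit of quantification.

What the generator does *not* emulate: assay drift or runs, censoring
informativeness, time-varying physiology during anesthesia (covariates
are static), dose timing errors, and model misspecification of any kind
— the data really come from the fitted model family. Passing recovery
tests therefore demonstrate internal consistency of the estimation
stack, not robustness to the ways real clinical data deviate from the
model.

A note on what recovery can show at these study conditions: with the
reference between-subject variability and a 25.7% proportional error,
the exact maximum-likelihood estimates of $V_1$ and $Q$ are themselves
quite variable (and correlated) from study to study. On one synthetic
replicate where the fit returned $V_1$ +37% and $Q$ −43%, the exact
marginal likelihood (computed by importance sampling) preferred those
values over the generating truth by about 21 units — the dispersion is a
property of maximum likelihood at this design and noise level, not of
the conditional approximation, which tracked the exact value within ~2
units. At a 10% proportional error the same pipeline recovers all
typical values within a few percent. The recovery harness
(`recovery_experiment()`) reports median relative biases over replicate
studies; at the default conditions the medians stay within 15% for all
four typical values and within 5% for clearance.

## Problem sizes and runtimes

The package's own test suite runs fits at 8–78 subjects, bootstrap at
3–10 replicates, VPC at 15–500 replicates and Monte Carlo attainment at
150–2500 subjects; a full 78-dog, full-omega fit takes under ten seconds
on one core and the ten-replicate recovery experiment about a minute.
These sizes are the package's choices for desk-scale verification; all
defaults for production use (1000 bootstrap replicates, 500 VPC
replicates, 2500 Monte Carlo subjects) match the emulated analysis.

## Known limitations

- No censoring likelihood for below-LOQ data (exclusion only).
- No three-compartment closed form; the likelihood-ratio machinery is
  generic over nested fits but only the two-compartment structure is
  implemented.
- No absorption or infusion input; bolus only.
- Standard errors come from the bootstrap, not from an asymptotic
  covariance of the objective.
- The FOCE-type objective shares the known small-sample biases of
  conditional approximations under large proportional error.
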