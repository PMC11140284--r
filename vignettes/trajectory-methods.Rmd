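---
title: "Methods: latent trajectory analysis of visual function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent trajectory analysis of visual function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vistraj` implements a five-stage workflow for heterogeneous trajectories
of visual function in ageing cohorts: (1) a single-class latent linear
growth curve with SEM fit indices, (2) growth-mixture class enumeration,
(3) univariate predictor screening, (4) multivariable logistic models of
class membership, and (5) linear/logistic models of distal outcomes. This
vignette explains the models, the estimation choices, the synthetic-data
generator that stands in for restricted survey microdata, and the known
limitations.

## The growth model and its mixture

Vision is scored 1–4 ("blind" up to "able to see and distinguish") at four
waves with time scores t = 0, 1, 2, 3, so the latent intercept is the
expected score at the first analysed wave. For subject $i$:

$$y_{iw} = \eta_{0i} + \eta_{1i} t_w + \varepsilon_{iw}, \qquad
\eta_i \sim N(\alpha_k, \Psi), \quad
\varepsilon_{iw} \sim N(0, \theta_w),$$

where $k$ is the subject's latent class, drawn with probability $\pi_k$.
Classes differ only in the growth-factor means $\alpha_k$; $\Psi$ (2×2,
free covariance) and the wave-specific residual variances $\theta_w$ are
shared across classes. This is the conventional default growth-mixture
specification, and the only one exercised against reference values; a
class-specific-variance extension was deliberately not added. Class 1 is
always the class with the larger intercept mean (canonical order), which
resolves label switching: two runs reaching the same likelihood report
identical ordered parameters.

The treatment of the 1–4 scale as continuous follows the reference
analysis style. The generator can clamp simulated scores to [1, 4]
(`censor_to_scale`), but its default leaves them uncensored because the
estimator assumes an unbounded normal model and recovery experiments
should not confound estimator error with censoring bias.

## Estimation

Both the one-class fit (`lgcm()`) and the mixture (`gmm()`) are estimated
by EM treating the growth factors — and for the mixture, class membership
— as missing data. Every update is closed-form (posterior responsibilities;
weighted means for $\alpha_k$; conditional second moments for $\Psi$ and
$\Theta$), so the observed-data log-likelihood is provably non-decreasing;
the smallest observed increment is stored on the fit object and asserted
in the test suite. Missing waves are handled by marginalising each
subject's likelihood over its observed waves (full-information ML),
grouped by missingness pattern.

Defaults that matter:

* **Starts.** 50 EM starts: the first from k-means on per-subject OLS
  (intercept, slope) estimates, the rest seed-controlled random
  perturbations of it. The best converged start is reported, along with
  per-start outcomes.
* **Convergence.** Absolute log-likelihood change < 1e−6 (1e−8 for the
  one-class fit), at most 500 iterations per start.
* **Variance floors.** $\theta_w \ge 10^{-4}$ and $\Psi$ eigenvalues
  $\ge 10^{-6}$, preventing degenerate density spikes; activations are
  counted on the fit object.
* **Preconditions.** At least 10 subjects per class; complete cases by
  default, or at least 3 observed waves per subject with
  `allow_partial = TRUE` (matching the usual at-least-three-waves
  sensitivity design).

## Fit indices

For complete data the model test statistic is the classical
$(n-1)\,F$ with
$F = \ln|\Sigma| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p +
(\bar y - \mu)'\Sigma^{-1}(\bar y - \mu)$
and $S$ the unbiased sample covariance. (Other software scales by $n$;
at $n \approx 2235$ the difference is negligible.) With partial data the
statistic is the likelihood-ratio against a saturated multivariate-normal
model estimated by EM. The baseline model frees means and variances and
zeroes covariances; under it the likelihood factorises by wave, so its
FIML fit is the per-wave marginal normal fit. CFI, TLI and RMSEA follow
their standard definitions with clamping to [0, 1]; SRMR is the RMS of
standardized covariance residuals over the lower triangle including the
diagonal, excluding mean residuals (the most common convention). With
wave-specific residuals the model has 9 free parameters against 14
moments, hence 5 degrees of freedom.

## Class enumeration

`enumerate_classes()` fits K = 1..K_max and reports AIC, BIC, aBIC
(sample-size term $\ln((n+2)/24)$), relative entropy
$1 - \sum_{ik} -p_{ik}\ln p_{ik} / (n \ln K)$ (NA for one class), an
approximate Lo–Mendell–Rubin test, the bootstrap likelihood ratio test,
and modal class shares. The selected K is the largest K such that at
every step $k \le K$ both tests reject at $\alpha = 0.05$ and all modal
shares are at least 5%.

The LMR test is implemented as the ad hoc small-sample-adjusted LRT
($2\Delta LL$ divided by $1 + 1/(d \ln n)$, referred to $\chi^2_d$ with
$d$ the parameter difference) and is flagged `approximate`; empirically
it rejects a one-class null at about the nominal 5% rate. The BLRT is the
authoritative test when the two disagree: it simulates `B` cohorts from
the fitted (K−1)-class model, refits both models on each, and reports
$p = (1 + \#\{LRT_b \ge LRT_{obs}\})/(B+1)$. A replicate whose refits
fail is redrawn up to a cap and then counted conservatively as exceeding
the observed statistic. Because the smallest attainable bootstrap p-value
is $1/(B+1)$, `enumerate_classes()` warns when B is too small for the
test ever to reject at the chosen $\alpha$ — with $\alpha = 0.05$, use
$B \ge 20$ (the package default is B = 100).

## Predictors and consequences

Screening routes each predictor by kind: class-by-level counts to the
uncorrected Pearson $\chi^2$ (the uncorrected form reproduces published
two-class baseline tables exactly), continuous variables to a
Mann–Whitney test with tie-corrected normal Z. Class membership enters
all downstream models by modal assignment, ties broken toward the
higher-intercept class; posterior-weighted (bias-adjusted three-step)
approaches are a documented limitation, not implemented.

The predictor model is a binomial GLM with outcome 1 for the
high-baseline declining class, Wald standard errors, and ±1.96·SE
intervals on the link scale exponentiated to odds-ratio bounds.
Separation and collinearity raise errors naming the offending terms.
Dose-response uses a restricted cubic spline (truncated-power basis,
Harrell normalisation, default 4 knots at the 0.05/0.35/0.65/0.95
quantiles, linear beyond the boundary knots by construction); the
nonlinearity p-value is a Wald test that all nonlinear coefficients are
zero, and the reported curve is centred (log-odds 0) at the reference
exposure, by default the cohort median. Distal outcomes use OLS (the
unadjusted class coefficient is exactly the group mean difference) or
logistic regression for the fall indicator; model 2 adds sex, birthplace,
residence, occupation, education, economic status and marital status.
No multiplicity correction is applied, matching the descriptive character
of the workflow.

Missing predictor values are handled by chained equations (linear + noise
for continuous, logistic draws for binary, multinomial draws for
factors; five sweeps), with Rubin pooling
$T = \bar W + (1 + 1/m)B$ across the m completed fits. With nothing
missing the result is the direct fit with zero between-imputation
variance.

## The synthetic cohort generator

The generator exists because the motivating survey microdata are
access-restricted. It draws exactly the estimation model above — class,
growth factors, wave noise — plus class-conditional baseline predictors
(binary/categorical probabilities or normal location-scale per class) and
distal outcomes (class-shifted means with Gaussian noise; a logistic fall
indicator), and MCAR masking of single vision observations. Its defaults
are the published two-class structure: proportions (0.819, 0.181), class
means (3.992, −0.174) and (2.641, 0.296) on the 1–4 scale.

Variance components were not published. The package defaults
($\psi_{00} = 0.06$, $\psi_{11} = 0.004$, $\psi_{01} = 0$,
$\theta_w = 0.02$) were calibrated once so that the generating model's
relative entropy equals 0.998, the classification sharpness reported for
the two-class solution; a superficially plausible alternative with larger
components ($\psi_{00} = 0.3$, $\theta_w = 0.2$) was rejected because it
implies entropy ≈ 0.73 — residual noise would swamp the slope contrast,
contradicting the near-deterministic classification it is meant to
emulate. Predictor prevalences per class follow the published baseline
table; variables reported there as non-significant (birthplace, medical
insurance, sleep, blood pressure, vegetable intake, hypertension,
diabetes, stroke, heart disease) are generated class-independent so the
screening stage has true negatives. Age and BMI are normal with medians
matched to the published per-class values and spreads of IQR/1.35;
skewness is not modelled, since only location contrasts matter
downstream. Outcome shifts equal the published unadjusted contrasts, with
noise scales chosen to give realistic contrast standard errors at
n = 2235 (e.g. SD 6 for the 0–30 cognition score).

What passing tests show — and do not show. Recovery tests demonstrate
that the estimator recovers the generating structure when the model is
correctly specified, with continuous unbounded scores, exact linearity
and MCAR missingness. They do not address ordinal measurement (the real
instrument has 4 levels), ceiling effects, informative dropout, or survey
design features (weights, clustering), all of which are out of scope.

## Numerical and testing notes

Problem sizes were chosen to keep the full suite at desk scale: recovery
experiments run at n = 700–2235 with 8–50 starts; the bootstrap-LRT
null-calibration study uses 200 replicates of n = 60 with B = 19 and
loose per-fit tolerances (identical for observed and bootstrap fits, so
the p-value remains uniform under the null); enumeration tests use B = 20,
the smallest B able to reject at $\alpha = 0.05$. Degenerate inputs are
contract-tested: zero-variance configurations simulate deterministic
trajectories, singular implied covariances raise a condition-number
diagnostic, empty classes fail the start rather than the fit, and
one-class enumerations skip the class-contrast stages of the pipeline
with an explanatory trace.
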