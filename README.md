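# vistraj

Growth mixture modelling of visual-function trajectories in longitudinal
ageing cohorts.

Repeated measurements of visual function in older adults do not follow one
common path: most people start near the top of the scale and decline slowly,
while a minority starts impaired and improves (typically after cataract or
glaucoma treatment). `vistraj` implements the five-stage latent-trajectory
workflow used to study this heterogeneity on a cohort measured at four
survey waves on a 1–4 vision scale, for epidemiologists and biostatisticians
who want the whole chain — from trajectory identification to predictor and
consequence models — as tested, scriptable R functions.

## The model

Stage 1 fits a single-class latent linear growth-curve model. For subject
*i* at wave *w* with time score *t<sub>w</sub>* ∈ {0, 1, 2, 3}:

    y_iw = eta0_i + eta1_i * t_w + eps_iw,
    (eta0_i, eta1_i)' ~ N(alpha, Psi),   eps_iw ~ N(0, theta_w)

estimated by maximum likelihood (full-information over each subject's
observed waves if requested), with the usual SEM fit indices — χ²/df, CFI,
TLI, RMSEA, SRMR — computed from the ML discrepancy.

Stage 2 generalises this to a K-class growth mixture: class *k* has its own
growth-factor mean vector α<sub>k</sub>, while Ψ and Θ are shared. The
observed-data likelihood

    LL = sum_i log sum_k pi_k * N(y_i; Lambda alpha_k, Lambda Psi Lambda' + Theta)

is maximised by multi-start EM treating class membership and the growth
factors as missing data. Class enumeration uses AIC/BIC/aBIC, relative
entropy, an approximate Lo–Mendell–Rubin test, the parametric bootstrap
likelihood ratio test, and a ≥5% smallest-class rule.

Stages 3–5 screen baseline predictors (Pearson χ², Mann–Whitney Z), model
class membership by multivariable logistic regression (with a
restricted-cubic-spline dose-response option and chained-equation multiple
imputation with Rubin pooling), and model distal outcomes by linear or
logistic regression, unadjusted and covariate-adjusted.

A synthetic cohort generator with exactly this mixture structure (plus
class-conditional predictors, class-shifted outcomes and MCAR wave
missingness) makes every stage testable with known ground truth.

## Worked example

```r
library(vistraj)

cohort <- simulate_trajectories(sim_config(seed = 42))  # n = 2235, two classes
fit1 <- lgcm(cohort)                                    # stage 1
fit2 <- gmm(cohort, K = 2, n_starts = 50, seed = 7)     # stage 2
print(fit2)
```

```
Growth mixture model, K = 2 (n = 2235)
log-likelihood -76.529; AIC 177.058, BIC 245.602, aBIC 207.476
entropy 0.998
                         proportion intercept   slope
high-baseline decline        0.8193    3.9818 -0.1719
low-baseline improvement     0.1807    2.6276  0.2959
```

81.9% of subjects follow the high-baseline declining trajectory (intercept
3.98 on the 1–4 scale, losing 0.17 points per wave) and 18.1% the
low-baseline improving one (intercept 2.63, gaining 0.30 per wave); entropy
0.998 means the posterior classification is essentially deterministic. The
one-class fit gives `coef(fit1)[1:2]` = (3.737, −0.087), the
proportion-weighted average of the class trajectories, and its fit indices
(`fit1$fit`) judge the linear shape. Downstream:

```r
cohort <- simulate_covariates_outcomes(cohort, sim_config(seed = 42))
labels <- assign_labels(fit2)
screen <- screen_predictors(cohort, labels)                  # stage 3
preds  <- logistic_fit(cohort, as.integer(attr(labels, "class_index") == 1),
                       screen$variable[screen$selected])     # stage 4
```

or run everything at once from a configuration:

```r
bundle <- run_pipeline(pipeline_config(sim = sim_config(seed = 42), seed = 42))
write_report(bundle, "report")
```

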