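---
title: "Markovian multistate Cox models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markovian multistate Cox models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msmcox` fits multistate models for disease-course data -- a patient moving
among a finite set of clinical states in continuous time -- and turns the
fitted model into individual predictions. This vignette is the package's
account of the statistical machinery, the defaults it chose where several
choices were defensible, and the limits of what its validation shows.

## The model

Let $X(t)$ be the state occupied at time $t$, taking values in states
$\{1, \dots, R\}$ connected by a directed, acyclic set of transitions.
Three quantities characterize the process under the Markov assumption
(the future depends on the past only through the current state and time):
transition probabilities $\pi_{kl}(s,t) = \Pr\{X(t)=l \mid X(s)=k\}$,
transition intensities $\lambda_{kl}(t)$ (instantaneous rates), and
cumulative intensities $\Lambda_{kl}(t) = \int_0^t \lambda_{kl}(u)\,du$.
All clocks are "forward": hazards are indexed by time since the common
origin (study entry), matching the Markov model class, not by time since
the last transition.

Each transition gets its own Cox proportional hazards model
$$\lambda_{kl}(t; Z) = \lambda_{kl,0}(t)\, e^{\beta_{kl}^\top Z_{kl}},$$
with a transition-specific covariate subset $Z_{kl}$. Because the full
likelihood factorizes over transitions, each partial likelihood is
maximized separately and totals (log likelihood, AIC) are sums.

Estimation building blocks:

* **Nelson–Aalen.** $\hat\Lambda_{kl}(t) = \sum_{t_j \le t}
  dN_{kl}(t_j) / Y_k(t_j)$ over the event times of the transition, where
  $Y_k$ counts subjects in state $k$ just before $t_j$. Tied events are
  aggregated into a single jump.
* **Cox fits.** Newton–Raphson on the Breslow-ties log partial
  likelihood (Efron available by option), relative tolerance $10^{-9}$,
  at most 50 iterations, step-halving on any non-increase. Covariates
  are centred at their transition-specific means during iteration;
  reported coefficients, baselines and predictions are on the original
  scale. The Breslow baseline
  $\hat\Lambda_{kl,0}(t) = \sum_{t_j\le t} dN_{kl}(t_j) / \sum_{i \in
  R_k(t_j)} e^{\hat\beta^\top Z_i}$ is used for both tie methods; with
  Breslow ties and no covariates it *equals* the Nelson–Aalen estimator
  identically, which the test suite asserts at $10^{-12}$.
* **Aalen–Johansen.** Predictions come from the product integral
  $P(t_0, t) = \prod_{t_0 < t_j \le t} (I + \Delta\hat\Lambda(t_j))$
  over the pooled jump times of the profile-specific cumulative hazards
  $\hat\Lambda_{kl,0}(t)e^{\hat\beta^\top z}$. Rows are stochastic by
  construction; matrices multiply in time order; between jumps $P$ is a
  right-continuous step function (no interpolation).

## Diagnostics

Per transition, three residual families assess the Cox assumptions:

* **Martingale** residuals $r_i = \delta_i - \hat\Lambda_{kl,0}
  (\text{interval}_i)\, e^{\hat\beta^\top Z_i}$ for linearity of
  continuous covariates (loess smooth, span 0.75, attached).
* **dfbetas** for influence: the default is the one-step score-residual
  approximation $I(\hat\beta)^{-1} s_i$ standardized by the coefficient
  standard errors; the exact leave-one-out refit (kept as the test
  oracle, refused above 2000 episodes) differences the coefficient
  vectors directly.
* **Scaled Schoenfeld** residuals $d\,\hat V\,(Z_{(j)} - \bar Z(t_j))$
  at each event time for proportionality, with a loess smooth, a
  pointwise $\pm 2\,\mathrm{se}$ band, and a linear trend test of
  residual against event time.

A caveat the package's validation made explicit: the one-step dfbetas
approximation is accurate while risk sets remain large, and degrades for
events in nearly-empty risk sets (e.g. an uncensored right tail). The
bundled 30-episode agreement instance therefore uses a fixed-horizon
(administratively censored) design -- the typical clinical follow-up
situation -- and the documentation recommends the exact method when a
handful of late events dominate a small transition.

## Prediction and scoring

For a new individual (baseline covariates plus starting state), the
start-state row of $P(0, t)$ yields occupancy curves, the per-state
probabilities at a horizon $\tau$, the most likely state (ties broken by
the smallest state index), and absorbing-state probabilities such as
death by day $\tau$. A cohort-style mixture over starting states is
available through the `init` argument; mid-course prediction starts the
product integral at $t_0 > 0$ with the same fitted hazards.

Forecast quality is summarized by the logarithmic score
$-\tfrac1n\sum_i \log \tilde P\{X_i(t_1) = x_i(t_1)\}$ (0 is perfect,
$\log R$ is the uniform forecast) and by a confusion matrix of predicted
(most likely) versus realized states with per-state accuracy. Subjects
censored before $t_1$ cannot be scored and are excluded with a reported
count -- the conservative choice for censored data. Probabilities are
floored at $10^{-12}$ before the logarithm, with a flag when the floor
fires, since the score is otherwise unbounded. Evaluation is in-sample
by default; passing a held-out subject table gives out-of-sample
assessment.

## The simulator

`simulate_paths()` draws clock-forward Markov paths: per transition a
constant or Weibull baseline intensity multiplied by $e^{\beta^\top z}$,
covariates binary or normal, an initial-state distribution, and
administrative (plus optional exponential) censoring. Sojourn times
invert the total exit cumulative hazard -- in closed form when all
outgoing hazards are constant, otherwise by bracketed root-finding to
$10^{-10}$ -- and destinations are drawn proportionally to the
intensities at the event time. This keeps the generator in exactly the
model class the estimator assumes.

That alignment is deliberate and bounds what the tests can show: the
simulator emulates proportional-hazards effects, competing exits,
right-censoring and multiple initial states, but *not* time-dependent
covariates, non-Markov (sojourn-clock) dynamics, informative censoring,
or measurement error. Passing validation therefore demonstrates
correctness of the estimation and prediction machinery under the model,
not robustness to violations of it -- with one exception: the
proportionality-diagnostic power check deliberately simulates crossing
(Weibull shape 0.5 vs 2) group hazards outside the PH class.

Bundled scenarios (`make_fixture()`): a hand-traceable 3-subject
illness-death table with its hand-derived episode and Nelson–Aalen
tables frozen beside it; a 500-subject illness-death cohort (rates 0.1,
0.05, 0.2 per day; binary covariate, true log hazard ratio $\log 2$;
30-day administrative censoring); and a synthetic 7-state,
14-transition hospital-course cohort with two admission states, three
care-level states and two absorbing states, in which death from
non-critical states is deliberately rare. Its day$^{-1}$ rates were
chosen once so that ward stays resolve within days, invasive
ventilation has a roughly two-week median total stay, and overall
mortality is a few percent -- the shape of a hospitalized-cohort
dataset. All fixtures regenerate bit-identically from fixed seeds.

## Numerical and design choices

* **Tie handling** defaults to Breslow because it makes the
  null-model-baseline = Nelson–Aalen identity exact; Efron is available
  per fit.
* **Acyclicity is enforced at construction.** Banning repeated passage
  through a transition is guaranteed structurally by a DAG, and makes
  episode expansion and path simulation terminate by construction. A
  state in no transition (simultaneously initial and absorbing) is
  rejected rather than given an arbitrary role.
* **State roles are in/out-degree.** Initial means in-degree zero;
  starting distributions over transient states are still allowed, so
  "can start there" is a property of the data/spec, not of the graph.
* **Zero-length stays are rejected** at import: they break
  $t_{start} < t_{stop}$ and the risk sets. Merge or jitter
  pass-through states upstream.
* **Missing covariates**: subjects missing any covariate used anywhere
  in a model are dropped with a logged count (complete case) -- the
  simplest defensible default.
* **Separation**: a positive log partial likelihood (analytically
  impossible; numerically a diverging linear predictor) or a per-SD
  log hazard ratio beyond 10 aborts with a monotone-likelihood error
  naming the remedy.
* **Over-unit jump mass**: for extreme profiles a single product factor
  can ask a state to lose more than its whole mass; the factor's
  diagonal is clamped at zero and the row renormalized, with a warning
  naming the time and state. This keeps every matrix row-stochastic
  instead of propagating negative probabilities.
* **Hazard smoothing** uses an Epanechnikov kernel over Nelson–Aalen
  increments, default bandwidth one eighth of the jump-time range, with
  boundary correction by renormalizing the kernel mass inside the
  observation window. The smoother is a display device; tests validate
  only its mass conservation against the unsmoothed cumulative.
* **Confidence intervals** are Wald on the log-HR scale at a
  configurable level (default 95%); coefficient p-values are unadjusted
  Wald tests, matching standard software tables.
* **Problem sizes in the validation suite** -- 200 replicates of
  $n{=}500$ for parameter recovery, 1000 replicates of $n{=}300$ for
  test calibration, 20 replicates of $n{=}2000$ for scoring, one
  $n{=}5000$ cohort against the Kolmogorov closed form, and a 15-day
  evaluation horizon (mid-course, where the state distribution is most
  mixed and forecast differences are informative) -- were fixed as the
  package's standing study conditions.

## Known limitations

No variance bands for Nelson–Aalen curves or predicted probabilities;
no time-dependent covariates, left truncation, interval censoring or
recurrent states; no shared coefficients or stratified joint fits
across transitions; no penalized estimation or frailties; calibration
and sharpness are summarized only through the logarithmic score.
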