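---
title: "Estimating reproduction numbers and growth rates: models, filters and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating reproduction numbers and growth rates: models, filters and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigrowth)
```

# The two statistics and why they are linked

Public-health surveillance tracks two summaries of an incidence curve
$I_1, \dots, I_T$: the instantaneous reproduction number $R_t$ (secondary
infections per effective primary case; dimensionless) and the instantaneous
growth rate $r_t$ (log-derivative of smoothed incidence; per day). The
renewal model ties $R_t$ to the data through the generation-time
distribution $w_j$,

$$\mathbb{E}[I_t] = \Lambda_t R_t, \qquad
  \Lambda_t = \sum_{j \ge 1} I_{t-j} w_j,$$

while model-agnostic growth rates differentiate a smoothed incidence
$S_t = \sum_j a_j I_{t+j}$. Both operations are discrete convolutions: the
total infectiousness $\Lambda_t$ is an epidemiologically informed smoothing
kernel, one particular choice of Savitzky–Golay (SG) filter whose weights
are the generation-time probabilities and whose window is the
generation-time support. This package implements both routes plus the
moment-generating-function bridge $R\,M_w(-r) = 1$ between them, and lets
you quantify when each statistic is the more reliable one.

## Assumptions

* Cases equal infections; reporting is complete and undelayed.
* The generation time is well characterised, time-invariant, and
  approximated by the serial interval; support starts at one day (no
  same-day transmission).
* Observation noise is Poisson (negative binomial available in the
  simulator); transmission is homogeneous — no superspreading, spatial or
  age structure.
* The $R \leftrightarrow r$ transforms assume locally exponential growth or
  decay.

# Generation times and their discretization

Generation times are gamma distributed with shape $a$ and rate $b$ (per
day), discretized onto integer days. We assign day $j \ge 2$ the gamma mass
of $[j - \tfrac12, j + \tfrac12]$ and give day 1 everything below $1.5$
days. This centred convention keeps the discrete mean within a few
hundredths of a day of the continuous mean $a/b$; an interval convention
that assigns $[j-1, j]$ to day $j$ would shift the mean by half a day and
propagate a systematic $\sim\!6\%$ bias into every MGF-based transform,
which is why we rejected it. The support is truncated where the remaining
tail mass drops below `tail_cutoff` (default $10^{-4}$, bounding the
convolution length at negligible cost in mass) and renormalised.

The default disease parameters throughout are $a = 3$, $b = 0.375$/day —
mean 8 days, the scale of Ebola-like serial intervals; the exact published
serial-interval parameters behind that mean are not fixed by our sources,
so the mean is the declared quantity and the shape a generic choice.
`misspecify_mean(gt, f)` rescales the rate to $b/f$ at fixed shape, so only
the mean changes; this isolates mean misspecification, the practically
dominant serial-interval error.

# The renewal simulator

`simulate_renewal()` draws $I_t \sim \text{Poisson}(\Lambda_t R_t)$ (or
negative binomial with dispersion $k$) under any positive $R_t$ profile.
Design choices:

* **Seeding.** The model is silent about initial conditions, so the first
  $\max(7, L/2)$ days are constant imports of `seed_cases` (default 50),
  which guarantees $\Lambda_t > 0$ when endogenous transmission starts.
* **Deterministic mode** propagates means instead of sampling; with
  constant $R$ its log-incidence slope converges to the $r$ solving
  $R\,M_w(-r)=1$, which the tests use as an analytic cross-check of the
  simulator against the transforms.
* **Extinction** is flagged, never raised: a faded epidemic is a valid
  outcome.
* The default seasonal scenario is
  $R_t = 1 + 0.75\sin(2\pi t/120)$ over $T = 300$ days. These sinusoid
  parameters are this package's choice: they produce two full seasons with
  incidence swinging from a handful to hundreds of daily cases, which
  exercises both the easy (high-count) and hard (trough) estimation
  regimes. What the generator does *not* emulate — reporting delays,
  weekday effects, underreporting, importation waves, superspreading — is
  exactly what passing tests say nothing about.

# Reproduction-number inference

`estimate_rt()` runs a grid filter/smoother: the latent $R_t$ performs a
Gaussian random walk with daily standard deviation $\eta\sqrt{R_{t-1}}$
(state noise $\eta = 0.1$ by default; larger values track faster changes at
the price of noisier estimates), projected onto a grid of candidate values
(default 2000 points on $[0.01, 10]$, uniform prior). Each day multiplies
the propagated prior by the Poisson likelihood of $I_t$ with mean
$\Lambda_t R$; a backward pass then conditions every day on the full curve.
Numerical choices:

* Likelihoods are evaluated in log space with max-subtraction before
  exponentiation; non-finite log-likelihoods are floored at $-700$ and the
  smoother's predicted probabilities at $10^{-300}$ before division.
* Estimation starts on day 2, the first day with a defined $\Lambda_t$; day
  1 reports the prior. Positive counts on a day with $\Lambda_t = 0$ are an
  impossible observation and raise an error rather than being absorbed.
* The **smoothed** posterior mean is the headline estimate (it minimises
  mean squared error); credible intervals are equal-tailed 2.5%/97.5%
  posterior quantiles, taken as the first grid point whose CDF reaches the
  probability, so reported intervals are never anti-conservative by
  rounding.
* One-step-ahead predictions use the *filtered* side only — the state
  distribution before seeing the day's count — mixed with the Poisson
  observation law; interval quantiles come from bisection on the exact
  mixture CDF. Their empirical coverage is the package's validation signal
  for the fitted model.

Grid resolution is a pure discretization parameter: doubling it moves
posterior means by well under 1% (tested), so scaled-down grids are used
freely in the faster tests.

# Growth-rate filters

SG coefficients are the local least-squares polynomial fit over an odd
window $m$, evaluated (or differentiated) at the window centre; with
polynomial order $\le 1$ they reduce exactly to the $1/m$ moving average.
Defaults $m = 15$ days, order 2: the window spans roughly two mean
generation times, long enough to suppress Poisson noise and short enough to
resolve a 120-day season.

* `growth_from_log_incidence()` smooths counts (derivative-0 filter),
  floors at 0.5 cases, takes logs, then applies the derivative-1 filter.
  Staging avoids $\log 0$ on raw counts; days whose smoothed count hit the
  floor are reported `NA` rather than as a spurious zero growth rate.
* `growth_from_total_infectiousness()` needs no explicit smoothing stage —
  $\Lambda_t$ is already a filtered series — so a single derivative-1 pass
  over $\log \Lambda_t$ suffices.
* Edges where the window does not fit are `NA`; padding would smuggle in a
  boundary model we have no basis for.
* Both estimators are exact on noiseless exponentials (a convolution of an
  exponential is the same exponential rescaled), which anchors the test
  suite at $10^{-6}$ tolerance.
* No credible intervals accompany the SG-based estimates: they are
  deterministic filters with no probability model attached; only the
  posterior-transform route propagates uncertainty.

**Lag conventions.** Because $\Lambda_t$ looks backwards over the
generation time, its growth-rate series trails the incidence-based one by
about the mean generation time $E[w]$ (the recovered lag in the default
scenario is 8 days, equal to the mean). Two statements of the alignment
convention circulate — shift each series by half $E[w]$ towards a common
centre, or shift $\Lambda_t$ by the full $E[w]$ against $S_t$ — and they
are consistent: we adopt half-shifts of each series ($\Lambda$-based left,
incidence-based right, by $\mathrm{round}(E[w]/2)$) when comparing with the
model-based estimate, which implies the full-$E[w]$ relative lag between
the two model-agnostic series. Every shift is an explicit argument and is
recorded in the returned object; `align_lag()` estimates the lag
empirically by correlation matching, breaking ties toward the smaller
magnitude.

# Transforms and their domains

Three monotone maps convert $R$ to $r$: the gamma closed form
$r = b(R^{1/a}-1)$, a bisected root of $R\,M_w(-r)=1$ on the discretized
MGF (bracket expanded geometrically from zero, tolerance $10^{-12}$,
capped at $|r| \le 20$/day beyond which a root would be outside any
epidemiologically meaningful regime), and the linearised SIR relation
$r = (R-1)/E[w]$. All three agree at the threshold $R=1 \mapsto r=0$ and to
first order around it. Posterior credible intervals are transformed by
mapping the quantile bounds directly — exact for monotone maps, no
resampling. Sign equivalence $\operatorname{sign}(r) =
\operatorname{sign}(R-1)$ holds for every kind by construction.

# The misspecification experiment

One epidemic is simulated under the true generation time; estimation then
runs twice, assuming the true distribution and one whose mean is 33%
smaller (`factor = 0.67`), each posterior transformed through its own
assumed distribution — what an analyst holding the wrong serial interval
would actually report. Robustness is summarised by **error-inflation
factors**: the ratio of median errors (misspecified over correctly
specified), for $\widehat R_t$ against the true profile and for the derived
$\widehat r_t$ against the true growth rate. Relative errors for $r$ are
ill-posed near its threshold crossings (the truth passes through zero), so
the reported relative errors floor the denominator at 0.01/day and the
inflation factor for $r$ uses median absolute error, whose scale cancels in
the ratio. Summary metrics throughout are restricted to days with more than
`incidence_floor` (default 10) cases and defined values for all estimators,
since low-count days are uninformative for every method.

# Problem sizes and determinism

The test suite and experiments use deliberately scaled problem sizes, all
stated here as the package's own choices: the seasonal scenario at
$T = 300$ with a 600-point grid for shared fixtures (2000 points in the
default experiment configuration), the smoother-vs-filter comparison over
40 replicate epidemics of $T = 100$, and the calibration study over 200
constant-$R$ epidemics ($R \in \{0.8, 1.5, 2\}$, $T = 150$, 10 seed cases,
a 1500-point grid on $[0.2, 4]$ chosen so grid spacing stays below the
posterior width even at peak counts). Every stochastic step is seeded;
identical configuration and seed reproduce byte-identical outputs.

# Known limitations

* No correction for reporting delay, underreporting or day-of-week
  artefacts; estimates describe the case curve, not the infection curve.
* Poisson-only inference likelihood (the simulator's negative-binomial
  option has no inference counterpart), so overdispersed data will show
  undercovering intervals.
* Time-varying or negative serial intervals are out of scope, as are
  sliding-window estimators of $R_t$ and spline or state-space growth-rate
  estimators outside the SG family.
* The grid filter's cost is quadratic in grid size; very high incidence
  needs a finer grid precisely where the matrices get expensive.
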