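# epigrowth

Tools for tracking pathogen transmissibility from daily case counts, built
around the two summary statistics that drive real-time epidemic policy: the
**instantaneous reproduction number** `R_t` (average secondary infections per
effective primary case; `R_t > 1` means growth) and the **instantaneous
growth rate** `r_t` (the time derivative of log-smoothed incidence, in units
of 1/day). The package is for epidemiologists and modellers who want to
estimate either quantity from an incidence curve, convert between them, and
understand how the smoothing choices behind `r_t` relate to the
epidemiological assumptions behind `R_t`.

## The model

The renewal model links incidence `I_t` to transmissibility through the
generation-time distribution `w_j` (probability that a secondary case
appears `j` days after its primary case):

    E[I_t] = Lambda_t * R_t,      Lambda_t = sum_{j>=1} I_{t-j} * w_j

`Lambda_t`, the **total infectiousness**, is a backward-looking weighted
moving average of the incidence — structurally the same object as a
Savitzky–Golay (SG) smoothing kernel

    S_t = sum_{j=-(m-1)/2}^{(m-1)/2} a_j * I_{t+j}

used by model-agnostic growth-rate estimators `r_t = d log S_t / dt`. The
package exploits this correspondence in three estimators of `r_t` (posterior
transform of `R_t`, SG derivative of log-smoothed incidence, SG derivative
of `log Lambda_t`) and in the lag law that connects them: the
`Lambda_t`-based estimate trails the incidence-based one by roughly the mean
generation time `E[w]`.

Under an exponential-growth assumption the two statistics are linked through
the moment generating function `M_w` of the generation time:

    R * M_w(-r) = 1,  which for gamma(a, b) generation times gives
    r = b * (R^(1/a) - 1)

so `R = 1` and `r = 0` describe the same epidemic threshold.

`R_t` estimation uses a Bayesian grid filter/smoother: a Gaussian random
walk on `R` (standard deviation `eta * sqrt(R)` per day) filtered forward
against a Poisson renewal likelihood and smoothed backward, yielding
minimum-mean-squared-error posterior means, equal-tailed 95% credible
intervals, and one-step-ahead predictions of the incidence itself for
validation.

## Worked example

```r
library(epigrowth)

gt <- discretize_gamma(3, 0.375)          # gamma generation time, mean 8 d
profile <- seasonal_rt_profile(300, baseline = 1, amplitude = 0.75,
                               period = 120)
epi <- simulate_renewal(profile, gt, seed_cases = 50, rng_seed = 1)
epi
#> Renewal-model epidemic: 300 days, 25,484 cases total
#>   seed 1, 18 seeding day(s), true R_t in [0.25, 1.75]

post <- estimate_rt(epi$incidence, gt)    # filter + smoother + predictions
post
#> Rt posterior over 300 days (grid of 2000 points in [0.01, 10.00], eta = 0.1)
#>   final-day smoothed R: 1.00 (95% CrI 0.72-1.32)

# three growth-rate estimates
transform_posterior(post, transform_spec("gamma_closed_form", gt))
#> Growth-rate series (model_transform): 300 days, 0 undefined, shift +0 d, range [-0.1368, 0.3172] /day
growth_from_total_infectiousness(epi$incidence, gt)
#> Growth-rate series (sg_total_infectiousness): 300 days, 15 undefined, shift -4 d, range [-0.1319, 0.2158] /day

# the implicit-filter lag equals the mean generation time
align_lag(growth_from_total_infectiousness(epi$incidence, gt, shift_days = 0),
          growth_from_log_incidence(epi$incidence), max_lag = 16)
#> [1] 8

growth_from_R_gamma(2, shape = 3, rate = 0.375)   # r implied by R = 2
#> [1] 0.09747039
```

The final-day posterior says transmission is hovering at the threshold
(`R ≈ 1.00`), the growth-rate series bound the epidemic's speed between
roughly −0.14 and +0.32 per day across the seasons, and the recovered
8-day lag between the two model-agnostic estimators matches the mean
generation time. One-step-ahead 95% prediction intervals covered 95% of the
observed daily counts in this run.

End-to-end experiments (seasonal comparison; estimation under a
generation-time mean misspecified 33% low) are available as
`run_seasonal_experiment()` / `run_misspecification_experiment()` or from
the shell:

```sh
exec/epigrowth experiment seasonal --seed 1 --out runs/seasonal/
exec/epigrowth transform --R 2 --kind gamma --shape 3 --rate 0.375
```

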