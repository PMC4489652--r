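# selfexcite

Self-exciting contagion models for daily catalogs of rare violent
incidents — mass killings, school shootings, and similar event lists.

## The problem

Incident catalogs of this kind often look "bursty": several events within
a couple of weeks, then quiet stretches.  The scientific question is
whether an incident transiently raises the probability of further
incidents (contagion, e.g. through widespread media coverage), and by how
much, after allowing for ordinary structure such as secular trend,
day-of-week and seasonal preferences.  The package is aimed at
quantitative researchers in injury epidemiology and criminology who work
with such catalogs as CSV files (one row per incident: date, state,
coordinates, victims killed, firearm and shooter-suicide flags).

## The model

Events are discretized to whole days.  The expected number of events on
day *t_n* given the history is

    N_exp(t_n) = N0(t_n) + N_sec * sum_{t_i < t_n} P(t_n - t_i; T)

with the excitation kernel

    P(Δ) = exp(-(Δ-1)/T) - exp(-Δ/T),   Δ ≥ 1,

the integral of an exponential contagion density of mean `T` days over
the 24 hours of the target day.  The kernel telescopes to unit mass, so
`N_sec` (the branching ratio) is the expected number of secondary events
incited by one event, and `T` (`T_excite`) is the mean contagion duration
in days.  Daily counts are Poisson with this conditional mean; the
baseline `N0(t)` is constant, linear, or a Gaussian-weighted running mean
of the data with optional day-of-week/month modulation.  Fitting is by
maximum likelihood with profile-likelihood confidence intervals, and the
contagion test is a likelihood-ratio test calibrated by parametric
bootstrap (the contagion duration is undefined under the no-contagion
null, so χ² asymptotics are unreliable there).

The package also provides a seeded synthetic-catalog generator (used by
all tests and as the bootstrap engine), Mantel-type permutation tests for
joint temporal/geographic clustering, and state-level ecological
statistics: the binomial-CDF incidence flag `F(k_i | N_i, μ)` under the
national rate `μ`, the firearm-ownership proxy (state fraction of
suicides by firearm), and incidence–covariate correlations.

## A worked example

Simulate eight years of a mass-killing-like process (baseline 0.08
events/day, branching ratio 0.3, 13-day contagion window), then fit and
test:

```r
library(selfexcite)

spec   <- generator_spec(n_days = 3000, N0 = 0.08,
                         N_secondary = 0.3, T_excite = 13, seed = 42)
series <- simulate_series(spec)
fit    <- fit_contagion(series)
fit
#> Self-excitation contagion model fit
#>   events: 354 over 3000 days; baseline: constant
#>   N_secondary = 0.2260   T_excite = 6.05 days
#>   logLik full = -1119.020   null = -1125.772
#>   LRT statistic = 13.505 (asymptotic chi-sq df=2 p = 0.001168;
#>    use lrt_contagion() for bootstrap calibration)

round(confint(fit), 3)
#>             lower upper
#> N_secondary 0.085  0.41
#> T_excite    1.546 17.46

lrt_contagion(fit, n_boot = 999, seed = 7)
#> Contagion likelihood-ratio test
#>   Lambda = 13.5047
#>   parametric bootstrap p = 0.001 (n_boot = 999, seed = 7)
```

Reading the output: the fitted branching ratio 0.226 means each incident
incites ~0.23 further incidents on average (truth 0.3 is inside the
profile 95% interval [0.085, 0.41]); the fitted contagion window is ~6
days with a wide interval [1.5, 17.5] containing the true 13 — the
duration is weakly identified at ~350 events, which is exactly why the
intervals are profile-based and asymmetric.  The bootstrap p = 0.001
rejects the no-contagion null.

Real catalogs enter through `read_catalog()` (with filters such as
`list(min_killed = 4, firearm = TRUE)`) and `to_daily_series()`;
`weekday_seasonal_tests()`, `suicide_severity_comparison()`,
`time_distance_correlation()` and `state_incidence()` cover the
descriptive, spatial and ecological stages.  A thin command-line
front-end with `simulate`, `describe`, `fit`, `lrt`, `spatial` and
`states` subcommands is installed at
`inst/scripts/contagion-cli.R`.

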