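# periodicHMM

Hidden Markov models of animal movement whose state transition probabilities
vary periodically with hour of day.

## Why

Long hourly GPS records (months to years per animal) show strong diurnal
structure: a panther travels at night and rests at midday. Standard movement
HMMs assume a constant transition matrix, and when they are fitted to such
data the only way the likelihood can express the daily cycle is by adding
latent states — BIC then "discovers" five, six or more movement states that
have no biological meaning. This package implements HMMs (and finite mixture
models) whose transition probabilities depend on hour of day, the model
machinery to select the number of states, and the simulation experiment
showing that omitting temporal heterogeneity — or ignoring GPS measurement
error — inflates the selected state count.

## The model

For step lengths and optional turning angles $y_t$, hidden states $z_t$ and
hour covariate $x_t$,

$$P(Y,Z\mid\theta,X)=P(z_1\mid x_1)P(y_1\mid z_1)\prod_{t=2}^{T}
P(z_t\mid z_{t-1},x_t)\,P(y_t\mid z_t),$$

with log-Normal or Weibull step lengths, von Mises turning angles, and
multinomial-logit transition rows
$\pi_{ij}(t)=\exp\eta_{ij}(t)/\bigl(1+\sum_{j'\ge2}\exp\eta_{ij'}(t)\bigr)$
whose linear predictors $\eta_{ij}(t)$ are constant, piecewise-constant over
hour blocks, quadratic in $t/24$, sinusoidal with a 24 h period, or fully
hourly. Setting all rows equal gives a finite mixture model. Fitting is
direct maximum likelihood on the scaled forward recursion (C++ core),
decoding via Viterbi, selection via BIC with the free-parameter count
$k_i(n-1)+k_t\,n(n-1)+k_e\,n$.

## Worked example

Simulate a panther-like year of hourly fixes (two states, log-Normal steps
around 15 m and 500 m, nocturnal travelling), then fit and compare models:

```r
library(periodicHMM)

fx  <- pantherFixture(T = 10000, seed = 1)      # synthetic hourly series
fit <- fitHMM(fx$series, hmmSpec(2, "sinusoidal"), nStarts = 5, seed = 1)
fit
#> Fitted HMM-sinusoidal with 2 state(s)
#>   loglik -54696.14 | free parameters 11 | observations 10000
#>   BIC 109493.6 | AIC 109414.3 | best start 1/5
#>   states (by increasing mean step):
#>    meanlog     sdlog
#> 1 2.700783 0.7936166
#> 2 6.198109 0.5939442
```

The generating values were meanlog $\log 15 \approx 2.708$ (sdlog 0.8) and
$\log 500 \approx 6.215$ (sdlog 0.6); both are recovered to two decimals.
A grid over state counts and transition structures:

```r
fitGrid(fx$series, nRange = 2:3,
        transitions = c("homogeneous", "sinusoidal"), nStarts = 3, seed = 1)
#> Model grid (4 candidates)
#>            label n n_free   loglik      BIC      AIC   dBIC converged selected
#>  HMM-homogeneous 2      7 -55240.9 110546.3 110495.8 1052.7      TRUE    FALSE
#>   HMM-sinusoidal 2     11 -54696.1 109493.6 109414.3    0.0      TRUE     TRUE
#>  HMM-homogeneous 3     14 -55237.6 110604.2 110503.2 1110.6      TRUE    FALSE
#>   HMM-sinusoidal 3     26 -54682.5 109604.5 109417.0  110.9      TRUE    FALSE
#> selected: HMM-sinusoidal with n = 2
```

The sinusoidal two-state model wins by over 1000 BIC units against the
homogeneous alternatives, and adding a third state costs 111 BIC units —
temporal heterogeneity, not extra states, explains the data. The observed
diagnostics confirm the diurnal signal: hourly mean step lengths range from
47 m (midday) to 503 m (night), and the step-length ACF is −0.177 at lag 12
but +0.175 at lag 24.

Diagnostics and decoding:

```r
obs  <- hourlyProfile(fx$series)                 # observed hourly means ± SE
pred <- predictHourlyProfile(fit, T = 10000)     # out-of-sample prediction
acf  <- predictStepAcf(fit, T = 10000, maxLag = 48)
z    <- viterbiPath(fit$spec, fit$theta, fx$series)
```

Real fix tables enter through `readFixes()` + `deriveSteps()` (projected
x/y in metres, hourly fixes; gaps break the series into segments). A thin
command-line wrapper with `derive | simulate | fit | grid | experiment |
diagnose` subcommands is installed at
`system.file("cli", "periodicHMM-cli.R", package = "periodicHMM")`.

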