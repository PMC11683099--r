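# ccdm

Coupling coordination analysis of health resource allocation and
regional economic development.

## The problem

Health systems and regional economies develop interactively: economic
growth funds health resources, and a healthy workforce feeds growth.
Policy analysts evaluating whether the two systems develop *together* —
for a set of provinces observed over a decade, say — use a standard
toolkit: entropy-weighted composite evaluation indices per subsystem,
the relative development degree to see which side lags, the coupling
coordination degree model (CCDM) to grade coordinated development, and
a fixed-effects panel regression to identify its drivers. `ccdm`
implements that entire pipeline as a tested, reusable R package for
researchers in health economics and regional science.

## The model

For each region-year, indicators are min-max standardized with
direction handling (cost indicators such as CPI are reversed), pooled
over the whole panel, and aggregated with entropy weights
(w<sub>j</sub> ∝ 1 − e<sub>j</sub>, where e<sub>j</sub> is the
normalized Shannon entropy of indicator j) into comprehensive
evaluation indices U<sub>h</sub> (health) and U<sub>e</sub> (economy).
Then

- relative development degree: **S = U<sub>h</sub>/U<sub>e</sub>**,
  with S ≤ 0.8 health lagging, 0.8 < S < 1.2 dynamic equilibrium,
  S ≥ 1.2 economy lagging;
- coupling degree: **C = 2√(U<sub>h</sub>U<sub>e</sub>)/(U<sub>h</sub>+U<sub>e</sub>)** ∈ [0, 1];
- coordination index: **T = αU<sub>h</sub> + βU<sub>e</sub>** (default α = β = 0.5);
- coupling coordination degree: **D = √(C·T)**, classified into ten
  grades (I extreme disorder … X high-quality coordination) across
  low-, medium- and high-level coordination stages.

With α = β = 0.5, D = (U<sub>h</sub>U<sub>e</sub>)<sup>1/4</sup>
exactly. Drivers of coordination are estimated by the two-way within
estimator of

ln D<sub>it</sub> = α + β′ ln x<sub>it</sub> + δ<sub>i</sub> + η<sub>t</sub> + ε<sub>it</sub>

with cluster-robust inference, preceded by a diagnostic battery:
Levin–Lin–Chu, Im–Pesaran–Shin and Fisher-combined ADF panel unit-root
tests, a residual-based panel cointegration check, and poolability F /
Breusch–Pagan LM / robust (wild-bootstrap) Hausman model selection.

## Worked example

Real panels come from statistical yearbooks; the bundled generator
emulates their qualitative structure with known ground truth.

```r
library(ccdm)
library(dplyr)

panel <- simulate_indicator_panel(synthetic_config(seed = 42))
records <- run_coordination(panel)
records |>
  group_by(year) |>
  summarise(across(c(U_h, U_e, S, D), mean))
#>  year   U_h   U_e     S     D
#>  2011 0.008 0.114 0.059 0.162
#>  2012 0.035 0.234 0.160 0.298
#>  2013 0.088 0.301 0.316 0.400
#>  2014 0.161 0.361 0.491 0.486
#>  2015 0.248 0.422 0.648 0.563
#>  2016 0.355 0.471 0.844 0.633
#>  2017 0.475 0.512 1.026 0.696
#>  2018 0.614 0.568 1.197 0.761
#>  2019 0.763 0.619 1.350 0.822
#>  2020 0.930 0.661 1.532 0.878
```

Both composite indices rise year on year; the mean relative development
degree starts below 0.8 (health resources lag), crosses 0.8 in 2016 and
1.2 in 2018 (the economy becomes the lagging side); the mean coupling
coordination degree climbs from mild disorder (0.162) to good
coordination (0.878). `plot_coordination(records)` draws the D
trajectories with the stage boundaries.

The regression stage, on a synthetic panel whose true coefficients are
the published driver estimates:

```r
sim <- simulate_fem_panel(synthetic_config(
  seed = 42, n_regions = 30, n_years = 20, fem = list(sigma = 0.05)
))
fit_fem(sim$data)
#> Fixed-effects (twoways) panel regression of lnD
#> 600 obs (30 units x 20 periods), cluster SEs
#>
#>                      term  estimate std.error statistic   p.value
#>         ln_gdp_per_capita 0.2346299   0.01938  12.10513 7.328e-13
#>         ln_industry_share 0.0782504   0.01976   3.95921 4.469e-04
#>      ln_tech_fiscal_share 0.0003422   0.02256   0.01517 9.880e-01
#>  ln_health_exp_per_capita 0.1697410   0.01837   9.24068 3.837e-10
#>  ln_physician_nurse_share 0.1831407   0.02784   6.57894 3.298e-07
#>          ln_beds_per_1000 0.0813799   0.02246   3.62325 1.101e-03
#>
#> Intercept -6.4124 | within R-squared 0.3918 | sigma 0.0482
```

Each estimate sits within two cluster-robust standard errors of its
true value (0.2478, 0.072, 0.021, 0.164, 0.1838, 0.1223; intercept
−6.578). `tidy()`, `glance()` and `autoplot()` give broom-style access
to any fit, and `panel_diagnostics()` runs the full pre-estimation
battery.

A thin command-line driver is installed under `exec/`:

```sh
ccdm simulate --out run --seed 42
ccdm coordination --input run/panel.csv --out run
ccdm regress --coordination run/coordination.csv --drivers drivers.csv --out run
ccdm validate
```

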