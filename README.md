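# mahigrow

Projecting the length distribution at catch of age-0 common dolphinfish
(*Coryphaena hippurus*) under thermal scenarios.

## What this package does, and for whom

Mediterranean dolphinfish are fished as juveniles (roughly 20–60 cm furcal
length, FL) around fish-attracting devices in autumn. Both how fast they
grow and when they hatch are driven by sea-surface temperature (SST), so
warming shifts the size structure available to the fishery. `mahigrow` is
aimed at fisheries scientists who want to turn a daily SST scenario —
observed, uniformly warmed, or carrying a marine heatwave — into the
distribution of fish length at catch, with calibrated uncertainty in the
growth model behind it.

The pipeline has four parts:

1. **Environment** — daily SST series, parametric scenario transforms,
   degree-day accumulation, and photoperiod from solar geometry.
2. **Spawning phenology** — a temperature-dependent spawning-intensity
   curve turned into a hatch-date probability distribution that initialises
   the simulation.
3. **Growth model** — a two-stage, individually varying model fitted by
   MCMC. Otolith radius at age follows a Gompertz curve whose asymptote
   grows with the accumulated temperature experienced since birth:

   `OtR(i, a) = [L∞0(i) + L∞slope · CummTemp(a)] · exp(−b(i) e^(−c(i) a))`

   with lag corrections for autocorrelated increment residuals, and fish
   length at catch is the radius times a conversion set by the conditions
   at birth:

   `FL(i) = OtR(i) · (β0 + βT · T_b(i) + βP · P_b(i))`

   where `T_b` is the SST and `P_b` the photoperiod (daylight hours) on the
   birth day.
4. **Individual-based simulation** — sample birthdates, grow each fish
   under its thermal history, apply natural mortality (`m = 1.703` yr⁻¹)
   over the whole life and fishing mortality (`f = 5` yr⁻¹) over the days a
   fish is both above the 20 cm vulnerability size and inside the open
   season (Aug 15 onward), and evaluate survivors' lengths on Sep 15:
   `P_i = exp(−m·age/365 − f·days_vulnerable/365)`.

A synthetic-data generator reproduces every input (SST scenarios, otolith
daily-increment datasets, aged-catch records) from known parameters, so the
whole pipeline is testable offline; see the methods vignette
(`vignettes/growth-projection-methods.Rmd`) for the model, priors, sampler
design and limitations.

## Worked example

Simulate a Mediterranean-like baseline, a +3 °C end-of-century offset and a
2.5 °C month-long mid-summer heatwave, and compare the catch:

```r
library(mahigrow)

base <- generate_sst(sst_gen_spec(), seed = 1)   # daily SST, 2 years
specs <- list(
  baseline = scenario_spec("baseline"),
  heatwave = scenario_spec("heatwave", hw_start = "2003-07-10",
                           hw_end = "2003-08-13", hw_intensity_c = 2.5),
  warm3    = scenario_spec("uniform_offset", offset_c = 3)
)
ex <- run_scenario_experiment(base, specs, spawning_params(),
                              truth_params()$pop, mortality_params(),
                              n = 10000, seed = 2)
tidy(ex)
```

```
#> # A tibble: 3 × 8
#>   scenario n_fish n_catch mean_cm median_cm iqr_cm var_cm2 pct_change_mean
#>   <chr>     <dbl>   <int>   <dbl>     <dbl>  <dbl>   <dbl>           <dbl>
#> 1 baseline  10000    1476    24.6      24.4   4.92    8.75           0
#> 2 heatwave  10000    1718    24.6      24.4   4.64    8.65           0.175
#> 3 warm3    10000    1804    27.5      27.5   7.60   19.0            11.8
```

Read: under the baseline, 1,476 of 10,000 simulated fish survive to Sep 15
at or above 20 cm, averaging 24.6 cm. The uniform +3 °C scenario both
accelerates growth and broadens the spawning window, raising the mean
length ~12% and roughly doubling the length variance (more small late-born
fish *and* more large early-born ones). The month-long heatwave leaves the
spawning window untouched and accelerates growth for every fish alive
through it — yet the catch *mean* barely moves, because faster growth also
lets more small fish cross the 20 cm vulnerability threshold (n_catch rises
1,476 → 1,718), offsetting the per-fish gain in the threshold-filtered
average. `autoplot(ex)` draws the violin plot of per-fish percent
deviations from the baseline mean.

Fitting the growth model to (synthetic) otolith increments and catch
records, then validating on held-out fish:

```r
oto <- generate_otolith_dataset(base, n_fish = 20, seed = 3)
cd  <- generate_catch_dataset(base, n_fish = 1876, seed = 4)
sp  <- split_calibration_validation(cd$records, n_calibration = 1000, seed = 5)

cfg <- fit_config(n_chains = 3, n_iterations = 6000, burn_in = 1500,
                  thinning = 1, seed = 6)      # reduced budget
fit <- fit_integral_model(oto, sp$calibration, base, cfg = cfg)
tidy(fit)                                      # posterior summaries + R-hat
validate(fit, sp$validation, base, seed = 7)
```

```
#> Growth-model validation report
#>   accuracy (RMSD):        2.215 cm
#>   precision (mean IQR):   2.833 cm
#>   validation fish:        876
```

`select_lags()` chooses the residual lag order (2 on data generated with
the default lag coefficients), `compute_dic()` compares the
environment-dependent model against the `β0`-only reduction, and
`compute_rhat()` is the Gelman–Rubin convergence statistic used in the fit
summaries.

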