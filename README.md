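# phenofly

Temperature-driven phenology and life-table simulation for the greenhouse
whitefly *Trialeurodes vaporariorum* (Hemiptera: Aleyrodidae), a worldwide
pest of vegetable and potato crops and a vector of the potato yellow vein
virus. The package is aimed at quantitative entomologists and pest-risk
modellers who need to turn a temperature series — a constant regime, a
sinusoidal daily cycle, or an hourly field record — into predicted cohort
life tables and population growth rates for the species.

## The model

Every life process is a closed-form function of temperature `T`:

- **Development** (egg, nymph, puparium): median development rate follows a
  Janisch curve, `r(T) = 1 / (D_min · cosh(k (T − T_opt)))`, peaking at
  `1/D_min` at the stage optimum.
- **Immature mortality**:
  `m(T) = 1 − exp(−H (1 + e^{−(T−T_opt)/B}) (1 + e^{−(T_opt−T)/B}))`, with a
  shared optimum near 21.8 °C and stage-specific magnitude `H` and spread `B`.
- **Adult timing**: median oviposition time `t(T) = 1/(a e^{bT})`; female and
  male survival are the same curve shifted by additive log-time factors
  (males ≈ 25–30 % shorter-lived).
- **Fecundity**: asymmetric unimodal curve on the log scale,
  `ln F(T) = H / ((1 + e^{−(T−Tl)/Bl})(1 + e^{−(Tl−T)/Bh}))`, peaking near
  20 °C at ≈ 40 eggs/female.

Individual variability enters through median-normalized distribution links
(log-logistic, Weibull, lognormal; CDF fixed at 0.5 for normalized age 1)
estimated from daily, interval-censored cohort observations by accelerated
failure time (AFT) models. A stochastic individual-based simulator
accumulates physiological age by rate summation over the temperature series
(capturing the Kaufmann effect under fluctuation), applies per-step
survival `(1 − m(T))^Δx`, and allocates each female's drawn lifetime
fecundity over her oviposition window. Cohort schedules `l_x`, `m_x` yield
the life-table parameters `R0`, `GRR`, `T`, `r_m` (Euler–Lotka or the
approximate method), `λ = e^{r_m}` and doubling time `Dt = ln 2 / r_m`, and
`z_compare()` implements the z-score validation against observed life
tables. An empirically calibrated "adjusted" variant (mortality spread
× 1.3, adult times × 2, fecundity × 4) reproduces the much higher vitality
observed under naturally fluctuating field temperatures.

## Worked example

```r
library(phenofly)
b <- default_bundle()
b
#> Model bundle: Trialeurodes vaporariorum
#>   egg       D_min 4.98 d, T_opt 27.4 C, k 0.15; loglogistic link delta 0.044
#>   nymph     D_min 9.94 d, T_opt 25.4 C, k 0.11; loglogistic link delta 0.072
#>   puparium  D_min 3.46 d, T_opt 23.0 C, k 0.24; weibull link delta 0.298
#>   mortality optimum 21.8 C; fecundity peak near 20 C

1 / janisch_rate(b$development$egg, 15)   # median egg duration at 15 °C
#> [1] 16.38273

sims <- simulate_replicates(b, temp_series_constant(24, days = 250),
                            n = 100, reps = 4, seed = 1, adjusted = TRUE,
                            method = "approximate")
round(sims$params, 3)
#>       R0    GRR      T   r_m lambda    Dt
#> 1 40.646 58.956 25.144 0.147  1.159 4.704
#> 2 37.756 56.154 24.278 0.150  1.161 4.634
#> 3 34.935 49.607 24.627 0.144  1.155 4.804
#> 4 32.203 50.594 23.770 0.146  1.157 4.745
sims$pooled_params
#> Life-table parameters (approximate method)
#>   R0 = 36.611 females/female, GRR = 54.179, T = 24.50 d
#>   r_m = 0.1469 /d, lambda = 1.1583 /d, doubling time = 4.72 d
```

Four replicate cohorts of 100 eggs at a constant 24 °C — the species'
growth optimum — under the adjusted model: each initial female is replaced
by ≈ 37 daughters (`R0`) over a generation of ≈ 24.5 days, so the
population multiplies by λ ≈ 1.16 per day and doubles roughly every 4.7
days. The same machinery accepts `temp_series_sine(24, 5, days = 250)` for
a ±5 °C daily cycle or `read_temperature_series("hobo.csv")` for a field
record, and `z_table()` compares observed life-table parameters against the
replicate spread.

A thin command-line wrapper with `synth`, `fit-dev`, `fit-mortality`,
`fit-fecundity`, `fit-adult`, `simulate`, `life-table` and `validate`
subcommands ships in `inst/cli/phenofly.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "phenofly.R", package = "phenofly"))')" \
    simulate --constant 24 --n 100 --reps 4 --seed 42 --adjusted --out schedule.csv
```

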