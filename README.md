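# ttishelf

Predictive-microbiology toolkit for chilled, modified-atmosphere-packed
foods: microbial shelf-life modelling and the selection of enzymatic
Time–Temperature Integrator (TTI) smart labels that track it through the
cold chain.

It is aimed at food microbiologists and packaging researchers who have
isothermal storage-trial data (microbial counts over time at a few
temperatures) and want to (a) predict shelf-life at any chill temperature,
(b) pick a TTI label whose colour change expires when the product does, and
(c) validate those predictions under realistic, time-varying temperature
profiles.

## The models

**Primary growth.** Log10 counts follow the Baranyi–Roberts model: with
maximum rate μ (log10 CFU/g per day), lag λ (d), initial and maximum levels
y0 and ymax (log10 CFU/g), and h0 = μ̃λ in natural-log units,

    A(t) = t + (1/μ̃) ln(e^(−μ̃t) + e^(−h0) − e^(−μ̃t−h0))
    ỹ(t) = ỹ0 + μ̃ A(t) − ln(1 + (e^(μ̃A(t)) − 1) / e^(ỹmax−ỹ0))

**Secondary model.** Rates follow the Arrhenius equation,
`ln k = ln kref − (Ea/R)(1/T − 1/Tref)` with Tref = 4 °C; the activation
energy Ea (kJ/mol) measures temperature sensitivity. Time-like quantities
(lags, TTI response constants) carry the opposite sign.

**Shelf-life.** Time for the total viable count to climb from logN0 to the
acceptability limit logN1 (default 7 log10 CFU/g):
`t_SL(T) = (logN1 − logN0)/k(T) + λ(T)`.

**TTI kinetics.** The normalised colour response norm(a+b) of an enzymatic
label rises as a logistic `1/(1 + exp((k1 − t)/k2))` with visual endpoint
0.8; a global model `k_i = k_iref(C=1U) · C^(−e_i) · exp(+(Ea/R)(1/T −
1/Tref))` ties the constants to enzyme concentration and temperature.

**Matching and validation.** A label is admissible when its Ea lies within
±20 kJ/mol of the product's deterioration Ea; admissible labels are ranked
by the worst relative deviation between response-time and shelf-life curves
over 0–10 °C. Dynamic profiles are summarised by their effective temperature
(the constant temperature with the same mean Arrhenius factor), growth under
a profile is predicted by integrating the differential Baranyi system, and
predictions are judged by `RE% = |(k_exp − k_pred)/k_exp| · 100` against a
20% limit.

Reference kinetic tables for gilthead seabream fillets under MAP / MAP-PAD
(a CO2-emitting pad) and for M-/LP-type enzymatic labels are bundled as
tibbles (`seabream_growth_params()`, `tti_response_constants()`, …), so
every stage can be run and checked without external data. Seeded generators
(`gen_growth_curve()`, `gen_tti_series()`, `gen_temperature_profile()`)
produce synthetic studies with the same structure.

## Worked example

```r
library(ttishelf)
library(dplyr)

# temperature dependence of the measured TVC growth rates (MAP-PAD)
rates <- seabream_growth_params() |>
  filter(organism == "TVC", packaging == "MAP_PAD")
fit_arrhenius(rates, value = rate)
#> Arrhenius model (rate-like): kref = 0.413 at 4 degC, Ea = 103.6 kJ/mol, R^2 = 0.990

# shelf-life of the MAP-PAD product across the chill range
spec <- seabream_shelf_life_spec("MAP_PAD")
shelf_life_curve(spec, c(0, 2.5, 5, 10))
#> # A tibble: 4 × 2
#>   temperature_C shelf_life_d
#>           <dbl>        <dbl>
#> 1           0          16.9
#> 2           2.5        10.8
#> 3           5           6.91
#> 4          10           2.91

# rank M-type label concentrations against that shelf-life behaviour
cand <- tibble(model = rep(reference_tti_models()["M"], 8),
               conc = c(5, 10, 15, 20, 25, 50, 75, 100))
select_tti(spec, cand) |>
  select(rank, label, max_abs_relative_deviation, conservative_at_abuse)
#> # A tibble: 8 × 4
#>    rank label max_abs_relative_deviation conservative_at_abuse
#>   <int> <chr>                      <dbl> <lgl>
#> 1     1 M-50U                      0.380 TRUE
#> 2     2 M-25U                      0.445 FALSE
#> 3     3 M-75U                      0.563 TRUE
#> # … 5 more rows

# validation metric for a non-isothermal trial
round(relative_error(k_experimental = 0.348, k_predicted = 0.398))
#> [1] 14
```

The Arrhenius refit recovers an activation energy of ≈104 kJ/mol from the
four printed rates (the published table reports 113.1 kJ/mol from the
underlying replicate fits). The shelf-life curve tracks the observed
crossing days (17/13/8/3 at 0/2.5/5/10 °C) within ±3 days, and the M-25U
label — the one actually deployed on MAP-PAD fillets — ranks in the top two
concentrations. The final line reproduces the reported 14% validation error
for the total viable count.

Each fitted object supports `tidy()`, `glance()` and `autoplot()`;
`run_pipeline()` chains all stages (growth fits → Arrhenius → shelf-life →
TTI fits → matching → dynamic validation) from tabular inputs and
`write_report()` serialises the result to JSON.

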