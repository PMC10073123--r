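# dualcarbon

Source apportionment of the carbonaceous fraction of PM2.5 from paired
stable-carbon and radiocarbon measurements.

## The problem

Total carbon (TC) in fine particulate matter comes from a mixture of
fossil-fuel combustion, C3-plant material (most trees; biogenic
aerosol or C3 biomass burning), and C4-plant material (e.g. burned
maize residues). The two isotope ratios separate these cleanly:

- **Δ¹⁴C** splits fossil from contemporary carbon. Fossil carbon is
  radiocarbon-dead (−1000‰); carbon fixed from today's atmosphere sits
  near +30‰.
- **δ¹³C** splits C3 from C4 photosynthesis (endmembers here:
  −26.7 ± 1.8‰ vs −16.4 ± 1.4‰; fossil fuel −29.0 ± 1.3‰).

For a sample with observed (δ¹³C, Δ¹⁴C), the conservative mixing model is

    δ¹³C_obs = Σ_k f_k δ¹³C_k ,   Δ¹⁴C_obs = Σ_k f_k Δ¹⁴C_k ,   Σ_k f_k = 1

with `k ∈ {fossil, C3, C4}` — exactly determined for three sources.
The package provides four complementary estimators of the fraction
triple `f`:

1. `solve_exact()` — the closed-form linear solution (with an explicit
   feasibility flag when the algebraic solution leaves the simplex);
2. `enumerate_mixtures()` — IsoSource-style exhaustive enumeration of
   simplex lattice points reproducing δ¹³C within a tolerance (default
   0.1‰), with the radiocarbon-derived fossil fraction applied as a band
   constraint;
3. `fit_mixture()` / `pool_and_fit()` — a Bayesian mixing model
   (Dirichlet prior moment-matched to the enumeration, Gaussian
   likelihood with endmember and residual variance, adaptive
   random-walk Metropolis MCMC on log-ratio coordinates, split-R̂/ESS
   diagnostics) for per-sample, site-season, or site-annual pooling;
4. `table2_report()` / `share_of_pm25()` — conversion of fractions to
   per-source carbon concentrations and shares of total PM2.5 mass.

Supporting tools: seasonal levoglucosan (biomass-burning tracer)
summaries, one-way ANOVA with Tukey HSD letter displays, OLS
regression (`seasonal_levoglucosan()`, `oneway_anova()`, `tukey_hsd()`,
`ols_regression()`), and a synthetic-data generator with known truth for
parameter-recovery studies (`simulate_dataset()`, `recovery_report()`).

The package ships a 48-sample field dataset (2019–2020) from a rural
pine forest (TRF), an urban campus (SNU), an urban forest (HUF), and an
urban traffic island (CRI) in South Korea: `load_table1()`.

## Worked example

```r
library(dualcarbon)

samples <- load_table1()

# exact mass balance at the forest-site mean isotope values
solve_exact(-25.7, -380.7)
#>    f_fossil      f_C3      f_C4 feasible
#> 1 0.3987379 0.4151362 0.1861259     TRUE

# feasible-mixture enumeration for the same observation
enumerate_mixtures(list(d13c = -25.7, D14c = -380.7))
#> Feasible set: 78 mixtures (increment 0.005, tol_d13c 0.1 permil, fossil band 0.3987 +/- 0.05)
#>  source      mean          sd  min   max
#>  fossil 0.3978846 0.028813318 0.35 0.445
#>      C3 0.4160256 0.035914391 0.35 0.480
#>      C4 0.1860897 0.008740391 0.17 0.205

# site-annual Bayesian apportionment (forest vs urban)
pool_and_fit(samples[samples$site %in% c("TRF", "SNU"), ],
             grouping = "site_annual", cfg = mcmc_config(seed = 42))
#> Pooled mixing fits (site_annual): 2 group(s)
#>  group source  mean    sd  q2.5 q97.5  rhat      ess n_obs
#>    TRF fossil 0.400 0.016 0.367 0.432 1.000 3676.845    21
#>    TRF     C3 0.419 0.021 0.377 0.461 1.001 3230.367    21
#>    TRF     C4 0.182 0.015 0.153 0.212 1.000 4504.377    21
#>    SNU fossil 0.439 0.018 0.404 0.473 1.002 3597.756    18
#>    SNU     C3 0.311 0.022 0.268 0.356 1.003 3134.610    18
#>    SNU     C4 0.250 0.017 0.217 0.285 1.001 4537.174    18
```

Reading the fit: at the urban site roughly 44% of PM2.5 carbon is
fossil (posterior mean, 95% CI 40–47%), with the remainder split
between C3 (31%) and C4 (25%) plants; the forest site carries a similar
fossil share on half the TC concentration, so most forest-interior
PM2.5 carbon is transported, not locally emitted. `rhat` near 1 and
large `ess` indicate converged chains. If ~30% of PM2.5 mass is carbon,
the fossil-carbon share of total PM2.5 is
`share_of_pm25(0.3, 0.44) ≈ 0.13`.

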