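---
title: "Dual-isotope source apportionment of PM2.5 carbon: models and methods"
author: "dualcarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-isotope source apportionment of PM2.5 carbon: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualcarbon)
```

## The mixing model and its assumptions

Total carbon (TC) in a PM2.5 filter sample is treated as a conservative
mixture of three sources — fossil fuel, C3 plants, C4 plants — each with
an assumed isotopic signature (an *endmember*, mean ± SD per isotope).
Conservative mixing means the observed isotope value is the
fraction-weighted average of the source values, with no fractionation
between emission and collection; this is the standard assumption for
carbonaceous aerosol, where no trophic or chemical discrimination step
intervenes. With two isotopes and the closure constraint the system is
exactly determined for three sources.

Default endmembers (permil): δ¹³C −29.0 ± 1.3 (fossil), −26.7 ± 1.8
(C3), −16.4 ± 1.4 (C4); Δ¹⁴C −1000 (fossil, radiocarbon-dead) and +30
(both plant sources, contemporary tropospheric CO₂). The plant Δ¹⁴C
values are reference constants rather than measured distributions, so
they carry a small default SD of 5‰ (configurable through
`default_endmembers()` or `endmember_set()`); sensitivity to this choice
is negligible because the fossil–biogenic Δ¹⁴C span is ~1030‰.

Because the two plant endmembers share one Δ¹⁴C value, the radiocarbon
balance alone fixes the fossil fraction,
`f_fossil = (Δ¹⁴C_bio − Δ¹⁴C_obs) / (Δ¹⁴C_bio − Δ¹⁴C_fossil)`
(`fossil_fraction_14c()`), and δ¹³C then splits the non-fossil remainder
between C3 and C4. `solve_exact()` performs the full 3×3 linear solve;
the two views agree to machine precision under the default endmembers,
which the test suite asserts.

**Out-of-simplex solutions are flagged, never clipped.** A sample whose
Δ¹⁴C exceeds the contemporary endmember yields a negative algebraic
fossil fraction; the solver returns it unclipped with
`feasible = FALSE`. This is deliberate: the out-of-range value is the
diagnostic that identifies physically impossible observations (the
packaged dataset contains one such sample, +589.7‰, flagged
`excluded = TRUE` and dropped from all default summaries and fits).
Downstream consumers decide: attribution refuses infeasible triples
unless forced, the enumerator accepts an explicitly clipped band centre,
and the Bayesian model absorbs mild infeasibility through its noise
terms.

## Feasible-mixture enumeration

`enumerate_mixtures()` scans the simplex lattice at a configurable
increment and retains triples satisfying two constraints:

- `|Σ f_k δ¹³C_k − δ¹³C_obs| ≤ tol_d13c`, default 0.1‰ — the classical
  mass-balance tolerance of exhaustive-enumeration mixing tools;
- `|f_fossil − f14C| ≤ fossil_band_halfwidth`, default ±0.05, where
  `f14C` is the radiocarbon-derived fossil fraction.

A single permil-scale tolerance cannot be applied to Δ¹⁴C: the
endmember span of ~1030‰ means a 0.1‰ Δ¹⁴C window contains no lattice
point at any workable increment. The radiocarbon measurement therefore
enters as the band on the fossil fraction — its natural, linearly
propagated form. `fossil_band_from_sd()` derives the half-width from a
Δ¹⁴C measurement SD; the default ±0.05 corresponds to ~±26‰ of
measurement error at 2 coverage.

The grid increment defaults to 0.005 (0.5%), between the conventional
1% of enumeration tools and the fine grids needed for convergence
studies; `increment` is capped at 0.05 so summaries are never computed
over a handful of points. Iteration uses integer step counts with
`f_C4 = 1 − f_fossil − f_C3`, so closure is exact, no floating-point
drift accumulates, and the point order (fossil outer, C3 inner) is
deterministic. A `pin_fossil` mode fixes the fossil coordinate exactly
at the (generally off-grid) radiocarbon value and enumerates only the
C3 axis: this is the zero-width-band limit used to verify that the
enumeration mean converges to `solve_exact()` as the increment shrinks.
Empty feasible sets raise an error that reports both constraints and
suggests remediation — a silent empty summary would poison the prior
stage.

## The Bayesian model

For observations `i` (sharing one fraction triple `p`) and isotope `j`:

    x_ij ~ Normal( Σ_k p_k μ_jk ,  sqrt( Σ_k p_k² σ_jk² + σ_j² ) )
    p ~ Dirichlet(α),   σ_j ~ half-Normal(scale_j)

The `Σ p_k² σ_jk²` term propagates endmember uncertainty (a mixture of
independent endmember draws); `σ_j` is a per-isotope residual SD
capturing measurement error and real within-group heterogeneity.
Residual prior scales default to 1‰ for δ¹³C and 100‰ for Δ¹⁴C — weakly
informative at each isotope's natural scale. There is no concentration
dependence, isotope covariance, or discrimination offset.

**Prior from enumeration.** `build_prior()` moment-matches the
feasible-set summary to a Dirichlet: `α_k = m_k ν` with `ν` chosen so
the average implied variance `m_k(1−m_k)/(ν+1)` equals the average
feasible-set variance, each `α_k` floored at 0.5 so no source is ruled
out a priori, and `ν` capped at 1e5 against degenerate (near-zero
variance) summaries. A Dirichlet was chosen over the logistic-normal
family used by some mixing packages because the enumeration supplies
only means and variances; moment matching is transparent and directly
testable against the Dirichlet mean/variance formulas. For pooled fits
(`pool_and_fit()`), the per-sample feasible-set means and variances are
averaged within the group before matching; the between-sample spread is
deliberately left to the likelihood, which sees every observation.
Samples whose radiocarbon fraction falls outside [0, 1] contribute with
a clipped band centre; if no sample in a group can be enumerated the
fit falls back to a uniform Dirichlet(1,1,1) with a warning.

**Sampler.** Adaptive random-walk Metropolis on four unconstrained
coordinates: `logit(f_fossil)`, `logit(f_C3 / (f_C3 + f_C4))`, and the
two log residual SDs. This stick-breaking parameterization aligns the
coordinates with the two physical constraints — the radiocarbon balance
pins the first, the δ¹³C balance the second — so the posterior is
nearly axis-aligned even when the fossil direction is an order of
magnitude tighter than the C3/C4 direction (typical for pooled fits,
where an early shared-scale blocked sampler mixed at effective sample
sizes below ten; the component-wise design restores ESS in the
hundreds-to-thousands). The Jacobian determinant is `p₁p₂p₃`, identical
to the additive log-ratio transform, so the Dirichlet prior contributes
`Σ α_k log p_k` and every draw lies on the simplex by construction.
Each coordinate carries its own proposal scale, adapted in batches of
50 during burn-in toward ~35% acceptance (Robbins–Monro step `1/√batch`)
and frozen afterwards so the post-burn-in chain is a valid Markov
chain. Chains initialize at the prior centre with overdispersed jitter.
Defaults: 4 chains × 10 000 iterations, 5 000 burn-in, no thinning,
seed 42; everything is driven by a single integer seed and is
bit-reproducible. Convergence is reported (split-R̂ and ESS per
parameter, Geyer initial-positive-pair truncation for the
autocorrelation sum); a fit with any R̂ > 1.05 warns and carries
`converged = FALSE` rather than erroring, so long pooled runs are never
discarded silently. Intervals are 95% equal-tailed credible intervals,
with no multiplicity adjustment.

A gradient-based sampler would be overkill here: the posterior is
4-dimensional, unimodal, and cheap to evaluate, and the random-walk
design keeps the package dependency-free and exactly seeded.

## Attribution conventions

Per-source concentrations are `TC × f_k`, computed per sample and then
averaged within groups — the mean of products, not the product of
means, since TC and fractions co-vary across samples. Percentages are
group-mean fractions × 100 (the "mean relative contribution"
convention). Both conventions are documented because summary tables in
the literature rarely state which they use; with either convention the
three per-source group means sum to the group-mean TC, which the tests
assert. `share_of_pm25()` composes the carbonaceous share of PM2.5 mass
with a source's share of that carbon.

## What the synthetic-data generator emulates — and what it does not

`simulate_dataset()` draws, per sample: a true fraction triple from a
Dirichlet (default α = (5.9, 3.7, 2.4), i.e. mean ≈ (0.49, 0.31, 0.20)
with realistic across-sample spread — roughly half the carbon fossil,
as in the packaged field data); realized endmember values from their
Gaussians; observed isotopes as the true mixture plus measurement noise
(default SDs 0.2‰ for δ¹³C, 10‰ for Δ¹⁴C, AMS-scale); log-normal TC
(median 6 μg C m⁻³, log-SD 0.45); and levoglucosan linear in the true
C4 *fraction* (intercept 5 ng m⁻³, slope 150 ng m⁻³ per unit f_C4,
noise SD 15, truncated at zero, ~30% masked missing — matching the
assay-missingness of the field table). Because the observation is a
mixture of independently drawn endmembers plus noise, its variance is
exactly the Bayesian likelihood's `Σ p² σ² + σ_meas²`: simulations are
well-specified by construction, which is what makes the
parameter-recovery and interval-calibration tests meaningful.

Choices a user should know: levoglucosan couples to the C4 fraction
(mirroring how tracer–fraction relationships are usually plotted)
rather than to the C4 *concentration*; truncation at zero (not
resampling) introduces a small positive bias at default noise levels,
accepted and documented; dates are deterministic within season cells so
datasets are byte-identical under a fixed seed.

What it does **not** emulate: atmospheric transport, seasonal
covariance between sources and TC, autocorrelation in time, shared
endmember realizations across co-located samples, or measurement-error
heteroscedasticity. Passing recovery tests therefore demonstrate that
the estimator is correct *under its own assumptions* — they do not
validate the endmember values or the conservative-mixing assumption for
any particular airshed.

## Numerical choices and degenerate inputs

- Feasibility tolerance 1e−9 on simplex membership; closure enforced
  structurally everywhere (solver, enumerator, sampler), never by
  normalizing sums.
- The exact solver refuses collinear endmember configurations (singular
  2×2 reduced system, relative determinant < 1e−9) with an error naming
  the degeneracy; the radiocarbon balance refuses equal fossil/biogenic
  Δ¹⁴C means and refuses to run when the two plant Δ¹⁴C means differ
  (use the full solver instead).
- An SD over a single value is reported as 0 with `n = 1`, not as `NA`
  or an error, so single-sample groups stay in summary tables.
- One-way ANOVA with zero within-group variance and unequal means
  reports `F = Inf`, `p = 0` (detected at relative 1e−10 to absorb
  floating-point sums); all-identical data error out.
- OLS on constant `y` reports `R² = 0`, slope 0; constant `x` errors.
- Grid membership tests in the enumerator use a 1e−9 epsilon so
  tolerance boundaries are inclusive regardless of rounding direction.
- Tukey HSD uses the Tukey–Kramer statistic with `ptukey()` for exact
  studentized-range tail probabilities (no Monte-Carlo fallback is
  needed since the distribution function is available); the compact
  letter display uses insert-and-absorb over the significance matrix,
  lettered in descending-mean order.

## Problem sizes used by the test suite

Unit tests run fits at 2 chains × 2 000–4 000 iterations; the
convergence and calibration checks use a 0.001 enumeration grid over
the 47 retained field samples, and 100 replicate synthetic datasets of
n = 50 observations fitted at 2 × 2 500 iterations. These sizes were
chosen so the full suite exercises every stage — enumeration, prior
construction, pooled MCMC, recovery, coverage — at Monte-Carlo error
well below the assertion tolerances while remaining quick on a single
CPU.

## Known limitations

- Exactly three sources; no marine-aerosol or secondary-organic
  endmember, and no model-selection machinery to choose among endmember
  sets. The C4 endmember doubles for any source with enriched δ¹³C and
  contemporary Δ¹⁴C, so its interpretation (biomass burning vs other
  C4-derived carbon) rests on the levoglucosan diagnostics, not on the
  isotopes alone.
- The pooled model assumes one fraction triple per group; real groups
  mix samples with different true fractions, so pooled residual SDs
  absorb between-sample variability and pooled posterior means estimate
  a variance-weighted group-typical composition rather than the mean of
  per-sample fractions.
- Endmember means are treated as known constants with stated SDs; no
  hierarchical endmember estimation.
- The enumeration prior and the likelihood use the same observations,
  so the prior is mildly double-informed by the data; with the default
  band and tolerance the prior is broad enough that the likelihood
  dominates, but users pooling many samples with a very narrow band
  should be aware of it.
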