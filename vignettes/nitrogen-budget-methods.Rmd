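---
title: "Methods: plant-soil-atmosphere nitrogen budgets for ridge-furrow forage trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant-soil-atmosphere nitrogen budgets for ridge-furrow forage trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbudget)
library(dplyr)
```

`nbudget` assembles apparent nitrogen budgets for multi-year factorial field
trials of mulched ridge-furrow forage systems — the kind of trial that crosses
planting pattern (flat planting, FP; ridges with biodegradable mulch, JM;
ridges with conventional plastic mulch, PM) with a nitrogen-rate ladder
(0/80/160/240 kg N ha⁻¹, labelled C0–C3) over replicated plots and several
growing seasons. This vignette documents the measurement models, the tunable
parameters, the numerical conventions, and what the synthetic trial generator
does and does not emulate.

## The measurement models

### Soil inorganic nitrogen stocks

A layer's nitrate-N or ammonium-N stock converts a concentration on dry soil
to a mass per land area:

$$NR_i \;=\; \frac{\gamma_i \, h_i \, N_i}{10} \qquad [\mathrm{kg\,ha^{-1}}]$$

with bulk density $\gamma_i$ (g cm⁻³), thickness $h_i$ (cm) and concentration
$N_i$ (mg kg⁻¹). The divisor 10 is the exact unit conversion
(g cm⁻³ × cm × mg kg⁻¹ → kg ha⁻¹); no empirical constant is involved. Profile
stocks sum contiguous layers, by default three 20 cm layers covering 0–60 cm;
`soil_stocks()` rejects gapped or overlapping profiles rather than guessing.
Bulk density may vary by layer, but a single site value (1.45 g cm⁻³ for the
sandy loam these defaults describe) is typical. Sampling position on ridged
plots (furrow centre) is a field-protocol matter; the stock arithmetic is
position-free.

### Static-chamber N₂O flux

A closed chamber of height $H$ accumulates N₂O; the ordinary least-squares
slope $dc/dt$ (µL L⁻¹ min⁻¹) of headspace concentration against elapsed
minutes gives

$$F \;=\; \rho \, H \, \frac{dc}{dt} \, \frac{273}{273+T} \times 60,
\qquad \rho = \frac{2 \times 14}{22.4} = 1.25\ \mathrm{kg\,m^{-3}}$$

The density constant uses 28 g of nitrogen per mole of N₂O, so fluxes are on
an N₂O-N mass basis throughout. The product of the printed formula is
mg m⁻² h⁻¹; the package converts once to its canonical internal unit,
µg m⁻² h⁻¹, which is the unit the seasonal integration constant expects. That
single convention keeps every downstream constant dimensionally exact, and
with typical field fluxes of tens of µg m⁻² h⁻¹ it yields seasonal totals on
the 1–3 kg ha⁻¹ scale such trials report — the consistency check that fixed
the convention.

Slope quality is reported, not enforced: deployments with at least three
points and $r^2 < 0.90$ are flagged (`chamber_fluxes(..., r2_flag = )`) but
kept, since discarding chambers silently biases seasonal totals. Negative
slopes produce negative fluxes (chamber uptake) and are retained. With two
points $r^2$ is 1 by construction; a constant series gives slope 0 with $r^2$
undefined.

Ridge-furrow plots are sampled at both microsites; the plot-level flux is the
area-weighted mean $w\,F_{ridge} + (1-w)\,F_{furrow}$. Ridge geometry is
rarely dimensioned precisely, so $w$ defaults to 0.5 and is configurable
everywhere it is used.

### Seasonal totals

Dated plot-level fluxes integrate by the trapezoidal rule,

$$f \;=\; \sum_i \frac{F_{i+1}+F_i}{2} \, t_i \times 24 \times 10^{-5}
\qquad [\mathrm{kg\,ha^{-1}}]$$

with $t_i$ the interval in whole days. Nothing is extrapolated outside the
first and last campaign; the estimate is exactly additive over contiguous
date ranges and invariant to refining a piecewise-linear series. For a smooth
seasonal curve sampled at a 15-day cadence the trapezoid tracks dense
numerical integration to well under 1 % (verified in the test suite against a
quarter-day grid).

### Plant nitrogen and the ledger

Organ nitrogen accumulation is content times dry matter,
$A = (N\%/100) \times DM$, summed over leaves and stems and then over the
season's cuts; hay yield is the dry-matter sum (reported in t ha⁻¹,
accumulated N in kg ha⁻¹). Percentages are stored as percent (3.0 means 3 %),
converted only inside the arithmetic.

The apparent balance per treatment-year is

$$N_{balance} = \underbrace{(N_{rate} + N_{soil,pre})}_{N_{input}}
 - \underbrace{(N_{soil,post} + N_{plant} + N_{2}O_{season})}_{N_{output}},
 \qquad ANLR = \frac{N_{balance}}{N_{rate}} \times 100$$

ANLR (apparent nitrogen loss rate, %) is undefined at zero fertilizer and is
rendered as an em dash in report tables. Components enter the ledger as
replicate means (budget tables are conventionally reported per
treatment-year), each year uses its own measured pre-season reserve — no
carryover chaining — and the identities hold exactly; rounding
(half-away-from-zero, two decimals) happens only in `budget_table()`.
Balances below −20 kg ha⁻¹ classify as deficit, above +20 as surplus, the
band being configurable: ±20 kg ha⁻¹ is roughly the magnitude below which a
seasonal balance is indistinguishable from measurement uncertainty in such
budgets, and it reproduces the qualitative deficit/equilibrium/surplus
labelling of the C0–C1/C2/C3 levels that motivated the feature.

The budget is *apparent*: biological N fixation (substantial in legume
systems), leaching and NH₃ volatilization are deliberately outside the
ledger, which can make unfertilized treatments look more deficient than they
are. The package documents this rather than modelling it.

### Treatment statistics

`anova_factorial()` fits the crossed fixed-effects model (rate × pattern ×
year, or any subset, with interactions capped by `max_order`). Balanced
designs use the exact orthogonal decomposition; unbalanced data fall back to
Type II sums of squares with a warning — the trials this package targets are
balanced, so that path is secondary. Terms with numerically zero sums of
squares report $F = 0, p = 1$ rather than 0/0. Significance tags follow the
field convention (`**` p < 0.01, `*` p < 0.05, `ns`). Shapiro–Wilk (on
residuals) and Levene (centred on cell means, the classical form) prechecks
are advisory only. The LSD display is protected — computed only when the
omnibus F is significant — with
$LSD = t_{1-\alpha/2,\,df}\sqrt{2\,MSE/n}$; because one common threshold
governs all pairs, the "shares a letter" relation is an indifference graph
and the contiguous-run lettering over descending means represents it exactly
(a property the tests verify against exhaustive pairwise comparison).

## The synthetic trial generator

`synthetic_design()` fixes the study conditions: 2 years × 3 patterns × 4
rates × 3 replicates; three cuts (early June, mid July, late August); chamber
campaigns every 15 days from mid-April to mid-October; three 20 cm soil
layers sampled pre-season and after the third cut. Its structural defaults
encode the qualitative findings such trials report:

* pattern multipliers PM 1.15 > JM 1.08 > FP 1.00, applied to plant N, soil
  nitrate and N₂O flux (ammonium carries no pattern effect — it is the
  immobile, colloid-bound pool);
* plant dose–response quadratic with its peak at 160 kg ha⁻¹ plus a small
  positive linear tilt (2 × 10⁻⁴ per kg), so the level ranking is
  C2 > C3 > C1 > C0 rather than a symmetric C1 = C3 tie;
* flux season = 12 µg m⁻² h⁻¹ baseline plus a Gaussian peak (centre day 200,
  sd 25 d) of amplitude 48 + 0.25 × rate, chosen once so seasonal totals
  land inside the 1.2–3.0 kg ha⁻¹ band observed in the field;
* concentrations decaying exponentially with depth (0.015 cm⁻¹) and rising
  with rate; second-year multipliers of 1.55 for soil reserves, 1.2 for
  fluxes and 1.12 for plant N, mirroring the reported wetter-year retention;
* tissue N of 1.6–3.6 % declining over cuts (the dilution effect) with a
  0.55 leaf share of plant N, which makes ~6 t ha⁻¹ hay carry ~150 kg N
  ha⁻¹ — an internally consistent combination typical of alfalfa, chosen in
  preference to forcing any single published yield figure.

Noise is multiplicative lognormal with unit mean (CV 0.08 by default) for all
strictly positive measurements, and additive Gaussian for chamber temperature
with sd 10 × CV °C, so `cv = 0` reproduces the stored truth exactly — every
observation has a truth value, and `recover_effects()` closes the loop:
pattern ordering and peak rate recovered from replicate means, seasonal
emission totals compared against dense integration of the truth curve.
Chamber series are generated by inverting the flux formula (linear rise over
30 min at 0/10/20/30 min from an ambient 0.33 µL L⁻¹), so flux recovery is
well-posed by construction.

What the generator does **not** emulate: within-season soil N dynamics
(mineralization, nitrification, leaching pulses), weather beyond the fixed
seasonal curves, spatial autocorrelation among plots, cut-to-cut carryover,
or realistic within-treatment variance structure (the CV is conventional, not
fitted). Passing recovery tests therefore demonstrates that the measurement
pipeline is arithmetically faithful, not that it is robust to every
real-world pathology.

## Numerical conventions and edge cases

* Internal computation never rounds; `round_report()` rounds half away from
  zero at report time (matching how printed budget tables round), with a
  2⁻⁵³-scale guard so decimal halves just below their binary representation
  still round away from zero.
* CSV tables are written with 17 significant digits and parsed with base R's
  correctly rounded reader, so `read_table(write_table(x))` is
  bit-for-bit exact.
* Dates are ISO; integration intervals are whole-day differences.
* Degenerate inputs fail loudly with classed conditions: fewer than two
  chamber points, all-equal sampling minutes, duplicate flux dates or cut
  indices, gapped soil profiles, negative components, unknown positions.
* Seeds govern every stochastic path (`synthetic_design(seed = )`,
  simulation-based tests); identical configurations write identical files.

## Problem sizes

The test-suite simulations use the full default factorial (72 plot-years, 13
campaign dates, ~2,500 chamber samples per trial), 1,000 randomized soil
profiles for the arithmetic property checks, 200 seeded replicates for the
Levene power check, and 50 randomized mean sets for the letter-display
oracle — sizes at which every oracle comparison is exact or tightly bounded
while the whole suite runs in about a minute.

## A worked ledger

```{r}
components <- trial_budget_components() |>
  select(-published_balance, -published_anlr)
budget <- nitrogen_budget(components)
budget_table(budget) |>
  filter(label %in% c("FPC0", "PMC2"))
glance(budget)
```

The near-equilibrium row (PMC2: balances 9.73 and 1.84 kg ha⁻¹, loss rates
6.08 % and 1.15 %) against the deficit of the unfertilized flat planting and
the heavy surplus of every C3 treatment is the pattern the budget method is
designed to expose: a moderate rate under conventional plastic mulch closes
the ledger; zero fertilizer mines the soil pool; the highest rate leaves
nitrogen in the system to be lost.
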