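---
title: "Modelling the isolated impact of community case management on child mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the isolated impact of community case management on child mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(listlite)
library(dplyr)
```

## The problem

Integrated community case management (iCCM) delivers curative child-health
interventions — antibiotics for pneumonia, ORS + zinc for diarrhea,
antimalarials — through community health workers rather than facilities.
Evaluating such a program from survey data is confounded: facility coverage
may be falling (stockouts, strikes), other programs (e.g. bednet campaigns)
may be scaling up simultaneously, and the population is growing. Neither a
rise nor a fall in *total* coverage of an intervention, on its own, says
what the community program achieved.

`listlite` implements the Lives Saved Tool (LiST) style of deterministic,
linear multi-cause mortality modelling for exactly this question: given
coverage trajectories disaggregated by *delivery channel* (community /
facility / other), it projects cause-specific under-five deaths, attributes
lives saved to individual interventions without double counting, and
isolates the community program's impact by a counterfactual comparison.

## The model

### Residual cascade

Each cause of death $k$ has a baseline death count $D_k$. Each intervention
$i$ has a cause-specific effectiveness $e_{i,k} \in [0,1]$ — the
proportional mortality reduction at 100% coverage — and a total coverage
$c_{i,t}$ (the sum over delivery channels) in year $t$. A single
intervention scaled from zero coverage to $c$ leaves

$$D_k \,(1 - e_{i,k}\, c)$$

deaths. Further interventions act only on the *residual* un-prevented
deaths, which prevents double counting: with the interventions applied in
sequence,

$$D_{k,t} \;=\; D_k \cdot \prod_i \frac{1 - e_{i,k}\, c_{i,t}}
{1 - e_{i,k}\, c_{i,\mathrm{base}}} \cdot \frac{b_t}{b_\mathrm{base}},$$

where $b_t$ are annual live births. The ratio form is our generalisation to
nonzero baseline coverage: it reduces exactly to $D_k(1 - e c)$ when
baseline coverage is zero, and leaves deaths unchanged when coverage does
not change (the no-change fixed point). The product commutes, so the
engine's result is independent of intervention order; the ordered step
ledger is still produced because attribution consumes it.

The degenerate case $e_{i,k}\, c_{i,\mathrm{base}} = 1$ (the baseline
already eliminates the cause) is reported as a configuration error rather
than producing an infinity.

Structural assumptions, all inherited from the LiST family of models:

* deterministic and linear — identical inputs give bit-identical outputs;
* mortality and the cause-of-death structure change only in response to
  coverage changes;
* causes are independent (no comorbidity overlap); total mortality is the
  plain sum over causes;
* effectiveness is *channel-invariant*: a treatment delivered by a
  community health worker averts deaths exactly as one delivered at a
  facility. This is flagged in the run metadata because it is the single
  strongest assumption behind channel-based counterfactuals.

### Attribution of lives saved

When several interventions act on one cause, lives saved are attributed in
two blocks. All *preventive* interventions come first, ordered along the
continuum of care (periconceptual, pregnancy, delivery, postnatal,
childhood), then the *curative* ones; ties keep declared configuration
order. The preventive block's full effect on baseline deaths is attributed
to it, split among its members in proportion to
$\Delta c_i \times e_{i,k}$ (coverage increase times effectiveness). The
curative block then receives only the *additional* deaths averted on the
preventive residual, split by the same weight formula. Consequences:

* shares sum *exactly* to total lives saved (additivity, tested to 1e-9);
* a curative intervention is attributed less wherever a preventive one on
  the same cause scales up alongside it — scaling up bednets makes
  antimalarials "worth" less, because fewer malaria deaths remain for them
  to avert;
* negative coverage changes are allowed and yield negative entries ("lives
  lost"), preserving additivity, which is what makes declining-coverage
  scenarios analysable at all.

Two interpretation choices were genuinely open and are fixed here: the
within-block weight uses the per-cause $\Delta c \cdot e_{i,k}$, not an
aggregate over causes (keeps cross-cause independence and makes per-cause
attribution rows well-defined); and a block whose weights are all zero
contributes zero without evaluating 0/0.

### Percent mortality reduction

An intervention's percent reduction is 100 × its cumulative attributed
lives saved divided by the no-change baseline's total deaths over the same
span of years. `percent_reduction_table(years = ...)` lets the caller pick
the span: the default is the whole horizon, while in a before–after survey
design passing the endline year reproduces the conventional endline
"percent reduction in mortality". Full precision is kept internally;
rounding to one decimal happens only at display, so additivity is never
destroyed by intermediate rounding. (This matters: rounded components can
legitimately sum to a figure 0.1 away from the rounded total.)

### The facility-only counterfactual

To isolate a community program, `build_facility_only_counterfactual()`
constructs a scenario identical to the observed one except that every
intervention's *community* coverage is frozen at its base-year value;
facility and other channels keep their observed trajectories. Differencing
the two projections (counterfactual minus observed, so that a beneficial
program is positive) yields the program-attributable deaths averted per
year — even when total coverage fell and deaths rose in both scenarios,
the program's impact is positive whenever the no-community-change series
rises faster.

Design choices made here:

* Facility-side shifts (stockouts, task shifting, strikes) are treated as
  background common to both scenarios, not program effect. Alternative
  counterfactuals such as reallocating community users back to facilities
  are out of scope.
* Whether the "other" (pharmacy) channel should also be frozen is not
  dictated by the methodology; the default freezes only `community`, and a
  `freeze_other = TRUE` flag pins both, with the choice recorded in output
  metadata.
* Both scenarios must share base-year total coverage per intervention
  (`check_baseline_equality()`, tolerance 1e-9); comparison aborts
  otherwise, since a baseline mismatch would masquerade as program impact.
  The constructed counterfactual satisfies this by construction.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `effectiveness` | fraction of cause-specific deaths averted at 100% coverage | none (user input) | the science lives here; from effectiveness reviews |
| `coverage` | fraction of the population (never percent) | none | percent-looking values (> 1) are rejected at ingest with a hint |
| `growth_rate` | births per birth per year | 0 | explicit birth tables override it |
| `years` in `percent_reduction_table()` | calendar years | full horizon | endline year reproduces before–after reporting |
| `freeze_other` | logical | `FALSE` | pharmacies are usually background, not program |
| `tol` in `check_baseline_equality()` | coverage fraction | 1e-9 | numerical, not epidemiological, tolerance |

Coverage between survey years is interpolated piecewise-linearly per
(intervention, channel) and held constant beyond the first/last record —
the minimal assumption given that surveys provide only before/after points.
The interpolation rule is recorded in output metadata.

## What the synthetic generator emulates

`fixture_spec()` + `generate_config()` / `generate_coverage()` produce
seeded, byte-reproducible worlds for testing. Baseline deaths are drawn
uniformly in 5 000–40 000 per cause (magnitudes typical of subnational
under-five burdens), effectiveness in 0.2–0.8, community coverage gains in
0.05–0.25, base facility coverage in 0.25–0.5, and birth cohorts of
50 000–500 000 growing 0–3%/year. Four regimes reproduce the canonical
channel-shift narratives: `ideal` (community growth on a flat facility
base), `task_shifting` (users migrate channels, total flat), `stockout`
(facility falls, community partially compensates, total declines) and
`concurrent_itn` (a preventive bednet campaign scales up alongside the
curative package). Generation uses one isolated RNG stream per fixture and
never touches the global random state.

What the generator does *not* emulate: calibrated country parameters,
sampling error in survey coverage, secular trends unrelated to coverage,
herd or indirect effects, age structure within 0–59 months, or
need-adjusted ("among cases") coverage denominators. A green test on
synthetic worlds therefore establishes the *arithmetic* contracts —
additivity, monotonicity, order-invariance, fixed points — not country
realism.

One shipped example (`inst/extdata/iccm_itn_synthetic.yaml`) is a
*calibrated synthetic* world: its invented cause structure and
effectiveness values are chosen so the joint iCCM + ITN scale-up displays,
at one decimal, per-intervention reductions of 3.7 / 2.1 / 2.7 / 2.4
summing to 10.9 — the canonical prevention-before-cure pattern. No country
is represented.

## Numerical choices

* Deaths are reals internally; display rounding is the caller's job.
  Cascades of rounded intermediates are exactly how hand-worked examples
  drift by one death (a two-step 50%/50% cascade on 10 000 gives 5 625, not
  5 626).
* The attribution guard: a block with zero summed weights but numerically
  nonzero impact (only reachable through exactly cancelling signed deltas)
  raises an internal error instead of silently dividing.
* Ties in intervention ordering break by declared configuration order, then
  id, making every run reproducible.
* Degenerate inputs — zero baseline deaths in a percent denominator — give
  `NA` ("undefined"), never `NaN` propagation.

## Worked example

```{r worked}
cfg <- read_config(system.file("extdata/worked_example.yaml",
                               package = "listlite"))
cov <- read_coverage_csv(system.file("extdata/worked_example_coverage.csv",
                                     package = "listlite"))
scn <- scenario("worked", cfg$demography, cov, c(2010, 2011))
proj <- project(scn, cfg)
proj$deaths
```

A 50%-effective intervention reaching half the population averts a quarter
of the cause's deaths: 10 000 becomes 7 500.

```{r compare}
obs_cov <- read_coverage_csv(system.file(
  "extdata/declining_total_coverage.csv", package = "listlite"))
obs <- scenario("observed", demography(2008, base_births = 100000,
                                       growth_rate = 0.02),
                obs_cov, c(2008, 2013))
# a treatment intervention 60% effective against diarrhea mortality
cfg2 <- lst_config(
  causes = tibble::tibble(cause_id = "diarrhea", name = "Diarrhea",
                          baseline_deaths = 10000),
  interventions = tibble::tibble(intervention_id = "treatment",
                                 name = "Treatment", category = "curative",
                                 stage = "childhood"),
  effectiveness = tibble::tibble(intervention_id = "treatment",
                                 cause_id = "diarrhea", effectiveness = 0.6),
  demography = obs$demography)
cf <- build_facility_only_counterfactual(obs)
cmp <- compare_scenarios(obs, cf, cfg2)
tidy(cmp)
```

Total coverage *fell* from 52% to 48%, yet the community program's impact
is positive every year: without the community channel's growth, coverage
would have fallen to 38% and deaths would have risen faster.

## Known limitations

* No age-structured cohort survival, risk factors (stunting, wasting,
  birth outcomes), neonatal/maternal sub-models, or herd effects.
* "Coverage" of a curative intervention is treated as a dimensionless
  fraction; whether the denominator is population or cases in need is left
  to the user's data definition.
* The model cannot say *why* care-seeking shifted between channels — only
  whether the shift, as observed, was beneficial under the stated
  counterfactual.
* A single effectiveness per intervention-cause pair: no empirical
  difference between delivery points is modelled, so true program impact
  may be larger or smaller than projected where community- and
  facility-delivered care differ in quality.
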