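---
title: "Methods: from daily weather to welfare-footprint hours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from daily weather to welfare-footprint hours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatfootprint)
```

This vignette is the package's own account of its model: what is computed,
under which assumptions, which defaults are discretionary, and what the
synthetic tests do and do not establish about real data.

## The pipeline

Heat stress harms cattle welfare through both the *intensity* of a given day
and the *accumulation* of thermal burden over months. The package therefore
works on two time scales and then couples them:

1. Daily weather → **CCI** (apparent temperature, °C) → one of six acute
   stress categories.
2. Multi-year CCI series → **Annual Thermal Load** (ATL, °C·days) → one of
   five chronic risk classes.
3. Each stress day (acute ≥ moderate) × the location's chronic class → one
   of thirteen **scenarios**.
4. Per scenario, a **Pain-Track** converts the daily episode into hours of
   discomfort by intensity; day counts scale these to annual hours.
5. A **shade** policy lowers acute categories by one step, and the contrast
   in annual hours plus a finishing-phase cost model gives the mitigation
   picture.

All computations run on *daily means*: the input archive provides daily
averages, and every downstream quantity (categories, ATL, day counts) is
defined per day. No diurnal cycle is modelled; the within-day temporal
structure lives entirely inside the Pain-Track phase durations.

## CCI and its pluggable coefficients

`CCI = Ta + FRH + FWS + FRAD`. The package treats the three correction
functions as a *strategy*:

* `"published"` — a transcription of the established beef-cattle CCI
  correction equations (continuous in all inputs; see
  `cci_published_constants()` for the formulas and caveats). Directionality
  is what matters and is property-tested: more humidity or radiation never
  lowers CCI at warm temperatures, more wind never raises it.
* `"identity"` — all corrections zero, so CCI equals air temperature. Every
  exact worked example in the test suite uses this set, so none of the
  package's headline numbers depends on a particular coefficient
  transcription.

Acute categories are half-open `[lo, hi)` bands at 25/30/35/40/45 °C. The
choice that CCI = 30.0 is already "moderate" makes the stress-day predicate
`CCI >= 30` consistent with the ATL threshold below — a day that contributes
zero excess is never counted as a stress day and vice versa.

## Annual Thermal Load

`ATL = Σ_d max(0, CCI_d − threshold)` per calendar year, threshold 30 °C
(configurable; 30 °C is the onset of moderate stress, where sustained
thermoregulatory effort begins). Years are averaged arithmetically. Feb 29
is summed like any other day; "a year" means all days of the calendar year.

Risk bands: low < 100 ≤ moderate < 500 ≤ high < 1200 ≤ very high ≤ 2000 <
extreme. Lower bounds are inclusive, but the extreme class is *strictly*
above 2000 — the published band wording ("1200–2000", then ">2000") puts
2000.0 itself in very high, and the implementation follows that reading.

## Scenario assignment and clamping

The thirteen-cell grid omits combinations that do not occur in the source
risk landscape (extreme acute in a moderate-chronic region; extreme-danger
acute in moderate or high). Synthetic or unusual data can still produce such
days, so behaviour must be defined:

* chronic `low` (absent from the grid entirely): stress days are assessed in
  the moderate-risk column — the nearest defined chronic context, and the
  conservative one;
* undefined cells: the chronic dimension is clamped upward to the nearest
  defined cell (`E-M → E-H`; `ED-M`, `ED-H → ED-VH`), preserving the acute
  severity.

Every clamping emits a warning and is echoed into the location report, so no
silent reinterpretation occurs.

## Pain-Tracks and interval arithmetic

Each scenario's daily episode is segmented into three phases — initial
stress (compensatory mobilisation), overload (sustained effort at capacity),
recovery (or prolonged dysfunction) — each with an hour interval for its
duration and a probability distribution over intensities (none, annoying,
hurtful, disabling, excruciating). Daily hours at intensity *k* are
`Σ_phases p(k|phase) × duration(phase)`, evaluated at both interval bounds.

Two conventions matter:

* **Jointly attained bounds.** Lo combines with lo, hi with hi. This is what
  reproduces the published M-M cumulative-pain table exactly (hurtful
  `[2.0, 3.2]` h from phases `[1,2]`, `[2,3]`, `[1,2]`), and it means the
  five intensity intervals always sum to the phase-duration sum
  (conservation, tested on random configurations).
* **Point probabilities.** Only durations carry interval uncertainty, as in
  the published tables.

The packaged phase durations disagree with the packaged daily totals for
three scenarios (M-M sums to 4–7 h against a declared 5–7 h total; M-H and
M-E similarly). That inconsistency is in the source tables; the loader keeps
the phase sums authoritative, warns, and records the discrepancy in a
`consistency` attribute rather than reconciling it silently.

### The twelve stand-in probability matrices

Only the M-M Pain-Track probabilities are published in full; the package
must still ship a complete default. The design brief we set ourselves: the
defaults must (a) pin M-M exactly, (b) encode the qualitative account of how
severity shifts across scenarios — more chronic load or more acute stress
means a greater share of hurtful/disabling time, with excruciating reserved
for extreme-danger days at small probability (≤ 0.05) — and (c) guarantee the
mitigation invariant that a one-step acute downshift never *increases* hours
at any severe intensity, at either interval bound.

A construction that simply shifts probability mass one intensity step per
severity step cannot satisfy (c): the published phase-duration table is
non-monotone along the acute axis (e.g. strong/very-high days total 10–12 h
but extreme/very-high days 9–11 h, because extreme days in such regions come
from drier heat waves with some nocturnal relief), so once shifted
distributions saturate near the top of the intensity scale, severe *hours*
track the shrinking durations downward and the invariant breaks for
extreme → extreme-danger comparisons.

The packaged defaults therefore give each of the twelve scenarios a single
severity profile applied to all three phases, calibrated so that hurtful and
disabling hours are non-decreasing along both axes at both bounds (locked in
by tests), while M-M keeps its published phase structure. These matrices are
documented stand-ins, not published values: any analysis with access to
scenario-specific evidence should override them via
`load_paintrack_config()`.

## Shade model

Shade is a one-category downshift of each day's acute category (floored at
no stress) — deliberately conservative given reported radiant-temperature
reductions under shade of the order of a full category width. The chronic
class stays at the unshaded baseline when scenarios are reassigned: the ATL
class describes the regional thermal landscape in which the animal lives,
and published regional comparisons label regions by their unshaded load. A
`recompute_chronic` flag exposes the alternative (CCI lowered by 5 °C per
downshift step, one band width, before re-deriving the class).

Reductions are reported as bound-wise hour intervals and as percentages of
interval midpoints; both are kept so the percentage convention loses no
information.

## Economics

Per finishing cycle: amortised cost = investment / (lifespan × cycles/yr);
revenue = carcass differential × per-kg price (arroba price / 15, or a
per-kg override); net = revenue − cost with anti-tone interval subtraction.
Defaults: investment US$75–93, lifespan 10 y, 3 cycles/y, 5 kg differential
(the conservative published figure; the underlying trial reported 8 kg),
US$45–56/arroba, US$3–4/kg override. Monetary values stay unrounded until
rendering (the printed net range "US$12–16" is `[11.9, 16.17]` rounded).

Payback is reported under three conventions — best case (lowest investment,
highest available per-cycle revenue, i.e. the per-kg ceiling when an
override exists), midpoint, worst case — because a single printed payback
figure is only reproducible under the best-case pairing (75 / 20 → 4 cycles
= 16 months). Note one unresolved source inconsistency: the printed
per-animal amortised cost of "US$2.3" is not derivable from the stated
inputs (75–93 over 30 cycles is 2.5–3.1); the package implements the stated
division and does not chase the printed figure.

## Synthetic climate generator

`generate_location()` produces daily series as seasonal sinusoid + AR(1)
noise for temperature, humidity coupled linearly (negatively by default) to
the temperature anomaly, independent wind noise, and a deterministic
seasonal radiation cycle. Outputs are clipped to physical ranges (RH in
[5, 100] %, wind and radiation ≥ 0) and are byte-identical for identical
(archetype, years, seed).

What it emulates: the gross drivers of chronic classification — mean warmth,
seasonal contrast (small in the tropics, large in temperate zones),
humidity–temperature coupling, and autocorrelated warm runs that mimic heat
waves (the AR(1) coefficient is an archetype field so tests can force runs).
What it does not emulate: diurnal cycles, spatial correlation between
locations, real geography, radiation noise, or humidity saturation physics.
Passing tests on synthetic data therefore validate the *pipeline arithmetic
and its invariants*, not any claim about particular real locations.

The five presets were calibrated once against the ATL oracle (published
factor set, five years, seeds 1–10) so each lands in its documented risk
class — temperate → low through tropical_extreme → extreme — and then
frozen; the tests require at least 8 of 10 seeds to reproduce the class, and
the calibrated parameters achieve 10 of 10.

## Validation and gap handling

Daily series are validated per calendar year: runs of at most 3 consecutive
missing days (any variable) are filled by linear interpolation between the
flanking days — interpolants are convex combinations, so imputation cannot
create new extremes — and a year passes at ≥ 95% post-imputation coverage.
Both knobs are arguments. This is a declared package convention: the source
archive's own gap handling is not documented, and annual sums are only
comparable across locations if coverage is enforced.

## Problem sizes and determinism

The test suite and the acceptance script are sized for interactive use: the
exact worked examples run on single constructed years; property suites use
1000 random years for the ATL oracle, dozens of random Pain-Track
configurations, and 2-year random CCI series for the shade invariant; the
preset-calibration check runs 5 presets × 10 seeds × 5 years. Everything is
seeded; the pipeline is deterministic given (inputs, configuration, seed),
and rerunning a manifest writes byte-identical reports.

## Known limitations

* Daily means flatten diurnal structure; hourly CCI would sharpen both the
  category assignment and the phase durations, at the cost of data
  availability.
* The twelve stand-in Pain-Track matrices are exactly that; conclusions
  about *absolute* hours in non-M-M scenarios inherit their uncertainty,
  though the monotone structure makes *contrasts* (shade vs no shade)
  directionally robust by construction.
* Secondary welfare burdens of heat (disease, mortality, reproductive
  failure) are outside the model, as are interventions other than shade.
* The economics cover the finishing phase only; lifetime shade provision
  would change both costs and benefits.
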