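---
title: "Methods: Markov cohort cost-utility analysis of sodium reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov cohort cost-utility analysis of sodium reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltshift)
```

## The model

`saltshift` simulates a closed cohort of adults aged 35 and over from a
2011 base year to death or age 100, in annual cycles, separately for each
of 52 strata (sex × 5-year age band × Māori/non-Māori ethnicity). Four
primary health states are modelled — healthy, coronary heart disease
(CHD), stroke, dead — with first-year *tunnel* sub-states inside each
disease state (`chd_year1 → chd_later` after one cycle) so that the much
larger first-year treatment costs attach to incident cases only; the
tunnel is invisible to the QALY logic. There are no transitions between
CHD and stroke (the first event defines the disease path) and no
recurrent-event states.

Within a cycle the transition order is: incidence first (healthy occupants
split into incident CHD, incident stroke, or remain healthy, with the two
incidence risks renormalised in the degenerate case where they sum above
one); then death risks. Disease occupants face case fatality plus
background (non-CVD) mortality, summed and capped at one — a deliberate,
simple competing-risk treatment; CVD deaths are attributed in proportion
to case fatality's share of the capped total. Remaining healthy occupants
face background mortality alone. Occupancy conservation is asserted every
cycle at 10⁻⁶ (tested at 10⁻⁹ over random states).

Cohorts enter at their band midpoint (e.g. the 50–54 band starts at
age 52.5) and advance one year per cycle, crossing band boundaries as they
age; rates, costs, disability and blood-pressure coefficients are always
looked up at the *current* band. A single-year-of-age refinement was
considered and rejected: with 5-year input tables it changes nothing but
the interpolation artefacts. Accrual is end-of-cycle (plain annual cycles,
no half-cycle correction by default; `half_cycle = TRUE` averages start-
and end-of-cycle occupancy for users who prefer it). Cohorts reaching
age 100 are frozen and stop accruing.

## The sodium → blood pressure → disease pathway

A policy is a cumulative sodium-reduction schedule Δn(t) in mmol/day
(population mean), scaled to each sex by the intake ratios 4013/3544 (men)
and 3115/3544 (women) and capped at the sex's baseline intake. The
systolic blood-pressure response is β(age)·Δn/100 with β = 5.5, 6.6, 9.2,
10.3 mm Hg per 100 mmol/day for the 30s, 40s, 50s and 60s. For ages 70+
the table stops; we hold the 60s value constant, the conservative choice
(a linear continuation of the 50s→60s slope is available via
`bp_coefficients(extrapolation = "linear")`). An alternative meta-analysis
of the sodium–BP relation is provided for scenario analyses as a flat,
age-invariant 5.8 mm Hg per 100 mmol/day; the published account of that
scenario gives no per-age values, so a single coefficient of that
magnitude is an approximation that deliberately weakens the age gradient.

BP reductions map to incidence multipliers via HR₂₀^(ΔsBP/20), making
successive reductions compose multiplicatively (tested at 10⁻¹²). The
hazard ratios for a 20 mm Hg reduction are published only as age ranges —
0.49–0.67 (CHD) and 0.38–0.67 (stroke) — without the per-decade values,
which sit in non-public technical reports. Our default table assigns the
strongest value to ages 35–44 and the weakest to 85+ and interpolates
log-linearly across decades; it is fully overridable
(`hazard_ratio_table()`). Multipliers apply to incidence only, never to
case fatality: the pathway acts on the occurrence of first events, while
case-fatality improvements are carried separately by the secular trend.

## Secular trends, QALYs, costs

Incidence and case fatality decline 2.0 %/yr, background mortality
1.75 %/yr (non-Māori) and 2.25 %/yr (Māori), all to `trend_end_year` and
constant thereafter. The default end year is 2026; one published table
footnote implies 2031, so the end year is an explicit configuration knob
rather than a hard-coded constant.

A life year is worth 1 − pYLD (background prevalent disability per person)
for the healthy, additionally minus the disability weight (CHD 0.081,
stroke 0.226, floored at zero) for disease occupants. With the
mid-age Māori female pYLD of 0.288 this gives the 0.712 QALY ceiling per
life year gained. Every living person accrues the healthy annual
health-system cost (non-CVD category); disease occupants additionally
accrue the first-year or subsequent-year excess (CVD category). Costs and
QALYs discount at 3 %/yr (0 % and 6 % as scenarios); all costs are 2011
NZ$.

Direct intervention costs follow two patterns: one-off law or campaign
costs at year 0 (undiscounted), and recurring programme costs
(counselling NZ$575,000/yr, labelling NZ$621,000/yr). Recurring costs
accrue **scaled by the fraction of the cohort still alive**: the
programmes serve the modelled closed cohort, which shrinks. This reading
reproduces the published per-adult direct-cost magnitudes (≈3.6 and
≈4.1 NZ$ per adult discounted); a flat annuity would roughly double them.

## The intervention schedules

Counselling, labelling and both mandatory reformulation options take full
effect in year 1; mandatory compliance phase-in is unstated in the source
material and defaults to immediate. The UK package ramps in seven equal
annual increments of 22.7/7 ≈ 3.2 mmol/day; the media campaign is a 30 %
share of the package effect (scenario range 15–45 %). The sinking lid
steps down 9.0 mmol/day per year — `((3544 − 2300)/22.99)/6` — reaching
the 2300 mg/day target in six years. All effects persist for the cohort's
lifetime unless a `sunset_year` is set, after which exposure reverts to
zero.

The salt tax needed a design decision: the source states the elasticity
(−0.1), the 20 % cap on any one year's demand change, the 2300 mg/day
target and the 10-year horizon, but not the year-by-year rule. We adopt a
constant proportional annual demand reduction
p = 1 − (target/baseline)^(1/horizon), which satisfies the cap
(p ≈ 4.2 %), hits the target exactly at the horizon, yields strictly
decreasing absolute annual reductions with the largest (6.5 mmol/day) in
year one, and implies an annual price increase of p/|elasticity| ≈ 42 %.
Whether the 20 % cap binds demand or price is ambiguous in the source
text; both readings are exposed (`cap_basis`), and the price reading is
infeasible at the default elasticity, which is itself informative.

Counselling's population-mean effect is the per-hour trial effect
(7.6 mmol/day) times the national annual counselling volume (4600 h)
diluted over all 2.3 million adults — about 0.015 mmol/day. This dilution
is the only reading consistent with counselling's near-zero health gain
relative to the mandatory options; it is also why its ICER is sensitive
to modelling choices that barely move any other intervention.

## Generalised CEA and equity outputs

Observed rates already contain current practice (counselling and the
endorsement label), so the "do nothing" comparator divides observed
incidence by the product of the current-practice multipliers
(independent pathways through the same BP mechanism compose
multiplicatively); re-applying them reproduces the observed rates to
10⁻⁹. Each intervention is then run alone on the do-nothing world, and
incremental QALYs, net cost (direct + ΔCVD + Δnon-CVD costs), the ICER
(with Dominant labelling) and the per-adult decomposition are reported.
The deterministic ICER is a ratio of expected values; from PSA draws the
pipeline reports both conventions (ratio-of-means and mean-of-ratios),
since the published convention is not stated.

The inequality report divides the model's CVD deaths in a report year
(default 2021) by the persons alive that year, per 100,000, within sex ×
baseline age band, giving Māori−non-Māori rate differences and ratios,
plus discounted per-person QALY gains over the first ten years. The
equity scenario (`equity_substitution()`) gives Māori strata the
non-Māori background mortality and disability — removing the "penalty"
that higher competing risks impose on their potential health gain —
while leaving disease rates untouched; it is idempotent.

## Uncertainty machinery

The PSA draws each parameter from its declared distribution (normal, or
gamma by moment matching: shape = (mean/sd)², scale = sd²/mean). Effect
sizes are normal truncated at zero; truncated draws are clamped and
counted, never resampled, keeping the draw count fixed and the stream
reproducible. Draw streams are keyed by *parameter name*, so parameters
shared between interventions receive identical draws at the same seed —
common random numbers, stabilising incremental comparisons. Uncertainty
intervals are percentile intervals by order statistics (draws 50 and 1950
of 2000 for 95 %); whether the published intervals were percentile or
normal-approximation is unstated, and percentile is the distribution-free
choice. The tornado evaluates each parameter at its 2.5th/97.5th
percentiles with all others at their means, ranking by absolute output
range.

## The synthetic baseline generator

The generator builds smooth log-linear age gradients anchored to the
published magnitudes: non-Māori male implied CVD mortality (incidence ×
case fatality) of 4·10⁻⁴ at 52.5 and 6·10⁻³ at 77.5; a Māori:non-Māori
mortality ratio of 4.5 at 52.5 declining to 2.4 at 77.5 (clamped to
[1.2, 6]); case fatality rising log-linearly with age; Gompertz background
mortality; pYLD anchored at 0.288 for Māori women aged 60–64; costs
anchored at the published female 60–64 values (NZ$2,381 healthy,
NZ$16,258/5,395 CHD first/subsequent year, NZ$20,553/5,991 stroke) with
gentle age gradients and the standard scale-up factors (disease ×1.2 at
all ages; healthy ×1.1/1.2/1.3 at 65–74/75–84/85+). A seeded log-normal
jitter (SD 3 %) emulates sampling noise; monotone age gradients and
Māori ≥ non-Māori dominance are re-enforced after jittering, so the
invariants hold for every seed. Stored prevalence is set near the steady
state incidence/(incidence + case fatality + background mortality), which
is also what `check_coherence()` audits (default tolerance ±50 %,
generous because empiric prevalence from short look-back administrative
windows runs low). The population is an NZ-like pyramid normalised to
2.3 million adults, with a Māori share declining from 12 % to 3 % across
age bands.

Two generator choices deserve emphasis. First, the CVD-attributable share
removed from healthy annual costs (to avoid double counting) is never
quantified in the source; it is a configuration fraction, default 10 %,
and the published NZ$2,381 anchor is interpreted as the *post-removal*
value. Second, the CHD:stroke split of CVD mortality defaults to 50:50 —
higher on the stroke side than raw national CHD:stroke death tallies —
because the modelled stroke state covers haemorrhagic as well as
ischaemic stroke, other CVD deaths sit in background mortality, and the
emulated analysis reports BP-mediated health gains carried more by stroke
than by CHD; the even split embeds that reported burden structure, and
with it the default bundle reproduces the expected tornado ordering
(effect size first, stroke hazard ratio above CHD).

What the generator does **not** emulate: real stratum-level irregularities
(data artefacts, cohort effects), within-stratum heterogeneity in sodium
intake or risk, any correlation structure between rates and costs beyond
the shared age gradients, and the absolute scale of the non-public data
(the comparator's 24.7M QALYs and NZ$120B costs are synthetic-scale, about
25 % below the published population totals). Passing tests therefore
demonstrate correctness of the *machinery* and of structural,
ratio-scale and ordering results — not agreement with the real cohort's
absolute population totals, which are unattainable without the restricted
source data.

## Numerical choices and problem sizes

Tolerances: occupancy conservation 10⁻⁶ (hard error) / 10⁻⁹ (tested);
round-trip and back-calculation identities 10⁻⁹; HR multiplicativity
10⁻¹². Degenerate inputs: incidence pairs summing above one renormalise;
death risks cap at one; rates removed in back-calculation clamp at one
with a warning; zero-QALY interventions report an undefined ICER rather
than dividing by zero. Ties in the tornado ranking keep registry order.

The default analysis is 52 strata × 63 annual cycles; a full
deterministic eight-intervention CEA takes ~0.2 s, and an
eight-intervention PSA at the standard 2000 draws a few minutes on one
core, which is why the test suite exercises the PSA at reduced draw
counts while `scripts/acceptance.R` runs one intervention at the full
2000.

## Known limitations

Structural uncertainty is not captured: one model form, no CHD↔stroke
transitions, no recurrence, closed cohort (no entrants after 2011, no
migration), no future health-cost growth, no BP trend, health-system
perspective only. Counselling's absolute QALY gain and ICER are the least
transferable outputs, being hypersensitive to the dilution reading of its
effect size. The tax module reports the implied price path but not
revenue against a published figure, which would require salt price and
volume data the source does not provide (`solve_tax_schedule()` exposes
the pieces for users who have them).
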