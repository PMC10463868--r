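---
title: "Methods: the cost-effectiveness model behind radcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cost-effectiveness model behind radcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcea)
```

radcea implements a full decision-analytic comparison of two
radiotherapy strategies for head-and-neck cancer — intensity-modulated
radiotherapy (IMRT) versus three-dimensional conformal radiotherapy
(3D-CRT) — from a societal perspective. This vignette is the package's
own account of the model, the defaults it chooses where a modeller has
genuine latitude, and what its tests do and do not establish.

## The Markov cohort model

Radiotherapy for head-and-neck tumours trades tumour control against
two chronic toxicities: xerostomia (dry mouth, from parotid
irradiation) and dysphagia (swallowing difficulty, from pharyngeal
constrictor irradiation). Each is graded low (stage 0–1) or high
(stage 2+). The default state space is the composite of the two
gradings — LXLD, LXHD, HXLD, HXHD — plus *lost to follow-up* (LTF) and
*death*. We use composite states because per-patient outcomes carry
both toxicities at once, and because influence analyses naturally ask
about "LXLD patients" as a group; the state set is just a labelled
table (`health_states()`), so a four-state single-toxicity reading runs
unchanged.

A strategy is a row-stochastic transition matrix over these states
plus per-state payoffs. The cohort row vector is propagated by
left-multiplication each cycle; the trace (cycle × state occupancy
matrix) satisfies, and is tested against, three structural guarantees:
rows sum to 1 within 1e-9, death occupancy is non-decreasing, and the
undiscounted occupancy totals agree with the fundamental matrix
$(I - Q)^{-1}$ of the absorbing chain to 1e-6.

Two modelling assumptions are enforced as *validation rules* rather
than conventions:

* **Absorbing death.** The death row must be the identity on death.
* **LTF mortality.** Patients lost to follow-up are unobserved, not
  immortal: their per-cycle death probability must equal the cohort's.
  `validate_matrix()` takes the cohort death probability explicitly,
  or infers it when all observed alive states share one value; if the
  alive states disagree and no value is given, validation refuses to
  guess.

### Accumulation conventions

Costs and QALYs accrue from cycle 1 (cycle-0 occupancy earns nothing);
utilities are per-year so QALY accrual scales with the cycle length;
both streams discount by $(1+r)^{-t \cdot \Delta}$ with $\Delta$ the
cycle length in years. One accrual convention had to be fixed: we use
the cycle-end convention by default, because it makes the calibrated
fixture exactly reproducible by hand multiplication. The half-cycle
correction (averaging adjacent trace rows, placing transitions
mid-cycle) is a flag, and a property test pins it between the
start-of-cycle and end-of-cycle conventions. A per-strategy `upfront`
cost covers one-off treatment-course spending at cycle 0, undiscounted,
for analysts who do not want delivery costs smeared over cycles.

### Run-control defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `cycle_length_years` | 0.25 | years | quarterly cycles suit acute-to-chronic toxicity transitions |
| `n_cycles` | 20 | cycles | a 5-year horizon; QALY totals of 3–4 need multiple years |
| `discount_rate` | 0.03 | per year | conventional HTA base case, applied to costs and QALYs alike |
| `half_cycle` | off | — | reproducibility of the simple fixture takes priority; the flag is tested separately |
| `death_prob` (synthetic) | 0.02 | per cycle | a plausible cohort mortality for a mixed head-and-neck population |

All are configuration, not constants.

## Costing

Costing is bottom-up: per-patient records in seven closed categories —
visits, laboratory, diagnosis, radiotherapy (direct medical);
transport, lodging (direct non-medical); productivity loss (indirect).
Amounts in Rials convert to USD at ingestion at one fixed study-period
rate (36,692 IRR/USD, configurable); a single average rate is used
because the study window is short and a time-varying rate would add
noise without information. Indirect costs use the human-capital
approach, days absent × daily wage summed over patient, companion, and
home nursing; wages are per-record inputs with no national default
baked in.

`aggregate_costs()` reports *per-patient means* (the per-person
presentation of published cost tables), with group subtotals as sums of
category means. Reporting quirks are handled explicitly:

* Whole-dollar prose figures are the **floor** of the full-precision
  totals, because the published whole-dollar figures are consistent
  with truncation and not with rounding (e.g. 13761.33 → \$13,761).
  Full precision is retained internally.
* A published subtotal can disagree with its own column sum by a cent.
  `flag_total_discrepancies()` recomputes every subtotal and flags
  reported values off by more than half a cent; the package reports the
  recomputed sum and never force-matches a transcription.

The same policy applies downstream: the published incremental
effectiveness (−0.45) and ICER (−7367.27) are not consistent with the
published cost/QALY cells themselves (which give −0.46 and ≈−7289.43);
`rank_strategies()` recomputes from full precision and relies on the
categorical dominance verdict instead of a negative ICER, which is
ambiguous between "dominant" and "dominated" on its own.

## EQ-5D-3L utilities

Profiles are five digits over mobility, self-care, usual activities,
pain/discomfort, anxiety/depression, each level 1–3. Scoring uses the
standard additive TTO form: full-health value, minus a constant if any
dimension exceeds level 1, minus per-dimension level decrements, minus
an N3 term if any dimension is at level 3. Monotonicity (worsening a
dimension never raises utility) is guaranteed by requiring level-3
decrements ≥ level-2 decrements and is property-tested under random
valid value sets. Utilities below zero (states worse than dead) are
permitted and flow into the engine unchanged.

The Iranian TTO tariff's coefficients are not redistributable data, so
value sets are pluggable CSVs and the package ships only a clearly
labelled toy set. Per-state utilities require an explicit `state_label`
per response — how respondents map to model states is an input, not an
inference the package makes.

## Ranking

`rank_strategies()` sorts by ascending cost (ties by descending QALY),
applies weak dominance (no worse on both axes, strictly better on one;
exact ties dominate nothing), then removes extendedly dominated
strategies — those whose incoming frontier ICER exceeds their outgoing
one — iterating to convergence, which yields the lower convex hull of
the cost-QALY cloud. The whole procedure is checked against a
brute-force oracle (pairwise dominance plus explicit convex blends)
over hundreds of random instances. Dominated strategies keep their
incremental cost/QALYs against the reference so a two-strategy table
reads like a published ranking, but get no ICER.

## Sensitivity analysis

**One-way / tornado.** A parameter is a path into the model (a state
utility, a state cost, an upfront cost, or a transition entry) with a
low–high range bracketing the base. Perturbing one transition
probability renormalises the remaining non-death entries of its row
proportionally while keeping the death probability fixed — this is the
only renormalisation consistent with the LTF-mortality rule. Bars sort
by descending swing; ties keep input order.

**PSA.** Default distribution families follow HTA practice: gamma for
costs (non-negative, right-skewed), beta for utilities and single
probabilities, Dirichlet for whole transition rows, all
method-of-moments matched from mean and sd (or a concentration
vector). Draws use one seeded generator with a documented order —
parameters in declaration order, draws as the outer loop — so extending
the number of draws preserves the earlier stream, and a zero-variance
run reproduces the base case bitwise. Draws whose matrices fail
validation are rejected and redrawn, with a hard cap of 100× the
requested draws.

**CE plane and CEAC.** Increments are comparator minus reference, with
ΔQALY on the x-axis and Δcost on the y-axis. Quadrants are numbered
clockwise from the north-east: I (+,+), II (+,−), III (−,−),
IV (−,+) — quadrant IV is "less effective and more costly", i.e. the
comparator is dominated there. Points on an axis go to the adjacent
lower-numbered quadrant and are flagged. The CEAC reports, per
willingness-to-pay value, the fraction of draws in which each strategy
has the strictly highest net monetary benefit, splitting exact ties
equally so probabilities sum to 1. The default WTP grid runs from 0 to
three times the largest base-case strategy cost in 101 steps.

## Synthetic data and the calibrated fixture

The generator emulates the study's *shape*: 97 respondents (49
reference / 48 comparator — the true split is not public, so this is a
labelled placeholder), per-category cost means equal to the published
per-person table, gamma cost noise with CV 0.4 (healthcare costs are
non-negative and right-skewed; the study reports no dispersion, so the
CV is a knob, not a claim), absenteeism split 70/30 between patient and
companion days at fixed synthetic wages, severity-graded EQ-5D level
probabilities per toxicity state sampled independently across
dimensions, and transition matrices that satisfy every validation rule
by construction. Everything is a pure function of config + seed.

What the generator does *not* emulate: cross-dimension correlation in
EQ-5D responses, between-category cost correlation within a patient,
real survival of head-and-neck cohorts, or the unpublished transition
probabilities of the source model. Passing the parameter-recovery
tests therefore shows the *pipeline* is unbiased at scale, not that the
synthetic cohort resembles any real one.

The **calibrated fixture** (`gen_calibrated_fixture()`) is the bridge
to the published base case: a single transient state with per-cycle
payoffs chosen so five undiscounted one-year cycles give exactly
(9209.76, 3.63) for 3D-CRT and (12562.90, 3.17) for IMRT. The source
model's transition probabilities are not printed anywhere, so the
published cells cannot be *re-derived* — the fixture instead proves the
engine, ranking, and sensitivity layers reproduce them exactly when
fed equivalent inputs, and carries a modest-noise PSA parameterisation
(beta sd 0.03 on utilities, gamma sd 5% on cycle costs) under which the
Monte Carlo cloud concentrates in quadrant IV and the reference arm
wins the CEAC at every WTP, matching the study's qualitative findings.
`gen_toxicity_fixture()` is the six-state analogue used to demonstrate
tornado behaviour, with the widest uncertainty on the reference arm's
LXLD and HXLD utilities — the parameters the study found most
influential.

## Numerical choices and problem sizes

Tolerances: row-stochasticity, initial distributions, CEAC probability
sums, and the LTF rule at 1e-9; fundamental-matrix agreement at 1e-6;
exact (bitwise) equality where determinism is the claim. Degenerate
inputs have defined behaviour: zero QALY differences give an undefined
(NA) ICER rather than an error, zero-CV generators return means
exactly, empty inputs raise classed validation errors naming the
offending row or field.

The shipped test suite exercises: traces to 10,000 cycles against the
closed form, 1,000 generated matrices for conservation, 500 random
instances against the ranking oracle, 1,000-draw PSAs, and
20,000-patient synthetic recovery runs (observed maximum category error
about 0.6% against a 2% tolerance; EQ-5D sample means within 1 SE of
the 243-profile enumeration). These sizes were chosen so the full suite
settles in well under a minute per module while keeping Monte-Carlo
tolerances honest at 3 standard errors.

## Known limitations

* Cohort-level modelling only: no microsimulation, tunnel states, or
  time-varying transition matrices.
* The value-set form is fixed to additive decrements with optional
  constant and N3 terms; 5L instruments and crosswalks are out of
  scope.
* Indirect costs use the human-capital approach only (no friction
  cost), and no inflation adjustment across years is applied.
* The ICER/NMB layer is two-outcome (cost, QALY); multi-criteria and
  budget-impact analyses are out of scope.
* Expected value of perfect information is not computed; the PSA output
  is draws, quadrants, and acceptability curves.
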