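---
title: "A Markov model of liquid-biopsy recurrence surveillance in colorectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov model of liquid-biopsy recurrence surveillance in colorectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crclbce)
```

## The decision problem

Next-generation-sequencing liquid biopsy (NGS-LB) detects circulating tumor
DNA in blood and can flag colorectal-cancer (CRC) recurrence months before
imaging. Whether annual NGS-LB surveillance is worth paying for depends on
how small survival and progression improvements trade off against the test's
reimbursement price and the downstream treatment costs it shifts. `crclbce`
implements a decision-analytic state-transition model that quantifies this
trade-off for the healthcare systems of Spain, France and Germany: for a
hypothetical cohort of 60-year-old patients in CRC stage III it computes
remaining life expectancy (LE), quality-adjusted life-years (QALYs) and
total direct treatment costs (TDC) under standard care and under six
NGS-LB strategies, and summarizes each comparison as an incremental
cost-effectiveness ratio (ICER) judged against a willingness-to-pay (WTP)
threshold of 23,500 €/QALY.

## Model structure

The model has six health states: CRC stages I–IV plus two absorbing states,
death from general (all-cause, non-CRC) mortality and death from CRC.
Cycles are annual, matching the annual resolution of every input
probability and of the surveillance schedule. Three structural assumptions
shape the transition graph:

* recurrence moves a patient only to the immediately next stage (no stage
  jumps, no regression — the literature documents jumps but quantifies none);
* stage IV is persistent: no progression out of it and no cure;
* patients in stage III/IV cannot be healed, which deliberately understates
  the benefit of surveillance (a conservative bias).

At age $a$ a patient in stage $s$ faces three competing risks: general
mortality $q(a)$ from the life table, CRC-specific death
$d_s = m_{\mathrm{mort}} \cdot p^{\mathrm{crc}}_s$, and progression
$p_s = m_{\mathrm{tx}} \cdot p^{\mathrm{rec}}_s$. The default
*sequential* composition conditions each risk on escaping the previous one:

$$P(\text{general death}) = q,\qquad
  P(\text{CRC death}) = (1-q)\,d_s,$$
$$P(\text{next stage}) = (1-q)(1-d_s)\,p_s,\qquad
  P(\text{stay}) = (1-q)(1-d_s)(1-p_s).$$

This guarantees a valid probability row at every age, including the forced
$q = 1$ terminal year, and reduces to the marginal inputs whenever the other
risks vanish. An *additive* composition (marginal probabilities, exits
rescaled if they exceed 1) is available behind
`study_config(composition = "additive")` for calibration experiments; it is
not the default because it needs exactly that rescaling patch-up at high
ages.

The two effect multipliers $m_{\mathrm{mort}}, m_{\mathrm{tx}} \in
\{1, 0.99, 0.97\}$ encode the assumed 0/1/3% improvements in survival
("MortSuccess") and stage progression ("TxSuccess") from earlier recurrence
detection. The mortality multiplier applies to the CRC-specific death
probability in *every* occupied stage, including IV. Standard care has both
multipliers at 1 and no test costs; the zero-effect validation strategy has
both multipliers at 1 *with* test costs and must reproduce standard care's
LE and QALYs bit-exactly — this is the model's internal integrity check and
is asserted in the test suite.

## Parameters

All defaults are bundled in `default_parameters()` exactly as printed in
their sources (cent precision, EUR reference year 2019; historical costs
were brought forward at 4%/year for Spain and France and 3%/year for
Germany, see `inflate_cost()`).

| parameter | I | II | III | IV | unit |
|---|---|---|---|---|---|
| utility | 0.74 | 0.74 | 0.67 | 0.25 | — |
| annual stay (no recurrence) | 0.983 | 0.944 | 0.887 | — | probability |
| recurrence (direct row) | 0.010 | 0.025 | 0.077 | — | probability |
| CRC death | 0.015 | 0.039 | 0.078 | 0.33 | probability/yr |

Costs are tiered per stage: *initial* (first year after entering a stage),
*follow-up* (every subsequent year), *advanced* (the last treatment year of
patients dying of CRC). The NGS-LB test costs 441.45 € per test
(the 2019 French RIHN reimbursement lump sum at an assumed 50% rate);
LB-enabled strategies charge one test per patient-year: at start, on the
stage III→IV switch, and annually during follow-up, never more than one per
cycle. Stage I/II parameters are bundled and the engine accepts stage I/II
starting cohorts, but the reference analysis starts in stage III, so those
cells are inert there (their tornado bars are exactly zero — a useful
negative control).

### The two recurrence rows

The published parameter table carries two mutually inconsistent recurrence
parameterizations: an annual probability of *not* having a recurrence
(0.887 for stage III, annualized from 3-year cumulative incidences — its
complement 0.113 is the annual recurrence probability) and a directly
tabulated *probability of recurrence* (0.077 for stage III). Both are
implemented (`study_config(recurrence_source = )`); since the original
model's choice is not stated, we calibrated once against the published
LE/QALY results: the direct row reproduces them clearly better in all six
country–sex cells, so the package's *calibrated reference configuration*
(`calibrated_study_config()`, used by `reproduce_study()` and the
acceptance script) selects `alt_table_row` together with
`initial_cost_at_start = TRUE` as a single global setting. The plain
`study_config()` default stays with the annualized-incidence reading, which
is the more defensible derivation when no calibration target is available.
`annualize_recurrence()` makes the connection explicit:
$1-(1-0.30)^{1/3} \approx 0.113 \approx 1-0.887$ within printed rounding.

## Life tables and the synthetic generator

General mortality comes from national 2019 period life tables (INE, INSEE,
DESTATIS) by single year of age and sex. Those values are not
redistributable here, so the package ships a deterministic synthetic
generator with the same age-exponential structure: a Gompertz–Makeham
hazard $\mu(a) = \lambda + \alpha e^{\beta a}$, converted exactly to annual
death probabilities
$q(a) = 1 - \exp\!\left(-\lambda - \tfrac{\alpha}{\beta} e^{\beta a}(e^\beta - 1)\right)$.
The six default parameter sets (`gompertz_makeham_defaults()`) were fitted
once by root-finding on $\alpha$ (with $\lambda = 5\cdot10^{-4}$ and
$\beta$ = 0.092 for men, 0.105 for women) so that remaining life expectancy
at 60 matches realistic 2019 period values ordered Spain ≥ France ≥ Germany
within sex, with women outliving men; the female tables imply a life
expectancy at birth of roughly 84 years. Tables are truncated at a terminal
age of 100 with $q(100) = 1$, which guarantees that every cohort is fully
absorbed within the 60-cycle horizon — the cohort analogue of "the model
stops when the last patient enters an absorbing state".

What the synthetic tables do *not* emulate: infant and young-adult
mortality humps (irrelevant for a cohort starting at 60), cohort effects,
and the exact national age profiles. Consequently, tests and the
acceptance report run on synthetic tables demonstrate the *machinery* —
probability structure, accrual arithmetic, engine agreement, orderings —
at realistic mortality levels, not numeric equality with results computed
from the official national tables. Users holding the national CSVs can
drop them in via `load_life_table()` / `reproduce_study(life_table_dir=)`
(a `convert_wide_life_table()` helper reshapes the common one-column-per-sex
layout).

## Accrual conventions

Rewards are attached to cycles $k = 0, 1, \dots$ with discount factor
$(1+r)^{-k}$, $r = 3\%$ for both costs and effects (0% runs are always
written alongside). A patient alive at the start of a cycle is credited
with that cycle's life-year, utility weight, follow-up or initial cost, and
LB test; patients dying of CRC during a cycle receive that cycle's
*advanced* cost instead of their initial/follow-up charge (general-mortality
deaths keep the ordinary charge — the advanced tier is cancer end-of-life
treatment; `advanced_cost_on_general_death` flips this for calibration).
Because the process is memoryless, the dying fraction of a stage is split
proportionally between that cycle's entrants and continuing occupants.
Half-cycle correction (trapezoid of consecutive occupancies) is off by
default — the behaviour of the cited modelling software when unconfigured —
and applies to effect accrual when enabled.

The deterministic cohort engine (`run_cohort()`) and the seeded
patient-level microsimulation (`run_microsim()`) share the transition
matrices and accrual rules; the cohort trace is the exact expectation of
the microsimulation, and the suite asserts agreement within three Monte
Carlo standard errors at $n = 100{,}000$. The original analysis reports
both a Markov model and Monte Carlo simulation without stating which
produced the published table, so both engines are first-class and
cross-checked.

## Economics and sensitivity analysis

Comparisons are strictly pairwise against standard care (no efficiency
frontier across the active strategies, matching the study design): 3
countries × 2 sexes × 6 active comparators = 36 comparative assessments,
from 42 main runs plus 6 validation runs (both the 42 and 48 run counts
that appear in different parts of the source report are recoverable from
the grid manifest). ICERs divide unrounded increments; when the QALY
increment is not positive a dominance label replaces the ratio
(`dominant` / `dominated` / `equivalent`), never a signed number.
European-style formatting with thousands separators exists only in the
reporting layer (`format_grid_results()`).

The one-way sensitivity analysis (`one_way_sa()`) perturbs every
independent parameter by ±10%: the four utilities, the active recurrence
probabilities, the four CRC death probabilities, all twelve cost cells, the
LB test cost, and the start age (±10% of 60 years, rounded to whole years —
its bars are legitimately asymmetric because mortality grows exponentially
with age). Perturbed probabilities and utilities are clipped into [0, 1]
with a warning and re-enter the ordinary competing-risk composition; no
renormalization shortcuts. The reported swing per parameter is
$\max(|ICER_{low}-ICER_{base}|, |ICER_{high}-ICER_{base}|)/ICER_{base}$
— the source reports a single unspecified "% change" per parameter, so this
convention is declared and both one-sided ICERs are retained in the output
for auditing. Entries sort by decreasing swing, ties alphabetically.

## Problem sizes and numerical choices

The reference runs use 60 annual cycles (start age 60, terminal age 100
forces absorption earlier), an early-stop threshold of $10^{-9}$ living
occupancy, row-stochasticity asserted at $10^{-12}$ and mass conservation
at $10^{-10}$ per cycle. The microsimulation cross-checks use
$n = 100{,}000$ individuals (seconds per cell; standard errors on LE around
0.01 years). The full comparator grid (48 runs) evaluates in about two
seconds on one core, and the complete test suite in well under a minute.

## Known limitations

* The published national life tables are not bundled; headline LE/QALY/cost
  levels computed on synthetic tables approximate but do not equal results
  from official tables. Re-running with user-supplied national CSVs is the
  supported path to exact reproduction.
* Total-cost levels are additionally sensitive to cost-timing conventions
  of the original modelling software that the source does not fully
  specify; all plausible switches are implemented and exposed
  (`initial_cost_at_start`, `advanced_cost_on_general_death`,
  `lb_followup_in_stage_iv`, `half_cycle_correction`), but the bundled
  calibration fixes them once, globally, rather than per result.
* No probabilistic sensitivity analysis: the source distributions are
  unknown, and the original analysis performed none; uncertainty handling
  is deliberately limited to the one-way ±10% design.
* Assay sensitivity of NGS-LB is not a model parameter; the effect of
  surveillance enters only through the two multipliers.
* No tunnel states (time-in-stage memory), treatment lines, stage
  regression, indirect or societal costs, or equipment/training costs.

## A minimal session

```{r}
lt <- synthesize_life_table(gompertz_makeham_defaults("FRA", "female"),
                            country = "FRA", sex = "female")
cfg <- calibrated_study_config("FRA", "female")
par <- default_parameters("FRA", "female")
cmp <- default_comparators()

std <- summarize_outcomes(run_cohort(cfg, lt, par, cmp$standard_care), par)
lb <- summarize_outcomes(run_cohort(cfg, lt, par, cmp$mort3_tx3), par)
std
lb
compute_icer(std, lb, wtp = cfg$wtp_threshold)
```
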