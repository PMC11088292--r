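# crclbce

Cost-effectiveness modelling of next-generation-sequencing liquid-biopsy
(NGS-LB) recurrence surveillance in colorectal cancer (CRC) for the
healthcare systems of Spain, France and Germany.

NGS-LB detects circulating tumor DNA in blood and can reveal CRC recurrence
well before imaging, but the test is expensive and its clinical benefit is
still unproven. This package is for health economists and HTA analysts who
want to explore that trade-off quantitatively: it implements a
decision-analytic six-state Markov cohort model (CRC stages I–IV plus two
absorbing death states) with a matching patient-level Monte Carlo
microsimulation, runs it over national or synthetic life tables, and
reports life expectancy (LE), quality-adjusted life-years (QALYs), total
direct treatment costs (TDC), incremental cost-effectiveness ratios and
one-way tornado sensitivity analyses.

## The model in brief

A cohort starts at age 60 in CRC stage III and evolves in annual cycles.
In stage *s* at age *a* the competing risks are composed sequentially:

    P(general death) = q(a)
    P(CRC death)     = (1 − q(a)) · m_mort · p_crc(s)
    P(next stage)    = (1 − q(a)) · (1 − m_mort·p_crc(s)) · m_tx · p_rec(s)
    P(stay)          = remainder

where `q(a)` is the life-table annual death probability and the effect
multipliers `m_mort, m_tx ∈ {1, 0.99, 0.97}` encode assumed 0/1/3%
improvements in survival ("MortSuccess") and stage progression
("TxSuccess") from NGS-LB surveillance. Progression is strictly to the next
stage; stage IV is persistent. Costs are tiered per stage — initial
(first year), follow-up (annual), advanced (last treatment year of CRC
deaths) — in 2019 euros, plus 441.45 € per NGS-LB test and year. Costs and
effects are discounted at 3% and ICERs are judged against a
willingness-to-pay threshold of 23,500 €/QALY:

    ICER = (C_LB − C_std) / (E_LB − E_std)   [€/LYG and €/QALYG]

See `vignette("crc-liquid-biopsy-model")` for the full account of the
model, its assumptions and the calibration choices.

## Worked example

```r
library(crclbce)

lt  <- synthesize_life_table(gompertz_makeham_defaults("FRA", "female"),
                             country = "FRA", sex = "female")
cfg <- calibrated_study_config("FRA", "female")
par <- default_parameters("FRA", "female")
cmp <- default_comparators()

std <- summarize_outcomes(run_cohort(cfg, lt, par, cmp$standard_care), par)
lb  <- summarize_outcomes(run_cohort(cfg, lt, par, cmp$mort3_tx3), par)
std
#> <accruals> standard care: cost 57071.19 EUR, LE 6.6372 y, QALY 3.9971 (discounted)
lb
#> <accruals> MortSuccess 3% - TxSuccess 3%: cost 60131.43 EUR, LE 6.7879 y, QALY 4.0884 (discounted)
compute_icer(std, lb, wtp = cfg$wtp_threshold)
#> <CE> MortSuccess 3% - TxSuccess 3% vs standard care: dCost 3060.24, dQALY 0.0913, C/QALYG 33514.50 (above WTP 23500)
```

Read: a 60-year-old French woman in stage III under standard care has a
discounted remaining life expectancy of 6.64 years (4.00 QALYs) at a
discounted treatment cost of 57,071 €. Annual NGS-LB surveillance that
improved survival and slowed progression by 3% each would add 0.15
discounted life-years (0.09 QALYs) for 3,060 € more, i.e. 33,514 € per QALY
gained — above the 23,500 € threshold but well below the 50,000 € level
used in many healthcare systems. These numbers use the package's synthetic
life tables; supply the official 2019 national tables as CSVs
(`load_life_table()`, `reproduce_study(life_table_dir = )`) to compute the
exact national results.

The whole experiment — the comparator grid in all six country × sex cells
at 0% and 3% discounting, survival curves, tornado analysis and a run
manifest — is one call (or `Rscript inst/cli/crclbce.R reproduce`):

```r
reproduce_study("results_dir")
```

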