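# pd1cea

Trial-based cost-effectiveness analysis of first-line PD-1 inhibitor
regimens (sintilimab, toripalimab, camrelizumab — each combined with
pemetrexed/platinum chemotherapy) for advanced non-squamous non-small cell
lung cancer, from the perspective of the Chinese national medical insurance
payer. The package implements the full modelling chain as tested, reusable
functions, for health economists who need to rebuild or audit this class of
analysis rather than rerun a point-and-click model:

1. **Survival evidence** — digitized Kaplan–Meier curves (coordinate tables
   plus numbers-at-risk) are the input. A synthetic-trial module simulates
   arms with known ground truth, estimates KM curves and emulates figure
   digitization, so the whole chain is testable without scraping figures.
2. **Pseudo-IPD reconstruction** — the Guyot algorithm rebuilds per-patient
   `(time, event)` records from each curve and its risk table, with
   interval-level diagnostics and fidelity QC.
3. **Parametric extrapolation** — exponential, Weibull, log-normal,
   log-logistic and Gompertz models are fitted to the pseudo-IPD by maximum
   likelihood; the extrapolation model is selected by AIC with a BIC
   near-tie break.
4. **Markov cohort model** — three states (progression-free, progressive
   disease, death; death absorbing, no backward transitions), 3-week
   cycles, 30-year horizon. Cycle transition probabilities come from the
   fitted survival functions: with cycle boundaries t0, t1,

   ```
   q_pf = 1 - S_PFS(t1)/S_PFS(t0)          exit from progression-free
   q_os = 1 - S_OS(t1)/S_OS(t0)            conditional mortality
   P(PF -> death) = min(q_os, q_pf)        P(PF -> PD) = q_pf - P(PF -> death)
   P(PD -> death) = q_os
   ```

   Progression-free cycles accrue PD-1 drug, chemotherapy (4 induction
   cycles of pemetrexed+carboplatin, then pemetrexed maintenance) and
   administration costs plus utility 0.804; progressive disease accrues
   second-line docetaxel costs plus utility 0.321; grade ≥3 adverse-event
   management enters once at model entry as an incidence-weighted cost.
   Costs and QALYs are discounted at 5 %/year.
5. **Decision analysis** — incremental cost-effectiveness ratios
   (ICER = ΔC/ΔE), strict and extended dominance, the 3× per-capita-GDP
   willingness-to-pay threshold (3 × 95,749 = 287,247 CNY/QALY), one-way
   (tornado) sensitivity analysis, and probabilistic sensitivity analysis
   (10,000 Monte Carlo draws; Gamma costs, Beta utilities) summarised as
   cost-effectiveness acceptability curves.

## Worked example

The packaged replication scenario calibrates three synthetic arms to the
source trials' survival (PFS medians 8.9 / 9.7 / 11.0 months; OS median
27.1 months for camrelizumab, not reached within follow-up for the other
two arms) and prices every model input from the published cost and
adverse-event tables:

```r
library(pd1cea)
cfg <- default_config()
run <- cea_run(cfg, out_dir = "results")   # simulate -> reconstruct -> fit -> model -> CEA
run$cea_table
```

```
     strategy   cost  qalys delta_cost delta_qalys   icer dominance on_frontier frontier_icer
   sintilimab 268919 1.2958         NA          NA     NA      none        TRUE            NA
  toripalimab 270222 1.2685     1302.6   -0.027302     NA    strict       FALSE            NA
 camrelizumab 316412 1.5257    47493.2    0.229966 206523      none        TRUE        206523
```

Sintilimab is the least costly strategy; toripalimab costs more and yields
no additional QALYs (strictly dominated); camrelizumab gains 0.23 QALYs at
an ICER of ~207,000 CNY/QALY — below the 287,247 CNY/QALY threshold, so
`check_wtp_decision()` prefers camrelizumab. The tornado analysis is led by
the camrelizumab price, and the acceptability curves put camrelizumab at
~92 % probability of cost-effectiveness at the threshold:

```
Tornado (ICER camrelizumab vs sintilimab):
              parameter icer_low icer_high    width
 cost_drug_camrelizumab   107891    206523 98632.38
   cost_drug_sintilimab   290588    206523 84064.85
             utility_pf   246456    178345 68111.69

CEAC at the 287247 CNY/QALY threshold: sintilimab 5.6%, toripalimab 2.4%, camrelizumab 92.1%
```

The same pipeline runs as a five-stage scripted workflow with CSV/JSON
artifacts between stages:

```sh
Rscript analysis/01_simulate_trials.R    # digitized curve + risk-table CSVs
Rscript analysis/02_reconstruct_ipd.R    # Guyot pseudo-IPD + fidelity QC
Rscript analysis/03_fit_survival.R       # five-family fits, AIC/BIC selection
Rscript analysis/04_markov_cea.R         # cohort traces, costs, QALYs, ICERs
Rscript analysis/05_sensitivity.R        # tornado, PSA, CEAC (+ figures)
```

Real digitized evidence drops in at stage 2: place
`{strategy}_{endpoint}_curve.csv` (`time,survival`) and
`{strategy}_{endpoint}_risk.csv` (`time,n_at_risk`) files under
`results/curves/` instead of running stage 1.

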