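---
title: "Methods: survival-evidence reconstruction and Markov cost-effectiveness modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival-evidence reconstruction and Markov cost-effectiveness modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the modelling decisions behind `pd1cea`: the health
economic model, the statistical machinery feeding it, what the packaged
synthetic replication does and does not emulate, and the numerical
conventions a user should know before trusting or modifying results.

## The decision problem

Three PD-1 inhibitors combined with pemetrexed/platinum chemotherapy are
compared as first-line treatment for advanced non-squamous NSCLC from the
Chinese national medical insurance payer perspective. Evidence on each
regimen comes from a different phase III trial, so the comparison is
indirect: survival evidence enters as digitized Kaplan–Meier curves per arm
and endpoint (PFS, OS), is converted to pseudo individual-patient data,
extrapolated parametrically, and run through a common cohort model. Only
direct medical costs are counted (CNY); health effects are
quality-adjusted life-years.

## Markov cohort model

Three mutually exclusive states: progression-free (PF), progressive
disease (PD), death (absorbing). Everyone starts in PF; backward
transitions are not permitted. The cycle matches the 3-week dosing
schedule; with 1 month = 365.25/12 days one cycle is 21/(365.25/12) ≈
0.6899 months, and the same conversion (21/365.25 years) is used for QALY
accrual and discounting, so time units are consistent everywhere. The
default horizon of 522 cycles spans 30 years, operationalizing a lifetime
horizon; under the fitted models the surviving occupancy at the horizon is
negligible, and the horizon is configurable.

Cycle-specific transition probabilities are derived from the fitted
survival functions. With `t0 = k·Δ`, `t1 = (k+1)·Δ`:

* `q_pf = 1 − S_PFS(t1)/S_PFS(t0)` — conditional probability of leaving PF;
* `q_os = 1 − S_OS(t1)/S_OS(t0)` — conditional probability of death.

The PFS and OS marginals do not identify how PF exits split between
progression and death, so the split is a modelling convention, isolated in
one function (`cycle_transition_probs`) so alternatives can be swapped:
OS-derived mortality bounds PF deaths, `P(PF→death) = min(q_os, q_pf)`;
the remainder progresses; PD patients face the same conditional mortality
`q_os`. This construction cannot produce negative probabilities even when
fitted PFS and OS curves cross — the known failure mode of
partitioned-survival constructions — and it degrades gracefully: if the
two curves coincide, all exits are deaths. Its cost is that PD mortality
equals average cohort mortality rather than the (higher) post-progression
mortality, which biases PD occupancy slightly upward; this is a structural
assumption, stated rather than hidden.

Accrual is discrete (TreeAge-style): occupancy at the start of cycle k
earns cycle k's costs and utilities, discounted by
`(1+r)^(−k·21/365.25)` at r = 5 %/year (0–8 % in sensitivity analysis). A
half-cycle correction (averaging adjacent occupancies) is available behind
a flag and off by default. PF cycles accrue the PD-1 agent (until
progression by default; a treatment cap in cycles is configurable),
chemotherapy — pemetrexed+carboplatin for the first 4 induction cycles,
then pemetrexed maintenance until progression — and administration costs,
weighted by utility 0.804. PD cycles accrue second-line docetaxel therapy
at utility 0.321. Regimen durations are not part of the published cost
table, so the induction/maintenance convention above follows the trial
designs and is fully overridable in the configuration. Grade ≥3
adverse-event management cost enters once at model entry as
Σ incidence × unit cost, because trial-reported incidences are cumulative
whole-treatment rates — charging them per cycle would multiply-count.

## Reconstructing pseudo-IPD (Guyot algorithm)

Inputs per curve: ordered `(time, survival)` coordinates beginning at
(0, 1) and a numbers-at-risk table. Within each interval between risk
times, the algorithm alternates between (a) placing events at the
digitized step times so the running KM estimate tracks the coordinates and
(b) adjusting the interval's censoring count — censoring times spread
uniformly, the standard identifying assumption — until the implied number
at risk matches the published count. In the final interval the censoring
total is projected from the earlier intervals' censoring rate; when a
reported total event count is available, final-interval censoring is
re-adjusted until the event total matches (both code paths exist; when the
total is unreported, e.g. median OS not reached, no adjustment is done).

Conventions chosen where the published pseudocode leaves room:

* implied counts are rounded half-away-from-zero;
* negative implied counts are clamped to zero and surfaced via a `clamped`
  diagnostic flag, never silently;
* each adjustment loop is capped at 100 iterations; failure to match a
  published count raises an error naming the interval;
* a published count that is unreachable even with zero censoring
  (digitization noise) is replaced by the implied count, as in the
  reference implementation;
* risk-table entries beyond the last digitized coordinate are dropped:
  no coordinates exist there to carry events;
* survivors at the end of the coordinates are censored at the last
  coordinate time.

Every reconstruction is validated by re-estimating KM from the pseudo-IPD
and comparing against the digitized coordinates (`rmse_survival`,
`max_abs_dev`); the workflow refuses scenarios whose curves do not
round-trip within 0.02 absolute survival.

## Parametric extrapolation and model selection

Five families are fitted by maximum likelihood under right censoring
(via `flexsurv`), parameterized as: exponential (rate λ); Weibull (shape,
scale); log-normal and log-logistic by location/scale of log event time;
Gompertz by hazard `h(t) = b·exp(a·t)` with b > 0 and a unrestricted — the
common health-economics convention; a < 0 gives a defective distribution
and a → 0 recovers the exponential. Information criteria are computed from
the censored-data log-likelihood as `AIC = 2k − 2ℓ` and
`BIC = k·ln(n) − 2ℓ` with k = 1 for the exponential and 2 otherwise.

Selection policy `aic_then_bic` (default) ranks by AIC and breaks
near-ties (ΔAIC < 2) by BIC. The rationale: among these families several
nest or closely mimic one another, so AIC differences below 2 are
uninformative; BIC's stronger parsimony penalty then prefers the
one-parameter exponential unless the data genuinely demand a second
parameter. In repeated simulation this keeps the *extrapolated* curve near
truth even when the named family differs — the property that matters for
the economics. Non-converged fits are returned flagged, excluded from
selection, and refitting uses up to three perturbed starts.

## Parameter inputs and their uncertainty

All economic inputs ship in `default_config()`: per-cycle drug prices
(sintilimab 3,558; toripalimab 3,636; camrelizumab 3,558 CNY, with
negotiated-price ranges extending downward only), pemetrexed 833,
carboplatin 364, administration 6,348, second-line therapy 2,792 CNY per
cycle; unit costs for the four costed grade ≥3 adverse events
(neutropenia 818, leukopenia 818, thrombocytopenia 10,707, anemia 987
CNY) with per-strategy incidences; utilities PF 0.804 / PD 0.321; the
willingness-to-pay threshold 3 × 95,749 = 287,247 CNY/QALY (three times
the 2024 per-capita GDP).

For the probabilistic sensitivity analysis, costs get Gamma and utilities
Beta distributions, moment-matched to the published low/high ranges read
as 95 % intervals: `se = (high − low)/(2·1.96)`, Gamma
`shape = base²/se²`, `scale = se²/base`, Beta by method of moments. A
range too wide for a Beta with the stated mean degenerates to a fixed
parameter with a warning. Survival-model parameters are *not* resampled by
default: the published uncertainty ranges cover economic parameters only,
and the PSA isolates their effect conditional on the fitted curves;
survival uncertainty is structural (family choice) rather than sampling
uncertainty here, and is visible instead in the selection diagnostics.

The one-way (tornado) analysis varies the three PD-1 prices over their
asymmetric price-reduction ranges, the discount rate over 0–8 %, and
every other parameter by ±25 % (utilities clipped to [0, 1]). The
published ranges for chemotherapy, administration and second-line costs
are exactly ±25 %, so the convention is uniform in practice; for the
utilities the published literature ranges (PF 0.536–0.883, PD 0.05–0.473)
are kept for the PSA spread but deliberately not used as one-way bars: at
any plausible QALY gap those ranges would swamp the tornado (the PD range
alone spans an 8.5-fold swing), turning the diagram into a statement about
utility-study heterogeneity rather than decision-relevant price
uncertainty. The literature-range comparison is still exercised in the
test suite via `one_way_sa` with explicit specifications.

ICERs are computed on the efficiency frontier after removing strictly
dominated strategies (no cheaper, no-less-effective alternative exists)
and extendedly dominated ones (a more effective alternative has a lower
incremental ICER); the threshold decision walks the frontier and returns
the most effective strategy whose step ICER is within willingness-to-pay.
CEAC probabilities are the fraction of PSA iterations in which a strategy
attains the highest net monetary benefit `wtp·QALYs − cost`, with exact
ties split equally so the probabilities always partition to one.

## The synthetic replication scenario

The packaged scenario exists so the full chain — digitization artifacts
included — runs end-to-end with known ground truth. It emulates: three
arms with exponential event times calibrated to the trials' PFS medians
(8.9 / 9.7 / 11.0 months); OS median 27.1 months for camrelizumab with 30
months of follow-up (median reached, as reported); latent OS medians 23
and 21 months for sintilimab and toripalimab with administrative censoring
at 18 months, so their observed medians are *not reached* — matching the
primary publications — while the latent values are consistent with
subsequently reported mature estimates from those trials. Risk tables are
printed every 3 months, the typical spacing of published figures.

Choices a user should understand:

* **Arm size 5,000.** The replication isolates the designed economic
  structure from trial sampling noise (at trial-scale n ≈ 300 the
  between-arm median gaps that drive the QALY difference have sampling
  error of the same order as the gaps themselves). Trial-scale behaviour
  is exercised separately throughout the test suite at n = 300.
* **Digitization fidelity scales with the curve.** Coordinates are thinned
  to 1,000 points selected at equal arc length along the step path —
  emulating curve-following extraction, which clicks true step corners and
  concentrates points where the curve moves — with Gaussian y-jitter
  (sd 0.002) clipped and re-monotonized by cumulative minimum. Density
  must scale with the information in the figure: a digitization much
  coarser than the underlying steps makes digitization error, not
  sampling error, the dominant error term, and at large n that systematic
  error (not statistical noise) starts to decide AIC model selection. For
  trial-scale arms 120 points resolves essentially every visible step and
  is the default used in the tests.
* **Censoring is administrative only** (optional exponential dropout is
  available, default 0). Real trials censor for other reasons; the
  uniform-censoring assumption inside the Guyot algorithm is therefore
  *exactly* wrong within intervals here, which makes the round-trip checks
  conservative rather than flattering.
* **What passing does not show.** The synthetic scenario cannot validate
  the indirect-comparison assumption (a common cohort model applied to
  single-arm evidence from different trials), the choice of latent OS for
  arms whose median was not reached, or any real-world cost or adherence
  pattern. It validates the *machinery*: reconstruction fidelity,
  estimation, model selection, probability coherence, accounting
  identities, and the qualitative decision structure.

## Numerical conventions and degenerate inputs

* Occupancy rows must sum to 1 within 1e−12 and dead occupancy must be
  non-decreasing; violations are errors, not warnings.
* Chaining the conditional per-cycle exit probabilities telescopes back to
  the fitted survival function to 1e−9 over the full horizon (exactly, for
  the memoryless exponential) — this identity is asserted in tests.
* A survival function that reaches zero makes the state absorbing into
  death from that cycle on, flagged in the transition grid.
* `S(0) = 1` is enforced for the log-time families; Gompertz uses `expm1`
  and an explicit `|a| < 1e−12` exponential limit.
* Fit convergence tolerance is the optimizer default (1e−8 scale);
  likelihood ties in selection resolve by BIC, then first-listed family.
* Empty records, zero events, negative times, rising survival, rising
  risk counts, and risk times outside the coordinate span are all rejected
  at construction with specific messages.
* All simulation entry points take explicit seeds and restore the
  caller's RNG state; reruns are bit-identical.

## Problem sizes used in the checks

The test suite works at: n = 300 (trial-scale round trips), n = 5,000
(parameter recovery, 10 seeds per family), n = 10,000 with 100 replicates
(model-selection stability — the size at which the required 0.01
sup-distance guarantee is statistically attainable, since the sup-norm
error of a fitted exponential is ≈ 0.37/√events), 10,000 PSA iterations on
the packaged scenario, and 522-cycle horizons throughout.

## Known limitations

* The PF→PD/death split and PD mortality are conventions, not estimates;
  alternative constructions (e.g. independent post-progression survival
  evidence) would change PD-state costs and QALYs.
* Extrapolation rests on a single selected family per curve; structural
  survival uncertainty is only partially visible in AIC/BIC tables, and
  long-horizon results inherit it.
* Adverse events carry costs but no disutilities or timing; second-line
  therapy is costed as a flat per-cycle amount without its own survival
  effect.
* The indirect comparison inherits cross-trial differences in populations
  and follow-up that no amount of reconstruction removes.
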