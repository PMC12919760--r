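---
title: "A Markov cohort model for adjuvant T-DM1 in residual HER2+ early breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for adjuvant T-DM1 in residual HER2+ early breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdm1cea)
```

## The decision problem

Patients with HER2-positive early breast cancer who retain residual
invasive disease after neoadjuvant therapy face a high risk of recurrence.
Adjuvant trastuzumab-emtansine (T-DM1) roughly halves the hazard of
invasive disease or death relative to trastuzumab, at a much higher
acquisition cost. Whether the upfront cost is offset by avoided
recurrences — metastatic disease being several times more expensive to
manage than early disease — is the economic question this package models,
from a health-system perspective in 2024 US dollars with a
willingness-to-pay threshold of US$6831 per QALY.

## Model structure

`state_space()` defines six clinical states over an expanded
18-compartment space:

* residual invasive disease, split into **on-treatment** and
  **off-treatment** profiles (same transition risks; different costs and
  utilities). The cohort starts 100% on treatment and switches off after
  the adjuvant phase;
* **non-metastatic recurrence**, implemented as a 12-compartment monthly
  tunnel: patients who survive 12 months of recurrence treatment move to
  remission automatically. Within the tunnel only background mortality
  applies, and there is **no edge to first-line metastatic disease** — the
  trial that informs the transitions classified metastatic spread within
  two months of a locoregional event as a metastatic first event, so no
  data support that conditional transition;
* **remission**, with a monthly probability of 0.0076 of progressing to
  first-line metastatic disease;
* **first-line** and **later-line metastatic disease** (1L/2L+ mBC), with
  arm-specific monthly progression probabilities, because the metastatic
  regimens available depend on prior adjuvant exposure;
* **death**, absorbing.

Cycles are monthly (one year is exactly 12 cycles), the horizon is 48
years (to age 100 from baseline age 52), and payoffs use the trapezoidal
half-cycle correction: effective occupancy in cycle $k$ is the average of
the start- and end-of-cycle rows. Discounting is $(1+r)^{-k/12}$ with
$r = 0.05$ for both costs and effects.

Background mortality comes from a packaged synthetic life table —
Gompertz-like annual probabilities $q(a) = 0.0005 + 0.003\,e^{0.095(a-52)}$,
increasing to age 100 — because no national source is prescribed for this
model; it is user-replaceable via `read_life_table()`. Annual
probabilities convert to monthly as $1-(1-q)^{1/12}$ and combine with
every disease risk as independent competing risks,
$1-(1-p_a)(1-p_b)$. Row sums exceeding 1 by more than $10^{-9}$ are an
error; smaller excess (floating-point noise) is renormalized.

## Survival extrapolation

Invasive-disease-free survival is extrapolated with a mixture-cure model,

$$S(t) = \pi + (1-\pi)\,S_{\text{lat}}(t),$$

where a fraction $\pi$ of patients is cured (subject to background
mortality only — the cure fraction never shields anyone from all-cause
death, which is added at the model-assembly layer) and the remainder
follows a standard parametric latent distribution. Four latent families
are supported (exponential, Weibull, log-normal, log-logistic);
`fit_mixture_cure()` maximizes the likelihood in which events contribute
$(1-\pi)f_{\text{lat}}(t)$ and censored records
$\pi + (1-\pi)S_{\text{lat}}(t)$, using a deterministic bounded multistart
(cure-fraction starts 0.1/0.5/0.9 on the logit scale, latent starts from
event-time moments, objective tolerance $10^{-8}$ via `nlminb`), so
refitting identical data is bit-identical. Data with no events sit on a
likelihood ridge; the fit then reports the boundary solution $\pi = 1$
with a flag rather than an arbitrary interior point.
`rank_by_information_criteria()` orders fits by AIC with BIC alongside,
breaking ties by parsimony and then a fixed family order.

The **base case is parameterized analytically** rather than from a
particular simulated dataset: the control curve's cure fraction is solved
from the published control disease-free survival anchor (71.11%), and the
treated curve applies the hazard ratio 0.54 to the latent hazard
($S_{\text{lat}}^{0.54}$) with its own cure fraction solved from the
treated anchor (85.58%). The anchor timepoint is **assumed to be 84
months** (the trial's follow-up); the source analysis does not state it.
The latent distribution is log-normal with meanlog 2.5 and sdlog 0.8 — a
median latent recurrence time of about a year with a long right tail,
plausible for post-neoadjuvant relapse kinetics; this, too, is an
assumption, since the fitted parameters behind the published model are in
unpublished supplementary material. The simulate-fit-select chain in
`analysis/01`-`02` demonstrates that the estimation machinery recovers
such parameters from trial-sized data and selects the log-normal family
by both criteria.

Survival converts to per-cycle exit probabilities as
$p_k = 1 - S((k+1)\Delta)/S(k\Delta)$. Disease-free exits split into
locoregional recurrence, metastatic disease, and death with **destination
shares 0.25/0.60/0.15** — an assumption (the event composition behind the
published reductions is not printed), shared by both arms, which makes the
modeled locoregional and metastatic relative reductions coincide by
construction (the published ones differ: 64% vs 49% at 3 years).

### Treatment-effect waning

The full effect persists to month 84, is absent from month 120, and wanes
in between. `effective_hazard_ratio()` interpolates **log-linearly in the
HR** (continuous, positive, standard HTA practice; a linear-in-HR mode is
available). In the assembled model the treated arm's per-cycle hazard is
blended with the control hazard,
$h_w = h_{\text{trt}}^{\,w}\, h_{\text{ctl}}^{\,1-w}$ with $w$ falling
from 1 at month 84 to 0 at month 120 — exactly the log-linear
interpolation of the arms' (time-varying) hazard contrast — so both arms'
disease-free exit hazards are identical for every cycle from month 120
on.

## Costs and utilities

Costs enter as five components per state: acquisition, administration,
diagnostics, adverse events (only an additional complete blood count in
the T-DM1 arm), and supportive care. Dosing is weight-based at the
reference 67 kg: 14 administrations of 3.6 mg/kg T-DM1, or 6 mg/kg
trastuzumab with an 8 mg/kg loading dose; cost is linear in milligrams at
the price per minimum concentration unit (no vial wastage). Fourteen
administrations every 21 days span roughly nine months, so treatment-phase
costs are spread over the **first 10 monthly cycles** (configurable),
after which residual-state occupants carry the off-treatment profile.

The published analysis prints discounted per-arm mean costs per state and
component, but not the monthly unit costs behind them.
`calibrate_cost_inputs()` therefore **back-solves** each monthly unit cost
by dividing the printed component mean by the arm's discounted effective
occupancy on the relevant basis. The calibration is per arm because the
metastatic-line regimens — and hence drug-inclusive monthly supportive
costs — differ with prior adjuvant exposure. These values are tagged
`calibrated` in the bundle's provenance table, and by construction the
model reproduces the printed component table; the drug price per mg and
the blood-count unit cost are derived from the same calibration. The
arm-to-metastatic-regimen mapping (which published monthly progression
probability applies to which arm and line) is likewise an `assumption`
flag in the bundle.

Utilities are state-constant (0.77 on-treatment residual, 0.78
off-treatment, 0.77 recurrence, 0.78 remission, 0.77 1L mBC, 0.52 2L+
mBC, 0 death). QALYs accrue as
$\sum_k \sum_s \text{occ}_{\text{eff}}(k,s)\,u(s)\,d(k)/12$; life-years
use $u \equiv 1$ for alive states, so QALYs never exceed life-years.
`incremental_summary()` labels a comparison *Dominant* when it saves money
and gains QALYs, *Dominated* in the mirror case, and otherwise reports the
ICER against the threshold; the identity NMB $= \Delta E \lambda - \Delta C$
holds to $10^{-9}$ on every emitted comparison.

## Uncertainty analysis

The PSA follows the published distributional choices: **gamma** for
utilities (sampled, then truncated at 1 with truncations counted — gamma
support exceeds 1, an unusual but deliberate mirroring of the source's
stated choice instead of the conventional beta), **log-normal** for
administration, adverse-event and supportive-care costs, and a **normal
on the log-HR scale** (the 1-dimensional multivariate normal) for the
treatment effect. All distributions are moment-matched from a mean and a
standard error. The SEs are not reported in the source; defaults are 20%
of the mean for costs and 10% for utilities, exposed in `bundle$psa` and
echoed by every report. Per-arm cost parameters are sampled
independently — a conservative choice that widens the incremental-cost
cloud relative to sampling shared unit costs, so the modeled dominance
probability is sensitive to these conventions and should be read
qualitatively. Draws that fail the model run are counted and excluded,
never silently dropped. The CEAC reports, per threshold, the fraction of
draws with positive NMB.

The one-way analysis (`one_way_dsa()`) varies each parameter to its
bounds with all others at base and reports the NMB swing; default ranges
(±20% for weight, prices, probabilities and cost components, ±10% for
utilities, 0–10% for the discount rate) are fixture assumptions.

## Synthetic trial data

`simulate_trial_ipd()` emulates the pivotal adjuvant trial: 743 patients
per arm, control event times from the mixture-cure model, treated latent
hazards scaled by HR 0.54, administrative censoring at 101 months (the
8.4-year follow-up), and cure fractions either given directly
(`hr_only` mode) or calibrated to the published 84-month anchors
(`anchor` mode, the default). All randomness flows through a single
integer seed; reruns are bit-identical. The generator reproduces the
mixture-cure *structure* the analysis assumes — it does not emulate
staggered accrual, dependent censoring, event-type-specific treatment
effects, or covariate heterogeneity, so passing tests show parameter
recovery and internal consistency, not real-world validity.

## Numerical choices and validation

* Cohort traces conserve probability mass to $10^{-10}$ over all 576
  cycles, checked on every run; death occupancy is monotone.
* The deterministic engine is validated against an individual-level
  micro-simulation oracle (50,000 simulated patients) within binomial
  Monte-Carlo error on randomized instances, and against closed forms
  (geometric survival, discounted life expectancy) to $10^{-9}$.
* Parameter recovery: across 50 seeded replicates at 2000 patients per
  arm, the median absolute error of the fitted cure fraction is within
  0.03 and the log-normal family wins both information criteria in at
  least 90% of replicates (these are the test suite's acceptance
  properties; the replication sizes were chosen to keep the whole suite
  under a minute while leaving Monte-Carlo error well below the margins
  tested).
* AIC/BIC stored on fits always match recomputation from the
  log-likelihood to $10^{-9}$.

## Known limitations

* The exact published totals (ΔE = 1.02 QALYs, ΔC = −US$3192) are not
  reproducible from printed inputs alone — the fitted survival parameters
  and per-cycle cost decompositions live in unpublished supplementary
  material. With the assumptions above, the model lands close
  (ΔE ≈ 1.05, ΔC ≈ −US$3092, dominant) and all printed component
  increments are reproduced by calibration.
* Common destination shares make locoregional and metastatic reductions
  equal; the published values differ.
* The dominance probability from the PSA depends on unreported SEs and
  the per-arm cost-sampling convention; the qualitative conclusion
  (dominant in well over half the draws, probability of cost-effectiveness
  rising with the threshold) is stable.
* Adverse events beyond the additional blood count, second-line
  effectiveness differences, and societal costs are out of scope, as in
  the source analysis.
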