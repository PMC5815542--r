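---
title: "A Markov cohort cost-utility model for intermittent catheterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for intermittent catheterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathcea)
```

## The decision problem

Most people with a spinal cord injury (SCI) develop detrusor sphincter
dyssynergia and must empty the bladder by intermittent catheterisation (IC),
typically 4–6 times a day, for the rest of their lives. The dominant
complication is recurrent urinary tract infection (UTI), and in Brazil —
where first-line treatment is ciprofloxacin — a substantial fraction of
episodes are antibiotic-resistant. Two catheter technologies compete:
cheap uncoated PVC catheters that need manually applied lubricant, and
pre-lubricated hydrophilic-coated catheters that cost roughly eight times
more per month but carry a lower UTI risk.

`cathcea` implements the full decision-analytic pipeline for comparing the
two from the public-payer perspective: evidence pooling, a Markov cohort
engine, economic accumulation, incremental cost-effectiveness analysis and
deterministic one-way sensitivity analysis. Everything runs from packaged
or synthetically generated inputs, so every stage is testable offline.

## Evidence synthesis

Four randomised comparisons (one row per arm in
`catheter_trials()`) provide the UTI evidence. For each arm the monthly
rate is the directly reported UTIs per patient-month where available, or
total incidence divided by follow-up months otherwise. Per-study relative
risks (hydrophilic over PVC monthly rates) are pooled by a patient-weighted
mean with hydrophilic-arm sizes as weights,

$$\widehat{RR} \;=\; \frac{\sum_i RR_i\,N_i}{\sum_i N_i},$$

and the PVC arms' rates are pooled the same way with PVC-arm sizes, giving
the baseline monthly UTI probability of the model. The default pooling mode
rounds per-study RRs to two decimals before weighting, which is how the
published computation behaved; `rr_mode = "exact"` pools unrounded ratios
(both display as 0.84 on the packaged data).

```{r evidence}
ev <- pool_evidence(catheter_trials())
ev
glance(ev)
```

Two cells of the packaged table deserve a note. One study's follow-up was
reported as a 3–6 month range; it is stored as the midpoint but never used,
because that study reports its monthly rates directly. Those stored rates
carry a third decimal (0.478/0.479) recovered from the published
patient-weighted column: the displayed two-decimal cells (0.48/0.48) are
internally inconsistent with that column, and only the three-decimal values
reproduce the pooled 62.48% exactly. Display rounding everywhere uses
round-half-up, matching how the printed tables were rounded.

## State space and transitions

The cohort model has twelve alive states — three renal stages
(no impairment, significant impairment, renal failure) crossed with four
UTI levels (no UTI, UTI treated first-line, resistant to first line,
resistant to second line) — plus one absorbing dead state. Cycles are
monthly, from entry (age 36, 80% male) until extinction of the cohort.

Within a cycle, from any alive state:

1. **Death** occurs with the state's adjusted probability (below).
2. **Renal progression** moves survivors forward (never backward) with
   monthly probabilities that were never published for this cohort; they
   are exposed as config parameters with order-of-magnitude placeholder
   defaults (0.0004 and 0.0029 per month) and every packaged acceptance
   quantity is independent of them.
3. **UTI level is redrawn** from `uti_branch_probs(p, r1, r2)`:
   no UTI with probability $1-p$; a first-line-treatable episode with
   $p(1-r_1)$; first-line-resistant with $p\,r_1(1-r_2)$; resistant to both
   oral lines with $p\,r_1 r_2$. A UTI episode therefore lasts exactly one
   cycle and resolves — the simplest structure consistent with every cycle
   carrying the same UTI risk regardless of history or renal stage.

The baseline monthly UTI probability is the pooled PVC value 0.6248, used
*directly* as a probability even though it was derived as an event rate
(one trial arm exceeds 2.6 events/month, so the two notions differ); this
mirrors how the published input table labels the value. Setting
`rate_to_prob = TRUE` applies $1-e^{-r}$ instead. The hydrophilic arm
multiplies the UTI probability by the pooled relative risk (0.84) and the
other event probabilities by 0.90, capped at 1.

**Overlay events.** Bladder stones, kidney stones, urethral injury and
urosepsis are modelled as expected per-cycle event counts on the alive
states (at-risk mass at the cycle start times the arm-adjusted monthly
probability), not as Markov states — the state space is renal × UTI only.
They carry costs and utility decrements; urosepsis additionally feeds
mortality (next section).

## Mortality

Background mortality comes from an annual life table, converted to a
monthly probability with $p = 1-(1-q)^{1/12}$ and looked up at the cohort's
current integer age. Condition-specific excess mortality is applied on the
hazard scale,

$$q' = 1 - \exp\{-h\,(1 + m)\}, \qquad h = -\log(1-q),$$

so a multiplier of $m=0$ reproduces background mortality exactly, and
multipliers for co-occurring conditions add in $m$ (additive excess hazard
avoids multiplicative explosion at the very large multipliers involved).
Three sources contribute to each alive state's $m$:

* **Renal stage**: 18 (significant impairment) or 54 (renal failure).
* **UTI level**: in the default `"weighted"` mode, every active-UTI state
  carries the resistance-weighted multiplier
  `weighted_uti_multiplier(145.27, 0.34)` ≈ 49.39 — the expected multiplier
  over an episode given that only resistant episodes (34%) carry excess
  mortality. In `"state_specific"` mode the first-line state carries 0 and
  the two resistant states carry 145.27. Weighted mode is the default
  because the published input table lists the weighted value as a model
  input; for the same reason `m_uti_weighted` is an independent parameter
  and is deliberately *not* recomputed when `r1` is varied in sensitivity
  analysis (doing so would make the ICER swing by ~20% with `r1`, which
  contradicts the near-flat published sensitivity of the ICER to the
  resistance level).
* **Urosepsis**: the event is an overlay, not a state, so its multiplier
  (797.6) enters as expected excess hazard, `p_urosepsis × 797.6`, for
  every alive state. Whether the original analysis applied it per event or
  per state is unknowable from the outside; the per-event expectation is
  this package's documented choice.

## Cycle accounting

The package uses the mid-period convention throughout: deaths are assumed
to occur, on average, halfway through the monthly cycle. Concretely, each
cycle's accrued occupancy is the mean of the adjacent cycle-boundary rows,
and discounting evaluates at the cycle midpoint. This makes the engine
exactly consistent with `life_expectancy()`, which uses the same
convention: with all disease parameters zeroed, undiscounted model LYG
equals the life-table remaining expectation to machine precision (the test
suite asserts 0.01-year agreement). Start-of-cycle ("spreadsheet")
accounting is available via `model_parameters(accrual = "start")`; it
overstates person-time by half a cycle (~0.04 years) relative to the
mid-period expectation, which is why it is not the default.

## Economics

Costs (2016 BRL, public-payer perspective) comprise monthly consumables
(PVC: catheter 74.27 + lubricant 132.75 at the reference 2 tubes/day,
scaling linearly in `tubes_per_day`; hydrophilic: 608.27), per-event
treatment costs, and monthly costs of the impaired renal states. Each UTI
episode incurs the treatment cost (554.16) plus one pooled antibiotics
course (60.50) regardless of line — the input schedule prices antibiotics
once, with parenteral third-line treatment folded into the event cost.
(Published payer estimates for a UTI hospitalisation episode circulate both
near 525.60 and at 554.16; the declared input-table value 554.16 is used.)

Utilities start from a baseline `u0` and subtract decrements while a state
or event applies. **The cohort's baseline utility was never published**:
the default `u0 = 0.50` is a package assumption, flagged as such in
`config_schema()`, and no packaged acceptance quantity depends on it. State
decrements (UTI 0.060, resistant UTI 0.104, significant impairment 0.155,
renal failure 0.250) apply per cycle spent in the state; event decrements
(stones 0.050, urethral injury 0.104, urosepsis 0.160) apply for one cycle
per expected event; per-state utility is floored at 0.

Costs, QALYs and LYG are discounted at 5%/year
($(1+r)^{-t/12}$ at cycle $t$); UTI counts are never discounted. Male and
female cohorts run separately against sex-specific life tables and are
mixed 80/20 at the outcome level — blending outcomes, not mortality tables.

```{r basecase}
res <- run_cea()
res
```

The incremental analysis reports Δcost/ΔQALY, Δcost/ΔLYG and Δcost per UTI
avoided from full-precision deltas, classifies dominance, and flags
cost-effectiveness against the 147,000 BRL/QALY willingness-to-pay
threshold estimated for Brazil. The secondary analysis
(`analysis = "secondary"`) zeroes the four overlay events so UTI is the
only complication, a preset mirroring the published secondary scenario.

## Synthetic life tables

The original mortality input (the national 2014 period life table) is not
redistributable, so the package generates Gompertz–Makeham stand-ins:
$q(x) = 1 - \exp\{-(a + b c^x)\}$ with a terminal age of 110. The frozen
defaults (male $a=1.2\times10^{-3}$, $b=10^{-4}$, $c=1.085$; female
$a=5\times10^{-4}$, $b=5\times10^{-5}$, $c=1.090$) give life expectancy at
birth of about 72.2 and 78.7 years, emulating the Brazilian 2014
sex-specific pattern. They are a calibrated stand-in, not a reproduction:
real Brazilian mortality has a pronounced young-adult (external-cause) hump
that a Makeham constant only crudely approximates. Consequently the
pipeline reproduces the *structure* and *orderings* of the published
results (directions of all deltas, DSA orderings, magnitudes of the ICERs)
rather than their exact values, which also depend on unpublished renal
progression rates and the unpublished baseline utility.

`simulate_trial()` complements the tables with Poisson per-patient UTI
counts for exercising the evidence stage; it emulates count sampling only
(no dropout, no overdispersion, no per-patient frailty), so passing tests
demonstrate internal consistency of the pipeline, not agreement with any
real trial.

## Validation strategy

Three independent oracles guard the engine:

* **Life-table oracle**: brute-force monthly survival products verify
  `life_expectancy()`, and the zero-disease cohort must reproduce both the
  background survival curve and the life-table expectation.
* **Enumeration oracle**: the transition matrix is checked element-wise
  against an independent expansion of the death/renal/UTI branching tree,
  plus row-stochasticity to 1e-12.
* **Microsimulation oracle**: `run_microsim()` samples individual patient
  paths under identical rules and accumulates the same economics; the
  cohort trace must agree within 3 Monte-Carlo standard errors on cost,
  QALYs, LYG and UTI count (the acceptance suite uses 20,000 patients;
  unit tests use 4,000).

Numerical conventions worth knowing: cohort extinction is declared when
alive mass falls below 1e-9; occupancy conservation is asserted at 1e-9
per cycle; the life-table writer emits 12 significant digits, which
round-trips bit-exactly through its reader; displayed values use
round-half-up while all internal arithmetic is full precision.

## Sensitivity analysis

`run_one_way()` re-runs the pipeline varying exactly one parameter per
scenario (enforced), with the default scenario set covering lubricant
tubes/day {1, 4}, first-line resistance {0.165, 0.45} (the published
"16%" scenario is the text's 16.5%), and the hydrophilic UTI reduction
{26%, 53%} (relative risks 0.74, 0.47). `tornado_order()` ranks scenarios
by absolute ICER deviation; `autoplot()` draws the tornado. The expected
pattern — strong sensitivity to lubricant use and to the treatment effect,
near-insensitivity to the resistance level — is asserted by the test
suite.

## Problem sizes

The shipped configuration runs cohorts of 13 states over at most 888
monthly cycles (entry at 36, terminal age 110), four cohort runs per
pipeline (2 arms × 2 sexes), seven pipeline runs per DSA, and a 20,000 ×
~900-cycle microsimulation in the acceptance suite; the whole test suite
completes in well under a minute on a single core. These sizes are the
package's defaults and can be shrunk via shorter life tables for quick
experiments.

## Known limitations

* Renal progression probabilities and baseline utility are assumptions;
  absolute QALY and cost levels inherit that uncertainty (orderings and
  oracle agreements do not).
* The synthetic life tables approximate period mortality without
  cause-of-death structure.
* UTI episodes are memoryless one-cycle events: no chronic or recurrent
  UTI states, no within-episode duration.
* Indwelling catheters, urostomies, urethral stricture as a persistent
  state, and hospital-acquired resistance dynamics are out of scope, as is
  probabilistic sensitivity analysis.
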