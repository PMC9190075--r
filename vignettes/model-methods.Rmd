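---
title: "Methods: the antenatal depression screening cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the antenatal depression screening cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antescreen)
```

## The decision problem

The model compares four ways of identifying depression among women at their
first antenatal appointment — the Whooley questions, the EPDS, the Whooley
followed by the EPDS for Whooley-positives, and routine midwife assessment
without an instrument — on expected QALYs and expected costs per woman over
a nine-month horizon (booking to three months post-birth). The perspective
is the NHS and Personal Social Services; no discounting is applied (the
horizon is under a year).

The structure is a decision tree with two stages:

1. **Screening node.** Each strategy's accuracy block gives the marginal
   probability of a positive screen and the conditional probabilities that a
   positive is a true positive and that a negative is a true negative. The
   tree never stores both members of a complementary pair: the second is
   always computed as one minus the first. (The source tables print both,
   and rounding makes some pairs sum to 1.0001; deriving complements keeps
   every node exactly normalised.) The two-stage strategy has its own block:
   only stage-1-positive *and* stage-2-positive women screen positive, and
   the two screen-negative groups (stage-1 negatives; stage-1
   positive / stage-2 negative) carry separate true-negative probabilities.

2. **Treatment pathway**, identical for all strategies. Screen-positives
   are treated: facilitated self-help with probability 0.7921, otherwise a
   high-intensity psychological intervention, responding with probability
   1 − RR·AR (RR 0.73 and 0.48 respectively; AR 0.67), i.e. 0.5109 and
   0.6784. Responders take the depressed→non-depressed nine-month QALY
   trajectory; non-responders the depressed→depressed one. False positives
   keep the well trajectory and consume a fraction (default 20%) of the
   treatment cost before their status is recognised. False negatives
   spontaneously recover with probability 0.33 (midpoint of the 25–40%
   range reported for untreated controls); otherwise they are identified
   later within the horizon with probability 0.1025 (a 41%-over-36-months
   detection rate rescaled linearly to 9 months) and then treated exactly
   like true positives — same response probabilities, full treatment cost,
   no penalty for the delayed start — or they remain depressed and
   untreated. Women who recover spontaneously receive the non-depressed
   other-care cost and the depressed→non-depressed trajectory. These two
   assignments for false negatives are not spelled out by the source
   tables, but they are the only ones that reproduce the published per-arm
   means, and we adopt them as the model's definition.

Every woman in an arm incurs that arm's screening cost, including the
no-screen "mental-health conversation" (3 midwife minutes, £7.95). The
two-stage screening cost is itself derived: stage-1 cost plus the stage-2
cost weighted by the stage-1 positivity rate (£4.53 + 0.0895 × £9.38 ≈
£5.37).

## Parameters and their uncertainty

All defaults are returned by `default_parameters()` and can be overridden
through a flat YAML tree (`load_parameters()`, `dump_default_config()`);
unknown keys are hard errors, because a silently ignored typo in a scenario
override would corrupt results. Derived parameters (the two response
probabilities, later identification, the weighted two-stage screen cost)
are recomputed after any override of their sources unless set explicitly.

Sampling distributions follow the source tables' declarations:

* **Probabilities** — beta, with the first shape parameter equal to the
  weighted event count behind the estimate and the second solved from the
  mean (`beta_from_probability()`). This reproduces both the point estimate
  and the information content; re-centred parameters (scenarios,
  configuration overrides) keep their effective sample size.
* **Costs** — gamma by method of moments with SE = 30% of the mean
  (`gamma_from_mean_se()`); note the shape is then 1/0.09 ≈ 11.1 for every
  cost.
* **QALY trajectories** — beta on [0, 1] by method of moments from
  (value, 0.30 × value). The source prints symmetric 95% intervals whose
  upper limits exceed 1, which no distribution on [0, 1] can honour; the
  declared "beta with 30% SE" is implemented and the printed intervals are
  treated as a normal approximation.
* **Health-state utilities** (ante/postnatal, depressed/not) do not enter
  the tree — the printed nine-month trajectories do — so they are carried
  only for scenario 5's rescaling and are not sampled. The trajectories are
  used exactly as printed because no simple area-under-curve construction
  with obvious segment durations reproduces them from the utilities; the
  original transition-timing assumption is unstated.

One extraction ambiguity is worth recording: the two-stage block's
"true positive given both positive" estimate (0.7500) is printed with an
event count of 8460, which is large relative to the stage-2-positive
denominator, but it is exactly the count its printed 95% interval
(0.741–0.759) implies, so it is used as the beta's effective event count.

## Deterministic outputs and reporting conventions

`evaluate_all()` returns the four arm means; `incremental_vs_reference()`
and `dominance_frontier()` implement pairwise ICERs and the
dominance / extended-dominance frontier (sorted by cost; strictly dominated
arms removed; interior arms removed while adjacent incremental ICERs fail
to increase strictly). Exact (cost, QALY) ties are kept on the frontier and
flagged.

ICERs support two conventions. The library default divides full-precision
deltas. The `"rounded"` convention rounds the incremental cost to whole
pounds and incremental QALYs to four decimals first — the convention under
which the published ICERs are the ratios of their published deltas. With
incremental QALYs of order 0.0001–0.005, a single unit in the last printed
digit moves such a ratio by anything from 2% to 50%, so reported ICERs at
this scale should be read as order-of-magnitude statements; both
conventions are exposed to make the choice explicit.

Costs are reported in whole pounds and QALYs to four decimals in the
human-readable tables; CSVs keep full precision.

## Probabilistic sensitivity analysis

`run_psa()` propagates parameter uncertainty by Monte Carlo. Two structural
choices deserve explanation:

* **Vectorised evaluation.** Draws form a table (one row per iteration, one
  column per parameter) and the tree algebra is evaluated on whole columns.
  A property test pins each row to `evaluate_arm()` on the corresponding
  single-draw parameter set, so vectorisation is purely an implementation
  detail.
* **Independent draws per arm (default).** Each arm's simulated
  cost-outcome pairs come from its own draws of *all* parameters, as in
  trial-based net-benefit bootstraps. The alternative — one draw of the
  shared treatment/QALY/cost parameters reused by every arm
  (`common_draws = TRUE`) — makes arm differences almost deterministic
  functions of the accuracy draws: the cheapest arm then wins nearly every
  iteration at low willingness to pay and the pairwise cost-effectiveness
  planes collapse into two quadrants. The published analysis this model
  follows describes the opposite behaviour (all four options similarly
  likely to be cost-effective at λ = 0; scatter roughly equal across all
  four quadrants), which the independent-draw structure reproduces, so it
  is the default.

`ceac()` computes, per willingness-to-pay value, each arm's probability of
attaining the maximal net monetary benefit; exact ties split equally, so
each row sums to one by construction. The default λ grid is £0–£50,000 in
£1,000 steps, covering the NICE £20,000–£30,000 band. `ce_plane()` gives
per-iteration incremental pairs, and `convergence_check()` reports the CEAC
drift between the final cumulative blocks (a binomial-noise-scale check
that 5,000 iterations suffice).

## Sensitivity scenarios

`builtin_scenarios()` defines the thirteen one-way analyses as declarative
overrides; `apply_scenario()` is pure (the base object is never modified)
and re-centres the overridden distributions under the same dispersion
rules. Choices made where the definitions left room:

* **1a/1b** — the no-screen block is replaced by GP-detection probabilities
  (positive 0.25; true positive given positive 0.40; true negative given
  negative 0.8667) and the contact cost by £31 (1a) or £0 (1b; the
  detection probabilities stay at their 1a values). The source prints
  intervals but no event counts for these, so beta effective sample sizes
  are recovered from the intervals by normal-approximation moment matching
  (`effective_n_from_ci()`). The replacement block implies a higher
  depression prevalence than the base-case blocks (it comes from a
  different population); it is used as printed, consistent with the
  analysis it reproduces.
* **2a/2b** — interpreted as *all* treated women receiving the single
  modality (p = 1 or 0). A narrower reading (only the moderate-severity
  women reallocating) would need the mild/moderate/severe split, which is
  not reported.
* **4** — the 2% quality-of-life decrement applies to false positives only,
  via a multiplier on their (otherwise well) QALY; the base case keeps the
  multiplier at 1.
* **5a/5b** — the depressed-state utilities move ±15%, and the two
  depressed trajectories are rescaled by the ratio of an area-under-curve
  proxy (six months at the antenatal utility plus three months at the
  postnatal one) at adjusted versus base utilities. Because both depressed
  utilities scale together, the depressed→depressed trajectory scales by
  exactly ±15%; the depressed→non-depressed trajectory mixes depressed and
  recovered time, so only its antenatal (depressed) component is moved —
  a flagged approximation, since the original utility→QALY mapping is
  unrecoverable.
* **7a** sets spontaneous recovery to zero, which makes the corresponding
  beta degenerate; degenerate distributions (mean 0 or 1, or zero SE) are
  sampled as constants throughout.

`run_scenarios()` runs the base case plus any subset, with one seed shared
across scenarios (common random numbers). The per-scenario PSA uses the
same 5,000 iterations as the base case: the vectorised engine runs all
thirteen in about two seconds, so no scaled-down iteration count is needed,
and at materially fewer iterations the closest scenario orderings (the
utility-increase scenario in particular) sit inside Monte-Carlo noise.

## Synthetic cohorts and the microsimulation oracle

`derive_cohort_config()` inverts the strategy-level accuracy blocks into
per-woman quantities: prevalence and Whooley sensitivity/specificity from
the Whooley block (prevalence ≈ 0.101); EPDS accuracy *conditional on the
Whooley result* from the two-stage block (marginal independence could not
reproduce that block); EPDS accuracy among Whooley-negatives solved so the
marginal EPDS accuracy matches the EPDS block; midwife-judgement
sensitivity/specificity (≈ 0.21 / 0.98) from the no-screen block.
`simulate_cohort()` then draws women by simple random sampling — the
original survey's stratified design and weights are deliberately not
emulated (they are unpublished); the generator targets the weighted
probabilities directly. `estimate_strategy_params()` recovers each block as
observed proportions with raw counts, and `implied_strategy_accuracy()`
supplies the generator-true values recovery is judged against.

`microsimulate_arm()` walks every woman through the full tree with a
Bernoulli draw at each chance node and the same value assignments as the
analytic pathway. For the three instrument arms her outcome class comes
from her simulated screen results; the midwife-judgement arm is not
observable in the emulated survey (its source block implies a different
prevalence, ≈ 0.139), so that arm's screening node is replayed from the
strategy's analytic outcome distribution. Arm means then converge to
`evaluate_arm()` for all four strategies, which is the module's purpose.

Because the four printed accuracy blocks are only consistent with each
other to their printed precision, the cohort-implied EPDS and two-stage
blocks differ from the printed ones in the fourth decimal; the
corresponding microsimulation biases (≈ 3 × 10⁻⁵ QALYs) are an order of
magnitude below Monte-Carlo error at the cohort sizes used.

What passing these checks shows — and does not show: the generator
validates the analytic algebra and the parameter-estimation loop under the
model's own assumptions (independence of screen errors given the Whooley
conditioning, no severity structure, no time-varying onset). It does not
validate those assumptions against real perinatal data.

## Numerical choices and problem sizes

* Complements computed, never stored; outcome distributions assert
  summation to 1 at 10⁻⁹.
* Degenerate distributions sampled as constants; infeasible beta
  moment-matching (variance ≥ m(1−m)) is an error naming the parameter.
* CEAC ties split equally; probabilities sum to one exactly.
* Reproducibility: every stochastic entry point takes an integer seed;
  equal (parameters, size, seed) gives bit-identical results. Run
  manifests record command, configuration hash, seed, size and package
  version.
* Default sizes: 5,000 PSA iterations (base case and every scenario);
  cohort of 200,000 women for oracle-grade microsimulation checks and
  10,000 for exploratory runs; λ grid of 51 points.

## Limitations

The model inherits the published analysis's simplifications: no severity
strata (treatment modality is a single Bernoulli), no onset of depression
after a true-negative screen, spontaneous recovery only among false
negatives, a nine-month horizon that excludes longer-run maternal and child
outcomes, and accuracy data from a single inner-city survey. ICERs at
incremental QALYs of order 10⁻³–10⁻⁴ are printing-precision-limited (see
the conventions section); conclusions should rest on the acceptability
curves rather than any single ratio.
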