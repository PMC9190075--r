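# antescreen

Decision-tree cost-effectiveness model of screening for depression at the
first antenatal appointment.

## The problem

Depression affects roughly one in ten women in early pregnancy and is often
missed at routine maternity contacts. UK guidance suggests midwives consider
brief case-finding at the booking appointment, but the tools differ in
accuracy and burden. This package implements a decision-analytic model
comparing four strategies over a nine-month horizon (booking appointment to
three months post-birth), from an NHS and Personal Social Services
perspective:

* **Whooley** — the two Whooley questions (positive if either answered yes);
* **EPDS** — the Edinburgh Postnatal Depression Scale at a cut-off of 13;
* **Whooley–EPDS** — the EPDS administered only to Whooley-positives, with a
  positive screen requiring both;
* **no screen** — routine midwife assessment without an instrument.

It is aimed at health economists and perinatal-mental-health researchers who
want to reproduce, stress-test or re-parameterise the published analysis.

## The model

Each arm splits a cohort of women into true positive (TP), false positive
(FP), true negative (TN) and false negative (FN) fractions from the
strategy's screening accuracy. Screen-positives enter treatment (facilitated
self-help with probability 0.7921, otherwise high-intensity psychological
therapy) and respond with probability 1 − RR × AR, where RR is the
treatment's relative risk of no improvement (0.73 / 0.48) and AR the
absolute risk of no improvement untreated (0.67). False negatives
spontaneously recover with probability 0.33; failing that they are
identified later within the horizon with probability 0.1025 (41% over three
years, rescaled) and treated like true positives, or remain depressed and
untreated. Nine-month QALY trajectories (depressed→non-depressed 0.6553,
depressed→depressed 0.5991, non-depressed→non-depressed 0.7422) and 2015/16
unit costs (treatment, screening at £2.65 per midwife minute, other health
and social care of £2005/£1680 for depressed/non-depressed women) value the
pathways. Arm value per woman:

```
E[QALY] = Σ_k p_k · QALY_k ,   E[cost] = c_screen + Σ_k p_k · cost_k ,   k ∈ {TP, FP, TN, FN}
```

Strategies are compared by incremental cost-effectiveness ratios
(ICER = ΔC/ΔE) under rules of dominance and extended dominance, and by net
monetary benefit NMB(λ) = λ·E − C. A probabilistic sensitivity analysis
draws every probability from a beta (parameterised by its weighted event
count), every cost from a gamma (SE = 30% of the mean), and every QALY
trajectory from a method-of-moments beta, producing four-way
cost-effectiveness acceptability curves; thirteen one-way scenarios (1a–7b)
re-run everything under alternative assumptions. A per-woman
microsimulation of the same tree acts as a brute-force check on the
analytic expectations.

## Worked example

```r
library(antescreen)
cmd_basecase(out_dir = "basecase")
#> Mean QALYs and costs per woman:
#>      strategy mean_qaly mean_cost
#>       whooley    0.7302      1772
#>          epds    0.7305      1798
#>  whooley_epds    0.7302      1747
#>     no_screen    0.7255      1764
#> Frontier: whooley_epds -> epds
#> Excluded: whooley (extended_dominated), no_screen (dominated)
```

Per woman screened, every instrument buys a little under 0.005 QALYs
relative to routine assessment. No screening is dominated: the two-stage
Whooley–EPDS is both cheaper (fewer women reach treatment, and treatment
dwarfs screening costs) and more effective. The Whooley alone is removed by
extended dominance, leaving a trade-off frontier from Whooley–EPDS to EPDS.
The probabilistic analysis (`cmd_psa(seed = 1)`) shows how thin these
margins are: at a willingness to pay of £20,000–£30,000 per QALY each
screening arm is cost-effective in roughly a quarter to a third of
simulations against roughly a fifth for no screening.

Other entry points: `run_psa()` / `ceac()` / `ce_plane()` for the
probabilistic analysis, `run_scenarios()` or `cmd_scenarios()` for the
thirteen sensitivity scenarios, `cmd_simulate()` /  `microsimulate_arm()`
for synthetic cohorts and the microsimulation oracle, and
`inst/cli/antescreen.R` as a shell wrapper over the same functions.

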