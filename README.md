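# etkasim

A discrete daily-step simulator of deceased-donor kidney allocation in the
Eurotransplant Kidney Allocation System (ETKAS), built to ask one question:
what happens to a realistic waiting list when the serologic
histocompatibility components of the point score — the full HLA-match
priority, the match-grade points and the HLA mismatch probability (MMP) —
are replaced by T-cell epitope-score equivalents (PIRCHE-II-style)?

It is aimed at transplant immunologists and allocation-policy modellers who
want to prototype scoring changes on synthetic cohorts before touching real
registry data.

## What it simulates

* **Virtual population** — genotypes over HLA-A/-B/-C/-DRB1/-DQB1 from a
  haplotype frequency table under Hardy-Weinberg random mating
  (study-scale: 400,000 individuals).
* **Waiting list** — a 10,400-patient bootstrap with country, urgency, age,
  blood group, PRA and accrued waiting time per annual-report-style
  marginals; sensitized patients get unacceptable antigens by drawing
  non-self eplets until their population frequencies sum to the target PRA.
* **Daily chain** — Poisson departures (10.5/day), registrations
  (16.7/day) and donor arrivals (6.2 kidneys/day); each kidney runs the
  cascade: ABO identity, donor-type acceptance, virtual crossmatch,
  point scoring, tiered ranking, and a ranked offer walk with a constant
  per-candidate refusal probability of 0.1.
* **Seven scenarios** — baseline `ETKAS` plus `ETKASPIR-A` … `-F`, crossing
  the priority tier (full HLA match vs epitope score < 9), the 400-point
  match function (serologic grade vs strata `400/266/133/0`, exponential
  `400·0.958·e^(−0.032s)`, or linear `400·max(0, 1−(s+1)/90)`) and the MMP
  variant (serologic vs epitope risk-profile
  `(1 − f_bg·r·(1 − min(1, RP/200)))^20`).
* **Metrics** — risk-strata frequencies, distribution-weighted mean
  log-scores (WML, SWML = Σ WML), match-grade distributions,
  Jensen-Shannon distances, exchange/balance series, waiting-time
  summaries, Wilcoxon comparisons and a graft-survival projection.

No real registry data are bundled: deterministic generators synthesize
haplotype tables, serology maps and eplet tables with registry-like shape,
and a deterministic eplet-load surrogate stands in for the external
epitope-score service (real score exports plug in via `table_scorer()`).

## Worked example

A two-year epitope-matching run at the desk-scale profile:

```r
library(etkasim)

fx  <- fixture_set("tiny", seed = 42)
cfg <- simulation_config("ETKASPIR-E", years = 2, seed = 7,
                         demographics = default_demographics_config("tiny"),
                         fixtures = fx)
run <- run_simulation(cfg, quiet = FALSE)
#> ETKASPIR-E: 730 days, 1486 transplants, 3 discards, 2.04 transplants/day,
#> refusal fraction 0.092

tx <- post_burn_in(run, 1)              # drop the 1-year burn-in
tx <- tx[tx$type == "transplant", ]
strata_frequencies(tx$score)
#> Risk-strata distribution:
#>   [0,9)  [9,35) [35,90]     >90
#>  0.8850  0.0562  0.0484  0.0105
wml(tx$score)
#> WML per stratum: 0.0440, 0.1789, 0.1892, 0.0495; SWML = 0.4616
```

Reading the output: the chain transplanted 2.04 kidneys/day (the tiny
profile configures 2.0/day), 9.2% of individual offers were refused
(configured probability 0.1), and after burn-in 88.5% of transplants fell
in the lowest epitope-risk stratum (score < 9) — the tiny 8-haplotype pool
is deliberately easy to match. The SWML is the scalar summary used to
compare scenarios: lower means more transplants at lower epitope scores.

A command-line front end wraps the same functions:

```sh
inst/exec/allosim fixtures --profile tiny --seed 42 --out fx/
inst/exec/allosim simulate --scenario ETKASPIR-E --years 2 --seed 7 \
    --profile tiny --out run/
inst/exec/allosim analyze run/
```

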