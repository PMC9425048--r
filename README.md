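# ovitraits

Trait construction and genetic-parameter estimation for feed efficiency,
methane emissions and body composition in growing sheep.

Feed-intake facilities for sheep produce four raw data streams: automated
feeder event logs (RFID entry/exit times and grams eaten per visit),
twice-weekly liveweights over a 42-day test, portable accumulation chamber
(PAC) gas concentration profiles (three timed CH4/CO2 readings per ~1-h
session, two rounds about 14 days apart), and CT slice stacks segmented
into fat, lean and bone by Hounsfield-unit bands. `ovitraits` turns those
streams into the standard traits and estimates their genetic parameters
under pedigree-based animal models. It is aimed at quantitative
geneticists and animal scientists who work with this kind of facility
data — or who need a fully synthetic, ground-truthed stand-in for it.

## What it computes

* **Residual feed intake (RFI).** Energy intake (MJ ME/day, from mean
  daily intake x dry-matter fraction x energy density) is regressed on
  metabolic mid-weight (day-21 weight^0.75), average daily gain, and
  management factors:

  `y = b0 + b1*MMWT + b2*ADG + Flock + Cohort + Pen(Cohort) + e`

  and the residual `e` is the RFI trait (negative = eats less than
  predicted). Growth summaries come from piecewise-linear interpolation
  or an OLS line through the weighings; feeding-behavior traits
  (events/day, duration, intake/event, per-event feeding rate) come from
  the same event log.
* **Gas traits.** Chamber concentration slopes are converted to g/day via
  the ideal gas law over the free chamber volume, ratio-scaled to the
  contemporary lot mean, and combined into CH4+CO2 (mol/day) and
  CH4/(CH4+CO2) (mol/mol), the methane-yield proxy.
* **CT composition.** HU-band segmentation, rectangular-rule volume
  integration, HU-to-density mass conversion, and the depot identities
  (carcass fat, total fat, carcass weight, CT weight, dressing-out %).
* **Genetic parameters.** REML under animal models structured by the
  pedigree numerator relationship matrix (sparse A-inverse by Henderson's
  rules with inbreeding): direct and maternal heritabilities,
  repeatability for the repeated gas records, and genetic/phenotypic
  correlations from bivariate fits, all with delta-method standard errors
  and the 2-SE significance convention.
* **Synthetic cohorts.** A generator that emulates the whole study —
  linked multi-flock pedigree, true breeding values, fixed effects,
  feeder events, growth curves, chamber kinetics with lot nuisance, CT
  stacks — with exact stored ground truth, so every stage is validated by
  round trips and parameter recovery.

## Worked example

```r
library(ovitraits)

cfg <- sim_config(seed = 42, n_sires = 50, progeny_per_sire = 10)
res <- run_pipeline(cfg, out_dir = tempfile("ovitraits_"), stage = "all")

res$fits$univariate$rfi
#> Animal-model REML fit for trait 'rfi'
#>  records: 500  fixed-effect rank: 1  converged: TRUE
#>  variance components:
#> additive maternal residual
#>  0.41560  0.26008  1.37478
#>  ratios:
#>             estimate     se
#> h2_direct     0.2027 0.1331
#> h2_maternal   0.1268 0.0796

res$report$correlations[, c("pair", "r_g", "r_g_se", "r_p")]
#>              pair        r_g    r_g_se        r_p
#> 1 rfi x ch4_ratio -0.2877272 0.2900791 -0.1459257
```

On this 500-animal demo the RFI heritability estimate is 0.20 with SE
0.13 — under two standard errors from the simulated truth of 0.42, as
expected at this cohort size — and the maternal component (simulated at
zero for RFI) absorbs some of the family variance, a familiar
small-sample trade-off in dam models. The RFI x methane-yield genetic
correlation lands on the simulated truth (-0.29 estimated vs -0.28
simulated) though its SE at this size still spans zero; at the full
default size (`sim_config()` alone, ~1000 animals) the SEs approach the
magnitudes seen in real studies of this design. `run_pipeline` also writes `traits.csv`, parameter and
correlation tables, a truth-vs-estimate `recovery.csv` and a seed-stamped
`manifest.json` under the output directory, and
`inst/cli/ovitraits.R` exposes the same stages as a command-line tool
(`simulate | traits | fit | report | all`).

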