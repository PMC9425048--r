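---
title: "Trait construction and genetic-parameter estimation for sheep feed efficiency, methane and body composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait construction and genetic-parameter estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovitraits)
```

## Scope

`ovitraits` implements the full analysis chain used in feed-intake
facilities for growing sheep: raw automated-feeder event logs, twice-weekly
liveweights, portable-accumulation-chamber (PAC) gas concentration
profiles and CT slice stacks are turned into residual feed intake (RFI),
daily methane and carbon dioxide traits, and carcass/visceral tissue
masses; pedigree-based animal models estimated by REML then yield
heritabilities (direct and maternal), repeatabilities and genetic and
phenotypic correlations. Because raw facility data of this kind are
proprietary, the package ships a synthetic cohort generator with complete
ground truth, and every stage is validated by forward-model/inverse-pipeline
round trips and by parameter recovery.

## Trait construction

**Intake and RFI.** Feeder events are summed per animal per day (an event
belongs to the calendar day its entry time falls on), and the mean of the
42 daily totals is the animal's intake, converted to metabolizable energy
as `MJ = kg as-fed x DM fraction x MJ ME per kg DM`. The typeset energy
formula in facility reports is sometimes ambiguous between a product and a
quotient; only the product reproduces a plausible ~25.6 MJ/day from
~2.5 kg/day of pellets at typical pellet composition (93% DM, 10.9 MJ/kg
DM), so the product is implemented. Growth over the 42-day test is
summarised two ways — piecewise-linear interpolation between weighings,
and an OLS line through them — giving the day-21 weight (whose 0.75 power
is the metabolic mid-weight, MMWT) and average daily gain (ADG). Both
routes are provided because they are both in field use and agree to
r > 0.95 at realistic weighing noise; the interpolation route is the
default. RFI is the residual of

    energy intake ~ MMWT + ADG + Flock + Cohort + Pen(Cohort)

fitted by OLS; residuals are returned per animal and are exactly centered
and orthogonal to the model columns. Feeding-behavior traits (events/day,
duration, intake/event) use the rate-per-event convention: the feeding
rate is the mean of per-event intake/duration ratios, not pooled intake
over pooled time, because the per-event definition is what repeated
records of an animal's eating bouts measure.

**Gas traits.** Each chamber session records three timed concentrations
(about 0, 30 and 60 minutes) per gas. The emission rate is the OLS slope
of concentration on time, converted to mass per day with the ideal-gas
law: slope (mol fraction/min) x free chamber volume in moles at the
recorded temperature and pressure x molar mass x 1440 min/day. The free
volume is the 827-L chamber volume minus the animal's volume,
approximated as 1 L per kg liveweight; the approximation and the
subtraction are both configurable since published conversions differ on
these points, and the package's tests assert self-consistency (the
pipeline inverts its own forward model to better than 2% with nuisance
terms off) rather than any one external convention. The slope uses all
three readings and their exact recorded times rather than the endpoint
difference, which damps single-reading noise. Lot-to-lot nuisance (driven
by variable waiting times off pasture) is removed by ratio scaling: each
value is divided by its lot mean and multiplied by the grand trait mean,
which leaves every lot with the same mean, preserves the grand mean
exactly, and removes the between-lot mean variance. Scaling cells are
round-by-lot (lots are re-allocated between the two rounds) and the grand
mean is taken over all animal-rounds. Molar traits use molar masses 16.04
(CH4) and 44.01 (CO2): the sum CH4+CO2 in mol/day is an intake proxy and
CH4/(CH4+CO2) is a methane-yield proxy that is invariant to any common
multiplicative measurement error in the two gases.

**CT composition.** Pixels are classified by inclusive Hounsfield-unit
bands — defaults 40–115 fat, 116–200 lean, 201–255 bone on the offset
display scale used by livestock protocols (true fat attenuation is
negative; the offset is scanner-convention dependent, so the bands are
configuration, never hard-coded). Per-slice areas are integrated to
volumes by the rectangular rule (area sum x 30-mm slice spacing;
trapezoidal available behind a flag, matching the convention of
multiplying by the inter-image distance), and converted to mass with a
linear HU-to-density map (defaults pass through roughly 0.95 g/cm3 for
fat and 1.30 g/cm3 for bone) applied at the area-weighted mean HU per
depot. The carcass/viscera split and the subcutaneous/intermuscular split
are taken as given per-slice labels, as they are produced manually in
practice; the synthetic generator emits them. Derived traits follow the
standard identities (carcass fat = subcutaneous + intermuscular; total
fat adds visceral fat; carcass weight = carcass fat + lean + bone; CT
weight adds visceral fat and non-fat viscera; dressing-out % = carcass /
CT weight — the ratio-to-CT-weight definition is used; a ratio to live
weight also circulates, and the difference matters because CT weight
excludes gut fill).

## The animal model and the REML engine

For trait vector `y`,

    y = Xb + Z_a a + Z_m m + Z_p p + e

with `a ~ N(0, A sigma2_a)` structured by the pedigree numerator
relationship matrix A, `m` a dam-linked maternal effect, `p` a
permanent-environment effect for repeated records, and `e ~ N(0, I
sigma2_e)`. A is built by the tabular method; its sparse inverse is built
directly by Henderson's rules with the inbreeding correction (Mendelian
sampling variances from Meuwissen–Luo inbreeding coefficients), so the
mixed-model equations scale to pedigrees far beyond the sizes at which
the dense inverse is checked against it. Unknown parents are treated as
unrelated non-inbred founders; genetic groups are out of scope.

The maternal effect defaults to a *genetic* dam effect (the dam's
position in A), with an i.i.d. dam option, because field reports often
say only that "dam was fitted as a random effect"; the direct–maternal
covariance is fixed at zero since no such covariance is reported for
these traits. Heritabilities are ratios to the summed fitted components;
the repeatability is `(sigma2_a + sigma2_m + sigma2_pe) / sigma2_p`.

The restricted likelihood is evaluated through the sparse Cholesky
factorization of the mixed-model coefficient matrix (`-2 logL = n log
sigma2_e + sum_r q_r log sigma2_r + log|C| + y'Py`, constants dropped).
It is maximized by a bounded quasi-Newton search on log-variances
(components floored at 1e-8 of the phenotypic variance) followed by a
Newton polish on the natural scale using central-difference derivatives.
The polish matters: it takes the optimum from line-search precision to
the ~1e-8 agreement needed to match the closed-form balanced half-sib
ANOVA estimator to 1e-6 in heritability. A dedicated average-information
update loop was considered and rejected: with likelihood evaluations this
cheap, the generic optimizer plus polish reaches the same optimum with
far less machinery, and the observed-information matrix (numerical
Hessian at the optimum) supplies the same standard-error convention
(delta method on the inverse information) that AI-REML implementations
report. Estimates are invariant to record order and to factor-level
relabelling; convergence is declared when the optimizer converges or the
gradient is numerically flat at the returned point.

Bivariate models estimate 2x2 additive and residual covariance matrices
on the animals recorded for both traits (repeated records are averaged
first; complete-case pairing mirrors how CT-subset correlations are
estimated in practice). Covariances are optimized through their Cholesky
factors, which enforces positive-definiteness without constraints;
`r_g = cov_a / sqrt(va1 va2)`, and `r_p` uses the summed components.
Correlations that land outside [-1, 1] by numerical slack are projected
and flagged as boundary estimates.

## The synthetic cohort generator

The generator's defaults are the study conditions they emulate: five
cohorts over three years in three genetically linked flocks; ~1000
phenotyped ewe lambs from 100 sires with 10 progeny each (20% link sires
with progeny in two cohorts, split between them); every lamb with a known
dam and dams carrying two progeny so maternal variance is estimable; a
42-day test with weighing on days {0, 3, 7, ...} twice weekly and 1-kg
weighing noise; ~13.7 feeder visits per day with gamma-distributed visit
sizes; two PAC rounds on test days 21 and 35 in lots of 10 with a
multiplicative log-normal lot nuisance (SD 0.12 on the log scale) —
exactly the structure the lot scaling removes; 31 CT slices at 30-mm
spacing for the first three cohorts. Trait means, SDs, heritabilities,
maternal fractions and repeatabilities default to published point
estimates for this population (e.g. RFI h2 0.42, CH4 h2 0.32 with
repeatability 0.31, visceral fat h2 0.93), so parameter-recovery tests
double as plausibility checks. Genetic correlations among the core block
(day-21 weight, ADG, RFI, CH4, CO2) use published values where available;
the two unreported entries (weight-ADG, CH4-CO2) are set to moderate
positive values (0.40, 0.60) chosen once for positive-definiteness and
biological plausibility. CT depots are genetically independent of each
other and of the core block by default — a simplification: real depot
masses are strongly genetically correlated, so cross-block correlation
estimates from default synthetic data are null by construction.

Breeding values descend the pedigree by Mendelian sampling with
inbreeding-corrected segregation variances, so `Cov(a_i, a_j) = a_ij G`
holds exactly in expectation. Every phenotype is stored as its exact
component sum (mean + fixed + direct + maternal + permanent environment +
residual), and the raw streams are forward models of those latents: daily
feeder sums average to the latent intake exactly (day factors are
normalized), the chamber concentration slope is the latent emission
mapped through the same ideal-gas algebra the pipeline inverts, and CT
slice areas are Beta-shaped axial profiles sampled at slice midpoints so
the continuous volume is known in closed form and the reconstruction
error is pure midpoint-rule discretization, which vanishes as spacing
shrinks (tested at 30/15/5 mm).

What the generator does *not* emulate: selection or assortative mating,
the 14-day adaptation period, circadian feeding structure, chamber CO2
absorption or humidity effects, rumen-content segmentation error, and
between-depot genetic correlations. Passing recovery tests therefore
demonstrate that the pipeline and estimator are correct for data
generated under the stated model, not that real data meet that model.

## Numerical choices and limitations

* Day indexing: the first test-period weighing is day 0; the
  interpolation grid is days 0–42 inclusive, and day-21 weights come from
  that grid. Events on days without a weighing use the nearest segment;
  weighings outside 0–42 are extrapolated by the nearest segment slope
  with a warning.
* The repeated-measures "day as repeated measure" pre-processing step
  used by some facilities for intake is represented by the plain 42-day
  mean; the exact mixed-model specification of that step is not
  recoverable from published descriptions, and the mean is the
  transparent default.
* Problem sizes in the test-suite recovery studies (100 sires x 10
  progeny, 20 replicates per scenario; 50-animal pedigrees for the dense
  oracle) were chosen so that Monte-Carlo error is comfortably inside the
  stated recovery tolerances while a full run stays desk-scale.
* Ratio standard errors at a variance floor (boundary) are reported from
  the same observed-information machinery but flagged; they should be
  read with the usual caution about boundary REML asymptotics.
* The PAC conversion exposes temperature, pressure, chamber volume and
  the animal-volume subtraction as configuration; only self-consistency
  is asserted, not any specific published conversion constant.
* Bivariate fits are complete-case and single-record; maternal and
  permanent-environment terms are available univariately but are not
  carried into the bivariate parameterization by default.

## Reproducing the headline numbers

`scripts/acceptance.R` reruns the growth-method agreement study from
scratch at a given seed: it simulates a 200-animal cohort with 1-kg
weighing noise, computes MMWT by both growth routes, and writes the
Pearson correlation between them to JSON. The test suite
(`tests/testthat/test-acceptance.R`) holds the full battery: worked
arithmetic identities, the 2-SE significance rule against a table of
published estimate/SE pairs, lot-scaling properties, REML-versus-oracle
equivalences, parameter recovery, CT round trips and RFI residual
geometry.
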