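---
title: "Performance-based dietary net energy for pen-fed feedlot cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Performance-based dietary net energy for pen-fed feedlot cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedlotNE)
```

## The problem

Finishing trials that test a new feed ingredient against a corn-based
control usually cannot measure the diet's net energy (NE) directly.
What a feedlot can measure, pen by pen, is growth (body weights over
~145 days), feed delivered (dry matter intake, DMI), and the carcass at
harvest.  `feedlotNE` turns those pen records into *performance-based*
dietary NE: the NE concentration the diet must have had for the
observed intake to support the observed maintenance and gain.  Once
each diet has an observed NE, the energy value of a single test
ingredient fed as a partial replacement for corn follows from the
*replacement technique*.

The intended unit of analysis throughout is the pen (the experimental
unit in a randomized complete block finishing trial), never the
individual steer.

## The energy model

Let `W` be the median feeding shrunk body weight (kg), the mean of the
initial shrunk BW and the carcass-adjusted final BW.  Two classical
allometric equations give the daily energy demands (Mcal/d):

* maintenance: `EM = 0.077 W^0.75`
* retained (gain) energy at average daily gain `ADG` (kg/d):
  `EG = ADG^1.097 × 0.0493 W^0.75`

Intake splits between maintenance and gain according to the diet's NE
for maintenance (`NEm`, Mcal/kg DM) and for gain (`NEg`):

```
DMI = EM / NEm + EG / NEg,      NEg = 0.877 NEm − 0.41
```

Substituting the linear `NEg`–`NEm` relation and clearing denominators
yields a quadratic in `NEm` with coefficients `a = −0.41 EM`,
`b = 0.877 EM + 0.41 DMI + EG`, `c = −0.877 DMI`.
`solve_dietary_nem()` returns the root `(−b − √(b² − 4ac)) / (2c)` —
the larger positive root, the only one that exceeds the zero-gain bound
`0.41/0.877 ≈ 0.468` Mcal/kg — and verifies the intake identity to a
relative 1e-9 before returning.  One sometimes sees the intake relation
quoted with the maintenance term dropped (`DMI = EG/NEg`); only the
two-term relation encoded in the quadratic coefficients reproduces
standard worked results, so that is what the package implements.

By AM–GM, `b² ≥ 4ac` always holds here, so the quadratic cannot lose
its real roots; the infeasible-performance error path triggers when the
admissible root does not exceed the zero-gain bound (a diet too poor to
support any gain under the maintenance-only closed form `EM/DMI`).

`predict_adg()` is the exact algebraic inverse — energy above
maintenance deposits at `NEg` and the `EG` equation is inverted for
ADG — and is both a user-facing "what gain should this diet support"
tool and the forward model of the synthetic generator, which is what
makes the round-trip identity (`solve ∘ forward = identity` to 1e-9,
tested property) meaningful.

```{r worked}
# control treatment means: initial shrunk BW 386 kg, carcass-adjusted
# final BW 640 kg, ADG 1.74 kg/d, DMI 10.69 kg DM/d
pen_energetics(386, 640, 1.74, 10.69, tabular_nem = 2.09,
               tabular_neg = 1.40)
```

## Carcass-adjusted performance

Gut fill makes live final weight a noisy endpoint.  The package
standardises the endpoint through the carcass: a common dressed yield
(the simple mean of per-steer hot-carcass-weight over shrunk final BW,
across all finishers — 0.6433 in the motivating data) divides each
HCW to give the carcass-adjusted final BW.  Initial BW carries a fixed
4% shrink (`shrink_bw()`, configurable).  No additional shrink is
applied to the carcass-adjusted endpoint, because it is defined
entirely from HCW.  Performance is computed on a deads-and-removals-
excluded basis (`exclude_deads_removals()`).

Feed accounting follows hospital-pen practice: feed moved with a
temporarily hospitalised steer stays credited to its home pen if the
steer returns; if it never returns, all its hospital deliveries are
deducted back to the date of hospitalisation (`pen_dmi()`).  Head-days
use date-of-disposition accounting — a dead or removed steer accrues
head-days through the day before it left its home pen.  The source
trials rarely state this convention explicitly, so it is a documented
assumption here, isolated in `pen_head_days()`.

## The replacement technique

If a test diet differs from the control only by a fraction `y` of the
diet DM in which a test ingredient displaces corn, then the whole
diet-level NE difference is attributed to that substitution:

```
NE_ingredient = (NE_test_diet − NE_control_diet) / y + NE_corn_displaced
```

with the displaced 50:50 dry-rolled:high-moisture corn blend carrying
2.24 Mcal/kg NEm and 1.52 Mcal/kg NEg.  (Some secondary summaries of
these blend values transpose the two numbers; only the 2.24-NEm /
1.52-NEg ordering is consistent with corn book values and with the
worked results, and it is the package default.)  By default
`replacement_summary()` rounds the treatment-mean diet NE to 2 decimals
before differencing, because ingredient values of this kind are defined
from reported-precision treatment means; full-precision mode is a
configuration flag (`printed_precision = FALSE`).  The difference is
divided by a ~0.20 inclusion, so the technique amplifies diet-level
noise five-fold — SEMs on ingredient values are correspondingly wide,
which is why the package reports them from pen-level fits rather than
desk arithmetic.

## Carcass metrics

Carcass equations arrive from the US grading system and are defined on
imperial units; traits are stored metric and converted exactly
(2.54 cm/in, 6.4516 cm²/in², 2.20462 lb/kg):

* `usda_calculated_yield_grade()`: `2.50 + 2.5·fat(in) + 0.2·KPH(%) +
  0.0038·HCW(lb) − 0.32·REA(in²)`.
* `retail_yield()`: the classical four-trait boneless-retail-cuts
  regression (intercept 51.34).  Published pen means in this literature
  often sit a few tenths above what this constant set yields at
  treatment-mean traits — plants sometimes use variant constants — so
  agreement is asserted only within one percentage point, and the
  constant set is pinned in one place so alternates can be swapped.
* `empty_body_fat()`: a Guiroy-type linear equation on rib fat, HCW,
  ribeye area and a numeric quality-grade code.  The coding is a
  configuration default, `marbling/100 + 1` (so 400 = Small00 = low
  Choice codes as 5.0); that anchoring reproduces reported
  empty-body-fat means to ~0.01 and is flagged prominently because
  grade coding conventions differ between plants.
* `adjusted_final_bw()`: final BW adjusted to the common 28%
  empty-body-fat endpoint at 14.26 kg per EBF percentage point,
  computed per steer and then averaged (treatment-mean arithmetic does
  not reproduce per-steer averaging exactly; tests treat the reported
  means as near-agreement targets with stated tolerances).

Quality grades bin marbling in 100-point bands anchored at 400 (Select
below 400, then Low/Average/High Choice, Prime at 700+); yield-grade
classes are the bounded floor of the calculated grade.

## Diet reconstruction

`weighted_composition()` and `diet_tabular_ne()` are inclusion-weighted
sums over ingredient assays and book NE values; both are linear on the
inclusion simplex (tested properties).  Two feeding periods (high-
moisture corn exhausted on day 101 and replaced by dry-rolled corn) are
combined by `period_weighted_diet()`, weighted by delivered feed DM by
default — diet NE exposure is intake-weighted — with day-weighting as a
sensitivity option.

The bundled ingredient NE table sets corn book values (DRC 2.20/1.50,
HMC 2.28/1.54, so the 50:50 blend carries exactly the 2.24/1.52
displaced-corn values; coproducts are assigned the DRC values by
convention).  The meal-supplement and grass-hay entries are
*calibrated* so the weighted control-diet tabular NE comes to
2.09/1.40 Mcal/kg: they are labelled as calibration constants, not
sourced assays.  With that single calibration the test-diet tabular NE
values come to 2.09 (CBCDS) and ~2.09 (WCGF, vs a conventional 2.08);
the one-hundredth residual on WCGF is documented rather than forced by
a second tuning knob.  Corn NDF/ADF are fixed at the stated 9%/3%
estimate; supplement nutrient profiles are reconstructions from their
stated formulations, so reconstructed diet fiber is asserted within one
percentage point of reported diet composition.

## Pen-level statistics

`fit_rcbd()` fits the additive two-factor model (treatment + block) on
one response per pen through `stats::lm`, with a random-block REML
variant through `lmerTest::lmer` because trial reports are inconsistent
about whether block is fixed or random — with complete balanced blocks
the treatment F-test is identical either way (tested), and every report
states which variant produced it.  Least-squares means, their standard
errors and unadjusted pairwise t-tests come from contrast algebra on
the fitted model (treatment prediction averaged over block levels);
tests cross-check them against `emmeans` on unbalanced data.  The
significance conventions are `p ≤ 0.05` significant and
`0.05 < p ≤ 0.10` a tendency; compact letter displays use unadjusted
pairwise comparisons at the 0.10 threshold (no multiplicity
adjustment, matching the reporting convention of these trials), via an
insert-and-absorb algorithm implemented in `letter_grouping()`.

Grade distributions are analysed at the pen level as binomial counts
(`fit_binomial_proportions()`): a logit-link GLM with block and
treatment effects, likelihood-ratio treatment test, and logit-scale LS
means back-transformed to percentages.  A grade class entirely absent
(or full) in the data is reported with a `separation` flag and boundary
means rather than silently trusted Wald output.

Degenerate inputs follow explicit conventions: a zero-variance response
with equal means takes `p = 1`; with unequal means (an exact
deterministic difference) `p = 0`.

## The synthetic generator

`generate_study()` emulates the design of a 30-pen weight-blocked
finishing trial: 3 treatments × 10 blocks × 8 steers, two weigh groups
(146 and 145 days on feed, averaging 145.5), initial BW drawn from
N(401, 43.2) kg and *sorted into weight blocks exactly as an allotment
crew would*, pen DMI drawn around treatment means (10.69/10.76/10.67
kg/d), and pen ADG generated through `predict_adg()` at the configured
true diet NEm (2.11/2.09/2.08 Mcal/kg).  The median-weight/ADG circular
dependency is resolved by fixed-point iteration from the initial shrunk
BW (tolerance 1e-8; convergence is asserted and iteration counts are
returned).  Hot carcass weight is final shrunk BW times a per-steer
dressed-yield draw (0.6433 ± 0.012); ribeye area and rib fat are
conditionally Gaussian given final BW with config-pinned coefficients;
marbling and KPH are Gaussian draws.  Grade-class frequencies emerge
from the marbling distribution rather than being configured directly.

Because the generator's forward model is the package's own energy
system, the analysis stage is *correctly specified* on synthetic data:
parameter-recovery tests (200 studies: estimator bias ≤ 0.01 Mcal/kg,
mean absolute error within the design's own 10-pen sampling error) test
the pipeline's algebra and accounting, not a modelling approximation.
The corollary is equally important: passing them says nothing about how
well the energy model describes real cattle, about correlated daily
intake dynamics, weather, disease beyond a removal coin-flip, or
non-Gaussian carcass traits — none of which are simulated.

Dispersion defaults were set once from the pen-level standard errors a
well-run university feedlot trial reports (DMI SEM ≈ 0.13 kg/d,
observed-NEm SEM ≈ 0.021 Mcal/kg for 10 pens): pen DMI CV 0.038 and pen
ADG residual SD 0.09 kg/d reproduce those two, at the cost of a
somewhat smaller ADG SEM than such trials show (real pens vary in ways
this generator ties to intake).  Removal probability is 4/240.

```{r synth}
st <- generate_study(synthetic_config(), seed = 1)
res <- run_pipeline(st$steers, st$feed, st$carcass)
res$stats[res$stats$response %in% c("adg_kg_d", "dmi_kg_d",
                                    "nem_mcal_kg"), 1:6]
```

## Numerical and design choices

* Quadratic root selection: the `(−b − √disc)/(2c)` root, validated by
  the worked control example and by the residual check on the intake
  identity.
* Median `W` uses the carcass-adjusted final BW, not the live final BW.
* Display rounding is decimal round-half-even at the conventional
  column precisions (BW integer; ADG/NE 2 dp; G:F 3 dp; percentages
  2 dp), with full precision retained in every CSV/data.frame;
  `round_half_even()` treats values within 1e-9 of a half-step as
  exact decimal halves.
* All energies are Mcal and masses kg; unit conversion happens only
  inside the carcass equations.
* Test problem sizes: the recovery study uses 200 simulated trials and
  the null-calibration study 2,000 pen-level replicates — sizes chosen
  to put Monte-Carlo error well below the tolerances being asserted
  while keeping the default suite around a minute.
* The orchestration surface is the function layer (`run_pipeline()`,
  `render_table()`, `worked_example()`) plus `scripts/acceptance.R`;
  an analysis package of this kind is driven from R, so no shell
  executable is shipped.

## Known limitations

* The energy equations are for implanted beef-breed finishing steers;
  no frame, sex or breed adjustments are provided.
* Ingredient NE entries for supplements and hay are calibrated, not
  assayed; diet-level tabular NE inherits that calibration.
* The retail-yield constant set undershoots some published pen means by
  a few tenths of a percentage point (variant plant equations).
* The binomial grade model uses pen totals; it does not model
  within-pen steer correlation beyond the binomial.
* Satterthwaite denominator df (random-block variant) follow
  `lmerTest`; no Kenward–Roger emulation is attempted.
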