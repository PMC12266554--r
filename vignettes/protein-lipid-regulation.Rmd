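---
title: "Protein-lipid regulation in caged nurse bees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-lipid regulation in caged nurse bees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeNGF)
```

# The model

`beeNGF` analyses feeding experiments in the Nutritional Geometry Framework
(NGF) restricted to two nutrients, protein (P) and lipid (L), both in mg
per bee accumulated over an experiment horizon (six days by default — the
window during which nurse bees develop their hypopharyngeal glands, HPG).

**Food rails.** A diet with protein and lipid wet-mass fractions $(p, l)$
confines intake to the ray $\{(a\,p,\ a\,l) : a \ge 0\}$, where $a$ is the
amount of food eaten. The study diets all satisfy $p + l = 0.5$ over a
constant carbohydrate–vitamin–cellulose background, so the five rails span
P:L ratios from 1:2.3 (P15:L35) to 2.3:1 (P35:L15).

**Intake target and rules of compromise.** The intake target
$IT = (P_T, L_T)$ is the point an unconstrained animal regulates toward.
On a rail that misses the target, the amount eaten is governed by a rule of
compromise. All five rules have closed forms in $a$ (see
`?predict_intake`); two facts about their geometry matter for the numerics:

* *Equal distance* solves $\Delta P = -\Delta L$. Since
  $\Delta P + \Delta L = a(p+l) - (P_T+L_T)$ is strictly increasing in $a$,
  the complementary-error solution $a = (P_T+L_T)/(p+l)$ always exists and
  is unique and positive for valid inputs; the function nevertheless keeps
  a guard that falls back to the distance minimiser (flagged) should a
  non-positive amount ever arise from degenerate inputs. Note that
  $|\Delta P| = |\Delta L|$ has a *second* root with both errors of the
  same sign when the target and rail are biased the same way; that root is
  not a trade-off and is not the rule. The test-suite oracle therefore
  brackets its root search between the two threshold amounts
  $P_T/p$ and $L_T/l$.
* When a rail passes through the target, all five rules coincide with the
  target point; such rails are *uninformative* for rule classification, and
  `classify_rule()` requires at least two informative rails (cross-product
  test with tolerance $10^{-9}$ mg²).

**Rule classification.** `classify_rule()` scores each rule by the summed
squared Euclidean distance (mg²) between observed and predicted points
across diets and picks the minimiser. Both axes carry the same units, so
distances are unweighted by default; a per-axis standardisation is
available (`standardize = TRUE`) for data whose protein and lipid spreads
differ by an order of magnitude. Exact residual ties are broken in the
fixed order strict restraint, closest distance, equal distance, protein
priority, lipid priority — the order in which the rules constrain the
geometry most.

**Intake-target inference.** No closed-form estimator of the target exists
for this design; the package uses the intake point of the no-choice diet
with maximal mean per-capita consumption. The rationale is the defining
property of the target: on its own rail an animal can satisfy both
nutrients simultaneously, so consumption is maximised there, and under
strict restraint consumption falls off on either side as the first
threshold binds earlier. Exact consumption ties are broken toward the diet
whose P:L ratio is nearest 1 on the log scale — a deterministic rule that
is symmetric in the two nutrients — and recorded in the result's `source`
field.

# The synthetic cage generator

No raw cage data accompany the study design, so `simulate_experiment()`
generates datasets with the statistical structure the analysis assumes.
Its defaults *are* the study conditions:

| parameter | default | units | rationale |
|---|---|---|---|
| no-choice arm | 5 diets + no-food control × 12 cages × 30 bees | — | study design |
| choice arm | 3 pairings × 12 cages × 25 bees | — | study design |
| horizon | 6 | days | HPG development window |
| intake target | (30, 20) | mg/bee | 1.5:1 ratio on the P30:L20 rail; 100 mg/bee total food at the target, a realistic six-day pollen-diet intake for a nurse bee |
| daily mortality hazard | 0.0267 | /bee/day | $1-(1-0.0267)^6 = 15.0\%$ six-day mortality, the reported cage attrition; diet-independent because no diet effect on survival was found |
| feeding noise CV | 0.15 | — | day-to-day cage appetite variation; lognormal with mean 1, applied to the whole cage-day so that dish allocation (the behaviour under test) is preserved |
| weighing noise SD | 0.5 | mg | balance precision (0.1 mg) plus 24 h humidity-equilibration drift |
| HPG model | 60 + 0.5 × protein | µm | positive protein dependence; lipid slope 0 |
| acini per bee | 10 | — | dissection protocol; exposed as a parameter because protocols of 10 and 12 both circulate |
| body lipid | lognormal(log 3, 0.25) | mg | diet-independent: adult bees barely assimilate dietary lipid |

Agents demand an equal share of the rule-implied full-horizon amount each
day. In choice cages the two complementary rails are mixed in the unique
non-negative combination reaching the target; if the target lies outside
the cone spanned by the rails, agents use the rail closest in angle to the
target and the record is flagged (`target_outside_cone`). The
`no_regulation` rule makes each dish be eaten at half its own no-choice
rate — the theoretical null of the choice analysis — which is how the
type-I error of the theoretical-vs-experimental tests is checked.

Deaths are drawn daily (binomial) and dead bees are removed before feeding,
so the generator's truth matches the accounting convention exactly: daily
per-capita intake divides by the end-of-day live census.

**What the generator does not emulate.** Dish crowding and queueing (the
plausible cause of residual consumption of inferior diets in real choice
cages), individual feeding bouts, diet-dependent palatability, evaporation
imbalance between dishes, and between-cage heterogeneity in the intake
target. Passing tests therefore demonstrate that the *pipeline* is correct
and well calibrated — they do not show that real bees follow the generator's
assumptions.

**Seeding.** One master seed; each cage gets a child seed from a stable
31-based string hash of (master, cage id) reduced modulo $2^{31}-1$, so any
cage can be regenerated in isolation and the whole experiment is
reproducible byte for byte.

# Accounting choices

* Census denominator: bees alive at the end of the day's 24 h feeding
  window (dead bees are removed daily).
* Negative apparent consumption within 1 mg (the tolerance default) is
  retained and flagged as weighing noise — clamping would bias totals
  upward. Larger dish-mass gains mark a suspect record: excluded from
  totals and listed in the result, never silently dropped.
* Self-selected P:L ratio is total protein over total lipid for the whole
  experiment, not a mean of daily ratios (daily ratios are noisier and
  their mean is a biased estimator of the regulated ratio).
* No blank-dish evaporation correction by default; the 24 h equilibration
  of dishes before each weighing controls evaporation by design.

# Inference choices

* **Bonferroni families** are explicit arguments with study defaults:
  m = 3 for the dish-preference tests (one per pairing) and m = 6 for the
  theoretical-vs-experimental and ratio-vs-target tests (two diets × three
  pairings), giving the adjusted threshold 0.05/6 = 0.0083.
* **Welch t** is the default for theoretical-vs-experimental comparisons
  (the halved no-choice totals have roughly a quarter of the variance of
  the choice totals, so pooling is inappropriate); one-sample t for ratios
  against the target.
* **Theoretical-ratio replication**: theoretical ratios are built from the
  12 cage-level no-choice replicates per diet, index-paired across the two
  paired diets (df = 11). Expanding to per-bee replicates would manufacture
  hundreds of pseudo-replicates from 12 cages; the cage is the experimental
  unit here.
* **HPG values** are log-transformed for the ANOVA (variance grows with
  the mean across treatments); the treatment-mean regressions on protein
  and lipid intake use untransformed means, matching how such inlays are
  presented.
* **Survival** uses a Cox proportional-hazards model with a gamma frailty
  on cage as the random effect; treatment is tested by a likelihood-ratio
  χ² between the integrated (marginal) likelihoods of the treatment and
  frailty-only models, with df = number of treatments − 1. The penalized
  partial likelihoods that the fitting routine reports per model are *not*
  comparable across models and are not used. Calibration and power of this
  test are themselves checked by simulation in the test suite.
* **Mixed ANOVA** of choice consumption uses a split-plot layout: pairing
  between cages, dish role (protein-rich vs lipid-rich) within cages, cage
  as the error stratum. MANOVA uses the per-cage (total protein, total
  lipid) response with Pillai's trace; on noise-free synthetic data the
  residual matrix is rank-deficient and the multivariate test is reported
  as degenerate rather than fabricated.
* Report numbers are rounded only at the presentation layer (ratios to
  2 dp, thresholds to 4 dp); all internal values keep full precision.

# Degenerate inputs

Zero-variance samples whose mean equals the null are defined results
(statistic 0, p = 1), not errors; all-identical ANOVA data give F = 0,
p = 1 with a scale-aware zero-variance detection (fitted sums of squares
of exactly constant data are tiny but non-zero in floating point); a
no-event survival dataset, an empty cage, a lipid-free total, and a dish
whose demand exceeds its mass are errors with specific messages.

# Problem sizes

The test suite validates the closed forms against independent numeric
oracles (root-finding and numeric minimisation) on 1000 random
diet–target pairs at 10⁻⁶ tolerance, checks rule recovery under 2 mg
isotropic observation noise across 100 seeded replicates, calibrates
mortality on 1000 simulated cages, and estimates the family-wise type-I
rate of the theoretical-vs-experimental tests on 500 seeded no-regulation
experiments of one pairing (12 + 12 no-choice and 12 choice cages each).
These sizes give binomial confidence intervals tight enough to detect
meaningful miscalibration while keeping the default test run to a few
minutes on one CPU.

# Limitations

The generator's agents share a single deterministic intake target; real
cages exhibit between-cage target variation that would widen every
confidence interval. The strict-restraint choice allocation assumes
perfect compensation between complementary dishes, so simulated choice
cages sit on the target ratio almost exactly — tighter than the 1.13–1.52
spread such experiments report across pairings. The Cox frailty LRT is an
approximation to a full mixed-model likelihood ratio; its empirical size
at α = 0.05 is close to, but not exactly, nominal. And because the
experimental F/t/p statistics of any particular real dataset depend on
unpublished raw data, the package reproduces the *procedures* and the
recomputable design quantities, not those specific statistics.
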