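---
title: "Within-trial cost-utility analysis for cluster randomised trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-trial cost-utility analysis for cluster randomised trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`ceaclust` implements a within-trial cost-utility analysis for cluster
randomised trials of complex interventions — the setting it was built
around is staff training in positive behaviour support (PBS) for adults
with intellectual disability who display behaviour that challenges,
evaluated across 23 community service teams (11 randomised to the
intervention, 12 to treatment as usual) with roughly 246 participants
followed at baseline, 6, 12 and 36 months. The pipeline takes
participant-level resource use, EQ-5D health states, therapist activity
logs and a unit-cost schedule, and produces the decision quantities a
reimbursement body needs: adjusted incremental costs and QALYs with
bootstrap intervals, the ICER, the cost-effectiveness plane and
acceptability curve, and the probability the intervention is
cost-effective at a willingness to pay of £30,000 per QALY.

Because trial data of this kind are not publicly deposited, the package
includes a first-class synthetic-data generator that reproduces the
*statistical structure* the analysis assumes, so every stage is testable
end to end.

## Utilities and QALYs

Health states are 5-dimension, 3-level EQ-5D descriptions (the youth
wording, EQ-5D-Y, is used for its simpler language; levels map 1→1, 2→2,
3→3). States are valued with an additive tariff

\[ u = 1 - c\,\mathbf{1}\{\text{any level} > 1\} - \sum_d \delta_{d,\ell_d}
   - n_3\,\mathbf{1}\{\text{any level} = 3\}, \]

with the UK MVH time-trade-off value set as the packaged default
(full health 1, worst state −0.594). No youth-specific value set existed
for this design, and the adult 3-level tariff applied to EQ-5D-Y
responses is the convention followed here; the coefficient file is
swappable for any value set of the same additive form. Proxy (carer)
responses are the base case — many participants cannot reliably
self-report — with self responses available for sensitivity analysis.

QALYs are the area under the piecewise-linear utility curve, in years.
If a participant dies, utility is set to 0 at the date of death, the
curve runs as a straight line from the last available measurement to
that point, and contributes nothing thereafter. Costs and QALYs accruing
after 12 months are discounted at 3.5% a year (NICE reference case),
implemented as discrete annual weighting: the 12–36-month area is sliced
at months 24 and 36 into years 2 and 3 with weights $(1+r)^{-1}$ and
$(1+r)^{-2}$. Because trapezoidal integration is linear in the node
utilities, the discounted QALY is computed exactly as a weighted sum of
the observed utilities (the weights are obtained by valuing unit
vectors), with a slower exact path for participants who died.

## Costing

Resource-use quantities are priced by category: contacts at an hourly
professional rate times a typical appointment duration, items (e.g.
medication) per unit, accommodation per occupied week by class
(residential by bedroom count, supported living 24h or less, floating
support), and informal (unpaid) care at £24/hour — the rate of a home
care worker — for the reported weekly hours over the 26-week recall
window. Private care is priced at public unit costs. Each assessment's
recall window covers the preceding 6 months only; the 12–30-month gap is
deliberately *not* extrapolated, so "36-month costs" means costs
observed in the four recall windows. All costs are 2014/2015 GBP; the
packaged unit-cost table carries placeholder rates of realistic
magnitude and is meant to be replaced by the user's national schedule.

The intervention cost has two parts: staff training (total cost divided
by the number of intervention-arm participants — a conservative
allocation) and delivery (mean logged therapist hours times an NHS Band
6 hourly rate). Activity logs typically cover only part of the arm;
unlogged participants receive the arm-mean delivery cost, mirroring the
use of a single arm mean (individual hours are available behind a
flag). The intervention cost attaches to the first year, so it is never
discounted. The healthcare perspective sums NHS and personal social
services components; the societal perspective adds accommodation,
informal care, criminal justice and out-of-pocket costs.

## Missing data

Missingness is assumed missing at random given disability level, living
situation and accommodation type — the covariates found predictive of
missingness. Incomplete cost/utility cells are imputed by chained
equations (10 cycles), each incomplete variable regressed on those
covariates, arm, the cluster staffing ratio and the other cost/utility
variables, on the natural scale. Utilities are imputed per timepoint
and QALYs computed *within* each completed dataset, so the death rule
is preserved. The number of imputations follows the
percentage-of-missingness rule (35% missing → 35 datasets; minimum 5).
Utility cells after death are not imputed — they carry the death-rule
value.

Two posterior-draw methods are offered, and the choice of default was
made on calibration evidence. Predictive mean matching (5 donors,
type-1 matching) is the field's customary choice because it keeps
imputations on the observed support — attractive for zero-inflated,
right-skewed costs. But in paired simulations at this design's own
scale (~246 participants, 35% missing occasions) PMM attenuated the
adjusted treatment contrast by roughly 4–6% relative to the
complete-data estimate on the same trials, a known finite-sample
weakness when the treatment signal is small relative to residual
spread and donor pools are thin. Proper Bayesian normal-theory draws
showed no measurable attenuation, so `"norm"` is the default and
`"pmm"` remains available (`method = "pmm"`). Normal draws can fall
slightly outside the instrument's range or below zero cost; this is
analysis-neutral for the linear estimators used here and is documented
rather than truncated (truncation would reintroduce bias). A further
deliberate numerical detail: the ridge used to stabilise the
imputation regressions is proportional to each column's own scale; an
absolute ridge would silently shrink small-scale coefficients (a 0/1
arm dummy next to GBP-scale costs) and attenuate the treatment effect.

The imputer is written in the package rather than delegated, and is
validated by calibration: pooled post-imputation estimates centre on the
complete-data oracle under MAR, and differ from complete-case estimates
by a small fraction of a standard error under MCAR.

## Inference

Adjusted incremental costs and QALYs come from linear regression of the
outcome on the treatment indicator, the baseline value of the outcome
(always included, to control regression to the mean given baseline
imbalance) and the cluster staffing ratio, with a random intercept per
cluster. The trial phrase "size of the team" and "staff/participant
ratio" are treated as one configurable cluster-level covariate.

Uncertainty uses a bootstrap-within-imputation scheme: for each
completed dataset, whole clusters are resampled with replacement within
arm (two-stage bootstrap is not available once covariate adjustment is
needed, and cluster resampling respects the design; resampled copies
become distinct pseudo-clusters), both regressions are refitted on the
*same* resample so each draw is a correlated (ΔC, ΔQ) pair, and draws
are pooled across imputations into one cloud — 35 imputations × 200
replications = 7000 draws. Intervals are bias-corrected percentile
intervals computed against the pooled point estimate. Participant-level
resampling is available behind a flag for comparison.

One small-sample correction is applied by default: resampling $G$
clusters with replacement gives a bootstrap variance of an arm mean
that is only $(G-1)/G$ of the sampling variance (the same $(n-1)/n$
deflation as the elementary bootstrap of a mean). With 11 and 12
clusters per arm that understates the standard error by ~4–5%, enough
to erode interval coverage. Each imputation's draw deviations around
its point-estimate pair are therefore rescaled by
$\sqrt{2 / \left(\frac{G_1-1}{G_1} + \frac{G_2-1}{G_2}\right)}$;
the correction can be switched off.

Two engines back the refits. `lme4::lmer` is the user-facing default
for one-off fits (singular fits fall back to OLS with a warning). The
bootstrap default is an exact profiled-REML solver for the
single-random-intercept model (`lmm_ri`): the REML criterion is
profiled over the variance ratio with cluster-wise Woodbury identities,
making each refit roughly an order of magnitude faster while agreeing
with `lme4` to numerical precision (a test asserts this, including at
the singular boundary, where the solver returns OLS — the same answer
`lme4` gives). Without it, the ~10^5 refits behind the bootstrap would
dominate the runtime of any simulation study.

The validity of proxy-completed EQ-5D-Y in this population is probed by
a responsiveness model: utility at each timepoint against the
concurrent ABC-C score, adjusting for disability, accommodation and
living situation, with random intercepts for service and participant.
A clearly negative slope (about −0.002 per ABC-C point in the packaged
study conditions) indicates the instrument tracks challenging
behaviour.

## Decision outputs

The ICER is ΔC/ΔQ with dominance labels on the off-diagonal quadrants
("dominant": cheaper and more effective; "dominated": costlier and less
effective; undefined at ΔQ = 0). The CEAC reports, for each willingness
to pay λ on a £0–£50,000 grid in £500 steps, the fraction of draws with
λ·ΔQ − ΔC > 0; ties count as not cost-effective, a deterministic rule.
Printed ratios are computed from unrounded internal values, so they
need not reproduce a ratio recomputed from rounded components.
Curve, plane cloud and summary are exported as CSV so plots are
reproducible from text artifacts.

## The synthetic-data generator

The generator's defaults *are* the study conditions: 11 + 12 clusters,
~246 participants, assessments at 0/6/12/36 months, an undiscounted
incremental 0.175 QALYs and £399 of healthcare cost built in, 35%
missing-at-random post-baseline records, 52% of participants with an
unpaid carer (follow-up informal care averaging 16 h/week in the
intervention arm vs 30 in control, which is what drives the societal
saving), a utility decrement of 0.002 per ABC-C point, modest intraclass
correlations (0.05), and a small constant death hazard (0.1%/month) so
the death rule is exercised — the trial itself reports no deaths, so
this path is exercised only synthetically.

Costs are right-skewed by construction: contact counts are
gamma-mixed Poisson (negative binomial) and informal-care hours gamma
with shape below 2. The cost contrast is carried by the psychiatric
contact rate, calibrated against the unit-cost table so the expected
healthcare difference equals the target exactly. Utilities are built
from a latent variable, linear in the behaviour score with cluster,
participant and occasion noise, mapped to the *nearest* tariff-valued
state (ties broken toward the lexicographically smaller code). The
latent intercept puts the population mean utility near 0.70, plausible
for adults with intellectual disability and challenging behaviour.
Because the nearest-state map is a step function with a plateau below
full health (no state value between 0.883 and 1), a naive latent shift
would be attenuated; the generator therefore solves numerically for the
latent shift whose *post-mapping* expected contrast equals the target,
so the generating values are recovered without bias. Masking
probabilities are logistic in the missingness covariates with the
intercept calibrated by root finding to hit the target masked fraction
on the realised covariate distribution; baseline is never masked.

Two missingness summaries coexist deliberately: the *masked record
fraction* (the generator's 35% target) and the *fraction of
participants with any incomplete cell*, which drives the
imputation-count rule and is necessarily larger when records are masked
independently. The generator does not attempt the trial's full
covariate joint distribution — only the features the analysis touches —
and passing tests on synthetic data show the pipeline's internal
consistency, not that real-world utilities follow a latent-linear
model.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use deliberately chosen
problem sizes: marginal calibration at ~4,000 participants (3
Monte-Carlo-SE bands computed from cluster-level means), MAR recovery
over 30 replications of ~2,000-participant trials with 5 imputations,
parameter recovery and interval coverage over 100 replications at the
trial's own scale (~246 participants) with 10 imputations × 50
bootstrap replications, and responsiveness recovery over 100 panels of
~2,000 participants. Default seeds are fixed (the generator's is
20140101) and every stochastic operation takes an explicit seed;
identical seeds give byte-identical outputs.

## Limitations

No half-cycle correction; no extrapolation beyond the trial horizon (a
decision model would need long-term effectiveness evidence that does
not exist for this intervention class); no multilevel imputation model
(cluster enters the imputation model as a fixed covariate); no MNAR
sensitivity analysis; no EVPI. The 12–30-month resource-use gap is a
design feature of the 6-month recall instrument, not a modelling
choice, and totals labelled "36 months" should be read accordingly.
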