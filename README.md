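# ceaclust

Within-trial cost-utility analysis for cluster randomised trials, built
around the economic evaluation of staff training in positive behaviour
support (PBS) for adults with intellectual disability whose behaviour
challenges: 23 community teams randomised 11:12 to intervention or
treatment as usual, ~246 participants, followed at baseline, 6, 12 and
36 months. The package is for health economists and trial statisticians
who need the full pipeline from participant-level tables to decision
quantities:

- **EQ-5D-3L tariff valuation** of proxy- or self-reported health
  states (UK MVH TTO value set packaged; swappable coefficient file);
- **QALYs** as the trapezoidal area under the utility curve, with the
  death rule (straight line to 0 at the date of death) and NICE-style
  3.5% annual discounting after 12 months;
- **costing** of CSRI-style resource use via a unit-cost table
  (contacts at hourly rate × appointment duration, accommodation by
  class per week, informal care at £24/h over the 26-week recall
  window), intervention costing (training cost split over
  intervention-arm participants + Band-6 therapist delivery hours), and
  healthcare vs societal perspectives;
- **multiple imputation** by chained equations with predictive mean
  matching (m = percentage of incomplete participants);
- **cluster-adjusted inference**: random-intercept regression of costs
  and QALYs on treatment, baseline values and the cluster staffing
  covariate; paired cluster-bootstrap draws across imputations
  (35 × 200 = 7000); bias-corrected percentile intervals;
- **decision outputs**: ICER ΔC/ΔQ with dominance labels,
  cost-effectiveness plane, acceptability curve over a £0–£50k
  willingness-to-pay grid, probability cost-effective at £30,000/QALY,
  net monetary benefit λ·ΔQ − ΔC;
- a **synthetic-data generator** producing cluster-trial datasets with
  the statistical structure the analysis assumes (right-skewed costs,
  utilities linked to a challenging-behaviour score, 35%
  missing-at-random records), so everything is testable without access
  to trial data.

See `vignettes/cost-utility-methods.Rmd` for the model, assumptions and
design choices.

## Worked example

```r
library(ceaclust)

design <- trial_design()               # 11 + 12 clusters, ~246 participants
params <- generative_params()          # the packaged study conditions
trial  <- generate_trial(design, params, seed = 20140101)
trial  <- apply_missingness(trial, seed = 20140102)   # 35% MAR records

intervention_cost(trial)$mean_per_participant
#> training + delivery, GBP per intervention-arm participant

result <- cea_analyse(trial, m = 10, reps = 100, seed = 42)
result
#> Within-trial cost-utility analysis (healthcare perspective, discounted)
#>   imputations x bootstrap reps: 10 x 100 = 1000 draws
#>   incremental cost:  1644 GBP (95% CI 1350 to 1911)
#>   incremental QALYs: 0.167 (95% CI 0.063 to 0.299)
#>   ICER: 9857 GBP per QALY
#>   P(cost-effective at 30000 GBP/QALY): 0.98

write_cea_outputs(result, "outputs/")  # ceac.csv, plane.csv, draws.csv, summary.csv
```

The incremental cost is the adjusted healthcare-perspective difference
including the intervention cost (training + delivery); the incremental
QALYs are adjusted for baseline utility and discounted; the ICER is
their ratio; the final line is the CEAC read at the £30,000 NICE
threshold. This run's generating truths were 0.175 QALYs and £399 of
healthcare cost plus the intervention cost; a single ~246-participant
trial estimates them with the sampling noise shown by the intervals.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/ceaclust simulate --out trialdir --seed 7
Rscript inst/cli/ceaclust analyse --trial trialdir --out outputs \
    --imputations 10 --reps 100 --seed 42
```

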