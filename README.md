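# volunteerbias

Quantify and correct volunteer (self-selection) bias in cohort studies
with inverse-probability weights.

A volunteer cohort over-represents the healthy, educated and well-off, so
cohort associations between health and socio-demographic variables can be
attenuated, have understated dispersion, or even carry the wrong sign
(collider bias). Given a representative reference sample from the same
eligible population, `volunteerbias`:

* harmonizes both person tables to a shared codebook and builds a sparse
  design of all level dummies plus all two-way interactions,
* fits an **L1-penalized probit participation model** (cohort vs
  reference) with cross-validated penalty selection,
* turns fitted participation probabilities into normalized
  **inverse participation-odds weights**,
* re-estimates bivariate associations (linear probability and
  standardized linear models) with HC1-robust standard errors, reporting
  per-association **bias reduction** against the reference benchmark,
* reports **effective sample sizes** (Kish and regression-specific) and
  leave-one-out robustness refits,
* ships a **synthetic-population generator** (Gaussian-copula categorical
  variables with a configurable probit selection mechanism) so every
  stage can be validated against known ground truth, and
* includes **collider-bias simulations** with exact truncated-normal
  theory for the canonical selection archetypes.

See `vignette("weighting-methods")` for the methodology.

## Worked example

Simulate a 200 000-person population, draw a 5.5% volunteer cohort whose
participation loads on health, SES and age, and a census-like reference
sample (5% subsample, 95% response):

```r
library(volunteerbias)

cb  <- default_codebook()
pop <- generate_population(default_population_spec(200000L, seed = 42))
cohort    <- draw_volunteers(pop, default_selection_spec(seed = 42), cb)
reference <- draw_reference_sample(pop, 0.05, 0.95, seed = 42)

nrow(cohort); nrow(reference)
#> [1] 11046
#> [1] 9508
c(pop = mean(pop$self_health == "poor"),
  cohort = mean(cohort$self_health == "poor"))
#>    pop cohort
#>  0.093  0.026
```

Healthy-volunteer selection has cut the cohort's poor-health share to a
third of its population value. Fit the participation model:

```r
m <- participation_model(cohort, reference, cb, seed = 42)
m
#> Participation model (penalized probit, cohort vs reference)
#>   cohort n = 11046, reference n = 9508
#>   design: 377 columns after pruning (377 before)
#>   chosen lambda = 0.000848874; 86 slope(s) selected
#>   Kish effective sample size: 7202 (65.2% of cohort)

w <- weights(m)
weighted_mean(cohort$self_health == "poor", w$weight)
#> [1] 0.081
```

The weighted poor-health share (8.1%) is back near the population's 9.3%.
Associations, three ways — reference benchmark, unweighted cohort,
weighted cohort:

```r
cmp <- estimate_associations(
  list(assoc("self_health=poor", "employment=paid_work"),
       assoc("self_health=poor", "age_group=60-69"),
       assoc("self_health", "education", type = "std")),
  cohort, reference, w, cb)
cmp[, c("outcome", "exposure", "beta_ref", "beta_unweighted",
        "beta_weighted", "bias_reduction")]
#>            outcome             exposure    beta_ref beta_unweighted beta_weighted bias_reduction
#> 1 self_health=poor employment=paid_work -0.16354960     -0.05495347   -0.15170436      0.8909239
#> 2 self_health=poor      age_group=60-69  0.08761219      0.03068063    0.08195335      0.9006028
#> 3      self_health            education -0.29425679     -0.22287782   -0.27619425      0.7469488

mean_bias_reduction(cmp)
#> [1] 0.846

ess_report(w, cmp)
#> Effective sample size (cohort n = 11046)
#>   Kish (weight distribution): 7202 (65.2%)
#>   regression-specific: mean 2259, range 974..4750 over 3 models
```

Unweighted, every association is attenuated toward zero by roughly half
to two thirds; weighting removes 85% of the gap on average, at the price
of a reduced effective sample size.

At full scale (`run_pipeline(default_run_config(seed = 1))`: 500 000
persons, 13 associations, 10-fold cross-validation) the estimated weights
achieve a mean bias reduction of 0.944 — slightly better than the
true-probability oracle weights' 0.937 on the same draw — with a Kish
effective sample size of 54.8% of the 27 418-person cohort.

## Collider simulations

Selection on both of two independent variables makes them negatively
associated in the selected sample; the package pairs every Monte-Carlo
scenario with its exact truncated-normal theory:

```r
sc <- collider_preset("selection-on-both", n = 30000L)
scenario_theory(sc)$selected_slope
#> [1] -0.3830397
sb <- scenario_bias(sc, replicates = 12, seed = 42)
c(sb$mean_selected_slope, sb$mc_se)
#> [1] -0.3884  0.0051
```

`adjustment_vs_weighting()` shows that linearly adjusting for a covariate
on the collider path does not remove selection bias, while weighting by
the true selection probability does.

## License

MIT (see `LICENSE`).
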