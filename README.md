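# turtledose

Dose–response models linking ingested plastic debris to sea turtle
mortality, estimated from necropsy and stranding records.

## The problem

Plastic ingestion kills sea turtles by gut impaction and perforation, but no
controlled trial can establish how the probability of death grows with the
number of ingested items. The available evidence is observational: necropsy
records (debris count and mass in the gastro-intestinal tract, curved
carapace length, age class, species, cause of death) and coarser stranding
registers (debris presence/absence, an examination-level score for how
thoroughly the gut was inspected).

The statistical obstacle is that the outcome — *was this death caused by
plastic?* — is only partially observed. Deaths from known non-plastic causes
(KNP: boat strike, net drowning) are definite 0s; deaths diagnosed as
plastic-caused (KP) are definite 1s; unknown (Ukn) and indeterminate (Ind)
causes leave the outcome anywhere in \[0,1\]. `turtledose` represents each
record by interval bounds on that probability — \[0,0\], \[1,1\], or
\[0,1\] — and estimates the logistic dose–response

> logit P(death due to plastic) = β₀ + β₁ · (debris count / CCL) + age-class
> offsets (model M3; alternatives M1: count + CCL, M2: count + CCL +
> number–weight residual)

by a Monte Carlo procedure: in each of 1000 replicates, every \[0,1\]
record receives an independent Uniform(0,1) response draw and the model is
refitted by maximising the fractional-response (Bernoulli-form) likelihood
Σ yᵢ log pᵢ + (1−yᵢ) log(1−pᵢ). The ensemble of replicate fits yields median
coefficients, min/max envelopes, and the share of replicates with a
significant load term. Supporting components: a negative binomial regression
of debris counts on cause of death with AIC selection and Holm-corrected
pairwise contrasts (compact letter displays); curve prediction/inversion
(reference-animal and cohort-averaged 50%-mortality loads); a logistic
presence/absence model for stranding registers; and a synthetic cohort
generator for end-to-end validation — the raw field data are not public, so
everything is verified by parameter recovery and oracle equivalence on
synthetic cohorts.

It is written for quantitative ecologists and biostatisticians working on
wildlife debris-ingestion risk; all functions take and return plain data
frames and S3 objects.

## Worked example

```r
library(turtledose)

params <- generator_params(seed = 1)        # reference study conditions
cohort <- generate_necropsy_cohort(params)  # 246 animals
table(cohort$cod)
#> Ind KNP  KP Ukn
#>  20  82  10 134

select_by_aic(cohort)                       # debris-count model comparison
#>   code   aic delta_aic  k converged significantly_worse
#> 1   CA 458.2     0.000  8      TRUE               FALSE
#> 2  CAS 463.2     5.013 13      TRUE                TRUE
#> 3    C 466.0     7.831  5      TRUE                TRUE
#> ...

ens <- mc_fit(cohort, "M3", n_reps = 1000, seed = 3)
ens
#> Monte Carlo dose-response ensemble: M3
#>   1000 replicates (0 failed), n = 246 records, 154 interval-labelled
#>   mean AIC: 323.01   share of replicates with p(load) < 0.05: 17.4%
#>                          median      lo      hi
#> (Intercept)             -1.1322 -2.2191 -0.5309
#> load_per_ccl             1.3385  0.2445  5.0369
#> ...

ctx <- prediction_context()                 # 43.5 cm juvenile, loads 0..250
invert_for_probability(ens, ctx, 0.5)       # 50% mortality, reference animal
#> [1] 19.3
population_ed50(ens, cohort)                # 50% mortality, cohort average
#> [1] 12.7
mortality_at_load(ens, ctx, 1)              # risk from a single item
#> [1] 0.363
```

Reading the output: the cause-of-death table shows the familiar pattern —
most deaths unresolved (Ukn/Ind), a control group of known non-plastic
deaths, few definite plastic deaths. The AIC table says debris counts are
structured by age class (model `CA`) far beyond the intercept-only model
(Δ ≈ 102). The ensemble's load coefficient is positive in every replicate
envelope shown, and inverting the median curve puts 50% mortality near 19
items for the median-sized juvenile, or near 13 items averaged over the
cohort mix — the cohort average is lower because small animals reach a
lethal density at fewer items. The single-item risk (~36%) is the fitted
curve's low-load end; see the methods vignette for why label noise flattens
(attenuates) the fitted curve relative to the generating one.

The full pipeline — simulate, count model, Monte Carlo dose–response for
both labelling variants, predictions, stranding model, markdown report —
runs from one call:

```r
cfg <- pipeline_config(out_dir = "run", seed = 1)
manifest <- run_pipeline(cfg)
render_report(manifest)                     # writes run/report.md
```

Reruns with the same configuration reproduce every artifact byte-for-byte.

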