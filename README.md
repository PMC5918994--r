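# snvppv

Estimate the proportion of true positives (positive predictive value, PPV
— also called precision) of a human SNV call list, using only summary
statistics that any variant caller provides.

## The problem

A variant call list of size N can be viewed as N trials in which a call is
either a true variant (TP) or a false one (FP), with

    PPV = TP / N = TP / (TP + FP).

TP and FP can only be counted directly against a gold-standard sample
(e.g. NA12878 / Genome in a Bottle), where the true variants are known.
For a real study there is no truth set — but call-set summary statistics
such as the transition/transversion ratio (Ti/Tv), the
heterozygous/homozygous-alternate ratio (Het/Hom), the median depth
(MedDp), the fraction of low-depth calls (DpLt5) and a WES/WGS indicator
carry strong information about call-list quality. `snvppv` learns the
relationship between these statistics and PPV from gold-standard-derived
training observations and then predicts the PPV of a new call list, with a
95% prediction interval.

## The model

Binomial regression is badly overdispersed for this problem, so the TP
count Y in N calls is modeled as Beta-binomial,

    E[Y]   = N mu
    Var[Y] = N mu (1 - mu) (1 + N sigma) / (1 + sigma),

where `mu` is the expected PPV and `sigma >= 0` the dispersion
(`sigma = 0` recovers the Binomial; `alpha = mu/sigma`,
`beta = (1-mu)/sigma` link to the usual Beta shape parameterization). Both
parameters are regressions on call-set statistics:

    logit(mu) = x' beta        (mean part, p terms)
    log(sigma) = z' gamma      (dispersion part, q terms, z a subset of x)

A model is referred to by its term counts `(p, q)`. The package ships the
candidate specifications as `named_spec("m11_6")`, `"m11_1"`, `"m15_1"`
and `"global_mean_18"`; quantitative covariates are mean-centered before
squares and interactions are formed. Fitting is exact maximum likelihood
(quasi-Newton with analytic gradients), with Wald inference, AIC, Akaike
weights, AIC-gated backward elimination, a Box-Cox dispersion-link scan,
and GLM-style diagnostics (randomized quantile residuals, Binomial hat
values, Cook's distances). Prediction intervals for the observed
proportion Y/N use a Normal approximation with the Beta-binomial variance
and are truncated to [0, 1]; leave-one-out refits measure their actual
coverage.

The package also contains the surrounding tooling: VCF/BED ingestion with
SNV filtering (QUAL, depth, contigs, target regions, non-reference
genotype), call-set statistics, a truth-set validation engine producing
TP/FP/FN/PPV/sensitivity, and a seeded synthetic-data generator for
training tables and toy truth/call VCF pairs.

## Worked example

```r
library(snvppv)

# a training table: one row per validated call list
# (columns y, n, titv, hethom, med_dp, dp_lt5, wes_indicator)
tab <- simulate_training_table(sim_config(n_obs = 500, seed = 42))

fit <- bbfit(tab, named_spec("m11_6"))
fit
#> Beta-binomial regression (11, 6)
#>   log-likelihood: -2980.62   AIC: 5995.24

# PPV prediction interval for a new 41,000-call WES list
new_set <- data.frame(titv = 2.9, hethom = 1.6, med_dp = 48,
                      dp_lt5 = 0.04, wes_indicator = 1)
predict_interval(fit, new_set, n = 41000)
#>       point     lower     upper length_pct
#> 1 0.9698458 0.9604518 0.9792398   1.878801

# comparing two candidate models by AIC
akaike_weights(c(7219.47, 7230.74))
#> [1] 0.9964 0.0036
```

The interval says: a call list with these summary statistics is expected
to contain about 97.0% true variants, and the observed proportion for this
particular list should fall between 96.0% and 97.9% with 95% probability
(interval length 1.88 percentage points).

Building a training row from files instead of the generator:

```r
calls <- read_snvs("calls.vcf", filter_spec(min_qual = 30, min_dp = 5,
                                            contigs = c(1:22, "X"),
                                            require_nonref = TRUE))
truth <- read_snvs("truth.vcf", filter_spec(require_nonref = TRUE))
conf  <- read_regions("confident.bed")
report <- match_variants(calls, truth, conf,
                         stats = compute_stats(calls, wes_indicator = 1))
as_training_row(report)   # y, n, titv, hethom, med_dp, dp_lt5, ...
```

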