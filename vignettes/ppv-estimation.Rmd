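---
title: "Estimating the true-positive proportion of SNV call sets with Beta-binomial regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the true-positive proportion of SNV call sets with Beta-binomial regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvppv)
```

## The model and its assumptions

An SNV call list of size $N$ is treated as $N$ binary trials: each call is
either a true variant (TP) or a false one (FP), and the observed
true-positive proportion is $\mathrm{PPV} = Y/N$ with $Y$ the TP count.
Against a gold-standard sample $Y$ is observable; the goal is to predict
$Y/N$ for call lists where it is not, from call-set summary statistics
alone.

Binomial regression is far too narrow for this response: distinct call
lists with identical summary statistics differ by much more than binomial
noise. The package therefore models $Y$ as Beta-binomial in the
mean/dispersion parameterization

$$E[Y] = N\mu, \qquad
  \mathrm{Var}[Y] = N\mu(1-\mu)\,\frac{1 + N\sigma}{1 + \sigma},$$

with $\sigma = 0$ the Binomial limit and
$\alpha = \mu/\sigma,\ \beta = (1-\mu)/\sigma$ the bridge to the usual
Beta shapes. Both parameters depend on covariates:

$$\operatorname{logit}(\mu) = x'\beta, \qquad
  \log(\sigma) = z'\gamma,$$

where $z$ is always a subset of $x$; a model is written $(p, q)$ after the
lengths of $\beta$ and $\gamma$. A Box-Cox alternative
$\sigma = (z'\gamma)^{1/\lambda}$ is available for the dispersion link and
approaches the log link as $\lambda \to 0$; `lambda_scan()` compares the
two by AIC over $1/\lambda \in \{2, 3, \dots\}$.

Assumptions worth keeping in mind:

* Observations (call lists) are treated as independent, although lists
  derived from the same sample by varying filters are correlated in
  reality.
* Prediction intervals assume $Y/N$ is approximately Normal with the
  Beta-binomial variance, and ignore coefficient-estimation uncertainty.
  Both shortcuts are justified only with a training set of a few hundred
  observations; `loo_intervals()` exists precisely to audit the resulting
  coverage.
* Ti/Tv is only informative on autosomes and X; call lists should be
  restricted to chromosomes 1–22 and X upstream (the `contigs` filter),
  since mitochondrial, Y and male-X regions carry abnormal Ti/Tv.

## Covariates and model pool

Five predictors summarize a call set: Ti/Tv, Het/Hom, median depth
(`med_dp`, in reads), the proportion of calls with depth below five
(`dp_lt5`), and the binary `wes_indicator` (1 = whole-exome, 0 =
whole-genome). Quantitative covariates are centered to their training
means before any square or interaction is formed; the stored centers are
re-applied when scoring new data. The WES indicator is never centered and
never squared.

The shipped specifications:

* `global_mean_18` — intercept, the five main effects, the four squares,
  the four WES interactions, `med_dp:hethom`, `titv:med_dp`,
  `titv:dp_lt5`, and a configurable 18th slot. Only seventeen second-order
  terms are enumerable from the construction rules, so the remaining slot
  defaults to `titv:hethom` and can be overridden; nothing downstream
  depends on the choice.
* `m15_1` — the `m11_1` mean part plus the four Het/Hom-related terms
  (`hethom`, `hethom^2`, `wes_indicator:hethom`, `med_dp:hethom`). This
  follows from the way the 11-term model is obtained: dropping every
  Het/Hom-related covariate from the 15-term model leaves exactly the
  11-term mean part, so the converse defines the 15-term list.
* `m11_1` / `m11_6` — the 11-term mean part (intercept, WES, Ti/Tv,
  MedDp, DpLt5, Ti/Tv², MedDp², WES:Ti/Tv, WES:MedDp, WES:DpLt5,
  Ti/Tv:MedDp) with intercept-only dispersion, or with the 6-term
  dispersion part (intercept, WES, Ti/Tv, DpLt5, Ti/Tv², WES:Ti/Tv).

Factor covariates (preparation kit, variant caller) expand to
treatment-coded dummies with the alphabetically first level as reference,
so kit/caller-aware models of the $(19, 1)$ kind can be built as
user-supplied specs.

## Fitting: numerical choices

`bbfit()` maximizes the exact Beta-binomial log-likelihood jointly over
$(\beta, \gamma)$ with BFGS, rather than reproducing the backfitting of
GAMLSS-style software — the objective is identical, the optimizer simpler
to verify. Details that matter:

* **Warm start.** $\beta$ starts at the Binomial logistic regression of
  $y/n$ on $X$; the dispersion intercept at a method-of-moments estimate
  $(\hat\phi - 1)/\bar N$ from the Pearson overdispersion $\hat\phi$;
  other $\gamma$ entries at 0.
* **Column scaling.** Design columns are rescaled to unit root-mean-square
  inside the optimizer (raw `med_dp^2` spans $\sim 10^4$), which keeps the
  BFGS metric and the finite-difference observed information
  well-conditioned. Estimates and covariance are mapped back afterwards.
* **Dispersion floor.** Under the log link, $\sigma$ is evaluated as
  $\exp(z'\gamma) + 10^{-8}$. The floor keeps the
  $\log\Gamma$ differences in the likelihood accurate (at $\sigma =
  10^{-12}$ the shape parameters reach $10^{12}$ and cancellation destroys
  the objective) while biasing $\mathrm{Var}[Y]$ by at most a factor
  $1 + 10^{-8}N$ — negligible for call lists up to millions of records.
  The mean predictor is clamped to $|x'\beta| \le 30$.
* **Convergence.** Relative log-likelihood tolerance $10^{-10}$, at most
  500 iterations with one restart. Wald standard errors come from the
  inverse numeric observed information; if the information matrix is not
  positive definite, the fit is flagged rather than silently reported.
  Repeated refits that only need point estimates (leave-one-out,
  `lambda_scan()`) skip the information matrix.
* **Box-Cox feasibility.** $z'\gamma \le 0$ is infeasible under
  $\sigma = (z'\gamma)^{1/\lambda}$; such points receive a large penalty
  so the optimizer retreats, and the true optimum may legitimately sit
  near the boundary, in which case standard errors are unavailable but the
  AIC is still comparable.

Wald $z$-values are referred to the standard Normal; AIC is
$-2\ell + 2(p+q)$ and `akaike_weights()` converts AIC vectors to relative
weights.

## Prediction intervals

For a new call set with covariates $x, z$ and size $N$,

$$\widehat{Y/N} \sim \mathcal N\!\left(\hat\mu,\;
  \hat\mu(1-\hat\mu)\frac{1 + N\hat\sigma}{N(1 + \hat\sigma)}\right),$$

and the 95% interval $\hat\mu \pm z_{0.975}\,\mathrm{sd}$ uses the exact
Normal quantile ($z_{0.975} \approx 1.959964$), is truncated to $[0, 1]$,
and reports its post-truncation length in percent. In the Binomial limit
with $\hat\mu = 0.5$ and $N = 100$ the length is
$2 \times 1.959964 \times \sqrt{0.25/100} = 19.6\%$ — the closed-form
anchor used in the tests. The variance vanishes as $\mu \to 1$, so
intervals tighten exactly where call lists are good; summaries restricted
to points with predicted PPV above 95% isolate that regime.
`loo_intervals()` refits the model $n$ times (warm-started from the
full-data fit), predicts each held-out observation, and reports coverage;
`summarize_lengths()` gives the five-number summary with type-7
(R-default linear interpolation) quartiles, fixed so that quartile values
are convention-stable.

Truncation before measuring length is a deliberate choice: PPV is a
proportion, and an interval reaching outside $[0, 1]$ overstates the
uncertainty a user actually faces. For high-PPV call sets the truncation
rarely binds.

## Model selection

`backward_eliminate()` drops, at each step, the removable term with the
largest Wald p-value — but only accepts the removal if the refitted AIC
decreases, trying candidates in decreasing p-value order and stopping when
no removal lowers the AIC. The intercept is never removable; a main effect
is pinned while any square or interaction references it (marginality); a
mean term is pinned while the dispersion part uses it. Ties break toward
higher-order terms, then alphabetically, making the trace deterministic.

A consequence of AIC gating worth stating explicitly: removing one
pure-noise degree of freedom changes the deviance by an asymptotically
$\chi^2_1$ amount, and the removal is accepted only when that change is
below 2 — probability $P(\chi^2_1 < 2) \approx 0.843$. So even an exactly
useless term survives elimination about 16% of the time; this is the price
of a stopping rule that deliberately keeps terms with moderate evidence
instead of enforcing a rigid p-value cutoff. The acceptance suite asserts
a nominal 95% removal rate for a single appended noise covariate; that
expectation fails by design of the stopping rule, at the predicted ~84%
(the simulated rate is reported by `scripts/acceptance.R` as
`noise_term_removal_pct`), and is retained as documentation of the
trade-off rather than softened.

The elimination is run on the mean part with intercept-only dispersion
first; dispersion terms are refined afterwards with the mean part fixed —
mirroring the two-stage path global $(18,1) \to (15,1) \to (11,1) \to
(11,6)$.

## Diagnostics

"Weighted residuals" are implemented as randomized quantile residuals:
for each row, $u \sim U(F(y-1), F(y))$ under the fitted Beta-binomial CDF
and the residual is $\Phi^{-1}(u)$. For a discrete response this is the
construction with the advertised mean-0/sd-1 behavior under a
well-specified model; the randomization is fixed by a seed (default 423).
This is an interpretation — the residual type is not uniquely determined
by the mean-0/sd-1 property alone — and it matches the residuals of the
GAMLSS model family the fitting mirrors.

Hat values use the Binomial working weights $w_i = N_i\hat\mu_i
(1-\hat\mu_i)$ under the logit link ($H = W^{1/2}X(X'WX)^{-1}X'W^{1/2}$):
exact Beta-binomial leverage is not defined here, and the Binomial
approximation is known to give only partial information — it is used for
covariate-space outlier screening, not inference. Note that the working
weight suppresses leverage exactly where $\hat\mu \to 1$, so a
covariate-space outlier with a near-perfect predicted PPV can carry a
modest hat value. Cook's distances use the standard one-step GLM form
$D_i = r_i^2 h_i / (p(1-h_i)^2)$ with $r_i$ the raw Binomial Pearson
residual. `diagnose()` flags rows at $|r| > 3$, $h > 2p/n$, $D > 4/n$ and
can refit without the top-influence rows to measure the shift in fitted
values — the workflow that isolates artifacts such as a call list whose
homozygous calls collapse at a high QUAL cutoff, producing an abnormal
Het/Hom ratio.

## The synthetic-data generator

`simulate_training_table()` emulates the structure of a
gold-standard-derived training set: covariates drawn independently and
uniformly over realistic call-set ranges — Ti/Tv in $[1, 3.5]$, Het/Hom in
$[1, 7]$, median depth in $[5, 150]$ reads, DpLt5 in $[0, 0.5]$, an even
WES/WGS mix — call-list sizes $N$ uniform on $[5000, 60000]$ (a typical
filtered exome call list sits in the tens of thousands), and $Y$ drawn by
Beta-then-Binomial composition from the linked $(\mu_i, \sigma_i)$. The
default coefficient vectors are the fitted $(11, 6)$ coefficients of the
WGS/WES study the package implements, so the generator's dispersion
pattern — near-Binomial at high Ti/Tv, strongly overdispersed in the
middle of the range — is the empirically observed one. Defaults were fixed
once, from those published estimates and ranges, and are not tuned. An
optional knob induces the negative Ti/Tv–Het/Hom association seen in real
training sets, for probing collinearity behavior.

What the generator does **not** emulate: correlation between observations
derived from the same sample, non-uniform covariate clouds (real designs
cluster by kit and caller), caller-specific quality covariates, and any
read-level error structure. Passing calibration tests on this generator
therefore validates the statistical machinery — likelihood, intervals,
selection, diagnostics — under the model's own assumptions; it does not
certify accuracy on any particular sequencing pipeline, which requires
gold-standard validation data.

`simulate_vcf_pair()` builds toy truth/call record sets whose validation
outcome is exact by construction ($\mathrm{tp} = n_\mathrm{true}$,
$\mathrm{fp} = n_\mathrm{false}$), with substitution types hitting target
Ti/Tv ratios for the true and false components — false calls depress
Ti/Tv, as in real data.

## Validation engine

`match_variants()` restricts calls and truth to the confident regions,
then matches on (contig, position, ref, alt) **and genotype class** by
default — the stricter reading of call-set validation; a
`genotype_aware = FALSE` switch relaxes to site/allele identity. VCF
positions are 1-based, BED half-open 0-based, and a record at position $p$
is inside $(\mathrm{start}, \mathrm{end})$ iff $\mathrm{start} \le p-1 <
\mathrm{end}$. Duplicates after multi-allelic decomposition count once, so
$\mathrm{tp} + \mathrm{fp} = N$. Specificity is deliberately not reported:
without a universe of negative sites, true negatives are ill-defined for
variant calling.

## Problem sizes used by the test suite

The suite's simulation scales were chosen to make the statistical
assertions sharp at desk scale: calibration and recovery checks use
training tables of 500 observations (the scale of the motivating study's
training set) with 50 replicates where a rate is being estimated; module
unit tests use 60–400 rows. The full suite, including the leave-one-out
run over all 500 rows, completes in about a minute on one CPU.

## Known limitations

* Coefficient-estimation uncertainty is excluded from prediction
  intervals by design; for small training tables the intervals will be
  anti-conservative.
* Binomial-approximation leverage and influence understate problems in the
  dispersion part of the model.
* The Het/Hom ratio is ancestry-dependent; a model trained on a single
  individual cannot carry Het/Hom effects across ancestries, which is the
  practical reason the 11-term mean part omits it.
* Indels, structural variants, and haplotype-aware truth-set comparison
  (vcfeval-style allele trimming) are out of scope; matching is exact on
  normalized SNV records.
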