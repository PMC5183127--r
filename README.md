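# sadcompare

Likelihood-based comparison of species-abundance distribution (SAD)
models for ecological count data.

A community sample in ecology is a vector of abundances — counts of
individuals for each of the S species observed at a site — and its
distribution (many rare species, few common ones) is one of the most
universal patterns in the field. `sadcompare` fits four widely used
discrete models to such vectors by maximum likelihood, all defined on
abundances n = 1, 2, 3, …:

- **log-series** — P(n) = −pⁿ/(n ln(1−p)), 1 parameter
- **Poisson lognormal** — Poisson mixed over a lognormal rate,
  zero-truncated, 2 parameters (μ, σ)
- **negative binomial** — Gamma-mixed Poisson, zero-truncated,
  2 parameters (k, q)
- **Zipf** — P(n) = n⁻ˢ/ζ(s), 1 parameter

and compares them per site with small-sample corrected AIC,
AICc = −2ℓ̂ + 2K + 2K(K+1)/(S−K−1), and Akaike weights
wᵢ = exp(−Δᵢ/2)/Σⱼ exp(−Δⱼ/2). The model with the greatest weight is the
site's best model. Because the negative binomial nests the log-series
(its k → 0 boundary), raw likelihoods favour the 2-parameter models
almost tautologically; the AICc penalty is what makes the comparison
fair, and the package reports both views (weights and per-site
log-likelihood deviations) so the effect of the penalty is visible.

It also ships a synthetic-community generator with per-site ground truth
and sub-seeds, so the full fit-and-select chain is testable — parameter
recovery, model-selection recovery — without access to the large survey
compilations this kind of analysis is usually run on.

## Worked example

```r
library(sadcompare)

co <- community(c(55, 21, 13, 8, 5, 3, 1, 1), site_id = "example")
compare_site(fit_all(co), site_id = co$site_id)
```

```
<sad_site_comparison> site 'example' (S = 8)
            family   loglik K    aicc delta_aicc    weight  best
         logseries -27.4726 1 57.6118    0.00000 0.6772881  TRUE
 poisson_lognormal -27.7017 2 61.8034    4.19160 0.0832873 FALSE
         neg_binom -27.3380 2 61.0759    3.46409 0.1198275 FALSE
              zipf -29.2066 1 61.0798    3.46794 0.1195970 FALSE
```

Read: the two-parameter negative binomial has the highest raw
log-likelihood (−27.34 vs −27.47), but the margin is far smaller than the
AICc penalty for its extra parameter, so the one-parameter log-series
carries 68% of the Akaike weight and is the best model for this site.
(The weights sum to 1 over the four candidates.)

Collections and summaries:

```r
spec <- synthetic_spec(n_sites = 100, families = "logseries",
                       S_range = c(200, 200), seed = 101)
rec <- recovery_experiment(spec)
rec$report[, c("family", "prop_best_aicc", "prop_best_loglik", "mean_weight")]
```

```
     family prop_best_aicc prop_best_loglik mean_weight
1 logseries           0.84             0.42   0.6121056
```

On 100 communities truly generated from a log-series, the log-series is
the AICc-best model at 84% of sites but has the highest raw
log-likelihood at only 42% — the complexity-penalty effect summarized
above.

## Command line

```sh
Rscript exec/sadcompare run --input communities.csv --output outdir --seed 42
Rscript exec/sadcompare simulate --output communities.csv --truth truth.csv --sites 100 --seed 7
```

`run` expects a long-format CSV with columns `site_id`, `species_id`,
`abundance` (positive integers; decimals are a hard error naming the row)
and optional `dataset_id`, and writes `site_results.csv` (one row per
site × family: parameters, log-likelihood, AICc, weight, flags),
best-model counts per dataset, log-likelihood deviations, an exclusion
log, and a JSON metadata sidecar. Reruns on the same input are
byte-identical.

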