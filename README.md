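# lexRates

Sister-pair rates of lexical gain, loss and turnover, with Bayesian
Poisson regression on sociodemographic predictors.

## What this package is for

Why do some languages change their vocabulary faster than others?  A
classical comparative design answers this with **phylogenetically
independent sister pairs**: two languages that share an immediate
common ancestor on a time-calibrated family tree form a natural
experiment — one ancestral language split in two, and any lexical
difference between the daughters accumulated since the split.  Because
each language appears in at most one pair, the pairs are statistically
independent, side-stepping the non-independence that plagues
cross-linguistic regressions.

Given cognate-coded basic-vocabulary wordlists (ABVD-style: one row
per word form, tagged with its language, semantic unit/concept,
cognate-set id and loan flag), the package counts, for every sister
pair and every concept attested in both sisters:

* **word gains** — cognate sets found in exactly one sister and in no
  other language of the family (innovations since the split);
* **word losses** — cognate sets absent from one sister but present in
  the other *and* in at least one background language (inherited words
  lost by one daughter);
* **lexical turnover** — gains + losses.

Cognate sets present in both sisters, or absent from both, carry no
information and are ignored; loan words are removed first so that
shared cognates reflect inheritance, not borrowing.

The per-pair counts are then modelled as Poisson outcomes of five
standardized predictors (historical population size, geographic
isolation, and three 4-point conflict/warfare scales):

```
y_i ~ Poisson(mu_i)
log(mu_i) = alpha + beta1 * logPopulation + beta2 * conflictWithin
          + beta3 * isolation + beta4 * warfareInternal
          + beta5 * warfareExternal
alpha ~ Normal(0, 10),  beta_k ~ Normal(0, 2)
```

fitted by an adaptive-Metropolis MCMC sampler (3 chains x 10,000
iterations, 2,000 warm-up; 24,000 pooled draws), summarized by
posterior medians and 90% highest-posterior-density intervals, and
compared across a 10-model candidate set (null, full, five singles,
three combinations) by WAIC weights and Bayesian R².

A synthetic cognate-evolution generator closes the loop: it draws
covariates, simulates per-pair event counts from the log-linear model,
and **constructs a cognate matrix that reproduces those counts
exactly**, so the entire pipeline — tree parsing, pair filtering,
counting, design construction, fitting — is verifiable end to end
without any external data.

## Worked example

Everything below runs on a synthetic study with known truth
(isolation effect 0.9, population 0.5, external warfare −0.5, ...):

```r
library(lexRates)
sim   <- simulateStudy(simTruth(seed = 101))      # 25 pairs, 210 concepts
tree  <- parseTimeTree(sim$newick)
pairs <- filterPairs(extractCherries(tree), min_support = 0.80)
mat   <- filterLoans(sim$matrix)
events <- tabulateEvents(pairs, mat)
head(events[c("pair_id", "gains", "losses", "turnover")], 3)
#>      pair_id gains losses turnover
#> 1 L01a--L01b     0      0        0
#> 2 L02a--L02b     7     19       26
#> 3 L03a--L03b     6     12       18

design <- buildDesign(pairs, sim$predictors, events)   # pair_mean mode
gvif(design)            # collinearity check: all values well below 2
#>         predictor     gvif flagged
#> 1   logPopulation 1.072666   FALSE
#> 2  conflictWithin 1.090128   FALSE
#> 3       isolation 1.068796   FALSE
#> 4 warfareInternal 1.108231   FALSE
#> 5 warfareExternal 1.040019   FALSE

fit <- fitPoissonGLM(design, response = "turnover",
                     cfg = samplerConfig(seed = 42))
posteriorTable(fit)
#>         parameter median hpdi_lower hpdi_upper rhat  ess
#> 1           alpha   2.86       2.77       2.95    1 1073
#> 2   logPopulation   0.44       0.36       0.52    1 1198
#> 3  conflictWithin   0.31       0.19       0.43    1 1041
#> 4       isolation   0.93       0.81       1.03    1 1221
#> 5 warfareInternal  -0.21      -0.31      -0.12    1 1290
#> 6 warfareExternal  -0.48      -0.57      -0.38    1 1255
```

The posterior medians recover the generating coefficients (isolation
0.93 vs. truth 0.9, and so on), every 90% HPDI that should exclude
zero does, and the convergence diagnostics pass (split-Rhat 1.00,
effective sample sizes ≈ 1,000).  Model comparison puts all WAIC
weight on the generating full model:

```r
cmp <- compareModels(design, response = "turnover",
                     cfg = samplerConfig(seed = 42))
head(cmp$table, 3)
#>                  model n_predictors waic se_waic d_waic   weight    r2
#> 1                 full            5  156    9.56      0 1.00e+00 0.952
#> 2 betweenGroupBarriers            2  267   43.44    111 7.39e-25 0.935
#> 3  demographyGeography            2  271   36.57    115 9.08e-26 0.932
```

Real data enter through the same verbs: `readWordlists()` for an
ABVD-style CSV/TSV export, `parseTimeTree()` for a Newick tree with
node supports, `readPredictors()` for the per-language covariate
table, or the staged file-based pipeline (`readRunConfig()`,
`runExtractPairs()`, `runCount()`, `runFit()`), which writes pair,
event, coefficient and model-comparison CSVs plus provenance stamps.

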