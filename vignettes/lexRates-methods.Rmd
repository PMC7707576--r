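---
title: "Methods: sister-pair lexical rates and their Bayesian Poisson models"
author: "lexRates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sister-pair lexical rates and their Bayesian Poisson models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexRates)
```

## The comparative design

The package implements a sister-pair analysis of lexical evolution.  A
*sister pair* (a cherry of the time-calibrated family tree) is two
languages whose most recent common ancestor is shared with no other
sampled language.  Differences between the two daughters accumulated
after their split, and because every language belongs to at most one
pair, pairs contribute independent observations.  The design trades
sample size for robustness: it needs no ancestral-state reconstruction
and no divergence-time estimates in the regression itself.

`extractCherries()` finds the cherries; `filterPairs()` applies three
screens modelled on standard practice with Bayesian language
phylogenies:

* minimum clade support, default posterior probability **0.80** — the
  pair must be a well-attested clade;
* a strict upper bound on divergence time — pairs whose "divergence"
  spans the entire tree depth are opposite ends of the phylogeny, not
  close relatives, and are excluded;
* an explicit reject list for decisions that cannot be automated
  (e.g. pairs whose subgrouping disagrees with a reference catalogue).

Polytomies are never cherries by default (`polytomy_pairs = FALSE`),
because sister pairs should come from a fully resolved tree; the
greedy pairing of polytomy tips exists only for sensitivity checks.
Both the single-branch divergence time and the two-branch path length
are carried on every pair, since published pair tables are ambiguous
about which "branch length" they report; on an ultrametric tree one is
exactly twice the other.

## Counting gains, losses and turnover

For one pair (A, B) with background languages G (by default every
other language in the matrix), and for every concept attested in
*both* sisters, each cognate set present in exactly one sister is one
event:

* present elsewhere in the family at the same concept → a **loss**,
  charged to the sister lacking it (the word was inherited and lost);
* present nowhere else → a **gain** by the sister holding it (an
  innovation since the split).

Sets present in both sisters or absent from both are uninformative.
Each qualifying set is one event regardless of concept, so a synonym
cell can contribute several events.  Decisions the data format forces
but the design leaves open:

* **Missing data vs. absence.**  A (language, concept) cell with no
  entry at all is *unattested* (nothing was collected); a cell whose
  entries were all loans is *attested but empty*.  Concepts unattested
  in either sister are skipped for that pair — a gap in collection
  cannot be distinguished from a loss, and conflating them would
  inflate loss counts.  Attested-but-empty cells do take part:
  the sister genuinely lacks a native word there.
* **Concept-scoped background matching** (default).  A background
  occurrence of a cognate-set id under a *different* concept does not
  rescue a loss, because cognacy is meaningful only within a meaning
  class.  `concept_scoped = FALSE` relaxes this to family-wide id
  matching for sensitivity analysis.
* **Loans** are removed before counting (`filterLoans()`); otherwise
  every borrowed word with no native cognate would masquerade as a
  gain, making sisters look more innovative than they are.

The counter is validated two ways: against a deliberately naive
brute-force classifier that enumerates every (concept, cognate set)
combination and applies the rules case by case, on a thousand random
matrices; and against the synthetic generator's exact round trip
(below).

## Predictors and the design table

Five per-language covariates enter the models after the
transformations in `transformPredictors()`:

| column | raw variable | transform |
|---|---|---|
| `logPopulation` | historical population size | `log` |
| `isolation` | km to nearest landmass inhabited by a different culture | `log(x + 1)` |
| `conflictWithin` | conflict within the community, ordinal 1–4 | reversed `5 − v` |
| `warfareInternal` | warfare between communities of one culture, 1–4 | reversed `5 − v` |
| `warfareExternal` | warfare with other cultures, 1–4 | reversed `5 − v` |

then each column is z-standardized over the analysis sample, making
effect sizes directly comparable.  `log(x + 1)` is used for distance
because a culture sharing the island is coded 0 km and the plain log
would be undefined; the +1 km offset preserves ordering and maps 0 to
0\.  The ordinal reversal `5 − v` puts *more* conflict at higher
values; any strictly decreasing map is equivalent after
standardization.  Standardization happens per language, before pair
aggregation, so all pairing modes share one predictor table.

**The pairing-mode question.**  The regression links a *pair-level*
count to *language-level* predictors, and the mapping from two sister
languages to one design row is genuinely under-determined.  The
package makes the choice explicit (`buildDesign(mode = ...)`):

* `pair_mean` (default): predictor = mean of the two sisters'
  standardized values, response = pair-total count.  This is the only
  symmetric, orientation-free summary of the pair's predictor level,
  and the default for all shipped analyses and simulations.
* `two_row`: one row per language with its own branch counts; doubles
  the nominal sample size and makes rows within a pair dependent, so
  it is offered for sensitivity, not inference.
* `signed_contrast` (experimental): within-pair differences oriented
  by a focal predictor, response = one branch's count.

Collinearity among the five predictors is checked with variance
inflation factors (`gvif()`); all predictors being continuous after
standardization, the generalized VIF reduces to the plain VIF
`1/(1 − R²_j)`, flagged at the conservative threshold 2.  Pairwise
Pearson correlations (`correlationMatrix()`) and a Pearson chi-square
independence test (`chisqIndependence()`) support the same screening;
the chi-square keeps conflict ordinals at their four levels and bins a
near-continuous variable at its raw distinct values, which routinely
triggers (and reports) the low-expected-count caveat.

## The Bayesian Poisson models

Each response (gains, losses, turnover) is modelled as
`y_i ~ Poisson(mu_i)` with
`log(mu_i) = alpha + sum_k beta_k x_ik`, under regularizing priors
`alpha ~ Normal(0, 10)` and `beta_k ~ Normal(0, 2)` — wide on the
intercept, mildly conservative on standardized effects.  No exposure
offset is used by default (the headline models are formulated on raw
counts); `offset =` accepts a log-exposure column such as pair path
length for sensitivity analyses.

**Sampler.**  Fits use the package's adaptive random-walk Metropolis
kernel, compiled via Rcpp.  During warm-up the global proposal scale
follows a Robbins–Monro recursion targeting 23.4% acceptance and the
proposal covariance is refreshed every 50 iterations from the second
half of the warm-up history (discarding the early transient); both are
frozen afterwards, so the post-warm-up chain is a valid
Metropolis sampler.  The kernel uses R's RNG, making every fit
bit-reproducible from `samplerConfig(seed = )`.  Defaults are 3 chains
× 10,000 iterations with 2,000 warm-up, pooling 24,000 draws; on these
small design matrices (≤ 50 rows, 6 parameters) a full fit takes well
under a second, and typical effective sample sizes are around 1,000.

**Diagnostics.**  Convergence is gated on split-Rhat ≤ 1.01 and
effective sample size ≥ 400 per parameter (autocorrelation-truncated
by Geyer's initial positive sequence).  Failures annotate the result
and raise a warning — never a silent pass; the staged pipeline
(`runFit()`) refuses to proceed unless told `allow_unconverged`.

**Summaries.**  Point estimates are posterior medians; uncertainty is
the 90% highest-posterior-density interval, computed as the narrowest
window of `ceiling(0.9 n)` consecutive sorted draws, ties broken
toward the lowest start.  An effect is called "significant" when its
90% HPDI excludes zero.  Model comparison uses WAIC
(`−2(lppd − p_waic)`, log-sum-exp stabilized, with a standard error
from the pointwise deviance spread), Akaike-style WAIC weights, and a
Poisson Bayesian R² computed per draw as
`Var_i(mu_i) / (Var_i(mu_i) + mean_i(mu_i))` — the model-implied
residual variance of a Poisson being its mean.  The fitted-value
variance uses the population form (divisor *n*), which keeps the
per-draw ratio an exact deterministic function of that draw's rates.
The 10-model candidate set is the null, the full model, the five
single-predictor models and three intermediate combinations; the
combinations are configuration, defaulting to demography+geography,
the three conflict scales, and geographic+social isolation
(`defaultModelSet()`).

## The synthetic generator

`simulateStudy()` makes the pipeline testable end to end with no
external data.  Its defaults are the study conditions of the shipped
analyses: **25 sister pairs**, **210 concepts**, **4 background
languages per pair** (disjoint across pairs, so loss detection is
unambiguous), population log-normal with median ≈ 26,500 speakers,
distance a mixture of 15% zeros (same-island neighbours) and a
log-normal with mean on the order of 100 km, conflict ordinals
categorical with most mass on the low-conflict codes, cherry
divergence times 500–2,500 years on a 4,300-year-deep ultrametric
tree with supports 0.85–1.  Gains and losses are simulated as two
independent Poisson log-linear processes with intercepts `log 8` and
`log 10` — a few tens of events per pair, the order observed in real
sister-pair counts — and a default coefficient vector
`(0.5, 0.2, 0.9, −0.3, −0.5)` mixing strong, weak and negative
effects.  When the two processes share one coefficient vector, their
sum (turnover) follows the same log-linear model with intercept
`log(e^{a_g} + e^{a_l})`, which is what the recovery reports target.

`realizeCognateMatrix()` then builds an actual cognate matrix whose
counts are *exactly* the simulated events: each pair's sisters share a
retained cognate set per concept (uninformative filler), every gain is
a globally unique set in the gaining sister, and every loss charged to
a sister is a set placed in the other sister plus one background
language.  Events are spread round-robin over concepts — several
events may share a concept, as synonym cells make legal — with a
capacity error naming the vocabulary size required when a pair carries
more than `n_concepts × max_events_per_concept` events.  The round
trip `tabulateEvents(realizeCognateMatrix(E)) = E` is exact by
construction, not statistical, and is asserted over randomized event
tables in the tests.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: sound change and orthographic
noise in cognate coding, undetected borrowing (loans appear only as
pre-flagged rows for filter tests), non-cherry tree shape, correlated
covariates (each predictor is drawn independently), and missing
wordlist entries (every synthetic cell is attested).  Real ABVD-style
data have all of these; the package's validation demonstrates the
*pipeline* is correct under its stated rules, not that the rules
capture every property of field data.

## Validation scale and expectations

The shipped validation (test suite and `scripts/acceptance.R`) runs at
the analysis scale the package targets: 1,000 random matrices for the
counter-vs-oracle check, 100 random event tables for the round trip,
and 20 end-to-end replicates of 25 pairs × 210 concepts for posterior
recovery (medians within 2 posterior SDs of truth for ≥ 90% of
parameters; every |β| ≥ 0.5 effect's 90% HPDI excluding zero in a
majority of replicates), interval calibration under a zero-effect
truth (coverage of zero close to the nominal 90%, within a binomial
band widened slightly upward because prior shrinkage makes credible
intervals mildly conservative), and WAIC selection of the generating
full model.  The whole set completes in about a minute on one CPU.

## Known limitations

* A `CognateMatrix` cell that is attested but empty survives
  filtering in memory but has no row representation on disk, so
  `writeWordlists()` after `filterLoans()` loses the distinction;
  serialize before filtering when it matters.
* The counter treats the background as a flat set: a cognate set
  shared only between the two sisters is always classified as
  (two copies of) inherited-nothing — there is no attempt to infer
  deeper ancestry from tree structure.
* `two_row` mode ignores the within-pair dependence of its two rows;
  it is a sensitivity device.
* The Metropolis sampler is tuned for the small, well-conditioned
  designs this analysis produces (tens of rows, ≤ 6 parameters).  For
  much larger designs a gradient-based sampler would be preferable;
  the backend contract (draws + pointwise log-likelihood) keeps that
  swap local to `fitPoissonGLM()`.
* The chi-square screening test is asymptotic and its binning of
  near-continuous variables is a convention; with many sparse cells
  its p-value is approximate, which the function reports.
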