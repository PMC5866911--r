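---
title: "Heat-stress feeding behaviour: phenotypes, Bayes-C GWAS and window decomposition"
author: "heatfeed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-stress feeding behaviour: phenotypes, Bayes-C GWAS and window decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Grow-finish pigs change their feeding behaviour as heat load rises: some
animals barely react while others sharply reduce time at the feeder. If
that individual difference is partly genetic, it can be selected on.
`heatfeed` implements the full chain needed to study this on electronic
feeder (RFID) data: heat-load classification of days, construction of
standardized pairwise feeding-behaviour traits, Bayesian whole-genome
regression to estimate genomic heritability and localize signal into
1-Mb windows, and a gene-ontology over-representation test for the genes
under those windows. A synthetic-data generator with known truth makes
every stage testable without access to confidential farm data.

## Heat-load classification

Hourly temperature `T` (deg C) and relative humidity `RH` (percent) give
the temperature-humidity index

$$\mathrm{THI} = T - (0.55 - 0.0055\,\mathrm{RH})(T - 14.5),$$

evaluated exactly and never clamped. Each day is summarized by its
maximum hourly THI and binned with lower-inclusive boundaries into
Normal (< 23.33), Alert ([23.33, 26.11)), Danger ([26.11, 28.88)) and
Emergency (>= 28.88) categories. Two fixed points of the formula are
useful for testing: at `T = 14.5` the THI is 14.5 regardless of
humidity, and at `RH = 100` the THI equals the temperature.

Days with fewer than `min_hours = 18` hourly records are dropped rather
than imputed: weather-station gaps are rare and a day's maximum computed
from a fragment of the day would be biased downward. The threshold is an
argument, not a constant, because the right choice depends on the gap
structure of the sensor at hand.

`fit_barn_model()` regresses barn temperature on a cubic polynomial of
outdoor THI by ordinary least squares (`stats::lm`), the standard check
that an outdoor weather station is an acceptable proxy for conditions
inside the barn.

## Pairwise-THI feeding traits

Each animal-day is summarized by the count of 20-second RFID feeder
detections ("pings", at most 4320 in a day). Per animal and heat-load
category we take the mean daily count, subtract the mean of the animal's
sire-breed-by-sex contemporaries in that category, and scale the
deviations to unit sample standard deviation within the category. The
resulting z-values have mean 0 and SD 1 in every category by
construction, which the tests assert to 1e-10.

For each ordered pair of categories (cooler, hotter) the trait is
`z(cooler) - z(hotter)`: positive values mark animals that reduced their
relative feeding activity as heat load rose, i.e. heat-sensitive
animals. Four categories give six traits. An animal contributes a trait
only when it has data in both categories; animals that experienced a
single category carry no contrast and are excluded.

Two construction choices were genuinely open and are worth recording.
First, standardization pools across grow-finish groups; the contemporary
group enters later as a fixed effect of the GWAS model rather than in
phenotype construction. Second, the sample (n-1) standard deviation is
used; the mean-0/SD-1 contract holds either way, so this only rescales
by a factor common to all animals.

## The Bayes-C / Bayes-Cpi model

For one trait `y` (length n) the model is

$$y = X\beta + Zu + e,$$

with `X` the incidence of intercept, sex, sire breed and contemporary
group (farrowing group x pen), `Z` the column-centered marker dosages,
and `e ~ N(0, sigma^2_e I)`. Each marker effect is a mixture: with
probability `pi` it is exactly zero, otherwise `N(0, sigma^2_u)` with a
single effect variance shared by all included markers. Fixed effects get
a flat prior; the variances get scaled-inverse-chi-square priors with 4
degrees of freedom and scale set so the prior mode equals the supplied
prior variance (0.10 by default for both, appropriate for traits with
total variance of a few tenths, which the standardized pairwise traits
are). Breed and sex stay in `X` even though the trait is already a
breed-sex deviation, to absorb residual population stratification
carried by the genotypes.

The Gibbs sampler (compiled C++) cycles: each fixed effect from its
normal full conditional; each marker, in a fresh random permutation per
iteration, sampling the inclusion indicator from the marginal likelihood
with the effect integrated out and then the effect from its normal full
conditional; the two variances from their scaled-inverse-chi-square full
conditionals; and, in Bayes-Cpi mode, `pi` from `Beta(m - k + 1, k + 1)`
(uniform prior), where `k` is the number of currently included markers.

### The per-marker prior scale and why it is tied to pi

The supplied genetic prior variance is interpreted on the genomic scale
and converted to a per-marker scale as

$$S_u = \frac{\sigma^2_{g,\mathrm{prior}}}{(1-\pi)\sum_j 2p_j(1-p_j)},$$

recomputed inside the sampler as `pi` moves. The `(1 - pi)` factor is
not cosmetic. Without it the model has an unidentifiable ridge: on data
with no genetic signal the effect variance can collapse towards zero,
every Bayes factor for inclusion flattens to 1, and `pi` performs a pure
random walk over (0, 1) — we observed exactly this in development traces.
Spreading the prior genomic variance over only the `(1 - pi) m` markers
expected to carry effects creates a restoring force: as `pi` rises the
per-marker scale grows, inclusion of noise markers is penalized harder,
and on null data the posterior of `pi` concentrates near 1 (about 0.9986
at n = 500, m = 1000 in the test suite), which is also how the
variable-selection software this model family comes from behaves.

### Chains, convergence, reproducibility

Bayes-Cpi runs 8100 iterations (burn-in 100) and extends in 8000-
iteration blocks until the split-half difference of the post-burn-in
mean of `pi` falls below 1e-4, capped at 56,100 iterations; the
per-iteration `pi` trace is kept for inspection with `plot(fit)`. The
Bayes-C analysis chain defaults to 41,000 iterations, burn-in 1000,
thinning 40, i.e. 1000 saved states. The sampler draws from R's RNG
stream, so a seed makes entire fits byte-reproducible, and chain blocks
resume exactly (the extension is a continuation, not a restart).

Per saved state the sampler records the variances, `pi`, the genomic
variance (the sample variance of `Zu` across animals) and
`h^2 = var_g / (var_g + sigma^2_e)`. The reported heritability is the
posterior mean over all saved states; its uncertainty is the sample SD
of the final 100 saved states, a deliberately simple spread measure that
matches how such analyses conventionally report it.

### Correctness checks

Two independent oracles guard the sampler. With `pi = 0` and the
variances held fixed (the infinite-degrees-of-freedom limit,
`fix_variances = TRUE`), the posterior mean of `u` has the closed form
`(Z'Z + I sigma^2_e / sigma^2_u)^{-1} Z'y`; the test suite checks
agreement within batch-means Monte-Carlo standard errors (naive standard
errors understate the error because the chain is autocorrelated). And
per saved state the stored genomic variance must equal the variance of
`Zu` recomputed from the saved effects, which ties the summary output to
the states themselves.

## 1-Mb window decomposition

Markers are assigned to non-overlapping windows `floor(bp / 1e6)` per
chromosome — genome-anchored windows, matching the integer megabase
positions such analyses report; sliding windows were rejected to keep
window identities stable across traits. Per saved state the window share
is `var(Z_w u_w) / var(Zu)` across animals, and the reported percentage
is 100 times the posterior mean of the per-state shares (the alternative
— share of posterior means — over-weights states with small total
variance; states with exactly zero total genomic variance are skipped
and counted). Windows above 1% of genomic variance are flagged
`reported`, above 3% `top`. For gene-list construction,
`merge_adjacent()` keeps only the largest window of each run of adjacent
windows all exceeding 3%, reading "greatest estimated effect" as the
greatest variance percentage.

With unlinked markers the shares are nearly additive; the suite checks
that they sum to 90–110% and that a planted major QTL's window ranks
first in at least 9 of 10 seeded replicates.

## Gene-ontology over-representation

Genes overlap a window if their 1-based inclusive interval intersects
`[k Mb, (k+1) Mb)` by at least one base (GenomicRanges does the interval
work); duplicates across windows collapse. For each term with at least
one annotated background gene, the expected count is `n K / N` and the
two-sided p-value is the minimum-likelihood binomial tail: the sum of
`P(X = j)` over all outcomes no more likely than the observed count
under `Binomial(n, K/N)`. Bonferroni correction multiplies by the number
of terms tested within the same ontology aspect, mirroring tools that
correct within ontology. The background is an explicit argument
(defaulting to all annotated genes) rather than a constant, because
published expected counts are often computed against tool-internal
backgrounds that differ slightly from any file the user can supply.

## The synthetic cohort

The generator emulates the structure of a grow-finish feeding study:
grow-finish groups of about 240 pigs in six pens, two farrowing groups
per grow-finish group, three sire breeds (Duroc, Landrace, Yorkshire, in
roughly 0.19/0.48/0.33 proportions) over a composite dam line, litters
of 6 full sibs nested in paternal half-sib families of about 24.
Genotypes come from a gene drop: founder allele frequencies uniform on
`maf_range`, Bernoulli founder haplotypes, independent Mendelian
sampling per marker (no linkage map — deliberately, since the window
analysis only needs positions, not LD).

Daily ping counts are negative-binomial with mean

`baseline(breed, sex, category) + permanent_animal + g * contrast(category)`

where `contrast` is the linear 0/1/2/3 coding of the ordered categories
and `g` is the genetic heat-response value from `n_qtl` planted additive
QTL. The defaults encode the study conditions this package models:
baseline means per breed-sex-category (e.g. Landrace gilts fall from
129.3 pings/day on Normal days to 62.4 on Emergency days, while Duroc
barrows rise from 154.8 to 194.3), 60/20/12/8 days per category (a
realistic mid-western summer exposure for a four-month stay), permanent
animal SD of 15 pings/day, negative-binomial size 20 (day-to-day CV
around 25% at typical means — the within-animal dispersion is not
published anywhere, so this is the one free parameter, chosen once as
realistic), and 10% per-category dropout mimicking tag loss. Counts are
overdispersed rather than Poisson because published standard errors of
daily ping means exceed Poisson expectation.

`target_h2` calibrates the genetic variance by solving, in closed form
up to root finding, the heritability of a designated pairwise trait
(default Normal-Emergency) under the generative model: category-mean
noise `(mu + mu^2/size)/n_days`, the shared permanent effect, and the
per-category standardization. The realized heritability recorded in the
truth set is the squared correlation between each derived trait and the
true genetic values — exact for this generative model because the
genetic effect enters each trait linearly. At n = 800 the realized value
for the target trait lands within about 0.05 of the target.

What the simulator does **not** reproduce: linkage disequilibrium and
recombination hotspots, feeder-slot competition between penmates,
diurnal feeding rhythms within a day, and chip-specific marker panels.
Passing tests therefore demonstrate correctness of the estimators under
a faithful but idealized architecture, not robustness to every artefact
of real feeder data.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately scaled instances chosen to
exercise each property at the smallest size where it is informative:
ridge equivalence at 50 animals x 100 markers; heritability recovery at
800 animals x 2000 markers with 20 QTL and 10,000-iteration chains;
window ranking at 300 x 500 across ten seeds; the Bayes-Cpi null at
500 x 1000. Degenerate inputs fail loudly rather than silently: zero
variance within a category, all-missing markers, ping dates missing from
the day classification, and rank-deficient barn-model designs all raise
errors naming the offending records; negative simulated daily means are
clamped at 0.1 pings with a message counting the clamps.

## A worked example

```{r, eval = FALSE}
library(heatfeed)

cfg <- sim_config(n_animals = 480, n_snps = 2000, n_qtl = 20,
                  target_h2 = 0.25, seed = 42)
sim <- simulate_study(cfg)

prof   <- category_profile(daily_counts(sim$pings), sim$day_classes)
z      <- standardize_deviations(prof, sim$meta)
traits <- pairwise_traits(z)
trait_correlations(traits)

qc  <- qc_genotypes(sim$G, sim$map)
des <- build_design(traits, "Normal-Emergency", sim$meta, qc$G)

prior <- bayesc(des, pi = "estimate", seed = 1)       # Bayes-Cpi
fit   <- bayesc(des, pi = mean(prior$samples$pi),     # Bayes-C
                seed = 1)
summary(fit)
windows <- window_variance(fit, qc$map)
windows[windows$reported, ]
```

`run_pipeline()` chains these stages for all six traits, feeds each
trait's Bayes-Cpi posterior `pi` into its Bayes-C run, and writes a JSON
manifest with seeds, counts and checksums so a rerun with the same
configuration is reproducible and skippable.

## Known limitations

The sampler implements Bayes-C/Bayes-Cpi only; BayesA/B/R variants,
REML/GBLUP and multi-trait models are out of scope. Mean-dosage filling
of missing genotypes ignores pedigree information and slightly shrinks
marker variance. The `pi` posterior on small null datasets is heavy
on the high side but not degenerate at 1; chains on data with
`m` close to `n` deserve a look at `plot(fit)` before trusting a single
number. Window percentages are posterior means of ratios and are not
guaranteed to sum to exactly 100 when markers are correlated.
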