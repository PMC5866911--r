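# heatfeed

Genetics of heat-stress response in grow-finish pigs, measured through
feeding behaviour. `heatfeed` is for quantitative geneticists and
livestock scientists who have (or want to simulate) electronic-feeder
RFID data, weather records and SNP genotypes, and who want to estimate
how heritable the *change* in feeding activity under heat load is and
where in the genome that variation sits.

The package covers the full chain:

1. **Heat-load classification** — hourly temperature-humidity index
   `THI = T − (0.55 − 0.0055·RH)(T − 14.5)` (°C), days binned by their
   maximum THI into Normal / Alert / Danger / Emergency with
   lower-inclusive cut points 23.33, 26.11, 28.88 °C.
2. **Pairwise-THI traits** — daily RFID ping counts per animal are
   averaged within each category, expressed as deviations from the
   sire-breed × sex mean, standardized to mean 0 / SD 1 per category,
   and differenced between each of the six category pairs
   (`z(cooler) − z(hotter)`).
3. **Marker QC** — minor-allele-frequency filter (markers with
   MAF < 5% removed, the boundary kept), removal of markers without a
   unique map position, mean-dosage fill of residual missing genotypes.
4. **Bayes-C / Bayes-Cπ whole-genome regression** — the mixture model
   `y = Xβ + Zu + e` with marker effects zero with probability π and
   otherwise `N(0, σ²ᵤ)` (common variance), fitted by a compiled Gibbs
   sampler; genomic heritability `h² = var(Zu)/(var(Zu) + σ²ₑ)` per
   posterior state; Bayes-Cπ estimates π, whose posterior mean then
   fixes π for the Bayes-C analysis chain.
5. **1-Mb windows** — genomic variance decomposed into
   `floor(bp/1e6)` windows per chromosome (posterior mean of per-state
   variance shares), with 1% / 3% flags and pruning of adjacent
   high-variance windows.
6. **GO over-representation** — genes overlapping reported windows are
   tested per ontology term with a two-sided (minimum-likelihood)
   binomial test against `Binomial(n, K/N)`, Bonferroni-corrected
   within aspect.
7. **Synthetic cohorts** — a generator with pedigree gene drop, planted
   QTL, negative-binomial daily counts and known variance components,
   so every stage above is testable against ground truth.

## Worked example

```r
library(heatfeed)

cfg <- sim_config(n_animals = 480, n_snps = 2000, n_qtl = 20,
                  target_h2 = 0.25, seed = 42)
sim <- simulate_study(cfg)
print(sim$truth)
#> Simulation truth set
#>   20 QTL, genetic variance 7.108 (target h2 0.25)
#>   realized h2 per pairwise trait:
#>     Normal-Alert    Normal-Danger Normal-Emergency     Alert-Danger
#>            0.070            0.186            0.312            0.039
#>  Alert-Emergency Danger-Emergency
#>            0.134            0.024

prof   <- category_profile(daily_counts(sim$pings), sim$day_classes)
z      <- standardize_deviations(prof, sim$meta)
traits <- pairwise_traits(z)

qc  <- qc_genotypes(sim$G, sim$map)
des <- build_design(traits, "Normal-Emergency", sim$meta, qc$G)
fit <- bayesc(des, pi = 0.99, n_iter = 10000, burnin = 1000, thin = 10,
              seed = 1)
print(fit)
#> BayesC whole-genome regression: trait 'Normal-Emergency'
#>   381 animals, 1967 markers, 27 fixed-effect columns
#>   chain: 10000 iterations (burn-in 1000, thin 10), 900 saved states
#>   posterior mean h2: 0.370 (SD of last 100 samples 0.054)
#>   posterior mean pi: 0.990000

windows <- window_variance(fit, qc$map)
head(windows[order(-windows$pct_genomic_variance),
             c("chromosome", "window_mb", "pct_genomic_variance", "n_snps")])
#>    chromosome window_mb pct_genomic_variance n_snps
#> 30          2         9            30.241105     22
#> 55          3        14            11.544584     24
#> 10          1         9             7.138932     21
#> 60          3        19             6.785582     25
#> 16          1        15             6.201658     16
#> 17          1        16             5.904524     19
```

The simulated cohort carries a planted genetic heat response with a
target Normal-Emergency heritability of 0.25 (realized 0.31 in this
draw); the fit recovers a posterior mean h2 of 0.37, and the windows
table ranks 1-Mb regions by their share of genomic variance -- four of
the six top windows above contain planted QTL (chromosome 2 window 9,
chromosome 3 window 14, chromosome 1 windows 9 and 16). `run_pipeline(pipeline_config(...))`
chains all stages for all six traits and writes TSV outputs plus a JSON
manifest; `inst/scripts/run-pipeline.R` wraps it for the shell.

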