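# Shared fixtures, built in code at test time.

# Random dosage matrix with per-marker allele frequencies.
toy_dosages <- function(n, m, freq = NULL, seed = 1) {
  set.seed(seed)
  freq <- freq %||% runif(m, 0.1, 0.5)
  Z <- vapply(freq, function(p) rbinom(n, 2L, p), integer(n))
  dimnames(Z) <- list(sprintf("A%03d", seq_len(n)),
                      sprintf("M%03d", seq_len(m)))
  Z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small cohort with pings spanning all four THI categories.
toy_cohort <- function(n_animals = 40, seed = 3) {
  cfg <- sim_config(n_animals = n_animals, n_groups = 1, n_snps = 50,
                    n_chromosomes = 2, n_qtl = 5, target_h2 = 0.2,
                    n_days_per_category = c(Normal = 10, Alert = 6,
                                            Danger = 4, Emergency = 3),
                    dropout = 0, seed = seed)
  simulate_study(cfg)
}

# Batch-means Monte-Carlo standard errors of posterior-mean effects.
batch_mcse <- function(effects, n_batches = 40) {
  S <- nrow(effects)
  bs <- S %/% n_batches
  bm <- vapply(seq_len(n_batches), function(b) {
    colMeans(effects[((b - 1) * bs + 1):(b * bs), , drop = FALSE])
  }, numeric(ncol(effects)))
  apply(bm, 1, sd) / sqrt(n_batches)
}
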