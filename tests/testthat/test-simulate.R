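test_that("weather simulation is deterministic, bounded and well-shaped", {
  w <- simulate_weather(5, weather_profile(), seed = 2)
  expect_equal(nrow(w), 5 * 24)
  expect_true(all(w$rh_pct >= 0 & w$rh_pct <= 100))
  expect_identical(w, simulate_weather(5, weather_profile(), seed = 2))
  expect_equal(nrow(simulate_weather(0)), 0L)
  expect_error(simulate_weather(-1), "n_days")
})

test_that("constant 30 C / 50% profile classifies every day as Alert", {
  prof <- weather_profile(t_mean = 30, t_diurnal_amp = 0, rh_mean = 50,
                          rh_diurnal_amp = 0, t_sd = 0, rh_sd = 0)
  w <- simulate_weather(4, prof, seed = 1)
  d <- classify_days(w)
  expect_equal(d$max_thi_c, rep(25.7375, 4))
  expect_true(all(d$category == "Alert"))
})

test_that("a seasonal profile spanning 10-35 C produces all four categories", {
  prof <- weather_profile(t_mean = 22.5, t_season_amp = 10,
                          t_diurnal_amp = 2.5, rh_mean = 60,
                          rh_season_amp = -15, rh_diurnal_amp = 5,
                          t_sd = 0.5, rh_sd = 2, season_period = 120)
  w <- simulate_weather(120, prof, seed = 7)
  expect_true(all(w$temp_c > 5) && all(w$temp_c < 40))
  d <- classify_days(w)
  expect_setequal(as.character(unique(d$category)), thi_categories())
})

test_that("population structure matches the configured design", {
  cfg <- sim_config(n_animals = 240, n_groups = 1, n_pens_per_group = 6,
                    seed = 3)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$meta), 240L)
  expect_setequal(unique(pop$meta$sire_breed),
                  c("Duroc", "Landrace", "Yorkshire"))
  expect_equal(as.integer(table(pop$meta$pen)), rep(40L, 6))
  expect_equal(length(unique(pop$meta$farrowing_group)), 2L)
  # pedigree: every offspring has a sire and dam among the founders
  off <- pop$pedigree[!is.na(pop$pedigree$sire), ]
  founders <- pop$pedigree$id[is.na(pop$pedigree$sire)]
  expect_true(all(off$sire %in% founders))
  expect_true(all(off$dam %in% founders))
  # empty cohort
  empty <- simulate_population(sim_config(n_animals = 0))
  expect_equal(nrow(empty$meta), 0L)
})

test_that("gene-drop genotypes have valid dosages, MAFs and relatedness", {
  cfg <- sim_config(n_animals = 2000, n_groups = 4, n_snps = 2000,
                    maf_range = c(0.1, 0.5), seed = 5)
  pop <- simulate_population(cfg)
  geno <- simulate_genotypes(pop$pedigree, cfg)
  expect_true(all(geno$G %in% 0:2))
  expect_equal(dim(geno$G), c(2000L, 2000L))
  # realized MAFs near the founder range (binomial draw + drift slack)
  maf <- compute_maf(geno$G)
  expect_true(all(maf >= 0.05 & maf <= 0.55))
  # map: unique positions within chromosome
  expect_false(any(duplicated(geno$map[c("chromosome", "position_bp")])))

  # VanRaden relatedness of full sibs around 0.5
  p <- colMeans(geno$G) / 2
  W <- sweep(geno$G, 2, 2 * p)
  GRM <- tcrossprod(W) / sum(2 * p * (1 - p))
  ped <- pop$pedigree[match(rownames(geno$G), pop$pedigree$id), ]
  fam <- paste(ped$sire, ped$dam)
  sibs <- split(seq_len(nrow(GRM)), fam)
  vals <- unlist(lapply(sibs, function(ix) {
    if (length(ix) < 2) return(NULL)
    gg <- GRM[ix, ix]
    gg[upper.tri(gg)]
  }))
  expect_equal(mean(vals), 0.5, tolerance = 0.05)
  expect_error(simulate_genotypes(pop$pedigree,
                                  sim_config(n_snps = 3, n_chromosomes = 5)),
               "n_snps")
})

test_that("simulated pings reproduce the configured baselines", {
  cfg <- sim_config(n_animals = 800, n_groups = 4, seed = 3, target_h2 = 0.1)
  sim <- simulate_study(cfg)
  # conservation: every ping animal and date is known
  expect_true(all(sim$pings$animal_id %in% sim$meta$animal_id))
  expect_true(all(sim$pings$date %in% sim$day_classes$date))
  expect_true(all(sim$pings$pings >= 0))
  # Landrace pooled Normal mean near its configured 134.3 pings/day
  prof <- category_profile(daily_counts(sim$pings), sim$day_classes)
  land <- sim$meta$animal_id[sim$meta$sire_breed == "Landrace"]
  pn <- prof[prof$animal_id %in% land & prof$category == "Normal", ]
  expect_gt(nrow(pn), 300)
  expect_equal(mean(pn$mean_pings), 134.3, tolerance = 3 / 134.3)
})

test_that("the generator is deterministic and the heritability dial is monotone", {
  cfg <- sim_config(n_animals = 120, n_groups = 1, n_snps = 100,
                    n_chromosomes = 2, n_qtl = 5, target_h2 = 0.2, seed = 21)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$pings, s2$pings)
  expect_identical(s1$G, s2$G)
  expect_identical(s1$truth$qtl_effects, s2$truth$qtl_effects)

  h2_at <- function(vg) {
    cfg <- sim_config(n_animals = 500, n_groups = 2, n_snps = 300,
                      n_chromosomes = 3, n_qtl = 10, var_genetic = vg,
                      dropout = 0, seed = 33)
    sim <- simulate_study(cfg)
    sim$truth$realized_h2[["Normal-Emergency"]]
  }
  grid <- c(0, 2, 20)
  h2s <- vapply(grid, h2_at, numeric(1))
  expect_true(all(diff(h2s) >= 0))
})

test_that("zero variance components give realized h2 of zero", {
  cfg <- sim_config(n_animals = 80, n_groups = 1, n_snps = 60,
                    n_chromosomes = 2, n_qtl = 5, var_genetic = 0,
                    var_animal = 0, dropout = 0, seed = 9)
  sim <- simulate_study(cfg)
  expect_equal(unname(sim$truth$realized_h2), rep(0, 6))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_qtl = 50, n_snps = 10), "n_qtl")
  expect_error(sim_config(var_animal = -1), "var_animal")
  bad_base <- default_baseline_pings()
  bad_base$mean_pings[1] <- 0
  expect_error(sim_config(baseline_pings = bad_base), "positive")
})

test_that("a simulated study round-trips through its writers", {
  sim <- toy_cohort(n_animals = 12, seed = 14)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("pings.tsv", "meta.tsv", "days.tsv", "genotypes.tsv", "map.tsv",
      "genotypes.ped", "genotypes.map", "truth_qtl.tsv")))))
  pings <- read_pings(file.path(dir, "pings.tsv"))
  expect_equal(nrow(pings), nrow(sim$pings))
  G <- read_dosage(file.path(dir, "genotypes.tsv"))
  expect_equal(unname(G), unname(sim$G * 1.0))
})
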