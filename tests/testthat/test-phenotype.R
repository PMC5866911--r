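make_days <- function() {
  make_day_classes(c(Normal = 3, Alert = 2, Danger = 2, Emergency = 1),
                   start_date = "2015-07-01")
}

test_that("daily_counts aggregates detections and honours the roster", {
  base <- as.POSIXct("2015-07-01 08:00:00", tz = "UTC")
  det <- data.frame(animal_id = c("a1", "a1", "a1", "a2"),
                    timestamp = base + c(0, 20, 40, 0))
  dc <- daily_counts(det)
  expect_equal(dc$pings[dc$animal_id == "a1"], 3L)
  expect_equal(dc$pings[dc$animal_id == "a2"], 1L)

  # duplicates are removed with a message
  det_dup <- rbind(det, det[1, ])
  expect_message(dc2 <- daily_counts(det_dup), "duplicate")
  expect_equal(dc2, dc)

  # roster animal-day with no detections appears with count 0
  ros <- data.frame(animal_id = c("a1", "a3"),
                    date = as.Date("2015-07-01"))
  dc3 <- daily_counts(det, roster = ros)
  expect_equal(dc3$pings[dc3$animal_id == "a3"], 0L)

  # pre-aggregated counts pass through; physical bound enforced
  cnt <- data.frame(animal_id = "a1", date = "2015-07-01", pings = 4320)
  expect_equal(daily_counts(cnt)$pings, 4320L)
  cnt$pings <- 4321
  expect_error(daily_counts(cnt), "physical maximum")
})

test_that("category_profile averages per animal and category", {
  days <- make_days()
  pings <- data.frame(
    animal_id = c("a1", "a1", "a1", "a2"),
    date = days$date[c(1, 2, 4, 1)],   # two Normal days + one Alert
    pings = c(100L, 200L, 150L, 50L))
  prof <- category_profile(pings, days)
  n_row <- prof[prof$animal_id == "a1" & prof$category == "Normal", ]
  expect_equal(n_row$mean_pings, 150)
  expect_equal(n_row$n_days, 2L)
  expect_equal(prof$mean_pings[prof$animal_id == "a1" &
                               prof$category == "Alert"], 150)
  # no Danger data -> no Danger row
  expect_false(any(prof$category == "Danger"))
  # unknown date is a hard error naming the date
  bad <- rbind(pings, data.frame(animal_id = "a1",
                                 date = as.Date("2020-01-01"), pings = 1L))
  expect_error(category_profile(bad, days), "2020-01-01")
})

test_that("standardization yields mean 0 / SD 1 per category and the
           two-animal case gives z of +-0.7071", {
  sim <- toy_cohort()
  prof <- category_profile(daily_counts(sim$pings), sim$day_classes)
  z <- standardize_deviations(prof, sim$meta)
  for (cc in unique(z$category)) {
    zz <- z$z[z$category == cc]
    expect_lt(abs(mean(zz)), 1e-10)
    expect_lt(abs(sd(zz) - 1), 1e-10)
  }

  prof2 <- data.frame(animal_id = c("a1", "a2"),
                      category = factor(c("Normal", "Normal"),
                                        levels = thi_categories(),
                                        ordered = TRUE),
                      mean_pings = c(100, 200), n_days = c(3L, 3L))
  meta2 <- data.frame(animal_id = c("a1", "a2"),
                      sire_breed = "Duroc", sex = "gilt")
  z2 <- standardize_deviations(prof2, meta2)
  expect_equal(sort(z2$z), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # all animals identical -> degenerate category
  prof3 <- prof2
  prof3$mean_pings <- c(100, 100)
  expect_error(standardize_deviations(prof3, meta2), "degenerate")
})

test_that("z-values are invariant to a constant shift within a breed-sex cell", {
  sim <- toy_cohort(seed = 5)
  prof <- category_profile(daily_counts(sim$pings), sim$day_classes)
  z1 <- standardize_deviations(prof, sim$meta)
  cell <- sim$meta$animal_id[sim$meta$sire_breed == "Landrace" &
                             sim$meta$sex == "gilt"]
  prof2 <- prof
  prof2$mean_pings[prof2$animal_id %in% cell] <-
    prof2$mean_pings[prof2$animal_id %in% cell] + 57
  z2 <- standardize_deviations(prof2, sim$meta)
  expect_equal(z2$z, z1$z, tolerance = 1e-10)
})

test_that("pairwise traits: six per full animal, exclusions, sign convention", {
  z <- data.frame(
    animal_id = c(rep("full", 4), rep("two", 2), "one"),
    category = factor(c(thi_categories(), "Normal", "Alert", "Normal"),
                      levels = thi_categories(), ordered = TRUE),
    z = c(1.0, -0.5, 0.25, -1, 0.3, 0.1, 2))
  tt <- pairwise_traits(z)
  expect_setequal(tt$animal_id, c("full", "two"))
  full <- tt[tt$animal_id == "full", pairwise_trait_names()]
  expect_equal(sum(!is.na(full)), 6L)
  expect_equal(full[["Normal-Alert"]], 1.5)  # z(Normal) - z(Alert)
  expect_equal(full[["Alert-Danger"]], -0.75)
  two <- tt[tt$animal_id == "two", pairwise_trait_names()]
  expect_equal(sum(!is.na(two)), 1L)

  # antisymmetry: the trait equals cooler minus hotter, so reversing the
  # pair negates the value
  zw <- attr(tt, "z")
  for (pair in pairwise_trait_names()) {
    cats <- strsplit(pair, "-")[[1]]
    fwd <- zw[, cats[1]] - zw[, cats[2]]
    expect_equal(unname(tt[[pair]]), unname(fwd))
    expect_equal(unname(zw[, cats[2]] - zw[, cats[1]]), unname(-fwd))
  }
})

test_that("trait correlations match a sum-formula Pearson oracle", {
  set.seed(21)
  sim <- toy_cohort(n_animals = 60, seed = 8)
  prof <- category_profile(daily_counts(sim$pings), sim$day_classes)
  z <- standardize_deviations(prof, sim$meta)
  tt <- pairwise_traits(z)
  r <- trait_correlations(tt)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 6))

  pearson <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]; n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  for (i in 1:5) for (j in (i + 1):6) {
    a <- tt[[pairwise_trait_names()[i]]]
    b <- tt[[pairwise_trait_names()[j]]]
    if (sum(!is.na(a) & !is.na(b)) >= 3)
      expect_equal(r[i, j], pearson(a, b), tolerance = 1e-12)
  }

  # too few complete pairs -> NA
  tt_small <- tt[1:2, ]
  r2 <- trait_correlations(tt_small)
  expect_true(is.na(r2[1, 2]))
})

test_that("a cohort with no genetic variance shows no trait-truth correlation", {
  cfg <- sim_config(n_animals = 150, n_groups = 1, n_snps = 100,
                    n_chromosomes = 2, n_qtl = 5, var_genetic = 0,
                    target_h2 = NULL, dropout = 0, seed = 17)
  sim <- simulate_study(cfg)
  expect_equal(unname(sim$truth$realized_h2), rep(0, 6))
  prof <- category_profile(daily_counts(sim$pings), sim$day_classes)
  z <- standardize_deviations(prof, sim$meta)
  tt <- pairwise_traits(z)
  g <- sim$truth$genetic_values[tt$animal_id]
  for (tr in pairwise_trait_names()) {
    ok <- !is.na(tt[[tr]])
    if (sum(ok) > 10) {
      r <- suppressWarnings(cor(tt[[tr]][ok], g[ok]))
      if (!is.na(r)) expect_lt(abs(r), 3 / sqrt(sum(ok)))
    }
  }
})
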