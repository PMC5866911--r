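# Synthetic-data generator: weather, a two-generation pig population,
# gene-drop genotypes with planted QTL, and overdispersed daily RFID
# ping counts with known variance components.

#' Default breed x sex x THI-category baseline feeding activity
#'
#' Mean daily RFID ping counts for each sire breed, sex and heat-load
#' category. Duroc- and Yorkshire-sired pigs feed more as heat load
#' rises while Landrace-sired pigs feed markedly less, and barrows
#' exceed gilts throughout.
#'
#' @return data frame `sire_breed`, `sex`, `category`, `mean_pings`.
#' @export
default_baseline_pings <- function() {
  cats <- thi_categories()
  vals <- rbind(
    c("Duroc",     "barrow", 154.8, 179.0, 183.5, 194.3),
    c("Duroc",     "gilt",   152.0, 159.1, 162.1, 171.1),
    c("Yorkshire", "barrow", 156.5, 160.5, 170.7, 188.4),
    c("Yorkshire", "gilt",   130.9, 135.5, 137.5, 137.2),
    c("Landrace",  "barrow", 140.3, 131.7, 118.0,  71.2),
    c("Landrace",  "gilt",   129.3, 115.6, 101.7,  62.4)
  )
  out <- data.frame(
    sire_breed = rep(vals[, 1], each = 4),
    sex = rep(vals[, 2], each = 4),
    category = rep(cats, times = 6),
    mean_pings = as.numeric(t(vals[, 3:6])),
    stringsAsFactors = FALSE
  )
  out
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort. Defaults emulate the
#' grow-finish study structure at reduced scale: two groups of ~240
#' pigs in six pens each, three sire breeds over a Landrace-Yorkshire
#' dam line, litters of 6 full sibs in paternal half-sib families of
#' ~24, and a polygenic-plus-major-QTL architecture for the heat
#' response.
#'
#' @param n_animals number of phenotyped offspring.
#' @param n_groups grow-finish groups.
#' @param n_pens_per_group pens per group.
#' @param breed_labels sire-breed names.
#' @param breed_props sire-breed proportions (sires are allocated
#'   deterministically in these proportions, so every breed is present).
#' @param litter_size full sibs per litter.
#' @param dams_per_sire litters per sire (paternal half-sib family size
#'   is `litter_size * dams_per_sire`).
#' @param n_chromosomes,chrom_length_mb,n_snps marker panel layout.
#' @param maf_range founder allele-frequency interval, within (0, 0.5].
#' @param n_qtl markers given a causal effect on the heat response.
#' @param target_h2 intended heritability of the designated pairwise
#'   trait (see `target_pair`); used to calibrate `var_genetic` when the
#'   latter is NULL.
#' @param target_pair pairwise trait the calibration targets.
#' @param var_genetic variance of the genetic heat-response value
#'   across animals (per unit of category contrast); NULL = calibrate
#'   from `target_h2`.
#' @param var_animal variance of the permanent animal effect
#'   (pings/day scale).
#' @param dispersion negative-binomial size parameter of daily counts
#'   (variance mu + mu^2/dispersion).
#' @param baseline_pings breed x sex x category mean table, see
#'   [default_baseline_pings()].
#' @param n_days_per_category named counts of days per heat-load
#'   category.
#' @param dropout probability that an animal has no usable records in a
#'   category (electronic-tag loss).
#' @param seed integer master seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_animals = 480, n_groups = 2, n_pens_per_group = 6,
                       breed_labels = c("Duroc", "Landrace", "Yorkshire"),
                       breed_props = c(0.19, 0.48, 0.33),
                       litter_size = 6, dams_per_sire = 4,
                       n_chromosomes = 5, chrom_length_mb = 20,
                       n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       n_qtl = 20,
                       target_h2 = 0.15, target_pair = "Normal-Emergency",
                       var_genetic = NULL, var_animal = 225,
                       dispersion = 20,
                       baseline_pings = default_baseline_pings(),
                       n_days_per_category = c(Normal = 60, Alert = 20,
                                               Danger = 12, Emergency = 8),
                       dropout = 0.10, seed = 1) {
  cfg <- list(n_animals = as.integer(n_animals), n_groups = as.integer(n_groups),
              n_pens_per_group = as.integer(n_pens_per_group),
              breed_labels = breed_labels, breed_props = breed_props,
              litter_size = as.integer(litter_size),
              dams_per_sire = as.integer(dams_per_sire),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_mb = chrom_length_mb,
              n_snps = as.integer(n_snps),
              maf_range = maf_range, n_qtl = as.integer(n_qtl),
              target_h2 = target_h2, target_pair = target_pair,
              var_genetic = var_genetic, var_animal = var_animal,
              dispersion = dispersion, baseline_pings = baseline_pings,
              n_days_per_category = n_days_per_category,
              dropout = dropout, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_animals < 0) stop_invalid("n_animals must be >= 0")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop_invalid("maf_range must lie within (0, 0.5]")
  if (!is.null(cfg$var_genetic) && cfg$var_genetic < 0)
    stop_invalid("var_genetic must be >= 0")
  if (cfg$var_animal < 0) stop_invalid("var_animal must be >= 0")
  if (cfg$dispersion <= 0) stop_invalid("dispersion must be > 0")
  if (cfg$n_qtl > cfg$n_snps) stop_invalid("n_qtl must be <= n_snps")
  if (any(cfg$baseline_pings$mean_pings <= 0))
    stop_invalid("baseline_pings must be strictly positive")
  if (length(cfg$breed_props) != length(cfg$breed_labels))
    stop_invalid("breed_props must match breed_labels")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop_invalid("dropout must lie in [0, 1)")
  invisible(cfg)
}

#' Weather profile for the simulator
#'
#' Daily mean and diurnal/seasonal amplitudes for temperature and
#' relative humidity. Temperature peaks mid-afternoon; humidity moves in
#' anti-phase. Gaussian noise is added hourly and RH is clamped to
#' \[0, 100\].
#'
#' @param t_mean,t_season_amp,t_diurnal_amp temperature profile (deg C).
#' @param rh_mean,rh_season_amp,rh_diurnal_amp humidity profile (pct).
#' @param t_sd,rh_sd hourly noise standard deviations.
#' @param season_period days per seasonal cycle.
#' @param start_date first calendar day.
#' @return list of class `weather_profile`.
#' @export
weather_profile <- function(t_mean = 20, t_season_amp = 0, t_diurnal_amp = 6,
                            rh_mean = 60, rh_season_amp = 0,
                            rh_diurnal_amp = 15,
                            t_sd = 1, rh_sd = 5,
                            season_period = 365, start_date = "2014-06-01") {
  structure(list(t_mean = t_mean, t_season_amp = t_season_amp,
                 t_diurnal_amp = t_diurnal_amp, rh_mean = rh_mean,
                 rh_season_amp = rh_season_amp,
                 rh_diurnal_amp = rh_diurnal_amp,
                 t_sd = t_sd, rh_sd = rh_sd,
                 season_period = season_period,
                 start_date = as.Date(start_date)),
            class = "weather_profile")
}

#' Simulate an hourly weather series
#'
#' 24 hourly records per day following the profile; deterministic for a
#' given seed.
#'
#' @param n_days number of days (>= 0).
#' @param profile a [weather_profile()].
#' @param seed integer seed.
#' @return data frame `timestamp` (POSIXct UTC), `temp_c`, `rh_pct`.
#' @export
simulate_weather <- function(n_days, profile = weather_profile(), seed = 1) {
  if (n_days < 0) stop_invalid("n_days must be >= 0")
  if (n_days == 0) {
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      temp_c = numeric(), rh_pct = numeric()))
  }
  with_seed(seed, {
    day <- rep(seq_len(n_days), each = 24)
    hour <- rep(0:23, times = n_days)
    season <- sin(2 * pi * (day - 1) / profile$season_period)
    diurnal <- sin(2 * pi * (hour - 9) / 24)  # peaks at 15:00
    temp <- profile$t_mean + profile$t_season_amp * season +
      profile$t_diurnal_amp * diurnal +
      stats::rnorm(length(day), 0, profile$t_sd)
    rh <- profile$rh_mean + profile$rh_season_amp * season -
      profile$rh_diurnal_amp * diurnal +
      stats::rnorm(length(day), 0, profile$rh_sd)
    rh <- pmin(100, pmax(0, rh))
    ts <- as.POSIXct(paste(profile$start_date + (day - 1),
                           sprintf("%02d:00:00", hour)), tz = "UTC")
    data.frame(timestamp = ts, temp_c = temp, rh_pct = rh)
  })
}

#' Simulate the population structure and pedigree
#'
#' Builds a two-generation pedigree: sires of the configured breeds
#' (allocated in `breed_props` proportions), composite-line dams, and
#' litters of full sibs nested in paternal half-sib families. Offspring
#' are assigned to grow-finish groups, pens (balanced round-robin within
#' group) and one of two farrowing groups per grow-finish group.
#'
#' @param cfg a [sim_config()].
#' @return list with `meta` (animal_id, sire_breed, sex,
#'   grow_finish_group, pen, farrowing_group) and `pedigree` (id, sire,
#'   dam; founders have NA parents).
#' @export
simulate_population <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_animals
  if (n == 0L) {
    return(list(meta = data.frame(animal_id = character(),
                                  sire_breed = character(), sex = character(),
                                  grow_finish_group = character(),
                                  pen = character(),
                                  farrowing_group = character()),
                pedigree = data.frame(id = character(), sire = character(),
                                      dam = character())))
  }
  with_seed(cfg$seed + 1L, {
    n_litters <- ceiling(n / cfg$litter_size)
    n_sires <- max(1L, ceiling(n_litters / cfg$dams_per_sire))
    # deterministic proportional allocation of sires to breeds
    counts <- floor(cfg$breed_props / sum(cfg$breed_props) * n_sires)
    rem <- n_sires - sum(counts)
    if (rem > 0) {
      frac <- cfg$breed_props / sum(cfg$breed_props) * n_sires - counts
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    sire_breed <- rep(cfg$breed_labels, times = counts)
    sire_ids <- sprintf("S%03d", seq_len(n_sires))
    dam_ids <- sprintf("D%04d", seq_len(n_litters))
    litter_sire <- rep(sire_ids, each = cfg$dams_per_sire)[seq_len(n_litters)]
    animal_litter <- rep(seq_len(n_litters),
                         each = cfg$litter_size)[seq_len(n)]
    ids <- sprintf("A%05d", seq_len(n))
    sex <- sample(c("barrow", "gilt"), n, replace = TRUE)

    litters_per_group <- ceiling(n_litters / cfg$n_groups)
    litter_group <- ((seq_len(n_litters) - 1L) %/% litters_per_group) + 1L
    litter_group <- pmin(litter_group, cfg$n_groups)
    litter_fg <- ((seq_len(n_litters) - 1L) %% 2L) + 1L  # two per group
    group <- litter_group[animal_litter]
    fg <- sprintf("G%d_F%d", group, litter_fg[animal_litter])

    pen <- character(n)
    for (g in unique(group)) {
      members <- which(group == g)
      shuffled <- sample(members)
      pen_no <- rep(seq_len(cfg$n_pens_per_group),
                    length.out = length(members))
      pen[shuffled] <- sprintf("G%d_P%d", g, pen_no)
    }

    meta <- data.frame(
      animal_id = ids,
      sire_breed = sire_breed[match(litter_sire[animal_litter], sire_ids)],
      sex = sex,
      grow_finish_group = sprintf("G%d", group),
      pen = pen,
      farrowing_group = fg,
      stringsAsFactors = FALSE
    )
    pedigree <- rbind(
      data.frame(id = sire_ids, sire = NA_character_, dam = NA_character_,
                 stringsAsFactors = FALSE),
      data.frame(id = dam_ids, sire = NA_character_, dam = NA_character_,
                 stringsAsFactors = FALSE),
      data.frame(id = ids, sire = litter_sire[animal_litter],
                 dam = dam_ids[animal_litter], stringsAsFactors = FALSE)
    )
    list(meta = meta, pedigree = pedigree)
  })
}

#' Simulate genotypes by gene drop through the pedigree
#'
#' Founder allele frequencies are drawn uniformly from `maf_range`;
#' founder haplotypes are Bernoulli draws and offspring receive one
#' randomly chosen allele per marker from each parent (independent
#' Mendelian sampling; no linkage). Dosages are 0/1/2. The map places
#' contiguous marker blocks on each chromosome with unique, sorted
#' base-pair positions.
#'
#' @param pedigree pedigree from [simulate_population()].
#' @param cfg a [sim_config()].
#' @return list `G` (offspring dosage matrix with animal row names),
#'   `map` (`marker_id`, `chromosome`, `position_bp`), `allele_freq`
#'   (founder frequencies).
#' @export
simulate_genotypes <- function(pedigree, cfg) {
  validate_sim_config(cfg)
  m <- cfg$n_snps
  if (m < cfg$n_chromosomes)
    stop_invalid("n_snps must be >= n_chromosomes")
  with_seed(cfg$seed + 2L, {
    founders <- pedigree$id[is.na(pedigree$sire)]
    kids <- pedigree$id[!is.na(pedigree$sire)]
    p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    nf <- length(founders)
    H1 <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m,
                 dimnames = list(founders, NULL))
    H2 <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)), nf, m,
                 dimnames = list(founders, NULL))
    si <- match(pedigree$sire[match(kids, pedigree$id)], founders)
    di <- match(pedigree$dam[match(kids, pedigree$id)], founders)
    nk <- length(kids)
    pick_s <- matrix(stats::rbinom(nk * m, 1L, 0.5), nk, m)
    pick_d <- matrix(stats::rbinom(nk * m, 1L, 0.5), nk, m)
    Hs <- H1[si, , drop = FALSE] * pick_s +
      H2[si, , drop = FALSE] * (1L - pick_s)
    Hd <- H1[di, , drop = FALSE] * pick_d +
      H2[di, , drop = FALSE] * (1L - pick_d)
    G <- Hs + Hd
    rownames(G) <- kids

    chrom_sizes <- diff(floor(seq(0, m, length.out = cfg$n_chromosomes + 1)))
    chrom <- rep(as.character(seq_len(cfg$n_chromosomes)),
                 times = chrom_sizes)
    pos <- unlist(lapply(chrom_sizes, function(sz) {
      sort(sample.int(cfg$chrom_length_mb * 1e6, sz))
    }))
    marker_id <- sprintf("M%05d", seq_len(m))
    colnames(G) <- marker_id
    map <- data.frame(marker_id = marker_id, chromosome = chrom,
                      position_bp = pos, stringsAsFactors = FALSE)
    list(G = G, map = map, allele_freq = p)
  })
}

# Linear contrast of the ordered heat-load categories: the genetic
# heat-response value enters the daily mean as g * contrast(category).
category_contrast <- function(category) {
  as.numeric(factor(as.character(category), levels = thi_categories())) - 1
}

#' Calibrate the genetic variance to a target trait heritability
#'
#' Closed-form approximation of the heritability of a pairwise-THI
#' trait under the generative model (permanent animal effect + genetic
#' value x category contrast + negative-binomial day noise averaged over
#' the category's days, standardized within category), solved for the
#' genetic variance by root finding.
#'
#' @param cfg a [sim_config()].
#' @param target_h2 desired heritability; default `cfg$target_h2`.
#' @param pair pairwise trait name; default `cfg$target_pair`.
#' @return the calibrated genetic variance (scalar).
#' @export
calibrate_var_genetic <- function(cfg, target_h2 = cfg$target_h2,
                                  pair = cfg$target_pair) {
  cats <- strsplit(pair, "-", fixed = TRUE)[[1]]
  if (length(cats) != 2L || !all(cats %in% thi_categories()))
    stop_invalid("pair must name two THI categories, e.g. 'Normal-Emergency'")
  x <- category_contrast(cats)
  mu <- vapply(cats, function(cc) {
    mean(cfg$baseline_pings$mean_pings[cfg$baseline_pings$category == cc])
  }, numeric(1))
  nd <- cfg$n_days_per_category[cats]
  v <- (mu + mu^2 / cfg$dispersion) / nd  # var of the category day-mean
  h2_of <- function(vg) {
    s2 <- cfg$var_animal + vg * x^2 + v
    s <- sqrt(s2)
    b <- x[1] / s[1] - x[2] / s[2]
    gen <- b^2 * vg
    tot <- cfg$var_animal * (1 / s[1] - 1 / s[2])^2 + gen +
      v[1] / s2[1] + v[2] / s2[2]
    gen / tot
  }
  if (target_h2 <= 0) return(0)
  hi <- 1e6
  if (h2_of(hi) < target_h2)
    stop_invalid("target_h2 = ", target_h2, " is unattainable for trait ",
                 pair, " under this configuration")
  stats::uniroot(function(vg) h2_of(vg) - target_h2,
                 lower = 1e-10, upper = hi, tol = 1e-10)$root
}

#' Plant QTL and simulate daily RFID ping counts
#'
#' Chooses `n_qtl` markers, gives them additive effects scaled so the
#' genetic heat-response value g has the configured variance, draws a
#' permanent animal effect, and simulates each animal-day count as
#' NegativeBinomial with mean
#' `baseline(breed, sex, category) + permanent + g * contrast(category)`
#' (clamped at a small positive floor when effects drive it negative,
#' with a message). Animals lose whole categories at the configured
#' dropout rate, mimicking tag loss.
#'
#' @param geno output of [simulate_genotypes()].
#' @param meta metadata from [simulate_population()].
#' @param day_classes day classification covering at least two
#'   categories (e.g. [make_day_classes()] or [classify_days()]).
#' @param cfg a [sim_config()].
#' @return list with `pings` (animal_id, date, pings) and `truth`
#'   (class `truth_set`): `qtl_ids`, `qtl_effects`, `genetic_values`,
#'   `var_genetic`, `target_h2`, `realized_h2` (squared correlation of
#'   each derived pairwise trait with the true genetic value).
#' @export
plant_qtl_and_simulate_pings <- function(geno, meta, day_classes, cfg) {
  validate_sim_config(cfg)
  cats_present <- unique(as.character(day_classes$category))
  if (length(cats_present) < 2L)
    stop_invalid("day_classes must cover at least two THI categories")
  vg <- cfg$var_genetic %||% calibrate_var_genetic(cfg)
  with_seed(cfg$seed + 3L, {
    G <- geno$G[meta$animal_id, , drop = FALSE]
    n <- nrow(G)
    qtl_idx <- sort(sample.int(ncol(G), cfg$n_qtl))
    a <- stats::rnorm(cfg$n_qtl)
    g_raw <- as.numeric(G[, qtl_idx, drop = FALSE] %*% a)
    vr <- stats::var(g_raw)
    scale <- if (vg > 0 && vr > 0) sqrt(vg / vr) else 0
    a <- a * scale
    g <- (g_raw - mean(g_raw)) * scale
    perm <- stats::rnorm(n, 0, sqrt(cfg$var_animal))

    keep <- matrix(stats::rbinom(n * 4L, 1L, 1 - cfg$dropout) == 1L,
                   n, 4L, dimnames = list(meta$animal_id, thi_categories()))
    base_key <- paste(cfg$baseline_pings$sire_breed,
                      cfg$baseline_pings$sex, cfg$baseline_pings$category)

    day_cat <- as.character(day_classes$category)
    cat_idx <- match(day_cat, thi_categories())
    nd <- nrow(day_classes)
    ai <- rep(seq_len(n), each = nd)
    di <- rep(seq_len(nd), times = n)
    use <- keep[cbind(ai, cat_idx[di])]
    ai <- ai[use]; di <- di[use]
    mu_base <- cfg$baseline_pings$mean_pings[
      match(paste(meta$sire_breed[ai], meta$sex[ai], day_cat[di]), base_key)]
    if (anyNA(mu_base))
      stop_invalid("baseline_pings is missing breed x sex x category cells")
    mu <- mu_base + perm[ai] + g[ai] * (cat_idx[di] - 1)
    n_clamped <- sum(mu < 0.1)
    if (n_clamped > 0)
      message("plant_qtl_and_simulate_pings: clamped ", n_clamped,
              " negative daily mean(s) at 0.1")
    mu <- pmax(mu, 0.1)
    pings <- stats::rnbinom(length(mu), size = cfg$dispersion, mu = mu)
    ping_df <- data.frame(animal_id = meta$animal_id[ai],
                          date = day_classes$date[di],
                          pings = as.integer(pings),
                          stringsAsFactors = FALSE)
    ping_df <- ping_df[order(ping_df$animal_id, ping_df$date), , drop = FALSE]
    rownames(ping_df) <- NULL

    realized <- realized_h2(ping_df, day_classes, meta, g)
    truth <- structure(
      list(qtl_ids = colnames(G)[qtl_idx], qtl_effects = a,
           genetic_values = stats::setNames(g, meta$animal_id),
           var_genetic = vg, target_h2 = cfg$target_h2,
           realized_h2 = realized),
      class = "truth_set")
    list(pings = ping_df, truth = truth)
  })
}

# Squared correlation of each derived pairwise trait with the true
# genetic values; 0 when there is no genetic variance.
realized_h2 <- function(pings, day_classes, meta, g) {
  out <- stats::setNames(rep(NA_real_, 6), pairwise_trait_names())
  if (stats::var(g) == 0) {
    out[] <- 0
    return(out)
  }
  prof <- category_profile(daily_counts(pings), day_classes)
  z <- standardize_deviations(prof, meta)
  traits <- pairwise_traits(z)
  gt <- g[match(traits$animal_id, meta$animal_id)]
  for (tr in pairwise_trait_names()) {
    if (!tr %in% names(traits)) next
    ok <- !is.na(traits[[tr]])
    if (sum(ok) >= 3L && stats::var(traits[[tr]][ok]) > 0)
      out[tr] <- stats::cor(traits[[tr]][ok], gt[ok])^2
  }
  out
}

#' Synthetic calendar with fixed category day counts
#'
#' Sequential dates assigned to the four heat-load categories with the
#' requested counts; the representative maximum THI of each category is
#' a mid-interval value.
#'
#' @param n_days_per_category named counts (names in
#'   [thi_categories()]).
#' @param start_date first day.
#' @return data frame like [classify_days()] output.
#' @export
make_day_classes <- function(n_days_per_category = c(Normal = 60, Alert = 20,
                                                     Danger = 12,
                                                     Emergency = 8),
                             start_date = "2014-06-01") {
  cats <- thi_categories()
  counts <- n_days_per_category[cats]
  counts[is.na(counts)] <- 0
  rep_thi <- c(Normal = 20, Alert = 24.5, Danger = 27.5, Emergency = 30.5)
  category <- rep(cats, times = counts)
  data.frame(
    date = as.Date(start_date) + seq_along(category) - 1,
    max_thi_c = unname(rep_thi[category]),
    category = factor(category, levels = cats, ordered = TRUE)
  )
}

#' Simulate a complete study
#'
#' Runs population, genotype and ping simulation under one
#' configuration. By default the heat-load calendar has exactly the
#' configured number of days per category; with `use_weather = TRUE` a
#' seasonal hourly weather series is simulated and classified instead,
#' so the classifier is exercised end-to-end.
#'
#' @param cfg a [sim_config()].
#' @param use_weather simulate and classify an hourly weather series
#'   instead of the fixed calendar.
#' @return list with `config`, `meta`, `pedigree`, `G`, `map`,
#'   `allele_freq`, `day_classes`, `pings`, `truth`, and `weather` when
#'   simulated.
#' @export
simulate_study <- function(cfg = sim_config(), use_weather = FALSE) {
  pop <- simulate_population(cfg)
  geno <- simulate_genotypes(pop$pedigree, cfg)
  weather <- NULL
  if (use_weather) {
    total <- sum(cfg$n_days_per_category)
    # one full warm-cold cycle so every heat-load category occurs
    profile <- weather_profile(t_mean = 25, t_season_amp = 9,
                               t_diurnal_amp = 5, rh_mean = 60,
                               rh_season_amp = -10, rh_diurnal_amp = 15,
                               season_period = total)
    weather <- simulate_weather(total, profile, seed = cfg$seed + 4L)
    days <- classify_days(weather)
  } else {
    days <- make_day_classes(cfg$n_days_per_category)
  }
  sim <- plant_qtl_and_simulate_pings(geno, pop$meta, days, cfg)
  out <- list(config = cfg, meta = pop$meta, pedigree = pop$pedigree,
              G = geno$G, map = geno$map, allele_freq = geno$allele_freq,
              day_classes = days, pings = sim$pings, truth = sim$truth)
  if (!is.null(weather)) out$weather <- weather
  out
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Simulation truth set\n")
  cat(sprintf("  %d QTL, genetic variance %.3f (target h2 %s)\n",
              length(x$qtl_ids), x$var_genetic,
              format(x$target_h2 %||% NA)))
  cat("  realized h2 per pairwise trait:\n")
  print(round(x$realized_h2, 3))
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Writes pings, metadata, day classes, dosage and map TSVs, PLINK
#' .ped/.map, the truth table, and the weather series when present.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$pings, file.path(dir, "pings.tsv"))
  write_tsv(sim$meta, file.path(dir, "meta.tsv"))
  write_day_classes(sim$day_classes, file.path(dir, "days.tsv"))
  write_dosage(sim$G, file.path(dir, "genotypes.tsv"))
  write_tsv(sim$map, file.path(dir, "map.tsv"))
  write_plink(sim$G, sim$map, file.path(dir, "genotypes"))
  truth_df <- data.frame(marker_id = sim$truth$qtl_ids,
                         effect = sim$truth$qtl_effects)
  write_tsv(truth_df, file.path(dir, "truth_qtl.tsv"))
  write_tsv(data.frame(animal_id = names(sim$truth$genetic_values),
                       genetic_value = sim$truth$genetic_values),
            file.path(dir, "truth_genetic_values.tsv"))
  if (!is.null(sim$weather)) {
    w <- sim$weather
    w$timestamp <- format(w$timestamp, "%Y-%m-%dT%H:%M:%SZ")
    write_tsv(w, file.path(dir, "weather.tsv"))
  }
  invisible(dir)
}
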