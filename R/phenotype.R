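# Feeding-behaviour phenotypes: daily RFID ping counts -> per-category
# means -> standardized breed-sex deviations -> pairwise-THI traits.

MAX_PINGS_PER_DAY <- 4320L  # 86,400 s / 20 s detection interval

#' The six pairwise THI trait names
#'
#' Ordered pairs (cooler, hotter) of the four heat-load categories; each
#' trait is the standardized feeding deviation in the cooler category
#' minus that in the hotter one.
#'
#' @return character vector of length 6, e.g. `"Normal-Alert"`.
#' @export
pairwise_trait_names <- function() {
  cats <- thi_categories()
  pairs <- utils::combn(cats, 2)
  paste(pairs[1, ], pairs[2, ], sep = "-")
}

#' Daily RFID ping counts per animal
#'
#' Accepts either pre-aggregated counts (columns `animal_id`, `date`,
#' `pings`), which are validated and passed through, or raw 20-second
#' feeder detections (columns `animal_id`, `timestamp`), which are
#' deduplicated on (animal, timestamp) and counted per animal-day.
#'
#' @param x data frame of counts or raw detections.
#' @param roster optional data frame (`animal_id`, `date`) of animal-days
#'   that must appear in the output; animal-days in the roster with no
#'   detections get a count of 0.
#' @return data frame `animal_id`, `date` (Date), `pings` (integer).
#' @export
daily_counts <- function(x, roster = NULL) {
  if ("pings" %in% names(x)) {
    need <- c("animal_id", "date", "pings")
    if (!all(need %in% names(x)))
      stop_invalid("counts need columns: ", paste(need, collapse = ", "))
    out <- data.frame(animal_id = as.character(x$animal_id),
                      date = as.Date(x$date),
                      pings = as.integer(x$pings))
  } else {
    need <- c("animal_id", "timestamp")
    if (!all(need %in% names(x)))
      stop_invalid("detections need columns: ", paste(need, collapse = ", "))
    ts <- x$timestamp
    if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
    key <- paste(x$animal_id, format(ts, "%Y-%m-%d %H:%M:%S"))
    dup <- duplicated(key)
    if (any(dup))
      message("daily_counts: removed ", sum(dup),
              " duplicate (animal, timestamp) detection(s)")
    id <- as.character(x$animal_id)[!dup]
    date <- as.Date(ts[!dup], tz = "UTC")
    agg <- aggregate(list(pings = rep(1L, length(id))),
                     by = list(animal_id = id, date = date), FUN = sum)
    out <- agg[order(agg$animal_id, agg$date), , drop = FALSE]
  }
  if (!is.null(roster)) {
    ros <- data.frame(animal_id = as.character(roster$animal_id),
                      date = as.Date(roster$date))
    key_out <- paste(out$animal_id, out$date)
    key_ros <- paste(ros$animal_id, ros$date)
    miss <- !(key_ros %in% key_out)
    if (any(miss)) {
      out <- rbind(out, data.frame(animal_id = ros$animal_id[miss],
                                   date = ros$date[miss], pings = 0L))
      out <- out[order(out$animal_id, out$date), , drop = FALSE]
    }
  }
  if (any(out$pings < 0L))
    stop_invalid("negative ping counts")
  if (any(out$pings > MAX_PINGS_PER_DAY))
    stop_invalid("ping counts exceed the physical maximum of ",
                 MAX_PINGS_PER_DAY, " per day")
  rownames(out) <- NULL
  out
}

#' Per-animal per-category feeding profile
#'
#' Mean daily ping count of each animal within each THI category it
#' experienced, with the number of contributing days.
#'
#' @param pings daily counts from [daily_counts()].
#' @param days day classification from [classify_days()].
#' @return data frame `animal_id`, `category`, `mean_pings`, `n_days`.
#' @export
category_profile <- function(pings, days) {
  idx <- match(pings$date, days$date)
  if (anyNA(idx)) {
    bad <- sort(unique(pings$date[is.na(idx)]))
    stop_invalid("ping dates absent from the day classification: ",
                 paste(bad, collapse = ", "))
  }
  cat <- days$category[idx]
  agg <- aggregate(list(mean_pings = pings$pings),
                   by = list(animal_id = pings$animal_id, category = cat),
                   FUN = mean)
  n <- aggregate(list(n_days = pings$pings),
                 by = list(animal_id = pings$animal_id, category = cat),
                 FUN = length)
  out <- merge(agg, n, by = c("animal_id", "category"))
  out$category <- factor(as.character(out$category),
                         levels = thi_categories(), ordered = TRUE)
  out <- out[order(out$animal_id, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardized breed-sex feeding deviations per THI category
#'
#' Within each THI category, each animal's mean daily ping count is
#' expressed as a deviation from the mean of animals of the same sire
#' breed and sex with data in that category, then the deviations are
#' scaled to standard deviation 1 (sample SD, n - 1) across all animals
#' in the category. The resulting z-values have mean 0 and SD 1 within
#' every category.
#'
#' @param profile output of [category_profile()].
#' @param meta animal metadata with `animal_id`, `sire_breed`, `sex`.
#' @return data frame `animal_id`, `category`, `z`.
#' @export
standardize_deviations <- function(profile, meta) {
  need <- c("animal_id", "sire_breed", "sex")
  if (!all(need %in% names(meta)))
    stop_invalid("meta needs columns: ", paste(need, collapse = ", "))
  m <- match(profile$animal_id, meta$animal_id)
  if (anyNA(m))
    stop_invalid("animals missing from metadata: ",
                 paste(unique(profile$animal_id[is.na(m)]), collapse = ", "))
  breed_sex <- paste(meta$sire_breed[m], meta$sex[m], sep = ":")
  out_list <- lapply(split(seq_len(nrow(profile)), profile$category,
                           drop = TRUE), function(rows) {
    if (length(rows) < 2L)
      stop_invalid("fewer than 2 animals with data in category ",
                   as.character(profile$category[rows[1]]))
    mp <- profile$mean_pings[rows]
    cell <- breed_sex[rows]
    dev <- mp - ave(mp, cell, FUN = mean)
    s <- stats::sd(dev)
    if (!is.finite(s) || s == 0)
      stop_invalid("degenerate category ",
                   as.character(profile$category[rows[1]]),
                   ": zero variance of breed-sex deviations")
    data.frame(animal_id = profile$animal_id[rows],
               category = profile$category[rows],
               z = dev / s)
  })
  out <- do.call(rbind, out_list)
  out <- out[order(out$animal_id, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise-THI feeding-behaviour traits
#'
#' For each ordered pair of heat-load categories (cooler, hotter), the
#' trait is z(cooler) - z(hotter); a positive value means the animal
#' reduced its relative feeding activity more than its breed-sex
#' contemporaries as heat load rose. A trait is emitted only for animals
#' with data in both categories; animals that experienced a single
#' category are excluded entirely.
#'
#' @param z standardized deviations from [standardize_deviations()].
#' @return data frame with `animal_id` and one column per pairwise trait
#'   (NA where a category was not experienced); the per-category
#'   z-values are attached as attribute `"z"`.
#' @export
pairwise_traits <- function(z) {
  cats <- thi_categories()
  wide <- matrix(NA_real_, nrow = length(unique(z$animal_id)),
                 ncol = length(cats),
                 dimnames = list(sort(unique(z$animal_id)), cats))
  wide[cbind(match(z$animal_id, rownames(wide)),
             match(as.character(z$category), cats))] <- z$z
  n_cat <- rowSums(!is.na(wide))
  wide <- wide[n_cat >= 2L, , drop = FALSE]
  if (nrow(wide) == 0L) {
    out <- data.frame(animal_id = character(),
                      matrix(numeric(), 0, 6,
                             dimnames = list(NULL, pairwise_trait_names())),
                      check.names = FALSE)
    attr(out, "z") <- wide
    return(out)
  }
  pairs <- utils::combn(cats, 2)
  traits <- sapply(seq_len(ncol(pairs)), function(j) {
    wide[, pairs[1, j]] - wide[, pairs[2, j]]
  })
  if (is.null(dim(traits))) traits <- matrix(traits, nrow = nrow(wide))
  colnames(traits) <- pairwise_trait_names()
  out <- data.frame(animal_id = rownames(wide), traits,
                    check.names = FALSE, row.names = NULL)
  attr(out, "z") <- wide
  out
}

#' Correlations among the six pairwise-THI traits
#'
#' Pearson correlations on pairwise-complete observations; entries with
#' fewer than `min_n` complete pairs are set to NA.
#'
#' @param traits output of [pairwise_traits()].
#' @param min_n minimum complete pairs for an entry to be reported.
#' @return symmetric 6 x 6 correlation matrix with unit diagonal; the
#'   pairwise sample sizes are attached as attribute `"n"`.
#' @export
trait_correlations <- function(traits, min_n = 3L) {
  m <- as.matrix(traits[, pairwise_trait_names(), drop = FALSE])
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(m))
  r[n < min_n] <- NA_real_
  diag(r) <- ifelse(diag(n) >= 1L, 1, NA_real_)
  attr(r, "n") <- n
  r
}

#' Read / write helpers for phenotype tables
#'
#' `read_pings()` expects `animal_id`, `date`, `pings`; `read_meta()`
#' expects at least `animal_id`, `sire_breed`, `sex` (plus
#' `grow_finish_group`, `pen`, `farrowing_group` for GWAS designs).
#' `write_traits()` writes the pairwise trait table with NA for missing.
#'
#' @param path file path.
#' @name phenotype-io
#' @export
read_pings <- function(path) {
  p <- read_tsv(path)
  daily_counts(p)
}

#' @rdname phenotype-io
#' @export
read_meta <- function(path) {
  m <- read_tsv(path)
  m$animal_id <- as.character(m$animal_id)
  m
}

#' @rdname phenotype-io
#' @param traits trait table from [pairwise_traits()].
#' @export
write_traits <- function(traits, path) {
  write_tsv(traits, path)
}

#' @rdname phenotype-io
#' @export
read_traits <- function(path) {
  t <- read_tsv(path)
  t$animal_id <- as.character(t$animal_id)
  t
}
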