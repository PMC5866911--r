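# Genotype quality control: minor-allele-frequency and map-position
# filters, plus the mean-dosage fill for residual missing genotypes.
# Dosage matrices are numeric matrices (animals x markers) with dimnames.

#' Minor allele frequencies of a dosage matrix
#'
#' @param G animals x markers dosage matrix (values 0/1/2, NA missing).
#' @return named numeric vector of MAFs; NaN for all-missing markers.
#' @export
compute_maf <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Minor allele frequency filter
#'
#' Removes markers whose MAF (computed from non-missing dosages) is
#' strictly below the threshold; markers exactly at the threshold are
#' kept. Markers with all genotypes missing are removed and reported
#' separately.
#'
#' @param G animals x markers dosage matrix with marker column names.
#' @param threshold MAF below which a marker is removed (default 0.05).
#' @return list with `kept` (marker ids) and `report` (data frame
#'   `marker_id`, `maf`, `status` in kept/low_maf/all_missing).
#' @export
maf_filter <- function(G, threshold = 0.05) {
  maf <- compute_maf(G)
  status <- ifelse(is.nan(maf), "all_missing",
                   ifelse(maf < threshold, "low_maf", "kept"))
  report <- data.frame(marker_id = colnames(G), maf = unname(maf),
                       status = unname(status), stringsAsFactors = FALSE)
  list(kept = colnames(G)[status == "kept"], report = report)
}

#' Unique-map-position filter
#'
#' Removes markers with an unknown position and every marker that shares
#' a (chromosome, position) with another marker: a unique map position is
#' a property of the marker, so all colliding markers are dropped rather
#' than keeping the first.
#'
#' @param map data frame `marker_id`, `chromosome`, `position_bp`.
#' @return list with `kept` (marker ids) and `report` (`marker_id`,
#'   `status` in kept/no_position/duplicate_position).
#' @export
map_filter <- function(map) {
  no_pos <- is.na(map$position_bp) | is.na(map$chromosome)
  key <- paste(map$chromosome, map$position_bp)
  dup_key <- key %in% key[duplicated(key)]
  status <- ifelse(no_pos, "no_position",
                   ifelse(dup_key, "duplicate_position", "kept"))
  report <- data.frame(marker_id = map$marker_id, status = status,
                       stringsAsFactors = FALSE)
  list(kept = map$marker_id[status == "kept"], report = report)
}

#' Mean-dosage fill for missing genotypes
#'
#' Replaces each missing dosage by the marker's mean dosage over
#' non-missing animals (a continuous value), preserving column means.
#' This is deliberately simple plumbing; markers with all genotypes
#' missing must have been removed beforehand.
#'
#' @param G animals x markers dosage matrix.
#' @return the matrix with no missing values.
#' @export
fill_missing <- function(G) {
  if (!anyNA(G)) return(G)
  mu <- colMeans(G, na.rm = TRUE)
  if (any(is.nan(mu)))
    stop_invalid("all-missing markers present; run maf_filter first")
  idx <- which(is.na(G), arr.ind = TRUE)
  G[idx] <- mu[idx[, 2]]
  G
}

#' Full genotype quality control
#'
#' Applies the unique-map-position filter, then the MAF filter, subsets
#' both the matrix and the map to the surviving markers, and fills the
#' remaining missing dosages by marker means.
#'
#' @param G animals x markers dosage matrix.
#' @param map marker map aligned to `colnames(G)`.
#' @param maf_threshold MAF removal threshold (default 0.05).
#' @return list `G` (complete, filtered), `map` (filtered), `report`
#'   (per-marker status from both filters).
#' @export
qc_genotypes <- function(G, map, maf_threshold = 0.05) {
  if (!identical(colnames(G), map$marker_id))
    map <- map[match(colnames(G), map$marker_id), , drop = FALSE]
  if (anyNA(map$marker_id))
    stop_invalid("markers in G missing from the map")
  mp <- map_filter(map)
  G1 <- G[, mp$kept, drop = FALSE]
  mf <- maf_filter(G1, maf_threshold)
  keep <- mf$kept
  report <- merge(mp$report, mf$report, by = "marker_id", all.x = TRUE,
                  suffixes = c("_map", "_maf"))
  report <- report[match(map$marker_id, report$marker_id), , drop = FALSE]
  rownames(report) <- NULL
  list(G = fill_missing(G1[, keep, drop = FALSE]),
       map = map[match(keep, map$marker_id), , drop = FALSE],
       report = report)
}

#' Read / write dosage matrices and marker maps
#'
#' The dosage TSV has a header of marker ids and an `animal_id` first
#' column; the map TSV has `marker_id`, `chromosome`, `position_bp`.
#'
#' @param path file path.
#' @name genoqc-io
#' @export
read_dosage <- function(path) {
  d <- read_tsv(path)
  ids <- as.character(d[[1]])
  G <- as.matrix(d[, -1, drop = FALSE])
  mode(G) <- "numeric"
  rownames(G) <- ids
  G
}

#' @rdname genoqc-io
#' @param G dosage matrix.
#' @export
write_dosage <- function(G, path) {
  df <- data.frame(animal_id = rownames(G), G, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname genoqc-io
#' @export
read_marker_map <- function(path) {
  m <- read_tsv(path)
  need <- c("marker_id", "chromosome", "position_bp")
  if (!all(need %in% names(m)))
    stop_invalid("map needs columns: ", paste(need, collapse = ", "))
  m$marker_id <- as.character(m$marker_id)
  m$chromosome <- as.character(m$chromosome)
  m
}

#' Read PLINK .ped/.map genotypes
#'
#' Whitespace-delimited PLINK text files with A/C/G/T alleles and 0 for
#' missing. Dosage is the count of the marker's minor allele (the less
#' frequent of the two observed alleles; ties broken alphabetically), so
#' an allele-label swap flips dosages x -> 2 - x but not MAFs.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file (chrom, marker id, cM, bp).
#' @return list `G` (dosage matrix, NA for missing) and `map`
#'   (`marker_id`, `chromosome`, `position_bp`).
#' @export
read_plink <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               stringsAsFactors = FALSE)
  map <- data.frame(marker_id = as.character(map_raw[[2]]),
                    chromosome = as.character(map_raw[[1]]),
                    position_bp = as.integer(map_raw[[4]]),
                    stringsAsFactors = FALSE)
  ped <- utils::read.table(ped_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop_invalid(".ped has ", ncol(ped), " columns; expected ",
                 6 + 2 * m, " for ", m, " markers")
  ids <- ped[[2]]
  G <- matrix(NA_real_, nrow = nrow(ped), ncol = m,
              dimnames = list(ids, map$marker_id))
  for (j in seq_len(m)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- c(a1[!miss], a2[!miss])
    if (length(alleles) == 0L) next
    tab <- sort(table(alleles), decreasing = TRUE)
    lv <- names(tab)
    minor <- if (length(lv) == 1L) NA_character_
             else if (tab[1] == tab[2]) sort(lv[1:2])[2] else lv[2]
    if (is.na(minor)) {
      G[!miss, j] <- 0
    } else {
      G[!miss, j] <- (a1[!miss] == minor) + (a2[!miss] == minor)
    }
  }
  list(G = G, map = map)
}

#' Write genotypes as PLINK .ped/.map
#'
#' Dosages are encoded with alleles A (reference) and B written as "G";
#' missing dosages become "0 0". Intended for round-tripping simulated
#' data through PLINK-format tooling.
#'
#' @param G dosage matrix (0/1/2/NA).
#' @param map marker map aligned to `colnames(G)`.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @export
write_plink <- function(G, map, prefix) {
  map_out <- data.frame(map$chromosome, map$marker_id, 0, map$position_bp)
  utils::write.table(map_out, paste0(prefix, ".map"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  allele_pairs <- function(d) {
    if (is.na(d)) return(c("0", "0"))
    switch(as.character(d), "0" = c("A", "A"), "1" = c("A", "G"),
           "2" = c("G", "G"),
           stop_invalid("write_plink needs integer dosages 0/1/2"))
  }
  rows <- vapply(seq_len(nrow(G)), function(i) {
    al <- unlist(lapply(G[i, ], allele_pairs))
    paste(c("FAM", rownames(G)[i], "0", "0", "0", "-9", al), collapse = " ")
  }, character(1))
  writeLines(rows, paste0(prefix, ".ped"))
  invisible(prefix)
}
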